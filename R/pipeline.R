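# End-to-end per-session driver: staging -> detection -> coupling, with an
# optional population stage (reactivation + CCA) when spikes and trials are
# provided. Pure function of (inputs, config, seed); results and a
# provenance record are written to disk when an output directory is given.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the per-session analysis pipeline
#'
#' @param session list with elements `manifest` (a `session_manifest`),
#'   `pre` and `post` (each a list with either `recordings` — named list of
#'   `recording`s for PFC/M1/HPC — or precomputed `nrems` + `events`),
#'   optionally `spikes` (`spike_train_set`, M1), `sleep_spikes`
#'   (post-sleep `spike_train_set`), `trials` (`trial_table`) and
#'   `swr_channels`.
#' @param config configuration from [default_config()].
#' @param seed integer seed controlling every randomized stage.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return list: per-block `nrems` and `events`, `coupling` (data.frame of
#'   summaries), optional `population` results, and `provenance`.
#' @export
run_session <- function(session, config = default_config(), seed = 1,
                        out_dir = NULL) {
  blocks <- list()
  for (b in c("pre", "post")) {
    blk <- session[[b]]
    if (is.null(blk)) next
    if (!is.null(blk$recordings)) {
      st <- with_stage(paste0("staging/", b), {
        s <- stage_sleep(blk$recordings$M1, config$staging, seed)
        if (nrow(s$intervals) == 0L) stop("no NREMS available")
        s
      })
      det <- with_stage(paste0("detection/", b),
        detect_oscillations(blk$recordings, st$intervals,
                            swr_channels = session$swr_channels %||% 1:3,
                            config = config$detection))
      blocks[[b]] <- list(nrems = st$intervals, detections = det,
                          events = list(
                            pfc_so_up = det$so_pfc$t_peak,
                            m1_so_up = det$so_m1$t_peak,
                            swr_peak = det$swr$t_peak,
                            swr_onset = det$swr$t_onset,
                            spindle_peak = c(det$spindle_m1$t_peak)))
    } else {
      if (is.null(blk$nrems) || nrow(blk$nrems) == 0L)
        stop(sprintf("[staging/%s] no NREMS available", b))
      ev <- blk$events
      if (is.null(ev$swr_onset)) ev$swr_onset <- ev$swr_peak
      blocks[[b]] <- list(nrems = blk$nrems, events = ev)
    }
  }
  if (length(blocks) == 0L) stop("[input] session has no sleep blocks")

  couple_block <- function(bl) {
    ev <- bl$events
    so_swr <- with_stage("coupling", so_swr_coupling(ev$m1_so_up, ev$swr_peak,
                                                     config$coupling$so_swr_window))
    pm <- pfc_m1_so_coupling(ev$pfc_so_up, ev$m1_so_up,
                             config$coupling$pfc_m1_window)
    sp <- if (length(ev$spindle_peak))
      so_spindle_coupling(ev$m1_so_up, ev$spindle_peak,
                          config$coupling$so_spindle_window)
    else list(value = NA_real_, n = 0L)
    list(so_swr = so_swr, pfc_m1 = pm, so_spindle = sp)
  }
  cpl <- lapply(blocks, couple_block)
  rows <- NULL
  for (b in names(cpl)) for (m in names(cpl[[b]])) {
    sm <- cpl[[b]][[m]]
    win <- if (!is.null(sm$window)) sm$window else c(NA_real_, NA_real_)
    rows <- rbind(rows, data.frame(block = b, metric = m, value = sm$value,
                                   n = sm$n, window_lo = win[1],
                                   window_hi = win[2]))
  }
  if (all(c("pre", "post") %in% names(cpl)) &&
      !is.na(cpl$post$so_swr$value) && !is.na(cpl$pre$so_swr$value))
    rows <- rbind(rows, data.frame(
      block = "delta", metric = "so_swr",
      value = delta_coupling(cpl$post$so_swr, cpl$pre$so_swr),
      n = cpl$post$so_swr$n,
      window_lo = config$coupling$so_swr_window[1],
      window_hi = config$coupling$so_swr_window[2]))

  population <- NULL
  if (!is.null(session$spikes) && !is.null(session$trials) &&
      !is.null(session$sleep_spikes) && "post" %in% names(blocks)) {
    population <- with_stage("population", {
      tens <- bin_zscore(session$spikes, session$trials,
                         config$gpfa$bin_s * c(-13, 27), # -195..405 ms default
                         bin_s = config$gpfa$bin_s,
                         min_rate_hz = config$gpfa$min_rate_hz)
      mod <- fit_gpfa(tens, q = min(config$gpfa$q,
                                    nrow(tens$counts[[1L]]) - 1L),
                      tol = config$gpfa$tol, max_iter = 100)
      trj <- extract_trajectories(mod, tens, config$gpfa$n_factors)
      tmpl <- projection_template(mod, tens, config$gpfa$n_factors)
      onsets <- blocks$post$events$swr_onset
      labs <- label_swr_conditions(onsets, blocks$post$events$m1_so_up,
                                   blocks$post$nrems, seed = seed)
      r_plus <- reactivation_fixed(session$sleep_spikes, onsets, mod, tmpl,
                                   tens$mean, tens$sd,
                                   fixed_ms = config$reactivation$fixed_ms,
                                   bin_s = config$reactivation$bin_s)
      r_minus <- reactivation_fixed(session$sleep_spikes,
                                    labs$swr_minus_onsets, mod, tmpl,
                                    tens$mean, tens$sd,
                                    fixed_ms = config$reactivation$fixed_ms,
                                    bin_s = config$reactivation$bin_s)
      list(model = mod, template = tmpl, labels = labs,
           reactivation = list(swr_plus = r_plus, swr_minus = r_minus,
                               delta = mean(r_plus, na.rm = TRUE) -
                                 mean(r_minus, na.rm = TRUE)))
    })
  }

  prov <- list(seed = seed,
               config_hash = config_hash(config),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package_version = as.character(utils::packageVersion("sleepmanifold")))
  res <- list(blocks = blocks, coupling = rows, population = population,
              provenance = prov)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (b in names(blocks)) {
      write_intervals(blocks[[b]]$nrems,
                      file.path(out_dir, paste0("nrems_", b, ".csv")))
      if (!is.null(blocks[[b]]$detections))
        for (nm in names(blocks[[b]]$detections))
          write_events(blocks[[b]]$detections[[nm]],
                       file.path(out_dir, paste0("events_", b, "_", nm, ".csv")))
    }
    utils::write.csv(rows, file.path(out_dir, "coupling.csv"),
                     row.names = FALSE)
    if (!is.null(population)) {
      re <- population$reactivation
      utils::write.csv(data.frame(
        condition = c("swr_plus", "swr_minus"),
        n_events = c(length(re$swr_plus), length(re$swr_minus)),
        mean_r = c(mean(re$swr_plus, na.rm = TRUE),
                   mean(re$swr_minus, na.rm = TRUE)),
        median_r = c(stats::median(re$swr_plus, na.rm = TRUE),
                     stats::median(re$swr_minus, na.rm = TRUE))),
        file.path(out_dir, "reactivation.csv"), row.names = FALSE)
    }
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of a configuration (md5 of its canonical YAML rendering)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}
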