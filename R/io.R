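# CSV and HDF5 interchange. Event/trial/interval tables travel as plain CSV
# (timestamps written at microsecond precision); whole sessions travel in an
# HDF5 container with one group per area.

#' Read / write event tables
#'
#' @param path CSV file path.
#' @return `read_events` returns an `event_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "area", "t_onset", "t_peak", "t_end")
  if (!all(need %in% names(d)))
    stop("event CSV missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  num <- function(col) if (col %in% names(d)) as.numeric(d[[col]]) else NA_real_
  event_table(d$kind, d$area, d$t_onset, d$t_peak, d$t_end,
              peak_amp = num("peak_amp"), trough_amp = num("trough_amp"))
}

#' @rdname read_events
#' @param table an `event_table`.
#' @export
write_events <- function(table, path) {
  d <- as.data.frame(table)
  for (col in c("t_onset", "t_peak", "t_end"))
    d[[col]] <- sprintf("%.6f", d[[col]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write interval sets as CSV (`start,end`)
#' @param path CSV file path.
#' @export
read_intervals <- function(path) {
  d <- utils::read.csv(path)
  interval_set(d$start, d$end)
}

#' @rdname read_intervals
#' @param x an `interval_set`.
#' @export
write_intervals <- function(x, path) {
  d <- data.frame(start = sprintf("%.6f", x$start), end = sprintf("%.6f", x$end))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a session container (HDF5)
#'
#' Layout: groups `/PFC`, `/M1`, `/HPC`, each with dataset `lfp`
#' (channels x time), `channel_ok`, and attributes `rate`, `t0`;
#' `/spikes/<area>/<unit_id>` spike-time vectors; `/manifest` attributes.
#'
#' @param recordings named list of `recording` objects (names = areas).
#' @param spikes optional `spike_train_set`.
#' @param manifest optional `session_manifest`.
#' @param path HDF5 file path (overwritten).
#' @export
write_session_h5 <- function(path, recordings, spikes = NULL, manifest = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (area in names(recordings)) {
    r <- recordings[[area]]
    rhdf5::h5createGroup(path, area)
    rhdf5::h5write(r$samples, path, paste0(area, "/lfp"))
    rhdf5::h5write(as.integer(r$channel_ok), path, paste0(area, "/channel_ok"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, area)
    rhdf5::h5writeAttribute(r$rate, gid, "rate")
    rhdf5::h5writeAttribute(r$t0, gid, "t0")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  if (!is.null(spikes)) {
    rhdf5::h5createGroup(path, "spikes")
    for (u in spikes$units) {
      grp <- paste0("spikes/", u$area)
      if (!grp %in% rhdf5::h5ls(path)$name)
        try(rhdf5::h5createGroup(path, grp), silent = TRUE)
      rhdf5::h5write(u$times, path, paste0(grp, "/", u$unit_id))
    }
  }
  if (!is.null(manifest)) {
    rhdf5::h5createGroup(path, "manifest")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "manifest")
    rhdf5::h5writeAttribute(manifest$animal_id, gid, "animal_id")
    rhdf5::h5writeAttribute(manifest$day, gid, "day")
    for (b in names(manifest$blocks))
      rhdf5::h5writeAttribute(manifest$blocks[[b]], gid, b)
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_session_h5
#' @param area which area group to read.
#' @return `load_recording` returns a `recording`.
#' @export
load_recording <- function(path, area) {
  if (!file.exists(path)) stop("file not found: ", path)
  area <- match.arg(area, c("PFC", "M1", "HPC"))
  ls <- rhdf5::h5ls(path)
  if (!area %in% ls$name[ls$group == "/"])
    stop("container has no group /", area)
  lfp <- rhdf5::h5read(path, paste0(area, "/lfp"))
  ok <- as.logical(rhdf5::h5read(path, paste0(area, "/channel_ok")))
  attrs <- rhdf5::h5readAttributes(path, area)
  rhdf5::h5closeAll()
  if (!"rate" %in% names(attrs))
    stop("container missing required attribute: rate")
  t0 <- if ("t0" %in% names(attrs)) as.numeric(attrs$t0) else 0
  recording(lfp, rate = as.numeric(attrs$rate), area = area, channel_ok = ok,
            t0 = t0)
}

#' Default analysis configuration
#'
#' One block per pipeline stage; every threshold, window and order the
#' pipeline uses, overridable via a YAML file with the same structure.
#'
#' @param path optional YAML file; values found there override the defaults.
#' @return nested named list.
#' @export
default_config <- function(path = NULL) {
  cfg <- list(
    staging = list(epoch_s = 6, delta_band = c(0.1, 4), gamma_band = c(30, 60),
                   min_run_s = 30, kmeans_restarts = 10),
    detection = list(
      so = list(hp = c(0.1, 2), lp = c(4, 5), peak_pct = 0.85,
                trough_pct = 0.40, dur_min = 0.150, dur_max = 0.500),
      spindle = list(hp = c(10, 6), lp = c(15, 8), upper_sd = 2.5,
                     lower_sd = 1.5, min_dur = 0.500, env_smooth = 0.200),
      swr = list(hp = c(150, 8), lp = c(250, 10), upper_sd = 4,
                 lower_sd = 1, min_dur = 0.050, env_smooth = 0.020),
      artifact_sd = 10),
    coupling = list(so_swr_window = c(-0.75, 0.75), pfc_m1_window = c(-0.2, 0.2),
                    so_spindle_window = c(-0.5, 1.0), multi_window = c(-1, 1),
                    swr_so_plus_s = 1, shuffle_reps = 1000, subsample_n = 100,
                    min_events = 10),
    dynamics = list(kernel_tertiles = 9, pad_tertiles = 6, sigmoid_bounds = c(-0.5, 1.5),
                    k_max = 20, scan_windows = 3:7, baseline_days = 1:4,
                    baseline_sd = 2),
    gpfa = list(bin_s = 0.015, q = 6, n_factors = 3, tol = 1e-6, max_iter = 500,
                min_rate_hz = 0.5, gp_noise = 1e-3),
    reactivation = list(bin_s = 0.015, sizes_ms = seq(75, 405, by = 30),
                        lag_step_ms = 15, max_ms = 405, fixed_ms = 195,
                        cca_window_s = 1, shuffle_reps = 1000))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}
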