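#' Write / read the montage and ROI map as JSON
#'
#' @param montage A `fnirs_montage`; `roi_map` a `roi_map`.
#' @param path Output file.
#' @return `write_*` return `path` invisibly; `read_roi_map_json` returns a
#'   `roi_map` identical to the one serialized.
#' @export
write_montage_json <- function(montage, path) {
  jsonlite::write_json(unclass(montage), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
write_roi_map_json <- function(roi_map, path) {
  jsonlite::write_json(unclass(roi_map), path, digits = NA)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_roi_map_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, as.integer), class = "roi_map")
}

#' Write a paradigm schedule as a TSV events table
#'
#' Three columns: `condition`, `onset_s`, `duration_s`.
#' @param schedule A `paradigm_schedule`.
#' @param path Output file.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a hemoglobin recording as long-format CSV
#'
#' Columns: `subject_id`, `channel`, `chromophore`, `time_s`, `value`
#' (umol/L).
#' @param hb An `fnirs_hb`.
#' @param path Output file.
#' @export
write_hb_csv <- function(hb, path) {
  n <- dim(hb$hb)[3]
  t_s <- (seq_len(n) - 1) / hb$sampling_rate_hz
  long <- do.call(rbind, lapply(seq_along(hb$retained_channel_ids), function(i) {
    do.call(rbind, lapply(c("HbO", "HbR"), function(ch) {
      data.frame(subject_id = hb$subject_id,
                 channel = hb$retained_channel_ids[i], chromophore = ch,
                 time_s = t_s, value = hb$hb[i, ch, ],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as tidy CSV
#'
#' Long format: `subject_id`, `roi`, `condition`, `label`, `chromophore`,
#' `feature_name`, `value`. The wide table from [subject_features()] is the
#' classifier-facing format; this is the interchange format.
#' @param features Wide feature table.
#' @param path Output file.
#' @export
write_features_csv <- function(features, path) {
  cols <- c(paste0("HbO_", feature_names()), paste0("HbR_", feature_names()))
  long <- do.call(rbind, lapply(cols, function(cl) {
    parts <- strsplit(cl, "_")[[1]]
    data.frame(
      subject_id = features$subject_id, roi = features$roi,
      condition = features$condition, label = features$label,
      chromophore = parts[1],
      feature_name = sub("^[^_]+_", "", cl),
      value = features[[cl]], stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy feature CSV back into the wide format
#' @param path Feature CSV written by [write_features_csv()].
#' @return Wide feature table.
#' @export
read_features_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long$col <- paste0(long$chromophore, "_", long$feature_name)
  wide <- stats::reshape(
    long[, c("subject_id", "roi", "condition", "label", "col", "value")],
    idvar = c("subject_id", "roi", "condition", "label"),
    timevar = "col", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Write a minimal SNIRF file for a raw recording
#'
#' Writes intensity data, time axis, per-column measurement lists,
#' wavelengths and the task/rest stimulus blocks in the SNIRF (HDF5) layout.
#' Requires the `rhdf5` package (Suggests); plain-text CSV/JSON is the
#' package's canonical interchange format.
#'
#' @param recording An `fnirs_raw`.
#' @param path Output `.snirf` file.
#' @export
write_snirf <- function(recording, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("write_snirf requires the rhdf5 package", call. = FALSE)
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  dims <- dim(recording$intensity)
  n_ch <- dims[1]; n_wl <- dims[2]; n_t <- dims[3]
  # columns ordered channel-major, wavelength within channel
  mat <- matrix(0, n_t, n_ch * n_wl)
  col <- 0L
  for (ch in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      col <- col + 1L
      mat[, col] <- recording$intensity[ch, w, ]
    }
  }
  h5w <- function(obj, name) rhdf5::h5write(obj, path, name)
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5createGroup(path, "nirs/probe")
  h5w("1.0", "formatVersion")
  h5w(mat, "nirs/data1/dataTimeSeries")
  h5w((seq_len(n_t) - 1) / recording$sampling_rate_hz, "nirs/data1/time")
  h5w(recording$montage$wavelengths_nm, "nirs/probe/wavelengths")
  col <- 0L
  for (ch in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      col <- col + 1L
      g <- sprintf("nirs/data1/measurementList%d", col)
      rhdf5::h5createGroup(path, g)
      h5w(ch, file.path(g, "sourceIndex"))
      h5w(ch, file.path(g, "detectorIndex"))
      h5w(w, file.path(g, "wavelengthIndex"))
      h5w(1L, file.path(g, "dataType"))
    }
  }
  for (cond in c("task", "rest")) {
    ev <- recording$schedule$events[recording$schedule$events$condition == cond, ]
    g <- if (cond == "task") "nirs/stim1" else "nirs/stim2"
    rhdf5::h5createGroup(path, g)
    h5w(cond, file.path(g, "name"))
    h5w(cbind(ev$onset_s, ev$duration_s, rep(1, nrow(ev))),
        file.path(g, "data"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a SNIRF file written by [write_snirf()]
#' @param path `.snirf` file.
#' @param montage,subject_id Montage to attach and subject id.
#' @return An `fnirs_raw` recording.
#' @export
read_snirf <- function(path, montage = build_montage(), subject_id = NA) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("read_snirf requires the rhdf5 package", call. = FALSE)
  }
  mat <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  t_s <- as.vector(rhdf5::h5read(path, "nirs/data1/time"))
  wl <- as.vector(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  fs <- 1 / stats::median(diff(t_s))
  n_wl <- length(wl)
  n_ch <- ncol(mat) / n_wl
  intensity <- array(0, dim = c(n_ch, n_wl, nrow(mat)),
                     dimnames = list(seq_len(n_ch), wl, NULL))
  col <- 0L
  for (ch in seq_len(n_ch)) {
    for (w in seq_len(n_wl)) {
      col <- col + 1L
      intensity[ch, w, ] <- mat[, col]
    }
  }
  stim <- rhdf5::h5read(path, "nirs/stim1/data")
  n_blocks <- nrow(stim)
  task_s <- stim[1, 2]
  rest <- rhdf5::h5read(path, "nirs/stim2/data")
  schedule <- build_schedule(
    pre_baseline_s = stim[1, 1], n_blocks = n_blocks, task_s = task_s,
    rest_s = rest[1, 2],
    post_baseline_s = max(t_s) + 1 / fs - (rest[n_blocks, 1] + rest[n_blocks, 2])
  )
  rhdf5::h5closeAll()
  structure(
    list(subject_id = subject_id, intensity = intensity,
         sampling_rate_hz = round(fs, 6), montage = montage,
         schedule = schedule),
    class = "fnirs_raw"
  )
}

#' Write the CMD analysis report as JSON
#' @param analysis A `cmd_analysis` result from [cmd_analysis()].
#' @param path Output file.
#' @export
write_report_json <- function(analysis, path) {
  conf <- analysis$confusion
  report <- list(
    reporting_roi = analysis$reporting_roi,
    confusion = list(TP = conf$TP, FN = conf$FN, TN = conf$TN, FP = conf$FP,
                     TPR = conf$TPR, FNR = conf$FNR, TNR = conf$TNR,
                     FPR = conf$FPR),
    cmd_subjects = as.vector(analysis$cmd_ids),
    p_values = as.list(analysis$prognosis$p_values),
    bonferroni_threshold = analysis$prognosis$bonferroni_threshold
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
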