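#' Average hemoglobin time courses within ROIs
#'
#' Unweighted mean of the retained channels of each requested ROI, per
#' chromophore. An ROI none of whose channels survived quality control
#' triggers an error (downstream classification for that ROI must be skipped
#' for this subject).
#'
#' @param hb An `fnirs_hb` recording.
#' @param roi_map A [build_roi_map()].
#' @param rois ROI names to average (default: all ten).
#' @return A named list (per ROI) of `roi_series` objects: `roi_id`,
#'   `chromophore`-named matrix `series` (2 x time), `n_channels_averaged`.
#' @export
roi_average <- function(hb, roi_map = build_roi_map(), rois = names(roi_map)) {
  out <- lapply(rois, function(roi) {
    keep <- which(hb$retained_channel_ids %in% roi_map[[roi]])
    if (length(keep) == 0) {
      stop("no retained channels in ROI ", roi, call. = FALSE)
    }
    series <- apply(hb$hb[keep, , , drop = FALSE], c(2, 3), mean)
    structure(
      list(roi_id = roi, series = series,
           n_channels_averaged = length(keep),
           sampling_rate_hz = hb$sampling_rate_hz, schedule = hb$schedule),
      class = "roi_series"
    )
  })
  names(out) <- rois
  out
}

#' Segment an ROI series into per-block epochs
#'
#' Cuts one epoch per task event, from 5 s before the task onset to 40 s
#' after it (the end of the block's rest period). Sample alignment uses the
#' package-wide rounding rule [time_to_sample()]; at 11 Hz each 45 s epoch is
#' 496 samples (495 intervals plus the start sample).
#'
#' @param roi_series A `roi_series` from [roi_average()].
#' @param schedule The paradigm schedule.
#' @param pre_s,post_s Epoch extent before/after the task onset, seconds.
#' @return A list of epochs; each epoch is a list with `time_s` (relative to
#'   the task onset) and `series` (chromophore x time matrix).
#' @export
epoch_blocks <- function(roi_series, schedule = roi_series$schedule,
                         pre_s = 5, post_s = 40) {
  fs <- roi_series$sampling_rate_hz
  n <- ncol(roi_series$series)
  onsets <- task_onsets(schedule)
  len <- as.integer(round((pre_s + post_s) * fs)) + 1L
  lapply(seq_along(onsets), function(k) {
    i0 <- time_to_sample(onsets[k] - pre_s, fs)
    i1 <- i0 + len - 1L
    if (i0 < 1 || i1 > n) {
      stop("recording too short to epoch block ", k, call. = FALSE)
    }
    list(
      time_s = (seq_len(len) - 1) / fs - pre_s,
      series = roi_series$series[, i0:i1, drop = FALSE],
      roi_id = roi_series$roi_id
    )
  })
}

#' Baseline-correct an epoch
#'
#' Subtracts, per chromophore, the mean over the 5 s pre-task baseline
#' (times in `[-5, 0)`) from the whole epoch. Idempotent.
#'
#' @param epoch One epoch from [epoch_blocks()].
#' @param baseline_s Baseline window `[start, end)` in epoch time, seconds.
#' @return The corrected epoch.
#' @export
baseline_correct <- function(epoch, baseline_s = c(-5, 0)) {
  sel <- epoch$time_s >= baseline_s[1] & epoch$time_s < baseline_s[2]
  if (!any(sel)) stop("epoch does not cover the baseline window", call. = FALSE)
  epoch$series <- epoch$series - rowMeans(epoch$series[, sel, drop = FALSE])
  epoch$baseline_corrected <- TRUE
  epoch
}

#' Average epochs across blocks
#'
#' Pointwise mean of equally long epochs, the block-averaged hemodynamic
#' response of one ROI.
#'
#' @param epochs List of epochs (same ROI, equal lengths).
#' @return A `block_average` epoch with `n_blocks_averaged` recorded.
#' @export
block_average <- function(epochs) {
  if (length(epochs) == 0) stop("no epochs", call. = FALSE)
  lens <- vapply(epochs, function(e) ncol(e$series), integer(1))
  if (length(unique(lens)) != 1) {
    stop("epoch length mismatch: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(epochs, `[[`, "series")) / length(epochs)
  structure(
    list(
      time_s = epochs[[1]]$time_s, series = avg,
      roi_id = epochs[[1]]$roi_id,
      baseline_corrected = isTRUE(epochs[[1]]$baseline_corrected),
      n_blocks_averaged = length(epochs)
    ),
    class = "block_average"
  )
}

#' Seven window features of a numeric vector
#'
#' mean, peak (maximum), variance (sample, n-1), median, peak-to-peak
#' (max - min), skewness (m3 / m2^1.5) and non-excess kurtosis (m4 / m2^2),
#' where the mk are central sample moments with 1/n normalisation. A
#' zero-variance window yields skewness 0 and kurtosis 0 by convention.
#'
#' @param x Numeric window.
#' @return Named numeric vector of the seven features.
#' @export
window_features <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  c(
    mean = m,
    peak = max(x),
    variance = if (n > 1) sum(d^2) / (n - 1) else 0,
    median = stats::median(x),
    peak_to_peak = max(x) - min(x),
    skewness = skew,
    kurtosis = kurt
  )
}

#' The seven feature names
#' @return Character vector in canonical order.
#' @export
feature_names <- function() {
  c("mean", "peak", "variance", "median", "peak_to_peak", "skewness",
    "kurtosis")
}

#' Extract imagery and rest feature vectors from a block average
#'
#' Computes the seven features per chromophore in the imagery window
#' (5-20 s after the task command, i.e. epoch time `[5, 20)`) and the rest
#' window (5-20 s after the rest command, i.e. epoch time `[25, 40)` since
#' the rest command follows the 20 s task). Windows are half-open in seconds
#' and mapped to samples by rounding the start and taking samples with
#' time < end. Peak is the maximum for both chromophores.
#'
#' @param avg A baseline-corrected `block_average`.
#' @param task_window,rest_window Two-element `[start, end)` windows in epoch
#'   time, seconds.
#' @return Data frame with two rows (conditions `imagery`, label 1, and
#'   `rest`, label 0) and columns `HbO_<feature>`, `HbR_<feature>`.
#' @export
extract_features <- function(avg, task_window = c(5, 20),
                             rest_window = c(25, 40)) {
  one <- function(win) {
    sel <- avg$time_s >= win[1] - 1e-9 & avg$time_s < win[2] - 1e-9
    if (!any(sel)) stop("feature window outside epoch", call. = FALSE)
    v <- c(window_features(avg$series["HbO", sel]),
           window_features(avg$series["HbR", sel]))
    names(v) <- c(paste0("HbO_", feature_names()),
                  paste0("HbR_", feature_names()))
    v
  }
  out <- as.data.frame(rbind(one(task_window), one(rest_window)))
  cbind(
    data.frame(condition = c("imagery", "rest"), label = c(1L, 0L),
               stringsAsFactors = FALSE),
    out
  )
}

#' Feature table for one preprocessed subject
#'
#' ROI-averages the recording, epochs and baseline-corrects each block,
#' block-averages, and extracts the imagery/rest feature vectors for each
#' requested ROI. With `mode = "per_block"` features are instead computed on
#' every individual epoch (5 imagery + 5 rest rows per ROI); the
#' block-average mode is the default analysis path.
#'
#' @param hb An `fnirs_hb` recording.
#' @param roi_map ROI map.
#' @param rois ROI names.
#' @param mode `"block_average"` (default) or `"per_block"`.
#' @param task_window,rest_window Feature windows, see [extract_features()].
#' @return Data frame with columns `subject_id`, `roi`, `block` (NA in
#'   block-average mode), `condition`, `label` and the 14 feature columns.
#'   ROIs with no retained channels are skipped with a warning.
#' @export
subject_features <- function(hb, roi_map = build_roi_map(),
                             rois = names(roi_map),
                             mode = c("block_average", "per_block"),
                             task_window = c(5, 20), rest_window = c(25, 40)) {
  mode <- match.arg(mode)
  rows <- list()
  for (roi in rois) {
    series <- tryCatch(roi_average(hb, roi_map, roi)[[roi]], error = function(e) {
      warning("skipping ROI ", roi, " for subject ", hb$subject_id, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(series)) next
    epochs <- lapply(epoch_blocks(series), baseline_correct)
    if (mode == "block_average") {
      fv <- extract_features(block_average(epochs), task_window, rest_window)
      fv <- cbind(data.frame(subject_id = hb$subject_id, roi = roi,
                             block = NA_integer_, stringsAsFactors = FALSE),
                  fv)
      rows[[length(rows) + 1L]] <- fv
    } else {
      for (k in seq_along(epochs)) {
        ba <- structure(
          list(time_s = epochs[[k]]$time_s, series = epochs[[k]]$series,
               roi_id = roi, baseline_corrected = TRUE,
               n_blocks_averaged = 1L),
          class = "block_average"
        )
        fv <- extract_features(ba, task_window, rest_window)
        fv <- cbind(data.frame(subject_id = hb$subject_id, roi = roi,
                               block = k, stringsAsFactors = FALSE),
                    fv)
        rows[[length(rows) + 1L]] <- fv
      }
    }
  }
  do.call(rbind, rows)
}
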