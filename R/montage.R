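#' Fixed 63-channel fNIRS montage
#'
#' Constructs the acquisition montage used throughout the pipeline: 63
#' measurement channels formed by 24 source and 24 detector optodes at a fixed
#' 3 cm source-detector separation, three measurement wavelengths
#' (703, 808, 850 nm) and an 11 Hz sampling rate. The source/detector labels
#' are opaque identifiers: the true optode pairing geometry is not part of this
#' model and nothing downstream depends on it.
#'
#' @return An object of class `fnirs_montage`: a list with `channel_ids`,
#'   `source`, `detector`, `source_detector_distance_cm`, `wavelengths_nm`
#'   and `sampling_rate_hz`.
#' @examples
#' m <- build_montage()
#' length(m$channel_ids)    # 63
#' m$wavelengths_nm         # 703 808 850
#' @export
build_montage <- function() {
  channels <- 1:63
  montage <- structure(
    list(
      channel_ids = channels,
      # opaque pairing labels (no geometric meaning; see package vignette)
      source = sprintf("S%02d", ((channels - 1L) %% 24L) + 1L),
      detector = sprintf("D%02d", ((channels - 1L) %/% 3L) %% 24L + 1L),
      source_detector_distance_cm = rep(3.0, 63L),
      wavelengths_nm = c(703, 808, 850),
      sampling_rate_hz = 11
    ),
    class = "fnirs_montage"
  )
  validate_montage(montage)
  montage
}

validate_montage <- function(m) {
  stopifnot(
    inherits(m, "fnirs_montage"),
    length(m$channel_ids) == 63L,
    all(m$source_detector_distance_cm == 3.0),
    length(m$wavelengths_nm) == 3L,
    all(diff(m$wavelengths_nm) > 0),
    m$sampling_rate_hz > 0
  )
  invisible(m)
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf(
    "fNIRS montage: %d channels, %s nm, %g Hz, %g cm separation\n",
    length(x$channel_ids), paste(x$wavelengths_nm, collapse = "/"),
    x$sampling_rate_hz, x$source_detector_distance_cm[1]
  ))
  invisible(x)
}

#' Region-of-interest to channel map
#'
#' The fixed assignment of measurement channels to the ten cortical regions of
#' interest: left/right prefrontal (LPFC, RPFC), premotor (LPMC, RPMC), primary
#' motor (LM1, RM1), parietal (LPC, RPC) and occipital (LOC, ROC) cortex.
#' Channels 21, 28 and 49 belong to no ROI; they are carried through
#' preprocessing but never enter an ROI average.
#'
#' @return An object of class `roi_map`: a named list of integer channel-id
#'   vectors, one per ROI.
#' @examples
#' build_roi_map()$LM1   # 54 55 57
#' @export
build_roi_map <- function() {
  map <- list(
    LPFC = c(8:12, 23:26, 29, 39),
    RPFC = c(3:7, 18:20, 22, 34, 35),
    LPMC = c(27, 36:38, 40, 41),
    RPMC = c(31, 33, 46, 47, 50, 51),
    LM1 = c(54, 55, 57),
    RM1 = c(30, 32, 45),
    LPC = c(13:15, 52, 53, 56),
    RPC = c(1, 2, 16, 17, 44, 48),
    LOC = 60:63,
    ROC = c(42, 43, 58, 59)
  )
  map <- lapply(map, as.integer)
  structure(map, class = "roi_map")
}

#' ROI names associated with the motor system
#'
#' The four ROIs over premotor and primary motor cortex on which
#' command-following classification is performed.
#' @return Character vector `c("LPMC", "RPMC", "LM1", "RM1")`.
#' @export
motor_rois <- function() c("LPMC", "RPMC", "LM1", "RM1")

#' Block-design paradigm schedule
#'
#' Builds the timed event schedule of the motor-imagery block paradigm: a
#' pre-baseline, `n_blocks` repetitions of (task, rest), and a post-baseline.
#' With the defaults this is the 300 s protocol: 50 s pre-baseline, five
#' 20 s-imagery / 20 s-rest blocks, 50 s post-baseline. The rest command of
#' each block starts when its task period ends, so blocks tile the middle of
#' the recording without gaps.
#'
#' @param pre_baseline_s Pre-baseline duration in seconds.
#' @param n_blocks Number of task/rest block repetitions.
#' @param task_s Task (imagery) duration per block, seconds.
#' @param rest_s Rest duration per block, seconds.
#' @param post_baseline_s Post-baseline duration in seconds.
#' @return An object of class `paradigm_schedule`: a list with an `events`
#'   data frame (`condition`, `onset_s`, `duration_s`), `pre_baseline_s`,
#'   `post_baseline_s` and `total_duration_s`.
#' @examples
#' sched <- build_schedule()
#' sched$total_duration_s                                   # 300
#' subset(sched$events, condition == "task")$onset_s        # 50 90 130 170 210
#' @export
build_schedule <- function(pre_baseline_s = 50, n_blocks = 5, task_s = 20,
                           rest_s = 20, post_baseline_s = 50) {
  if (!(n_blocks > 0 && task_s > 0 && rest_s > 0 &&
        pre_baseline_s >= 0 && post_baseline_s >= 0)) {
    stop("invalid paradigm: n_blocks, task_s and rest_s must be positive; ",
         "baselines must be non-negative", call. = FALSE)
  }
  block_s <- task_s + rest_s
  task_onsets <- pre_baseline_s + (seq_len(n_blocks) - 1) * block_s
  events <- data.frame(
    condition = rep(c("task", "rest"), times = n_blocks),
    onset_s = as.vector(rbind(task_onsets, task_onsets + task_s)),
    duration_s = rep(c(task_s, rest_s), times = n_blocks),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      events = events,
      pre_baseline_s = pre_baseline_s,
      post_baseline_s = post_baseline_s,
      total_duration_s = pre_baseline_s + n_blocks * block_s + post_baseline_s
    ),
    class = "paradigm_schedule"
  )
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  n_task <- sum(x$events$condition == "task")
  cat(sprintf(
    "Paradigm: %g s pre-baseline, %d task/rest blocks, %g s post-baseline (total %g s)\n",
    x$pre_baseline_s, n_task, x$post_baseline_s, x$total_duration_s
  ))
  invisible(x)
}

#' Task onsets of a schedule
#' @param schedule A `paradigm_schedule`.
#' @return Numeric vector of task onsets in seconds.
#' @export
task_onsets <- function(schedule) {
  schedule$events$onset_s[schedule$events$condition == "task"]
}

#' Convert a time in seconds to a 1-based sample index
#'
#' The single onset-to-sample rule used everywhere in the package:
#' `round(t * rate) + 1`. At 11 Hz most onsets fall between samples, so a
#' centralised rounding rule keeps all stages aligned.
#' @param t_s Time(s) in seconds from the start of the recording.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Integer sample index (1-based).
#' @export
time_to_sample <- function(t_s, sampling_rate_hz) {
  as.integer(round(t_s * sampling_rate_hz)) + 1L
}
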