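#' Molar extinction coefficients for HbO and HbR
#'
#' Fixed table of hemoglobin molar extinction coefficients
#' (cm^-1 per mol/L) at the instrument wavelengths, compiled from the
#' standard published hemoglobin absorption spectra. The same table drives
#' both the forward simulator and the inverse modified Beer-Lambert solve,
#' so concentration round trips are exact by construction; the table choice
#' affects only the absolute concentration scale.
#'
#' @param wavelengths_nm Wavelengths to look up (default: all three).
#' @return Matrix with rows per wavelength and columns `HbO`, `HbR`.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(703, 808, 850)) {
  tab <- matrix(
    c(
      298.2, 1687.8,   # 703 nm: HbR-dominant
      856.4,  717.1,   # 808 nm: near-isosbestic
      1058.0,  691.3   # 850 nm: HbO-dominant
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("703", "808", "850"), c("HbO", "HbR"))
  )
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab))) {
    stop("extinction-coefficient table does not cover wavelength(s): ",
         paste(setdiff(key, rownames(tab)), collapse = ", "), call. = FALSE)
  }
  tab[key, , drop = FALSE]
}

# Design matrix mapping (HbO, HbR) in umol/L to delta-OD per wavelength:
# OD = eps[cm^-1/M] * 1e-6 [M/umol] * distance[cm] * DPF * C[umol/L]
mbll_design_matrix <- function(wavelengths_nm, dpf = 6.0, distance_cm = 3.0) {
  extinction_coefficients(wavelengths_nm) * 1e-6 * distance_cm * dpf
}

#' Coefficient of variation of an intensity series
#'
#' CV = sample standard deviation / mean x 100, the channel signal-quality
#' metric used for rejection.
#' @param series Numeric intensity series.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
#' @export
coefficient_of_variation <- function(series) {
  if (length(series) == 0) stop("empty series", call. = FALSE)
  m <- mean(series)
  if (m == 0) stop("CV undefined: series mean is zero", call. = FALSE)
  stats::sd(series) / m * 100
}

#' Reject channels with excessive coefficient of variation
#'
#' Computes the CV of the raw intensity of every channel at every wavelength
#' and discards a channel if its CV exceeds `threshold` percent (strictly) at
#' any wavelength.
#'
#' @param recording A raw recording (`fnirs_raw`).
#' @param threshold Rejection threshold in percent.
#' @return A list with `recording` (restricted to retained channels) and
#'   `qc` (class `qc_report`): a data frame with one row per channel x
#'   wavelength (`channel`, `wavelength_nm`, `cv_percent`, `rejected`,
#'   `reason`).
#' @export
reject_channels <- function(recording, threshold = 15) {
  ints <- recording$intensity
  n_ch <- dim(ints)[1]
  wl <- recording$montage$wavelengths_nm
  cv <- t(vapply(seq_len(n_ch), function(ch) {
    vapply(seq_along(wl), function(w) coefficient_of_variation(ints[ch, w, ]),
           numeric(1))
  }, numeric(length(wl))))
  bad <- apply(cv > threshold, 1, any)
  qc <- data.frame(
    channel = rep(recording$montage$channel_ids, each = length(wl)),
    wavelength_nm = rep(wl, n_ch),
    cv_percent = as.vector(t(cv)),
    rejected = rep(bad, each = length(wl)),
    reason = ifelse(rep(bad, each = length(wl)),
                    sprintf("CV > %g%%", threshold), ""),
    stringsAsFactors = FALSE
  )
  class(qc) <- c("qc_report", "data.frame")
  if (all(bad)) {
    stop("all channels rejected (CV > ", threshold,
         "%): recording unusable", call. = FALSE)
  }
  out <- recording
  out$intensity <- ints[!bad, , , drop = FALSE]
  out$retained_channel_ids <- recording$montage$channel_ids[!bad]
  list(recording = out, qc = qc)
}

#' Convert raw intensity to optical density
#'
#' OD(t) = -log10(I(t) / mean(I)) per channel and wavelength, referencing
#' each series to its own temporal mean (the usual continuous-wave
#' convention, which makes OD invariant to detector gain).
#'
#' @param recording A raw recording, possibly channel-restricted.
#' @return An `fnirs_od` object: `od` array (channel x wavelength x time),
#'   `retained_channel_ids`, `sampling_rate_hz`, `montage`, `schedule`.
#' @export
to_optical_density <- function(recording) {
  ints <- recording$intensity
  if (any(ints <= 0)) stop("non-positive intensity", call. = FALSE)
  series_mean <- rowMeans(ints, dims = 2)        # channel x wavelength
  od <- -log10(ints / as.vector(series_mean))    # mean recycles along time
  structure(
    list(
      subject_id = recording$subject_id, od = od,
      retained_channel_ids = recording$retained_channel_ids %||%
        recording$montage$channel_ids,
      sampling_rate_hz = recording$sampling_rate_hz,
      montage = recording$montage, schedule = recording$schedule
    ),
    class = "fnirs_od"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered moving standard deviation with window w samples (edge-truncated).
moving_sd <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- (s2 - s^2 / cnt) / pmax(cnt - 1, 1)
  sqrt(pmax(v, 0))
}

# MARA-style correction of one series. Returns list(series, segments).
correct_motion_series <- function(x, fs, window_s, sd_threshold,
                                  amp_threshold, spline_lambda = 1e-8) {
  n <- length(x)
  w <- max(2L, as.integer(round(window_s * fs)))
  msd <- moving_sd(x, w)
  thr <- sd_threshold * max(stats::median(msd), 1e-12)
  flag <- msd > thr
  jump <- abs(diff(x)) > amp_threshold
  flag[which(jump)] <- TRUE
  flag[which(jump) + 1L] <- TRUE
  if (!any(flag)) return(list(series = x, segments = NULL))
  # dilate flags by one window on each side and merge into segments
  idx <- which(flag)
  lo <- pmax(idx - w, 1L)
  hi <- pmin(idx + w, n)
  mask <- logical(n)
  for (k in seq_along(idx)) mask[lo[k]:hi[k]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])

  z <- x
  shift <- 0
  pos <- 1L
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    if (pos <= a - 1L) z[pos:(a - 1L)] <- x[pos:(a - 1L)] + shift
    seg <- x[a:b]
    len <- length(seg)
    wb <- min(w, len)
    if (len >= 4L) {
      fit <- stats::smooth.spline(seq_len(len), seg, lambda = spline_lambda,
                                  all.knots = TRUE)
      residual <- seg - stats::predict(fit, seq_len(len))$y
    } else {
      residual <- numeric(len)
    }
    if (a > 1L) {
      prev_level <- mean(z[max(1L, a - w):(a - 1L)])
      z[a:b] <- residual - mean(residual[seq_len(wb)]) + prev_level
    } else if (b < n) {
      nxt <- mean(x[(b + 1L):min(n, b + w)])
      z[a:b] <- residual - mean(residual[(len - wb + 1L):len]) + nxt
    } else {
      z[a:b] <- residual - mean(residual) + mean(seg)
    }
    if (b < n) {
      seg_end_level <- mean(z[(b - wb + 1L):b])
      next_level <- mean(x[(b + 1L):min(n, b + w)])
      shift <- seg_end_level - next_level
    }
    pos <- b + 1L
  }
  if (pos <= n) z[pos:n] <- x[pos:n] + shift
  list(series = z, segments = segs)
}

#' Sliding-window motion-artifact correction with cubic-spline subtraction
#'
#' Identifies motion-contaminated samples per channel and wavelength where
#' either the moving standard deviation (window `window_s`) exceeds
#' `sd_threshold` times the series' median moving SD, or the sample-to-sample
#' change exceeds `amp_threshold` OD. Flagged samples are dilated into
#' contiguous segments; within each segment a near-interpolating cubic
#' smoothing spline is fitted and subtracted so the artifact shape is removed,
#' and the segment plus all subsequent data are re-leveled to preserve
#' continuity with the preceding clean data (spline-interpolation /
#' MARA-style correction). Clean recordings pass through unchanged.
#'
#' @param od An `fnirs_od` recording.
#' @param window_s Sliding-window length in seconds.
#' @param sd_threshold Multiplier on the median moving SD.
#' @param amp_threshold Sample-to-sample OD change threshold.
#' @return A list with `od` (corrected `fnirs_od`) and `artifacts`: a data
#'   frame of corrected segments (`channel`, `wavelength_nm`, `start`, `end`,
#'   sample indices).
#' @export
correct_motion <- function(od, window_s = 1.0, sd_threshold = 6,
                           amp_threshold = 0.5) {
  fs <- od$sampling_rate_hz
  if (round(window_s * fs) < 2) {
    stop("window_s must cover at least 2 samples", call. = FALSE)
  }
  arr <- od$od
  segs_out <- list()
  for (ch in seq_len(dim(arr)[1])) {
    for (w in seq_len(dim(arr)[2])) {
      res <- correct_motion_series(arr[ch, w, ], fs, window_s, sd_threshold,
                                   amp_threshold)
      arr[ch, w, ] <- res$series
      if (!is.null(res$segments)) {
        segs_out[[length(segs_out) + 1L]] <- data.frame(
          channel = od$retained_channel_ids[ch],
          wavelength_nm = od$montage$wavelengths_nm[w],
          start = res$segments[, 1], end = res$segments[, 2]
        )
      }
    }
  }
  out <- od
  out$od <- arr
  artifacts <- if (length(segs_out)) do.call(rbind, segs_out) else
    data.frame(channel = integer(0), wavelength_nm = numeric(0),
               start = integer(0), end = integer(0))
  list(od = out, artifacts = artifacts)
}

# Zero-phase band-pass of one series: Butterworth magnitude response applied
# in the frequency domain on an even-reflection-padded copy (exactly linear,
# exactly zero-phase, DC removed).
bandpass_series <- function(x, fs, low, high, order = 3) {
  n <- length(x)
  xm <- mean(x)
  y <- c(x - xm, rev(x - xm))
  N <- 2L * n
  f <- fs * (seq_len(N) - 1) / N
  f <- pmin(f, fs - f)
  hp <- 1 / sqrt(1 + (low / pmax(f, 1e-12))^(2 * order))
  lp <- 1 / sqrt(1 + (f / high)^(2 * order))
  H <- hp * lp
  H[f == 0] <- 0
  Re(stats::fft(stats::fft(y) * H, inverse = TRUE))[seq_len(n)] / N
}

#' Zero-phase band-pass filter
#'
#' Removes cardiac, respiratory, Mayer-wave and low-frequency drift
#' interference by restricting each channel/wavelength series to the
#' `low`-`high` Hz band. The filter applies a third-order Butterworth
#' magnitude response in the frequency domain with even-reflection padding,
#' so it is exactly zero-phase and removes the mean.
#'
#' @param od An `fnirs_od` recording.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of each (high-/low-pass) edge.
#' @return The filtered `fnirs_od`.
#' @export
bandpass <- function(od, low = 0.01, high = 0.1, order = 3) {
  fs <- od$sampling_rate_hz
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid filter band: need 0 < low < high < sampling_rate/2",
         call. = FALSE)
  }
  arr <- od$od
  d <- dim(arr)
  n <- d[3]
  # all channel/wavelength series as columns, even-reflection padded
  Y <- t(matrix(arr, d[1] * d[2], n))
  Y <- sweep(Y, 2, colMeans(Y))
  Y <- rbind(Y, Y[n:1, , drop = FALSE])
  N <- 2L * n
  f <- fs * (seq_len(N) - 1) / N
  f <- pmin(f, fs - f)
  H <- 1 / sqrt(1 + (low / pmax(f, 1e-12))^(2 * order)) /
    sqrt(1 + (f / high)^(2 * order))
  H[f == 0] <- 0
  filtered <- Re(stats::mvfft(stats::mvfft(Y) * H, inverse = TRUE)) / N
  out <- od
  out$od <- array(t(filtered[seq_len(n), , drop = FALSE]), dim = d,
                  dimnames = dimnames(arr))
  out
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' Solves, per channel and sample, the overdetermined linear system
#' `dOD(lambda) = [eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR] * d * DPF`
#' across the three wavelengths by least squares, yielding relative HbO and
#' HbR concentration changes in umol/L.
#'
#' @param od An `fnirs_od` recording.
#' @param dpf Differential path-length factor.
#' @param distance_cm Source-detector distance in cm.
#' @return An `fnirs_hb` object: `hb` array (channel x chromophore x time,
#'   chromophores `HbO`, `HbR`), plus `retained_channel_ids`,
#'   `sampling_rate_hz`, `montage`, `schedule`.
#' @export
mbll <- function(od, dpf = 6.0, distance_cm = 3.0) {
  E <- mbll_design_matrix(od$montage$wavelengths_nm, dpf, distance_cm)
  if (kappa(E) > 1e8) stop("ill-conditioned extinction matrix", call. = FALSE)
  # closed-form least squares: conc = (E'E)^-1 E' od
  P <- solve(crossprod(E), t(E))   # 2 x n_wavelengths
  arr <- od$od
  n_ch <- dim(arr)[1]
  n <- dim(arr)[3]
  hb <- array(0, dim = c(n_ch, 2, n),
              dimnames = list(od$retained_channel_ids, c("HbO", "HbR"), NULL))
  for (ch in seq_len(n_ch)) {
    hb[ch, , ] <- P %*% arr[ch, , ]
  }
  structure(
    list(
      subject_id = od$subject_id, hb = hb,
      retained_channel_ids = od$retained_channel_ids,
      sampling_rate_hz = od$sampling_rate_hz,
      montage = od$montage, schedule = od$schedule
    ),
    class = "fnirs_hb"
  )
}

#' Preprocessing configuration
#'
#' @param cv_threshold Channel-rejection CV threshold, percent.
#' @param motion Logical: apply motion-artifact correction.
#' @param window_s,sd_threshold,amp_threshold Motion-correction parameters,
#'   see [correct_motion()].
#' @param band Two-element numeric band (Hz), or `NULL` to skip filtering.
#' @param dpf Differential path-length factor.
#' @param distance_cm Source-detector distance (cm).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cv_threshold = 15, motion = TRUE,
                              window_s = 1.0, sd_threshold = 6,
                              amp_threshold = 0.5, band = c(0.01, 0.1),
                              dpf = 6.0, distance_cm = 3.0) {
  structure(
    list(cv_threshold = cv_threshold, motion = motion, window_s = window_s,
         sd_threshold = sd_threshold, amp_threshold = amp_threshold,
         band = band, dpf = dpf, distance_cm = distance_cm),
    class = "preprocess_config"
  )
}

#' Full preprocessing chain
#'
#' Applies, in order: channel rejection by coefficient of variation, optical
#' density conversion, sliding-window + cubic-spline motion correction,
#' 0.01-0.1 Hz zero-phase band-pass, and the modified Beer-Lambert conversion
#' to HbO/HbR concentration changes.
#'
#' @param recording A raw recording (`fnirs_raw`).
#' @param config A [preprocess_config()].
#' @return A list with `hb` (`fnirs_hb`), `qc` (`qc_report`) and `artifacts`
#'   (motion-correction segment table).
#' @export
preprocess_chain <- function(recording, config = preprocess_config()) {
  rej <- reject_channels(recording, threshold = config$cv_threshold)
  od <- to_optical_density(rej$recording)
  artifacts <- NULL
  if (isTRUE(config$motion)) {
    mc <- correct_motion(od, window_s = config$window_s,
                         sd_threshold = config$sd_threshold,
                         amp_threshold = config$amp_threshold)
    od <- mc$od
    artifacts <- mc$artifacts
  }
  if (!is.null(config$band)) {
    od <- bandpass(od, low = config$band[1], high = config$band[2])
  }
  hb <- mbll(od, dpf = config$dpf, distance_cm = config$distance_cm)
  list(hb = hb, qc = rej$qc, artifacts = artifacts)
}
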