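#' Canonical double-gamma hemodynamic response function
#'
#' Standard canonical HRF: a gamma-density main lobe peaking at `peak_s`
#' minus a scaled gamma-density undershoot peaking at `undershoot_s`. Both
#' gamma densities use rate 1, so the mode of each lobe equals its `shape - 1`
#' and `canonical_hrf(0, ...) == 0` (causality).
#'
#' @param t Time(s) in seconds, `t >= 0`.
#' @param peak_s Time-to-peak of the main lobe (s).
#' @param undershoot_s Time-to-trough of the undershoot (s).
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return Numeric vector of dimensionless amplitudes.
#' @examples
#' h <- canonical_hrf(seq(0, 30, 0.1))
#' seq(0, 30, 0.1)[which.max(h)]   # ~6 s
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                          undershoot_ratio = 1 / 6) {
  if (peak_s <= 0 || undershoot_s <= 0 || undershoot_ratio < 0) {
    stop("invalid HRF parameter: peak_s and undershoot_s must be positive, ",
         "undershoot_ratio non-negative", call. = FALSE)
  }
  if (any(t < 0)) stop("canonical_hrf is causal: t must be >= 0", call. = FALSE)
  stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
}

#' Subject profile for the synthetic cohort generator
#'
#' Describes one virtual subject: behavioral diagnosis, whether the brain
#' actually follows the motor-imagery command (`responder`), hemodynamic
#' response amplitude, noise level, motion-artifact rate, designated
#' bad channels and the 6-month GOS-E outcome.
#'
#' By default healthy controls (HC) and MCS+ subjects are responders and
#' VS/UWS and MCS- subjects are not; a VS/UWS or MCS- responder is a planted
#' cognitive-motor-dissociation (CMD) case.
#'
#' @param subject_id Character id.
#' @param diagnosis One of `"HC"`, `"VS/UWS"`, `"MCS-"`, `"MCS+"`.
#' @param responder Logical; `NULL` picks the diagnosis default above.
#' @param hbo_amplitude Peak task-evoked HbO increase in motor ROIs (umol/L).
#' @param hbr_ratio Scaling of HbR relative to HbO (negative: HbR decreases).
#' @param noise_scale Multiplier on all physiological noise components.
#' @param artifact_rate Motion-artifact events per minute.
#' @param bad_channel_ids Channels whose noise is inflated past the
#'   coefficient-of-variation rejection threshold.
#' @param gose_6mo Integer 1..8 or `NA` (lost to follow-up / not applicable).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, diagnosis = "HC", responder = NULL,
                            hbo_amplitude = 0.5, hbr_ratio = -0.3,
                            noise_scale = 1, artifact_rate = 0.5,
                            bad_channel_ids = integer(0), gose_6mo = NA) {
  diagnosis <- match.arg(diagnosis, c("HC", "VS/UWS", "MCS-", "MCS+"))
  if (is.null(responder)) responder <- diagnosis %in% c("HC", "MCS+")
  if (diagnosis == "HC" && !responder) {
    stop("healthy controls are responders by definition", call. = FALSE)
  }
  if (hbo_amplitude < 0) stop("hbo_amplitude must be >= 0", call. = FALSE)
  if (!is.na(gose_6mo) && (gose_6mo < 1 || gose_6mo > 8)) {
    stop("gose_6mo must be in 1..8 or NA", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id), diagnosis = diagnosis,
      responder = isTRUE(responder), hbo_amplitude = hbo_amplitude,
      hbr_ratio = hbr_ratio, noise_scale = noise_scale,
      artifact_rate = artifact_rate,
      bad_channel_ids = as.integer(bad_channel_ids),
      gose_6mo = if (is.na(gose_6mo)) NA_integer_ else as.integer(gose_6mo)
    ),
    class = "subject_profile"
  )
}

# Physiological noise amplitudes (umol/L) at noise_scale = 1. Chosen once so
# that raw-intensity channel CV lands around 5-10% (below the 15% rejection
# threshold) for good channels; see the methods vignette.
.noise_defaults <- list(
  cardiac_hz = 1.1, cardiac_amp = 2.2,
  resp_hz = 0.25, resp_amp = 0.8,
  mayer_hz = 0.1, mayer_amp = 0.5,
  drift_sd = 0.8,
  hbr_noise_ratio = 0.4,
  instrument_od_sd = 0.003,
  bad_channel_noise_mult = 8,
  hbr_lag_s = 1,
  artifact_channel_fraction = 0.2,
  phase_diffusion = 0.04   # rad^2/s; oscillation coherence time ~1 min
)

#' Simulate one subject's raw fNIRS recording
#'
#' Generates a raw 3-wavelength intensity recording with known ground truth.
#' Responders receive a planted HbO response (task boxcar convolved with the
#' canonical HRF, normalised to peak `hbo_amplitude`) on all motor-ROI
#' channels, with an HbR response `hbr_ratio` times the HbO response delayed
#' by 1 s. Physiological noise (cardiac ~1.1 Hz, respiratory ~0.25 Hz, Mayer
#' waves ~0.1 Hz, 1/f drift) is added per channel in concentration space,
#' mapped to optical density with the same modified Beer-Lambert forward model
#' the preprocessing inverts, spiked with Poisson-timed motion artifacts
#' (one-sample spikes and persistent baseline shifts, in OD units), and
#' exponentiated into strictly positive detector intensities.
#'
#' @param profile A [subject_profile()].
#' @param schedule A [build_schedule()] paradigm.
#' @param montage A [build_montage()] montage.
#' @param seed Integer seed; required (reproducibility contract).
#' @return A list with elements `recording` (class `fnirs_raw`) and `truth`
#'   (class `ground_truth`: `responder`, `response_channels`, `planted_hbo`,
#'   `planted_hbr`, `artifact_index`, `artifact_type`).
#' @export
simulate_subject <- function(profile, schedule = build_schedule(),
                             montage = build_montage(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("simulate_subject requires an explicit seed", call. = FALSE)
  }
  stopifnot(inherits(profile, "subject_profile"))
  with_local_seed(seed, {
    fs <- montage$sampling_rate_hz
    n <- round(schedule$total_duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    nd <- .noise_defaults
    n_ch <- length(montage$channel_ids)

    # planted response (umol/L), identical on every motor-ROI channel
    roi_map <- build_roi_map()
    motor_ch <- sort(unlist(roi_map[motor_rois()], use.names = FALSE))
    planted_hbo <- numeric(n)
    if (profile$responder && profile$hbo_amplitude > 0) {
      boxcar <- numeric(n)
      ev <- schedule$events[schedule$events$condition == "task", ]
      for (k in seq_len(nrow(ev))) {
        i0 <- time_to_sample(ev$onset_s[k], fs)
        i1 <- min(n, time_to_sample(ev$onset_s[k] + ev$duration_s[k], fs) - 1L)
        boxcar[i0:i1] <- 1
      }
      h <- canonical_hrf(seq(0, 30, by = 1 / fs))
      r <- stats::convolve(boxcar, rev(h), type = "open")[seq_len(n)] / fs
      if (max(r) > 0) r <- r / max(r)
      planted_hbo <- profile$hbo_amplitude * r
    }
    lag <- round(nd$hbr_lag_s * fs)
    planted_hbr <- profile$hbr_ratio *
      c(numeric(lag), planted_hbo[seq_len(n - lag)])

    # concentration-space noise, independent per channel: quasi-periodic
    # cardiac/respiratory/Mayer oscillations plus 1/f drift, HbR at reduced
    # amplitude. Each oscillation carries a random phase walk (finite
    # coherence time): physiological rhythms are not phase-locked to the
    # paradigm, which is exactly why block averaging raises response SNR.
    freqs <- c(nd$cardiac_hz, nd$resp_hz, nd$mayer_hz)
    amps <- c(nd$cardiac_amp, nd$resp_amp, nd$mayer_amp)
    sin_noise <- function() {
      out <- matrix(0, n, n_ch)
      for (j in seq_along(freqs)) {
        dphi <- matrix(stats::rnorm(n * n_ch, 0,
                                    sqrt(nd$phase_diffusion / fs)), n, n_ch)
        phase <- apply(dphi, 2, cumsum) +
          rep(stats::runif(n_ch, 0, 2 * pi), each = n)
        out <- out + amps[j] * sin(2 * pi * freqs[j] * tt + phase)
      }
      out
    }
    drift_noise <- function() {
      W <- matrix(stats::rnorm(n * n_ch), n, n_ch)
      f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
      f <- pmin(f, fs - f)
      shape <- 1 / sqrt(pmax(f, 0.005))
      shape[1] <- 0
      D <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / n
      sds <- apply(D, 2, stats::sd)
      sds[sds == 0] <- 1
      nd$drift_sd * sweep(D, 2, sds, "/")
    }
    scale_ch <- rep(profile$noise_scale, n_ch)
    scale_ch[profile$bad_channel_ids] <-
      scale_ch[profile$bad_channel_ids] * nd$bad_channel_noise_mult
    hbo <- t(sweep(sin_noise() + drift_noise(), 2, scale_ch, "*"))
    hbr <- nd$hbr_noise_ratio *
      t(sweep(sin_noise() + drift_noise(), 2, scale_ch, "*"))
    if (profile$responder) {
      hbo[motor_ch, ] <- sweep(hbo[motor_ch, , drop = FALSE], 2, planted_hbo, "+")
      hbr[motor_ch, ] <- sweep(hbr[motor_ch, , drop = FALSE], 2, planted_hbr, "+")
    }

    # forward modified Beer-Lambert: concentrations (umol/L) -> delta-OD
    E <- mbll_design_matrix(montage$wavelengths_nm,
                            dpf = 6.0,
                            distance_cm = montage$source_detector_distance_cm[1])
    od <- array(0, dim = c(n_ch, length(montage$wavelengths_nm), n))
    for (w in seq_along(montage$wavelengths_nm)) {
      od[, w, ] <- E[w, 1] * hbo + E[w, 2] * hbr
      if (profile$noise_scale > 0) {
        od[, w, ] <- od[, w, ] + profile$noise_scale * nd$instrument_od_sd *
          matrix(stats::rnorm(n_ch * n), n_ch, n)
      }
    }

    # motion artifacts: global events, OD units, all channels/wavelengths
    artifact_index <- integer(0)
    artifact_type <- character(0)
    if (profile$artifact_rate > 0) {
      n_events <- stats::rpois(1, profile$artifact_rate *
                                 schedule$total_duration_s / 60)
      if (n_events > 0) {
        at <- sort(sample.int(n, n_events))
        types <- sample(c("spike", "shift"), n_events, replace = TRUE)
        # each event disturbs a random subset of channels (loose optodes);
        # a whole-head persistent shift would fail every channel's CV screen
        n_hit <- max(1L, round(nd$artifact_channel_fraction * n_ch))
        for (k in seq_len(n_events)) {
          hit <- sample.int(n_ch, n_hit)
          sgn <- sample(c(-1, 1), 1)
          if (types[k] == "spike") {
            amp <- sgn * stats::runif(1, 0.5, 2.0)
            od[hit, , at[k]] <- od[hit, , at[k]] + amp
          } else {
            amp <- sgn * stats::runif(1, 0.2, 1.0)
            od[hit, , at[k]:n] <- od[hit, , at[k]:n] + amp
          }
        }
        artifact_index <- at
        artifact_type <- types
      }
    }

    # detector intensities: strictly positive by construction
    i0 <- matrix(stats::runif(n_ch * 3, 500, 2000), n_ch, 3)
    intensity <- array(0, dim = dim(od))
    for (w in seq_len(3)) intensity[, w, ] <- i0[, w] * 10^(-od[, w, ])
    dimnames(intensity) <- list(
      channel = montage$channel_ids,
      wavelength = montage$wavelengths_nm,
      NULL
    )

    recording <- structure(
      list(
        subject_id = profile$subject_id, intensity = intensity,
        sampling_rate_hz = fs, montage = montage, schedule = schedule
      ),
      class = "fnirs_raw"
    )
    truth <- structure(
      list(
        subject_id = profile$subject_id, responder = profile$responder,
        response_channels = if (profile$responder) motor_ch else integer(0),
        planted_hbo = planted_hbo, planted_hbr = planted_hbr,
        artifact_index = artifact_index, artifact_type = artifact_type,
        bad_channel_ids = profile$bad_channel_ids
      ),
      class = "ground_truth"
    )
    list(recording = recording, truth = truth)
  })
}

#' Planted concentration time course for one channel
#' @param truth A `ground_truth` object.
#' @param channel Channel id.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return Numeric vector (zero for channels without a planted response).
#' @export
planted_series <- function(truth, channel, chromophore = c("HbO", "HbR")) {
  chromophore <- match.arg(chromophore)
  series <- if (chromophore == "HbO") truth$planted_hbo else truth$planted_hbr
  if (channel %in% truth$response_channels) series else numeric(length(series))
}

#' Simulate a virtual cohort
#'
#' Builds subject profiles for a cohort of healthy controls and patients and
#' simulates each subject. HC and MCS+ subjects follow the command; a
#' `cmd_fraction` share (rounded to the nearest integer, chosen at random) of
#' VS/UWS and of MCS- subjects are planted responders, i.e. CMD cases.
#' Six-month GOS-E outcomes are drawn so that patient responders have an
#' elevated probability of a favorable outcome (GOS-E >= 4); a fraction of
#' patients is lost to follow-up (`gose_6mo = NA`).
#'
#' @param n_hc,n_mcs_plus,n_vs,n_mcs_minus Group sizes (>= 0).
#' @param cmd_fraction Proportion of VS/UWS and MCS- subjects planted as CMD.
#' @param seed Integer seed; required.
#' @param p_favorable_responder,p_favorable_nonresponder Probability of a
#'   favorable 6-month outcome for patient responders / non-responders.
#' @param p_lost_followup Probability that a patient's GOS-E is missing.
#' @param simulate Logical; if `FALSE`, only profiles are generated (cheap,
#'   useful for streaming large cohorts subject-by-subject).
#' @param ... Passed to [subject_profile()] (e.g. `noise_scale`,
#'   `hbo_amplitude`, `artifact_rate`).
#' @return A list of class `fnirs_cohort`; each element has `profile`, `seed`
#'   and (when `simulate = TRUE`) `recording` and `truth`.
#' @export
simulate_cohort <- function(n_hc, n_mcs_plus, n_vs, n_mcs_minus,
                            cmd_fraction = 0, seed,
                            p_favorable_responder = 0.45,
                            p_favorable_nonresponder = 0.05,
                            p_lost_followup = 0.1,
                            simulate = TRUE, ...) {
  if (missing(seed) || is.null(seed)) {
    stop("simulate_cohort requires an explicit seed", call. = FALSE)
  }
  stopifnot(n_hc >= 0, n_mcs_plus >= 0, n_vs >= 0, n_mcs_minus >= 0,
            cmd_fraction >= 0, cmd_fraction <= 1)
  profiles <- with_local_seed(seed, {
    mk_group <- function(n, diagnosis, prefix, responders) {
      lapply(seq_len(n), function(i) {
        resp <- responders[i]
        gose <- NA_integer_
        if (diagnosis != "HC") {
          if (stats::runif(1) >= p_lost_followup) {
            fav <- stats::runif(1) < (if (resp) p_favorable_responder
                                      else p_favorable_nonresponder)
            gose <- if (fav) sample(4:8, 1) else sample(1:3, 1)
          }
        }
        subject_profile(sprintf("%s%03d", prefix, i), diagnosis = diagnosis,
                        responder = resp, gose_6mo = gose, ...)
      })
    }
    plant <- function(n) {
      k <- round(cmd_fraction * n)
      resp <- rep(FALSE, n)
      if (k > 0) resp[sample.int(n, k)] <- TRUE
      resp
    }
    c(
      mk_group(n_hc, "HC", "HC", rep(TRUE, n_hc)),
      mk_group(n_mcs_plus, "MCS+", "MCSP", rep(TRUE, n_mcs_plus)),
      mk_group(n_vs, "VS/UWS", "VS", plant(n_vs)),
      mk_group(n_mcs_minus, "MCS-", "MCSM", plant(n_mcs_minus))
    )
  })
  subject_seeds <- with_local_seed(seed + 1L, {
    sample.int(.Machine$integer.max, length(profiles))
  })
  cohort <- lapply(seq_along(profiles), function(i) {
    entry <- list(profile = profiles[[i]], seed = subject_seeds[i])
    if (simulate) {
      sim <- simulate_subject(profiles[[i]], seed = subject_seeds[i])
      entry$recording <- sim$recording
      entry$truth <- sim$truth
    }
    entry
  })
  structure(cohort, class = "fnirs_cohort")
}

#' Cohort metadata table
#' @param cohort A `fnirs_cohort`.
#' @return Data frame with `subject_id`, `diagnosis`, `responder` (planted
#'   ground truth) and `gose_6mo`.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(
      subject_id = s$profile$subject_id, diagnosis = s$profile$diagnosis,
      responder = s$profile$responder, gose_6mo = s$profile$gose_6mo,
      stringsAsFactors = FALSE
    )
  }))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
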