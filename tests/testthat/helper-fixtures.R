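# Shared fixtures, all built in code.

# Wide feature table for one ROI with a controllable class separation
# (units of the within-class SD).
make_feature_table <- function(n_subjects = 30, separation = 2, roi = "LPMC",
                               seed = 1) {
  set.seed(seed)
  cols <- c(paste0("HbO_", feature_names()), paste0("HbR_", feature_names()))
  rows <- lapply(seq_len(n_subjects), function(i) {
    one <- function(cond) {
      shift <- if (cond == "imagery") separation else 0
      v <- stats::rnorm(length(cols), shift, 1)
      names(v) <- cols
      cbind(
        data.frame(subject_id = sprintf("S%02d", i), roi = roi,
                   condition = cond,
                   label = if (cond == "imagery") 1L else 0L,
                   stringsAsFactors = FALSE),
        as.data.frame(t(v))
      )
    }
    rbind(one("imagery"), one("rest"))
  })
  do.call(rbind, rows)
}

# Short paradigm + quiet subject for fast preprocessing tests.
quiet_subject <- function(responder = TRUE, noise_scale = 1,
                          artifact_rate = 0, seed = 7, ...) {
  profile <- subject_profile("T01", diagnosis = if (responder) "HC" else "VS/UWS",
                             responder = responder, noise_scale = noise_scale,
                             artifact_rate = artifact_rate, ...)
  simulate_subject(profile, seed = seed)
}

# A flat OD recording wrapper around a single constructed series, for
# motion-correction and filter tests.
od_from_series <- function(x, fs = 11) {
  arr <- array(0, dim = c(1, 3, length(x)))
  for (w in 1:3) arr[1, w, ] <- x
  structure(
    list(subject_id = "fix", od = arr, retained_channel_ids = 1L,
         sampling_rate_hz = fs, montage = build_montage(),
         schedule = build_schedule()),
    class = "fnirs_od"
  )
}

# Patient records for a fixed clinical-scale cohort: 19 MCS+ (13 responders),
# 28 VS/UWS (4 CMD), 16 MCS- (3 CMD); 6-month outcomes 3/4 favorable among
# CMD vs 1/31 among followed-up true DOC (5 of 37 lost to follow-up:
# 4 true VS/UWS, 1 true MCS-), 0/20 true VS/UWS, 1/11 true MCS-.
clinical_records <- function() {
  diagnosis <- c(rep("MCS+", 19), rep("VS/UWS", 28), rep("MCS-", 16))
  response <- c(rep(TRUE, 13), rep(FALSE, 6),          # MCS+
                rep(TRUE, 4), rep(FALSE, 24),          # VS/UWS
                rep(TRUE, 3), rep(FALSE, 13))          # MCS-
  gose <- c(
    rep(NA_integer_, 19),
    c(5, 4, 6, 2),                                     # CMD from VS/UWS
    c(rep(2L, 20), rep(NA_integer_, 4)),               # true VS/UWS
    c(3, 2, 2),                                        # CMD from MCS-
    c(4L, rep(2L, 11), NA_integer_)                    # true MCS-
  )
  subject_records(sprintf("P%02d", seq_along(diagnosis)), diagnosis,
                  response, gose)
}

# Exact-arithmetic two-sided Fisher oracle: integer numerators over the
# common denominator choose(n, c1); exact for totals <= 40 (all counts
# < 2^53). Independent of the package's dhyper-based enumeration.
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (min(r1, r2, c1, b + d) == 0) return(1.0)
  support <- max(0, c1 - r2):min(r1, c1)
  num <- choose(r1, support) * choose(r2, c1 - support)
  den <- choose(r1 + r2, c1)
  num_obs <- choose(r1, a) * choose(r2, c_)
  sum(num[num <= num_obs]) / den
}
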