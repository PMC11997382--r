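test_that("coefficient of variation matches the sigma/mu definition", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)  # sample SD 1, mean 2
  x <- stats::runif(50, 1, 2)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(numeric(0)), "empty")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

make_recording <- function(intensity) {
  structure(
    list(subject_id = "x", intensity = intensity, sampling_rate_hz = 11,
         montage = build_montage(), schedule = build_schedule()),
    class = "fnirs_raw"
  )
}

test_that("channel rejection is strict and per-wavelength", {
  n <- 1100
  ints <- array(100, dim = c(63, 3, n))
  # sinusoid of amplitude a on mean 100: CV = a/sqrt(2) percent
  tt <- seq_len(n)
  cv_wave <- function(cv_target) {
    100 + cv_target * sqrt(2) * sin(2 * pi * tt / 50)
  }
  for (ch in 1:63) for (w in 1:3) ints[ch, w, ] <- cv_wave(5)
  ints[7, 2, ] <- cv_wave(20)      # bad at a single wavelength
  ints[9, 1, ] <- cv_wave(15)      # near the threshold
  res <- reject_channels(make_recording(ints), threshold = 15.5)
  rejected <- unique(res$qc$channel[res$qc$rejected])
  expect_equal(rejected, 7)
  # rejection is strict: a channel whose CV equals the threshold exactly
  # is retained (set the threshold to the channel's own measured CV)
  cv9 <- max(res$qc$cv_percent[res$qc$channel == 9])
  expect_equal(cv9, 15, tolerance = 1e-2)
  res_eq <- reject_channels(make_recording(ints), threshold = cv9)
  expect_true(9 %in% res_eq$recording$retained_channel_ids)
  expect_false(7 %in% res_eq$recording$retained_channel_ids)
  # all channels bad is fatal
  for (ch in 1:63) for (w in 1:3) ints[ch, w, ] <- cv_wave(30)
  expect_error(reject_channels(make_recording(ints)), "unusable")
})

test_that("optical density references the temporal mean", {
  ints <- array(0, dim = c(63, 3, 2))
  ints[] <- 5
  rec <- make_recording(ints)
  rec$retained_channel_ids <- 1:63
  expect_true(all(to_optical_density(rec)$od == 0))
  ints[1, 1, ] <- c(1, 0.1)
  rec <- make_recording(ints)
  od <- to_optical_density(rec)$od[1, 1, ]
  expect_equal(od, c(-log10(1 / 0.55), -log10(0.1 / 0.55)), tolerance = 1e-12)
  # gain invariance
  rec2 <- make_recording(ints * 7)
  expect_equal(to_optical_density(rec2)$od, to_optical_density(rec)$od)
  ints[2, 1, 1] <- 0
  expect_error(to_optical_density(make_recording(ints)), "non-positive")
})

test_that("motion correction removes spikes and steps, passes clean data", {
  fs <- 11
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  clean <- 0.05 * sin(2 * pi * 0.05 * tt)
  res <- correct_motion(od_from_series(clean))
  expect_lt(max(abs(res$od$od[1, 1, ] - clean)), 1e-12)
  expect_equal(nrow(res$artifacts), 0)

  spike <- clean
  spike[1650] <- spike[1650] + 1.0
  res <- correct_motion(od_from_series(spike))
  expect_gt(nrow(res$artifacts), 0)
  expect_lt(abs(res$od$od[1, 1, 1650] - clean[1650]), 0.1)

  step <- clean
  step[1700:length(step)] <- step[1700:length(step)] + 0.8
  res <- correct_motion(od_from_series(step))
  before <- mean(res$od$od[1, 1, 1000:1500])
  after <- mean(res$od$od[1, 1, 1900:2400])
  expect_lt(abs(after - before), 0.05)
})

test_that("motion correction is idempotent on its own output", {
  fs <- 11
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  x <- 0.05 * sin(2 * pi * 0.05 * tt)
  x[700] <- x[700] + 1.2                      # spike
  x[2000:length(x)] <- x[2000:length(x)] + 0.6  # step
  once <- correct_motion(od_from_series(x))
  expect_gt(nrow(once$artifacts), 0)
  twice <- correct_motion(once$od)
  expect_equal(nrow(twice$artifacts), 0)      # second pass flags nothing
  expect_equal(twice$od$od, once$od$od)
})

test_that("band-pass keeps the analysis band and kills DC and cardiac", {
  fs <- 11
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  dc <- bandpass(od_from_series(rep(3, length(tt))))
  expect_lt(max(abs(dc$od)), 1e-6 * 3)
  inband <- bandpass(od_from_series(sin(2 * pi * 0.05 * tt)))
  mid <- seq(round(length(tt) * 0.25), round(length(tt) * 0.75))
  amp <- max(abs(inband$od[1, 1, mid]))
  expect_lt(abs(amp - 1), 0.05)
  cardiac <- bandpass(od_from_series(sin(2 * pi * 1.1 * tt)))
  expect_lt(max(abs(cardiac$od[1, 1, mid])), 0.1)
  expect_error(bandpass(od_from_series(tt), low = 0.1, high = 0.01),
               "invalid filter band")
})

test_that("band-pass output is zero-mean for arbitrary input", {
  set.seed(4)
  for (i in 1:5) {
    x <- stats::rnorm(3300) * 10^stats::runif(1, -2, 2)
    out <- bandpass(od_from_series(x))
    expect_lt(abs(mean(out$od[1, 1, ])), 1e-6 * stats::sd(x))
  }
})

test_that("MBLL inverts the forward model and matches a brute-force solve", {
  E <- cmdnirs:::mbll_design_matrix(c(703, 808, 850))
  mk_od <- function(conc_hbo, conc_hbr) {
    n <- length(conc_hbo)
    arr <- array(0, dim = c(1, 3, n))
    for (w in 1:3) arr[1, w, ] <- E[w, 1] * conc_hbo + E[w, 2] * conc_hbr
    structure(
      list(subject_id = "x", od = arr, retained_channel_ids = 1L,
           sampling_rate_hz = 11, montage = build_montage(),
           schedule = build_schedule()),
      class = "fnirs_od"
    )
  }
  z <- mbll(mk_od(numeric(5), numeric(5)))
  expect_true(all(z$hb == 0))
  hb1 <- mbll(mk_od(rep(1.0, 4), rep(-0.3, 4)))
  expect_lt(max(abs(hb1$hb[1, "HbO", ] - 1.0)), 1e-6)
  expect_lt(max(abs(hb1$hb[1, "HbR", ] + 0.3)), 1e-6)
  hb2 <- mbll(mk_od(rep(2.0, 4), rep(-0.6, 4)))
  expect_equal(hb2$hb, 2 * hb1$hb, tolerance = 1e-12)   # linearity

  # brute-force per-sample least squares oracle on random OD
  set.seed(8)
  od <- mk_od(stats::rnorm(20), stats::rnorm(20))
  od$od <- od$od + array(stats::rnorm(60, sd = 0.01), dim = dim(od$od))
  fast <- mbll(od)
  for (i in seq_len(20)) {
    ref <- stats::lsfit(E, od$od[1, , i], intercept = FALSE)$coefficients
    expect_lt(max(abs(fast$hb[1, , i] - ref)), 1e-10)
  }
})

test_that("preprocessing chain is deterministic and order-consistent", {
  sim <- quiet_subject(responder = TRUE, noise_scale = 0, seed = 17)
  cfg <- preprocess_config(motion = FALSE)
  a <- preprocess_chain(sim$recording, cfg)
  b <- preprocess_chain(sim$recording, cfg)
  expect_identical(a$hb$hb, b$hb$hb)

  # linear stages commute on noise-free input: filter-then-MBLL equals
  # MBLL-applied-to-filtered-OD by linearity (public order is fixed)
  od <- to_optical_density(reject_channels(sim$recording)$recording)
  route1 <- mbll(bandpass(od))$hb
  hb_first <- mbll(od)
  od_like <- od
  od_like$od <- hb_first$hb
  route2 <- bandpass(od_like)$od
  expect_lt(max(abs(route1 - route2)), 1e-9)
})

test_that("zero-signal simulation preprocesses to zero concentrations", {
  sim <- quiet_subject(responder = FALSE, noise_scale = 0, seed = 19)
  out <- preprocess_chain(sim$recording, preprocess_config(motion = FALSE))
  expect_lt(max(abs(out$hb$hb)), 1e-9)
})
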