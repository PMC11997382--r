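mk_hb <- function(series_list, fs = 11, schedule = build_schedule()) {
  # series_list: named by channel id, each a 2 x n matrix (HbO, HbR)
  ids <- as.integer(names(series_list))
  n <- ncol(series_list[[1]])
  hb <- array(0, dim = c(length(ids), 2, n),
              dimnames = list(ids, c("HbO", "HbR"), NULL))
  for (i in seq_along(ids)) hb[i, , ] <- series_list[[i]]
  structure(
    list(subject_id = "F", hb = hb, retained_channel_ids = ids,
         sampling_rate_hz = fs, montage = build_montage(),
         schedule = schedule),
    class = "fnirs_hb"
  )
}

test_that("ROI averaging is the unweighted channel mean", {
  n <- 3300
  one <- matrix(stats::rnorm(2 * n), 2)
  hb <- mk_hb(list(`54` = one, `55` = one * 0 + 1, `57` = one * 0 + 3))
  avg <- roi_average(hb, rois = "LM1")$LM1
  expect_equal(avg$n_channels_averaged, 3)
  expect_equal(avg$series, (one + 1 + 3) / 3, ignore_attr = TRUE)
  # single-channel ROI passes through; constant channels average exactly
  hb2 <- mk_hb(list(`54` = one, `55` = one))
  avg2 <- roi_average(hb2, rois = "LM1")$LM1
  expect_equal(avg2$series, one, ignore_attr = TRUE)
  expect_error(roi_average(mk_hb(list(`1` = one)), rois = "LM1"),
               "no retained channels")
})

test_that("epoching cuts 5 blocks of 496 samples aligned to task onsets", {
  n <- 3300
  series <- matrix(seq_len(2 * n), 2, byrow = TRUE)
  hb <- mk_hb(list(`54` = series))
  roi <- roi_average(hb, rois = "LM1")$LM1
  epochs <- epoch_blocks(roi)
  expect_length(epochs, 5)
  expect_true(all(vapply(epochs, function(e) ncol(e$series), 1L) == 496L))
  expect_equal(epochs[[1]]$time_s[1], -5)
  expect_equal(epochs[[1]]$time_s[496], 40)
  # epoch 1 starts at 45 s absolute = sample index round(45*11)+1
  expect_equal(unname(epochs[[1]]$series[1, 1]),
               series[1, time_to_sample(45, 11)])
  # translation equivariance: shifting the schedule by one block shifts
  # epoch content by exactly 40 s of samples
  shifted <- build_schedule(pre_baseline_s = 90)
  ep_shift <- epoch_blocks(roi, shifted)
  expect_equal(ep_shift[[1]]$series[1, ],
               epochs[[1]]$series[1, ] + round(40 * 11))
})

test_that("epoching fails when the recording cannot cover the epochs", {
  series <- matrix(1, 2, 500)
  hb <- mk_hb(list(`54` = series))
  roi <- roi_average(hb, rois = "LM1")$LM1
  expect_error(epoch_blocks(roi), "too short")
})

test_that("baseline correction zeroes the pre-task mean and is idempotent", {
  ep <- list(time_s = seq(-5, 40, by = 1 / 11),
             series = rbind(stats::rnorm(496, 3), stats::rnorm(496, -2)),
             roi_id = "LM1")
  bc <- baseline_correct(ep)
  sel <- bc$time_s >= -5 & bc$time_s < 0
  expect_lt(max(abs(rowMeans(bc$series[, sel]))), 1e-12)
  expect_equal(baseline_correct(bc)$series, bc$series)
  const <- ep
  const$series[] <- 7
  expect_true(all(abs(baseline_correct(const)$series) < 1e-12))
})

test_that("block averaging is the pointwise mean across epochs", {
  base <- list(time_s = 1:10, series = rbind(1:10, 10:1), roi_id = "LM1",
               baseline_corrected = TRUE)
  same <- block_average(list(base, base, base))
  expect_equal(same$series, base$series)
  expect_equal(same$n_blocks_averaged, 3)
  neg <- base
  neg$series <- -base$series
  expect_true(all(block_average(list(base, neg))$series == 0))
  short <- base
  short$series <- short$series[, 1:5]
  expect_error(block_average(list(base, short)), "length mismatch")
  # variance of the average of 5 iid unit-variance epochs ~ 1/5
  set.seed(12)
  ratios <- replicate(200, {
    eps <- lapply(1:5, function(i) {
      e <- base
      e$series <- matrix(stats::rnorm(200), 2)
      e
    })
    stats::var(as.vector(block_average(eps)$series))
  })
  expect_lt(abs(mean(ratios) - 1 / 5), 0.3 / 5)
})

test_that("window features match hand-computed values and conventions", {
  f <- window_features(c(0, 1, 2, 3, 4))
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["median"]], 2)
  expect_equal(f[["peak"]], 4)
  expect_equal(f[["peak_to_peak"]], 4)
  expect_equal(f[["variance"]], 2.5)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 1.7)          # m4/m2^2 = 6.8/4
  k <- window_features(rep(3, 10))
  expect_true(all(k[c("variance", "peak_to_peak", "skewness", "kurtosis")] == 0))
  x <- stats::rnorm(40)
  fx <- window_features(x)
  fn <- window_features(-x)
  expect_equal(fn[["mean"]], -fx[["mean"]])
  expect_equal(fn[["median"]], -fx[["median"]])
  expect_equal(fn[["skewness"]], -fx[["skewness"]])
  expect_equal(fn[["variance"]], fx[["variance"]])
  expect_equal(fn[["peak_to_peak"]], fx[["peak_to_peak"]])
})

test_that("imagery and rest windows index the schedule, not literal times", {
  # rest command onset = task onset + 20 s, so the rest feature window
  # [25, 40) in epoch time is 5-20 s after the rest command
  sched <- build_schedule()
  ev <- sched$events
  rest_onsets <- ev$onset_s[ev$condition == "rest"]
  expect_equal(rest_onsets - task_onsets(sched), rep(20, 5))
  ba <- structure(
    list(time_s = seq(-5, 40, by = 1 / 11),
         series = rbind(HbO = seq_len(496), HbR = -seq_len(496)),
         roi_id = "LM1", baseline_corrected = TRUE, n_blocks_averaged = 5L),
    class = "block_average"
  )
  rownames(ba$series) <- c("HbO", "HbR")
  fv <- extract_features(ba)
  task_sel <- ba$time_s >= 5 & ba$time_s < 20
  expect_equal(fv$HbO_mean[fv$condition == "imagery"],
               mean(ba$series["HbO", task_sel]))
  rest_sel <- ba$time_s >= 25 & ba$time_s < 40
  expect_equal(fv$HbO_mean[fv$condition == "rest"],
               mean(ba$series["HbO", rest_sel]))
  expect_equal(fv$label, c(1L, 0L))
  expect_error(extract_features(ba, task_window = c(100, 120)), "window")
})

test_that("noise-free responders separate cleanly; non-responders are null", {
  resp <- quiet_subject(responder = TRUE, noise_scale = 0, seed = 23)
  hb <- preprocess_chain(resp$recording, preprocess_config(motion = FALSE))$hb
  fx <- subject_features(hb, rois = c("LPMC", "RM1"))
  for (roi in c("LPMC", "RM1")) {
    im <- fx$HbO_mean[fx$roi == roi & fx$condition == "imagery"]
    re <- fx$HbO_mean[fx$roi == roi & fx$condition == "rest"]
    expect_gt(im, re)
  }
  null <- quiet_subject(responder = FALSE, noise_scale = 0, seed = 23)
  hb0 <- preprocess_chain(null$recording, preprocess_config(motion = FALSE))$hb
  fx0 <- subject_features(hb0, rois = "LPMC")
  expect_lt(max(abs(fx0$HbO_mean)), 1e-9)
  expect_lt(max(abs(fx0$HbR_mean)), 1e-9)
})

test_that("per-block feature mode yields one row pair per block", {
  sim <- quiet_subject(responder = TRUE, noise_scale = 0, seed = 29)
  hb <- preprocess_chain(sim$recording, preprocess_config(motion = FALSE))$hb
  fx <- subject_features(hb, rois = "LM1", mode = "per_block")
  expect_equal(nrow(fx), 10)                  # 5 blocks x 2 conditions
  expect_equal(sort(unique(fx$block)), 1:5)
  expect_true(all(fx$label[fx$condition == "imagery"] == 1L))
})
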