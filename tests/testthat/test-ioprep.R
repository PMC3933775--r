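test_that("band-pass keeps 10 Hz, suppresses 50 Hz and removes DC", {
  rate <- 1024
  t <- seq(0, 6, by = 1 / rate)
  eeg <- continuous_eeg(rbind(sin(2 * pi * 10 * t),
                              sin(2 * pi * 50 * t),
                              rep(5, length(t))), rate)
  out <- bandpass_notch(eeg)
  expect_equal(ncol(out$data), ncol(eeg$data))  # shape preserved
  mid <- seq(2 * rate, 4 * rate)                # avoid edge transients
  g10 <- sd(out$data[1, mid]) / sd(eeg$data[1, mid])
  g50 <- sd(out$data[2, mid]) / sd(eeg$data[2, mid])
  expect_gt(g10, 0.95); expect_lt(g10, 1.05)
  expect_lt(g50, 0.1)
  expect_lt(max(abs(out$data[3, ])), 1e-3 * 5)
})

test_that("band-pass is idempotent in the passband", {
  rate <- 512
  t <- seq(0, 6, by = 1 / rate)
  eeg <- continuous_eeg(matrix(sin(2 * pi * 10 * t), nrow = 1), rate)
  once <- bandpass_notch(eeg)
  twice <- bandpass_notch(once)
  mid <- seq(2 * rate, 4 * rate)
  ratio <- sd(twice$data[1, mid]) / sd(once$data[1, mid])
  expect_gt(ratio, 0.99); expect_lt(ratio, 1.01)
})

test_that("corner frequencies above Nyquist are rejected", {
  eeg <- continuous_eeg(matrix(rnorm(256), nrow = 1), 100)
  expect_error(bandpass_notch(eeg, high = 60), "Nyquist")
  expect_error(bandpass_notch(eeg, low = 0, high = 40), "low")
})

test_that("the default epoch window spans 922 samples at 1024 Hz", {
  eeg <- continuous_eeg(matrix(0, 2, 5000), 1024)
  ev <- data.frame(onset_sample = 2000, category = "animal")
  ep <- extract_epochs(eeg, ev, tmin = -0.1, tmax = 0.8)
  expect_equal(n_samples(ep), 922L)
  expect_equal(ep$times[1], -102 / 1024)
  expect_equal(ep$times[922], 819 / 1024)
})

test_that("zero events give an empty epoch set with valid metadata", {
  eeg <- continuous_eeg(matrix(0, 2, 2000), 1024)
  ev <- data.frame(onset_sample = integer(0), category = character(0))
  ep <- extract_epochs(eeg, ev)
  expect_equal(n_trials(ep), 0L)
  expect_equal(n_samples(ep), 922L)
  expect_equal(ep$rate, 1024)
})

test_that("epochs extracted from tiled continuous data equal the tiles", {
  rate <- 256
  idx <- topodecode:::epoch_index_grid(-0.1, 0.3, rate)
  tile <- matrix(rnorm(3 * length(idx)), nrow = 3)
  onsets <- c(300, 800, 1300)
  cont <- matrix(0, 3, 1700)
  for (o in onsets) cont[, o + idx] <- tile
  eeg <- continuous_eeg(cont, rate)
  ev <- data.frame(onset_sample = onsets, category = c("a", "b", "a"))
  ep <- extract_epochs(eeg, ev, tmin = -0.1, tmax = 0.3)
  for (i in 1:3) expect_equal(ep$data[i, , ], tile)
  expect_equal(ep$labels, c("a", "b", "a"))
})

test_that("events without full window support are skipped with a warning", {
  eeg <- continuous_eeg(matrix(rnorm(2 * 2000), 2), 1024)
  ev <- data.frame(onset_sample = c(50, 800), category = c("a", "b"))
  expect_warning(ep <- extract_epochs(eeg, ev), "skipped")
  expect_equal(n_trials(ep), 1L)
  expect_equal(ep$metadata$skipped_events, 1L)
})

test_that("artifact rejection removes exactly the exceeding trials", {
  ep <- toy_epochs(n_per = 5, noise_sd = 0.1)
  res0 <- reject_artifacts(ep, threshold = 100)
  expect_equal(n_trials(res0$epochs), 10L)
  expect_equal(sum(res0$report$n_rejected), 0L)

  ep$data[4, 2, 7] <- 150
  res1 <- reject_artifacts(ep, threshold = 100)
  expect_equal(res1$epochs$metadata$rejected_trials, 4L)
  expect_equal(n_trials(res1$epochs), 9L)
  expect_equal(res1$report$n_rejected[res1$report$condition == "A"], 1L)
  expect_equal(res1$report$fraction[res1$report$condition == "A"], 0.2)
})

test_that("rejection matches the injector's ground truth and is monotone", {
  des <- small_design(n_exemplars = 10, n_blocks = 5, repeats = 5)
  sched <- make_schedule(des, seed = 20)
  cfg <- sim_eeg_config(noise_sd = 1, common_component = NULL, eeg_rate = 64)
  ep <- simulate_epochs(sched, cfg, epoch_window = c(0, 0.25), seed = 21)
  art <- inject_artifacts(ep, rate = 0.1, amplitude = 150, seed = 22)
  res <- reject_artifacts(art, threshold = 100)
  expect_equal(res$epochs$metadata$rejected_trials,
               art$metadata$artifacts$selected)
  # monotone: higher threshold rejects no more trials
  n_rej <- vapply(c(50, 100, 140, 200), function(thr) {
    length(reject_artifacts(art, thr)$epochs$metadata$rejected_trials)
  }, integer(1))
  expect_true(all(diff(n_rej) <= 0))
})

test_that("rejecting every trial of a condition names it in the error", {
  ep <- toy_epochs(n_per = 3, noise_sd = 0.1)
  ep$data[ep$labels == "B", 1, 1] <- 500
  expect_error(reject_artifacts(ep, 100), "condition\\(s\\): B")
})

test_that("CV/V split has the protocol's arithmetic and is a disjoint cover", {
  ep <- simulate_recording(seed = 30, design = small_design(n_exemplars = 8,
                                                            n_blocks = 5))
  # 80 trials per condition
  sp <- split_cv_validation(ep, list(animal = "animal", human = "human"),
                            n_cv = 60, seed = 31)
  expect_equal(sum(sp$cv$labels == "animal"), 60L)
  expect_equal(sum(sp$cv$labels == "human"), 60L)
  expect_equal(sum(sp$v$labels == "animal"), 20L)
  expect_length(intersect(sp$indices$cv, sp$indices$v), 0)
  expect_setequal(c(sp$indices$cv, sp$indices$v),
                  which(ep$labels %in% c("animal", "human")))
})

test_that("too few accepted trials excludes the recording", {
  ep <- toy_epochs(n_per = 59, n_channels = 4, n_samples = 8)
  expect_error(split_cv_validation(ep, list(A = "A", B = "B"), n_cv = 60,
                                   seed = 1),
               "recording excluded")
  ep61 <- toy_epochs(n_per = 61, n_channels = 4, n_samples = 8)
  expect_warning(sp <- split_cv_validation(ep61, list(A = "A", B = "B"),
                                           n_cv = 60, seed = 1),
                 "fewer than 20")
  expect_equal(n_trials(sp$v), 2L)
})

test_that("the split is deterministic given the seed", {
  ep <- toy_epochs(n_per = 30, n_channels = 4, n_samples = 8)
  s1 <- suppressWarnings(split_cv_validation(ep, list(A = "A", B = "B"),
                                             n_cv = 20, seed = 99))
  s2 <- suppressWarnings(split_cv_validation(ep, list(A = "A", B = "B"),
                                             n_cv = 20, seed = 99))
  expect_identical(s1$indices, s2$indices)
})

test_that("label-set pairs pool raw categories into decoding conditions", {
  ep <- simulate_recording(seed = 40, design = small_design(n_exemplars = 2,
                                                            n_blocks = 2))
  sp <- suppressWarnings(split_cv_validation(
    ep, list(living = c("animal", "human"), manmade = "manmade"),
    n_cv = 3, seed = 41))
  expect_setequal(unique(sp$cv$labels), c("living", "manmade"))
})

test_that("EDF files round-trip within quantization accuracy", {
  ce <- continuous_eeg(matrix(rnorm(5 * 700, sd = 30), 5), 256,
                       c("Fp1", "Fp2", "Cz", "O1", "O2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(ce, path)
  back <- read_edf(path)
  expect_equal(back$rate, 256)
  expect_identical(back$channels, ce$channels)
  expect_lt(max(abs(back$data[, 1:700] - ce$data)), 0.01)
  # zero-padded record tail survives at quantization accuracy
  expect_lt(max(abs(back$data[, 701:ncol(back$data)])), 0.01)
})

test_that("the epoch container round-trips data, labels and time axis", {
  ep <- toy_epochs(n_per = 4, n_channels = 5, n_samples = 16)
  dir <- withr::local_tempdir()
  write_epochs(ep, dir)
  back <- read_epochs(dir)
  expect_lt(max(abs(back$data - ep$data)), 1e-5)  # float32 storage
  expect_identical(back$labels, ep$labels)
  expect_equal(back$times, ep$times)
  expect_equal(back$rate, ep$rate)
})
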