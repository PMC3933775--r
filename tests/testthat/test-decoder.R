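test_that("a single-component fit recovers the grand-mean topography", {
  ep <- toy_epochs(n_per = 10, n_channels = 5, n_samples = 20,
                   mu_a = 1:5, mu_b = 1:5, seed = 2)
  g <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "A"),
                                          K = 1))
  X <- topodecode:::pool_topographies(subset_trials(ep, ep$labels == "A"))
  expect_equal(as.numeric(g$means), colMeans(X), tolerance = 1e-9)
  expect_equal(g$weights, 1)
})

test_that("EM recovers a well-separated two-component mixture", {
  set.seed(7)
  d <- 6
  mu1 <- c(rep(3, 3), rep(-3, 3))
  mu2 <- -mu1
  X <- rbind(
    matrix(rnorm(400 * d), ncol = d) + matrix(mu1, 400, d, byrow = TRUE),
    matrix(rnorm(400 * d), ncol = d) + matrix(mu2, 400, d, byrow = TRUE)
  )
  fit <- topodecode:::fit_gmm(X, 2)
  sep <- sqrt(sum((mu1 - mu2)^2))
  err <- min(sqrt(sum((fit$means[1, ] - mu1)^2)) + sqrt(sum((fit$means[2, ] - mu2)^2)),
             sqrt(sum((fit$means[1, ] - mu2)^2)) + sqrt(sum((fit$means[2, ] - mu1)^2)))
  expect_lt(err / 2, 0.1 * sep)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  # agrees with an independent EM implementation up to local optima
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01 * abs(mc$loglik))
})

test_that("the EM log-likelihood trace is non-decreasing", {
  set.seed(8)
  X <- matrix(rnorm(3000), ncol = 5) + rep(c(0, 4), each = 300)
  fit <- topodecode:::fit_gmm(X, 3)
  expect_true(all(diff(fit$ll_trace) >= -1e-6 * abs(fit$loglik)))
})

test_that("identical models give zero discrimination everywhere", {
  ep <- toy_epochs(n_per = 6, n_channels = 5, n_samples = 16, seed = 3)
  g <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "A"), 1))
  g2 <- g
  g2$condition <- "B"
  D <- discrimination_score(g, g2, ep, cond_a = "A", cond_b = "B")
  expect_true(all(abs(D) < 1e-12))
})

test_that("swapping the conditions negates D(t) exactly", {
  ep <- toy_epochs(n_per = 8, n_channels = 5, n_samples = 16,
                   mu_a = c(1, 0, 0, 0, -1), mu_b = c(-1, 0, 0, 0, 1), seed = 4)
  ga <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "A"), 1))
  gb <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "B"), 1))
  D1 <- discrimination_score(ga, gb, ep, cond_a = "A", cond_b = "B")
  # swapping the condition labels (keeping the models) negates D exactly
  D2 <- discrimination_score(ga, gb, ep, cond_a = "B", cond_b = "A")
  expect_equal(as.numeric(D1), -as.numeric(D2), tolerance = 1e-12)
})

test_that("LLRs are invariant to a common offset across channels", {
  ep <- toy_epochs(n_per = 6, n_channels = 5, n_samples = 12,
                   mu_a = c(2, 0, 0, 0, -2), seed = 5)
  ga <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "A"), 1))
  gb <- suppressWarnings(fit_condition_gmm(subset_trials(ep, ep$labels == "B"), 1))
  shifted <- ep
  shifted$data <- ep$data + 57.3  # common reference shift
  D1 <- discrimination_score(ga, gb, ep, cond_a = "A", cond_b = "B")
  D2 <- discrimination_score(ga, gb, shifted, cond_a = "A", cond_b = "B")
  expect_equal(as.numeric(D1), as.numeric(D2), tolerance = 1e-9)
})

test_that("D(t) peaks inside a high-SNR synthetic effect window", {
  ep <- simulate_recording(seed = 50, separation = 6,
                           design = small_design(n_exemplars = 5, n_blocks = 3),
                           window = c(0.30, 0.40))
  ep <- subset_trials(ep, ep$labels %in% c("animal", "human"))
  ep <- decimate_epochs(ep, 4)
  ga <- fit_condition_gmm(subset_trials(ep, ep$labels == "animal"), 2)
  gb <- fit_condition_gmm(subset_trials(ep, ep$labels == "human"), 2)
  D <- discrimination_score(ga, gb, ep, cond_a = "animal", cond_b = "human")
  peak_t <- ep$times[which.max(D)]
  expect_gte(peak_t, 0.30)
  expect_lte(peak_t, 0.40)
})

test_that("period selection: constant input falls back to earliest window", {
  times <- (0:99) / 100
  p <- select_periods(rep(1, 100), times, min_duration = 0.05)
  expect_true(p$fallback)
  expect_equal(nrow(p$windows), 1L)
  expect_equal(p$windows$start_idx, 1L)  # earliest index on total tie
  expect_equal(p$windows$end_idx, 5L)
})

test_that("period selection reproduces a boxcar bump", {
  times <- (0:999) / 1000
  D <- rep(0, 1000)
  D[301:400] <- 1  # 100 ms bump on a flat floor
  p <- select_periods(D, times, threshold_quantile = 0.9, min_duration = 0.02)
  expect_false(p$fallback)
  expect_equal(nrow(p$windows), 1L)
  expect_lte(abs(p$windows$start_idx - 301L), 1)
  expect_lte(abs(p$windows$end_idx - 400L), 1)
})

test_that("period selection agrees with the brute-force run scan", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    D <- rnorm(n)
    times <- (seq_len(n) - 1) / 256
    tq <- sample(c(0.8, 0.9, 0.95), 1)
    md <- sample(c(0.01, 0.02, 0.05), 1)
    got <- select_periods(D, times, threshold_quantile = tq, min_duration = md)
    want <- periods_oracle(D, times, tq, md)
    expect_equal(as.matrix(got$windows[, c("start_idx", "end_idx")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("min_duration longer than the epoch errors", {
  expect_error(select_periods(rnorm(10), (0:9) / 100, min_duration = 1),
               "epoch length")
})

test_that("AUC matches exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0.9, 0.2, 0.8, 0.4), c("A", "B", "B", "A"),
                   positive = "A"), 0.75)
  expect_equal(auc(c(5, 4, 3), c("A", "A", "B"), positive = "A"), 1)
  expect_equal(auc(rep(1, 6), rep(c("A", "B"), 3), positive = "A"), 0.5)
  expect_error(auc(1:3, c("A", "A", "A")), "two classes")
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(4:20, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    lab <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    expect_equal(auc(sc, lab, positive = "A"), auc_oracle(sc, lab, "A"))
  }
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(40); lab <- rep(c("A", "B"), 20)
  expect_equal(auc(sc, lab, positive = "A"),
               as.numeric(suppressMessages(pROC::auc(lab, sc, levels = c("B", "A"),
                                                     direction = "<"))))
})

test_that("trials matching a template map score strongly positive", {
  d <- 5
  ga <- structure(list(K = 1L, means = matrix(c(2, -1, 0, 1, -2), 1),
                       vars = matrix(0.01, 1, d), weights = 1,
                       condition = "A"), class = "gmm_model")
  gb <- ga
  gb$means <- -ga$means
  gb$condition <- "B"
  times <- (0:9) / 100
  arr <- array(rep(as.numeric(ga$means), each = 1), dim = c(1, d, 10))
  for (s in 1:10) arr[1, , s] <- as.numeric(ga$means)
  ep <- epoch_set(arr, "A", times, 100)
  dec <- structure(list(gmm_a = ga, gmm_b = gb,
                        periods = select_periods(c(rep(0, 9), 1), times,
                                                 min_duration = 0.01),
                        decimation = 1, rate = 100,
                        channels = ep$channels, conditions = c("A", "B")),
                   class = "trained_decoder")
  sc <- classify_trials(dec, ep)
  expect_gt(sc, 0)
  # one-timepoint H: the score is that single LLR
  X <- topodecode:::average_reference(matrix(arr[1, , 10], 1))
  llr1 <- topodecode:::gmm_logdens(ga, X) - topodecode:::gmm_logdens(gb, X)
  expect_equal(sc, as.numeric(llr1))
})

test_that("label-swapped decoders negate every trial score", {
  ep <- toy_epochs(n_per = 10, n_channels = 6, n_samples = 20,
                   mu_a = c(1, 1, 0, 0, -1, -1), mu_b = c(-1, -1, 0, 0, 1, 1),
                   seed = 6)
  dec <- suppressWarnings(cross_validate(ep, K_grid = 1, n_folds = 2,
                                         seed = 7, decimation = 1))
  swapped <- dec
  swapped$gmm_a <- dec$gmm_b
  swapped$gmm_b <- dec$gmm_a
  swapped$conditions <- rev(dec$conditions)
  test_ep <- toy_epochs(n_per = 10, n_channels = 6, n_samples = 20,
                        mu_a = c(1, 1, 0, 0, -1, -1),
                        mu_b = c(-1, -1, 0, 0, 1, 1), seed = 8)
  s1 <- classify_trials(dec, test_ep)
  s2 <- classify_trials(swapped, test_ep)
  expect_equal(s1, -s2, tolerance = 1e-9)
  expect_equal(auc(s1, test_ep$labels, positive = "A"),
               1 - auc(s2, test_ep$labels, positive = "A"))
})

test_that("cross-validation folds partition the CV set stratified by label", {
  ep <- toy_epochs(n_per = 13, n_channels = 4, n_samples = 10, seed = 9)
  set.seed(10)
  folds <- topodecode:::stratified_folds(ep$labels, 6)
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_len(n_trials(ep)))
  expect_equal(sum(duplicated(unlist(folds))), 0L)
  per_cond <- sapply(folds, function(f) c(sum(ep$labels[f] == "A"),
                                          sum(ep$labels[f] == "B")))
  expect_lte(max(per_cond[1, ]) - min(per_cond[1, ]), 1)
  expect_lte(max(per_cond[2, ]) - min(per_cond[2, ]), 1)
})

test_that("a singleton K grid is selected trivially", {
  ep <- toy_epochs(n_per = 8, n_channels = 4, n_samples = 12, seed = 10)
  dec <- suppressWarnings(cross_validate(ep, K_grid = 1, n_folds = 4,
                                         seed = 11, decimation = 1))
  expect_equal(dec$K_selected, 1L)
  expect_error(suppressWarnings(cross_validate(ep, K_grid = integer(0))),
               "non-empty")
})

test_that("cross-validated AUC is high for a strong synthetic effect", {
  ep <- simulate_recording(seed = 60, separation = 4,
                           design = small_design(n_exemplars = 6, n_blocks = 5))
  sp <- suppressWarnings(split_cv_validation(
    ep, list(animal = "animal", human = "human"), n_cv = 50, seed = 61))
  dec <- cross_validate(sp$cv, K_grid = 1:2, n_folds = 6, seed = 62)
  expect_gte(dec$cv_auc, 0.9)
  # and the decoder transfers to the held-out validation trials
  v_auc <- auc(classify_trials(dec, sp$v), sp$v$labels, positive = "animal")
  expect_gte(v_auc, 0.9)
})

test_that("decoders are deterministic given the seed", {
  ep <- toy_epochs(n_per = 8, n_channels = 4, n_samples = 12, seed = 12)
  d1 <- suppressWarnings(cross_validate(ep, K_grid = 1:2, n_folds = 4,
                                        seed = 5, decimation = 1))
  d2 <- suppressWarnings(cross_validate(ep, K_grid = 1:2, n_folds = 4,
                                        seed = 5, decimation = 1))
  expect_identical(d1$fold_auc, d2$fold_auc)
  expect_equal(d1$gmm_a$means, d2$gmm_a$means)
})
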