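#' Per-timepoint discrimination score between two condition models
#'
#' For every trial and latency, the log-likelihood ratio
#' `LLR(t) = log p(x(t) | gmm_a) - log p(x(t) | gmm_b)` of the
#' average-referenced topography is computed; the discrimination score is
#' `D(t) = mean over condition-A trials of LLR(t) - mean over condition-B
#' trials of LLR(t)`. D(t) is large at latencies where the two sets of
#' template maps differ, and is exactly antisymmetric under swapping the
#' conditions.
#'
#' @param gmm_a,gmm_b [fit_condition_gmm()] models of the two conditions.
#' @param epochs An [epoch_set()] containing trials of both conditions.
#' @param cond_a,cond_b Labels identifying the two conditions; default the
#'   models' `condition` fields.
#' @return Numeric vector `D(t)` with attribute `times`.
#' @export
discrimination_score <- function(gmm_a, gmm_b, epochs,
                                 cond_a = gmm_a$condition,
                                 cond_b = gmm_b$condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!all(c(cond_a, cond_b) %in% epochs$labels)) {
    stop("both conditions must be present in `epochs`", call. = FALSE)
  }
  llr <- trial_time_llr(gmm_a, gmm_b, epochs)
  d <- rowMeans(llr[, epochs$labels == cond_a, drop = FALSE]) -
       rowMeans(llr[, epochs$labels == cond_b, drop = FALSE])
  attr(d, "times") <- epochs$times
  d
}

# samples x trials matrix of per-topography log-likelihood ratios.
trial_time_llr <- function(gmm_a, gmm_b, epochs) {
  X <- pool_topographies(epochs)
  matrix(gmm_logdens(gmm_a, X) - gmm_logdens(gmm_b, X),
         nrow = n_samples(epochs))
}

#' Select the discriminative periods H from a score trace
#'
#' H is the set of maximal runs of consecutive timepoints whose score
#' reaches the `threshold_quantile` quantile of `D`, keeping only runs at
#' least `min_duration` long. If no run qualifies (or `D` is constant, where
#' a top quantile is undefined), the fallback is the single `min_duration`
#' window centred on the earliest maximum of `D`.
#'
#' @param D Numeric score trace (e.g. from [discrimination_score()]).
#' @param times Time axis in seconds; defaults to `attr(D, "times")`.
#' @param threshold_quantile Quantile of `D` defining the exceedance
#'   threshold (default 0.9).
#' @param min_duration Minimum window duration in seconds (default 0.02).
#' @return An object of class `discriminative_periods`: list with `windows`
#'   (data frame `start_idx`, `end_idx`, `start_s`, `end_s`; half-open in
#'   time), `score`, `times`, `threshold`, `fallback`.
#' @export
select_periods <- function(D, times = attr(D, "times"),
                           threshold_quantile = 0.9, min_duration = 0.02) {
  force(times)
  D <- as.numeric(D)
  if (!all(is.finite(D))) stop("`D` must be finite", call. = FALSE)
  stopifnot(length(times) == length(D))
  dt <- median(diff(times))
  min_samples <- max(1L, as.integer(ceiling(min_duration / dt - 1e-9)))
  if (min_samples > length(D)) {
    stop("`min_duration` exceeds the epoch length", call. = FALSE)
  }

  windows <- NULL
  thr <- NA_real_
  fallback <- FALSE
  if (diff(range(D)) > 0) {
    thr <- quantile(D, threshold_quantile, names = FALSE)
    runs <- rle(D >= thr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sel <- runs$values & runs$lengths >= min_samples
    if (any(sel)) {
      windows <- data.frame(start_idx = starts[sel], end_idx = ends[sel])
    }
  }
  if (is.null(windows)) {
    fallback <- TRUE
    peak <- which.max(D)  # earliest maximum on ties
    start <- peak - (min_samples - 1L) %/% 2L
    start <- min(max(1L, start), length(D) - min_samples + 1L)
    windows <- data.frame(start_idx = start, end_idx = start + min_samples - 1L)
  }
  windows$start_s <- times[windows$start_idx]
  windows$end_s <- times[windows$end_idx] + dt
  structure(list(windows = windows, score = D, times = times,
                 threshold = thr, threshold_quantile = threshold_quantile,
                 min_duration = min_duration, fallback = fallback),
            class = "discriminative_periods")
}

#' @export
print.discriminative_periods <- function(x, ...) {
  cat(sprintf("discriminative_periods: %d window(s)%s\n", nrow(x$windows),
              if (x$fallback) " [fallback]" else ""))
  with(x$windows, cat(sprintf("  [%.3f, %.3f) s\n", start_s, end_s), sep = ""))
  invisible(x)
}

period_indices <- function(periods) {
  unlist(mapply(seq.int, periods$windows$start_idx, periods$windows$end_idx,
                SIMPLIFY = FALSE))
}

# Total H duration and its overlap with a reference interval, in seconds.
period_overlap <- function(periods, interval) {
  w <- periods$windows
  total <- sum(w$end_s - w$start_s)
  inside <- sum(pmax(0, pmin(w$end_s, interval[2]) - pmax(w$start_s, interval[1])))
  c(total = total, inside = inside)
}

#' Classify trials with a trained decoder
#'
#' Each trial's score is the sum over the discriminative periods H of its
#' topography log-likelihood ratios under the two condition models; positive
#' scores favour the decoder's first condition.
#'
#' @param decoder A [cross_validate()] result (`trained_decoder`).
#' @param epochs An [epoch_set()] sharing the decoder's channels and
#'   (pre-decimation) sampling rate.
#' @return Numeric per-trial scores.
#' @export
classify_trials <- function(decoder, epochs) {
  stopifnot(inherits(decoder, "trained_decoder"), inherits(epochs, "epoch_set"))
  if (!identical(epochs$channels, decoder$channels)) {
    stop("channel set does not match the decoder", call. = FALSE)
  }
  ep <- decimate_epochs(epochs, decoder$decimation)
  if (abs(ep$rate - decoder$rate) > 1e-9) {
    stop("sampling rate does not match the decoder", call. = FALSE)
  }
  llr <- trial_time_llr(decoder$gmm_a, decoder$gmm_b, ep)
  colSums(llr[period_indices(decoder$periods), , drop = FALSE])
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive-class score exceeds a random
#' negative-class score, ties counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels.
#' @param positive Label treated as the positive class (default: first
#'   label in sorted order).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("`labels` must contain exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- lev[1]
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Fit both condition GMMs and H on one (possibly relabelled) training set.
fit_pipeline <- function(epochs, labels, cond_a, cond_b, K,
                         threshold_quantile, min_duration, ...) {
  ep <- epochs
  ep$labels <- labels
  gmm_a <- fit_condition_gmm(subset_trials(ep, labels == cond_a), K, ...)
  gmm_a$condition <- cond_a
  gmm_b <- fit_condition_gmm(subset_trials(ep, labels == cond_b), K, ...)
  gmm_b$condition <- cond_b
  D <- discrimination_score(gmm_a, gmm_b, ep)
  periods <- select_periods(D, threshold_quantile = threshold_quantile,
                            min_duration = min_duration)
  list(gmm_a = gmm_a, gmm_b = gmm_b, periods = periods)
}

score_pipeline <- function(model, epochs) {
  llr <- trial_time_llr(model$gmm_a, model$gmm_b, epochs)
  colSums(llr[period_indices(model$periods), , drop = FALSE])
}

# Stratified non-overlapping folds: list of test-trial index vectors whose
# per-condition sizes differ by at most one.
stratified_folds <- function(labels, n_folds) {
  folds <- vector("list", n_folds)
  for (cn in unique(labels)) {
    idx <- sample(which(labels == cn))
    grp <- rep_len(seq_len(n_folds), length(idx))
    for (f in seq_len(n_folds)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

#' Train a topography decoder by k-fold cross-validation
#'
#' For each candidate number of Gaussians `K`, fits the two condition
#' mixtures and the discriminative periods H on the training folds and
#' measures the AUC of the summed-LLR classifier on the held-out fold, over
#' `n_folds` non-overlapping stratified folds. The `K` maximizing the mean
#' test AUC is selected (ties go to the smallest `K`) and the models and H
#' are refitted on the full CV set.
#'
#' @param cv An [epoch_set()] with exactly two condition labels (the CV
#'   dataset).
#' @param K_grid Candidate component counts (default 1..8).
#' @param n_folds Number of folds (default 6).
#' @param seed Integer seed (folds, k-means restarts).
#' @param decimation Temporal decimation factor applied before fitting and
#'   at classification time (default 4, e.g. 1024 -> 256 Hz).
#' @param threshold_quantile,min_duration Passed to [select_periods()].
#' @param ... Passed to [fit_condition_gmm()].
#' @return An object of class `trained_decoder`: the two `gmm_model`s, the
#'   `discriminative_periods`, `K_selected`, `cv_auc` (mean test AUC at the
#'   selected `K`), the per-`K` fold AUC matrix, the condition pair and the
#'   decimation.
#' @export
cross_validate <- function(cv, K_grid = 1:8, n_folds = 6, seed = NULL,
                           decimation = 4, threshold_quantile = 0.9,
                           min_duration = 0.02, ...) {
  stopifnot(inherits(cv, "epoch_set"), n_folds >= 2)
  if (length(K_grid) == 0) stop("`K_grid` must be non-empty", call. = FALSE)
  conds <- sort(unique(cv$labels))
  if (length(conds) != 2) stop("CV set must contain exactly two conditions", call. = FALSE)
  if (min(table(cv$labels)) < n_folds) {
    stop("each condition needs at least `n_folds` trials", call. = FALSE)
  }
  K_grid <- sort(unique(as.integer(K_grid)))
  ep <- decimate_epochs(cv, decimation)

  with_seed(seed, {
    folds <- stratified_folds(ep$labels, n_folds)
    fold_auc <- matrix(NA_real_, length(K_grid), n_folds,
                       dimnames = list(paste0("K", K_grid), NULL))
    for (ki in seq_along(K_grid)) {
      for (f in seq_len(n_folds)) {
        test <- folds[[f]]
        train <- subset_trials(ep, setdiff(seq_len(n_trials(ep)), test))
        model <- fit_pipeline(train, train$labels, conds[1], conds[2],
                              K_grid[ki], threshold_quantile, min_duration, ...)
        sc <- score_pipeline(model, subset_trials(ep, test))
        fold_auc[ki, f] <- auc(sc, ep$labels[test], positive = conds[1])
      }
    }
    mean_auc <- rowMeans(fold_auc)
    ki <- which.max(mean_auc)          # ties -> smallest K (sorted grid)
    final <- fit_pipeline(ep, ep$labels, conds[1], conds[2], K_grid[ki],
                          threshold_quantile, min_duration, ...)
    structure(
      list(gmm_a = final$gmm_a, gmm_b = final$gmm_b, periods = final$periods,
           K_selected = K_grid[ki], cv_auc = unname(mean_auc[ki]),
           fold_auc = fold_auc, K_grid = K_grid,
           conditions = conds, decimation = decimation,
           rate = ep$rate, channels = ep$channels,
           threshold_quantile = threshold_quantile,
           min_duration = min_duration),
      class = "trained_decoder"
    )
  })
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf(
    "trained_decoder: %s vs %s, K = %d (grid %s), CV AUC = %.3f, %d H window(s) @ %g Hz\n",
    x$conditions[1], x$conditions[2], x$K_selected,
    paste(range(x$K_grid), collapse = "-"), x$cv_auc,
    nrow(x$periods$windows), x$rate))
  invisible(x)
}

#' Export a trained decoder as JSON
#'
#' Writes the template maps, variances, weights and the H windows (ms) of
#' both condition models.
#'
#' @param decoder A `trained_decoder`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_decoder <- function(decoder, path) {
  out <- list(
    conditions = decoder$conditions, K = decoder$K_selected,
    cv_auc = decoder$cv_auc, decimation = decoder$decimation,
    rate = decoder$rate, channels = decoder$channels,
    gmm_a = decoder$gmm_a[c("means", "vars", "weights")],
    gmm_b = decoder$gmm_b[c("means", "vars", "weights")],
    h_windows_ms = data.frame(
      start = 1000 * decoder$periods$windows$start_s,
      end = 1000 * decoder$periods$windows$end_s
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
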