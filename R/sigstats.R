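#' One-sided Wilcoxon signed-rank p-value of true vs permuted AUCs
#'
#' Tests whether the differences `auc_true - auc_perm` have positive median
#' (the decoder outperforms its permutation null). Zero differences are
#' dropped; absolute values are midranked. For 25 or fewer non-zero
#' differences the p-value is exact (full enumeration of the sign-flip
#' distribution via a rank-sum recursion); above that a normal approximation
#' with tie correction and continuity correction is used. Being rank-based,
#' the p-value is invariant to any common monotone rescaling of the AUCs.
#'
#' @param auc_true Observed AUC (scalar).
#' @param auc_perm Numeric vector of permutation AUCs.
#' @return One-sided p-value, `P(W+ >= observed)` under the null.
#' @export
wilcoxon_signed_rank <- function(auc_true, auc_perm) {
  stopifnot(length(auc_true) == 1, length(auc_perm) >= 1)
  d <- auc_true - auc_perm
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(1)
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= 25) {
    # doubled midranks are integers; enumerate P(W+ >= w) by convolution
    r2 <- as.integer(round(2 * r))
    counts <- 1
    for (ri in r2) {
      padded <- c(counts, numeric(ri))
      counts <- padded + c(numeric(ri), counts)
    }
    w2 <- round(2 * w_obs)
    sum(counts[seq.int(w2 + 1L, length(counts))]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_obs - mu - 0.5) / sqrt(sig2)
    pnorm(z, lower.tail = FALSE)
  }
}

#' Smallest significant-count threshold of the group binomial test
#'
#' The group-level decision treats each of `n` comparisons as a Bernoulli
#' event with per-event chance probability `p_event` of reaching
#' significance, and asks for the smallest `k` such that observing `k` or
#' more significant comparisons has upper-tail probability at most
#' `alpha_group` (exact binomial tail).
#'
#' @param n Number of comparisons.
#' @param p_event Per-event chance significance probability, in (0, 1).
#' @param alpha_group Group-level significance level.
#' @return The smallest such `k` (possibly `n + 1` if no count suffices).
#' @export
min_significant_count <- function(n, p_event, alpha_group = 0.05) {
  stopifnot(n >= 1, p_event > 0, p_event < 1)
  for (k in 0:n) {
    tail <- pbinom(k - 1, n, p_event, lower.tail = FALSE)  # P(X >= k)
    if (tail <= alpha_group) return(as.integer(k))
  }
  as.integer(n + 1)
}

#' Validate a decoder against its label-permutation null
#'
#' Runs the true pipeline once (fit both condition mixtures and the
#' discriminative periods H on the CV set with `K` Gaussians, score the V
#' set) and then `n_perm` times with the CV labels randomly permuted,
#' refitting both mixtures and re-estimating H each time and scoring the
#' same V trials. Significance follows the signed-rank comparison of the
#' true AUC against the permutation AUCs; the mean permutation AUC is
#' reported as the chance level. The empirical permutation p-value
#' `p_perm = (1 + #{auc_perm >= auc_true}) / (n_perm + 1)` is also returned;
#' unlike the signed-rank p it is calibrated as a per-recording test.
#'
#' @param cv,v CV and validation [epoch_set()]s sharing the same two
#'   condition labels.
#' @param K Number of Gaussians per condition model (from
#'   [cross_validate()]'s `K_selected`; not re-selected per permutation).
#' @param n_perm Number of label permutations (default 200).
#' @param seed Integer seed.
#' @param alpha Significance level on the signed-rank p-value
#'   (default 0.001).
#' @param decimation,threshold_quantile,min_duration As in
#'   [cross_validate()]; applied identically to the true and permuted fits.
#' @param ... Passed to [fit_condition_gmm()].
#' @return An object of class `decoding_result`: `auc_true`, `auc_perm`,
#'   `chance_level`, `p_value` (signed-rank), `p_perm` (empirical),
#'   `significant`, `alpha`, `n_perm`, `seed`, `periods`.
#' @export
permutation_validate <- function(cv, v, K, n_perm = 200, seed = NULL,
                                 alpha = 0.001, decimation = 4,
                                 threshold_quantile = 0.9,
                                 min_duration = 0.02, ...) {
  stopifnot(inherits(cv, "epoch_set"), inherits(v, "epoch_set"))
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  if (n_trials(v) == 0) stop("validation set is empty", call. = FALSE)
  conds <- sort(unique(cv$labels))
  if (length(conds) != 2) stop("CV set must contain exactly two conditions", call. = FALSE)
  if (!all(v$labels %in% conds)) {
    stop("V labels must match the CV conditions", call. = FALSE)
  }
  cvd <- decimate_epochs(cv, decimation)
  vd <- decimate_epochs(v, decimation)

  with_seed(seed, {
    true_model <- fit_pipeline(cvd, cvd$labels, conds[1], conds[2], K,
                               threshold_quantile, min_duration, ...)
    auc_true <- auc(score_pipeline(true_model, vd), vd$labels,
                    positive = conds[1])
    auc_perm <- vapply(seq_len(n_perm), function(m) {
      perm <- sample(cvd$labels)
      model <- fit_pipeline(cvd, perm, conds[1], conds[2], K,
                            threshold_quantile, min_duration, ...)
      auc(score_pipeline(model, vd), vd$labels, positive = conds[1])
    }, numeric(1))
    p <- wilcoxon_signed_rank(auc_true, auc_perm)
    structure(
      list(auc_true = auc_true, auc_perm = auc_perm,
           chance_level = mean(auc_perm), p_value = p,
           p_perm = (1 + sum(auc_perm >= auc_true)) / (n_perm + 1),
           significant = p < alpha, alpha = alpha,
           n_perm = as.integer(n_perm), K = as.integer(K), seed = seed,
           conditions = conds, periods = true_model$periods),
      class = "decoding_result"
    )
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding_result: %s vs %s\n  AUC = %.3f (chance %.3f over %d permutations)\n  signed-rank p = %.3g (%ssignificant at alpha = %g); empirical p_perm = %.3g\n",
    x$conditions[1], x$conditions[2], x$auc_true, x$chance_level, x$n_perm,
    x$p_value, if (x$significant) "" else "not ", x$alpha, x$p_perm))
  invisible(x)
}

#' Write one-row decoding results table
#'
#' @param results A `decoding_result` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_decoding_results <- function(results, path) {
  if (inherits(results, "decoding_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(condition_a = r$conditions[1], condition_b = r$conditions[2],
               auc_true = r$auc_true, chance_level = r$chance_level,
               p_value = r$p_value, p_perm = r$p_perm,
               significant = r$significant, n_perm = r$n_perm)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled-subject (group-level) decoding
#'
#' Samples a fixed number of CV and V trials per condition from every
#' subject, pools them into one CV and one V set (a single pair of condition
#' mixtures across subjects), selects `K` by cross-validation on the pooled
#' CV set and validates against the permutation null. With the defaults and
#' 10 subjects this reproduces the pooled design of 200 CV and 40 V trials
#' per condition.
#'
#' @param subject_epochs List of [epoch_set()]s, one per subject, all
#'   labelled with the same two conditions.
#' @param n_cv_per_subject,n_v_per_subject Trials per condition drawn from
#'   each subject into the pooled CV and V sets (defaults 20 and 4).
#' @param seed Integer seed.
#' @param K_grid,n_folds,decimation,n_perm,alpha,... As in
#'   [cross_validate()] and [permutation_validate()].
#' @return A `decoding_result` with extra fields `K_selected`, `decoder`,
#'   `n_cv_pooled` and `n_v_pooled` (per condition).
#' @export
group_decode <- function(subject_epochs, n_cv_per_subject = 20,
                         n_v_per_subject = 4, seed = NULL, K_grid = 1:8,
                         n_folds = 6, decimation = 4, n_perm = 200,
                         alpha = 0.001, ...) {
  stopifnot(is.list(subject_epochs), length(subject_epochs) >= 1)
  conds <- sort(unique(subject_epochs[[1]]$labels))
  if (length(conds) != 2) stop("subjects must have exactly two conditions", call. = FALSE)
  per_subj <- n_cv_per_subject + n_v_per_subject

  with_seed(seed, {
    cv_parts <- v_parts <- vector("list", length(subject_epochs))
    for (s in seq_along(subject_epochs)) {
      ep <- subject_epochs[[s]]
      if (!identical(sort(unique(ep$labels)), conds)) {
        stop(sprintf("subject %d does not have conditions %s", s,
                     paste(conds, collapse = "/")), call. = FALSE)
      }
      cv_idx <- v_idx <- integer(0)
      for (cn in conds) {
        pool <- which(ep$labels == cn)
        if (length(pool) < per_subj) {
          stop(sprintf(
            "subject %d has %d \"%s\" trials; %d needed per condition",
            s, length(pool), cn, per_subj), call. = FALSE)
        }
        take <- sample(pool, per_subj)
        cv_idx <- c(cv_idx, take[seq_len(n_cv_per_subject)])
        v_idx <- c(v_idx, take[n_cv_per_subject + seq_len(n_v_per_subject)])
      }
      cv_parts[[s]] <- subset_trials(ep, cv_idx)
      v_parts[[s]] <- subset_trials(ep, v_idx)
    }
    cv <- bind_epochs(cv_parts)
    v <- bind_epochs(v_parts)
    decoder <- cross_validate(cv, K_grid = K_grid, n_folds = n_folds,
                              decimation = decimation, ...)
    res <- permutation_validate(cv, v, decoder$K_selected, n_perm = n_perm,
                                alpha = alpha, decimation = decimation, ...)
    res$K_selected <- decoder$K_selected
    res$decoder <- decoder
    res$n_cv_pooled <- table(cv$labels)
    res$n_v_pooled <- table(v$labels)
    res$seed <- seed
    res
  })
}

#' Concatenate epoch sets trial-wise
#'
#' All sets must share channels, times and rate.
#'
#' @param parts List of [epoch_set()]s.
#' @return A single [epoch_set()].
#' @export
bind_epochs <- function(parts) {
  stopifnot(length(parts) >= 1)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    stopifnot(identical(p$channels, ref$channels),
              isTRUE(all.equal(p$times, ref$times)), p$rate == ref$rate)
  }
  data <- array(0, dim = c(sum(vapply(parts, n_trials, integer(1))),
                           n_channels(ref), n_samples(ref)))
  at <- 0L
  for (p in parts) {
    data[at + seq_len(n_trials(p)), , ] <- p$data
    at <- at + n_trials(p)
  }
  epoch_set(data, unlist(lapply(parts, `[[`, "labels")), ref$times, ref$rate,
            ref$channels, metadata = list(log = "bind_epochs"))
}
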