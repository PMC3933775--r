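#' Global field power of a topography
#'
#' The spatial standard deviation of a scalp map: the root mean square of
#' the channel values around their mean. Reference-free and invariant to
#' adding a constant across channels.
#'
#' @param map Numeric vector of channel values (microvolts), or a
#'   `channels x n` matrix (one GFP per column).
#' @return GFP in microvolts (scalar or per-column vector).
#' @export
gfp <- function(map) {
  if (is.matrix(map)) {
    if (nrow(map) < 2) stop("GFP requires at least two channels", call. = FALSE)
    cm <- colMeans(map)
    return(sqrt(colMeans(sweep(map, 2, cm)^2)))
  }
  if (length(map) < 2) stop("GFP requires at least two channels", call. = FALSE)
  sqrt(mean((map - mean(map))^2))
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure: sort the p-values, find the largest `i` with
#' `p_(i) <= (i/m) q`, and flag every p-value at or below `p_(i)`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return Logical mask, `TRUE` where the null is rejected.
#' @export
fdr_mask <- function(p, q) {
  if (length(p) == 0) stop("`p` must be non-empty", call. = FALSE)
  stopifnot(all(p > 0), all(p <= 1))
  stop_if_not_scalar_prob(q, "q")
  p.adjust(p, method = "BH") <= q
}

#' Topographic consistency test (TCT)
#'
#' Detects the latencies at which the voltage topography is consistent
#' across trials of one condition. At every timepoint, the observed GFP of
#' the trial-average map is compared against a null built by shuffling each
#' trial's values across electrodes (independently per trial and per
#' randomization), averaging across trials, and taking the GFP; a
#' consistent topography survives averaging while shuffled ones cancel.
#' `p(t) = (1 + #{GFP_null >= GFP_obs}) / (n_rand + 1)`; significance is
#' controlled by Benjamini-Hochberg FDR at `fdr_q`, and a separate display
#' mask flags `1 - p > 0.999` (attainable only when `n_rand >= 999`).
#'
#' @param epochs An [epoch_set()] of one condition (at least 2 trials).
#' @param n_rand Number of electrode-shuffling randomizations (>= 100,
#'   default 1000).
#' @param fdr_q FDR level (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `tct_result`: `gfp_observed`, `p`,
#'   `significant_mask`, `display_mask`, `times`, `n_rand`, `fdr_q`, `seed`,
#'   and `significant_runs` (data frame of significant time ranges, with an
#'   `n100_band` flag marking overlap with 100 +/- 50 ms).
#' @export
run_tct <- function(epochs, n_rand = 1000, fdr_q = 0.05, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_trials(epochs) < 2) stop("TCT requires at least 2 trials", call. = FALSE)
  if (n_rand < 100) stop("`n_rand` must be at least 100", call. = FALSE)
  nt <- n_trials(epochs)
  nc <- n_channels(epochs)
  ns <- n_samples(epochs)

  gfp_obs <- gfp(colMeans(epochs$data))  # mean over trials: nc x ns matrix
  exceed <- integer(ns)
  with_seed(seed, {
    group <- rep(seq_len(nt * n_rand), each = nc)
    for (s in seq_len(ns)) {
      m <- epochs$data[, , s]                       # nt x nc
      # one permutation of the channels of every (trial, randomization):
      # order random keys within each group of nc values
      ord <- order(group, runif(nt * n_rand * nc))
      pos <- (ord - 1L) %% nc + 1L                  # permuted channel index
      tri <- rep(rep(seq_len(nt), each = nc), n_rand)
      vals <- m[cbind(tri, pos)]
      dim(vals) <- c(nc, nt, n_rand)
      null_gfp <- gfp(matrix(rowMeans(aperm(vals, c(1, 3, 2)), dims = 2), nrow = nc))
      exceed[s] <- sum(null_gfp >= gfp_obs[s])
    }
  })
  p <- (1 + exceed) / (n_rand + 1)
  sig <- fdr_mask(p, fdr_q)
  disp <- (1 - p) > 0.999

  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  sig_runs <- data.frame(
    start_s = epochs$times[starts[keep]],
    end_s = epochs$times[ends[keep]]
  )
  sig_runs$n100_band <- sig_runs$start_s <= 0.15 & sig_runs$end_s >= 0.05

  structure(
    list(gfp_observed = gfp_obs, p = p, significant_mask = sig,
         display_mask = disp, times = epochs$times,
         n_rand = as.integer(n_rand), fdr_q = fdr_q, seed = seed,
         significant_runs = sig_runs,
         n100_band = any(sig_runs$n100_band)),
    class = "tct_result"
  )
}

#' @export
print.tct_result <- function(x, ...) {
  cat(sprintf(
    "tct_result: %d/%d timepoints FDR-significant (q = %g, %d randomizations)%s\n",
    sum(x$significant_mask), length(x$p), x$fdr_q, x$n_rand,
    if (x$n100_band) "; consistency within 100 +/- 50 ms" else ""))
  invisible(x)
}

#' Write a TCT result as TSV (+ JSON summary)
#'
#' @param result A `tct_result`.
#' @param path Output TSV path (`time_ms`, `gfp`, `p`, `fdr_sig`,
#'   `display_sig`); a `.json` sidecar with the significant runs and the
#'   N100-band flag is written alongside.
#' @return `path`, invisibly.
#' @export
write_tct_result <- function(result, path) {
  df <- data.frame(time_ms = 1000 * result$times, gfp = result$gfp_observed,
                   p = result$p, fdr_sig = result$significant_mask,
                   display_sig = result$display_mask)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(significant_runs_ms = data.frame(
           start = 1000 * result$significant_runs$start_s,
           end = 1000 * result$significant_runs$end_s),
         n100_band = result$n100_band, fdr_q = result$fdr_q,
         n_rand = result$n_rand),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
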