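#' Subsampling null distribution of significant-gene counts
#'
#' Repeatedly draws `m` pairs without replacement from a comparison
#' stratum, runs the merged-period moderated test with BH-FDR on each
#' draw, and records the number of significant genes. The resulting
#' count distribution is the size-matched null against which another
#' stratum's count is compared.
#'
#' @param pd `paired_diff` of the comparison stratum.
#' @param m subsample size (at least 2, at most the stratum size);
#'   matched-power comparisons use the size of the smaller stratum.
#' @param N number of subsampling repetitions.
#' @param alpha FDR level of the per-draw test.
#' @param seed integer seed; the null is deterministic given the seed.
#' @return object of class `subsample_null`: list with `counts` (length
#'   `N`), `m`, `N`, `alpha`, `seed`.
#' @export
subsample_null <- function(pd, m, N = 1000, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(pd, "paired_diff"))
  T0 <- ncol(pd$diffs)
  if (m < 2) stop("subsample size m must be at least 2")
  if (m > T0) stop("subsample size m exceeds the stratum size (", T0, ")")
  run <- function() {
    counts <- integer(N)
    for (b in seq_len(N)) {
      idx <- sample.int(T0, m)
      tab <- de_test(pd$diffs[, idx, drop = FALSE], alpha = alpha)
      counts[b] <- sum(tab$significant)
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(counts = counts, m = m, N = N, alpha = alpha, seed = seed),
            class = "subsample_null")
}

#' Compare a stratum's significant-gene count to a subsampling null
#'
#' One-sided empirical p-value with add-one correction:
#' `p = (1 + #\{null counts >= reference\}) / (N + 1)`. A small p means
#' the reference stratum's count is larger than the comparison stratum
#' can produce at the matched sample size.
#'
#' @param reference_count significant-gene count of the reference
#'   stratum.
#' @param null a [subsample_null()].
#' @return object of class `strata_comparison`: list with
#'   `reference_count`, `p_value`, `null_quantiles` (50/90/95/97.5/99th
#'   percentiles of the null counts) and `null`.
#' @export
compare_strata <- function(reference_count, null) {
  stopifnot(inherits(null, "subsample_null"))
  if (length(null$counts) == 0) stop("the null distribution is empty")
  p <- (1 + sum(null$counts >= reference_count)) / (null$N + 1)
  structure(list(reference_count = reference_count, p_value = p,
                 null_quantiles = stats::quantile(
                   null$counts, c(0.5, 0.9, 0.95, 0.975, 0.99)),
                 null = null),
            class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat("strata_comparison: reference count", x$reference_count,
      "vs", x$null$N, "subsamples of size", x$null$m,
      "; p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
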