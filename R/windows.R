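#' Build moving windows over sorted follow-up times
#'
#' With `T` time-ordered pairs and window size `S`, window `j` contains
#' pairs `j .. j+S-1`, giving `T-S+1` overlapping windows; consecutive
#' windows share `S-1` pairs. `"auto"` sets `S = round(T/4)` (half-up),
#' with a minimum of 2.
#'
#' @param times follow-up times sorted ascending (years).
#' @param S window size, or `"auto"`.
#' @return object of class `window_set`: list with `windows` (data.frame
#'   `index`, `i_start`, `i_end`, `t_start`, `t_end`, `mean_time`),
#'   `S`, and `times`.
#' @export
build_windows <- function(times, S = "auto") {
  T <- length(times)
  if (T < 1) stop("at least one time is required")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (identical(S, "auto")) S <- max(2L, as.integer(floor(T / 4 + 0.5)))
  S <- as.integer(S)
  if (S < 1 || S > T) stop("window size S must satisfy 1 <= S <= T")
  idx <- seq_len(T - S + 1L)
  windows <- data.frame(
    index = idx,
    i_start = idx,
    i_end = idx + S - 1L,
    t_start = times[idx],
    t_end = times[idx + S - 1L],
    mean_time = vapply(idx, function(j) mean(times[j:(j + S - 1L)]),
                       numeric(1)))
  structure(list(windows = windows, S = S, times = times),
            class = "window_set")
}

#' Per-window differential-expression counts
#'
#' Runs the moderated paired test with BH-FDR inside every window (the
#' variance prior is re-fitted within each window, making each window an
#' independent analysis) and counts the significant genes, split by
#' direction.
#'
#' @param pd a `paired_diff` whose pairs are in the time order used to
#'   build `ws`.
#' @param ws a `window_set` built on `pd`'s (sorted) times.
#' @param alpha FDR level.
#' @return list with `series` (data.frame `index`, `mean_time`, `n_sig`,
#'   `n_up`, `n_down`) and `tables` (per-window test tables).
#' @export
window_de_counts <- function(pd, ws, alpha = 0.05) {
  stopifnot(inherits(pd, "paired_diff"), inherits(ws, "window_set"))
  if (ws$S < 2) stop("windows must contain at least 2 pairs")
  w <- ws$windows
  tables <- vector("list", nrow(w))
  n_sig <- n_up <- n_down <- integer(nrow(w))
  for (j in seq_len(nrow(w))) {
    sub <- pd$diffs[, w$i_start[j]:w$i_end[j], drop = FALSE]
    tab <- de_test(sub, alpha = alpha)
    tables[[j]] <- tab
    sig <- tab$significant
    n_sig[j] <- sum(sig)
    n_up[j] <- sum(sig & tab$direction == "up")
    n_down[j] <- sum(sig & tab$direction == "down")
  }
  series <- data.frame(index = w$index, mean_time = w$mean_time,
                       n_sig = n_sig, n_up = n_up, n_down = n_down)
  list(series = series, tables = tables)
}

#' Centered mean filter with shrinking edges
#'
#' Smooths a numeric series with a centered moving mean of odd width
#' `w`; at the edges the window shrinks symmetrically to the available
#' points, preserving the series length.
#'
#' @param x numeric vector.
#' @param w odd window width (`w = 1` is the identity).
#' @return smoothed vector of the same length.
#' @export
mean_filter <- function(x, w = 9) {
  if (w %% 2 == 0) stop("the mean filter width must be odd")
  if (w < 1) stop("the mean filter width must be at least 1")
  L <- length(x)
  k <- (w - 1) / 2
  vapply(seq_len(L), function(i) {
    h <- min(k, i - 1, L - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

#' Smooth a trajectory series
#'
#' Adds a `smoothed_n_sig` column to a per-window count series using
#' [mean_filter()].
#'
#' @param series data.frame with an `n_sig` column.
#' @param w odd mean-filter width.
#' @return the series with `smoothed_n_sig` added.
#' @export
smooth_series <- function(series, w = 9) {
  series$smoothed_n_sig <- mean_filter(series$n_sig, w = w)
  series
}

#' Full moving-window trajectory for a set of pairs
#'
#' Sorts the pairs by follow-up time, builds the moving windows, counts
#' significant genes per window and smooths the count series.
#'
#' @param pd a `paired_diff` (any pair order).
#' @param S window size or `"auto"` (see [build_windows()]).
#' @param alpha FDR level.
#' @param smooth_w odd mean-filter width.
#' @return list with `series` (including `smoothed_n_sig`), `tables`,
#'   `windows` (the `window_set`) and `pairs` (time-sorted metadata).
#' @export
de_trajectory <- function(pd, S = "auto", alpha = 0.05, smooth_w = 9) {
  ord <- order(pd$pairs$time_since_diagnosis)
  pd <- subset_pairs(pd, ord)
  ws <- build_windows(pd$pairs$time_since_diagnosis, S = S)
  res <- window_de_counts(pd, ws, alpha = alpha)
  res$series <- smooth_series(res$series, w = smooth_w)
  res$windows <- ws
  res$pairs <- pd$pairs
  res
}

#' Restrict pairs to late follow-up
#'
#' Keeps pairs sampled at least `min_months` after diagnosis (inclusive
#' boundary; times are stored in years, so the default 18 months keeps
#' times >= 1.5).
#'
#' @param pd a `paired_diff`.
#' @param min_months minimum follow-up in months.
#' @return the restricted `paired_diff`, with attribute `n_retained`;
#'   warns (but does not error) when nothing is retained.
#' @export
restrict_pairs <- function(pd, min_months = 18) {
  keep <- pd$pairs$time_since_diagnosis >= min_months / 12
  if (!any(keep)) warning("no pairs at or beyond ", min_months, " months")
  out <- subset_pairs(pd, keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Per-gene summary over windows
#'
#' For every gene, counts the windows in which it is significant
#' (`S_i`), and summarizes its p-values: the median p over the
#' significant windows when `S_i > 0`, otherwise the minimum p over all
#' windows. Genes are ordered by `S_i` descending, then by the summary
#' p ascending.
#'
#' @param tables per-window test tables from [window_de_counts()] /
#'   [de_trajectory()].
#' @param alpha FDR level defining significance (`q < alpha`).
#' @return data.frame with `gene`, `n_sig_windows`, `p_summary`,
#'   `p_type` (`"median_significant"` or `"min_all"`) and `n_windows`.
#' @export
per_gene_window_stats <- function(tables, alpha = 0.05) {
  if (length(tables) < 1) stop("at least one window table is required")
  genes <- tables[[1]]$gene
  P <- vapply(tables, function(t) t$p, numeric(length(genes)))
  P <- matrix(P, nrow = length(genes))
  Q <- vapply(tables, function(t) t$q, numeric(length(genes)))
  Q <- matrix(Q, nrow = length(genes))
  sig <- Q < alpha
  S_i <- rowSums(sig)
  p_summary <- numeric(length(genes))
  for (i in seq_along(genes)) {
    p_summary[i] <- if (S_i[i] > 0) stats::median(P[i, sig[i, ]])
    else min(P[i, ])
  }
  out <- data.frame(gene = genes, n_sig_windows = S_i,
                    p_summary = p_summary,
                    p_type = ifelse(S_i > 0, "median_significant", "min_all"),
                    n_windows = length(tables),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sig_windows, out$p_summary, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Mean log2 fold change per quarter of follow-up
#'
#' Bins pairs into quarter-year intervals ((k-1)/4, k/4] (times of
#' exactly 0 fall in the first quarter) and averages the log2
#' case-control differences of the selected genes within each quarter.
#' Quarters without pairs are `NA`.
#'
#' @param pd a `paired_diff`.
#' @param genes gene symbols to summarize (non-empty).
#' @return gene x quarter matrix; column names give the quarter's upper
#'   boundary in years, and the attribute `quarter_mid` the midpoints.
#' @export
quarterly_lfc <- function(pd, genes) {
  if (length(genes) == 0) stop("a non-empty gene selection is required")
  missing <- setdiff(genes, rownames(pd$diffs))
  if (length(missing))
    stop("genes not present: ", paste(missing, collapse = ", "))
  t <- pd$pairs$time_since_diagnosis
  qtr <- pmax(ceiling(t * 4), 1)
  n_q <- 32L
  out <- matrix(NA_real_, length(genes), n_q,
                dimnames = list(genes, sprintf("%.2f", (1:n_q) / 4)))
  for (k in seq_len(n_q)) {
    idx <- which(qtr == k)
    if (length(idx))
      out[, k] <- rowMeans(pd$diffs[genes, idx, drop = FALSE])
  }
  attr(out, "quarter_mid") <- ((1:n_q) - 0.5) / 4
  out
}

#' Overlap counts between per-stratum significant gene sets
#'
#' Computes the size of every exclusive intersection region (as drawn in
#' a Venn diagram) for two or more named gene sets.
#'
#' @param sig_sets named list (length >= 2) of character vectors.
#' @return named integer vector; names are the stratum names of each
#'   exclusive region joined by `"&"`.
#' @export
strata_signif_overlap <- function(sig_sets) {
  if (length(sig_sets) < 2) stop("at least 2 strata are required")
  if (is.null(names(sig_sets)) || any(names(sig_sets) == ""))
    stop("sig_sets must be named")
  nm <- names(sig_sets)
  universe <- unique(unlist(sig_sets))
  membership <- vapply(sig_sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe))
  out <- integer()
  for (k in seq_along(nm)) {
    for (combo in utils::combn(seq_along(nm), k, simplify = FALSE)) {
      inside <- rowSums(membership[, combo, drop = FALSE]) == length(combo)
      outside <- rowSums(membership[, -combo, drop = FALSE]) == 0
      region <- if (length(combo) == length(nm)) inside else inside & outside
      out[paste(nm[combo], collapse = "&")] <- sum(region)
    }
  }
  out
}

#' Plot a differential-expression count trajectory
#'
#' Number of significant genes per window against the window's mean
#' follow-up time, with the smoothed curve and a circle marking every
#' `pair_mark`-th pair along the time axis.
#'
#' @param traj result of [de_trajectory()].
#' @param pair_mark mark every this-many-th pair (0 disables).
#' @param ... passed to [graphics::plot()].
#' @return the trajectory, invisibly.
#' @export
plot_trajectory <- function(traj, pair_mark = 10, ...) {
  s <- traj$series
  graphics::plot(s$mean_time, s$n_sig, type = "l", col = "grey60",
                 xlab = "years since diagnosis",
                 ylab = "significant genes per window", ...)
  graphics::lines(s$mean_time, s$smoothed_n_sig, lwd = 2)
  if (pair_mark > 0 && !is.null(traj$pairs)) {
    tm <- traj$pairs$time_since_diagnosis
    marks <- tm[seq_along(tm) %% pair_mark == 0]
    graphics::points(marks, rep(0, length(marks)), col = "darkgreen")
  }
  invisible(traj)
}
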