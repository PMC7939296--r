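#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration, used when
#' matching the spread of log sample variances to a scaled-F model.
#'
#' @param y positive value.
#' @return `x` with `trigamma(x) = y` (Inf when `y` is 0 or tiny).
#' @export
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1L, is.finite(y) || is.infinite(y))
  if (y <= 0) stop("trigamma_inverse requires y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Models per-gene sample variances as scaled F draws
#' `s^2 ~ s0^2 * F(df, d0)` and estimates the prior degrees of freedom
#' `d0` and prior variance `s0^2` by matching the mean and variance of
#' `log(s^2)` to digamma/trigamma theory. When the observed spread of
#' `log(s^2)` does not exceed the spread expected from sampling alone,
#' the prior is degenerate: `d0 = Inf` and `s0^2` is the mean observed
#' variance.
#'
#' @param s_sq per-gene sample variances (at least 10 finite positive
#'   values).
#' @param df residual degrees of freedom of each variance (pairs minus
#'   one for a paired design).
#' @return object of class `ebayes_prior`: list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s_sq, df) {
  s_sq <- s_sq[is.finite(s_sq)]
  if (length(s_sq) < 10)
    stop("at least 10 finite per-gene variances are required")
  if (any(s_sq <= 0)) stop("variances must be positive")
  stopifnot(df >= 1)
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s_sq)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat("ebayes_prior: d0 =", x$d0, " s0_sq =", x$s0_sq, "\n")
  invisible(x)
}

#' Moderated paired t-test on case-control differences
#'
#' One-sample moderated t-test per gene on log2 case minus control
#' differences. The gene-wise variance is shrunk towards the prior:
#' `s~^2 = (d0*s0^2 + (n-1)*s^2) / (d0 + n - 1)`, the statistic is
#' `t = mean / (s~ / sqrt(n))` and two-sided p-values come from the t
#' distribution with `d0 + n - 1` degrees of freedom (standard normal in
#' the `d0 = Inf` limit). With `d0 = 0` the test reduces to the ordinary
#' one-sample t-test.
#'
#' @param diffs gene x pair matrix of differences (or a `paired_diff`),
#'   with at least 2 pairs.
#' @param fit an `ebayes_prior`; fitted from `diffs` when `NULL`.
#' @return data.frame with per-gene `gene`, `mean_diff`, `s_sq`,
#'   `t_mod`, `df_total`, `p` and `direction` (`"up"`/`"down"` by the
#'   sign of `mean_diff`).
#' @export
moderated_paired_test <- function(diffs, fit = NULL) {
  if (inherits(diffs, "paired_diff")) diffs <- diffs$diffs
  n <- ncol(diffs)
  if (n < 2) stop("the moderated paired test requires at least 2 pairs")
  mean_diff <- rowMeans(diffs)
  s_sq <- rowSums((diffs - mean_diff)^2) / (n - 1)
  if (is.null(fit)) fit <- fit_variance_prior(s_sq, df = n - 1)
  stopifnot(inherits(fit, "ebayes_prior"))
  d0 <- fit$d0
  if (is.infinite(d0)) {
    s_tilde_sq <- rep(fit$s0_sq, length(s_sq))
    df_total <- Inf
  } else {
    s_tilde_sq <- (d0 * fit$s0_sq + (n - 1) * s_sq) / (d0 + n - 1)
    df_total <- d0 + n - 1
  }
  s_tilde_sq <- pmax(s_tilde_sq, .Machine$double.xmin)
  t_mod <- mean_diff / sqrt(s_tilde_sq / n)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene = rownames(diffs), mean_diff = mean_diff, s_sq = s_sq,
             t_mod = t_mod, df_total = df_total, p = p,
             direction = ifelse(mean_diff > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity
#' enforcement; significance means `q < alpha` strictly.
#'
#' @param p p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return list with `q` (adjusted values) and `significant` (logical
#'   mask).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q < alpha)
}

#' Moderated test plus FDR in one call
#'
#' Convenience wrapper: fits the variance prior on the given
#' differences, runs [moderated_paired_test()] and attaches
#' [bh_adjust()] q-values.
#'
#' @inheritParams moderated_paired_test
#' @param alpha FDR level for the `significant` column.
#' @return the test table with additional `q` and `significant` columns.
#' @export
de_test <- function(diffs, alpha = 0.05, fit = NULL) {
  tab <- moderated_paired_test(diffs, fit = fit)
  adj <- bh_adjust(tab$p, alpha = alpha)
  tab$q <- adj$q
  tab$significant <- adj$significant
  tab
}

#' Serialize a gene test table as TSV
#'
#' @param tab data.frame from [de_test()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_test_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
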