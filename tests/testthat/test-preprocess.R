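test_that("QC thresholds are applied with the stated boundaries", {
  rec <- data.frame(
    sample_id = sprintf("P%03d_case", 1:7),
    RIN = c(8, 6.9, 8, 8, 8, 7, 8),
    ratio_260_280 = c(2.1, 2.1, 1.99, 2.0, 2.1, 2.1, 2.1),
    ratio_260_230 = c(1.8, 1.8, 1.8, 1.8, 1.69, 1.8, 1.8),
    rna_amount = c(100, 100, 100, 100, 100, 500, 50.0001),
    stringsAsFactors = FALSE)
  failing <- qc_filter(rec)
  expect_false("P001_case" %in% failing)  # all metrics pass
  expect_true("P002_case" %in% failing)   # RIN < 7
  expect_true("P003_case" %in% failing)   # 260/280 < 2
  expect_false("P004_case" %in% failing)  # 260/280 == 2 passes
  expect_true("P005_case" %in% failing)   # 260/230 < 1.7
  expect_true("P006_case" %in% failing)   # RNA == 500, open interval
  expect_false("P007_case" %in% failing)  # RNA just inside
})

test_that("pairs with a failing sample are flagged qc_fail", {
  pairs <- simulate_metadata(small_config(n_pairs = 3))
  rec <- data.frame(sample_id = c("P0001_case", "P0002_ctrl", "P0003_case"),
                    RIN = c(9, 5, 9), ratio_260_280 = 2.1,
                    ratio_260_230 = 1.8, rna_amount = 100,
                    stringsAsFactors = FALSE)
  out <- qc_flag_pairs(pairs, rec)
  expect_equal(out$excluded, c("", "qc_fail", ""))
  expect_equal(qc_flag_pairs(out, rec)$excluded, out$excluded)
})

test_that("degenerate zero-variance background subtracts cleanly", {
  b <- 50
  x <- matrix(c(5050, 2000, 50), 3, 1)
  pm <- make_pm(x, negative_controls = matrix(b, 12, 1))
  out <- background_correct(pm)
  expect_lt(abs(out$intensities[1, 1] - (5050 - b)), 1)
  expect_lt(abs(out$intensities[2, 1] - (2000 - b)), 1)
  expect_true(all(out$intensities > 0))  # even an all-background probe
})

test_that("normexp correction matches numeric integration of the posterior", {
  set.seed(5)
  n <- 400
  s_true <- rexp(n, 1 / 200)
  x <- matrix(s_true + rnorm(n, 100, 10), n, 1)
  nc <- matrix(rnorm(80, 100, 10), 80, 1)
  pm <- make_pm(x, negative_controls = nc)
  out <- background_correct(pm)$intensities[, 1]
  par <- dewindow:::.normexp_params(x[, 1], nc[, 1])
  mu <- par[["mu"]]; sigma <- exp(par[["logsigma"]])
  alpha <- exp(par[["logalpha"]])
  idx <- sample(n, 40)
  oracle <- vapply(x[idx, 1], function(xi) {
    num <- stats::integrate(function(s)
      s * dnorm(xi - s, mu, sigma) * dexp(s, 1 / alpha),
      0, xi + 8 * sigma, rel.tol = 1e-10)$value
    den <- stats::integrate(function(s)
      dnorm(xi - s, mu, sigma) * dexp(s, 1 / alpha),
      0, xi + 8 * sigma, rel.tol = 1e-10)$value
    num / den
  }, numeric(1))
  expect_lt(max(abs(out[idx] - oracle) / pmax(oracle, 1)), 1e-4)
  # signal recovery: corrected values track the true signal
  expect_lt(mean(abs(out - s_true)) , 2 * (10 + 10 / sqrt(80)))
  expect_true(all(out > 0))
})

test_that("quantile normalization replaces sorted values by rank means", {
  x <- matrix(2^c(1, 2, 3, 4, 5, 6), 3, 2)
  pm <- make_pm(x)
  out <- transform_normalize(pm, offset = 0)
  expect_equal(unname(out$intensities[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$intensities[, 2]), c(2.5, 3.5, 4.5))
})

test_that("identical samples are unchanged by the quantile step", {
  x <- matrix(rep(c(20, 300, 4000, 90), 3), 4, 3)
  out <- transform_normalize(make_pm(x), offset = 16)
  expect_equal(out$intensities, log2(x + 16),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("transform preserves within-sample ranks and equalizes quantiles", {
  set.seed(8)
  x <- matrix(rexp(500, 1 / 300), 100, 5)
  pm <- make_pm(x)
  out <- transform_normalize(pm)
  for (j in 1:5)
    expect_equal(order(out$intensities[, j]), order(x[, j]))
  sorted <- apply(out$intensities, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
  expect_error(transform_normalize(make_pm(matrix(c(-1, 2), 2, 1))),
               "positive")
})

test_that("the presence filter keeps probes at exactly the 70% boundary", {
  # 10 samples: present in 7 (70%, kept), 6 (60%, removed), 10 (kept)
  dp <- rbind(c(rep(0.01, 7), rep(0.5, 3)),
              c(rep(0.01, 6), rep(0.5, 4)),
              rep(0.01, 10),
              rep(0.05, 10))   # detection p == alpha is not "present"
  x <- matrix(100, 4, 10)
  pm <- make_pm(x, detection_p = dp)
  out <- filter_probes(pm)
  expect_equal(out$probes$probe_id, c("pr001", "pr003"))
})

test_that("HLA probes are removed by the HLA rule alone", {
  n <- 100
  is_hla <- c(rep(TRUE, 38), rep(FALSE, n - 38))
  pm <- make_pm(matrix(100, n, 4), is_hla = is_hla)
  out <- filter_probes(pm)  # all detection p are 0: only HLA removed
  expect_equal(nrow(out$intensities), n - 38)
  expect_equal(attr(out, "n_hla_removed"), 38)
  expect_false(any(out$probes$is_hla))
})

test_that("probe collapsing averages on the log scale", {
  x <- matrix(c(4, 6, 7, 1, 3, 5), 3, 2)
  pm <- make_pm(x, gene = c("A", "A", "B"))
  g <- collapse_to_genes(pm)
  expect_equal(unname(g["A", ]), c(5, 2))
  expect_equal(unname(g["B", ]), c(7, 5))
  # one probe per gene is the identity
  pm1 <- make_pm(x, gene = c("A", "B", "C"))
  expect_equal(unname(collapse_to_genes(pm1)), unname(x),
               ignore_attr = TRUE)
  # random 3-probe genes equal the brute-force mean
  set.seed(9)
  x3 <- matrix(rnorm(30), 10, 3)
  pm3 <- make_pm(x3, gene = rep(c("g1", "g2"), each = 5))
  g3 <- collapse_to_genes(pm3)
  expect_equal(unname(g3["g1", ]), unname(colMeans(x3[1:5, ])))
  pm_bad <- make_pm(x, gene = c("A", NA, "B"))
  expect_error(collapse_to_genes(pm_bad), "pr002")
})

test_that("pair differencing subtracts control from case columns", {
  pairs <- data.frame(pair_id = c("P1", "P2"), stringsAsFactors = FALSE)
  g <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("a", "b", "c"),
                              c("P1_case", "P1_ctrl", "P2_case", "P2_ctrl")))
  pd <- pair_differences(g, pairs)
  expect_equal(unname(pd$diffs),
               unname(g[, c(1, 3)] - g[, c(2, 4)]))
  # case == control gives zeros; case = control + 1 gives ones
  g2 <- g; g2[, c(1, 3)] <- g2[, c(2, 4)]
  expect_true(all(pair_differences(g2, pairs)$diffs == 0))
  g2[, c(1, 3)] <- g2[, c(2, 4)] + 1
  expect_true(all(pair_differences(g2, pairs)$diffs == 1))
  expect_error(pair_differences(g[, 1:3], pairs), "P2")
})

test_that("pipeline stages never increase the probe count", {
  cfg <- small_config(n_pairs = 12)
  coh <- simulate_cohort(cfg)
  pp <- preprocess_pipeline(coh$expr, coh$pairs)
  r <- pp$report
  expect_true(r$n_probes_raw >= r$n_probes_after_hla)
  expect_true(r$n_probes_after_hla >= r$n_probes_after_presence)
  expect_true(r$n_probes_after_presence >= r$n_genes)
  expect_equal(r$n_hla_removed, cfg$n_hla_probes)
  expect_equal(r$n_pairs, 12)
})
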