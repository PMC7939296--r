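test_that("window construction follows the T-S+1 sliding rule", {
  ws <- build_windows(1:8, S = 2)
  expect_equal(nrow(ws$windows), 7)
  expect_equal(ws$windows$i_start, 1:7)
  expect_equal(ws$windows$i_end, 2:8)
  expect_equal(ws$windows$t_start, 1:7)
  expect_equal(ws$windows$t_end, 2:8)
  ws1 <- build_windows(1:5, S = 5)
  expect_equal(nrow(ws1$windows), 1)
  expect_equal(ws1$windows$mean_time, 3)
  expect_error(build_windows(1:4, S = 5), "1 <= S <= T")
  expect_error(build_windows(c(3, 1, 2), S = 2), "sorted")
})

test_that("auto window size is round(T/4), at least 2, with 312 windows at T=415", {
  times <- sort(runif(415, 0, 8))
  ws <- build_windows(times, S = "auto")
  expect_equal(ws$S, 104)
  expect_equal(nrow(ws$windows), 312)
  expect_equal(build_windows(1:10, S = "auto")$S, 3)  # half-up rounding
  expect_equal(build_windows(1:6, S = "auto")$S, 2)   # minimum of 2
})

test_that("windows match exhaustive enumeration for small cohorts", {
  set.seed(41)
  for (T in c(2, 5, 9, 12)) {
    times <- sort(runif(T, 0, 8))
    for (S in 1:T) {
      ws <- build_windows(times, S = S)
      expect_equal(nrow(ws$windows), T - S + 1)
      for (j in seq_len(T - S + 1)) {
        members <- j:(j + S - 1)
        expect_equal(ws$windows$mean_time[j], mean(times[members]))
        expect_equal(ws$windows$t_start[j], times[j])
        expect_equal(ws$windows$t_end[j], times[j + S - 1])
      }
      if (S >= 2 && T - S + 1 >= 2) {
        # consecutive windows share exactly S-1 members
        shared <- length(intersect(1:S, 2:(S + 1)))
        expect_equal(shared, S - 1)
      }
    }
  }
})

test_that("a single all-pair window equals the merged-period analysis", {
  set.seed(43)
  x <- random_diffs(100, 20, mu = 0.3, sd = 0.5)
  pairs <- data.frame(pair_id = colnames(x),
                      time_since_diagnosis = sort(runif(20, 0, 8)),
                      stringsAsFactors = FALSE)
  pd <- structure(list(diffs = x, pairs = pairs), class = "paired_diff")
  ws <- build_windows(pairs$time_since_diagnosis, S = 20)
  res <- window_de_counts(pd, ws)
  merged <- de_test(x)
  expect_equal(res$series$n_sig, sum(merged$significant))
  expect_equal(res$tables[[1]]$p, merged$p)
  expect_equal(res$series$n_up + res$series$n_down, res$series$n_sig)
})

test_that("the mean filter smooths with shrinking symmetric edges", {
  expect_equal(mean_filter(rep(3, 15)), rep(3, 15))
  x <- numeric(21); x[11] <- 1
  sm <- mean_filter(x, w = 9)
  expect_equal(sm[7:15], rep(1 / 9, 9))
  expect_equal(sm[c(1:6, 16:21)], rep(0, 12))
  expect_equal(mean_filter(x, w = 1), x)
  expect_error(mean_filter(x, w = 4), "odd")
  s <- smooth_series(data.frame(n_sig = x))
  expect_equal(s$smoothed_n_sig, sm)
})

test_that("late-follow-up restriction keeps the 18-month boundary inclusive", {
  x <- random_diffs(10, 3)
  pairs <- data.frame(pair_id = colnames(x),
                      time_since_diagnosis = c(1.0, 1.5, 2.0),
                      stringsAsFactors = FALSE)
  pd <- structure(list(diffs = x, pairs = pairs), class = "paired_diff")
  out <- restrict_pairs(pd)
  expect_equal(out$pairs$time_since_diagnosis, c(1.5, 2.0))
  expect_equal(attr(out, "n_retained"), 2)
  all2 <- structure(list(diffs = x, pairs = transform(
    pairs, time_since_diagnosis = 2)), class = "paired_diff")
  expect_equal(ncol(restrict_pairs(all2)$diffs), 3)
  none <- structure(list(diffs = x, pairs = transform(
    pairs, time_since_diagnosis = 0.5)), class = "paired_diff")
  expect_warning(restrict_pairs(none), "no pairs")
})

test_that("under uniform times the retained fraction is about 1 - 1.5/8", {
  set.seed(47)
  n <- 2000
  x <- random_diffs(2, n)
  pairs <- data.frame(pair_id = colnames(x),
                      time_since_diagnosis = runif(n, 0, 8),
                      stringsAsFactors = FALSE)
  pd <- structure(list(diffs = x, pairs = pairs), class = "paired_diff")
  frac <- attr(restrict_pairs(pd), "n_retained") / n
  p <- 1 - 1.5 / 8
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("per-gene window summaries count and summarize correctly", {
  mk_tab <- function(p, q) data.frame(gene = c("gA", "gB"), p = p, q = q,
                                      stringsAsFactors = FALSE)
  tables <- list(mk_tab(c(0.001, 0.4), c(0.01, 0.6)),
                 mk_tab(c(0.003, 0.2), c(0.02, 0.5)),
                 mk_tab(c(0.005, 0.3), c(0.03, 0.55)))
  s <- per_gene_window_stats(tables)
  a <- s[s$gene == "gA", ]
  expect_equal(a$n_sig_windows, 3)
  expect_equal(a$p_summary, 0.003)       # median over significant windows
  expect_equal(a$p_type, "median_significant")
  b <- s[s$gene == "gB", ]
  expect_equal(b$n_sig_windows, 0)
  expect_equal(b$p_summary, 0.2)         # min over all windows
  expect_equal(b$p_type, "min_all")
  expect_equal(s$gene, c("gA", "gB"))    # sorted S desc
})

test_that("per-gene summaries equal a brute-force recount on random tables", {
  set.seed(53)
  genes <- sprintf("g%02d", 1:30)
  tables <- lapply(1:8, function(j) {
    p <- runif(30)
    data.frame(gene = genes, p = p, q = p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
  s <- per_gene_window_stats(tables, alpha = 0.5)
  for (g in sample(genes, 10)) {
    ps <- vapply(tables, function(t) t$p[t$gene == g], numeric(1))
    qs <- vapply(tables, function(t) t$q[t$gene == g], numeric(1))
    Si <- sum(qs < 0.5)
    row <- s[s$gene == g, ]
    expect_equal(row$n_sig_windows, Si)
    expect_equal(row$p_summary,
                 if (Si > 0) median(ps[qs < 0.5]) else min(ps))
  }
})

test_that("quarterly fold changes are group-by means over quarter bins", {
  set.seed(59)
  x <- random_diffs(5, 12)
  t <- c(0.1, 0.2, 0.3, 0.6, 1.3, 2.0, 2.01, 4.7, 4.75, 6.0, 7.99, 8.0)
  pairs <- data.frame(pair_id = colnames(x), time_since_diagnosis = t,
                      stringsAsFactors = FALSE)
  pd <- structure(list(diffs = x, pairs = pairs), class = "paired_diff")
  q <- quarterly_lfc(pd, rownames(x))
  bins <- pmax(ceiling(t * 4), 1)
  for (k in unique(bins))
    expect_equal(unname(q[, k]),
                 unname(rowMeans(x[, bins == k, drop = FALSE])))
  expect_true(all(is.na(q[, setdiff(1:32, bins)])))
  # all-zero differences give an all-zero (or NA) matrix
  pd0 <- structure(list(diffs = x * 0, pairs = pairs), class = "paired_diff")
  q0 <- quarterly_lfc(pd0, rownames(x))
  expect_true(all(q0 == 0 | is.na(q0)))
  expect_error(quarterly_lfc(pd, character()), "non-empty")
})

test_that("strata overlap counts match brute-force set algebra", {
  expect_equal(
    strata_signif_overlap(list(a = "x1", b = "x2", c = "x3")),
    c(a = 1L, b = 1L, c = 1L, `a&b` = 0L, `a&c` = 0L, `b&c` = 0L,
      `a&b&c` = 0L))
  same <- c("g1", "g2", "g3")
  out <- strata_signif_overlap(list(A = same, B = same, C = same))
  expect_equal(unname(out["A&B&C"]), 3L)
  expect_true(all(out[setdiff(names(out), "A&B&C")] == 0))
  set.seed(61)
  sets <- list(s1 = sample(letters, 12), s2 = sample(letters, 8),
               s3 = sample(letters, 15))
  out <- strata_signif_overlap(sets)
  brute <- function(members) {
    sum(vapply(letters, function(g) {
      inside <- vapply(sets, function(s) g %in% s, logical(1))
      all(inside[members]) && !any(inside[setdiff(names(sets), members)])
    }, logical(1)))
  }
  expect_equal(unname(out["s1"]), brute("s1"))
  expect_equal(unname(out["s1&s3"]), brute(c("s1", "s3")))
  expect_equal(unname(out["s1&s2&s3"]), brute(c("s1", "s2", "s3")))
  expect_equal(sum(out), length(unique(unlist(sets))))
  expect_error(strata_signif_overlap(list(a = "x")), "at least 2")
})
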