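#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, member genes.
#' Member symbols are uppercased and de-duplicated.
#'
#' @param path GMT file.
#' @param label optional collection label (defaults to the file name).
#' @return object of class `gene_set_collection`: a named list of
#'   character vectors with attribute `label`.
#' @export
read_gmt <- function(path, label = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": expected name, description and ",
           "at least one gene")
    genes <- unique(toupper(trimws(fields[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) < 1) stop("malformed GMT line ", i, ": empty set")
    sets[[fields[1]]] <- genes
  }
  structure(sets, label = label %||% basename(path),
            class = "gene_set_collection")
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (or a
#'   `gene_set_collection`).
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to
#'   `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hypergeometric overlap test of two gene sets
#'
#' Tests over-representation of `target` genes among `query` genes drawn
#' from a finite universe: with `K = |target|`, `k = |query intersect
#' target|`, the p-value is the hypergeometric upper tail
#' `P(X >= k)` for `|query|` draws from the universe containing `K`
#' successes (the one-sided 2x2 Fisher test).
#'
#' @param query character vector of query genes (within the universe).
#' @param target character vector of target-set genes (within the
#'   universe).
#' @param universe either the universe size (single number) or the
#'   character vector of universe genes.
#' @return one-row data.frame with `K`, `k`, `ratio` (`k/K`) and `p`.
#' @export
overlap_test <- function(query, target, universe) {
  query <- unique(toupper(query))
  target <- unique(toupper(target))
  if (is.character(universe)) {
    universe <- unique(toupper(universe))
    if (!all(query %in% universe) || !all(target %in% universe))
      stop("query and target must be subsets of the universe")
    N <- length(universe)
  } else {
    N <- as.integer(universe)
  }
  if (N < length(query) || N < length(target))
    stop("the universe cannot be smaller than the sets")
  K <- length(target)
  k <- length(intersect(query, target))
  p <- stats::phyper(k - 1, K, N - K, length(query), lower.tail = FALSE)
  data.frame(K = K, k = k, ratio = k / K, p = p)
}

#' Overlap tests across a gene-set collection
#'
#' Runs [overlap_test()] of one query list against every set in a
#' collection (sets are first intersected with the universe), with BH
#' adjustment across sets.
#'
#' @param query character vector of query genes.
#' @param collection a `gene_set_collection` or named list of character
#'   vectors.
#' @param universe character vector of universe genes (e.g. all genes
#'   surviving the presence filter).
#' @return data.frame with one row per set: `set`, `K`, `k`, `ratio`,
#'   `p`, `q`, sorted by `p`.
#' @export
overlap_tests <- function(query, collection, universe) {
  universe <- unique(toupper(universe))
  query <- intersect(unique(toupper(query)), universe)
  rows <- lapply(names(collection), function(nm) {
    target <- intersect(unique(toupper(collection[[nm]])), universe)
    if (length(target) == 0) return(NULL)
    cbind(set = nm, overlap_test(query, target, universe))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}

#' Rank genes by windows-significant count and p-value
#'
#' Computes the rank value `V_i = S_i - k_i * p_i` where `S_i` is the
#' number of windows in which gene `i` is significant and `p_i` its
#' summary p-value (median over significant windows when `S_i > 0`,
#' minimum over all windows otherwise). The scale factor `k_i` is
#' `0.8 / max p_j` taken over the genes of the same class (significant
#' somewhere vs nowhere), so `k_i * p_i <= 0.8 < 1` and the V ordering
#' is exactly the lexicographic ordering by (`S_i` descending, `p_i`
#' ascending). Ties in V are broken by gene symbol.
#'
#' @param summary data.frame from [per_gene_window_stats()] (columns
#'   `gene`, `n_sig_windows`, `p_summary`).
#' @return object of class `ranked_list`: data.frame `gene`, `S`, `p`,
#'   `k`, `V`, ordered by `V` descending.
#' @export
rank_values <- function(summary) {
  stopifnot(all(c("gene", "n_sig_windows", "p_summary") %in% names(summary)))
  if (nrow(summary) < 1) stop("the summary must cover at least one gene")
  S <- summary$n_sig_windows
  p <- summary$p_summary
  k <- numeric(nrow(summary))
  for (cls in list(S > 0, S == 0)) {
    if (!any(cls)) next
    pmax_cls <- max(p[cls])
    if (pmax_cls == 0)
      stop("the maximum p-value of a gene class is 0; k is undefined")
    k[cls] <- 0.8 / pmax_cls
  }
  V <- S - k * p
  out <- data.frame(gene = summary$gene, S = S, p = p, k = k, V = V,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$V, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("ranked_list", "data.frame")
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
.gsea_es <- function(stats_desc, idx, weight) {
  n <- length(stats_desc)
  m <- length(idx)
  inc <- if (weight == 0) rep(1, m) else abs(stats_desc[idx])^weight
  NR <- sum(inc)
  if (NR == 0) return(0)
  step <- rep(-1 / (n - m), n)
  step[idx] <- inc / NR
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a ranked gene
#' list: walking down the ranking, the running sum rises by
#' `|V|^weight` (normalized) at member genes and falls by `1/(n-m)`
#' elsewhere; the enrichment score ES is the signed maximum deviation.
#' The null is built from `n_perm` random gene-label permutations (a
#' random same-size gene set per permutation);
#' `p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1)`, `NES` is ES
#' divided by the mean `|ES_null|` of matching sign, and q-values are BH
#' within each sign class.
#'
#' @param ranked a `ranked_list` from [rank_values()] (or a named
#'   numeric vector of rank values).
#' @param sets a `gene_set_collection` or named list of character
#'   vectors.
#' @param n_perm number of permutations.
#' @param weight exponent on `|V|` (0 gives the unweighted statistic,
#'   invariant to monotone rescaling of V).
#' @param seed integer seed for the permutations.
#' @param min_size,max_size retained set-size bounds after intersecting
#'   each set with the ranked genes; sets outside are skipped with a
#'   warning.
#' @return data.frame with `set`, `size`, `ES`, `NES`, `p`, `q`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight = 1,
                           seed = NULL, min_size = 5, max_size = 500) {
  if (inherits(ranked, "ranked_list")) {
    stats_desc <- stats::setNames(ranked$V, ranked$gene)
  } else {
    stats_desc <- sort(ranked, decreasing = TRUE)
  }
  n <- length(stats_desc)
  genes <- names(stats_desc)
  run <- function() {
    rows <- list()
    for (nm in names(sets)) {
      members <- intersect(unique(toupper(sets[[nm]])), genes)
      m <- length(members)
      if (m < min_size || m > max_size || m >= n) {
        warning("skipping set '", nm, "': ", m,
                " ranked genes (outside [", min_size, ", ", max_size, "])")
        next
      }
      idx <- which(genes %in% members)
      es <- .gsea_es(stats_desc, idx, weight)
      es_null <- vapply(seq_len(n_perm), function(b)
        .gsea_es(stats_desc, sample.int(n, m), weight), numeric(1))
      p <- (1 + sum(abs(es_null) >= abs(es))) / (n_perm + 1)
      same_sign <- es_null[sign(es_null) == sign(es)]
      nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
      rows[[nm]] <- data.frame(set = nm, size = m, ES = es, NES = nes,
                               p = p, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(out)
    out$q <- NA_real_
    for (sgn in c(-1, 1)) {
      cls <- sign(out$ES) == sgn
      if (any(cls)) out$q[cls] <- stats::p.adjust(out$p[cls], method = "BH")
    }
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
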