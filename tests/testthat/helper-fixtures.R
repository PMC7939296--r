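# Shared fixtures, all built in code.

# a small, fast cohort configuration for unit tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_pairs = 40, n_probes = 300, n_genes = 250,
                   n_hla_probes = 10, n_negative_controls = 50, seed = 101)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# pairs reproducing the printed year-after-diagnosis x stage table
# (8 year rows x 5 stage categories, column sums 51/227/126/2/9)
table1_year_counts <- function() {
  matrix(c(7, 34, 11, 0, 2,
           7, 55, 24, 1, 3,
           11, 38, 22, 0, 1,
           9, 32, 22, 0, 1,
           4, 17, 13, 0, 1,
           6, 19, 14, 0, 1,
           6, 24, 19, 0, 0,
           1, 8, 1, 1, 0),
         nrow = 8, byrow = TRUE,
         dimnames = list(year = 1:8,
                         stage = c("in_situ", "invasive", "regional_lymph",
                                   "regional_muscle", "distant")))
}

table1_year_pairs <- function() {
  cnt <- table1_year_counts()
  rows <- list()
  for (y in 1:8) for (cat_ in colnames(cnt)) {
    n <- cnt[y, cat_]
    if (n == 0) next
    stage <- if (cat_ %in% c("in_situ", "invasive")) cat_ else "metastatic"
    substage <- if (stage == "metastatic") cat_ else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = sprintf("Y%dC%sN%02d", y, substr(cat_, 1, 3), seq_len(n)),
      time_since_diagnosis = y - 0.5, stage = stage, substage = substage,
      vital_status = "survived", tumor_size = NA_real_, excluded = "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# pairs carrying the printed per-stage tumor-size category counts
table1_size_pairs <- function() {
  sizes <- c(0.3, 0.75, 1, 1.5, 3.5, 5)
  counts <- list(invasive = c(12, 43, 1, 108, 28, 2),
                 regional_lymph = c(2, 11, 0, 46, 40, 2),
                 distant = c(1, 1, 0, 2, 2, 1))
  rows <- list()
  for (cat_ in names(counts)) {
    stage <- if (cat_ == "invasive") "invasive" else "metastatic"
    substage <- if (stage == "metastatic") cat_ else NA_character_
    ts <- rep(sizes, counts[[cat_]])
    rows[[cat_]] <- data.frame(
      pair_id = sprintf("S%s%03d", substr(cat_, 1, 3), seq_along(ts)),
      time_since_diagnosis = 1, stage = stage, substage = substage,
      vital_status = "survived", tumor_size = ts, excluded = "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# minimal probe_matrix constructor for preprocessing unit tests
make_pm <- function(intensities, negative_controls = NULL,
                    detection_p = NULL, gene = NULL, is_hla = NULL) {
  n <- nrow(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("pr%03d", seq_len(n))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("s%02d", seq_len(ncol(intensities)))
  if (is.null(negative_controls))
    negative_controls <- matrix(1, 10, ncol(intensities),
                                dimnames = list(NULL, colnames(intensities)))
  if (is.null(detection_p))
    detection_p <- matrix(0, n, ncol(intensities),
                          dimnames = dimnames(intensities))
  structure(list(
    intensities = intensities, detection_p = detection_p,
    negative_controls = negative_controls,
    probes = data.frame(probe_id = rownames(intensities),
                        gene = gene %||% rownames(intensities),
                        is_hla = is_hla %||% rep(FALSE, n),
                        stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(intensities),
                         pair_id = NA_character_, role = NA_character_,
                         stringsAsFactors = FALSE),
    signal_genes = list()), class = "probe_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gene x pair matrix of N(mu, sd) differences
random_diffs <- function(n_genes, n_pairs, mu = 0, sd = 1) {
  matrix(stats::rnorm(n_genes * n_pairs, mu, sd), n_genes, n_pairs,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("P%04d", seq_len(n_pairs))))
}
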