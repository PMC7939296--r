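#' RNA quality-control filter
#'
#' A sample fails QC if its RNA integrity number is below 7, its 260/280
#' absorbance ratio below 2, its 260/230 ratio below 1.7, or its RNA
#' amount outside the open interval (50, 500).
#'
#' @param records data.frame with columns `sample_id`, `RIN`,
#'   `ratio_260_280`, `ratio_260_230`, `rna_amount`.
#' @return character vector of failing sample ids.
#' @export
qc_filter <- function(records) {
  stopifnot(all(c("sample_id", "RIN", "ratio_260_280", "ratio_260_230",
                  "rna_amount") %in% names(records)))
  fail <- records$RIN < 7 |
    records$ratio_260_280 < 2 |
    records$ratio_260_230 < 1.7 |
    !(records$rna_amount > 50 & records$rna_amount < 500)
  records$sample_id[fail]
}

#' Flag pairs whose samples fail QC
#'
#' Appends the `qc_fail` exclusion flag to every pair with at least one
#' failing sample. Sample ids are expected in the `<pair_id>_case` /
#' `<pair_id>_ctrl` convention.
#'
#' @param pairs pair metadata data.frame.
#' @param records QC records as for [qc_filter()].
#' @return `pairs` with updated `excluded` column.
#' @export
qc_flag_pairs <- function(pairs, records) {
  failing <- qc_filter(records)
  bad_pairs <- unique(sub("_(case|ctrl)$", "", failing))
  hit <- pairs$pair_id %in% bad_pairs
  add <- hit & !grepl("qc_fail", pairs$excluded)
  pairs$excluded[add] <- ifelse(pairs$excluded[add] == "", "qc_fail",
                                paste0(pairs$excluded[add], ",qc_fail"))
  pairs
}

# moment fit of the normexp convolution per sample: noise mean/sd from the
# negative controls, exponential signal mean from the intensity excess
.normexp_params <- function(x, nc) {
  mu <- mean(nc)
  sigma <- max(stats::sd(nc), 1e-6)
  alpha <- max(mean(x) - mu, 1)
  c(mu = mu, logsigma = log(sigma), logalpha = log(alpha))
}

#' Background-correct probe intensities using negative controls
#'
#' Fits, per sample, a normal-plus-exponential (normexp) convolution
#' model by moments -- the Gaussian noise component taken from the
#' negative-control mean and standard deviation, the exponential signal
#' mean from the average intensity excess over the noise mean -- and
#' replaces every intensity by the posterior expected signal given the
#' observed value. Corrected intensities are strictly positive.
#'
#' @param m a `probe_matrix` with at least 10 negative-control probes.
#' @return the `probe_matrix` with corrected `intensities`.
#' @export
background_correct <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  if (nrow(m$negative_controls) < 10)
    stop("at least 10 negative-control probes per sample are required")
  out <- m$intensities
  for (s in seq_len(ncol(out))) {
    par <- .normexp_params(m$intensities[, s], m$negative_controls[, s])
    out[, s] <- limma::normexp.signal(par, m$intensities[, s])
  }
  m$intensities <- out
  attr(m, "background_corrected") <- TRUE
  m
}

#' Offset-log2 transform and quantile normalization
#'
#' Applies the variance-stabilizing transform `log2(x + offset)` to the
#' (background-corrected, positive) intensities and then quantile
#' normalizes across samples: every sample's sorted values are replaced
#' by the mean of the sorted values across samples, ties receiving the
#' mean of their candidate values. After normalization all samples share
#' the same sorted value vector.
#'
#' @param m a `probe_matrix` with positive intensities.
#' @param offset stabilizing offset added before the log (intensity
#'   units); the default 16 damps the variance inflation of
#'   near-background probes while leaving bright probes on an ordinary
#'   log2 scale.
#' @return the `probe_matrix` with `intensities` on the normalized log2
#'   scale.
#' @export
transform_normalize <- function(m, offset = 16) {
  stopifnot(inherits(m, "probe_matrix"))
  if (any(m$intensities <= 0))
    stop("transform_normalize requires strictly positive intensities")
  y <- log2(m$intensities + offset)
  yn <- limma::normalizeQuantiles(y, ties = TRUE)
  dimnames(yn) <- dimnames(y)
  m$intensities <- yn
  attr(m, "log2") <- TRUE
  m
}

#' Remove HLA probes and apply the detection/presence filter
#'
#' Drops all probes flagged as HLA-system probes, then keeps only probes
#' whose detection p-value is below `detect_alpha` (strictly) in at
#' least `presence_frac` (inclusive) of the samples.
#'
#' @param m a `probe_matrix` with `detection_p` populated.
#' @param detect_alpha detection threshold; a probe is "present" in a
#'   sample when its detection p-value is `< detect_alpha`.
#' @param presence_frac minimum fraction of samples a probe must be
#'   present in.
#' @param drop_hla whether to remove HLA-flagged probes.
#' @param presence whether to apply the presence filter (disable to
#'   remove HLA probes only, as at the head of the pipeline).
#' @return the filtered `probe_matrix`, with attribute `n_hla_removed`.
#' @export
filter_probes <- function(m, detect_alpha = 0.05, presence_frac = 0.70,
                          drop_hla = TRUE, presence = TRUE) {
  stopifnot(inherits(m, "probe_matrix"))
  keep <- rep(TRUE, nrow(m$probes))
  n_hla <- 0L
  if (drop_hla) {
    keep <- !m$probes$is_hla
    n_hla <- sum(m$probes$is_hla)
  }
  if (presence) {
    present_frac <- rowMeans(m$detection_p < detect_alpha)
    keep <- keep & present_frac >= presence_frac
  }
  m$intensities <- m$intensities[keep, , drop = FALSE]
  m$detection_p <- m$detection_p[keep, , drop = FALSE]
  m$probes <- m$probes[keep, , drop = FALSE]
  rownames(m$probes) <- NULL
  attr(m, "n_hla_removed") <- n_hla
  m
}

#' Collapse probes to genes
#'
#' Replaces the probes of each gene by their arithmetic mean per sample
#' (on the log2 scale, after transformation).
#'
#' @param m a `probe_matrix` whose probes all map to a gene symbol.
#' @return a gene x sample matrix with unique gene symbols as row names
#'   and the sample table attached as attribute `samples`.
#' @export
collapse_to_genes <- function(m) {
  stopifnot(inherits(m, "probe_matrix"))
  unmapped <- is.na(m$probes$gene) | m$probes$gene == ""
  if (any(unmapped))
    stop("probes without a gene mapping: ",
         paste(m$probes$probe_id[unmapped], collapse = ", "))
  sums <- rowsum(m$intensities, group = m$probes$gene)
  n <- as.vector(table(m$probes$gene)[rownames(sums)])
  gm <- sums / n
  attr(gm, "samples") <- m$samples
  gm
}

#' Case minus control log2 differences per pair
#'
#' @param g gene x sample matrix from [collapse_to_genes()] (columns
#'   named `<pair_id>_case` / `<pair_id>_ctrl`).
#' @param pairs pair metadata data.frame; every pair must have both
#'   samples present.
#' @return an object of class `paired_diff`: list with `diffs` (gene x
#'   pair matrix of log2 case minus control differences, columns in
#'   `pairs` order) and `pairs` (the metadata).
#' @export
pair_differences <- function(g, pairs) {
  case_cols <- paste0(pairs$pair_id, "_case")
  ctrl_cols <- paste0(pairs$pair_id, "_ctrl")
  missing <- !(case_cols %in% colnames(g)) | !(ctrl_cols %in% colnames(g))
  if (any(missing))
    stop("missing case or control sample for pair(s): ",
         paste(pairs$pair_id[missing], collapse = ", "))
  diffs <- g[, case_cols, drop = FALSE] - g[, ctrl_cols, drop = FALSE]
  colnames(diffs) <- pairs$pair_id
  structure(list(diffs = diffs, pairs = pairs), class = "paired_diff")
}

#' @export
print.paired_diff <- function(x, ...) {
  cat("paired_diff:", nrow(x$diffs), "genes x", ncol(x$diffs), "pairs\n")
  invisible(x)
}

#' Subset a paired-difference object
#'
#' @param pd a `paired_diff`.
#' @param idx pair indices (into `pd$pairs`) or a logical mask.
#' @return the subsetted `paired_diff`.
#' @export
subset_pairs <- function(pd, idx) {
  structure(list(diffs = pd$diffs[, idx, drop = FALSE],
                 pairs = pd$pairs[idx, , drop = FALSE]),
            class = "paired_diff")
}

#' Run the full probe-level preprocessing pipeline
#'
#' Fixed stage order: HLA probe removal, normexp background correction
#' against negative controls, offset-log2 transform with quantile
#' normalization, detection/presence filter, probe-to-gene collapsing,
#' case minus control pair differencing. Probe counts are non-increasing
#' across stages and recorded in the report.
#'
#' @param m raw `probe_matrix`.
#' @param pairs pair metadata (typically after [apply_exclusions()]).
#' @param detect_alpha,presence_frac see [filter_probes()].
#' @param offset see [transform_normalize()].
#' @return list with `diffs` (a `paired_diff`) and `report` (named list
#'   of per-stage probe/sample/gene counts).
#' @export
preprocess_pipeline <- function(m, pairs, detect_alpha = 0.05,
                                presence_frac = 0.70, offset = 16) {
  report <- list(n_probes_raw = nrow(m$intensities),
                 n_samples = ncol(m$intensities))
  m <- filter_probes(m, drop_hla = TRUE, presence = FALSE)
  report$n_hla_removed <- attr(m, "n_hla_removed")
  report$n_probes_after_hla <- nrow(m$intensities)
  m <- background_correct(m)
  m <- transform_normalize(m, offset = offset)
  m <- filter_probes(m, detect_alpha = detect_alpha,
                     presence_frac = presence_frac, drop_hla = FALSE)
  report$n_probes_after_presence <- nrow(m$intensities)
  g <- collapse_to_genes(m)
  report$n_genes <- nrow(g)
  pd <- pair_differences(g, pairs)
  report$n_pairs <- ncol(pd$diffs)
  list(diffs = pd, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param report the `report` element of [preprocess_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
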