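#' Apply the pair exclusion cascade
#'
#' Removes every pair whose `excluded` flag set is non-empty and reports
#' how many pairs each flag removed. Flags are comma-separated strings
#' drawn from `technical_outlier`, `control_cancer`, `second_cancer`,
#' `unknown_metastasis`, `qc_fail`. The operation is idempotent.
#'
#' @param pairs pair metadata data.frame with an `excluded` column.
#' @return the surviving pairs, with attributes `removed_counts` (named
#'   integer vector, pairs removed per flag; a pair carrying two flags
#'   counts under both) and `n_removed`.
#' @export
apply_exclusions <- function(pairs) {
  excl <- pairs$excluded
  excl[is.na(excl)] <- ""
  flagged <- excl != ""
  flags <- unlist(strsplit(excl[flagged], ",", fixed = TRUE))
  flags <- trimws(flags[flags != ""])
  out <- pairs[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_counts") <-
    if (length(flags)) c(table(flags)) else integer()
  attr(out, "n_removed") <- sum(flagged)
  out
}

# Table-1 style stage category: metastatic pairs are reported by substage
.stage_category <- function(pairs) {
  ifelse(pairs$stage == "metastatic", pairs$substage, pairs$stage)
}

.stage_categories <- c("in_situ", "invasive", "regional_lymph",
                       "regional_muscle", "distant")

#' Tabulate pairs by year after diagnosis and stage
#'
#' Year bins are half-open intervals (k-1, k], i.e. the ceiling of the
#' follow-up time, so a time of exactly 1.0 years counts as year 1;
#' times of exactly 0 fall in year 1. Metastatic pairs are split by
#' substage, matching the clinical overview layout.
#'
#' @param pairs pair metadata data.frame.
#' @return an object of class `stage_year_table`: a list with `counts`
#'   (8 x 5 matrix, years x stage categories), `row_totals`,
#'   `col_totals` and `total`.
#' @export
tabulate_stage_by_year <- function(pairs) {
  t <- pairs$time_since_diagnosis
  if (any(is.na(t)) || any(t < 0)) stop("pairs have invalid follow-up times")
  if (any(t > 8)) stop("follow-up time beyond 8 years is out of range")
  year <- pmax(ceiling(t), 1)
  cat_ <- factor(.stage_category(pairs), levels = .stage_categories)
  if (any(is.na(cat_))) stop("pairs have invalid stage/substage")
  counts <- table(factor(year, levels = 1:8), cat_)
  counts <- matrix(as.integer(counts), 8, length(.stage_categories),
                   dimnames = list(year = 1:8, stage = .stage_categories))
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 total = sum(counts)),
            class = "stage_year_table")
}

#' @export
print.stage_year_table <- function(x, ...) {
  m <- cbind(x$counts, Sum = x$row_totals)
  m <- rbind(m, Sum = c(x$col_totals, x$total))
  print(m)
  invisible(x)
}

#' Mean tumor size for one stage category
#'
#' Arithmetic mean of the recorded tumor sizes over pairs of the given
#' stage category, rounded to two decimals for reporting.
#'
#' @param pairs pair metadata data.frame.
#' @param stage one of `"invasive"`, `"regional_lymph"`,
#'   `"regional_muscle"`, `"distant"` (in-situ pairs carry no size).
#' @return mean size in cm, rounded to 2 decimals.
#' @export
mean_tumor_size <- function(pairs, stage) {
  stage <- match.arg(stage, .stage_categories)
  sizes <- pairs$tumor_size[.stage_category(pairs) == stage]
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L)
    stop("no pairs of stage '", stage, "' with a recorded tumor size")
  round(mean(sizes), 2)
}
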