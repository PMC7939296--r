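#' Simulate pair metadata for a matched case-control follow-up cohort
#'
#' Draws one record per case-control pair: follow-up time (uniform on
#' 0-8 years, mirroring a design in which blood sampling dates are
#' randomized independently of diagnosis), stage, metastatic substage,
#' vital status at end of follow-up, and tumor size sampled from the
#' configured clinical size categories (absent for in-situ cases). The
#' `excluded` column holds a comma-separated set of exclusion flags and
#' is empty for every generated pair; flags are attached by QC or by the
#' caller.
#'
#' @param config a [cohort_config()].
#' @return a data.frame with columns `pair_id`, `time_since_diagnosis`
#'   (years), `stage`, `substage` (`NA` unless metastatic),
#'   `vital_status`, `tumor_size` (cm, `NA` for in situ) and `excluded`.
#'   Deterministic given `config` (including its seed).
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_pairs
  empty <- data.frame(pair_id = character(), time_since_diagnosis = numeric(),
                      stage = character(), substage = character(),
                      vital_status = character(), tumor_size = numeric(),
                      excluded = character(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  withr::with_seed(.child_seed(config$seed, 0L), {
    stage <- sample(names(config$stage_probs), n, replace = TRUE,
                    prob = config$stage_probs)
    substage <- rep(NA_character_, n)
    met <- stage == "metastatic"
    if (any(met))
      substage[met] <- sample(names(config$substage_probs), sum(met),
                              replace = TRUE, prob = config$substage_probs)
    died <- stats::rbinom(n, 1L, config$died_prob[stage]) == 1L
    vital_status <- ifelse(died, "died", "survived")
    tumor_size <- rep(NA_real_, n)
    size_class <- ifelse(met, substage, stage)
    for (cl in names(config$tumor_size_weights)) {
      idx <- which(size_class == cl)
      if (length(idx))
        tumor_size[idx] <- sample(config$tumor_size_categories, length(idx),
                                  replace = TRUE,
                                  prob = config$tumor_size_weights[[cl]])
    }
    data.frame(pair_id = sprintf("P%04d", seq_len(n)),
               time_since_diagnosis = stats::runif(n, 0, 8),
               stage = stage, substage = substage,
               vital_status = vital_status, tumor_size = tumor_size,
               excluded = "", stringsAsFactors = FALSE)
  })
}

#' Simulate probe-level expression for a cohort
#'
#' Emulates a two-color-free Illumina-style bead array experiment: every
#' pair contributes a case and a control sample; each probe carries a
#' log-normal expression signal plus an additive Gaussian optical
#' background shared with the negative-control probes. A configurable
#' fraction of genes is expressed near the background so the
#' detection/presence filter has something to remove, and an extra block
#' of probes is flagged as HLA-system probes. Detection p-values are the
#' empirical upper-tail probability of each observed intensity under
#' that sample's negative-control distribution.
#'
#' Signals declared in `config$signal_specs` are added on the log2 scale
#' to the case samples of pairs whose stratum and follow-up time fall
#' inside the spec; the genes carrying each signal are recorded in the
#' result's `signal_genes` element.
#'
#' @param metadata data.frame from [simulate_metadata()]; must be
#'   non-empty.
#' @param config the [cohort_config()] used to generate `metadata`.
#' @return an object of class `probe_matrix`: a list with elements
#'   `intensities` (probe x sample), `detection_p` (probe x sample),
#'   `negative_controls` (control probe x sample), `probes` (data.frame
#'   `probe_id`, `gene`, `is_hla`), `samples` (data.frame `sample_id`,
#'   `pair_id`, `role`) and `signal_genes` (per signal spec, the gene
#'   symbols and directions of the injected shifts).
#' @export
simulate_expression <- function(metadata, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.data.frame(metadata) || nrow(metadata) == 0L)
    stop("metadata must be a non-empty data.frame of pairs")
  n_pairs <- nrow(metadata)
  withr::with_seed(.child_seed(config$seed, 1L), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    probe_gene <- c(genes,
                    if (config$n_probes > config$n_genes)
                      sample(genes, config$n_probes - config$n_genes,
                             replace = TRUE))
    hla_genes <- if (config$n_hla_probes > 0)
      sprintf("HLA.SYN%02d", seq_len(config$n_hla_probes)) else character()
    probes <- data.frame(
      probe_id = c(sprintf("ILMN_%05d", seq_len(config$n_probes)),
                   if (length(hla_genes)) sprintf("ILMN_HLA%02d",
                                                  seq_along(hla_genes))),
      gene = c(probe_gene, hla_genes),
      is_hla = c(rep(FALSE, config$n_probes), rep(TRUE, length(hla_genes))),
      stringsAsFactors = FALSE)
    n_all <- nrow(probes)

    n_low <- round(config$frac_low_expressed * config$n_genes)
    low_genes <- if (n_low > 0) sample(genes, n_low) else character()
    gene_mu <- stats::setNames(
      stats::runif(config$n_genes, config$expressed_log2_range[1],
                   config$expressed_log2_range[2]), genes)
    if (n_low > 0)
      gene_mu[low_genes] <- stats::runif(n_low, config$low_signal_log2_range[1],
                                         config$low_signal_log2_range[2])
    hla_mu <- stats::setNames(
      stats::runif(length(hla_genes), config$expressed_log2_range[1],
                   config$expressed_log2_range[2]), hla_genes)
    probe_mu <- c(gene_mu, hla_mu)[probes$gene] +
      stats::rnorm(n_all, 0, 0.25)

    samples <- data.frame(
      sample_id = as.vector(rbind(paste0(metadata$pair_id, "_case"),
                                  paste0(metadata$pair_id, "_ctrl"))),
      pair_id = rep(metadata$pair_id, each = 2L),
      role = rep(c("case", "ctrl"), times = n_pairs),
      stringsAsFactors = FALSE)
    n_samp <- nrow(samples)

    log2sig <- matrix(stats::rnorm(n_all * n_samp, 0, config$noise_sd),
                      n_all, n_samp) + probe_mu
    dimnames(log2sig) <- list(probes$probe_id, samples$sample_id)

    # inject time-localized case-control shifts
    eligible <- setdiff(genes, low_genes)
    signal_genes <- list()
    for (si in seq_along(config$signal_specs)) {
      sp <- config$signal_specs[[si]]
      if (sp$n_genes > length(eligible))
        stop("signal spec ", si, " asks for ", sp$n_genes,
             " genes but only ", length(eligible),
             " expressed genes are available")
      in_time <- metadata$time_since_diagnosis >= sp$time_window[1] &
        metadata$time_since_diagnosis <= sp$time_window[2]
      in_stratum <- if (sp$stage == "all") rep(TRUE, n_pairs) else
        metadata$stage == sp$stage & metadata$vital_status == sp$vital_status
      target_pairs <- metadata$pair_id[in_time & in_stratum]
      g <- sample(eligible, sp$n_genes)
      dir <- ifelse(stats::runif(sp$n_genes) < sp$direction_mix, 1, -1)
      signal_genes[[si]] <- data.frame(gene = g, direction = dir,
                                       stringsAsFactors = FALSE)
      if (length(target_pairs)) {
        rows <- which(probes$gene %in% g)
        shift <- sp$log2_effect * stats::setNames(dir, g)[probes$gene[rows]]
        cols <- paste0(target_pairs, "_case")
        log2sig[rows, cols] <- log2sig[rows, cols] + shift
      }
    }

    bg <- matrix(stats::rnorm(n_all * n_samp, config$background_mean,
                              config$background_sd), n_all, n_samp)
    intensities <- 2^log2sig + pmax(bg, 0)
    dimnames(intensities) <- dimnames(log2sig)
    nc <- matrix(pmax(stats::rnorm(config$n_negative_controls * n_samp,
                                   config$background_mean,
                                   config$background_sd), 0),
                 config$n_negative_controls, n_samp)
    dimnames(nc) <- list(sprintf("NC_%04d",
                                 seq_len(config$n_negative_controls)),
                         samples$sample_id)

    detection_p <- matrix(NA_real_, n_all, n_samp,
                          dimnames = dimnames(intensities))
    for (s in seq_len(n_samp)) {
      nc_sorted <- sort(nc[, s])
      detection_p[, s] <-
        (config$n_negative_controls -
           findInterval(intensities[, s], nc_sorted)) /
        config$n_negative_controls
    }

    structure(list(intensities = intensities, detection_p = detection_p,
                   negative_controls = nc, probes = probes,
                   samples = samples, signal_genes = signal_genes),
              class = "probe_matrix")
  })
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_metadata()] and
#' [simulate_expression()] from one configuration.
#'
#' @param config a [cohort_config()].
#' @return list with elements `pairs` (metadata data.frame) and `expr`
#'   (a `probe_matrix`).
#' @export
simulate_cohort <- function(config) {
  pairs <- simulate_metadata(config)
  list(pairs = pairs, expr = simulate_expression(pairs, config))
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("probe_matrix:", nrow(x$intensities), "probes x",
      ncol(x$intensities), "samples;",
      nrow(x$negative_controls), "negative controls;",
      sum(x$probes$is_hla), "HLA probes\n")
  invisible(x)
}

#' Write / read pair metadata as CSV
#'
#' Column layout is the one produced by [simulate_metadata()]:
#' `pair_id, time_since_diagnosis, stage, substage, vital_status,
#' tumor_size, excluded`.
#'
#' @param pairs metadata data.frame.
#' @param path CSV file path.
#' @return `read_pair_metadata` returns the data.frame;
#'   `write_pair_metadata` returns `path` invisibly.
#' @export
write_pair_metadata <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pair_metadata
#' @export
read_pair_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pair_id = "character",
                                       stage = "character",
                                       excluded = "character"))
  for (col in c("substage", "vital_status", "excluded"))
    if (is.logical(df[[col]])) df[[col]] <- as.character(df[[col]])
  df$excluded[is.na(df$excluded)] <- ""
  df$substage[df$substage == ""] <- NA_character_
  df
}

#' Write / read a probe matrix as a directory of TSV files
#'
#' Writes `intensities.tsv`, `detection_p.tsv`, `negative_controls.tsv`,
#' `probes.tsv` and `samples.tsv` into `dir`.
#'
#' @param pm a `probe_matrix`.
#' @param dir directory (created if missing).
#' @return `read_probe_matrix` returns a `probe_matrix`;
#'   `write_probe_matrix` returns `dir` invisibly.
#' @export
write_probe_matrix <- function(pm, dir) {
  stopifnot(inherits(pm, "probe_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(
    data.frame(id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wr(pm$intensities, "intensities.tsv")
  wr(pm$detection_p, "detection_p.tsv")
  wr(pm$negative_controls, "negative_controls.tsv")
  utils::write.table(pm$probes, file.path(dir, "probes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(pm$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    m
  }
  structure(list(intensities = rd("intensities.tsv"),
                 detection_p = rd("detection_p.tsv"),
                 negative_controls = rd("negative_controls.tsv"),
                 probes = utils::read.delim(file.path(dir, "probes.tsv"),
                                            stringsAsFactors = FALSE),
                 samples = utils::read.delim(file.path(dir, "samples.tsv"),
                                             stringsAsFactors = FALSE),
                 signal_genes = list()),
            class = "probe_matrix")
}
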