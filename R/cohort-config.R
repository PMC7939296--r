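#' Configuration for a synthetic matched case-control cohort
#'
#' Bundles every tunable of the synthetic cohort generator: cohort size,
#' stage and vital-status composition, tumor-size category weights, probe
#' layout of the expression array, noise and background levels, and the
#' list of injectable differential-expression signals.
#'
#' Defaults reproduce the composition of a 415-pair breast-cancer
#' follow-up cohort: stage proportions 51/227/137 (in situ / invasive /
#' metastatic), metastatic substages 126/2/9 (regional lymph / regional
#' muscle / distant), death probabilities 22/227 for invasive and 39/137
#' for metastatic cases, and tumor sizes drawn from the six clinical
#' categories 0.3, 0.75, 1, 1.5, 3.5 and 5 cm with stage-specific
#' weights. Follow-up times are uniform on 0-8 years by design.
#'
#' @param n_pairs number of case-control pairs.
#' @param stage_probs named probabilities for stages
#'   `in_situ`, `invasive`, `metastatic`; must sum to 1.
#' @param died_prob named per-stage probability that the case died before
#'   the end of follow-up.
#' @param substage_probs named probabilities of the metastatic substages
#'   `regional_lymph`, `regional_muscle`, `distant`; must sum to 1.
#' @param tumor_size_categories the discrete tumor sizes (cm) sampled from.
#' @param tumor_size_weights per-stage (invasive and metastatic substage)
#'   sampling weights over `tumor_size_categories`.
#' @param n_probes number of regular (non-HLA) probes; must be at least
#'   `n_genes` so every gene has a probe.
#' @param n_genes number of gene symbols the probes map to.
#' @param n_hla_probes number of additional probes flagged as HLA-system
#'   probes (removed early in preprocessing).
#' @param n_negative_controls number of negative-control probes.
#' @param frac_low_expressed fraction of genes whose probes sit near the
#'   optical background and therefore fail the detection/presence filter.
#' @param low_signal_log2_range,expressed_log2_range log2 ranges the
#'   per-gene baseline intensities are drawn from for the two classes.
#' @param noise_sd per-sample, per-probe log2 noise standard deviation.
#' @param background_mean,background_sd additive optical background
#'   (intensity units), shared by regular and negative-control probes.
#' @param signal_specs list of [signal_spec()] objects describing
#'   time-localized case-control expression shifts.
#' @param seed integer seed; all generator output is a deterministic
#'   function of the configuration including this seed.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [signal_spec()], [simulate_metadata()], [simulate_expression()]
#' @export
cohort_config <- function(n_pairs = 415,
                          stage_probs = c(in_situ = 51, invasive = 227,
                                          metastatic = 137) / 415,
                          died_prob = c(in_situ = 0.04,
                                        invasive = 22 / 227,
                                        metastatic = 39 / 137),
                          substage_probs = c(regional_lymph = 126,
                                             regional_muscle = 2,
                                             distant = 9) / 137,
                          tumor_size_categories = c(0.3, 0.75, 1, 1.5, 3.5, 5),
                          tumor_size_weights = list(
                            invasive        = c(12, 43, 1, 108, 28, 2),
                            regional_lymph  = c(2, 11, 0, 46, 40, 2),
                            regional_muscle = c(3, 12, 0, 48, 42, 3),
                            distant         = c(1, 1, 0, 2, 2, 1)),
                          n_probes = 2500,
                          n_genes = 2000,
                          n_hla_probes = 38,
                          n_negative_controls = 100,
                          frac_low_expressed = 0.2,
                          low_signal_log2_range = c(1, 4),
                          expressed_log2_range = c(7, 12),
                          noise_sd = 0.25,
                          background_mean = 100,
                          background_sd = 10,
                          signal_specs = list(),
                          seed = 1L) {
  stopifnot(length(n_pairs) == 1L, n_pairs >= 0)
  if (!setequal(names(stage_probs), c("in_situ", "invasive", "metastatic")))
    stop("stage_probs must be named in_situ, invasive, metastatic")
  if (any(stage_probs < 0) || abs(sum(stage_probs) - 1) > 1e-8)
    stop("stage_probs must be non-negative and sum to 1")
  if (any(substage_probs < 0) || abs(sum(substage_probs) - 1) > 1e-8)
    stop("substage_probs must be non-negative and sum to 1")
  if (any(died_prob < 0 | died_prob > 1))
    stop("died_prob entries must lie in [0, 1]")
  stopifnot(n_probes >= 1, n_genes >= 1, n_negative_controls >= 1,
            n_hla_probes >= 0, n_probes >= n_genes,
            frac_low_expressed >= 0, frac_low_expressed <= 1,
            noise_sd >= 0, background_sd >= 0, background_mean >= 0)
  for (w in tumor_size_weights)
    if (length(w) != length(tumor_size_categories) || any(w < 0) || sum(w) <= 0)
      stop("each tumor_size_weights entry must be non-negative weights, ",
           "one per tumor size category, with positive sum")
  for (sp in signal_specs)
    if (!inherits(sp, "signal_spec"))
      stop("signal_specs must be a list of signal_spec objects")
  cfg <- list(n_pairs = as.integer(n_pairs),
              stage_probs = stage_probs[c("in_situ", "invasive", "metastatic")],
              died_prob = died_prob,
              substage_probs = substage_probs[c("regional_lymph",
                                               "regional_muscle", "distant")],
              tumor_size_categories = tumor_size_categories,
              tumor_size_weights = tumor_size_weights,
              n_probes = as.integer(n_probes),
              n_genes = as.integer(n_genes),
              n_hla_probes = as.integer(n_hla_probes),
              n_negative_controls = as.integer(n_negative_controls),
              frac_low_expressed = frac_low_expressed,
              low_signal_log2_range = low_signal_log2_range,
              expressed_log2_range = expressed_log2_range,
              noise_sd = noise_sd,
              background_mean = background_mean,
              background_sd = background_sd,
              signal_specs = signal_specs,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Specification of a time-localized differential-expression signal
#'
#' Describes a case-control expression shift confined to one
#' stage/vital-status stratum and one follow-up time window. The
#' generator adds `log2_effect` (up for a fraction `direction_mix` of the
#' chosen genes, down for the rest) to the case sample of every pair
#' whose stratum matches and whose follow-up time falls inside
#' `time_window`.
#'
#' @param stage `"in_situ"`, `"invasive"`, `"metastatic"`, or `"all"` to
#'   target every pair regardless of stratum.
#' @param vital_status `"died"` or `"survived"`; ignored when
#'   `stage == "all"`.
#' @param time_window length-2 numeric, years since diagnosis, within
#'   the 0-8 year follow-up range.
#' @param n_genes number of genes carrying the shift.
#' @param log2_effect mean case minus control shift in log2 units.
#' @param direction_mix fraction of the affected genes shifted upwards.
#'
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(stage = "metastatic", vital_status = "died",
                        time_window = c(2, 4), n_genes = 200,
                        log2_effect = 1, direction_mix = 1) {
  stage <- match.arg(stage, c("all", "in_situ", "invasive", "metastatic"))
  vital_status <- match.arg(vital_status, c("died", "survived"))
  stopifnot(length(time_window) == 2L, time_window[1] <= time_window[2])
  if (time_window[1] < 0 || time_window[2] > 8)
    stop("time_window must lie within the 0-8 year follow-up range")
  stopifnot(n_genes >= 1, direction_mix >= 0, direction_mix <= 1)
  structure(list(stage = stage, vital_status = vital_status,
                 time_window = as.numeric(time_window),
                 n_genes = as.integer(n_genes),
                 log2_effect = as.numeric(log2_effect),
                 direction_mix = direction_mix),
            class = "signal_spec")
}

#' Write / read a cohort configuration as YAML
#'
#' @param config a [cohort_config()] object.
#' @param path file path of the YAML document.
#' @return `read_cohort_config` returns a `cohort_config`;
#'   `write_cohort_config` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$signal_specs <- lapply(x$signal_specs, unclass)
  x$tumor_size_weights <- lapply(x$tumor_size_weights, as.numeric)
  # named vectors must go out as YAML maps, not bare sequences
  for (f in c("stage_probs", "died_prob", "substage_probs"))
    x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$signal_specs <- lapply(x$signal_specs, function(sp) do.call(signal_spec, sp))
  x$stage_probs <- unlist(x$stage_probs)
  x$died_prob <- unlist(x$died_prob)
  x$substage_probs <- unlist(x$substage_probs)
  x$tumor_size_weights <- lapply(x$tumor_size_weights, unlist)
  do.call(cohort_config, x)
}

# deterministic child seed for the k-th consumer of a config seed
.child_seed <- function(seed, k) {
  as.integer((as.double(seed) + k * 10007) %% 2147483629)
}
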