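#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. Defaults
#' follow the published analysis: FDR 0.1 throughout, at least 10 mutant cell
#' lines per candidate driver, more than 300 CDE+ genes for a driver to be
#' reported genome-wide, the chi-squared approximation of Fisher's test when
#' every contingency cell exceeds 30, a day-0 read-count floor of 20 for
#' pooled screens, a screen-QC threshold of 0.6, and a 20% Cas9-activity gate
#' for the allele-frequency expansion analysis.
#'
#' @param alpha_fdr FDR threshold used for every BH-corrected call.
#' @param min_mutant_lines minimum mutant cell lines for a driver to be tested.
#' @param ccd_min_cde_pos minimum number of CDE+ genes for a scanned driver to
#'   be reported.
#' @param chi2_min_cell contingency cell count above which the chi-squared
#'   approximation replaces the exact Fisher test.
#' @param min_day0_count pooled-screen sgRNAs with any day-0 raw count below
#'   this are removed.
#' @param qc_threshold screen-quality metric (AUPRC) a screen must exceed.
#' @param cas9_activity_min cell lines below this Cas9 activity are discarded
#'   from the allele-frequency expansion analysis (strict less-than).
#' @param permutations permutations for the gene-sampling GSEA null and for
#'   Monte-Carlo fallbacks.
#' @param seed integer seed used by every randomized operation.
#' @param shrna_exclusion `"same_direction"` (default) excludes a CRISPR hit
#'   from the CDE sets only when the shRNA screen calls it in the same
#'   direction; `"any_direction"` excludes on any significant shRNA call.
#' @param sides `"two_sided"` (default) or `"one_sided"` differential-
#'   essentiality testing mode.
#' @param log_mutation_load apply log10(x+1) to the cohort mutation load.
#' @return A list of class `"cdescan_config"`.
#' @export
analysis_config <- function(alpha_fdr = 0.1,
                            min_mutant_lines = 10L,
                            ccd_min_cde_pos = 300L,
                            chi2_min_cell = 30L,
                            min_day0_count = 20L,
                            qc_threshold = 0.6,
                            cas9_activity_min = 0.20,
                            permutations = 10000L,
                            seed = 1L,
                            shrna_exclusion = c("same_direction", "any_direction"),
                            sides = c("two_sided", "one_sided"),
                            log_mutation_load = FALSE) {
  shrna_exclusion <- match.arg(shrna_exclusion)
  sides <- match.arg(sides)
  stopifnot(alpha_fdr > 0, alpha_fdr < 1,
            min_mutant_lines >= 1, ccd_min_cde_pos >= 0,
            chi2_min_cell >= 0, min_day0_count >= 0,
            qc_threshold >= 0, qc_threshold <= 1,
            cas9_activity_min >= 0, cas9_activity_min <= 1,
            permutations >= 1)
  seed <- as.integer(seed)
  stopifnot(!is.na(seed))
  structure(list(alpha_fdr = alpha_fdr,
                 min_mutant_lines = as.integer(min_mutant_lines),
                 ccd_min_cde_pos = as.integer(ccd_min_cde_pos),
                 chi2_min_cell = as.integer(chi2_min_cell),
                 min_day0_count = as.integer(min_day0_count),
                 qc_threshold = qc_threshold,
                 cas9_activity_min = cas9_activity_min,
                 permutations = as.integer(permutations),
                 seed = seed,
                 shrna_exclusion = shrna_exclusion,
                 sides = sides,
                 log_mutation_load = log_mutation_load),
            class = "cdescan_config")
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so that typos fail loudly.
#' @param path YAML file whose keys mirror [analysis_config()] arguments.
#' @return A `"cdescan_config"` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(analysis_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write a run manifest
#'
#' Records inputs, thresholds, seed and package version alongside every run so
#' results are reproducible from the manifest alone.
#' @param config a `"cdescan_config"` list.
#' @param inputs named character vector or list describing input files/objects.
#' @param path output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(config, inputs, path) {
  manifest <- list(
    package = "cdescan",
    version = as.character(utils::packageVersion("cdescan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = as.list(inputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
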