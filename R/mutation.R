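# Binary mutant/WT profile derivation and panel alignment.

#' Default loss-of-function hotspot list for p53
#'
#' The four most frequent pathogenic DNA-binding-domain hotspots used to
#' supplement the nonsense/frameshift/indel classes in `lof_only` mode.
#' @export
P53_LOF_HOTSPOTS <- c("R248Q", "R273H", "R248W", "R175H")

#' Default gain-of-function hotspot list for KRAS
#'
#' Three canonical activating hotspot variants; configurable because hotspot
#' choice is a modelling decision.
#' @export
KRAS_GOF_HOTSPOTS <- c("G12D", "G12V", "G13D")

# Variant classes that never qualify as non-synonymous
.silent_classes <- c("silent", "intronic")
# Classes qualifying as loss-of-function irrespective of protein change
.lof_classes <- c("nonsense", "frameshift", "indel")

#' Derive a binary mutation profile for one driver
#'
#' A cell line is mutant iff it carries at least one qualifying variant of
#' the driver. Silent and intronic variants never qualify. Modes:
#' `any_nonsynonymous` accepts every non-silent class; `lof_only` accepts
#' nonsense/frameshift/indel or a listed (pathogenic hotspot) protein change;
#' `gof_hotspots` accepts only the listed protein changes.
#'
#' @param muts a `"mutation_table"`.
#' @param driver gene id.
#' @param cell_lines cell lines the profile must cover (e.g. the screen
#'   panel); lines without qualifying variants are WT.
#' @param mode classification mode.
#' @param hotspots protein changes used by `lof_only` / `gof_hotspots`.
#' @return A list of class `"mutation_profile"`: `driver`, `mode`, `status`
#'   (named 0/1 integer vector over `cell_lines`), `hotspots`.
#' @export
derive_mutation_profile <- function(muts, driver, cell_lines,
                                    mode = c("any_nonsynonymous", "lof_only",
                                             "gof_hotspots"),
                                    hotspots = NULL) {
  mode <- match.arg(mode)
  if (mode == "gof_hotspots" && (is.null(hotspots) || length(hotspots) == 0))
    stop("derive_mutation_profile: gof_hotspots mode requires a hotspot list")
  if (mode == "lof_only" && is.null(hotspots)) hotspots <- P53_LOF_HOTSPOTS
  rec <- muts[muts$gene == driver, , drop = FALSE]
  if (nrow(rec) == 0)
    warning("derive_mutation_profile: driver '", driver,
            "' absent from mutation table; all-WT profile")
  qualifies <- switch(mode,
    any_nonsynonymous = !(rec$variant_classification %in% .silent_classes),
    lof_only = rec$variant_classification %in% .lof_classes |
      (!(rec$variant_classification %in% .silent_classes) &
         rec$protein_change %in% hotspots),
    gof_hotspots = !(rec$variant_classification %in% .silent_classes) &
      rec$protein_change %in% hotspots)
  mutant_lines <- unique(rec$cell_line[qualifies])
  status <- stats::setNames(as.integer(cell_lines %in% mutant_lines), cell_lines)
  structure(list(driver = driver, mode = mode, status = status,
                 hotspots = hotspots),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("mutation_profile: %s [%s], %d mutant / %d WT\n", x$driver,
              x$mode, sum(x$status == 1L), sum(x$status == 0L)))
  invisible(x)
}

#' Align two screens and a mutation table on their common panel
#'
#' Restricts both matrices to the intersection of genes and of cell lines
#' (identical ordering in both outputs) and the mutation table to the shared
#' cell lines; intersection sizes are reported via a message.
#'
#' @param v1,v2 `"viability_matrix"` objects.
#' @param muts optional `"mutation_table"`.
#' @return list(v1, v2, muts, genes, cell_lines).
#' @export
intersect_panels <- function(v1, v2, muts = NULL) {
  genes <- intersect(screen_genes(v1), screen_genes(v2))
  lines <- intersect(screen_lines(v1), screen_lines(v2))
  if (length(genes) == 0 || length(lines) == 0)
    stop("intersect_panels: empty gene or cell-line intersection")
  message(sprintf("intersect_panels: %d shared genes, %d shared cell lines",
                  length(genes), length(lines)))
  v1$values <- v1$values[genes, lines, drop = FALSE]
  v2$values <- v2$values[genes, lines, drop = FALSE]
  v1$n_missing <- sum(!is.finite(v1$values))
  v2$n_missing <- sum(!is.finite(v2$values))
  if (!is.null(muts)) muts <- muts[muts$cell_line %in% lines, , drop = FALSE]
  list(v1 = v1, v2 = v2, muts = muts, genes = genes, cell_lines = lines)
}
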