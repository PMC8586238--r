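# Domain containers and readers/writers for the delimited formats the
# pipeline touches: DepMap-style gene x cell-line score matrices, minimal
# MAF-like mutation tables, GMT gene sets, BED intervals (0-based half-open)
# and UCSC-style cytoband tables.

#' Construct a viability matrix
#'
#' Gene x cell-line post-knockout viability scores for one screen modality.
#' The package-wide sign convention is the DepMap gene-effect one: lower
#' score = more essential. Inputs scored the other way round can be flipped
#' with `invert = TRUE`.
#'
#' @param values numeric matrix, genes in rows (rownames), cell lines in
#'   columns (colnames).
#' @param modality `"crispr_ko"`, `"shrna"` or `"crispri"`.
#' @param invert flip the sign to restore the lower-is-essential convention.
#' @return A `"viability_matrix"` object.
#' @export
viability_matrix <- function(values, modality = c("crispr_ko", "shrna", "crispri"),
                             invert = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("viability_matrix: values must carry gene rownames and cell-line colnames")
  if (anyDuplicated(rownames(values)))
    stop("viability_matrix: duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("viability_matrix: duplicate cell-line identifiers")
  storage.mode(values) <- "double"
  if (invert) values <- -values
  all_na <- rowSums(is.finite(values)) == 0
  if (any(all_na))
    stop("viability_matrix: gene(s) with no finite value: ",
         paste(utils::head(rownames(values)[all_na], 5), collapse = ", "))
  structure(list(values = values, modality = modality,
                 n_missing = sum(!is.finite(values))),
            class = "viability_matrix")
}

#' @export
print.viability_matrix <- function(x, ...) {
  cat(sprintf("viability_matrix [%s]: %d genes x %d cell lines (%d missing)\n",
              x$modality, nrow(x$values), ncol(x$values), x$n_missing))
  invisible(x)
}

#' Genes of a viability matrix
#' @param x a `"viability_matrix"`.
#' @return Character vector of gene ids.
#' @export
screen_genes <- function(x) rownames(x$values)

#' Cell lines of a viability matrix
#' @param x a `"viability_matrix"`.
#' @return Character vector of cell-line ids.
#' @export
screen_lines <- function(x) colnames(x$values)

#' Load a screen matrix from CSV
#'
#' Expects the DepMap dialect: one header row of cell-line ids and one
#' leading column of gene ids. Orientation is checked with an explicit
#' heuristic: if `transpose = "auto"` and the file has at least five times as
#' many columns as rows, it is assumed to be cell-lines-by-genes and is
#' transposed (a message reports this).
#'
#' @param path CSV file path.
#' @param modality screen modality of the file.
#' @param invert flip sign on load (for inputs scored higher-is-essential).
#' @param transpose `"auto"`, `"never"` or `"always"`.
#' @return A `"viability_matrix"`.
#' @export
load_screen <- function(path, modality = c("crispr_ko", "shrna", "crispri"),
                        invert = FALSE,
                        transpose = c("auto", "never", "always")) {
  modality <- match.arg(modality)
  transpose <- match.arg(transpose)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("load_screen: need an id column plus data columns")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("load_screen: duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(!is.na(m) & is.na(suppressWarnings(array(as.numeric(m), dim(m)))))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("load_screen: unparseable numeric value at row '%s', column '%s'",
                 ids[rc[1L]], colnames(m)[rc[2L]]))
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  do_t <- switch(transpose,
                 never = FALSE,
                 always = TRUE,
                 auto = ncol(m) >= 5L * nrow(m))
  if (do_t) {
    message("load_screen: wide layout detected (", nrow(m), " rows x ",
            ncol(m), " columns); transposing to genes-by-cell-lines")
    m <- t(m)
  }
  viability_matrix(m, modality, invert = invert)
}

#' Write a viability matrix to CSV
#'
#' Round-trips bit-exactly through [load_screen()] (values are serialized at
#' full precision).
#' @param x a `"viability_matrix"`.
#' @param path output CSV path.
#' @export
write_screen <- function(x, path) {
  df <- data.frame(gene = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.variant_classes <- c("missense", "nonsense", "frameshift", "indel",
                      "splice", "silent", "intronic", "other")

# MAF-dialect -> internal variant classification
.maf_class_map <- c(
  "Missense_Mutation" = "missense", "Nonsense_Mutation" = "nonsense",
  "Frame_Shift_Del" = "frameshift", "Frame_Shift_Ins" = "frameshift",
  "In_Frame_Del" = "indel", "In_Frame_Ins" = "indel",
  "Splice_Site" = "splice", "Silent" = "silent", "Intron" = "intronic")

#' Construct a mutation table
#'
#' Minimal MAF-like record set: one row per (cell line, gene, variant).
#'
#' @param cell_line,gene character vectors.
#' @param variant_classification one of `r paste(.variant_classes, collapse = ", ")`;
#'   common MAF spellings (e.g. `Missense_Mutation`) are mapped automatically.
#' @param protein_change protein-level change (e.g. `"R248Q"`), `NA` allowed.
#' @param allele_frequency optional numeric in [0, 1].
#' @return A data.frame of class `"mutation_table"`.
#' @export
mutation_table <- function(cell_line, gene, variant_classification,
                           protein_change = NA_character_,
                           allele_frequency = NA_real_) {
  vc <- as.character(variant_classification)
  mapped <- .maf_class_map[vc]
  vc <- ifelse(is.na(mapped), vc, mapped)
  bad <- setdiff(unique(vc), .variant_classes)
  if (length(bad) > 0)
    stop("mutation_table: unknown variant classification(s): ",
         paste(bad, collapse = ", "))
  af <- as.numeric(allele_frequency)
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("mutation_table: allele_frequency must lie in [0, 1]")
  df <- data.frame(cell_line = as.character(cell_line),
                   gene = as.character(gene),
                   variant_classification = vc,
                   protein_change = as.character(protein_change),
                   allele_frequency = af,
                   stringsAsFactors = FALSE)
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Read a mutation table from a delimited file
#'
#' Required columns: `cell_line`, `gene`, `variant_classification`; optional:
#' `protein_change`, `allele_frequency`.
#' @param path TSV/CSV path (separator sniffed from the extension, `.csv` =
#'   comma, otherwise tab).
#' @return A `"mutation_table"`.
#' @export
read_mutation_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("cell_line", "gene", "variant_classification")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_mutation_table: missing column(s): ", paste(miss, collapse = ", "))
  mutation_table(df$cell_line, df$gene, df$variant_classification,
                 if ("protein_change" %in% names(df)) df$protein_change else NA,
                 if ("allele_frequency" %in% names(df)) df$allele_frequency else NA)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, members).
#' @param source_tag free-text provenance tag stored on the result.
#' @return A named list of character vectors with attribute `source_tag`.
#' @export
read_gmt <- function(path, source_tag = "pathway") {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) stop("read_gmt: empty gene set present")
  attr(sets, "source_tag") <- source_tag
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read BED intervals (0-based half-open)
#'
#' @param path BED3+ file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `name` when a fourth column is present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("read_bed: need at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4]])
  if (any(out$start >= out$end))
    stop("read_bed: intervals must satisfy start < end")
  out
}

#' Read a UCSC-style cytoband table
#'
#' @param path tab-delimited file: chrom, start, end, band name, stain.
#' @return data.frame with `chrom`, `start`, `end`, `band` (0-based half-open).
#' @export
read_cytobands <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("read_cytobands: need at least 4 columns")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), band = as.character(df[[4]]),
             stringsAsFactors = FALSE)
}

#' Assemble a genomic annotation bundle
#'
#' All coordinates are 0-based half-open (BED convention); chromosome naming
#' must be consistent across the tables.
#'
#' @param gene_locations data.frame: `gene`, `chrom`, `start`, `end`.
#' @param cytobands data.frame: `chrom`, `start`, `end`, `band`.
#' @param cfs_bands character vector of band names that are common fragile
#'   sites.
#' @param sgrna_sites data.frame: `chrom`, `position`, `sgrna_id`, `gene`.
#' @param hac_intervals data.frame: `chrom`, `start`, `end` (highly accessible
#'   chromatin).
#' @return A list of class `"genomic_annotation"`.
#' @export
genomic_annotation <- function(gene_locations, cytobands = NULL,
                               cfs_bands = character(0), sgrna_sites = NULL,
                               hac_intervals = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_locations)))
  if (any(gene_locations$start >= gene_locations$end))
    stop("genomic_annotation: gene intervals must satisfy start < end")
  if (!is.null(cytobands) && any(cytobands$start >= cytobands$end))
    stop("genomic_annotation: cytoband intervals must satisfy start < end")
  if (!is.null(hac_intervals) && any(hac_intervals$start >= hac_intervals$end))
    stop("genomic_annotation: HAC intervals must satisfy start < end")
  structure(list(gene_locations = gene_locations, cytobands = cytobands,
                 cfs_bands = as.character(cfs_bands),
                 sgrna_sites = sgrna_sites, hac_intervals = hac_intervals),
            class = "genomic_annotation")
}

# 0-based half-open intervals -> GRanges (1-based closed)
.granges_from_halfopen <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}
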