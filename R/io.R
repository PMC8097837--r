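#' Read a gene catalog table
#'
#' Reads a tab-separated catalog with columns \code{gene_id},
#' \code{length_aa} and optional \code{taxon} and \code{function}. Gzip
#' input is handled transparently.
#'
#' @param path path to a TSV (optionally .gz) file with a header row.
#' @return A \linkS4class{GeneCatalog}.
#' @export
readGeneCatalog <- function(path) {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- setdiff(c("gene_id", "length_aa"), colnames(tbl))
    if (length(need))
        stop("catalog file missing column(s): ", paste(need, collapse = ", "))
    GeneCatalog(tbl$gene_id, tbl$length_aa,
                taxon = if ("taxon" %in% colnames(tbl)) tbl$taxon,
                fun = if ("function" %in% colnames(tbl)) tbl[["function"]])
}

ALIGNMENT_COLUMNS <- c("specimen", "read_id", "gene_id", "score",
                       "gene_start", "gene_end", "aligned_bases")

#' Read translated-alignment records
#'
#' Reads the tab-separated alignment table produced by aligning WGS reads
#' against the protein gene catalog (blastx-style). Columns: specimen,
#' read_id, gene_id, score, gene_start, gene_end, aligned_bases.
#' Coordinates are 1-based inclusive on the amino-acid axis of the gene;
#' aligned_bases counts nucleotides. Gzip input is handled transparently.
#'
#' @param path path to a TSV (optionally .gz) file with a header row.
#' @return A data.frame of alignment records.
#' @export
readAlignments <- function(path) {
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- setdiff(ALIGNMENT_COLUMNS, colnames(tbl))
    if (length(need))
        stop("alignment file missing column(s): ", paste(need, collapse = ", "))
    validateAlignments(tbl)
}

#' Validate alignment records
#'
#' Checks the structural invariants of an alignment table: positive
#' aligned_bases, well-formed 1-based coordinates, non-negative scores.
#'
#' @param alignments data.frame with the alignment columns.
#' @param catalog optional \linkS4class{GeneCatalog}; when given, every
#'   gene_id must exist in it and gene_end must not exceed the gene length.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validateAlignments <- function(alignments, catalog = NULL) {
    stopifnot(is.data.frame(alignments))
    need <- setdiff(ALIGNMENT_COLUMNS, colnames(alignments))
    if (length(need))
        stop("alignment table missing column(s): ", paste(need, collapse = ", "))
    if (nrow(alignments)) {
        if (any(alignments$aligned_bases <= 0))
            stop("aligned_bases must be positive")
        if (any(alignments$gene_start < 1L))
            stop("gene_start must be >= 1 (1-based inclusive)")
        if (any(alignments$gene_end < alignments$gene_start))
            stop("gene_end must be >= gene_start")
        if (any(alignments$score < 0))
            stop("score must be non-negative")
        if (!is.null(catalog)) {
            len <- geneLengths(catalog)
            unknown <- setdiff(alignments$gene_id, names(len))
            if (length(unknown))
                stop("gene_id not in catalog: ",
                     paste(utils::head(unknown, 5), collapse = ", "))
            if (any(alignments$gene_end > len[alignments$gene_id]))
                stop("gene_end exceeds catalog gene length")
        }
    }
    alignments
}

#' Parse a specimen manifest
#'
#' Reads the CSV manifest naming each specimen, its FASTQ file pair(s) and
#' any covariates used in the statistical formula. A specimen may span
#' multiple rows (one per file pair); covariate values must agree across
#' the rows of one specimen.
#'
#' @param path path to a CSV file with columns \code{specimen}, \code{R1},
#'   \code{R2} plus arbitrary covariate columns.
#' @return A list with elements \code{specimens} (character vector),
#'   \code{files} (data.frame specimen/R1/R2, one row per pair) and
#'   \code{covariates} (data.frame, one row per specimen, rownames =
#'   specimen).
#' @export
parseManifest <- function(path) {
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- setdiff(c("specimen", "R1", "R2"), colnames(tbl))
    if (length(need))
        stop("manifest missing required column(s): ",
             paste(need, collapse = ", "))
    if (any(is.na(tbl$specimen)) || any(!nzchar(tbl$specimen)))
        stop("manifest: specimen must be non-empty")
    if (anyDuplicated(tbl[, c("specimen", "R1")]))
        stop("manifest: duplicate (specimen, R1) pair")
    cov_cols <- setdiff(colnames(tbl), c("specimen", "R1", "R2"))
    specs <- unique(tbl$specimen)
    covariates <- NULL
    if (length(cov_cols)) {
        per_spec <- lapply(specs, function(s) {
            rows <- unique(tbl[tbl$specimen == s, cov_cols, drop = FALSE])
            if (nrow(rows) > 1L)
                stop("manifest: covariates differ across rows of specimen ", s)
            rows
        })
        covariates <- do.call(rbind, per_spec)
    } else {
        covariates <- data.frame(row.names = seq_along(specs))
    }
    rownames(covariates) <- specs
    list(specimens = specs,
         files = tbl[, c("specimen", "R1", "R2")],
         covariates = covariates)
}
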