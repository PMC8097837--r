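GENOME_ALIGNMENT_COLUMNS <- c("gene_id", "genome_id", "contig_id", "start",
                              "end", "strand", "pct_identity")

.validateGenomeAlignments <- function(records) {
    stopifnot(is.data.frame(records))
    need <- setdiff(GENOME_ALIGNMENT_COLUMNS, colnames(records))
    if (length(need))
        stop("genome alignment table missing column(s): ",
             paste(need, collapse = ", "))
    if (nrow(records)) {
        if (any(records$start < 1L))
            stop("start must be >= 1 (1-based inclusive)")
        if (any(records$end < records$start))
            stop("end must be >= start")
        if (any(records$pct_identity < 0) || any(records$pct_identity > 100))
            stop("pct_identity must lie in [0, 100]")
    }
    records
}

.genomeAlignmentsToGRanges <- function(records) {
    GenomicRanges::GRanges(
        seqnames = records$contig_id,
        ranges = IRanges::IRanges(start = records$start, end = records$end),
        strand = ifelse(records$strand %in% c("+", "-"), records$strand, "*"),
        gene_id = records$gene_id,
        genome_id = records$genome_id,
        pct_identity = records$pct_identity)
}

#' Filter gene-to-genome alignments by identity and coverage
#'
#' Keeps alignments meeting a minimum percent identity and, when a catalog
#' is supplied, a minimum percent of the gene's nucleotide length covered
#' by the alignment interval.
#'
#' @param records data.frame of gene-to-genome alignments (columns gene_id,
#'   genome_id, contig_id, start, end, strand, pct_identity; nucleotide
#'   coordinates, 1-based inclusive).
#' @param catalog optional \linkS4class{GeneCatalog} supplying amino-acid
#'   gene lengths (nucleotide length = 3 x length_aa).
#' @param min_identity minimum percent identity (default 90).
#' @param min_coverage minimum percent of the gene covered (default 50;
#'   only applied when \code{catalog} is given).
#' @return The filtered data.frame.
#' @export
filterGenomeAlignments <- function(records, catalog = NULL,
                                   min_identity = 90, min_coverage = 50) {
    records <- .validateGenomeAlignments(records)
    keep <- records$pct_identity >= min_identity
    if (!is.null(catalog)) {
        len_nt <- 3 * geneLengths(catalog)[records$gene_id]
        if (any(is.na(len_nt)))
            stop("gene_id not in catalog: ",
                 paste(utils::head(unique(
                     records$gene_id[is.na(len_nt)]), 5), collapse = ", "))
        cov <- 100 * (records$end - records$start + 1) / len_nt
        keep <- keep & cov >= min_coverage
    }
    records[keep, , drop = FALSE]
}

#' Per-genome association summary
#'
#' Computes the proportion of a reference genome covered by alignments of
#' outcome-associated genes: the union length (overlaps counted once) of
#' the alignment intervals of genes in \code{associated_genes}, divided by
#' the genome's total length.
#'
#' @param records data.frame of gene-to-genome alignments for one genome.
#' @param associated_genes character vector of associated gene identifiers.
#' @param total_length total genome length in nucleotides (> 0).
#' @return List with \code{genome_id}, \code{total_length},
#'   \code{aligned_associated_bases} and \code{proportion_associated}.
#' @export
summarizeGenome <- function(records, associated_genes, total_length) {
    if (total_length <= 0)
        stop("total_length must be positive")
    records <- .validateGenomeAlignments(records)
    gid <- unique(records$genome_id)
    if (length(gid) > 1L)
        stop("records must come from a single genome")
    sel <- records[records$gene_id %in% associated_genes, , drop = FALSE]
    bases <- 0L
    if (nrow(sel)) {
        gr <- .genomeAlignmentsToGRanges(sel)
        bases <- sum(IRanges::width(GenomicRanges::reduce(
            gr, ignore.strand = TRUE)))
    }
    list(genome_id = if (length(gid)) gid else NA_character_,
         total_length = total_length,
         aligned_associated_bases = as.integer(bases),
         proportion_associated = bases / total_length)
}

#' Detect contiguous genomic islands
#'
#' Single-linkage merging of gene alignments along the genome: alignments
#' whose intervals are separated by at most \code{max_gap} nucleotides
#' (gap = start2 - end1 - 1) join one island. Islands never span contigs;
#' strand is ignored for contiguity. Each island carries its member genes
#' and, when a gene-to-CAG map is supplied, the CAGs they belong to.
#'
#' @param records data.frame of gene-to-genome alignments (one genome,
#'   typically restricted to genes of outcome-associated CAGs).
#' @param max_gap maximum tolerated gap in nucleotides (default 5000).
#' @param gene_to_cag optional named character vector mapping gene_id to
#'   cag_id (e.g. \code{membership(partition)}).
#' @return A \link[GenomicRanges]{GRanges}: one range per island with
#'   metadata columns \code{genome_id}, \code{member_genes} and
#'   \code{cag_ids} (CharacterList) and \code{span_bp}.
#' @export
detectIslands <- function(records, max_gap = 5000L, gene_to_cag = NULL) {
    if (max_gap < 0)
        stop("max_gap must be non-negative")
    records <- .validateGenomeAlignments(records)
    if (!nrow(records))
        return(GenomicRanges::GRanges())
    gr <- .genomeAlignmentsToGRanges(records)
    isl <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                                 ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(gr, isl, ignore.strand = TRUE)
    genes <- S4Vectors::splitAsList(
        gr$gene_id[S4Vectors::queryHits(hits)],
        factor(S4Vectors::subjectHits(hits), levels = seq_along(isl)))
    genes <- IRanges::CharacterList(lapply(genes, function(g) sort(unique(g))))
    isl$genome_id <- rep(unique(records$genome_id)[1L], length(isl))
    isl$member_genes <- genes
    if (!is.null(gene_to_cag)) {
        isl$cag_ids <- IRanges::CharacterList(lapply(genes, function(g) {
            sort(unique(unname(gene_to_cag[intersect(g, names(gene_to_cag))])))
        }))
    } else {
        isl$cag_ids <- IRanges::CharacterList(
            rep(list(character()), length(isl)))
    }
    isl$span_bp <- IRanges::width(isl)
    isl
}

#' Classify a CAG as core or accessory
#'
#' A CAG found (by member-gene alignment) in at least
#' \code{core_genome_fraction} of the reference genomes of the focal taxon
#' is classified core; otherwise accessory (strain-specific).
#'
#' @param cag a single CAG identifier.
#' @param genome_hits logical vector: presence of >= 1 member-gene
#'   alignment per reference genome.
#' @param specimen_detection logical vector: detection of the CAG per
#'   specimen.
#' @param core_genome_fraction classification threshold in [0, 1]
#'   (default 0.9).
#' @return List with \code{cag_id}, \code{genomes_present},
#'   \code{specimens_present} (fractions) and \code{classification}.
#' @export
classifyCoreAccessory <- function(cag, genome_hits, specimen_detection,
                                  core_genome_fraction = 0.9) {
    if (!length(genome_hits))
        stop("at least one genome must be evaluated")
    gp <- mean(genome_hits)
    sp <- if (length(specimen_detection)) mean(specimen_detection) else NA_real_
    list(cag_id = cag,
         genomes_present = gp,
         specimens_present = sp,
         classification = if (gp >= core_genome_fraction) "core" else "accessory")
}

# structural pre-validation of a GFF3 file so malformed lines are reported
# with their line number (the downstream parser does not track them)
.checkGFF3 <- function(path) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln) || startsWith(ln, "#")) next
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) != 9L)
            stop("malformed GFF line ", i, ": expected 9 tab-separated fields")
        st <- suppressWarnings(as.integer(f[4]))
        en <- suppressWarnings(as.integer(f[5]))
        if (is.na(st) || is.na(en) || st < 1L || en < st)
            stop("malformed GFF line ", i, ": bad coordinates")
    }
    invisible(path)
}

#' Annotate islands with overlapping GFF3 features
#'
#' Attaches to each island the reference features whose intervals overlap
#' it by at least one base (1-based inclusive coordinates on the same
#' assembly).
#'
#' @param islands GRanges from [detectIslands()].
#' @param gff either a path to a GFF3 file or a GRanges of features with
#'   metadata columns \code{type} and \code{product}.
#' @return The islands GRanges with an added \code{features} CharacterList
#'   column (entries "type: product") and an attribute-free overlap table
#'   in \code{S4Vectors::metadata(.)$feature_overlaps} (columns island,
#'   type, product).
#' @export
annotateIslands <- function(islands, gff) {
    if (is.character(gff)) {
        .checkGFF3(gff)
        tbl <- rtracklayer::readGFF(gff)
        feats <- GenomicRanges::GRanges(
            seqnames = tbl$seqid,
            ranges = IRanges::IRanges(start = tbl$start, end = tbl$end),
            type = as.character(tbl$type),
            product = if ("product" %in% colnames(tbl))
                vapply(tbl$product, function(p)
                    if (length(p)) paste(unlist(p), collapse = ";")
                    else NA_character_, character(1))
            else rep(NA_character_, nrow(tbl)))
    } else {
        feats <- gff
        if (!all(c("type", "product") %in%
                 colnames(S4Vectors::mcols(feats))))
            stop("feature GRanges needs 'type' and 'product' columns")
    }
    hits <- GenomicRanges::findOverlaps(islands, feats, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    lab <- paste0(feats$type[sh], ": ", feats$product[sh])
    islands$features <- IRanges::CharacterList(
        S4Vectors::splitAsList(lab, factor(qh, levels = seq_along(islands))))
    ov <- data.frame(island = qh,
                     type = as.character(feats$type[sh]),
                     product = as.character(feats$product[sh]),
                     stringsAsFactors = FALSE)
    S4Vectors::metadata(islands)$feature_overlaps <- ov
    islands
}
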