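#' @include AllGenerics.R
NULL

#' GeneCatalog: the deduplicated protein-coding gene reference
#'
#' Holds one row per catalog gene: a unique identifier, the amino-acid
#' length used for depth normalization, and optional taxonomic and
#' functional annotations.
#'
#' @slot table a \link[S4Vectors]{DataFrame} with columns \code{gene_id}
#'   (unique character), \code{length_aa} (integer >= 1), and optional
#'   \code{taxon} and \code{function} (character, NA where unannotated).
#'
#' @seealso [GeneCatalog()], [readGeneCatalog()]
#' @export
setClass("GeneCatalog", slots = c(table = "DataFrame"))

setValidity("GeneCatalog", function(object) {
    tbl <- object@table
    msgs <- character()
    if (!all(c("gene_id", "length_aa") %in% colnames(tbl)))
        msgs <- c(msgs, "catalog needs 'gene_id' and 'length_aa' columns")
    else {
        if (anyDuplicated(tbl$gene_id))
            msgs <- c(msgs, "gene_id values must be unique")
        if (any(is.na(tbl$length_aa)) || any(tbl$length_aa < 1L))
            msgs <- c(msgs, "length_aa must be >= 1 for every gene")
    }
    if (length(msgs)) msgs else TRUE
})

#' GeneAbundance: per-specimen, per-gene depth and relative abundance
#'
#' A thin wrapper around \link[SummarizedExperiment]{SummarizedExperiment}
#' with genes as rows and specimens as columns. The \code{"depth"} assay is
#' the length-normalized sequencing depth (aligned nucleotides / (3 x
#' amino-acid length)); the optional \code{"rel_abund"} assay holds each
#' specimen's depth normalized to sum to one over detected genes.
#'
#' @seealso [computeDepth()], [relativeAbundance()]
#' @export
setClass("GeneAbundance", contains = "SummarizedExperiment")

setValidity("GeneAbundance", function(object) {
    msgs <- character()
    anm <- SummarizedExperiment::assayNames(object)
    if (!"depth" %in% anm)
        return("a 'depth' assay is required")
    d <- SummarizedExperiment::assay(object, "depth")
    if (any(d < 0))
        msgs <- c(msgs, "depth must be non-negative")
    if ("rel_abund" %in% anm) {
        r <- SummarizedExperiment::assay(object, "rel_abund")
        if (any(r < 0) || any(r > 1))
            msgs <- c(msgs, "rel_abund must lie in [0, 1]")
        cs <- colSums(r)
        detected <- colSums(d) > 0
        if (any(abs(cs[detected] - 1) > 1e-9))
            msgs <- c(msgs, "rel_abund columns must sum to 1 (within 1e-9)")
        if (any((r > 0) & (d == 0)))
            msgs <- c(msgs, "rel_abund must be exactly 0 where depth is 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' CAGPartition: disjoint assignment of detected genes to CAGs
#'
#' An exhaustive, disjoint partition of the genes detected in at least one
#' specimen into co-abundant gene groups. Every detected gene maps to
#' exactly one CAG.
#'
#' @slot membership named character vector: names are gene identifiers,
#'   values are CAG identifiers.
#'
#' @seealso [shardedCluster()], [averageLinkageCluster()]
#' @export
setClass("CAGPartition", slots = c(membership = "character"))

setValidity("CAGPartition", function(object) {
    m <- object@membership
    msgs <- character()
    if (length(m)) {
        if (is.null(names(m)) || any(!nzchar(names(m))))
            msgs <- c(msgs, "membership must be named by gene_id")
        else if (anyDuplicated(names(m)))
            msgs <- c(msgs, "each gene must belong to exactly one CAG")
        if (any(is.na(m)) || any(!nzchar(m)))
            msgs <- c(msgs, "cag_id values must be non-empty")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "GeneCatalog", function(object) {
    tbl <- object@table
    n_tax <- if ("taxon" %in% colnames(tbl)) sum(!is.na(tbl$taxon)) else 0L
    n_fun <- if ("function" %in% colnames(tbl)) sum(!is.na(tbl[["function"]])) else 0L
    cat("GeneCatalog with", nrow(tbl), "genes\n")
    cat("  length_aa: ", min(tbl$length_aa), "-", max(tbl$length_aa), " aa\n", sep = "")
    cat("  annotated: ", n_tax, " taxon, ", n_fun, " function\n", sep = "")
})

setMethod("show", "CAGPartition", function(object) {
    m <- object@membership
    sizes <- table(m)
    cat("CAGPartition:", length(sizes), "CAGs over", length(m), "genes\n")
    if (length(sizes))
        cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
            ", max ", max(sizes), "\n", sep = "")
})

setMethod("geneIds", "GeneCatalog", function(x) as.character(x@table$gene_id))
setMethod("geneIds", "GeneAbundance", function(x) rownames(x))
setMethod("geneIds", "CAGPartition", function(x) names(x@membership))
setMethod("specimens", "GeneAbundance", function(x) colnames(x))

setMethod("geneLengths", "GeneCatalog", function(x) {
    stats::setNames(as.integer(x@table$length_aa), x@table$gene_id)
})

setMethod("depthMatrix", "GeneAbundance", function(x) {
    SummarizedExperiment::assay(x, "depth")
})

setMethod("relAbundance", "GeneAbundance", function(x) {
    if (!"rel_abund" %in% SummarizedExperiment::assayNames(x))
        stop("relative abundance not computed yet; see relativeAbundance()")
    SummarizedExperiment::assay(x, "rel_abund")
})

setMethod("cagIds", "CAGPartition", function(x) {
    unique(unname(x@membership))
})

setMethod("membership", "CAGPartition", function(x) x@membership)

setMethod("members", "CAGPartition", function(x, cag) {
    stopifnot(length(cag) == 1L)
    if (!cag %in% x@membership)
        stop("unknown CAG: ", cag)
    names(x@membership)[x@membership == cag]
})

setMethod("nCags", "CAGPartition", function(x) length(unique(x@membership)))

#' Construct a GeneCatalog
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param length_aa integer vector of amino-acid lengths (>= 1).
#' @param taxon optional character vector of taxon labels (NA allowed).
#' @param fun optional character vector of functional annotations (NA
#'   allowed); stored under the column name \code{"function"}.
#' @return A \linkS4class{GeneCatalog}.
#' @examples
#' GeneCatalog(c("g1", "g2"), c(100L, 250L), taxon = c("t1", NA))
#' @export
GeneCatalog <- function(gene_id, length_aa, taxon = NULL, fun = NULL) {
    tbl <- DataFrame(gene_id = as.character(gene_id),
                     length_aa = as.integer(length_aa))
    if (!is.null(taxon)) tbl$taxon <- as.character(taxon)
    if (!is.null(fun)) tbl[["function"]] <- as.character(fun)
    new("GeneCatalog", table = tbl)
}

#' Construct a CAGPartition
#'
#' @param membership named character vector mapping gene_id to cag_id.
#' @return A \linkS4class{CAGPartition}.
#' @export
CAGPartition <- function(membership) {
    new("CAGPartition", membership = membership)
}

#' Catalog annotation table
#'
#' @param x a \linkS4class{GeneCatalog}.
#' @return The underlying \link[S4Vectors]{DataFrame}.
#' @export
catalogTable <- function(x) {
    stopifnot(is(x, "GeneCatalog"))
    x@table
}
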