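#' Resolve multi-mapping reads by coverage-evenness EM
#'
#' Reads aligning comparably well to several catalog genes are resolved to
#' a single gene by iterative reweighting. Candidate weights start
#' proportional to alignment score; each iteration computes every gene's
#' per-position coverage from the current weighted assignments, scores each
#' gene by evenness of coverage -- mean coverage divided by (1 + coefficient
#' of variation across positions) -- and reassigns each read's full weight
#' to its best-scoring candidate gene. Iteration stops at a fixed point of
#' the assignment (or when the largest weight change falls below
#' \code{tol}), or after \code{max_iter} iterations. Resolution is
#' independent per specimen; ties are broken toward the lexicographically
#' smaller gene_id, so the result is deterministic.
#'
#' @param alignments data.frame of alignment records (see
#'   [readAlignments()] for the columns).
#' @param catalog a \linkS4class{GeneCatalog}; every aligned gene must be
#'   present (gene lengths bound the coverage vectors).
#' @param max_iter maximum number of reassignment iterations (default 100).
#' @param tol convergence tolerance on the largest per-candidate weight
#'   change (default 1e-6).
#' @return data.frame with columns specimen, read_id, gene_id,
#'   aligned_bases: one row per retained read, each read on exactly one
#'   gene. Uniquely-mapped reads are always retained on their sole gene.
#' @examples
#' cat <- GeneCatalog(c("gA", "gB"), c(100L, 100L))
#' aln <- data.frame(specimen = "s1", read_id = "r1", gene_id = c("gA", "gB"),
#'                   score = 50, gene_start = 1L, gene_end = 50L,
#'                   aligned_bases = 150L)
#' resolveMultimappers(aln, cat)  # tie resolved to gA
#' @export
resolveMultimappers <- function(alignments, catalog, max_iter = 100L,
                                tol = 1e-6) {
    stopifnot(max_iter >= 1L, tol > 0)
    validateAlignments(alignments, catalog)
    if (!nrow(alignments))
        return(data.frame(specimen = character(), read_id = character(),
                          gene_id = character(),
                          aligned_bases = integer()))
    lens <- geneLengths(catalog)
    out <- lapply(split(alignments, alignments$specimen),
                  .resolveOneSpecimen, lens = lens,
                  max_iter = max_iter, tol = tol)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

# per-specimen EM; aln has one specimen only
.resolveOneSpecimen <- function(aln, lens, max_iter, tol) {
    # collapse duplicate (read, gene) pairs to the best-scoring record
    ord <- order(aln$read_id, aln$gene_id, -aln$score)
    aln <- aln[ord, , drop = FALSE]
    aln <- aln[!duplicated(aln[, c("read_id", "gene_id")]), , drop = FALSE]

    reads <- factor(aln$read_id)
    genes <- factor(aln$gene_id)
    glev <- levels(genes)
    gi <- as.integer(genes)
    ri <- as.integer(reads)
    glen <- unname(lens[glev])

    # initial weights proportional to score within each read
    w <- aln$score
    tot <- tapply(w, ri, sum)[ri]
    w <- ifelse(tot > 0, w / tot, 1 / tabulate(ri)[ri])

    idx_by_gene <- split(seq_len(nrow(aln)), gi)
    assign_prev <- integer(length(levels(reads)))

    for (iter in seq_len(max_iter)) {
        # evenness score per gene from weighted per-position coverage
        escore <- numeric(length(glev))
        for (g in seq_along(glev)) {
            rows <- idx_by_gene[[as.character(g)]]
            if (is.null(rows)) next
            L <- glen[g]
            dcov <- numeric(L + 1L)
            for (k in rows) {
                if (w[k] <= 0) next
                dcov[aln$gene_start[k]] <- dcov[aln$gene_start[k]] + w[k]
                dcov[aln$gene_end[k] + 1L] <- dcov[aln$gene_end[k] + 1L] - w[k]
            }
            cov <- cumsum(dcov[seq_len(L)])
            m <- mean(cov)
            if (m <= 0) next
            cv <- stats::sd(cov) / m
            escore[g] <- m / (1 + cv)
        }
        # reassign each read's full weight to its best candidate gene;
        # ties to the lexicographically smaller gene_id (glev is sorted)
        sc <- escore[gi]
        best <- vapply(split(seq_len(nrow(aln)), ri), function(rows) {
            rows[which.max(sc[rows])]  # first max = smallest gene_id
        }, integer(1))
        assign_now <- integer(length(best))
        assign_now[as.integer(names(best))] <- best
        w_new <- numeric(length(w))
        w_new[best] <- 1
        if (identical(assign_now, assign_prev) || max(abs(w_new - w)) < tol) {
            w <- w_new
            break
        }
        w <- w_new
        assign_prev <- assign_now
    }
    keep <- which(w > 0.5)
    data.frame(specimen = aln$specimen[keep],
               read_id = aln$read_id[keep],
               gene_id = aln$gene_id[keep],
               aligned_bases = aln$aligned_bases[keep],
               stringsAsFactors = FALSE)
}

#' Compute length-normalized sequencing depth
#'
#' For each specimen and gene, depth is the total number of aligned
#' nucleotides from resolved reads divided by the nucleotide-equivalent
#' gene length (3 x amino-acid length). Genes with no assigned reads have
#' depth 0.
#'
#' @param assignments data.frame of resolved assignments (one gene per
#'   read), as returned by [resolveMultimappers()].
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param specimens optional character vector fixing the specimen columns
#'   (defaults to the specimens present in \code{assignments}).
#' @return A \linkS4class{GeneAbundance} with the \code{"depth"} assay
#'   (rows: all catalog genes; columns: specimens).
#' @export
computeDepth <- function(assignments, catalog, specimens = NULL) {
    stopifnot(is.data.frame(assignments))
    lens <- geneLengths(catalog)
    unknown <- setdiff(assignments$gene_id, names(lens))
    if (length(unknown))
        stop("gene_id not in catalog: ",
             paste(utils::head(unknown, 5), collapse = ", "))
    if (is.null(specimens))
        specimens <- sort(unique(assignments$specimen))
    genes <- names(lens)
    depth <- matrix(0, nrow = length(genes), ncol = length(specimens),
                    dimnames = list(genes, specimens))
    if (nrow(assignments)) {
        bases <- tapply(assignments$aligned_bases,
                        list(factor(assignments$gene_id, levels = genes),
                             factor(assignments$specimen, levels = specimens)),
                        sum)
        bases[is.na(bases)] <- 0
        depth <- bases / (3 * lens[genes])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(depth = depth),
        rowData = S4Vectors::DataFrame(length_aa = unname(lens[genes]),
                                       row.names = genes))
    new("GeneAbundance", se)
}

#' Compute per-specimen relative abundance
#'
#' Divides each gene's depth by the specimen's total depth over all genes,
#' yielding a per-specimen probability vector over detected genes.
#'
#' @param x a \linkS4class{GeneAbundance} with a \code{"depth"} assay.
#' @return The same object with a \code{"rel_abund"} assay added.
#' @export
relativeAbundance <- function(x) {
    stopifnot(is(x, "GeneAbundance"))
    d <- depthMatrix(x)
    totals <- colSums(d)
    if (any(totals == 0))
        stop("cannot normalize specimen(s) with zero total depth: ",
             paste(colnames(d)[totals == 0], collapse = ", "))
    r <- sweep(d, 2, totals, "/")
    SummarizedExperiment::assay(x, "rel_abund", withDimnames = FALSE) <- r
    validObject(x)
    x
}

#' Genes detected in one specimen
#'
#' A gene is detected iff its post-resolution depth is strictly positive
#' (no minimum-depth threshold is applied).
#'
#' @param x a \linkS4class{GeneAbundance}.
#' @param specimen a single specimen identifier.
#' @return Character vector of detected gene identifiers.
#' @export
detectedGenes <- function(x, specimen) {
    stopifnot(is(x, "GeneAbundance"), length(specimen) == 1L)
    if (!specimen %in% colnames(x))
        stop("unknown specimen: ", specimen)
    d <- depthMatrix(x)
    rownames(d)[d[, specimen] > 0]
}
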