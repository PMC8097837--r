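#' Run the full gene-level analysis pipeline
#'
#' Orchestrates the four analysis stages on pre-computed translated
#' alignments: (1) multi-mapping read resolution and length-normalized
#' depth / relative abundance, (2) sharded average-linkage clustering of
#' genes into CAGs at the user-specified cosine-distance threshold,
#' (3) per-CAG beta-binomial regression with BH-FDR control and
#' errors-in-response aggregation over taxonomic and functional
#' annotations, and (4), when reference genomes are supplied, per-genome
#' association summaries and contiguous-island detection for the genes of
#' significant CAGs. Results are returned as a list and, when
#' \code{output} is given, written to an HDF5 results store.
#'
#' @param alignments data.frame of alignment records (see
#'   [readAlignments()]).
#' @param catalog a \linkS4class{GeneCatalog}.
#' @param covariates data.frame of per-specimen covariates (rownames =
#'   specimen), e.g. from [parseManifest()].
#' @param formula right-hand-side formula string over covariate columns.
#' @param tau final cosine-distance clustering threshold (required).
#' @param fdr FDR threshold for calling a CAG outcome-associated
#'   (default 0.01).
#' @param max_gap island merge gap in nucleotides (default 5000).
#' @param shard_size,n_rounds,ann_neighbors,exact_final clustering
#'   controls, see [shardedCluster()].
#' @param seed integer seed controlling shard assignment.
#' @param genomes optional list with \code{alignments} (gene-to-genome
#'   records), \code{genome_table} (genome_id, total_length) and optional
#'   \code{min_identity}/\code{min_coverage}.
#' @param output optional path of the HDF5 results store to write.
#' @return List with \code{resolved}, \code{abundance}
#'   (\linkS4class{GeneAbundance}), \code{partition}, \code{cag_abundance},
#'   \code{counts}, \code{fits}, \code{aggregates}, \code{significant},
#'   \code{islands} (data.frame or NULL), \code{genome_summaries},
#'   \code{params} and \code{status}.
#' @export
runPipeline <- function(alignments, catalog, covariates, formula, tau,
                        fdr = 0.01, max_gap = 5000L, shard_size = 250L,
                        n_rounds = 5L, ann_neighbors = 20L,
                        exact_final = FALSE, seed = 0L, genomes = NULL,
                        output = NULL) {
    params <- list(formula = formula, tau = tau, fdr = fdr,
                   max_gap = max_gap, shard_size = shard_size,
                   n_rounds = n_rounds, ann_neighbors = ann_neighbors,
                   exact_final = exact_final, seed = seed)
    status <- list()

    resolved <- resolveMultimappers(alignments, catalog)
    ga <- relativeAbundance(computeDepth(resolved, catalog))
    status$abundance <- "ok"

    d <- depthMatrix(ga)
    profiles <- d[rowSums(d) > 0, , drop = FALSE]
    partition <- shardedCluster(profiles, tau = tau,
                                shard_size = shard_size,
                                n_rounds = n_rounds,
                                ann_neighbors = ann_neighbors,
                                seed = seed, exact_final = exact_final)
    cag_ab <- cagAbundance(partition, ga)
    status$cagclust <- "ok"

    counts <- buildCountTable(resolved, partition)
    fits <- fitAllCags(counts, covariates, formula)
    sig <- significantCags(fits, fdr)
    tbl <- catalogTable(catalog)
    aggregates <- NULL
    for (kind in intersect(c("taxon", "function"), colnames(tbl))) {
        agg <- aggregateByAnnotation(fits, partition, catalog, kind)
        if (nrow(agg)) {
            agg$label_kind <- kind
            aggregates <- rbind(aggregates, agg)
        }
    }
    status$assoc_stats <- "ok"

    islands <- NULL
    genome_summaries <- NULL
    if (!is.null(genomes)) {
        min_id <- if (!is.null(genomes$min_identity))
            genomes$min_identity else 90
        min_cov <- if (!is.null(genomes$min_coverage))
            genomes$min_coverage else 50
        grecs <- filterGenomeAlignments(genomes$alignments, catalog,
                                        min_identity = min_id,
                                        min_coverage = min_cov)
        assoc_genes <- names(membership(partition))[
            membership(partition) %in% c(sig$positive, sig$negative)]
        gs <- list(); isl <- list()
        for (i in seq_len(nrow(genomes$genome_table))) {
            g <- genomes$genome_table$genome_id[i]
            tl <- genomes$genome_table$total_length[i]
            rec_g <- grecs[grecs$genome_id == g, , drop = FALSE]
            s <- summarizeGenome(rec_g, assoc_genes, tl)
            s$genome_id <- g
            gs[[g]] <- as.data.frame(s, stringsAsFactors = FALSE)
            rec_assoc <- rec_g[rec_g$gene_id %in% assoc_genes, ,
                               drop = FALSE]
            if (nrow(rec_assoc)) {
                ir <- detectIslands(rec_assoc, max_gap = max_gap,
                                    gene_to_cag = membership(partition))
                if (length(ir))
                    isl[[g]] <- data.frame(
                        genome_id = g,
                        contig_id = as.character(
                            GenomicRanges::seqnames(ir)),
                        start = GenomicRanges::start(ir),
                        end = GenomicRanges::end(ir),
                        span_bp = ir$span_bp,
                        n_genes = lengths(ir$member_genes),
                        cag_ids = vapply(ir$cag_ids, paste,
                                         character(1), collapse = ";"),
                        stringsAsFactors = FALSE)
            }
        }
        genome_summaries <- do.call(rbind, gs)
        rownames(genome_summaries) <- NULL
        islands <- if (length(isl)) do.call(rbind, isl) else NULL
        if (!is.null(islands)) rownames(islands) <- NULL
        status$islands <- "ok"
    }

    result <- list(resolved = resolved, abundance = ga,
                   partition = partition, cag_abundance = cag_ab,
                   counts = counts, fits = fits, aggregates = aggregates,
                   significant = sig, islands = islands,
                   genome_summaries = genome_summaries,
                   params = params, status = status)
    if (!is.null(output))
        writeResultsStore(result, output)
    result
}
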