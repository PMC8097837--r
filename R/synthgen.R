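#' Configuration for the synthetic experiment generator
#'
#' Defines the study conditions emulated by [generateExperiment()]:
#' a block-structured community of co-abundant genes, a binary outcome
#' shifting the relative abundance of a subset of CAGs on the logit scale
#' with beta-binomial read sampling, multi-mapping alignment ambiguity
#' between homologous genes, and reference genomes carrying planted
#' contiguous islands of CAG member genes.
#'
#' @param n_genes number of catalog genes (default 500).
#' @param n_cags number of planted CAGs (default 60).
#' @param n_specimens_per_group specimens per outcome group (default 40).
#' @param n_associated number of outcome-associated CAGs (default 30).
#' @param effect_size logit-scale outcome effect magnitude (default 1.5);
#'   signs are allocated across the associated CAGs so that the expected
#'   total abundance of the community is balanced between groups, keeping
#'   unassociated CAGs compositionally null.
#' @param phi beta-binomial overdispersion of the read sampling
#'   (default 0.01).
#' @param baseline_sigma sd of the log-normal CAG base abundances
#'   (default 0.75).
#' @param specimen_sigma sd of the per-specimen log-normal fluctuation of
#'   each CAG around its base abundance (default 0.8); this fluctuation is
#'   shared by a CAG's member genes and independent across CAGs, which is
#'   what makes the genes co-abundant in blocks.
#' @param reads_per_specimen resolved reads per specimen (default 20000).
#' @param multimap_fraction fraction of reads receiving a second, spurious
#'   alignment to a homologous gene in another CAG (default 0.05).
#' @param read_length_nt aligned nucleotides per read (default 150).
#' @param gene_length_range amino-acid length range of catalog genes
#'   (default 150-350).
#' @param island_plan list configuring reference genomes and planted
#'   islands, or NULL to skip genomes; see [defaultIslandPlan()].
#' @return A list of class \code{synth_config}.
#' @export
syntheticConfig <- function(n_genes = 500L, n_cags = 60L,
                            n_specimens_per_group = 40L,
                            n_associated = 30L, effect_size = 1.5,
                            phi = 0.01, baseline_sigma = 0.75,
                            specimen_sigma = 0.8,
                            reads_per_specimen = 20000L,
                            multimap_fraction = 0.05,
                            read_length_nt = 150L,
                            gene_length_range = c(150L, 350L),
                            island_plan = defaultIslandPlan()) {
    stopifnot(n_genes >= n_cags, n_cags >= 1L, n_associated <= n_cags,
              phi > 0, phi < 1, multimap_fraction >= 0,
              multimap_fraction <= 1,
              gene_length_range[1] >= ceiling(read_length_nt / 3))
    structure(list(n_genes = as.integer(n_genes),
                   n_cags = as.integer(n_cags),
                   n_specimens_per_group = as.integer(n_specimens_per_group),
                   n_associated = as.integer(n_associated),
                   effect_size = effect_size, phi = phi,
                   baseline_sigma = baseline_sigma,
                   specimen_sigma = specimen_sigma,
                   reads_per_specimen = as.integer(reads_per_specimen),
                   multimap_fraction = multimap_fraction,
                   read_length_nt = as.integer(read_length_nt),
                   gene_length_range = as.integer(gene_length_range),
                   island_plan = island_plan),
              class = "synth_config")
}

#' Default reference-genome island plan
#'
#' Plants one contiguous island of member genes of an associated CAG on a
#' subset of synthetic reference genomes (accessory), plants the genes of
#' one unassociated CAG on every genome (core), and scatters background
#' genes. Default spacing and gene counts place the island span around
#' 20 kb.
#'
#' @param n_genomes number of reference genomes (default 5).
#' @param genome_length genome length in nucleotides (default 80000).
#' @param genes_per_island member genes per planted island (default 18).
#' @param gene_spacing intergenic gap inside the island in nucleotides
#'   (default 400).
#' @param island_genomes how many genomes carry the island (default 2,
#'   making it accessory at the usual 0.9 core threshold).
#' @param n_background scattered non-associated background genes per
#'   genome (default 10).
#' @return A list describing the plan.
#' @export
defaultIslandPlan <- function(n_genomes = 5L, genome_length = 80000L,
                              genes_per_island = 18L, gene_spacing = 400L,
                              island_genomes = 2L, n_background = 10L) {
    list(n_genomes = as.integer(n_genomes),
         genome_length = as.integer(genome_length),
         genes_per_island = as.integer(genes_per_island),
         gene_spacing = as.integer(gene_spacing),
         island_genomes = as.integer(island_genomes),
         n_background = as.integer(n_background))
}

# allocate +/- signs over the associated CAGs so the expected total
# community abundance is equal in both groups (greedy balance of the
# abundance change each shifted CAG contributes)
.balanceEffectSigns <- function(base_abund, effect) {
    ord <- order(base_abund, decreasing = TRUE)
    delta <- 0
    sign <- numeric(length(base_abund))
    for (i in ord) {
        b <- base_abund[i]
        up <- stats::plogis(stats::qlogis(b) + effect) - b
        dn <- stats::plogis(stats::qlogis(b) - effect) - b
        sign[i] <- if (abs(delta + up) <= abs(delta + dn)) 1 else -1
        delta <- delta + if (sign[i] > 0) up else dn
    }
    sign
}

#' Generate a complete synthetic gene-level metagenomics experiment
#'
#' Produces a gene catalog, read-level translated-alignment records, a
#' specimen manifest with a binary outcome covariate, optional reference
#' genomes with planted islands and GFF3 features, and the full planted
#' truth for every stage. Fully determined by \code{(config, seed)}.
#'
#' Genes are split into CAGs; each CAG draws a log-normal base abundance
#' and an independent per-specimen log-normal fluctuation shared by its
#' member genes. Associated CAGs are shifted on the logit scale by the
#' outcome, beta-binomial wobble at dispersion \code{phi} is applied, and
#' each specimen's reads are drawn multinomially over CAGs, then over
#' member genes proportionally to gene length (so depth is even within a
#' CAG). A configurable fraction of reads receives a second alignment to a
#' designated homolog in another CAG at slightly lower score.
#'
#' @param config a [syntheticConfig()] list.
#' @param seed integer seed; all stage-level randomness derives from it.
#' @return List with \code{catalog} (\linkS4class{GeneCatalog}),
#'   \code{alignments} (data.frame), \code{manifest} (data.frame ready to
#'   write as CSV), \code{covariates} (data.frame, rownames = specimen),
#'   \code{genomes} (NULL or list: genome_table, alignments, features,
#'   gff_lines) and \code{truth} (planted partition, per-CAG base
#'   abundance and effects, phi, per-read true source gene, planted
#'   islands, core/accessory CAG ids, specimen groups).
#' @export
generateExperiment <- function(config = syntheticConfig(), seed = 1L) {
    stopifnot(inherits(config, "synth_config"))
    set.seed(seed %% 2147483647L)
    cfg <- config

    ## --- catalog and planted partition -------------------------------
    gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
    length_aa <- sample(seq(cfg$gene_length_range[1],
                            cfg$gene_length_range[2]),
                        cfg$n_genes, replace = TRUE)
    # CAG sizes: random but >= 2 genes where possible
    raw <- stats::rgamma(cfg$n_cags, shape = 2)
    sizes <- pmax(2L, as.integer(round(raw / sum(raw) *
                                       (cfg$n_genes - 2L * cfg$n_cags))) + 2L)
    while (sum(sizes) > cfg$n_genes)
        sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    while (sum(sizes) < cfg$n_genes)
        sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
    cag_id <- sprintf("planted%03d", seq_len(cfg$n_cags))
    gene_cag <- rep(cag_id, sizes)  # genes grouped in catalog order
    truth_partition <- CAGPartition(stats::setNames(gene_cag, gene_id))

    # annotations: one taxon per ~3 CAGs, one function per ~5 CAGs
    taxa <- sprintf("taxon%03d", ((seq_len(cfg$n_cags) - 1L) %/% 3L) + 1L)
    funs <- sprintf("fn%03d", ((seq_len(cfg$n_cags) - 1L) %/% 5L) + 1L)
    catalog <- GeneCatalog(gene_id, length_aa,
                           taxon = rep(taxa, sizes),
                           fun = rep(funs, sizes))

    ## --- community model ---------------------------------------------
    base <- stats::rlnorm(cfg$n_cags, meanlog = 0,
                          sdlog = cfg$baseline_sigma)
    base <- base / sum(base)
    associated <- sort(sample(cfg$n_cags, cfg$n_associated))
    effects <- stats::setNames(numeric(cfg$n_cags), cag_id)
    if (cfg$n_associated > 0) {
        sgn <- .balanceEffectSigns(base[associated], cfg$effect_size)
        effects[associated] <- sgn * cfg$effect_size
    }

    n_spec <- 2L * cfg$n_specimens_per_group
    specimen <- sprintf("S%03d", seq_len(n_spec))
    group <- rep(c(0L, 1L), each = cfg$n_specimens_per_group)
    outcome <- ifelse(group == 1L, "case", "control")

    genes_by_cag <- split(seq_len(cfg$n_genes), gene_cag)[cag_id]
    glen_nt <- 3L * length_aa
    aa_per_read <- cfg$read_length_nt %/% 3L

    aln_list <- vector("list", n_spec)
    truth_reads <- vector("list", n_spec)
    for (s in seq_len(n_spec)) {
        # per-specimen CAG composition: base x specimen fluctuation,
        # logit-shifted by the outcome, then beta-binomial wobble
        lat <- base * stats::rlnorm(cfg$n_cags, 0, cfg$specimen_sigma)
        lat <- lat / sum(lat)
        mu <- stats::plogis(stats::qlogis(lat) + effects * group[s])
        a <- mu * (1 - cfg$phi) / cfg$phi
        b <- (1 - mu) * (1 - cfg$phi) / cfg$phi
        q <- stats::rbeta(cfg$n_cags, a, b)
        q[q <= 0] <- min(q[q > 0], 1e-8)
        p <- q / sum(q)
        w_cag <- as.integer(stats::rmultinom(1, cfg$reads_per_specimen, p))
        # reads to genes, proportional to gene length within the CAG
        src <- unlist(lapply(seq_len(cfg$n_cags), function(cg) {
            if (w_cag[cg] == 0L) return(integer())
            gidx <- genes_by_cag[[cg]]
            if (length(gidx) == 1L) return(rep(gidx, w_cag[cg]))
            sample(gidx, w_cag[cg], replace = TRUE,
                   prob = glen_nt[gidx])
        }), use.names = FALSE)
        n_reads <- length(src)
        read_id <- sprintf("%s_r%06d", specimen[s], seq_len(n_reads))
        start_aa <- 1L + as.integer(floor(stats::runif(n_reads) *
                                          (length_aa[src] - aa_per_read + 1L)))
        rec <- data.frame(specimen = specimen[s], read_id = read_id,
                          gene_id = gene_id[src], score = 100,
                          gene_start = start_aa,
                          gene_end = start_aa + aa_per_read - 1L,
                          aligned_bases = cfg$read_length_nt,
                          stringsAsFactors = FALSE)
        if (cfg$multimap_fraction > 0) {
            # homolog map: a gene's decoy partner sits one CAG block away
            mm <- which(stats::runif(n_reads) < cfg$multimap_fraction)
            if (length(mm)) {
                part_idx <- (src[mm] + sizes[1]) %% cfg$n_genes + 1L
                pstart <- pmin(start_aa[mm],
                               length_aa[part_idx] - aa_per_read + 1L)
                pstart <- pmax(pstart, 1L)
                extra <- data.frame(specimen = specimen[s],
                                    read_id = read_id[mm],
                                    gene_id = gene_id[part_idx],
                                    score = 95,
                                    gene_start = pstart,
                                    gene_end = pstart + aa_per_read - 1L,
                                    aligned_bases = cfg$read_length_nt,
                                    stringsAsFactors = FALSE)
                rec <- rbind(rec, extra)
            }
        }
        aln_list[[s]] <- rec
        truth_reads[[s]] <- data.frame(specimen = specimen[s],
                                       read_id = read_id,
                                       gene_id = gene_id[src],
                                       stringsAsFactors = FALSE)
    }
    alignments <- do.call(rbind, aln_list)
    rownames(alignments) <- NULL
    read_truth <- do.call(rbind, truth_reads)
    rownames(read_truth) <- NULL

    manifest <- data.frame(specimen = specimen,
                           R1 = paste0(specimen, "_R1.fastq.gz"),
                           R2 = paste0(specimen, "_R2.fastq.gz"),
                           outcome = outcome,
                           stringsAsFactors = FALSE)
    covariates <- data.frame(outcome = factor(outcome,
                                              levels = c("control", "case")),
                             row.names = specimen)

    ## --- reference genomes with planted islands ----------------------
    genomes <- NULL
    islands_truth <- NULL
    if (!is.null(cfg$island_plan) && cfg$n_associated > 0) {
        genomes <- .plantGenomes(cfg, catalog, cag_id, associated,
                                 genes_by_cag, glen_nt)
        islands_truth <- genomes$truth
        genomes$truth <- NULL
    }

    list(catalog = catalog,
         alignments = alignments,
         manifest = manifest,
         covariates = covariates,
         genomes = genomes,
         truth = list(partition = truth_partition,
                      cag_ids = cag_id,
                      base_abundance = stats::setNames(base, cag_id),
                      effects = effects,
                      associated_cags = cag_id[associated],
                      phi = cfg$phi,
                      read_truth = read_truth,
                      specimen_group = stats::setNames(group, specimen),
                      islands = islands_truth))
}

# place one contiguous island of an associated CAG's genes on a subset of
# genomes, one core CAG on every genome, and scattered background genes
# (background drawn from unassociated CAGs so only the planted island
# carries outcome-associated genes)
.plantGenomes <- function(cfg, catalog, cag_id, associated, genes_by_cag,
                          glen_nt) {
    plan <- cfg$island_plan
    gene_ids <- geneIds(catalog)
    island_cag <- cag_id[associated[1L]]
    core_pool <- setdiff(seq_along(cag_id), associated)
    core_cag <- cag_id[core_pool[1L]]
    isl_genes <- genes_by_cag[[island_cag]]
    isl_genes <- rep(isl_genes,
                     length.out = plan$genes_per_island)
    core_genes <- genes_by_cag[[core_cag]]
    assoc_genes <- unlist(genes_by_cag[associated], use.names = FALSE)
    bg_pool <- setdiff(seq_along(gene_ids),
                       c(assoc_genes, core_genes))

    extent <- sum(glen_nt[isl_genes]) +
        (length(isl_genes) - 1L) * plan$gene_spacing
    if (10000L + extent - 1L > plan$genome_length)
        stop("infeasible island plan: planted island (", extent,
             " bp) does not fit on the genome")

    genome_id <- sprintf("genome%02d", seq_len(plan$n_genomes))
    carriers <- genome_id[seq_len(plan$island_genomes)]
    aln <- list(); feats <- list(); truth <- list(); gff <- list()
    for (g in genome_id) {
        contig <- paste0(g, "_c1")
        rows <- list(); k <- 1L
        if (g %in% carriers) {
            pos <- 10000L
            starts <- ends <- integer(length(isl_genes))
            for (i in seq_along(isl_genes)) {
                gi <- isl_genes[i]
                starts[i] <- pos
                ends[i] <- pos + glen_nt[gi] - 1L
                pos <- ends[i] + 1L + plan$gene_spacing
                rows[[k]] <- data.frame(gene_id = gene_ids[gi],
                                        genome_id = g, contig_id = contig,
                                        start = starts[i], end = ends[i],
                                        strand = if (i %% 2L) "+" else "-",
                                        pct_identity = 98,
                                        stringsAsFactors = FALSE)
                k <- k + 1L
            }
            truth[[g]] <- data.frame(genome_id = g, contig_id = contig,
                                     start = starts[1L],
                                     end = ends[length(ends)],
                                     cag_id = island_cag,
                                     stringsAsFactors = FALSE)
            feats[[g]] <- data.frame(
                seqid = contig, start = starts[2L], end = ends[3L],
                type = "gene", product = "type II secretion system protein",
                stringsAsFactors = FALSE)
        }
        # core CAG genes scattered over the back half of the genome
        core_start <- as.integer(plan$genome_length * 0.6)
        pos <- core_start
        for (gi in core_genes) {
            if (pos + glen_nt[gi] > plan$genome_length) break
            rows[[k]] <- data.frame(gene_id = gene_ids[gi], genome_id = g,
                                    contig_id = contig, start = pos,
                                    end = pos + glen_nt[gi] - 1L,
                                    strand = "+", pct_identity = 99,
                                    stringsAsFactors = FALSE)
            k <- k + 1L
            pos <- pos + glen_nt[gi] + 2000L
        }
        # isolated background genes in the front region
        bg <- bg_pool[seq_len(min(plan$n_background, length(bg_pool)))]
        pos <- 40000L
        for (gi in bg) {
            if (pos + glen_nt[gi] > core_start - 6000L) break
            rows[[k]] <- data.frame(gene_id = gene_ids[gi], genome_id = g,
                                    contig_id = contig, start = pos,
                                    end = pos + glen_nt[gi] - 1L,
                                    strand = "-", pct_identity = 97,
                                    stringsAsFactors = FALSE)
            k <- k + 1L
            pos <- pos + glen_nt[gi] + 6000L
        }
        aln[[g]] <- do.call(rbind, rows)
        gl <- aln[[g]]
        gff[[g]] <- c(
            "##gff-version 3",
            sprintf("##sequence-region %s 1 %d", contig, plan$genome_length),
            if (g %in% carriers)
                sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=%s_t2ss;product=type II secretion system protein",
                        contig, feats[[g]]$start, feats[[g]]$end, g),
            sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s_f%03d;product=hypothetical protein",
                    contig, gl$start, gl$end, gl$strand, g,
                    seq_len(nrow(gl))))
    }
    feat_df <- do.call(rbind, feats)
    features <- if (!is.null(feat_df)) {
        GenomicRanges::GRanges(seqnames = feat_df$seqid,
                               ranges = IRanges::IRanges(feat_df$start,
                                                         feat_df$end),
                               type = feat_df$type,
                               product = feat_df$product)
    } else GenomicRanges::GRanges()
    list(genome_table = data.frame(genome_id = genome_id,
                                   total_length = plan$genome_length,
                                   stringsAsFactors = FALSE),
         alignments = do.call(rbind, aln),
         features = features,
         gff_lines = gff,
         truth = list(islands = do.call(rbind, truth),
                      island_cag = island_cag,
                      core_cag = core_cag,
                      carriers = carriers))
}

#' Planted decoy multi-mapping scenario
#'
#' One specimen: \code{n_reads} reads truly drawn from gene A (uniform
#' positions), of which \code{n_shared} also align spuriously to a decoy
#' gene B that receives no unique reads. Used to test that the
#' coverage-evenness EM assigns essentially all reads to the true source.
#'
#' @param n_reads reads from the true gene (default 500).
#' @param n_shared reads that also align to the decoy (default 20).
#' @param seed integer seed.
#' @return List with \code{catalog}, \code{alignments} and
#'   \code{true_gene}.
#' @export
simulateDecoyAlignments <- function(n_reads = 500L, n_shared = 20L,
                                    seed = 7L) {
    set.seed(seed %% 2147483647L)
    len_aa <- 300L
    aa_per_read <- 50L
    catalog <- GeneCatalog(c("geneA", "geneB"), c(len_aa, len_aa))
    start <- sample.int(len_aa - aa_per_read + 1L, n_reads, replace = TRUE)
    read_id <- sprintf("r%04d", seq_len(n_reads))
    aln <- data.frame(specimen = "s1", read_id = read_id,
                      gene_id = "geneA", score = 100,
                      gene_start = start, gene_end = start + aa_per_read - 1L,
                      aligned_bases = 150L, stringsAsFactors = FALSE)
    shared <- sample.int(n_reads, n_shared)
    dstart <- sample.int(len_aa - aa_per_read + 1L, n_shared, replace = TRUE)
    aln <- rbind(aln, data.frame(specimen = "s1", read_id = read_id[shared],
                                 gene_id = "geneB", score = 100,
                                 gene_start = dstart,
                                 gene_end = dstart + aa_per_read - 1L,
                                 aligned_bases = 150L,
                                 stringsAsFactors = FALSE))
    list(catalog = catalog, alignments = aln, true_gene = "geneA")
}

#' Planted block-structured depth profiles
#'
#' Directly generates a gene-by-specimen depth matrix with co-abundant
#' blocks (no read-level sampling): each block shares an independent
#' per-specimen log-normal profile, and each gene adds small multiplicative
#' noise. Used for clustering studies where read sampling is irrelevant.
#'
#' @param n_genes total genes.
#' @param n_blocks planted blocks (CAGs).
#' @param n_specimens specimens.
#' @param noise_sd sd of the per-gene log-normal noise (default 0.05);
#'   keeps within-block cosine distances well below between-block ones.
#' @param specimen_sigma sd of the block-level log-normal profile
#'   (default 1).
#' @param seed integer seed.
#' @return List with \code{profiles} (matrix, rownames gene ids) and
#'   \code{truth} (named character vector gene -> block).
#' @export
generateBlockProfiles <- function(n_genes, n_blocks, n_specimens,
                                  noise_sd = 0.05, specimen_sigma = 1,
                                  seed = 1L) {
    stopifnot(n_genes >= n_blocks)
    set.seed(seed %% 2147483647L)
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    block <- sort(rep_len(seq_len(n_blocks), n_genes))
    base <- matrix(stats::rlnorm(n_blocks * n_specimens, 0, specimen_sigma),
                   nrow = n_blocks)
    noise <- matrix(stats::rlnorm(n_genes * n_specimens, 0, noise_sd),
                    nrow = n_genes)
    profiles <- base[block, , drop = FALSE] * noise
    dimnames(profiles) <- list(gene_id,
                               sprintf("S%03d", seq_len(n_specimens)))
    list(profiles = profiles,
         truth = stats::setNames(sprintf("block%03d", block), gene_id))
}
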