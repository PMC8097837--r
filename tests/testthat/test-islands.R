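mk_records <- function(start, end, gene_id = NULL, contig = "c1",
                       genome = "G1", strand = "+", ident = 98) {
    n <- length(start)
    data.frame(gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n))
               else gene_id,
               genome_id = genome, contig_id = contig,
               start = as.integer(start), end = as.integer(end),
               strand = rep_len(strand, n),
               pct_identity = rep_len(ident, n),
               stringsAsFactors = FALSE)
}

test_that("genome summary uses union semantics for overlapping intervals", {
    rec <- mk_records(c(1, 201), c(100, 300))
    s <- summarizeGenome(rec, rec$gene_id, 1000L)
    expect_equal(s$proportion_associated, 0.2)
    # full overlap counted once
    dup <- mk_records(c(1, 1), c(100, 100))
    expect_equal(summarizeGenome(dup, dup$gene_id,
                                 1000L)$proportion_associated, 0.1)
    # empty associated set
    expect_equal(summarizeGenome(rec, character(0),
                                 1000L)$proportion_associated, 0)
    expect_error(summarizeGenome(rec, rec$gene_id, 0L), "total_length")
})

test_that("proportion is invariant to splitting intervals in halves", {
    set.seed(21)
    start <- sort(sample.int(5000, 12)) * 10L
    end <- start + sample(200:900, 12)
    rec <- mk_records(start, end)
    whole <- summarizeGenome(rec, rec$gene_id, 100000L)
    mid <- (start + end) %/% 2L
    halves <- mk_records(c(start, mid + 1L), c(mid, end),
                         gene_id = rep(rec$gene_id, 2))
    split_s <- summarizeGenome(halves, rec$gene_id, 100000L)
    expect_equal(split_s$proportion_associated,
                 whole$proportion_associated)
})

test_that("genome summary matches a per-base bitmap oracle", {
    set.seed(22)
    for (rep in 1:5) {
        n <- sample(5:25, 1)
        start <- sample.int(90000, n)
        end <- pmin(start + sample(100:5000, n, replace = TRUE), 100000L)
        rec <- mk_records(start, end)
        assoc <- sample(rec$gene_id, ceiling(n / 2))
        s <- summarizeGenome(rec, assoc, 100000L)
        sel <- rec$gene_id %in% assoc
        expect_equal(s$aligned_associated_bases,
                     bitmap_union_bases(start[sel], end[sel], 100000L))
    }
})

test_that("island merging follows the gap rule and contig boundaries", {
    rec <- mk_records(c(100, 450), c(400, 900))
    one <- detectIslands(rec, max_gap = 500L)
    expect_equal(length(one), 1L)
    expect_equal(GenomicRanges::start(one), 100L)
    expect_equal(GenomicRanges::end(one), 900L)
    expect_equal(one$span_bp, 801L)
    two <- detectIslands(rec, max_gap = 10L)
    expect_equal(length(two), 2L)
    # gap exactly max_gap merges; max_gap - 1 on the rule boundary:
    # gap = start2 - end1 - 1 = 49
    expect_equal(length(detectIslands(rec, max_gap = 49L)), 1L)
    expect_equal(length(detectIslands(rec, max_gap = 48L)), 2L)
    # different contigs never merge
    rec2 <- rec; rec2$contig_id <- c("c1", "c2")
    expect_equal(length(detectIslands(rec2, max_gap = 5000L)), 2L)
    expect_error(detectIslands(rec, max_gap = -1L), "max_gap")
})

test_that("island detection is order invariant and monotone in max_gap", {
    set.seed(23)
    start <- sample.int(50000, 30)
    rec <- mk_records(start, start + 600L)
    isl <- detectIslands(rec, max_gap = 2000L)
    shuffled <- detectIslands(rec[sample(nrow(rec)), ], max_gap = 2000L)
    expect_equal(GenomicRanges::start(isl), GenomicRanges::start(shuffled))
    expect_equal(GenomicRanges::end(isl), GenomicRanges::end(shuffled))
    counts <- vapply(c(10000L, 2000L, 500L, 50L), function(g)
        length(detectIslands(rec, max_gap = g)), integer(1))
    expect_true(all(diff(counts) >= 0))
    # every aligned gene belongs to exactly one island
    expect_equal(sort(unlist(isl$member_genes, use.names = FALSE)),
                 sort(unique(rec$gene_id)))
})

test_that("planted islands are recovered with exact boundaries", {
    ex <- default_experiment()
    truth <- ex$truth$islands
    part <- membership(ex$truth$partition)
    isl_cag <- truth$island_cag
    for (i in seq_len(nrow(truth$islands))) {
        g <- truth$islands$genome_id[i]
        rec <- ex$genomes$alignments
        rec <- rec[rec$genome_id == g &
                   part[rec$gene_id] == isl_cag, , drop = FALSE]
        isl <- detectIslands(rec, max_gap = 5000L, gene_to_cag = part)
        expect_equal(length(isl), 1L)
        expect_equal(GenomicRanges::start(isl), truth$islands$start[i])
        expect_equal(GenomicRanges::end(isl), truth$islands$end[i])
        expect_gte(isl$span_bp, 10000L)
        expect_lte(isl$span_bp, 35000L)
        expect_equal(unlist(isl$cag_ids), isl_cag, ignore_attr = TRUE)
    }
})

test_that("core/accessory classification follows the genome fraction", {
    all_there <- classifyCoreAccessory("c1", rep(TRUE, 20), rep(TRUE, 5))
    expect_equal(all_there$classification, "core")
    rare <- classifyCoreAccessory("c2", c(TRUE, rep(FALSE, 19)),
                                  rep(TRUE, 5), 0.9)
    expect_equal(rare$classification, "accessory")
    expect_equal(rare$genomes_present, 0.05)
    expect_error(classifyCoreAccessory("c3", logical(0), TRUE), "genome")

    # planted truth: island CAG accessory, core CAG on every genome
    ex <- default_experiment()
    part <- membership(ex$truth$partition)
    truth <- ex$truth$islands
    galn <- ex$genomes$alignments
    genomes <- ex$genomes$genome_table$genome_id
    hits_isl <- vapply(genomes, function(g) any(
        part[galn$gene_id[galn$genome_id == g]] == truth$island_cag),
        logical(1))
    hits_core <- vapply(genomes, function(g) any(
        part[galn$gene_id[galn$genome_id == g]] == truth$core_cag),
        logical(1))
    expect_equal(
        classifyCoreAccessory(truth$island_cag, hits_isl,
                              TRUE)$classification, "accessory")
    expect_equal(
        classifyCoreAccessory(truth$core_cag, hits_core,
                              TRUE)$classification, "core")
})

test_that("GFF overlap annotation respects inclusive bounds", {
    isl <- detectIslands(mk_records(c(100, 450), c(400, 900)),
                         max_gap = 500L)
    feats <- GenomicRanges::GRanges(
        "c1", IRanges::IRanges(c(850, 901), c(1200, 1200)),
        type = c("gene", "gene"),
        product = c("inside", "outside"))
    ann <- annotateIslands(isl, feats)
    expect_equal(unlist(ann$features), "gene: inside", ignore_attr = TRUE)

    # planted feature inside the planted island, via a real GFF3 file
    ex <- default_experiment()
    g <- ex$truth$islands$islands$genome_id[1]
    gff <- tempfile(fileext = ".gff3")
    writeLines(ex$genomes$gff_lines[[g]], gff)
    part <- membership(ex$truth$partition)
    rec <- ex$genomes$alignments
    rec <- rec[rec$genome_id == g &
               part[rec$gene_id] == ex$truth$islands$island_cag, ]
    isl2 <- detectIslands(rec, max_gap = 5000L)
    ann2 <- annotateIslands(isl2, gff)
    expect_true(any(grepl("type II secretion",
                          unlist(ann2$features))))

    # malformed GFF lines are reported with their line number
    bad <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3", "c1\tx\tgene\t10\t5"), bad)
    expect_error(annotateIslands(isl, bad), "line 2")
})

test_that("alignment filtering applies identity and coverage thresholds", {
    cat <- GeneCatalog(c("g1", "g2"), c(100L, 100L))  # 300 nt each
    rec <- mk_records(c(1, 1000), c(300, 1100),
                      gene_id = c("g1", "g2"), ident = c(95, 95))
    # g2 covers only 101/300 nt -> dropped at 50% coverage
    kept <- filterGenomeAlignments(rec, cat)
    expect_equal(kept$gene_id, "g1")
    # identity filter
    rec$pct_identity <- c(80, 95)
    kept2 <- filterGenomeAlignments(rec, cat, min_identity = 90,
                                    min_coverage = 0)
    expect_equal(kept2$gene_id, "g2")
})
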