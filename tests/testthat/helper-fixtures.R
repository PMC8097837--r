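# Session-level fixtures, built once and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

# small read-level experiment: fast enough for repeated pipeline runs
small_config <- function() {
    syntheticConfig(n_genes = 150L, n_cags = 20L,
                    n_specimens_per_group = 12L, n_associated = 8L,
                    reads_per_specimen = 4000L)
}

small_experiment <- function() {
    if (is.null(.fixture_env$small))
        .fixture_env$small <- generateExperiment(small_config(), seed = 101)
    .fixture_env$small
}

small_resolved <- function() {
    if (is.null(.fixture_env$small_res)) {
        ex <- small_experiment()
        .fixture_env$small_res <-
            resolveMultimappers(ex$alignments, ex$catalog)
    }
    .fixture_env$small_res
}

# default full-size experiment (study conditions); built on first use
default_experiment <- function() {
    if (is.null(.fixture_env$default))
        .fixture_env$default <- generateExperiment(syntheticConfig(),
                                                   seed = 1)
    .fixture_env$default
}

default_pipeline <- function() {
    if (is.null(.fixture_env$default_pipe)) {
        ex <- default_experiment()
        .fixture_env$default_pipe <- runPipeline(
            ex$alignments, ex$catalog, ex$covariates,
            formula = "outcome", tau = 0.25, seed = 11,
            genomes = ex$genomes)
    }
    .fixture_env$default_pipe
}

# map each pipeline CAG to the planted CAG contributing most of its genes
majority_planted <- function(partition, truth_partition) {
    m <- membership(partition)
    tm <- membership(truth_partition)
    vapply(split(tm[names(m)], m), function(z)
        names(sort(table(z), decreasing = TRUE))[1], character(1))
}
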