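# Shared simulated data sets, generated once per test run. The "default"
# objects use the generator's default configuration (the study conditions);
# the "small" objects use a reduced gene count for cheap structural checks.

.simCache <- new.env(parent = emptyenv())

cachedDefaultSim <- function() {
    if (is.null(.simCache$default))
        .simCache$default <- generateGenome(generatorConfig(), sequences = FALSE)
    .simCache$default
}

cachedDefaultWGBS <- function() {
    if (is.null(.simCache$wgbs))
        .simCache$wgbs <- simulateMethylome(cachedDefaultSim(), "WGBS",
                                            "supraE", seed = 101L)
    .simCache$wgbs
}

cachedDefaultMeans <- function() {
    if (is.null(.simCache$means))
        .simCache$means <- transcriptMeanMethylation(
            cachedDefaultWGBS(), cachedDefaultSim()$features)
    .simCache$means
}

smallConfig <- function(seed = 5L, ...)
    generatorConfig(n_genes = 120L, n_scaffolds = 2L, seed = seed, ...)

cachedSmallSim <- function() {
    if (is.null(.simCache$small))
        .simCache$small <- generateGenome(smallConfig(), sequences = TRUE)
    .simCache$small
}
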