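test_that("bin assignment maps endpoints and matches the proportional rule", {
    region <- GRanges("s1", IRanges(11L, 100L), strand = "+")  # length 90
    expect_equal(assignBin(region, 11L, 30L), 1L)
    expect_equal(assignBin(region, 100L, 30L), 30L)
    # exhaustive check of every position against the literal mapping
    for (B in c(15L, 30L)) {
        got <- assignBin(region, 11:100, B)
        want <- vapply(11:100, bruteBin, numeric(1),
                       start = 11, end = 100, strand = "+", B = B)
        expect_equal(got, as.integer(want))
    }
    expect_error(assignBin(region, 101L, 30L), "outside")
})

test_that("reversing a feature's strand reverses its bin vector", {
    plus <- GRanges("s1", IRanges(11L, 100L), strand = "+")
    minus <- GRanges("s1", IRanges(11L, 100L), strand = "-")
    pos <- 11:100
    expect_equal(assignBin(minus, pos, 30L),
                 rev(assignBin(plus, pos, 30L)))
})

test_that("metaplot equals the literal reference implementation", {
    set.seed(31)
    regions <- data.frame(scaffold = sample(c("s1", "s2"), 40, TRUE),
                          start = sample.int(2e4, 40),
                          strand = sample(c("+", "-"), 40, TRUE))
    regions$end <- regions$start + sample(100:900, 40)
    fs <- FeatureSet(cbind(transcript_id = paste0("r", 1:40), regions))
    n <- 800
    cpg <- data.frame(scaffold = sample(c("s1", "s2"), n, TRUE),
                      pos = sample.int(22000, n),
                      meth_pct = round(runif(n, 0, 100), 2))
    tab <- CpGTable(cpg$scaffold, cpg$pos, "+", cpg$meth_pct,
                    0L, 0L, sample = "m")
    for (w in list(c(1, 99), c(0, 100), c(10, 90))) {
        got <- profileStats(metaplot(tab, fs, B = 15L, winsor = w))
        want <- bruteMetaplot(cpg, regions, B = 15L, winsor = w)
        expect_equal(got$mean, unname(want[, "mean"]), tolerance = 1e-9)
        expect_equal(got$n, as.integer(want[, "n"]))
    }
})

test_that("winsor (0,100) reduces to the plain mean and clipping tames outliers", {
    x <- c(rep(10, 100), 1000)
    w0 <- winsorizedMean(x, 0, 100)
    expect_identical(w0$mean, mean(x))
    w <- winsorizedMean(x, 1, 99)
    expect_lt(w$mean, mean(x))
    expect_gte(w$mean, min(x))
    expect_lte(w$mean, max(x))
    # adding a value equal to the current mean leaves the plain mean fixed
    expect_equal(winsorizedMean(c(x, mean(x)), 0, 100)$mean, mean(x))
})

test_that("constant bins give zero CI and empty bins are reported missing", {
    fs <- FeatureSet(data.frame(transcript_id = "t1", scaffold = "s1",
                                start = 1L, end = 30L, strand = "+"))
    tab <- makeCpGs(c(2L, 3L, 4L), rep(40, 3), n_total = 10L)
    p <- profileStats(metaplot(tab, fs, B = 3L))
    expect_equal(p$mean[1], 40)
    expect_equal(p$ci[1], 0)
    expect_equal(p$n[2:3], c(0L, 0L))
    expect_true(all(is.na(p$mean[2:3])))
})

test_that("every CpG contributes exactly once per overlapped region", {
    sim <- cachedSmallSim()
    wg <- simulateMethylome(sim, "WGBS", "w", seed = 6L)
    p <- profileStats(metaplot(wg, sim$features, B = 30L))
    q <- granges(cpgSites(wg))
    strand(q) <- "*"
    hits <- findOverlaps(q, transcriptRanges(sim$features),
                         ignore.strand = TRUE)
    expect_equal(sum(p$n), length(hits))
})

test_that("CpG density is exact on periodic and CG-free sequences", {
    genome <- Biostrings::DNAStringSet(c(
        s1 = paste(rep("CG", 150), collapse = ""),
        s2 = paste(rep("AT", 150), collapse = "")))
    dense <- GRanges("s1", IRanges(1L, 300L), strand = "+")
    p <- profileStats(cpgDensity(dense, genome, B = 15L))
    expect_true(all(abs(p$mean - 0.5) <= 0.05))
    free <- GRanges("s2", IRanges(1L, 300L), strand = "+")
    expect_true(all(profileStats(cpgDensity(free, genome, B = 15L))$mean == 0))
    # pooling is invariant to region order
    two <- GRanges(c("s1", "s2"), IRanges(c(1L, 1L), c(300L, 300L)))
    expect_equal(profileStats(cpgDensity(two, genome, B = 15L)),
                 profileStats(cpgDensity(rev(two), genome, B = 15L)))
    beyond <- GRanges("s1", IRanges(200L, 400L))
    expect_error(cpgDensity(beyond, genome, B = 5L), "beyond")
})

test_that("flanked matrix places a TSS CpG in the first body column", {
    fs <- FeatureSet(data.frame(transcript_id = "t1", scaffold = "s1",
                                start = 5000L, end = 5999L, strand = "+"))
    tab <- makeCpGs(5000L, 100, n_total = 10L)
    m <- flankedMatrix(tab, fs, flank_len = 2000L, body_bins = 30L,
                       flank_bins = 20L)
    expect_equal(dim(m), c(1L, 70L))
    expect_equal(unname(m[1, "b1"]), 100)
    expect_true(all(is.na(m[1, setdiff(colnames(m), "b1")])))
})

test_that("flanked matrix is strand-symmetric", {
    # a minus-strand gene with CpGs mirrored about its center must produce
    # the same row as the plus-strand original
    fsP <- FeatureSet(data.frame(transcript_id = "p", scaffold = "s1",
                                 start = 5000L, end = 5999L, strand = "+"))
    fsM <- FeatureSet(data.frame(transcript_id = "m", scaffold = "s1",
                                 start = 5000L, end = 5999L, strand = "-"))
    offs <- c(-1500L, -250L, 100L, 420L, 999L, 1200L, 2600L)  # from TSS
    meth <- c(10, 20, 90, 80, 70, 30, 40)
    posP <- 5000L + offs
    posM <- 5999L - offs
    mP <- flankedMatrix(makeCpGs(posP, meth), fsP)
    mM <- flankedMatrix(makeCpGs(posM, meth), fsM)
    expect_equal(unname(mP), unname(mM))
})

test_that("body columns are consistent with the transcript mean", {
    fs <- FeatureSet(data.frame(transcript_id = "t1", scaffold = "s1",
                                start = 1001L, end = 1300L, strand = "+"))
    pos <- seq(1001L, 1291L, by = 10L)           # one CpG per body bin
    meth <- round(seq(0, 100, length.out = 30))
    tab <- makeCpGs(pos, meth, n_total = 100L)
    m <- flankedMatrix(tab, fs, body_bins = 30L)
    body <- m[1, paste0("b", 1:30)]
    expect_true(all(!is.na(body)))
    means <- transcriptMeanMethylation(tab, fs)
    expect_equal(mean(body), means$body_mean[1], tolerance = 1e-9)
})
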