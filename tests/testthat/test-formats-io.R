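test_that("readCGmap converts columns, strands and scales per the dialect", {
    f <- writeTempLines(c(
        "s1\tC\t101\tCG\tCG\t0.5\t5\t10",
        "s1\tG\t102\tCG\tCG\t0.2\t2\t10",
        "s1\tC\t300\tCHH\tCA\t0.9\t9\t10",
        "s2\tC\t50\tCHG\tCT\t0.1\t1\t10"))
    tab <- readCGmap(f, min_total = 1L)
    df <- as.data.frame(tab)
    expect_equal(nrow(df), 2L)          # CpG context only
    expect_equal(df$pos, c(101L, 102L)) # 1-based cytosine positions
    expect_equal(df$strand, c("+", "-"))
    expect_equal(df$meth_pct, c(50, 20))
    expect_equal(df$n_meth, c(5L, 2L))
    expect_equal(df$n_total, c(10L, 10L))
})

test_that("readCGmap depth filter, empty input and error paths", {
    f <- writeTempLines(c("s1\tC\t10\tCG\tCG\t0.5\t2\t4",
                          "s1\tC\t20\tCG\tCG\t0.5\t5\t10"))
    expect_equal(length(readCGmap(f, min_total = 10L)), 1L)
    onlyNonCpG <- writeTempLines("s1\tC\t10\tCHH\tCA\t0.5\t2\t4")
    expect_equal(length(readCGmap(onlyNonCpG)), 0L)
    empty <- writeTempLines(character())
    expect_equal(length(readCGmap(empty)), 0L)
    short <- writeTempLines(c("s1\tC\t10\tCG\tCG\t0.5\t2\t4", "s1\tC\t3"))
    expect_error(readCGmap(short), "line 2")
    badLevel <- writeTempLines("s1\tC\t10\tCG\tCG\t1.5\t2\t4")
    expect_error(readCGmap(badLevel), "outside")
})

test_that("CGmap write/read round-trips sites, strands and counts", {
    set.seed(42)
    n <- 50L
    nt <- sample(5:30, n, replace = TRUE)
    nm <- vapply(nt, function(t) sample(0:t, 1L), integer(1))
    tab <- CpGTable(sample(c("s1", "s2"), n, TRUE),
                    sample.int(1e6, n), sample(c("+", "-"), n, TRUE),
                    100 * nm / nt, nm, nt, sample = "rt")
    f <- tempfile()
    writeCGmap(tab, f)
    back <- readCGmap(f, sample = "rt")
    expect_identical(as.character(seqnames(cpgSites(back))),
                     as.character(seqnames(cpgSites(tab))))
    expect_identical(start(cpgSites(back)), start(cpgSites(tab)))
    expect_identical(as.character(strand(cpgSites(back))),
                     as.character(strand(cpgSites(tab))))
    expect_identical(methReads(back), methReads(tab))
    expect_identical(totalReads(back), totalReads(tab))
    expect_equal(methPct(back), methPct(tab), tolerance = 1e-12)
    # strand law: + iff the nucleotide column is C
    lines <- readLines(f)
    nuc <- vapply(strsplit(lines, "\t"), `[`, character(1), 2)
    expect_identical(nuc == "C",
                     as.character(strand(cpgSites(tab))) == "+")
})

test_that("readCGmap handles gzip transparently", {
    f <- tempfile(fileext = ".gz")
    con <- gzfile(f, "wt")
    writeLines("s1\tC\t7\tCG\tCG\t1\t4\t4", con)
    close(con)
    tab <- readCGmap(f)
    expect_equal(methPct(tab), 100)
})

test_that("readBismarkCoverage filters depth and validates the dialect", {
    f <- writeTempLines(c("s1\t5\t5\t44.444444\t4\t5",
                          "s1\t11\t11\t100.000000\t12\t0"))
    tab <- readBismarkCoverage(f, min_total = 10L)
    expect_equal(length(tab), 1L)       # 4+5 = 9 reads dropped
    expect_equal(methPct(tab), 100)
    expect_equal(totalReads(tab), 12L)
    expect_false(mcols(cpgSites(tab))$strand_resolved)
    expect_equal(as.character(strand(cpgSites(tab))), "+")
    bad <- writeTempLines("s1\t5\t6\t50\t1\t1")
    expect_error(readBismarkCoverage(bad), "dialect")
})

test_that("coverage percent column is consistent with counts on simulated data", {
    sim <- cachedSmallSim()
    f <- tempfile()
    tab <- simulateMethylome(sim, "RRBS", "hatchling", seed = 31L, path = f)
    lines <- strsplit(readLines(f), "\t")
    pct <- as.numeric(vapply(lines, `[`, character(1), 4))
    nm <- as.numeric(vapply(lines, `[`, character(1), 5))
    nu <- as.numeric(vapply(lines, `[`, character(1), 6))
    expect_true(all(abs(pct - 100 * nm / (nm + nu)) <= 0.01))
    back <- readBismarkCoverage(f, min_total = 1L)
    expect_equal(methPct(back), 100 * methReads(back) / totalReads(back),
                 tolerance = 1e-12)
})

test_that("coverage strand resolution by genome base lookup", {
    sim <- cachedSmallSim()
    f <- tempfile()
    simulateMethylome(sim, "RRBS", "hatchling", seed = 32L, path = f)
    tab <- readBismarkCoverage(f, min_total = 1L, genome = sim$genome)
    expect_true(all(mcols(cpgSites(tab))$strand_resolved))
    # plus-strand calls sit on the planted C positions, minus on the G
    plus <- start(cpgSites(tab))[as.character(strand(cpgSites(tab))) == "+"]
    expect_true(all(plus %in% sim$truth$cpgs$pos))
    minus <- start(cpgSites(tab))[as.character(strand(cpgSites(tab))) == "-"]
    expect_true(all((minus - 1L) %in% sim$truth$cpgs$pos))
})

test_that("gene model reader derives strand-aware TSS/TTS and round-trips", {
    f <- writeTempLines(c(
        "##gff-version 3",
        "s1\t.\tmRNA\t101\t200\t.\t+\t.\tID=txA",
        "s1\t.\texon\t101\t140\t.\t+\t.\tID=txA.e1;Parent=txA",
        "s1\t.\texon\t161\t200\t.\t+\t.\tID=txA.e2;Parent=txA",
        "s1\t.\tmRNA\t301\t400\t.\t-\t.\tID=txB",
        "s1\t.\texon\t301\t400\t.\t-\t.\tID=txB.e1;Parent=txB"),
        ext = ".gff3")
    fs <- readGeneModels(f)
    expect_equal(length(fs), 2L)
    expect_equal(start(transcriptRanges(fs)), c(101L, 301L))
    expect_equal(end(transcriptRanges(fs)), c(200L, 400L))
    expect_equal(tssPositions(fs), c(101, 400))   # minus-strand TSS at 3' end
    expect_equal(ttsPositions(fs), c(200, 301))
    # identity under write -> read
    f2 <- tempfile(fileext = ".gff3")
    writeGeneModels(fs, f2)
    fs2 <- readGeneModels(f2)
    expect_equal(transcriptIds(fs2), transcriptIds(fs))
    expect_identical(start(transcriptRanges(fs2)), start(transcriptRanges(fs)))
    expect_identical(end(transcriptRanges(fs2)), end(transcriptRanges(fs)))
    expect_identical(as.character(strand(transcriptRanges(fs2))),
                     as.character(strand(transcriptRanges(fs))))
    expect_equal(lapply(exonRanges(fs2), start), lapply(exonRanges(fs), start))
})

test_that("gene model reader warns on orphan exons and handles empty input", {
    f <- writeTempLines(c(
        "##gff-version 3",
        "s1\t.\tmRNA\t101\t200\t.\t+\t.\tID=txA",
        "s1\t.\texon\t101\t200\t.\t+\t.\tID=x.e1;Parent=ghost"),
        ext = ".gff3")
    expect_warning(fs <- readGeneModels(f), "parent")
    # the orphan record is dropped; the transcript keeps its span as exon
    expect_equal(start(exonRanges(fs)[["txA"]]), 101L)
    expect_equal(end(exonRanges(fs)[["txA"]]), 200L)
    emptyf <- writeTempLines("##gff-version 3", ext = ".gff3")
    expect_equal(length(readGeneModels(emptyf)), 0L)
})

test_that("RepeatMasker reader groups classes by prefix rules", {
    hdr <- c("   SW  perc ...", "score  div ...", "")
    rows <- c(
        " 100 1.0 0.0 0.0 s1 101 200 (0) + repA LINE/L2 1 100 (0) 1",
        " 100 1.0 0.0 0.0 s1 301 400 (0) C repB rRNA 1 100 (0) 2",
        " 100 1.0 0.0 0.0 s2 11 90 (0) + repC Simple_repeat 1 80 (0) 3",
        " 100 1.0 0.0 0.0 s2 101 220 (0) + repD DNA/hAT-Ac 1 100 (0) 4")
    f <- writeTempLines(c(hdr, rows), ext = ".out")
    rs <- readRepeatMasker(f)
    expect_equal(repeatGroup(rs), c("LINE", "OtherRE", "SimpleRepeat", "DNA"))
    expect_equal(as.character(strand(repeatRanges(rs))), c("+", "-", "+", "+"))
    expect_equal(start(repeatRanges(rs)), c(101L, 301L, 11L, 101L))
    headerOnly <- writeTempLines(hdr, ext = ".out")
    expect_equal(length(readRepeatMasker(headerOnly)), 0L)
    badCoord <- writeTempLines(c(hdr,
        " 100 1.0 0.0 0.0 s1 xx 200 (0) + repA LINE 1 100 (0) 1"), ext = ".out")
    expect_error(readRepeatMasker(badCoord), "coordinate")
})

test_that("repeat class grouping is a total function with OtherRE fall-through", {
    expect_equal(repeatClassGroup(c("DNA/TcMar", "LTR/Copia", "LINE", "SINE/tRNA",
                                    "Satellite/acro", "Simple_repeat",
                                    "Low_complexity", "snRNA", "Unknown")),
                 c("DNA", "LTR", "LINE", "SINE", "Satellite", "SimpleRepeat",
                   "OtherRE", "OtherRE", "OtherRE"))
})

test_that("TPM matrix validates and round-trips", {
    m <- matrix(c(0, 1.5, 2.25, 10), 2, 2,
                dimnames = list(c("t1", "t2"), c("brain", "arm")))
    f <- tempfile(fileext = ".tsv")
    writeTpmMatrix(m, f)
    expect_equal(readTpmMatrix(f), m)
    neg <- writeTempLines(c("transcript_id\ta", "t1\t-1"), ext = ".tsv")
    expect_error(readTpmMatrix(neg), "negative")
    dup <- writeTempLines(c("transcript_id\ta", "t1\t1", "t1\t2"),
                          ext = ".tsv")
    expect_error(readTpmMatrix(dup), "t1")
})

test_that("simulated TPM output re-reads to the in-memory truth", {
    sim <- cachedSmallSim()
    tpm <- simulateExpression(sim, seed = 9L)
    f <- tempfile(fileext = ".tsv")
    writeTpmMatrix(tpm, f)
    expect_equal(readTpmMatrix(f), tpm, tolerance = 1e-9)
})

test_that("term map reader groups genes under terms", {
    f <- writeTempLines(c("term_id\tgene_id", "GO:1\tg1", "GO:1\tg2",
                          "GO:2\tg2"), ext = ".tsv")
    tm <- readTermMap(f)
    expect_equal(tm[["GO:1"]], c("g1", "g2"))
    expect_equal(tm[["GO:2"]], "g2")
})
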