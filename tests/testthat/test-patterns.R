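test_that("transcript means average covered body CpGs and report exclusions", {
    fs <- FeatureSet(data.frame(transcript_id = c("t1", "t2"),
                                scaffold = "s1",
                                start = c(100L, 1000L), end = c(200L, 1100L),
                                strand = "+"))
    tab <- makeCpGs(c(110L, 190L), c(0, 100), n_total = 10L)
    m <- transcriptMeanMethylation(tab, fs)
    expect_equal(m$transcript_id, "t1")
    expect_equal(m$body_mean, 50)
    expect_equal(m$n_cpgs_body, 2L)
    expect_equal(attr(m, "excluded"), "t2")
})

test_that("transcript means equal a literal per-transcript scan", {
    set.seed(41)
    nG <- 300
    tx <- data.frame(transcript_id = sprintf("g%03d", 1:nG),
                     scaffold = sample(c("s1", "s2", "s3"), nG, TRUE),
                     start = sample.int(1e5, nG),
                     strand = sample(c("+", "-"), nG, TRUE))
    tx$end <- tx$start + sample(50:500, nG, TRUE)
    fs <- FeatureSet(tx)
    n <- 3000
    scaff <- sample(c("s1", "s2", "s3"), n, TRUE)
    pos <- sample.int(101000, n)
    meth <- runif(n, 0, 100)
    tab <- CpGTable(scaff, pos, "+", meth, 0L, 0L, sample = "x")
    got <- transcriptMeanMethylation(tab, fs)
    want <- vapply(seq_len(nG), function(i) {
        v <- meth[scaff == tx$scaffold[i] & pos >= tx$start[i] &
                  pos <= tx$end[i]]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    keep <- !is.na(want)
    expect_equal(got$transcript_id, tx$transcript_id[keep])
    expect_equal(got$body_mean, want[keep], tolerance = 1e-9)
})

test_that("k = 1 returns the overall mean as single center", {
    x <- c(1, 5, 9, 13)
    pa <- kmeansPatterns(stats::setNames(x, paste0("t", 1:4)), k = 1L,
                         seed = 2L)
    expect_equal(patternCenters(pa), mean(x))
    expect_true(all(as.data.frame(pa)$mp_label == 1L))
})

test_that("well-separated triplets are recovered with descending centers", {
    x <- stats::setNames(c(0, 1, 2, 50, 51, 52, 98, 99, 100),
                         paste0("t", 1:9))
    pa <- kmeansPatterns(x, k = 3L, seed = 4L)
    expect_equal(patternCenters(pa), c(99, 51, 1))
    expect_equal(unname(patternLabels(pa)), rep(c(3L, 2L, 1L), each = 3L))
})

test_that("Lloyd best-of-restarts reaches the exact 1-D optimum", {
    set.seed(51)
    for (r in 1:10) {
        n <- sample(10:50, 1)
        k <- sample(2:4, 1)
        x <- stats::setNames(round(runif(n, 0, 100), 3), seq_len(n))
        if (length(unique(x)) < k) next
        pa <- kmeansPatterns(x, k = k, seed = r, restarts = 10L)
        expect_equal(pa@inertia, kmeansExactWSS(x, k), tolerance = 1e-8)
    }
})

test_that("clustering is deterministic for a fixed seed and errors on degeneracy", {
    set.seed(61)
    x <- stats::setNames(runif(200, 0, 100), paste0("t", 1:200))
    a <- kmeansPatterns(x, k = 4L, seed = 9L)
    b <- kmeansPatterns(x, k = 4L, seed = 9L)
    expect_identical(patternLabels(a), patternLabels(b))
    expect_identical(patternCenters(a), patternCenters(b))
    expect_error(kmeansPatterns(c(a = 1, b = 1, c = 1, d = 2), k = 3L,
                                seed = 1L), "distinct")
})

test_that("labels are nearest-center with ties toward the lower label", {
    set.seed(71)
    x <- stats::setNames(runif(300, 0, 100), paste0("t", 1:300))
    pa <- kmeansPatterns(x, k = 4L, seed = 3L)
    centers <- patternCenters(pa)
    lab <- unname(patternLabels(pa))
    d <- abs(outer(x, centers, "-"))
    for (i in seq_along(x)) {
        best <- which(d[i, ] == min(d[i, ]))
        expect_equal(lab[i], min(best))
    }
    expect_true(all(diff(centers) < 0))
})

test_that("pattern recovery on archetype-like mixtures", {
    set.seed(81)
    truth <- sample(1:4, 1500, replace = TRUE)
    mu <- c(75, 50, 30, 2)[truth]
    x <- stats::setNames(pmin(pmax(mu + rnorm(1500, 0, 5), 0), 100),
                         paste0("t", 1:1500))
    pa <- kmeansPatterns(x, k = 4L, seed = 5L)
    tab <- table(truth, patternLabels(pa))
    expect_gte(adjustedRand(tab), 0.95)
    expect_true(all(abs(patternCenters(pa) - c(75, 50, 30, 2)) <= 3))
})

test_that("reference ordering transfers labels without re-clustering", {
    set.seed(91)
    ref_means <- data.frame(transcript_id = paste0("t", 1:100),
                            body_mean = runif(100, 0, 100),
                            n_cpgs_body = 5L)
    pa <- kmeansPatterns(ref_means, k = 3L, seed = 2L)
    # an identical sample reproduces the per-pattern means
    out <- applyReferenceOrder(pa, list(same = ref_means))
    perMP <- tapply(out$mean_same, out$mp_label, mean)
    perRef <- tapply(out$body_mean, out$mp_label, mean)
    expect_equal(perMP, perRef)
    # a permuted copy has the same per-pattern means
    shuf <- ref_means[sample.int(100), ]
    out2 <- applyReferenceOrder(pa, list(shuffled = shuf))
    expect_equal(tapply(out2$mean_shuffled, out2$mp_label, mean), perRef)
    # a missing transcript keeps its label with a missing value
    out3 <- applyReferenceOrder(pa, list(part = ref_means[-1, ]))
    expect_true(is.na(out3$mean_part[out3$transcript_id == "t1"]))
    expect_equal(out3$mp_label, out$mp_label)
    expect_error(applyReferenceOrder(pa, list(
        other = data.frame(transcript_id = "zz", body_mean = 1,
                           n_cpgs_body = 1L))), "overlap")
})

test_that("length statistics are log10 widths with literal quartiles", {
    fs <- FeatureSet(data.frame(transcript_id = paste0("t", 1:100),
                                scaffold = "s1",
                                start = seq(1L, by = 5000L, length.out = 100),
                                end = seq(1L, by = 5000L, length.out = 100) +
                                    sample(100:4000, 100) - 1L,
                                strand = "+"))
    means <- data.frame(transcript_id = paste0("t", 1:100),
                        body_mean = runif(100, 0, 100), n_cpgs_body = 3L)
    pa <- kmeansPatterns(means, k = 2L, seed = 6L)
    st <- patternLengthStats(pa, fs)
    w <- width(transcriptRanges(fs))
    expect_equal(st$lengths$log10_width, log10(w), tolerance = 1e-12)
    for (j in unique(st$lengths$mp_label)) {
        v <- st$lengths$log10_width[st$lengths$mp_label == j]
        expect_equal(unlist(st$quartiles[st$quartiles$mp_label == j,
                                         c("q25", "median", "q75")]),
                     quantile(v, c(0.25, 0.5, 0.75)),
                     ignore_attr = TRUE)
    }
    # a 1000-bp transcript maps to exactly 3
    fs1k <- FeatureSet(data.frame(transcript_id = "t1", scaffold = "s1",
                                  start = 1L, end = 1000L, strand = "+"))
    means1 <- data.frame(transcript_id = "t1", body_mean = 10,
                         n_cpgs_body = 1L)
    pa1 <- kmeansPatterns(rbind(means1,
        data.frame(transcript_id = "t2", body_mean = 90, n_cpgs_body = 1L)),
        k = 2L, seed = 1L)
    st1 <- patternLengthStats(pa1, fs1k)
    expect_equal(st1$lengths$log10_width[st1$lengths$transcript_id == "t1"], 3)
    # grouping partitions the assigned transcripts
    expect_equal(nrow(st$lengths), length(pa))
})
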