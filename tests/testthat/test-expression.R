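test_that("expressed set thresholds strictly and partitions the matrix", {
    m <- matrix(c(0, 0, 0.01, 0, 5, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("t1", "t2", "t3"), c("a", "b")))
    expect_equal(expressedSet(m), c("t2", "t3"))
    expect_equal(expressedSet(matrix(0, 2, 2,
        dimnames = list(c("x", "y"), c("a", "b")))), character())
    expect_equal(length(expressedSet(m)) +
                 sum(apply(m > 0, 1, function(r) !any(r))), nrow(m))
})

test_that("log transform is monotone with exact inverse", {
    tpm <- c(0, 0.3, 7, 1500)
    e <- logTpm(tpm)
    expect_true(all(diff(e) > 0))
    expect_equal(2^e - 1, tpm, tolerance = 1e-9)
    expect_identical(e[1], 0)
})

test_that("percentile curve groups are balanced and flat under constant methylation", {
    set.seed(101)
    e <- stats::setNames(runif(1003), sprintf("t%04d", 1:1003))
    m <- stats::setNames(rep(42, 1003), names(e))
    cur <- percentileMethylationCurve(e, m, n_groups = 100L)
    expect_equal(nrow(cur), 100L)
    expect_true(all(cur$mean_meth == 42))
    expect_lte(max(cur$n) - min(cur$n), 1L)
    expect_true(all(diff(cur$mean_expr) >= 0))
    expect_error(percentileMethylationCurve(e[1:50], m[1:50], 100L),
                 "n_groups")
})

test_that("Kruskal-Wallis and Dunn behave on degenerate and shifted groups", {
    # identical groups: H is exactly 0
    e <- stats::setNames(rep(c(1, 2, 3), 4), paste0("t", 1:12))
    g <- stats::setNames(rep(1:4, each = 3), names(e))
    res <- mpExpressionTest(e, g)
    expect_equal(res$kw$statistic, 0)
    # two groups three sd apart: tiny adjusted p
    set.seed(111)
    x <- stats::setNames(c(rnorm(100, 0, 1), rnorm(100, 3, 1)),
                         paste0("t", 1:200))
    gg <- stats::setNames(rep(1:2, each = 100), names(x))
    res2 <- mpExpressionTest(x, gg)
    expect_lt(res2$dunn$padj, 0.001)
    expect_equal(res2$group_stats$n, c(100L, 100L))
    # a one-member group is excluded from pairwise tests with a warning
    x3 <- stats::setNames(c(rnorm(20), rnorm(20, 2), 5), paste0("t", 1:41))
    g3 <- stats::setNames(c(rep(1, 20), rep(2, 20), 3), names(x3))
    expect_warning(res3 <- mpExpressionTest(x3, g3), "2 members")
    expect_equal(nrow(res3$dunn), 1L)
})

test_that("Kruskal-Wallis matches a permutation reference on small samples", {
    set.seed(121)
    x <- stats::setNames(rnorm(24), paste0("t", 1:24))
    g <- stats::setNames(rep(1:3, each = 8), names(x))
    res <- mpExpressionTest(x, g)
    H <- function(xx) unname(kruskal.test(xx, factor(g))$statistic)
    obs <- H(x)
    perm <- replicate(4000, H(stats::setNames(sample(x), names(x))))
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(res$kw$p.value - p_perm), 0.05)
})

test_that("z-score clustering standardizes rows and groups identical profiles", {
    set.seed(131)
    base <- matrix(rnorm(60), 6, 10)
    m <- rbind(base, base[1, , drop = FALSE] * 3 + 5)  # same profile, scaled
    rownames(m) <- paste0("t", 1:7)
    colnames(m) <- paste0("s", 1:10)
    res <- zscoreCluster(pmax(m, 0), k = 3L)
    z <- res$zscores
    expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-9)
    expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-9)
    # zero-variance rows are excluded and small k errors are caught
    m0 <- rbind(m, t0 = rep(2, 10))
    res0 <- zscoreCluster(m0, k = 3L)
    expect_equal(res0$excluded, "t0")
    expect_error(zscoreCluster(m, k = 100L), "nonzero variance")
    # three well-separated archetypes are recovered at k = 3
    proto <- matrix(rnorm(30), 3, 10)
    big <- proto[rep(1:3, each = 5), ] + matrix(rnorm(150, 0, 0.05), 15, 10)
    rownames(big) <- paste0("g", 1:15)
    colnames(big) <- paste0("s", 1:10)
    labs <- zscoreCluster(big - min(big), k = 3L)$labels
    expect_equal(length(unique(labs)), 3L)
    expect_true(all(tapply(labs, rep(1:3, each = 5),
                           function(v) length(unique(v))) == 1L))
})

test_that("top-n overlap obeys set identities and determinism", {
    set.seed(141)
    m <- matrix(runif(300), 100, 3,
                dimnames = list(sprintf("t%03d", 1:100), c("a", "b", "c")))
    # identical samples: union = intersection = n
    mid <- cbind(a = m[, 1], b = m[, 1])
    o <- topnOverlap(mid, n = 10L)
    expect_equal(length(o$union), 10L)
    expect_equal(length(o$intersection), 10L)
    # disjoint top sets: union 3n, empty intersection
    md <- cbind(a = c(rep(9, 10), rep(0, 20), runif(70, 0, 0.1)),
                b = c(rep(0, 10), rep(9, 10), rep(0, 10), runif(70, 0, 0.1)),
                c = c(rep(0, 20), rep(9, 10), runif(70, 0, 0.1)))
    rownames(md) <- sprintf("t%03d", 1:100)
    od <- topnOverlap(md, n = 10L)
    expect_equal(length(od$union), 30L)
    expect_equal(length(od$intersection), 0L)
    # membership signature counts always sum to the union size
    o3 <- topnOverlap(m, n = 25L)
    expect_equal(sum(o3$counts), length(o3$union))
    # determinism under ties: tied TPMs break by transcript id
    tied <- cbind(a = rep(1, 100), b = rep(1, 100))
    rownames(tied) <- sprintf("t%03d", 100:1)
    ot <- topnOverlap(tied, n = 5L)
    expect_equal(ot$union, sprintf("t%03d", 1:5))
    expect_error(topnOverlap(m, n = 1000L), "fewer")
})

test_that("hypergeometric enrichment matches exact combinatorics and BH", {
    universe <- paste0("g", 1:10)
    term_map <- list(T1 = paste0("g", 1:5))
    res <- goEnrichment(paste0("g", 1:4), universe, term_map)
    expect_equal(res$p, 5 / 210, tolerance = 1e-12)   # C(5,4)/C(10,4)
    expect_equal(res$k_obs, 4L)
    expect_equal(res$gene_ratio, 4 / (4 * 5 / 10))
    # empty observed overlap: upper tail from 0 is exactly 1
    res0 <- goEnrichment(paste0("g", 6:9), universe,
                         list(T1 = paste0("g", 1:5)))
    expect_equal(res0$p, 1)
    expect_error(goEnrichment(c("g1", "zz"), universe, term_map), "zz")
})

test_that("BH adjustment reproduces the hand-computed staircase", {
    # engineer three terms with p = (0.01, 0.02, 0.04) scale behaviour via
    # direct check of the adjustment contract on the output
    universe <- paste0("g", 1:40)
    gl <- paste0("g", 1:10)
    tm <- list(A = paste0("g", c(1:6, 21:24)),
               B = paste0("g", c(1:5, 21:30)),
               C = paste0("g", c(1:4, 21:26)))
    res <- goEnrichment(gl, universe, tm)
    expect_equal(res$padj, p.adjust(res$p, "BH"))
    expect_true(all(res$padj >= res$p))
    expect_true(all(res$padj <= 1))
    expect_true(all(res$k_obs <= pmin(res$n_list, res$K_universe)))
    # the textbook BH example
    expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
                 c(0.03, 0.03, 0.04))
})
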