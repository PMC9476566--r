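suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracle implementations used to check the package's fast paths.
# These deliberately use the most literal possible algorithm (loops,
# enumeration, dynamic programming) and none of the package internals.

# adjusted Rand index from a contingency table
adjustedRand <- function(tab) {
    n <- sum(tab)
    a <- sum(choose(rowSums(tab), 2))
    b <- sum(choose(colSums(tab), 2))
    idx <- sum(choose(tab, 2))
    expected <- a * b / choose(n, 2)
    (idx - expected) / ((a + b) / 2 - expected)
}

# exact optimal 1-D k-means by dynamic programming over sorted values
kmeansExactWSS <- function(x, k) {
    x <- sort(x)
    n <- length(x)
    cs <- cumsum(x)
    cs2 <- cumsum(x^2)
    sse <- function(i, j) {          # cost of one cluster covering x[i..j]
        s <- cs[j] - if (i > 1) cs[i - 1] else 0
        s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
        s2 - s^2 / (j - i + 1)
    }
    D <- matrix(Inf, k, n)
    for (j in 1:n) D[1, j] <- sse(1, j)
    if (k > 1)
        for (q in 2:k)
            for (j in q:n)
                for (i in q:j)
                    D[q, j] <- min(D[q, j], D[q - 1, i - 1] + sse(i, j))
    D[k, n]
}

# literal per-position scaled-bin assignment (1-based closed interval)
bruteBin <- function(pos, start, end, strand, B) {
    L <- end - start + 1
    d <- if (strand == "-") end - pos else pos - start
    min(floor(B * d / L), B - 1) + 1
}

# literal winsorized-mean metaplot over a CpG data.frame and region table
bruteMetaplot <- function(cpg, regions, B, winsor = c(1, 99)) {
    vals <- vector("list", B)
    for (r in seq_len(nrow(regions))) {
        for (i in seq_len(nrow(cpg))) {
            if (cpg$scaffold[i] == regions$scaffold[r] &&
                cpg$pos[i] >= regions$start[r] &&
                cpg$pos[i] <= regions$end[r]) {
                b <- bruteBin(cpg$pos[i], regions$start[r], regions$end[r],
                              regions$strand[r], B)
                vals[[b]] <- c(vals[[b]], cpg$meth_pct[i])
            }
        }
    }
    t(vapply(seq_len(B), function(b) {
        v <- vals[[b]]
        if (!length(v)) return(c(mean = NA_real_, n = 0))
        q <- quantile(v, winsor / 100, names = FALSE, type = 7)
        v <- pmin(pmax(v, q[1]), q[2])
        c(mean = mean(v), n = length(v))
    }, numeric(2)))
}

# literal context annotation for one CpG position
bruteContext <- function(scaffold, pos, tx, promoter_len = 2000) {
    # tx: data.frame transcript_id, scaffold, start, end, strand plus a list
    # column 'exons' of data.frames(start, end)
    ctx <- "intergenic"
    for (r in seq_len(nrow(tx))) {
        if (tx$scaffold[r] != scaffold) next
        if (pos >= tx$start[r] && pos <= tx$end[r] && ctx == "intergenic")
            ctx <- "intron"
        ex <- tx$exons[[r]]
        for (e in seq_len(nrow(ex)))
            if (pos >= ex$start[e] && pos <= ex$end[e] &&
                ctx %in% c("intergenic", "intron"))
                ctx <- "exon"
        if (tx$strand[r] == "+") {
            if (pos >= tx$start[r] - promoter_len && pos < tx$start[r])
                ctx <- "promoter"
        } else {
            if (pos > tx$end[r] && pos <= tx$end[r] + promoter_len)
                ctx <- "promoter"
        }
    }
    ctx
}

# tiny in-memory CpG table helper
makeCpGs <- function(pos, meth, scaffold = "s1", strand = "+",
                     n_total = 10L, sample = "t") {
    n_meth <- as.integer(round(meth / 100 * n_total))
    CpGTable(rep(scaffold, length.out = length(pos)), pos,
             rep(strand, length.out = length(pos)),
             100 * n_meth / n_total, n_meth,
             rep(n_total, length.out = length(pos)), sample = sample)
}

writeTempLines <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
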