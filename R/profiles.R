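#' @include AllClasses.R utils.R
NULL

#' Scaled bin index of a position within a region
#'
#' Regions of unequal length are rescaled to \code{B} equal bins. The bin of
#' a position is \code{floor(B * d / L)} clamped to \code{B - 1}, where
#' \code{L} is the region length and \code{d} the distance from the 5' end
#' respecting strand. Bins are numbered from 1 (5'-most).
#'
#' @param region a length-1 \link[GenomicRanges]{GRanges} (or any object
#'   with start/end/strand accessors of length 1).
#' @param pos integer vector of 1-based positions inside the region.
#' @param B number of bins.
#' @return integer bin indices in 1..B.
#' @export
assignBin <- function(region, pos, B) {
    s <- start(region); e <- end(region)
    st <- as.character(strand(region))
    if (length(s) != 1L)
        .stopf("assignBin expects a single region")
    if (any(pos < s | pos > e))
        .stopf("position outside region [%d, %d]", s, e)
    .binIndex(pos, s, e, st, as.integer(B)) + 1L
}

.regionRanges <- function(regions) {
    if (methods::is(regions, "FeatureSet")) transcriptRanges(regions)
    else if (methods::is(regions, "RepeatSet")) repeatRanges(regions)
    else if (methods::is(regions, "GRanges")) regions
    else .stopf("regions must be a FeatureSet, RepeatSet or GRanges")
}

.regionLabel <- function(regions) {
    if (methods::is(regions, "FeatureSet")) "transcripts"
    else if (methods::is(regions, "RepeatSet")) "repeats"
    else "regions"
}

## pool (bin, value) pairs for all CpG/region overlaps; strand ignored on
## the CpG side, bin orientation taken from the region strand
.poolBinValues <- function(cpgs, regions, B) {
    rr <- .regionRanges(regions)
    q <- granges(cpgSites(cpgs))
    strand(q) <- "*"
    hits <- findOverlaps(q, rr, ignore.strand = TRUE)
    if (!length(hits))
        return(data.frame(bin = integer(), value = numeric()))
    ri <- subjectHits(hits)
    bins <- .binIndex(start(q)[queryHits(hits)],
                      start(rr)[ri], end(rr)[ri],
                      as.character(strand(rr))[ri], B) + 1L
    data.frame(bin = bins, value = methPct(cpgs)[queryHits(hits)])
}

#' Scaled-bin winsorized-mean metaplot
#'
#' Pools the methylation percentages of all CpGs overlapping each region,
#' assigns each value to one of \code{B} strand-aware scaled bins, and
#' summarizes each bin by the winsorized mean (default limits the 1st and
#' 99th percentile of that bin's values) with a 95% normal-approximation
#' confidence half-width, \code{1.96 * sd / sqrt(n)}, computed on the
#' clipped values. Transcripts are conventionally profiled with 30 bins,
#' repeats with 15.
#'
#' @param cpgs a \linkS4class{CpGTable}.
#' @param regions a \linkS4class{FeatureSet}, \linkS4class{RepeatSet} or
#'   \code{GRanges}.
#' @param B number of bins (default 30).
#' @param winsor length-2 numeric, winsorization percentiles
#'   (default \code{c(1, 99)}); \code{c(0, 100)} gives the plain mean.
#' @return a \linkS4class{BinnedProfile}.
#' @export
metaplot <- function(cpgs, regions, B = 30L, winsor = c(1, 99)) {
    B <- as.integer(B)
    if (B < 1L) .stopf("B must be >= 1")
    pooled <- .poolBinValues(cpgs, regions, B)
    stats <- lapply(seq_len(B), function(b) {
        w <- winsorizedMean(pooled$value[pooled$bin == b],
                            winsor[1], winsor[2])
        ci <- if (w$n > 1L) 1.96 * w$sd / sqrt(w$n) else
            if (w$n == 1L) 0 else NA_real_
        data.frame(bin = b, mean = w$mean, ci = ci, n = w$n)
    })
    new("BinnedProfile", stats = do.call(rbind, stats), nbins = B,
        winsor = as.numeric(winsor), regionType = .regionLabel(regions))
}

#' Scaled-bin CpG density track
#'
#' For each bin, the number of CG dinucleotide starts assigned to the bin
#' divided by the number of bases assigned to it, pooled across regions.
#' Complements a methylation metaplot over the same regions.
#'
#' @param regions a \linkS4class{FeatureSet}, \linkS4class{RepeatSet} or
#'   \code{GRanges}.
#' @param genome FASTA path or \link[Biostrings]{DNAStringSet} covering all
#'   region scaffolds.
#' @param B number of bins (default 15).
#' @return a \linkS4class{BinnedProfile} whose \code{mean} column is the
#'   density (CG starts per base) and \code{n} the CG-start count; \code{ci}
#'   is NA.
#' @export
cpgDensity <- function(regions, genome, B = 15L) {
    B <- as.integer(B)
    rr <- .regionRanges(regions)
    seqs <- .asGenome(genome)
    cg <- numeric(B)
    bases <- numeric(B)
    for (i in seq_along(rr)) {
        sc <- as.character(seqnames(rr))[i]
        if (!sc %in% names(seqs))
            .stopf("scaffold '%s' absent from the genome", sc)
        if (end(rr)[i] > length(seqs[[sc]]))
            .stopf("region %d extends beyond scaffold '%s'", i, sc)
        s <- start(rr)[i]; e <- end(rr)[i]
        st <- as.character(strand(rr))[i]
        m <- Biostrings::matchPattern("CG", Biostrings::subseq(seqs[[sc]], s, e),
                                      fixed = TRUE)
        if (length(m)) {
            b <- .binIndex(start(m) + s - 1L, s, e, st, B) + 1L
            cg <- cg + tabulate(b, nbins = B)
        }
        bases <- bases + tabulate(.binIndex(s:e, s, e, st, B) + 1L, nbins = B)
    }
    stats <- data.frame(bin = seq_len(B),
                        mean = ifelse(bases > 0, cg / bases, NA_real_),
                        ci = NA_real_, n = as.integer(cg))
    new("BinnedProfile", stats = stats, nbins = B, winsor = c(0, 100),
        regionType = paste("CpG density:", .regionLabel(regions)))
}

#' Flanked per-transcript methylation matrix
#'
#' One row per transcript: \code{flank_bins} fixed-width windows over
#' \code{flank_len} bp upstream of the TSS, \code{body_bins} length-scaled
#' bins over the body (TSS to TTS), and \code{flank_bins} windows downstream
#' of the TTS. Each cell is the mean methylation percent of the CpGs it
#' contains (NA where none); upstream is always on the left regardless of
#' strand. This is the matrix behind gene-level methylation heatmaps.
#'
#' @param cpgs a \linkS4class{CpGTable}.
#' @param features a \linkS4class{FeatureSet}.
#' @param flank_len flank width in bp (default 2000).
#' @param body_bins scaled bins across the body (default 30).
#' @param flank_bins fixed-width windows per flank (default 20, i.e. 100 bp
#'   windows at the default flank).
#' @return numeric matrix, rows named by transcript id, columns
#'   \code{u1..u<flank_bins>, b1..b<body_bins>, d1..d<flank_bins>}.
#' @export
flankedMatrix <- function(cpgs, features, flank_len = 2000L,
                          body_bins = 30L, flank_bins = 20L) {
    if (flank_len < 0) .stopf("flank_len must be >= 0")
    body_bins <- as.integer(body_bins)
    flank_bins <- as.integer(flank_bins)
    tx <- transcriptRanges(features)
    ids <- transcriptIds(features)
    ncol <- 2L * flank_bins + body_bins
    cn <- c(if (flank_bins) paste0("u", seq_len(flank_bins)),
            paste0("b", seq_len(body_bins)),
            if (flank_bins) paste0("d", seq_len(flank_bins)))
    out <- matrix(NA_real_, nrow = length(tx), ncol = ncol,
                  dimnames = list(ids, cn))
    gr <- cpgSites(cpgs)
    cpos <- start(gr)
    cseq <- as.character(seqnames(gr))
    mp <- methPct(cpgs)
    wbin <- flank_len / max(flank_bins, 1L)
    for (i in seq_along(tx)) {
        sc <- as.character(seqnames(tx))[i]
        s <- start(tx)[i]; e <- end(tx)[i]
        st <- as.character(strand(tx))[i]
        lo <- s - flank_len; hi <- e + flank_len
        sel <- which(cseq == sc & cpos >= lo & cpos <= hi)
        if (!length(sel)) next
        p <- cpos[sel]
        # signed distance from the TSS in transcription direction
        col <- integer(length(p))
        inBody <- p >= s & p <= e
        col[inBody] <- flank_bins +
            .binIndex(p[inBody], s, e, st, body_bins) + 1L
        if (flank_bins) {
            if (st == "-") {
                up <- p > e; down <- p < s
                dup <- p[up] - e - 1L        # 0-based distance into the flank
                ddn <- s - p[down] - 1L
            } else {
                up <- p < s; down <- p > e
                dup <- s - p[up] - 1L
                ddn <- p[down] - e - 1L
            }
            # upstream windows count toward the TSS: window 1 is farthest out
            col[up] <- flank_bins - pmin(as.integer(floor(dup / wbin)),
                                         flank_bins - 1L)
            col[down] <- flank_bins + body_bins +
                pmin(as.integer(floor(ddn / wbin)), flank_bins - 1L) + 1L
        }
        keep <- col > 0L
        if (!any(keep)) next
        sums <- rowsum(mp[sel][keep], col[keep])
        cnt <- rowsum(rep(1, sum(keep)), col[keep])
        out[i, as.integer(rownames(sums))] <- sums[, 1] / cnt[, 1]
    }
    out
}
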