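#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames
NULL

.REPEAT_GROUPS <- c("DNA", "LTR", "LINE", "SINE",
                    "Satellite", "SimpleRepeat", "OtherRE")
.TE_GROUPS <- c("DNA", "LTR", "LINE", "SINE")
.CONTEXTS <- c("promoter", "exon", "intron", "intergenic")
.CATEGORIES <- c("methylated", "intermediate", "unmethylated")

#' CpGTable: strand-specific CpG methylation calls
#'
#' One row per strand-specific CpG cytosine. The genomic position is held in a
#' \link[GenomicRanges]{GRanges} of width-1 ranges (1-based, the Bioconductor
#' convention; external 0-based or dialect-specific coordinates are converted
#' at the I/O boundary). Metadata columns carry the methylation level in
#' percent (\code{meth_pct}), the methylated and total read counts
#' (\code{n_meth}, \code{n_total}), and, after classification or annotation,
#' \code{category}, \code{context}, \code{repeat_group} and
#' \code{intergenic_class}.
#'
#' @slot sites width-1 \code{GRanges} with the metadata columns above.
#' @slot sample scalar sample identifier.
#' @export
setClass("CpGTable", representation(sites = "GRanges", sample = "character"))

setValidity("CpGTable", function(object) {
    gr <- object@sites
    msg <- character()
    if (length(object@sample) != 1L)
        msg <- c(msg, "'sample' must be a single identifier")
    need <- c("meth_pct", "n_meth", "n_total")
    miss <- setdiff(need, colnames(mcols(gr)))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(gr)) {
        if (any(width(gr) != 1L))
            msg <- c(msg, "all sites must have width 1")
        m <- mcols(gr)$meth_pct
        nm <- mcols(gr)$n_meth
        nt <- mcols(gr)$n_total
        if (any(m < 0 | m > 100, na.rm = TRUE))
            msg <- c(msg, "meth_pct must lie in [0, 100]")
        if (any(nm > nt, na.rm = TRUE))
            msg <- c(msg, "n_meth must not exceed n_total")
        if (any(nm < 0 | nt < 0, na.rm = TRUE))
            msg <- c(msg, "read counts must be non-negative")
        pos <- nt > 0 & !is.na(nt)
        # tolerate source-file rounding of the level column (2 decimals -> 0.5%)
        if (any(abs(m[pos] - 100 * nm[pos] / nt[pos]) > 0.5 + 1e-9))
            msg <- c(msg, "meth_pct inconsistent with n_meth/n_total beyond file rounding")
        if (anyDuplicated(gr))
            msg <- c(msg, "(scaffold, pos, strand) must be unique within a sample")
    }
    if (length(msg)) msg else TRUE
})

#' FeatureSet: transcript models
#'
#' Transcript spans plus their exon structure on a shared scaffold namespace.
#' The transcription start site (TSS) and termination site (TTS) are derived
#' from the span and strand: on \code{+} the TSS is the span start, on
#' \code{-} it is the span end.
#'
#' @slot transcripts \code{GRanges} with a \code{transcript_id} metadata
#'   column, one range per transcript.
#' @slot exons \code{GRangesList} named by transcript id; exons are sorted in
#'   genomic order and non-overlapping within a transcript.
#' @export
setClass("FeatureSet",
         representation(transcripts = "GRanges", exons = "GRangesList"))

setValidity("FeatureSet", function(object) {
    tx <- object@transcripts
    ex <- object@exons
    msg <- character()
    if (!"transcript_id" %in% colnames(mcols(tx)))
        return("transcripts must carry a 'transcript_id' column")
    ids <- mcols(tx)$transcript_id
    if (anyDuplicated(ids))
        msg <- c(msg, "transcript ids must be unique")
    if (length(ex) && !all(names(ex) %in% ids))
        msg <- c(msg, "exon groups must be named by known transcript ids")
    if (length(tx) && any(width(tx) < 1L))
        msg <- c(msg, "transcript spans must have positive width")
    if (length(ex)) {
        ok <- vapply(seq_along(ex), function(i) {
            e <- ex[[i]]
            if (!length(e)) return(TRUE)
            span <- tx[match(names(ex)[i], ids)]
            inside <- all(start(e) >= start(span) & end(e) <= end(span))
            sorted <- !is.unsorted(start(e), strictly = TRUE)
            disjoint <- all(start(e)[-1] > end(e)[-length(e)]) || length(e) == 1L
            inside && sorted && disjoint
        }, logical(1))
        if (!all(ok))
            msg <- c(msg, "exons must be sorted, disjoint and nested in their span")
    }
    if (length(msg)) msg else TRUE
})

#' RepeatSet: RepeatMasker repeats grouped by class
#'
#' Repeat intervals with the raw RepeatMasker class/family string and the
#' grouping used throughout the analysis: transposon groups DNA, LTR, LINE,
#' SINE, and non-transposon groups Satellite, SimpleRepeat, OtherRE.
#'
#' @slot ranges \code{GRanges} with metadata columns \code{raw_class} and
#'   \code{group} (factor over the seven groups).
#' @export
setClass("RepeatSet", representation(ranges = "GRanges"))

setValidity("RepeatSet", function(object) {
    gr <- object@ranges
    if (!all(c("raw_class", "group") %in% colnames(mcols(gr))))
        return("ranges must carry 'raw_class' and 'group' columns")
    grp <- mcols(gr)$group
    if (length(gr) && !all(as.character(grp) %in% .REPEAT_GROUPS))
        return("unknown repeat group")
    TRUE
})

#' BinnedProfile: scaled-bin methylation or density profile
#'
#' Per-bin summary over a set of regions rescaled to a common number of bins:
#' the winsorized mean (percent), the half-width of the 95% confidence
#' interval for the mean, and the number of contributing values.
#'
#' @slot stats data.frame with columns \code{bin}, \code{mean}, \code{ci},
#'   \code{n}.
#' @slot nbins number of bins.
#' @slot winsor length-2 numeric, lower/upper winsorization percentiles.
#' @slot regionType free-text description of the regions profiled.
#' @export
setClass("BinnedProfile",
         representation(stats = "data.frame", nbins = "integer",
                        winsor = "numeric", regionType = "character"))

setValidity("BinnedProfile", function(object) {
    s <- object@stats
    msg <- character()
    if (!all(c("bin", "mean", "ci", "n") %in% colnames(s)))
        return("stats must have columns bin, mean, ci, n")
    if (nrow(s) != object@nbins)
        msg <- c(msg, "stats must have one row per bin")
    if (any(s$n < 0))
        msg <- c(msg, "n must be non-negative")
    if (any(s$ci < 0, na.rm = TRUE))
        msg <- c(msg, "ci must be non-negative")
    if (any(s$n <= 1L & !is.na(s$ci) & s$ci != 0))
        msg <- c(msg, "ci must be 0 where n <= 1")
    if (length(object@winsor) != 2L || object@winsor[1] > object@winsor[2])
        msg <- c(msg, "winsor must be (lo, hi) percentiles with lo <= hi")
    if (length(msg)) msg else TRUE
})

#' PatternAssignment: gene-body methylation patterns
#'
#' Result of one-dimensional k-means on per-transcript mean gene-body
#' methylation. Cluster labels are relabelled 1..k by descending center, so
#' pattern 1 is the most methylated.
#'
#' @slot assignments data.frame with columns \code{transcript_id},
#'   \code{body_mean}, \code{n_cpgs_body}, \code{mp_label}.
#' @slot centers numeric, strictly descending cluster centers (percent).
#' @slot inertia total within-cluster sum of squares of the winning run.
#' @slot seed,restarts the RNG seed and number of k-means++ restarts used.
#' @slot excluded transcript ids dropped for having too few covered CpGs.
#' @export
setClass("PatternAssignment",
         representation(assignments = "data.frame", centers = "numeric",
                        inertia = "numeric", seed = "integer",
                        restarts = "integer", excluded = "character"))

setValidity("PatternAssignment", function(object) {
    a <- object@assignments
    k <- length(object@centers)
    msg <- character()
    if (!all(c("transcript_id", "body_mean", "n_cpgs_body", "mp_label") %in%
             colnames(a)))
        return("assignments must have transcript_id, body_mean, n_cpgs_body, mp_label")
    if (k > 1 && any(diff(object@centers) >= 0))
        msg <- c(msg, "centers must be strictly descending")
    if (nrow(a) && (any(a$mp_label < 1L) || any(a$mp_label > k)))
        msg <- c(msg, "mp_label out of 1..k")
    if (length(msg)) msg else TRUE
})
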