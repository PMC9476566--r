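#' @include AllClasses.R
NULL

#' Build a CpGTable from vectors
#'
#' Low-level constructor used by the readers and the synthetic generator.
#' Positions are 1-based positions of the cytosine on the given strand.
#'
#' @param scaffold character vector of sequence names.
#' @param pos integer vector, 1-based cytosine positions.
#' @param strand character vector of "+", "-" (or "*" for unresolved).
#' @param meth_pct numeric in [0, 100].
#' @param n_meth,n_total integer read counts.
#' @param sample scalar sample identifier.
#' @param ... further per-site metadata columns (recycled by DataFrame rules).
#' @return a \linkS4class{CpGTable}.
#' @export
#' @examples
#' CpGTable(c("s1", "s1"), c(5L, 9L), c("+", "-"),
#'          c(50, 0), c(5L, 0L), c(10L, 8L), sample = "demo")
CpGTable <- function(scaffold, pos, strand, meth_pct, n_meth, n_total,
                     sample = "sample1", ...) {
    gr <- GRanges(scaffold, IRanges(pos, width = 1L), strand = strand)
    mcols(gr) <- DataFrame(meth_pct = as.numeric(meth_pct),
                           n_meth = as.integer(n_meth),
                           n_total = as.integer(n_total), ...)
    new("CpGTable", sites = gr, sample = as.character(sample))
}

## rebuild a CpGTable around an edited GRanges, keeping the sample tag
.replaceSites <- function(x, gr) {
    initialize(x, sites = gr, sample = x@sample)
}

#' Build a FeatureSet from a transcript table and exon intervals
#'
#' @param transcripts data.frame with columns transcript_id, scaffold, start,
#'   end (1-based inclusive), strand.
#' @param exons optional data.frame with columns transcript_id, start, end;
#'   when missing, each transcript becomes a single exon spanning its body.
#' @return a \linkS4class{FeatureSet}.
#' @export
FeatureSet <- function(transcripts, exons = NULL) {
    tx <- GRanges(transcripts$scaffold,
                  IRanges(transcripts$start, transcripts$end),
                  strand = transcripts$strand,
                  transcript_id = as.character(transcripts$transcript_id))
    if (is.null(exons)) {
        exl <- methods::as(granges(tx), "GRangesList")
        names(exl) <- mcols(tx)$transcript_id
    } else {
        key <- match(exons$transcript_id, transcripts$transcript_id)
        eg <- GRanges(transcripts$scaffold[key],
                      IRanges(exons$start, exons$end),
                      strand = transcripts$strand[key])
        spl <- S4Vectors::split(eg, factor(exons$transcript_id,
                                levels = transcripts$transcript_id))
        exl <- methods::as(spl, "GRangesList")
        exl <- exl[vapply(exl, length, integer(1)) > 0L]
        exl <- GenomicRanges::GRangesList(lapply(exl, GenomicRanges::sort))
    }
    new("FeatureSet", transcripts = tx, exons = exl)
}

#' Build a RepeatSet from a repeat table
#'
#' @param repeats data.frame with columns scaffold, start, end (1-based
#'   inclusive), strand, raw_class; the group column is derived with
#'   \code{\link{repeatClassGroup}} unless supplied.
#' @return a \linkS4class{RepeatSet}.
#' @export
RepeatSet <- function(repeats) {
    grp <- if (!is.null(repeats$group)) repeats$group else
        repeatClassGroup(repeats$raw_class)
    gr <- GRanges(repeats$scaffold, IRanges(repeats$start, repeats$end),
                  strand = repeats$strand,
                  raw_class = as.character(repeats$raw_class),
                  group = factor(grp, levels = .REPEAT_GROUPS))
    new("RepeatSet", ranges = gr)
}

#' Group a RepeatMasker class/family string
#'
#' Prefix rules over the class part (before any "/"): DNA, LTR, LINE, SINE
#' map to the four transposon groups; Satellite and Simple_repeat to the
#' non-transposon groups; anything else (rRNA, snRNA, Low_complexity,
#' Unknown, ...) to OtherRE.
#'
#' @param raw_class character vector of RepeatMasker class/family strings.
#' @return character vector over
#'   \{DNA, LTR, LINE, SINE, Satellite, SimpleRepeat, OtherRE\}.
#' @export
#' @examples
#' repeatClassGroup(c("LINE/L2", "Simple_repeat", "rRNA"))
repeatClassGroup <- function(raw_class) {
    cls <- sub("/.*$", "", as.character(raw_class))
    out <- rep("OtherRE", length(cls))
    out[startsWith(cls, "DNA")] <- "DNA"
    out[startsWith(cls, "LTR")] <- "LTR"
    out[startsWith(cls, "LINE")] <- "LINE"
    out[startsWith(cls, "SINE")] <- "SINE"
    out[startsWith(cls, "Satellite")] <- "Satellite"
    out[startsWith(cls, "Simple_repeat")] <- "SimpleRepeat"
    out
}

#' Winsorized mean
#'
#' Clips values below the \code{lo}-th percentile up to that percentile and
#' above the \code{hi}-th percentile down to it (percentiles by linear
#' interpolation, \code{\link[stats]{quantile}} type 7), then averages.
#' With limits (0, 100) this is exactly the arithmetic mean.
#'
#' @param x numeric values.
#' @param lo,hi winsorization percentiles in [0, 100].
#' @param na.rm drop NAs first.
#' @return list with \code{mean}, \code{sd} (of the clipped values) and
#'   \code{n}.
#' @export
winsorizedMean <- function(x, lo = 1, hi = 99, na.rm = TRUE) {
    if (na.rm) x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
    q <- stats::quantile(x, c(lo, hi) / 100, names = FALSE, type = 7)
    x <- pmin(pmax(x, q[1]), q[2])
    list(mean = mean(x), sd = if (n > 1L) stats::sd(x) else 0, n = n)
}

## bin index (0-based) for positions inside [start, end] (1-based closed),
## strand-aware: distance d from the 5' end, bin = floor(B * d / L), clamped.
.binIndex <- function(pos, start, end, strand, B) {
    n <- length(pos)
    start <- rep_len(start, n); end <- rep_len(end, n)
    L <- end - start + 1
    neg <- rep_len(strand == "-", n)
    d <- ifelse(neg, end - pos, pos - start)
    pmin(as.integer(floor(B * d / L)), B - 1L)
}

## evaluate an expression with a private, restored RNG stream
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

## derive a stage seed from a master seed, kept within 32-bit range
.deriveSeed <- function(seed, offset) {
    (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}

## open a connection transparently handling gzip by magic bytes
.openMaybeGz <- function(path) {
    magic <- readBin(path, "raw", n = 2L)
    if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
        gzfile(path, "rt")
    else
        file(path, "rt")
}

.readLinesAny <- function(path) {
    con <- .openMaybeGz(path)
    on.exit(close(con))
    readLines(con)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
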