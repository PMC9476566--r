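#' @include AllClasses.R utils.R
NULL

#' Per-transcript mean gene-body methylation
#'
#' Averages the methylation percent of all covered CpGs inside each
#' transcript span (TSS to TTS, both strands pooled). Transcripts with fewer
#' than \code{min_cpgs} covered CpGs are excluded and reported.
#'
#' @param cpgs a \linkS4class{CpGTable}.
#' @param features a \linkS4class{FeatureSet}.
#' @param min_cpgs minimum covered CpGs for a transcript to be reported
#'   (default 1).
#' @return data.frame with columns transcript_id, body_mean, n_cpgs_body;
#'   excluded transcript ids are attached as the \code{"excluded"}
#'   attribute.
#' @export
transcriptMeanMethylation <- function(cpgs, features, min_cpgs = 1L) {
    tx <- transcriptRanges(features)
    ids <- transcriptIds(features)
    q <- granges(cpgSites(cpgs))
    strand(q) <- "*"
    hits <- findOverlaps(q, tx, ignore.strand = TRUE)
    mp <- methPct(cpgs)
    n <- tabulate(subjectHits(hits), nbins = length(tx))
    sums <- numeric(length(tx))
    if (length(hits)) {
        agg <- rowsum(mp[queryHits(hits)], subjectHits(hits))
        sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    keep <- n >= min_cpgs & n > 0L
    out <- data.frame(transcript_id = ids[keep],
                      body_mean = sums[keep] / n[keep],
                      n_cpgs_body = n[keep],
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- ids[!keep]
    out
}

## k-means++ seeding in one dimension
.kmeansppCenters <- function(x, k) {
    centers <- numeric(k)
    centers[1] <- x[sample.int(length(x), 1L)]
    d2 <- (x - centers[1])^2
    for (j in seq_len(k - 1L) + 1L) {
        if (all(d2 == 0)) {
            centers[j] <- x[sample.int(length(x), 1L)]
        } else {
            centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
        }
        d2 <- pmin(d2, (x - centers[j])^2)
    }
    centers
}

## exact coordinate descent over cluster boundaries on sorted values:
## in one dimension every k-means fixed point partitions the sorted data
## into contiguous runs, so each boundary can be optimized exactly given
## its neighbours. Returns the refined boundaries (index of each run's
## last element) and the within-cluster sum of squares.
.refineBoundaries <- function(xs, b) {
    k <- length(b)
    cs <- cumsum(xs)
    cs2 <- cumsum(xs^2)
    sse <- function(i, j) {
        s <- cs[j] - if (i > 1) cs[i - 1] else 0
        s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
        s2 - s^2 / (j - i + 1)
    }
    if (k > 1) repeat {
        improved <- FALSE
        for (i in seq_len(k - 1)) {
            lo <- if (i > 1) b[i - 1] + 1L else 1L
            cand <- lo:(b[i + 1] - 1L)
            w <- vapply(cand, function(m)
                sse(lo, m) + sse(m + 1L, b[i + 1]), numeric(1))
            m <- cand[which.min(w)]
            if (m != b[i] &&
                min(w) < sse(lo, b[i]) + sse(b[i] + 1L, b[i + 1]) - 1e-12) {
                b[i] <- m
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    lo <- c(1L, b[-k] + 1L)
    list(b = b, wss = sum(mapply(sse, lo, b)))
}

#' Discover gene-body methylation patterns by 1-D k-means
#'
#' Clusters per-transcript mean gene-body methylation with Lloyd's
#' algorithm (k-means++ seeding, best of \code{restarts} runs by
#' within-cluster sum of squares), followed by an exact one-dimensional
#' boundary refinement: at any k-means fixed point the clusters are
#' contiguous runs of the sorted values, so each cluster boundary is
#' re-optimized exactly given its neighbours until no move improves the
#' objective. Clusters are relabelled 1..k by strictly descending center,
#' so pattern 1 is the most methylated; final labels are nearest-center
#' assignments with ties broken toward the lower label (higher
#' methylation).
#'
#' @param means data.frame from \code{\link{transcriptMeanMethylation}}
#'   (columns transcript_id, body_mean, n_cpgs_body), or a named numeric
#'   vector of body means.
#' @param k number of clusters (default 4).
#' @param seed integer RNG seed.
#' @param restarts number of seeded runs (default 10).
#' @return a \linkS4class{PatternAssignment}.
#' @export
kmeansPatterns <- function(means, k = 4L, seed = 1L, restarts = 10L) {
    if (is.numeric(means)) {
        means <- data.frame(transcript_id = names(means) %||%
                                as.character(seq_along(means)),
                            body_mean = as.numeric(means),
                            n_cpgs_body = NA_integer_,
                            stringsAsFactors = FALSE)
    }
    x <- means$body_mean
    k <- as.integer(k)
    if (length(x) < k)
        .stopf("need at least k = %d transcripts, got %d", k, length(x))
    if (length(unique(x)) < k)
        .stopf("degenerate input: only %d distinct body means for k = %d clusters",
               length(unique(x)), k)
    xs <- sort(x)
    bestWss <- Inf
    bestB <- NULL
    .withSeed(seed, {
        for (r in seq_len(restarts)) {
            init <- .kmeansppCenters(x, k)
            # Lloyd iterations; degenerate runs (collapsed or emptied
            # clusters) are discarded and the restart budget moves on
            fit <- tryCatch(
                suppressWarnings(stats::kmeans(x, centers = init,
                                               iter.max = 300L,
                                               algorithm = "Lloyd")),
                error = function(e) NULL)
            if (is.null(fit)) next
            lab <- apply(abs(outer(xs, sort(fit$centers[, 1]), "-")),
                         1L, which.min)
            sizes <- tabulate(lab, k)
            if (any(sizes == 0L)) next
            ref <- .refineBoundaries(xs, cumsum(sizes))
            if (ref$wss < bestWss - 1e-12) {
                bestWss <- ref$wss
                bestB <- ref$b
            }
        }
    })
    if (is.null(bestB))
        .stopf("k-means failed in all %d restarts", restarts)
    lo <- c(1L, bestB[-k] + 1L)
    segMeans <- vapply(seq_len(k), function(j)
        mean(xs[lo[j]:bestB[j]]), numeric(1))
    centers <- sort(segMeans, decreasing = TRUE)
    if (any(diff(centers) >= 0))
        .stopf("degenerate clustering: centers are not strictly descending")
    # nearest-center labels, ties toward the lower (more methylated) label
    dist <- abs(outer(x, centers, "-"))
    lab <- apply(dist, 1L, which.min)   # which.min takes the first tie
    out <- data.frame(transcript_id = means$transcript_id,
                      body_mean = x,
                      n_cpgs_body = means$n_cpgs_body,
                      mp_label = as.integer(lab),
                      stringsAsFactors = FALSE)
    new("PatternAssignment", assignments = out, centers = centers,
        inertia = bestWss, seed = as.integer(seed),
        restarts = as.integer(restarts),
        excluded = attr(means, "excluded") %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transfer a reference pattern ordering to other samples
#'
#' Each transcript keeps the pattern label it received in the reference
#' sample; the other samples' body means are reported under that fixed
#' grouping without re-clustering. This is how a clustering defined on one
#' sample is compared across tissues.
#'
#' @param reference a \linkS4class{PatternAssignment}.
#' @param other_samples named list of data.frames from
#'   \code{\link{transcriptMeanMethylation}} (one per sample).
#' @return data.frame with columns transcript_id, mp_label, body_mean
#'   (reference) and one \code{mean_<sample>} column per other sample (NA
#'   where the transcript is absent).
#' @export
applyReferenceOrder <- function(reference, other_samples) {
    ref <- as.data.frame(reference)
    out <- ref[, c("transcript_id", "mp_label", "body_mean")]
    if (is.null(names(other_samples)))
        names(other_samples) <- paste0("sample", seq_along(other_samples))
    any_overlap <- FALSE
    for (s in names(other_samples)) {
        tab <- other_samples[[s]]
        idx <- match(out$transcript_id, tab$transcript_id)
        if (any(!is.na(idx))) any_overlap <- TRUE
        out[[paste0("mean_", s)]] <- tab$body_mean[idx]
    }
    if (!any_overlap)
        .stopf("no transcript overlap between the reference and any sample")
    out
}

#' Transcript length distributions per methylation pattern
#'
#' log10 of the TSS-to-TTS span width in bp, grouped by pattern, with
#' per-pattern quartiles. Zero-width features are excluded with a warning.
#'
#' @param assignment a \linkS4class{PatternAssignment}.
#' @param features a \linkS4class{FeatureSet}.
#' @return list with \code{lengths} (data.frame transcript_id, mp_label,
#'   log10_width) and \code{quartiles} (per-pattern 25/50/75 percentiles).
#' @export
patternLengthStats <- function(assignment, features) {
    a <- as.data.frame(assignment)
    tx <- transcriptRanges(features)
    w <- width(tx)[match(a$transcript_id, transcriptIds(features))]
    bad <- is.na(w) | w < 1L
    if (any(w < 1L, na.rm = TRUE))
        .warnf("excluding %d zero-length feature(s)", sum(w < 1L, na.rm = TRUE))
    d <- data.frame(transcript_id = a$transcript_id[!bad],
                    mp_label = a$mp_label[!bad],
                    log10_width = log10(w[!bad]),
                    stringsAsFactors = FALSE)
    qs <- do.call(rbind, lapply(split(d$log10_width, d$mp_label), function(v)
        stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)))
    colnames(qs) <- c("q25", "median", "q75")
    list(lengths = d,
         quartiles = data.frame(mp_label = as.integer(rownames(qs)), qs))
}
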