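#' @include AllClasses.R
NULL

#' Accessors for sparseMethylome containers
#'
#' \code{cpgSites} returns the width-1 \code{GRanges} of a
#' \linkS4class{CpGTable}; \code{methPct}, \code{methReads},
#' \code{totalReads}, \code{sampleId}, \code{cpgCategory} and
#' \code{cpgContext} return the corresponding per-site vectors (the last two
#' are \code{NULL} until \code{\link{classifyCpGs}} /
#' \code{\link{annotateCpGs}} have been applied). \code{transcriptRanges},
#' \code{exonRanges}, \code{transcriptIds}, \code{tssPositions} and
#' \code{ttsPositions} access a \linkS4class{FeatureSet};
#' \code{repeatRanges} and \code{repeatGroup} a \linkS4class{RepeatSet};
#' \code{profileStats} a \linkS4class{BinnedProfile};
#' \code{patternLabels} and \code{patternCenters} a
#' \linkS4class{PatternAssignment}.
#'
#' @param x the object.
#' @return the accessed component.
#' @name accessors
#' @aliases cpgSites methPct methReads totalReads sampleId cpgCategory
#'   cpgContext transcriptRanges exonRanges transcriptIds tssPositions
#'   ttsPositions repeatRanges repeatGroup profileStats patternLabels
#'   patternCenters
NULL

#' @rdname accessors
#' @export
setGeneric("cpgSites", function(x) standardGeneric("cpgSites"))
#' @rdname accessors
#' @export
setGeneric("methPct", function(x) standardGeneric("methPct"))
#' @rdname accessors
#' @export
setGeneric("methReads", function(x) standardGeneric("methReads"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("cpgCategory", function(x) standardGeneric("cpgCategory"))
#' @rdname accessors
#' @export
setGeneric("cpgContext", function(x) standardGeneric("cpgContext"))
#' @rdname accessors
#' @export
setGeneric("transcriptRanges", function(x) standardGeneric("transcriptRanges"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))
#' @rdname accessors
#' @export
setGeneric("ttsPositions", function(x) standardGeneric("ttsPositions"))
#' @rdname accessors
#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @rdname accessors
#' @export
setGeneric("repeatGroup", function(x) standardGeneric("repeatGroup"))
#' @rdname accessors
#' @export
setGeneric("profileStats", function(x) standardGeneric("profileStats"))
#' @rdname accessors
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))
#' @rdname accessors
#' @export
setGeneric("patternCenters", function(x) standardGeneric("patternCenters"))

## ---- CpGTable methods -----------------------------------------------------

#' @rdname accessors
setMethod("cpgSites", "CpGTable", function(x) x@sites)
#' @rdname accessors
setMethod("methPct", "CpGTable", function(x) mcols(x@sites)$meth_pct)
#' @rdname accessors
setMethod("methReads", "CpGTable", function(x) mcols(x@sites)$n_meth)
#' @rdname accessors
setMethod("totalReads", "CpGTable", function(x) mcols(x@sites)$n_total)
#' @rdname accessors
setMethod("sampleId", "CpGTable", function(x) x@sample)
#' @rdname accessors
setMethod("cpgCategory", "CpGTable", function(x) mcols(x@sites)$category)
#' @rdname accessors
setMethod("cpgContext", "CpGTable", function(x) mcols(x@sites)$context)

#' @export
setMethod("length", "CpGTable", function(x) length(x@sites))

#' @export
setMethod("show", "CpGTable", function(object) {
    cat(sprintf("CpGTable '%s': %d strand-specific CpG sites\n",
                object@sample, length(object)))
    if (length(object)) {
        m <- methPct(object)
        cat(sprintf("  meth_pct: min %.1f / median %.1f / max %.1f\n",
                    min(m), stats::median(m), max(m)))
        if (!is.null(cpgCategory(object)))
            cat("  categories:",
                paste(sprintf("%s=%d", names(table(cpgCategory(object))),
                              table(cpgCategory(object))), collapse = " "), "\n")
        if (!is.null(cpgContext(object)))
            cat("  contexts:",
                paste(sprintf("%s=%d", names(table(cpgContext(object))),
                              table(cpgContext(object))), collapse = " "), "\n")
    }
    invisible(NULL)
})

#' Coerce a CpGTable to a data.frame
#'
#' One row per strand-specific CpG with columns scaffold, pos (1-based
#' position of the cytosine), strand, meth_pct, n_meth, n_total, sample and
#' any classification/annotation columns present.
#'
#' @param x a \linkS4class{CpGTable}.
#' @param ... ignored.
#' @return a data.frame.
#' @export
setMethod("as.data.frame", "CpGTable", function(x, ...) {
    gr <- x@sites
    df <- data.frame(scaffold = as.character(seqnames(gr)),
                     pos = start(gr),
                     strand = as.character(strand(gr)),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(mcols(gr)))
    df$sample <- x@sample
    df
})

## ---- FeatureSet methods ---------------------------------------------------

#' @rdname accessors
setMethod("transcriptRanges", "FeatureSet", function(x) x@transcripts)
#' @rdname accessors
setMethod("exonRanges", "FeatureSet", function(x) x@exons)
#' @rdname accessors
setMethod("transcriptIds", "FeatureSet",
          function(x) mcols(x@transcripts)$transcript_id)

#' @rdname accessors
setMethod("tssPositions", "FeatureSet", function(x) {
    tx <- x@transcripts
    ifelse(as.character(strand(tx)) == "-", end(tx), start(tx))
})

#' @rdname accessors
setMethod("ttsPositions", "FeatureSet", function(x) {
    tx <- x@transcripts
    ifelse(as.character(strand(tx)) == "-", start(tx), end(tx))
})

#' @export
setMethod("length", "FeatureSet", function(x) length(x@transcripts))

#' @export
setMethod("show", "FeatureSet", function(object) {
    cat(sprintf("FeatureSet: %d transcripts on %d scaffold(s)\n",
                length(object),
                length(unique(as.character(seqnames(object@transcripts))))))
    if (length(object))
        cat(sprintf("  span width: min %d / median %.0f / max %d bp\n",
                    min(width(object@transcripts)),
                    stats::median(width(object@transcripts)),
                    max(width(object@transcripts))))
    invisible(NULL)
})

## ---- RepeatSet methods ----------------------------------------------------

#' @rdname accessors
setMethod("repeatRanges", "RepeatSet", function(x) x@ranges)
#' @rdname accessors
setMethod("repeatGroup", "RepeatSet",
          function(x) as.character(mcols(x@ranges)$group))

#' @export
setMethod("length", "RepeatSet", function(x) length(x@ranges))

#' @export
setMethod("show", "RepeatSet", function(object) {
    cat(sprintf("RepeatSet: %d repeats\n", length(object)))
    if (length(object)) {
        tb <- table(factor(repeatGroup(object), levels = .REPEAT_GROUPS))
        cat(" ", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
    }
    invisible(NULL)
})

## ---- BinnedProfile methods ------------------------------------------------

#' @rdname accessors
setMethod("profileStats", "BinnedProfile", function(x) x@stats)

#' @export
setMethod("length", "BinnedProfile", function(x) x@nbins)

#' @export
setMethod("show", "BinnedProfile", function(object) {
    cat(sprintf("BinnedProfile (%s): %d bins, winsor (%g, %g) percentiles\n",
                object@regionType, object@nbins,
                object@winsor[1], object@winsor[2]))
    mn <- object@stats$mean
    if (any(!is.na(mn)))
        cat(sprintf("  bin means: min %.2f / max %.2f; total values %d\n",
                    min(mn, na.rm = TRUE), max(mn, na.rm = TRUE),
                    sum(object@stats$n)))
    invisible(NULL)
})

## ---- PatternAssignment methods --------------------------------------------

#' @rdname accessors
setMethod("patternLabels", "PatternAssignment", function(x) {
    stats::setNames(x@assignments$mp_label, x@assignments$transcript_id)
})
#' @rdname accessors
setMethod("patternCenters", "PatternAssignment", function(x) x@centers)

#' @export
setMethod("length", "PatternAssignment", function(x) nrow(x@assignments))

#' @export
setMethod("show", "PatternAssignment", function(object) {
    k <- length(object@centers)
    cat(sprintf("PatternAssignment: %d transcripts in %d patterns\n",
                length(object), k))
    tb <- table(factor(object@assignments$mp_label, levels = seq_len(k)))
    for (j in seq_len(k))
        cat(sprintf("  MP%d: center %.2f%%, %d transcripts\n",
                    j, object@centers[j], tb[j]))
    cat(sprintf("  inertia %.2f (seed %d, %d restarts); %d excluded\n",
                object@inertia, object@seed, object@restarts,
                length(object@excluded)))
    invisible(NULL)
})

#' Coerce a PatternAssignment to a data.frame
#' @param x a \linkS4class{PatternAssignment}.
#' @param ... ignored.
#' @return the assignment table (transcript_id, body_mean, n_cpgs_body,
#'   mp_label).
#' @export
setMethod("as.data.frame", "PatternAssignment",
          function(x, ...) x@assignments)
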