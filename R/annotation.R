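#' @include AllClasses.R utils.R
NULL

#' Annotate CpGs with genomic context
#'
#' Assigns each CpG exactly one context with precedence
#' promoter > exon > intron > intergenic, using the union of all transcripts
#' (a CpG in any transcript's exon is exonic). The promoter is
#' \code{promoter_len} bp immediately upstream of the TSS on the feature's
#' strand; an intron is any position inside a transcript span but in none of
#' its exons. CpG strand is ignored when overlapping features: methylation
#' is treated as symmetric across the dyad. CpGs on scaffolds without
#' features are intergenic.
#'
#' @param cpgs a \linkS4class{CpGTable}.
#' @param features a \linkS4class{FeatureSet}.
#' @param promoter_len promoter width in bp upstream of the TSS
#'   (default 2000).
#' @return the table with a \code{context} factor column added.
#' @export
annotateCpGs <- function(cpgs, features, promoter_len = 2000L) {
    gr <- cpgSites(cpgs)
    q <- granges(gr)
    strand(q) <- "*"
    tx <- transcriptRanges(features)
    prom <- GenomicRanges::promoters(tx, upstream = promoter_len,
                                     downstream = 0L)
    prom <- GenomicRanges::trim(prom)
    ex <- unlist(exonRanges(features), use.names = FALSE)
    ctx <- rep("intergenic", length(q))
    inTx <- .overlapsAny(q, tx, ignore.strand = TRUE)
    ctx[inTx] <- "intron"
    if (length(ex))
        ctx[.overlapsAny(q, ex, ignore.strand = TRUE)] <- "exon"
    if (length(prom))
        ctx[.overlapsAny(q, prom, ignore.strand = TRUE)] <- "promoter"
    mcols(gr)$context <- factor(ctx, levels = .CONTEXTS)
    .replaceSites(cpgs, gr)
}

.overlapsAny <- function(query, subject, ignore.strand = TRUE) {
    # disjoint scaffold namespaces are legitimate (-> no overlap), so the
    # seqlevel-merge warning is noise here
    withCallingHandlers(
        IRanges::overlapsAny(query, subject, ignore.strand = ignore.strand),
        warning = function(w) {
            if (grepl("sequence levels in common", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

#' Partition intergenic CpGs by repeat content
#'
#' Splits the intergenic compartment into transposable-element CpGs
#' (overlapping a DNA/LTR/LINE/SINE repeat), non-TE-repeat CpGs (overlapping
#' only Satellite/SimpleRepeat/OtherRE records) and repeat-free CpGs. A CpG
#' overlapping both a TE and a non-TE repeat counts as TE. All CpGs —
#' genic included — additionally receive a \code{repeat_group} column naming
#' the repeat group they overlap (TE groups take precedence); genic contexts
#' are never relabelled.
#'
#' @param annotated a \linkS4class{CpGTable} already annotated with
#'   \code{\link{annotateCpGs}}.
#' @param repeats a \linkS4class{RepeatSet}.
#' @return the table with \code{repeat_group} and \code{intergenic_class}
#'   columns added (\code{intergenic_class} is NA outside intergenic
#'   context).
#' @export
partitionIntergenic <- function(annotated, repeats) {
    ctx <- cpgContext(annotated)
    if (is.null(ctx))
        .stopf("table is not annotated; run annotateCpGs() first")
    gr <- cpgSites(annotated)
    q <- granges(gr)
    strand(q) <- "*"
    rr <- repeatRanges(repeats)
    grp <- as.character(mcols(rr)$group)
    # assign each CpG the highest-priority overlapping repeat group
    rgroup <- rep(NA_character_, length(q))
    for (g in rev(.REPEAT_GROUPS)) {   # reverse so TE groups overwrite last
        sel <- rr[grp == g]
        if (length(sel))
            rgroup[.overlapsAny(q, sel, ignore.strand = TRUE)] <- g
    }
    icls <- rep(NA_character_, length(q))
    inter <- as.character(ctx) == "intergenic"
    icls[inter] <- "repeat_free"
    icls[inter & rgroup %in% .REPEAT_GROUPS] <- "nonTE_repeat"
    icls[inter & rgroup %in% .TE_GROUPS] <- "TE"
    mcols(gr)$repeat_group <- factor(rgroup, levels = .REPEAT_GROUPS)
    mcols(gr)$intergenic_class <-
        factor(icls, levels = c("TE", "nonTE_repeat", "repeat_free"))
    .replaceSites(annotated, gr)
}

#' Context composition of an annotated table
#'
#' Per-context proportions for all CpGs and, when the table is classified,
#' for each methylation category; proportions sum to 1 within each subset.
#'
#' @param annotated an annotated \linkS4class{CpGTable}.
#' @param subset optional category name ("methylated", "intermediate",
#'   "unmethylated") to restrict to one subset.
#' @return data.frame with columns subset, context, n, proportion.
#' @export
contextComposition <- function(annotated, subset = NULL) {
    ctx <- cpgContext(annotated)
    if (is.null(ctx))
        .stopf("table is not annotated; run annotateCpGs() first")
    cat <- cpgCategory(annotated)
    one <- function(name, keep) {
        if (!sum(keep))
            return(NULL)
        tb <- table(ctx[keep])
        data.frame(subset = name, context = names(tb), n = as.integer(tb),
                   proportion = as.numeric(tb) / sum(tb),
                   stringsAsFactors = FALSE)
    }
    if (!is.null(subset)) {
        if (is.null(cat))
            .stopf("category subset requested but table is not classified")
        out <- one(subset, as.character(cat) == subset)
        return(if (is.null(out))
            data.frame(subset = character(), context = character(),
                       n = integer(), proportion = numeric())
            else out)
    }
    parts <- list(one("all", rep(TRUE, length(annotated))))
    if (!is.null(cat))
        for (s in .CATEGORIES)
            parts <- c(parts, list(one(s, as.character(cat) == s)))
    do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
}
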