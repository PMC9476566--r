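#' @include AllClasses.R utils.R
NULL

#' Transcripts expressed above a TPM threshold
#'
#' @param tpm TPM matrix (transcripts x samples).
#' @param threshold TPM cutoff; a transcript is expressed when its TPM
#'   strictly exceeds the threshold in at least one sample (default 0).
#' @return character vector of transcript ids.
#' @export
expressedSet <- function(tpm, threshold = 0) {
    rownames(tpm)[apply(tpm > threshold, 1L, any)]
}

#' log2(TPM + 1) transform
#'
#' @param tpm TPM matrix or vector.
#' @return same shape, log2(TPM + 1); zero iff TPM is zero.
#' @export
logTpm <- function(tpm) log2(tpm + 1)

#' Methylation as a function of expression percentile
#'
#' Transcripts are ranked by expression (average ranks for ties), split into
#' \code{n_groups} equal-frequency groups (sizes differing by at most one,
#' ties resolved deterministically by transcript id), and each group is
#' summarized by its mean body methylation. The resulting curve shows
#' whether methylation tracks expression.
#'
#' @param expr named numeric vector, one expression value per transcript
#'   (conventionally log2(TPM+1)).
#' @param body_means data.frame from
#'   \code{\link{transcriptMeanMethylation}} or a named numeric vector of
#'   body means.
#' @param n_groups number of percentile groups (default 100).
#' @return data.frame with columns percentile (1 = lowest expression),
#'   n, mean_expr, mean_meth.
#' @export
percentileMethylationCurve <- function(expr, body_means, n_groups = 100L) {
    if (is.data.frame(body_means))
        body_means <- stats::setNames(body_means$body_mean,
                                      body_means$transcript_id)
    ids <- intersect(names(expr), names(body_means))
    if (length(ids) < n_groups)
        .stopf("only %d transcripts with both expression and methylation; use n_groups <= %d",
               length(ids), length(ids))
    e <- expr[ids]
    m <- body_means[ids]
    ord <- order(e, ids, method = "radix")
    n <- length(ids)
    sizes <- rep(n %/% n_groups, n_groups)
    extra <- n %% n_groups
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    grp <- rep(seq_len(n_groups), times = sizes)
    data.frame(percentile = seq_len(n_groups),
               n = sizes,
               mean_expr = as.numeric(tapply(e[ord], grp, mean)),
               mean_meth = as.numeric(tapply(m[ord], grp, mean)))
}

#' Expression across methylation patterns: Kruskal-Wallis with Dunn post-hoc
#'
#' Tests whether expression differs between methylation patterns with the
#' unpaired non-parametric Kruskal-Wallis test, followed by Dunn's pairwise
#' z tests on the shared ranking (tie-corrected), adjusted over all pairs
#' (Bonferroni by default). Patterns with fewer than 2 members are excluded
#' from the pairwise tests with a warning.
#'
#' @param expr named numeric vector of expression values
#'   (e.g. log2(TPM+1)).
#' @param assignment a \linkS4class{PatternAssignment}, or a named vector /
#'   factor of group labels.
#' @param p_adjust_method adjustment for the Dunn pairwise p-values
#'   (default "bonferroni").
#' @return list with \code{kw} (statistic, df, p.value), \code{dunn}
#'   (data.frame group1, group2, z, p, padj) and \code{group_stats}
#'   (per-group n, median, q25, q75).
#' @export
mpExpressionTest <- function(expr, assignment,
                             p_adjust_method = "bonferroni") {
    if (methods::is(assignment, "PatternAssignment"))
        labels <- patternLabels(assignment)
    else labels <- assignment
    ids <- intersect(names(expr), names(labels))
    x <- expr[ids]
    g <- factor(labels[ids])
    if (nlevels(droplevels(g)) < 2L)
        .stopf("need at least two non-empty patterns")
    g <- droplevels(g)
    kw <- stats::kruskal.test(x, g)
    gs <- do.call(rbind, lapply(levels(g), function(l) {
        v <- x[g == l]
        data.frame(group = l, n = length(v),
                   median = stats::median(v),
                   q25 = stats::quantile(v, 0.25, names = FALSE),
                   q75 = stats::quantile(v, 0.75, names = FALSE))
    }))
    small <- gs$group[gs$n < 2L]
    if (length(small))
        .warnf("pattern(s) %s have < 2 members; excluded from pairwise tests",
               paste(small, collapse = ", "))
    use <- setdiff(levels(g), small)
    dunn <- NULL
    if (length(use) >= 2L) {
        keep <- g %in% use
        xv <- x[keep]; gv <- droplevels(g[keep])
        N <- length(xv)
        r <- rank(xv)
        ties <- table(r)
        tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
        rbar <- tapply(r, gv, mean)
        nn <- table(gv)
        pairs <- utils::combn(levels(gv), 2L)
        z <- apply(pairs, 2L, function(p) {
            se <- sqrt((N * (N + 1) / 12 - tiecorr) *
                       (1 / nn[[p[1]]] + 1 / nn[[p[2]]]))
            (rbar[[p[1]]] - rbar[[p[2]]]) / se
        })
        praw <- 2 * stats::pnorm(-abs(z))
        dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           z = as.numeric(z), p = praw,
                           padj = pmin(stats::p.adjust(praw,
                                                       p_adjust_method), 1),
                           stringsAsFactors = FALSE)
    }
    list(kw = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p.value = kw$p.value),
         dunn = dunn, group_stats = gs)
}

#' Row z-score hierarchical clustering of a TPM matrix
#'
#' Each row is standardized over samples ((x - mean) / sd), rows with zero
#' variance are excluded and reported, and the standardized rows are
#' clustered agglomeratively on Euclidean distance (complete linkage by
#' default, the common heatmap default) with the tree cut into \code{k}
#' clusters.
#'
#' @param tpm TPM matrix (transcripts x samples); conventionally already
#'   log-transformed.
#' @param k number of clusters (default 13).
#' @param linkage hclust agglomeration method (default "complete").
#' @return list with \code{labels} (named cluster vector), \code{zscores}
#'   (standardized matrix in dendrogram order), \code{hclust} (the tree)
#'   and \code{excluded} (zero-variance transcript ids).
#' @export
zscoreCluster <- function(tpm, k = 13L, linkage = "complete") {
    mu <- rowMeans(tpm)
    sd <- apply(tpm, 1L, stats::sd)
    usable <- sd > 0 & !is.na(sd)
    if (sum(usable) < k)
        .stopf("k = %d exceeds the %d rows with nonzero variance",
               k, sum(usable))
    z <- (tpm[usable, , drop = FALSE] - mu[usable]) / sd[usable]
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = linkage)
    labels <- stats::cutree(hc, k = k)
    list(labels = labels, zscores = z[hc$order, , drop = FALSE],
         hclust = hc, excluded = rownames(tpm)[!usable])
}

#' Union of top-expressed transcripts across samples
#'
#' Takes the \code{n} highest-TPM transcripts in each selected sample (ties
#' broken by transcript id for determinism) and returns the unified set with
#' per-sample membership, the Venn-style membership counts, and the
#' intersection.
#'
#' @param tpm TPM matrix.
#' @param samples column names to use (default all).
#' @param n top-set size per sample (default 1000).
#' @return list with \code{union} (character vector), \code{membership}
#'   (logical matrix union x samples), \code{counts} (table of membership
#'   signatures) and \code{intersection}.
#' @export
topnOverlap <- function(tpm, samples = colnames(tpm), n = 1000L) {
    if (nrow(tpm) < n)
        .stopf("samples have %d transcripts, fewer than n = %d", nrow(tpm), n)
    tops <- lapply(samples, function(s) {
        ord <- order(-tpm[, s], rownames(tpm), method = "radix")
        rownames(tpm)[ord[seq_len(n)]]
    })
    names(tops) <- samples
    uni <- sort(unique(unlist(tops)))
    membership <- vapply(tops, function(t) uni %in% t,
                         logical(length(uni)))
    rownames(membership) <- uni
    sig <- apply(membership, 1L, function(r)
        paste(samples[r], collapse = "&"))
    list(union = uni, membership = membership,
         counts = table(sig),
         intersection = uni[rowSums(membership) == length(samples)])
}

#' Hypergeometric GO over-representation test
#'
#' For each term, tests whether the gene list contains more term members
#' than expected from the universe, with the upper-tail hypergeometric
#' probability, Benjamini-Hochberg adjustment across tested terms, and the
#' gene ratio observed/expected where expected = n_list * K / N.
#'
#' @param gene_list character vector, must be a subset of \code{universe}.
#' @param universe character vector of background genes.
#' @param term_map named list: term id -> character vector of gene ids
#'   (genes outside the universe are ignored).
#' @param alpha FDR threshold for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame with columns term_id, k_obs, n_list, K_universe,
#'   N_universe, p, padj, gene_ratio, significant; sorted by p.
#' @export
goEnrichment <- function(gene_list, universe, term_map, alpha = 0.05) {
    extra <- setdiff(gene_list, universe)
    if (length(extra))
        .stopf("gene_list not contained in universe; offenders: %s",
               paste(utils::head(extra, 5), collapse = ", "))
    gene_list <- unique(gene_list)
    universe <- unique(universe)
    N <- length(universe)
    n <- length(gene_list)
    rows <- lapply(names(term_map), function(t) {
        members <- intersect(term_map[[t]], universe)
        K <- length(members)
        if (!K) return(NULL)
        k <- length(intersect(members, gene_list))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        expected <- n * K / N
        data.frame(term_id = t, k_obs = k, n_list = n, K_universe = K,
                   N_universe = N, p = p,
                   gene_ratio = if (expected > 0) k / expected else NA_real_,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(term_id = character(), k_obs = integer(),
                          n_list = integer(), K_universe = integer(),
                          N_universe = integer(), p = numeric(),
                          padj = numeric(), gene_ratio = numeric(),
                          significant = logical()))
    out <- do.call(rbind, rows)
    out$padj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$padj < alpha
    out <- out[order(out$p, out$term_id), ]
    rownames(out) <- NULL
    out[, c("term_id", "k_obs", "n_list", "K_universe", "N_universe",
            "p", "padj", "gene_ratio", "significant")]
}
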