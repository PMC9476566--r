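#' @include AllClasses.R utils.R
NULL

#' Count CpG dinucleotides in a genome, both strands
#'
#' Counts CG dinucleotide occurrences across all sequences and doubles the
#' number, since each CG site carries a cytosine on both strands. Ambiguous
#' bases never match.
#'
#' @param genome FASTA path or \link[Biostrings]{DNAStringSet}.
#' @return integer count of strand-specific CpG cytosines.
#' @export
#' @examples
#' countGenomeCpGs(Biostrings::DNAStringSet(c(s1 = "ACGT")))  # 2
countGenomeCpGs <- function(genome) {
    seqs <- .asGenome(genome)
    if (!length(seqs) || sum(Biostrings::width(seqs)) == 0L) {
        .warnf("empty genome: 0 CpGs")
        return(0L)
    }
    2L * sum(Biostrings::vcountPattern("CG", seqs, fixed = TRUE))
}

#' Classify CpGs by methylation level
#'
#' Sites with methylation strictly below \code{lo} percent are unmethylated,
#' strictly above \code{hi} percent methylated, and everything else —
#' including values exactly at the thresholds — intermediate. The defaults
#' (20, 80) are the conventional cutoffs for sparsely methylated
#' invertebrate genomes.
#'
#' @param x a \linkS4class{CpGTable}.
#' @param lo,hi thresholds in percent, 0 <= lo < hi <= 100.
#' @return the table with a \code{category} factor column added.
#' @export
classifyCpGs <- function(x, lo = 20, hi = 80) {
    if (!(lo >= 0 && lo < hi && hi <= 100))
        .stopf("classification thresholds must satisfy 0 <= lo < hi <= 100")
    m <- methPct(x)
    cat <- rep("intermediate", length(m))
    cat[m < lo] <- "unmethylated"
    cat[m > hi] <- "methylated"
    gr <- cpgSites(x)
    mcols(gr)$category <- factor(cat, levels = .CATEGORIES)
    .replaceSites(x, gr)
}

#' Summarize a classified methylome
#'
#' Counts and percentages per category, plus the fraction of the genome's
#' CpGs covered when the total genome CpG count (both strands) is supplied.
#'
#' @param x a classified \linkS4class{CpGTable}.
#' @param genome_cpg_count optional total strand-specific CpG count of the
#'   genome; must be at least the table size.
#' @return a list of class \code{MethylomeSummary} with fields
#'   \code{sample}, \code{n_covered}, \code{n_methylated},
#'   \code{n_intermediate}, \code{n_unmethylated}, \code{pct_methylated},
#'   \code{pct_intermediate}, \code{pct_unmethylated},
#'   \code{pct_genome_covered}.
#' @export
summarizeMethylome <- function(x, genome_cpg_count = NA) {
    cat <- cpgCategory(x)
    if (is.null(cat))
        .stopf("table is not classified; run classifyCpGs() first")
    n <- length(x)
    if (!is.na(genome_cpg_count) && genome_cpg_count < n)
        .stopf("genome_cpg_count (%d) smaller than table size (%d)",
               genome_cpg_count, n)
    tb <- table(cat)
    pct <- function(k) if (n > 0) 100 * k / n else NA_real_
    out <- list(sample = sampleId(x),
                n_covered = n,
                n_methylated = as.integer(tb[["methylated"]]),
                n_intermediate = as.integer(tb[["intermediate"]]),
                n_unmethylated = as.integer(tb[["unmethylated"]]),
                pct_methylated = pct(tb[["methylated"]]),
                pct_intermediate = pct(tb[["intermediate"]]),
                pct_unmethylated = pct(tb[["unmethylated"]]),
                pct_genome_covered =
                    if (is.na(genome_cpg_count)) NA_real_
                    else 100 * n / genome_cpg_count)
    class(out) <- "MethylomeSummary"
    out
}

#' @export
print.MethylomeSummary <- function(x, ...) {
    cat(sprintf("Methylome summary for '%s'\n", x$sample))
    cat(sprintf("  covered CpGs: %d (%.2f%% of genome CpGs)\n",
                x$n_covered, x$pct_genome_covered))
    cat(sprintf("  methylated (>hi): %d (%.2f%%)\n",
                x$n_methylated, x$pct_methylated))
    cat(sprintf("  intermediate:     %d (%.2f%%)\n",
                x$n_intermediate, x$pct_intermediate))
    cat(sprintf("  unmethylated (<lo): %d (%.2f%%)\n",
                x$n_unmethylated, x$pct_unmethylated))
    invisible(x)
}

#' Join CpG tables on common sites
#'
#' Intersects two or more tables on (scaffold, pos, strand) and reports the
#' per-sample methylation percent of every commonly detected site, in
#' deterministic (scaffold, pos, strand) order.
#'
#' @param tables list of \linkS4class{CpGTable}s (>= 2).
#' @return data.frame with columns scaffold, pos, strand and one meth_pct
#'   column per sample.
#' @export
joinCommonCpGs <- function(tables) {
    if (length(tables) < 2L)
        .stopf("need at least two tables to join")
    keys <- lapply(tables, function(t) {
        gr <- cpgSites(t)
        paste(as.character(seqnames(gr)), start(gr),
              as.character(strand(gr)), sep = "\r")
    })
    common <- Reduce(intersect, keys)
    samples <- vapply(tables, sampleId, character(1))
    if (anyDuplicated(samples))
        samples <- make.unique(samples)
    if (!length(common)) {
        out <- data.frame(scaffold = character(), pos = integer(),
                          strand = character())
        for (s in samples) out[[s]] <- numeric()
        return(out)
    }
    parts <- strsplit(common, "\r", fixed = TRUE)
    out <- data.frame(scaffold = vapply(parts, `[`, character(1), 1),
                      pos = as.integer(vapply(parts, `[`, character(1), 2)),
                      strand = vapply(parts, `[`, character(1), 3),
                      stringsAsFactors = FALSE)
    for (i in seq_along(tables))
        out[[samples[i]]] <- methPct(tables[[i]])[match(common, keys[[i]])]
    ord <- order(out$scaffold, out$pos, out$strand, method = "radix")
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Down-sample a CpG table
#'
#' Uniform sampling of sites without replacement, reproducible for a fixed
#' seed. Used to compare repeat classes at matched CpG numbers (e.g.
#' down-sampling every class to the satellite count).
#'
#' @param x a \linkS4class{CpGTable}.
#' @param n number of sites to keep (<= table size).
#' @param seed integer RNG seed.
#' @return a \linkS4class{CpGTable} with \code{n} sites, in original order.
#' @export
downsampleCpGs <- function(x, n, seed) {
    if (n > length(x))
        .stopf("cannot down-sample %d sites from a table of %d", n, length(x))
    idx <- .withSeed(seed, sample.int(length(x), n))
    .replaceSites(x, cpgSites(x)[sort(idx)])
}

#' Merge the two strands of each CpG dyad
#'
#' Optional destranding: plus- and minus-strand calls of the same CpG
#' (positions p and p+1) are merged by summing read counts; the merged site
#' is reported on "+" at the plus-strand cytosine position. Off by default
#' throughout the package, which treats the two strands as distinct sites.
#'
#' @param x a \linkS4class{CpGTable}.
#' @return a destranded \linkS4class{CpGTable}.
#' @export
destrandCpGs <- function(x) {
    gr <- cpgSites(x)
    st <- as.character(strand(gr))
    anchor <- ifelse(st == "-", start(gr) - 1L, start(gr))
    key <- paste(as.character(seqnames(gr)), anchor, sep = "\r")
    nm <- rowsum(as.numeric(methReads(x)), key)
    nt <- rowsum(as.numeric(totalReads(x)), key)
    first <- !duplicated(key)
    ord <- match(rownames(nm), key[first])
    scaff <- as.character(seqnames(gr))[first][ord]
    CpGTable(scaffold = scaff, pos = anchor[first][ord], strand = "+",
             meth_pct = 100 * nm[, 1] / pmax(nt[, 1], 1),
             n_meth = nm[, 1], n_total = nt[, 1], sample = sampleId(x))
}
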