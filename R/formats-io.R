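#' @include AllClasses.R utils.R
NULL

#' Read a CGmap per-cytosine methylation file
#'
#' CGmap rows have 8 tab-separated columns: chrom, nucleotide on the Watson
#' strand (C or G), 1-based position, context (CG/CHG/CHH), dinucleotide,
#' methylation level in [0, 1], methylated reads, total reads. Only CpG
#' context rows are retained; strand is derived from the nucleotide column
#' (C is the plus strand, G the minus strand) and the level is rescaled to
#' percent. Gzip input is detected automatically.
#'
#' @param path file path.
#' @param min_total minimum total read count; sites with fewer reads are
#'   dropped. Default 1 (no depth filter); a >= 10x filter is conventional
#'   for reduced-representation data.
#' @param sample sample tag stored on the result (defaults to the file name).
#' @return a \linkS4class{CpGTable}.
#' @export
readCGmap <- function(path, min_total = 1L, sample = basename(path)) {
    lines <- .readLinesAny(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(CpGTable(character(), integer(), character(), numeric(),
                        integer(), integer(), sample = sample))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 8L))
        .stopf("CGmap parse error at line %d: expected >= 8 tab-separated fields, got %d",
               which(nf < 8L)[1], nf[which(nf < 8L)[1]])
    m <- matrix(unlist(lapply(parts, `[`, 1:8)), ncol = 8L, byrow = TRUE)
    level <- as.numeric(m[, 6])
    if (anyNA(level) || any(level < 0 | level > 1))
        .stopf("CGmap validation error at line %d: methylation level outside [0, 1]",
               which(is.na(level) | level < 0 | level > 1)[1])
    keep <- m[, 4] == "CG"
    m <- m[keep, , drop = FALSE]
    level <- level[keep]
    n_meth <- as.integer(m[, 7])
    n_total <- as.integer(m[, 8])
    deep <- n_total >= min_total
    CpGTable(scaffold = m[deep, 1],
             pos = as.integer(m[deep, 3]),
             strand = ifelse(m[deep, 2] == "C", "+", "-"),
             meth_pct = 100 * level[deep],
             n_meth = n_meth[deep],
             n_total = n_total[deep],
             sample = sample)
}

#' Write a CpGTable as a CGmap file
#'
#' Inverse of \code{\link{readCGmap}}: the nucleotide column is C on plus
#' and G on minus strand, the dinucleotide column is "CG", the level column
#' is meth_pct / 100 at full precision. Round-trips exactly.
#'
#' @param x a \linkS4class{CpGTable}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
writeCGmap <- function(x, path) {
    gr <- cpgSites(x)
    lines <- sprintf("%s\t%s\t%d\tCG\tCG\t%s\t%d\t%d",
                     as.character(seqnames(gr)),
                     ifelse(as.character(strand(gr)) == "-", "G", "C"),
                     start(gr),
                     format(methPct(x) / 100, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     methReads(x), totalReads(x))
    writeLines(lines, path)
    invisible(path)
}

#' Read a Bismark coverage file
#'
#' Rows are (chrom, 1-based start, 1-based end, methylation percent,
#' methylated count, unmethylated count) with start == end for CpG calls.
#' Coverage rows carry no strand: if \code{genome} (a FASTA path or a
#' \link[Biostrings]{DNAStringSet}) is supplied, strand is resolved by base
#' lookup (C at the position means plus strand, G minus); otherwise every
#' site is recorded on "+" and the table is flagged unresolved via the
#' \code{strand_resolved} attribute column.
#'
#' @param path file path (gzip detected automatically).
#' @param min_total minimum total read count (methylated + unmethylated);
#'   default 10, the conventional depth filter for reduced-representation
#'   bisulfite data.
#' @param genome optional genome for strand resolution.
#' @param sample sample tag.
#' @return a \linkS4class{CpGTable} with a logical \code{strand_resolved}
#'   metadata column.
#' @export
readBismarkCoverage <- function(path, min_total = 10L, genome = NULL,
                                sample = basename(path)) {
    lines <- .readLinesAny(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(CpGTable(character(), integer(), character(), numeric(),
                        integer(), integer(), sample = sample,
                        strand_resolved = logical()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 6L))
        .stopf("coverage parse error at line %d: expected 6 tab-separated fields, got %d",
               which(nf != 6L)[1], nf[which(nf != 6L)[1]])
    m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
    s <- as.integer(m[, 2]); e <- as.integer(m[, 3])
    if (any(s != e))
        .stopf("coverage dialect error at line %d: start != end (per-CpG rows expected)",
               which(s != e)[1])
    n_meth <- as.integer(m[, 5])
    n_un <- as.integer(m[, 6])
    n_total <- n_meth + n_un
    pct <- as.numeric(m[, 4])
    ok <- n_total > 0
    if (any(abs(pct[ok] - 100 * n_meth[ok] / n_total[ok]) > 0.011))
        .warnf("coverage file percent column disagrees with counts beyond rounding at line %d",
               which(ok)[which(abs(pct[ok] - 100 * n_meth[ok] / n_total[ok]) > 0.011)[1]])
    keep <- n_total >= min_total
    scaff <- m[keep, 1]; pos <- s[keep]
    strand <- rep("+", sum(keep))
    resolved <- rep(FALSE, sum(keep))
    if (!is.null(genome) && sum(keep)) {
        seqs <- .asGenome(genome)
        for (sc in unique(scaff)) {
            i <- which(scaff == sc)
            if (!sc %in% names(seqs))
                .stopf("scaffold '%s' absent from the supplied genome", sc)
            base <- as.character(Biostrings::extractAt(
                seqs[[sc]], IRanges(pos[i], width = 1L)))
            strand[i] <- ifelse(base == "G", "-", "+")
            resolved[i] <- base %in% c("C", "G")
        }
    }
    # recompute percent from counts: full precision beats the rounded column
    CpGTable(scaffold = scaff, pos = pos, strand = strand,
             meth_pct = 100 * n_meth[keep] / pmax(n_total[keep], 1L),
             n_meth = n_meth[keep], n_total = n_total[keep],
             sample = sample, strand_resolved = resolved)
}

.asGenome <- function(genome) {
    if (methods::is(genome, "DNAStringSet")) return(genome)
    Biostrings::readDNAStringSet(genome)
}

#' Read transcript models from GFF3/GTF
#'
#' Imports mRNA/transcript and exon records, groups exons under their parent
#' transcript, and derives strand-aware TSS/TTS. Exons lacking a known
#' parent transcript are skipped with a warning.
#'
#' @param path GFF3 or GTF file (format detected by rtracklayer).
#' @return a \linkS4class{FeatureSet}.
#' @export
readGeneModels <- function(path) {
    gr <- rtracklayer::import(path)
    type <- tolower(as.character(gr$type))
    tx <- gr[type %in% c("mrna", "transcript")]
    txid <- .gffTranscriptId(tx)
    if (anyNA(txid) || !length(tx)) {
        tx <- tx[!is.na(txid)]
        txid <- txid[!is.na(txid)]
    }
    ex <- gr[type == "exon"]
    parent <- .gffExonParent(ex)
    orphan <- is.na(parent) | !(parent %in% txid)
    if (any(orphan)) {
        .warnf("skipping %d exon record(s) without a parent transcript",
               sum(orphan))
        ex <- ex[!orphan]
        parent <- parent[!orphan]
    }
    if (length(tx) && any(start(tx) > end(tx)))
        .stopf("gene model validation error: start > end")
    txdf <- data.frame(transcript_id = txid,
                       scaffold = as.character(seqnames(tx)),
                       start = start(tx), end = end(tx),
                       strand = as.character(strand(tx)),
                       stringsAsFactors = FALSE)
    exdf <- if (length(ex))
        data.frame(transcript_id = parent, start = start(ex), end = end(ex),
                   stringsAsFactors = FALSE)
    else NULL
    FeatureSet(txdf, exdf)
}

.gffTranscriptId <- function(tx) {
    md <- mcols(tx)
    id <- if ("ID" %in% colnames(md)) as.character(md$ID) else NA_character_
    if ("transcript_id" %in% colnames(md)) {
        alt <- as.character(md$transcript_id)
        id <- ifelse(is.na(id) | !nzchar(id), alt, id)
    }
    id
}

.gffExonParent <- function(ex) {
    if (!length(ex)) return(character())
    md <- mcols(ex)
    if ("Parent" %in% colnames(md)) {
        p <- md$Parent
        if (methods::is(p, "List"))
            return(vapply(p, function(v)
                if (length(v)) as.character(v[1]) else NA_character_,
                character(1)))
        return(as.character(p))
    }
    if ("transcript_id" %in% colnames(md))
        return(as.character(md$transcript_id))
    rep(NA_character_, length(ex))
}

#' Write a FeatureSet as GFF3
#'
#' Emits one mRNA record per transcript and its exon children; coordinates
#' are written 1-based inclusive. \code{readGeneModels} on the output
#' reproduces the input.
#'
#' @param x a \linkS4class{FeatureSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(x, path) {
    tx <- transcriptRanges(x)
    ids <- transcriptIds(x)
    out <- c("##gff-version 3")
    for (i in seq_along(tx)) {
        out <- c(out, sprintf("%s\tsparseMethylome\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                              as.character(seqnames(tx))[i], start(tx)[i],
                              end(tx)[i], as.character(strand(tx))[i], ids[i]))
        ex <- exonRanges(x)[[ids[i]]]
        if (!is.null(ex) && length(ex))
            out <- c(out, sprintf(
                "%s\tsparseMethylome\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                as.character(seqnames(tx))[i], start(ex), end(ex),
                as.character(strand(tx))[i], ids[i], seq_along(ex), ids[i]))
    }
    writeLines(out, path)
    invisible(path)
}

#' Read a RepeatMasker .out annotation
#'
#' Standard layout: 3 header lines then whitespace-separated columns with the
#' query sequence in column 5, 1-based begin/end in columns 6-7, strand in
#' column 9 ("+" or "C" for complement) and the repeat class/family in
#' column 11. Classes are grouped into DNA/LTR/LINE/SINE transposons and
#' Satellite/SimpleRepeat/OtherRE non-transposons
#' (see \code{\link{repeatClassGroup}}).
#'
#' @param path .out file (gzip detected automatically).
#' @return a \linkS4class{RepeatSet}.
#' @export
readRepeatMasker <- function(path) {
    lines <- .readLinesAny(path)
    if (length(lines) >= 1L && grepl("score|SW", lines[1]))
        lines <- lines[-seq_len(min(3L, length(lines)))]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(RepeatSet(data.frame(scaffold = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    raw_class = character())))
    parts <- strsplit(lines, "\\s+")
    nf <- lengths(parts)
    if (any(nf < 11L))
        .stopf("RepeatMasker parse error at line %d: fewer than 11 columns",
               which(nf < 11L)[1] + 3L)
    get <- function(j) vapply(parts, `[`, character(1), j)
    s <- suppressWarnings(as.integer(get(6)))
    e <- suppressWarnings(as.integer(get(7)))
    if (anyNA(s) || anyNA(e))
        .stopf("RepeatMasker parse error at line %d: unparseable coordinate",
               which(is.na(s) | is.na(e))[1] + 3L)
    RepeatSet(data.frame(scaffold = get(5), start = s, end = e,
                         strand = ifelse(get(9) == "C", "-", "+"),
                         raw_class = get(11), stringsAsFactors = FALSE))
}

#' Write a RepeatSet as a RepeatMasker-style .out file
#'
#' @param x a \linkS4class{RepeatSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRepeatMasker <- function(x, path) {
    gr <- repeatRanges(x)
    hdr <- c("   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
             "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
             "")
    body <- sprintf("  100   0.0  0.0  0.0  %s %d %d (0) %s rep%d %s 1 100 (0) %d",
                    as.character(seqnames(gr)), start(gr), end(gr),
                    ifelse(as.character(strand(gr)) == "-", "C", "+"),
                    seq_along(gr), mcols(gr)$raw_class, seq_along(gr))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a transcript-by-sample TPM matrix
#'
#' Tab-separated, first column transcript ids, remaining columns numeric
#' TPMs. Duplicate ids and negative values are rejected.
#'
#' @param path TSV file (gzip detected automatically).
#' @return a numeric matrix with transcript rownames and sample colnames.
#' @export
readTpmMatrix <- function(path) {
    con <- .openMaybeGz(path)
    on.exit(close(con))
    df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        .stopf("duplicate transcript_id in TPM matrix: '%s'",
               ids[duplicated(ids)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyNA(m))
        .stopf("non-numeric value in TPM matrix")
    if (any(m < 0))
        .stopf("negative TPM value for transcript '%s'",
               rownames(m)[which(rowSums(m < 0) > 0)[1]])
    if (anyDuplicated(colnames(m)))
        .stopf("duplicate sample name in TPM matrix")
    m
}

#' Write a TPM matrix as TSV
#'
#' @param tpm numeric matrix with transcript rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTpmMatrix <- function(tpm, path) {
    df <- data.frame(transcript_id = rownames(tpm), tpm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GO term-to-gene mapping
#'
#' Two-column TSV (term_id, gene_id), one pair per row, header optional
#' (detected when the first field is "term_id").
#'
#' @param path TSV file.
#' @return named list mapping term_id to a character vector of gene ids.
#' @export
readTermMap <- function(path) {
    lines <- .readLinesAny(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) && startsWith(lines[1], "term_id"))
        lines <- lines[-1]
    if (!length(lines)) return(list())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    term <- vapply(parts, `[`, character(1), 1)
    gene <- vapply(parts, `[`, character(1), 2)
    lapply(split(gene, term), unique)
}

#' Export an annotated CpG table as BED-like TSV
#'
#' 0-based half-open coordinates with a strand column, plus methylation and
#' annotation columns — the usual interchange form for genome browsers.
#'
#' @param x a \linkS4class{CpGTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCpGBed <- function(x, path) {
    df <- as.data.frame(x)
    out <- data.frame(chrom = df$scaffold, chromStart = df$pos - 1L,
                      chromEnd = df$pos, name = ".",
                      score = df$meth_pct, strand = df$strand)
    extra <- setdiff(colnames(df), c("scaffold", "pos", "strand"))
    out <- cbind(out, df[, extra, drop = FALSE])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
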