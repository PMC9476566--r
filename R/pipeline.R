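#' @include AllClasses.R utils.R formats-io.R methylome.R annotation.R
#' @include profiles.R patterns.R expression.R
NULL

.manifest <- function(out_dir, stage, params, inputs, outputs) {
    digests <- vapply(inputs[file.exists(unlist(inputs))],
                      function(p) unname(tools::md5sum(p)), character(1))
    list(stage = stage,
         tool = paste("sparseMethylome",
                      as.character(utils::packageVersion("sparseMethylome"))),
         timestamp_free = TRUE,   # manifests carry no clock, so runs diff clean
         params = params,
         input_md5 = as.list(digests),
         outputs = as.list(outputs))
}

.writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the methylome stage: classify, annotate, metaplot
#'
#' Chains CpG reading, classification, genomic-context annotation,
#' intergenic partitioning, context composition and gene/repeat metaplots,
#' writing every result plus a reproducibility manifest under
#' \code{out_dir}. Deterministic given its inputs.
#'
#' @param cgmap path to a CGmap file (the methylome input).
#' @param gff path to GFF3/GTF gene models.
#' @param rmout path to RepeatMasker .out annotation.
#' @param out_dir output directory (created).
#' @param min_total depth filter for the reader (default 1).
#' @param lo,hi classification thresholds (default 20/80).
#' @param promoter_len promoter width (default 2000).
#' @param gene_bins,repeat_bins metaplot bins (defaults 30, 15).
#' @param winsor winsorization percentiles (default c(1, 99)).
#' @param extra_cgmaps optional named character vector of further CGmap
#'   files; a common-CpG matrix across all samples is then emitted.
#' @return list with the classified annotated \linkS4class{CpGTable},
#'   summary, composition, profiles and the manifest path.
#' @export
runMethylome <- function(cgmap, gff, rmout, out_dir,
                         min_total = 1L, lo = 20, hi = 80,
                         promoter_len = 2000L,
                         gene_bins = 30L, repeat_bins = 15L,
                         winsor = c(1, 99),
                         extra_cgmaps = character()) {
    inputs <- c(cgmap, gff, rmout, unname(extra_cgmaps))
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        .stopf("missing input(s): %s", paste(missing, collapse = ", "))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    cpgs <- readCGmap(cgmap, min_total = min_total)
    features <- readGeneModels(gff)
    repeats <- readRepeatMasker(rmout)
    cpgs <- classifyCpGs(cpgs, lo = lo, hi = hi)
    cpgs <- annotateCpGs(cpgs, features, promoter_len = promoter_len)
    cpgs <- partitionIntergenic(cpgs, repeats)
    summ <- summarizeMethylome(cpgs)
    comp <- contextComposition(cpgs)
    geneProfile <- metaplot(cpgs, features, B = gene_bins, winsor = winsor)
    repProfile <- metaplot(cpgs, repeats, B = repeat_bins, winsor = winsor)

    outputs <- c(annotated = file.path(out_dir, "annotated_cpgs.tsv"),
                 summary = file.path(out_dir, "methylome_summary.tsv"),
                 composition = file.path(out_dir, "context_composition.tsv"),
                 gene_profile = file.path(out_dir, "gene_metaplot.tsv"),
                 repeat_profile = file.path(out_dir, "repeat_metaplot.tsv"))
    writeCpGBed(cpgs, outputs["annotated"])
    .writeTsv(as.data.frame(summ[-1], row.names = summ$sample),
              outputs["summary"])
    .writeTsv(comp, outputs["composition"])
    .writeTsv(profileStats(geneProfile), outputs["gene_profile"])
    .writeTsv(profileStats(repProfile), outputs["repeat_profile"])

    common <- NULL
    if (length(extra_cgmaps)) {
        others <- lapply(extra_cgmaps, readCGmap, min_total = min_total)
        common <- joinCommonCpGs(c(list(cpgs), others))
        outputs["common"] <- file.path(out_dir, "common_cpgs.tsv")
        .writeTsv(common, outputs["common"])
    }

    man <- .manifest(out_dir, "methylome",
                     params = list(min_total = min_total, lo = lo, hi = hi,
                                   promoter_len = promoter_len,
                                   gene_bins = gene_bins,
                                   repeat_bins = repeat_bins,
                                   winsor = winsor),
                     inputs = inputs, outputs = outputs)
    manifest_path <- .writeManifest(man, file.path(out_dir, "manifest.json"))
    list(cpgs = cpgs, summary = summ, composition = comp,
         gene_profile = geneProfile, repeat_profile = repProfile,
         common = common, manifest = manifest_path)
}

#' Run the pattern stage: k-means patterns and expression integration
#'
#' Consumes the methylome stage's classified table, computes per-transcript
#' gene-body means, discovers k methylation patterns, and integrates
#' expression: per-pattern Kruskal-Wallis with Dunn post-hoc, the
#' percentile-of-expression methylation curve, and optional GO
#' over-representation per pattern. All tables, the centers JSON and a
#' manifest are written under \code{out_dir}.
#'
#' @param methylome result of \code{\link{runMethylome}} (or a
#'   \linkS4class{CpGTable}).
#' @param gff gene models path (re-read so the stage stands alone).
#' @param tpm path to a TPM matrix TSV.
#' @param out_dir output directory.
#' @param expr_sample column of the TPM matrix to integrate (default first).
#' @param k clusters (default 4).
#' @param seed RNG seed for k-means (default 1).
#' @param min_cpgs minimum covered CpGs per transcript (default 1).
#' @param n_groups percentile groups (default 100).
#' @param term_map optional term->genes list for GO enrichment of each
#'   pattern against all assigned transcripts.
#' @return list with the \linkS4class{PatternAssignment}, test results,
#'   curve, enrichment (or NULL) and the manifest path.
#' @export
runPatterns <- function(methylome, gff, tpm, out_dir,
                        expr_sample = NULL, k = 4L, seed = 1L,
                        min_cpgs = 1L, n_groups = 100L, term_map = NULL) {
    cpgs <- if (methods::is(methylome, "CpGTable")) methylome
            else methylome$cpgs
    if (is.null(cpgs))
        .stopf("methylome stage output missing; run runMethylome() first")
    for (p in c(gff, tpm))
        if (!file.exists(p)) .stopf("missing input: %s", p)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    features <- readGeneModels(gff)
    tpmMat <- readTpmMatrix(tpm)
    if (is.null(expr_sample)) expr_sample <- colnames(tpmMat)[1]
    means <- transcriptMeanMethylation(cpgs, features, min_cpgs = min_cpgs)
    assignment <- kmeansPatterns(means, k = k, seed = seed)
    expr <- logTpm(tpmMat[, expr_sample])
    names(expr) <- rownames(tpmMat)
    test <- mpExpressionTest(expr, assignment)
    curve <- percentileMethylationCurve(expr, means, n_groups = n_groups)

    outputs <- c(patterns = file.path(out_dir, "pattern_assignments.tsv"),
                 centers = file.path(out_dir, "pattern_centers.json"),
                 curve = file.path(out_dir, "percentile_curve.tsv"),
                 kw = file.path(out_dir, "kw_dunn.tsv"))
    .writeTsv(as.data.frame(assignment), outputs["patterns"])
    jsonlite::write_json(list(centers = patternCenters(assignment),
                              inertia = assignment@inertia,
                              seed = seed, restarts = assignment@restarts),
                         outputs["centers"], auto_unbox = TRUE, digits = NA)
    .writeTsv(curve, outputs["curve"])
    .writeTsv(test$dunn, outputs["kw"])

    enrichment <- NULL
    if (!is.null(term_map)) {
        adf <- as.data.frame(assignment)
        universe <- adf$transcript_id
        enrichment <- do.call(rbind, lapply(seq_len(k), function(j) {
            res <- goEnrichment(adf$transcript_id[adf$mp_label == j],
                                universe, term_map)
            if (nrow(res)) cbind(mp_label = j, res) else NULL
        }))
        outputs["go"] <- file.path(out_dir, "go_enrichment.tsv")
        .writeTsv(enrichment, outputs["go"])
    }

    man <- .manifest(out_dir, "patterns",
                     params = list(k = k, seed = seed, min_cpgs = min_cpgs,
                                   n_groups = n_groups,
                                   expr_sample = expr_sample),
                     inputs = c(gff, tpm), outputs = outputs)
    manifest_path <- .writeManifest(man, file.path(out_dir, "manifest.json"))
    list(assignment = assignment, test = test, curve = curve,
         enrichment = enrichment, manifest = manifest_path)
}
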