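#' @include AllClasses.R utils.R formats-io.R
NULL

#' Configuration for the synthetic methylome generator
#'
#' Defines the study conditions the generator emulates: a sparsely
#' methylated genome in which fewer than 10% of CpGs are methylated and
#' about 7% show intermediate (20-80%) levels, four gene-body methylation
#' archetypes, methylation-depleted transposons with a satellite exception,
#' dense WGBS vs sparse RRBS coverage, and expression coupled to gene-body
#' methylation.
#'
#' Methylation is modelled as a binary site property: each CpG is either
#' methylated (true level \code{p_meth}) or unmethylated (\code{p_unmeth}),
#' and a compartment's "level" is the fraction of its CpGs that are
#' methylated — this is what makes partially methylated compartments show
#' crisp per-read levels, as sparse invertebrate methylomes do. A fraction
#' \code{intermediate_frac} of CpGs outside gene bodies is instead given a
#' uniform intermediate level, emulating tissue heterogeneity.
#'
#' @param n_scaffolds number of scaffolds (default 4).
#' @param n_genes total genes (default 2000).
#' @param gene_body_len gene body length in bp (default 600).
#' @param exons_per_gene exons per gene (default 3).
#' @param flank_len reserved flank per gene side, bp (default 2000).
#' @param body_cpg_spacing,flank_cpg_spacing,intergenic_cpg_spacing distance
#'   in bp between planted CpGs in gene bodies, flanks and intergenic space
#'   (defaults 15, 60, 25: gene bodies are CpG-enriched).
#' @param target_intergenic_frac design fraction of CpGs annotated
#'   intergenic (default 0.85).
#' @param archetype_weights mixture weights of the four gene archetypes
#'   (defaults from the observed pattern sizes 5482/8972/6545/17586).
#' @param archetype_levels plateau methylation level of the methylated
#'   segments of archetypes 1-4 (defaults 0.75, 0.75, 0.60, 0.02);
#'   archetype 2 is depleted over the promoter and first third of the body,
#'   archetype 3 ramps over body thirds (depleted, half level, full level).
#' @param te_level,satellite_level,simple_level,other_re_level,
#'   intergenic_level compartment methylation levels (defaults 0.05, 0.15,
#'   0.04, 0.04, 0.03: transposons are depleted, satellites are the
#'   exception).
#' @param p_meth,p_unmeth true per-read methylation probability of a
#'   methylated / unmethylated site (defaults 0.95, 0.02).
#' @param intermediate_frac fraction of non-body CpGs given an intermediate
#'   level (default 0.07).
#' @param intermediate_range uniform range of intermediate levels
#'   (default c(0.25, 0.75)).
#' @param gene_level_sd per-gene additive noise on archetype levels
#'   (default 0.05).
#' @param beta_precision beta dispersion of per-CpG methylation around its
#'   true level; larger is tighter (default 100).
#' @param wgbs_depth,rrbs_depth Poisson mean read depth (defaults 30, 40).
#' @param rrbs_retention fraction of CpG dyads covered by RRBS
#'   (default 0.03).
#' @param te_counts named counts of TE insertions per group (DNA, LTR,
#'   LINE, SINE).
#' @param te_len,satellite_arrays,satellite_len,simple_repeat_count,
#'   simple_len,other_re_count,other_len repeat geometry (bp / counts).
#' @param n_tissues tissue count for expression (default 13).
#' @param expr_intercept,expr_slope expected log2(TPM+1) =
#'   intercept + slope * true body methylation percent (defaults 0.5,
#'   0.055): expression increases with gene-body methylation through the
#'   mid-range.
#' @param expr_noise_sd cross-tissue noise sd of log2(TPM+1) for archetypes
#'   1-3 (default 0.3: highly methylated genes are stably expressed).
#' @param mp4_zero_inflation,mp4_noise_sd archetype-4 genes are silenced
#'   with this probability per tissue, otherwise expressed with this (much
#'   larger) noise sd (defaults 0.55, 1.2).
#' @param seed master seed; every downstream draw derives from it.
#' @return a list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(n_scaffolds = 4L,
                            n_genes = 2000L,
                            gene_body_len = 600L,
                            exons_per_gene = 3L,
                            flank_len = 2000L,
                            body_cpg_spacing = 15L,
                            flank_cpg_spacing = 60L,
                            intergenic_cpg_spacing = 25L,
                            target_intergenic_frac = 0.85,
                            archetype_weights = c(0.1421, 0.2325,
                                                  0.1696, 0.4558),
                            archetype_levels = c(0.75, 0.75, 0.60, 0.02),
                            te_level = 0.05,
                            satellite_level = 0.15,
                            simple_level = 0.04,
                            other_re_level = 0.04,
                            intergenic_level = 0.03,
                            p_meth = 0.95,
                            p_unmeth = 0.02,
                            intermediate_frac = 0.07,
                            intermediate_range = c(0.25, 0.75),
                            gene_level_sd = 0.05,
                            beta_precision = 100,
                            wgbs_depth = 30,
                            rrbs_depth = 40,
                            rrbs_retention = 0.03,
                            te_counts = c(DNA = 60L, LTR = 40L,
                                          LINE = 60L, SINE = 40L),
                            te_len = 500L,
                            satellite_arrays = 8L,
                            satellite_len = 2000L,
                            simple_repeat_count = 30L,
                            simple_len = 200L,
                            other_re_count = 20L,
                            other_len = 300L,
                            n_tissues = 13L,
                            expr_intercept = 0.5,
                            expr_slope = 0.055,
                            expr_noise_sd = 0.3,
                            mp4_zero_inflation = 0.55,
                            mp4_noise_sd = 1.2,
                            seed = 20L) {
    cfg <- as.list(environment())
    stopifnot(abs(sum(cfg$archetype_weights) - 1) < 1e-8,
              all(unlist(cfg[c("archetype_levels", "te_level",
                               "satellite_level", "simple_level",
                               "other_re_level", "intergenic_level",
                               "p_meth", "p_unmeth")]) >= 0),
              all(unlist(cfg[c("archetype_levels", "te_level",
                               "satellite_level", "simple_level",
                               "other_re_level", "intergenic_level",
                               "p_meth", "p_unmeth")]) <= 1),
              cfg$p_unmeth < cfg$p_meth)
    class(cfg) <- "GeneratorConfig"
    cfg
}

## archetype level at relative body position frac (0 at TSS, 1 at TTS)
.archetypeLevel <- function(archetype, frac, cfg) {
    l <- cfg$archetype_levels
    base <- cfg$p_unmeth
    switch(archetype,
           ifelse(frac >= 0, l[1], base),                      # MP1: uniform
           ifelse(frac < 1 / 3, base, l[2]),                   # MP2: TSS-depleted
           ifelse(frac < 1 / 3, base,
                  ifelse(frac < 2 / 3, l[3] / 2, l[3])),       # MP3: 5' third off
           rep(base, length(frac)))                            # MP4: none
}

.archetypePromoterLevel <- function(archetype, cfg)
    c(cfg$archetype_levels[1], cfg$p_unmeth, cfg$p_unmeth,
      cfg$p_unmeth)[archetype]

.archetypeDownstreamLevel <- function(archetype, cfg)
    c(cfg$archetype_levels[1], cfg$archetype_levels[2],
      cfg$archetype_levels[3], cfg$p_unmeth)[archetype]

#' Analytic archetype gene-body mean methylation
#'
#' The expected per-CpG methylation percent over a gene body of each
#' archetype, implied by the configured segment levels (archetype 2 averages
#' its depleted first third, archetype 3 its three-step ramp). These are the
#' values k-means centers should recover on generator output.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return numeric length-4, percent.
#' @export
archetypeBodyMeans <- function(config = generatorConfig()) {
    cfg <- config
    100 * vapply(1:4, function(a)
        mean(.archetypeLevel(a, seq(0.0005, 0.9995, length.out = 1000), cfg)),
        numeric(1))
}

#' Generate a synthetic genome, annotation and methylation truth
#'
#' Lays out non-overlapping gene cassettes (2 kb flank, CpG-enriched body
#' split into exons, 2 kb flank) on each scaffold, followed by an intergenic
#' zone holding TE insertions, satellite arrays, simple repeats, other
#' repeats and repeat-free space, sized so that the design fraction of CpGs
#' (85% by default) is intergenic. CpGs are planted at the configured
#' spacings; the background sequence contains no other CG dinucleotide, so
#' the planted catalog is the complete CpG complement of the genome. Each
#' CpG receives a true methylation level from its compartment (archetype
#' profile, repeat group or intergenic background), a binary
#' methylated/unmethylated state, and — outside gene bodies — a chance of an
#' intermediate level emulating tissue heterogeneity.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param sequences build the genome sequence (default TRUE; FALSE skips
#'   the FASTA-level genome and leaves only coordinates and truth, which is
#'   enough for every analysis that does not touch the sequence).
#' @return list of class \code{SyntheticMethylome} with elements
#'   \code{genome} (\link[Biostrings]{DNAStringSet} or NULL),
#'   \code{features} (\linkS4class{FeatureSet}), \code{repeats}
#'   (\linkS4class{RepeatSet}) and \code{truth} (list: \code{cpgs} per-CpG
#'   catalog with p_true, \code{genes} per-gene table with archetype and
#'   true body mean, \code{repeats}, \code{archetype_body_means},
#'   \code{config}).
#' @export
generateGenome <- function(config = generatorConfig(), sequences = TRUE) {
    cfg <- config
    .withSeed(cfg$seed, .generateGenomeImpl(cfg, sequences))
}

.generateGenomeImpl <- function(cfg, sequences) {
    margin <- 200L
    gap <- 200L
    bodyCp <- max(1L, cfg$gene_body_len %/% cfg$body_cpg_spacing)
    flankCp <- max(1L, cfg$flank_len %/% cfg$flank_cpg_spacing)
    nB <- cfg$n_genes * bodyCp
    nP <- cfg$n_genes * flankCp
    nD <- cfg$n_genes * flankCp
    f <- cfg$target_intergenic_frac
    # intergenic CpGs needed so that (downstream + intergenic zone) hits f
    nIntZone <- max(0, ceiling(f / (1 - f) * (nB + nP) - nD))

    mkPlan <- function(groups, len, level)
        data.frame(group = groups, len = rep_len(len, length(groups)),
                   level = rep_len(level, length(groups)),
                   stringsAsFactors = FALSE)
    repPlan <- rbind(
        mkPlan(rep(names(cfg$te_counts), cfg$te_counts), cfg$te_len,
               cfg$te_level),
        mkPlan(rep("Satellite", cfg$satellite_arrays), cfg$satellite_len,
               cfg$satellite_level),
        mkPlan(rep("SimpleRepeat", cfg$simple_repeat_count), cfg$simple_len,
               cfg$simple_level),
        mkPlan(rep("OtherRE", cfg$other_re_count), cfg$other_len,
               cfg$other_re_level))
    repPlan$raw_class <- c(DNA = "DNA/hAT", LTR = "LTR/Gypsy",
                           LINE = "LINE/L2", SINE = "SINE/tRNA",
                           Satellite = "Satellite", SimpleRepeat = "Simple_repeat",
                           OtherRE = "Unknown")[repPlan$group]
    repPlan <- repPlan[sample.int(nrow(repPlan)), , drop = FALSE]
    nRepCp <- sum(repPlan$len %/% cfg$intergenic_cpg_spacing)
    nFree <- max(0L, nIntZone - nRepCp)

    scaffolds <- sprintf("scaf%02d", seq_len(cfg$n_scaffolds))
    genesPer <- tabulate(rep(seq_len(cfg$n_scaffolds),
                             length.out = cfg$n_genes), cfg$n_scaffolds)
    repPer <- split(seq_len(nrow(repPlan)),
                    factor(rep(seq_len(cfg$n_scaffolds),
                               length.out = nrow(repPlan)),
                           levels = seq_len(cfg$n_scaffolds)))
    freePer <- tabulate(rep(seq_len(cfg$n_scaffolds), length.out = nFree),
                        cfg$n_scaffolds)

    archetypes <- sample.int(4L, cfg$n_genes, replace = TRUE,
                             prob = cfg$archetype_weights)
    geneOffsets <- stats::rnorm(cfg$n_genes, 0, cfg$gene_level_sd)

    chunks <- list()   # per-segment catalog pieces, bound once at the end
    addChunk <- function(scaffold, pos, region, level, gene, repeat_idx) {
        chunks[[length(chunks) + 1L]] <<- data.frame(
            scaffold = scaffold, pos = as.integer(pos), region = region,
            level = level, gene = gene, repeat_idx = repeat_idx,
            stringsAsFactors = FALSE)
    }
    txRows <- list(); exRows <- list(); repRows <- list()
    scafLens <- integer(cfg$n_scaffolds)
    gi <- 0L

    for (si in seq_len(cfg$n_scaffolds)) {
        cur <- margin + 1L
        for (g in seq_len(genesPer[si])) {
            gi <- gi + 1L
            st <- if (gi %% 2L == 0L) "-" else "+"
            leftFlank <- cur
            bodyStart <- cur + cfg$flank_len
            bodyEnd <- bodyStart + cfg$gene_body_len - 1L
            rightFlank <- bodyEnd + 1L
            cur <- rightFlank + cfg$flank_len + gap

            # exon/intron structure: exons_per_gene exons split the body
            bnd <- round(seq(bodyStart, bodyEnd + 1L,
                             length.out = 2L * cfg$exons_per_gene))
            exs <- bnd[seq(1L, length(bnd) - 1L, by = 2L)]
            exe <- bnd[seq(2L, length(bnd), by = 2L)] - 1L
            exe[length(exe)] <- bodyEnd
            txRows[[gi]] <- data.frame(
                transcript_id = sprintf("tx%05d", gi),
                scaffold = scaffolds[si], start = bodyStart, end = bodyEnd,
                strand = st, stringsAsFactors = FALSE)
            exRows[[gi]] <- data.frame(
                transcript_id = sprintf("tx%05d", gi),
                start = exs, end = exe, stringsAsFactors = FALSE)

            a <- archetypes[gi]
            adj <- function(l) pmin(pmax(l + geneOffsets[gi], 0), 1)
            bpos <- seq(bodyStart + 2L, bodyEnd - 2L, by = cfg$body_cpg_spacing)
            bpos <- bpos[seq_len(min(bodyCp, length(bpos)))]
            frac <- if (st == "-") (bodyEnd - bpos) / cfg$gene_body_len
                    else (bpos - bodyStart) / cfg$gene_body_len
            lf <- seq(leftFlank + 2L, bodyStart - 3L, by = cfg$flank_cpg_spacing)
            lf <- lf[seq_len(min(flankCp, length(lf)))]
            rf <- seq(rightFlank + 2L, rightFlank + cfg$flank_len - 3L,
                      by = cfg$flank_cpg_spacing)
            rf <- rf[seq_len(min(flankCp, length(rf)))]
            if (st == "-") { up <- rf; dn <- lf } else { up <- lf; dn <- rf }

            addChunk(scaffolds[si], c(bpos, up, dn),
                     c(rep("body", length(bpos)),
                       rep("promoter", length(up)),
                       rep("downstream", length(dn))),
                     c(adj(.archetypeLevel(a, frac, cfg)),
                       rep(adj(.archetypePromoterLevel(a, cfg)), length(up)),
                       rep(adj(.archetypeDownstreamLevel(a, cfg)), length(dn))),
                     gi, NA_integer_)
        }
        # intergenic zone: repeats then repeat-free space
        for (ri in repPer[[si]]) {
            rlen <- repPlan$len[ri]
            rstart <- cur
            rend <- cur + rlen - 1L
            cur <- rend + gap + 1L
            repRows[[ri]] <- data.frame(
                scaffold = scaffolds[si], start = rstart, end = rend,
                strand = "+", raw_class = repPlan$raw_class[ri],
                group = repPlan$group[ri], stringsAsFactors = FALSE)
            rp <- seq(rstart + 2L, rend - 2L, by = cfg$intergenic_cpg_spacing)
            if (length(rp))
                addChunk(scaffolds[si], rp, repPlan$group[ri],
                         repPlan$level[ri], NA_integer_, ri)
        }
        if (freePer[si] > 0L) {
            fp <- cur + 2L +
                cfg$intergenic_cpg_spacing * (seq_len(freePer[si]) - 1L)
            cur <- fp[length(fp)] + cfg$intergenic_cpg_spacing
            addChunk(scaffolds[si], fp, "free", cfg$intergenic_level,
                     NA_integer_, NA_integer_)
        }
        scafLens[si] <- cur + margin
    }

    catalog <- do.call(rbind, chunks)
    ord <- order(catalog$scaffold, catalog$pos, method = "radix")
    catalog <- catalog[ord, , drop = FALSE]
    rownames(catalog) <- NULL

    # binary site state: a compartment's level is the fraction of its sites
    # that are methylated. Inside gene bodies the fraction is honoured
    # exactly per gene segment (random positions, exact count), so a gene's
    # realized body mean carries only the designed per-gene variance;
    # elsewhere sites are independent Bernoulli draws.
    pi_site <- pmin(pmax((catalog$level - cfg$p_unmeth) /
                         (cfg$p_meth - cfg$p_unmeth), 0), 1)
    methylated <- stats::runif(nrow(catalog)) < pi_site
    body_idx <- which(catalog$region == "body")
    seg <- paste(catalog$gene[body_idx], catalog$level[body_idx])
    for (grp in split(body_idx, seg)) {
        m <- round(sum(pi_site[grp]))
        methylated[grp] <- FALSE
        if (m > 0L)
            methylated[grp[sample.int(length(grp), m)]] <- TRUE
    }
    p_true <- ifelse(methylated, cfg$p_meth, cfg$p_unmeth)
    # intermediate sites live outside gene bodies (so archetype body means
    # stay crisp) but the configured fraction refers to all CpGs
    nonbody <- catalog$region != "body"
    rate <- min(1, cfg$intermediate_frac / max(mean(nonbody), 1e-12))
    interm <- nonbody & stats::runif(nrow(catalog)) < rate
    p_true[interm] <- stats::runif(sum(interm), cfg$intermediate_range[1],
                                   cfg$intermediate_range[2])
    catalog$p_true <- p_true
    catalog$intermediate_site <- interm

    features <- FeatureSet(do.call(rbind, txRows), do.call(rbind, exRows))
    repDf <- if (length(repRows)) do.call(rbind, repRows) else
        data.frame(scaffold = character(), start = integer(),
                   end = integer(), strand = character(),
                   raw_class = character(), group = character())
    repeats <- RepeatSet(repDf)

    geneTab <- do.call(rbind, txRows)
    geneTab$archetype <- archetypes
    geneTab$level_offset <- geneOffsets
    bm <- tapply(catalog$p_true[catalog$region == "body"],
                 catalog$gene[catalog$region == "body"], mean)
    geneTab$true_body_mean_pct <- 100 * as.numeric(bm[as.character(seq_len(cfg$n_genes))])

    genome <- NULL
    if (sequences)
        genome <- .buildSequences(scaffolds, scafLens, catalog)

    out <- list(genome = genome, features = features, repeats = repeats,
                truth = list(cpgs = catalog, genes = geneTab,
                             repeats = repDf,
                             archetype_body_means = archetypeBodyMeans(cfg),
                             config = cfg))
    class(out) <- "SyntheticMethylome"
    out
}

## background sequence with every CG dinucleotide planted on purpose
.buildSequences <- function(scaffolds, lens, catalog) {
    lut <- charToRaw("ACGT")
    seqs <- vapply(seq_along(scaffolds), function(si) {
        len <- lens[si]
        codes <- sample.int(4L, len, replace = TRUE)
        v <- lut[codes]
        # break accidental CG dinucleotides (mutate the G to A)
        isC <- v == lut[2]; isG <- v == lut[3]
        acc <- which(isC[-len] & isG[-1])
        if (length(acc)) v[acc + 1L] <- lut[1]
        # planting C at pos and G at pos+1 cannot create a CG elsewhere:
        # any new pair would need a C ending at pos (overwritten) or a C at
        # pos+1 (it is a G)
        pos <- catalog$pos[catalog$scaffold == scaffolds[si]]
        v[pos] <- lut[2]; v[pos + 1L] <- lut[3]
        rawToChar(v)
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, scaffolds))
}

#' @export
print.SyntheticMethylome <- function(x, ...) {
    cfg <- x$truth$config
    cat(sprintf("SyntheticMethylome: %d genes, %d repeats, %d CpG dyads on %d scaffolds\n",
                nrow(x$truth$genes), nrow(x$truth$repeats),
                nrow(x$truth$cpgs), cfg$n_scaffolds))
    cat(sprintf("  archetype body means (analytic): %s\n",
                paste(sprintf("%.1f", x$truth$archetype_body_means),
                      collapse = ", ")))
    invisible(x)
}

#' Simulate a bisulfite methylome from generator truth
#'
#' For each retained CpG dyad, both strands are emitted with independent
#' draws: depth from Poisson (WGBS mean 30 by default; RRBS retains a
#' random ~3% of dyads at mean depth 40), per-strand methylation probability
#' from a Beta centred on the site's true level, methylated reads Binomial.
#' Zero-depth sites are not reported (uncovered). Output is an in-memory
#' \linkS4class{CpGTable}; when \code{path} is given the table is also
#' written as a CGmap file (WGBS) or Bismark-style coverage file (RRBS).
#'
#' @param truth a \code{SyntheticMethylome} (or its \code{$truth} list).
#' @param mode "WGBS" or "RRBS".
#' @param sample_id sample tag.
#' @param seed integer seed (independent of the generator's master seed).
#' @param path optional output file.
#' @return a \linkS4class{CpGTable}.
#' @export
simulateMethylome <- function(truth, mode = c("WGBS", "RRBS"),
                              sample_id = mode, seed = 1L, path = NULL) {
    mode <- match.arg(mode)
    if (methods::is(truth, "SyntheticMethylome") ||
        (is.list(truth) && !is.null(truth$truth)))
        truth <- truth$truth
    cfg <- truth$config
    cat0 <- truth$cpgs
    tab <- .withSeed(seed, {
        keep <- if (mode == "RRBS")
            stats::runif(nrow(cat0)) < cfg$rrbs_retention
        else rep(TRUE, nrow(cat0))
        cc <- cat0[keep, , drop = FALSE]
        n <- nrow(cc)
        depth_mean <- if (mode == "RRBS") cfg$rrbs_depth else cfg$wgbs_depth
        # both strands, independent draws around the same true level
        scaff <- rep(cc$scaffold, 2L)
        pos <- c(cc$pos, cc$pos + 1L)
        strand <- rep(c("+", "-"), each = n)
        p <- rep(cc$p_true, 2L)
        depth <- stats::rpois(2L * n, depth_mean)
        a <- p * cfg$beta_precision
        b <- (1 - p) * cfg$beta_precision
        q <- stats::rbeta(2L * n, pmax(a, 1e-8), pmax(b, 1e-8))
        n_meth <- stats::rbinom(2L * n, depth, q)
        covered <- depth > 0L
        ord <- order(scaff[covered], pos[covered], method = "radix")
        idx <- which(covered)[ord]
        CpGTable(scaffold = scaff[idx], pos = pos[idx],
                 strand = strand[idx],
                 meth_pct = 100 * n_meth[idx] / depth[idx],
                 n_meth = n_meth[idx], n_total = depth[idx],
                 sample = sample_id)
    })
    if (!is.null(path)) {
        if (mode == "RRBS") .writeCoverage(tab, path) else writeCGmap(tab, path)
    }
    tab
}

## Bismark-style coverage output (chrom, start, end, percent, meth, unmeth)
.writeCoverage <- function(x, path) {
    gr <- cpgSites(x)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                       as.character(seqnames(gr)), start(gr), start(gr),
                       formatC(methPct(x), format = "f", digits = 6),
                       methReads(x), totalReads(x) - methReads(x)),
               path)
    invisible(path)
}

#' Simulate tissue expression coupled to gene-body methylation
#'
#' Expected log2(TPM+1) increases linearly with a gene's true body
#' methylation percent; archetypes 1-3 get tight cross-tissue noise (highly
#' methylated genes are stably and highly expressed), archetype-4 genes are
#' zero-inflated with large tissue-specific bursts (silenced or variably
#' expressed).
#'
#' @param truth a \code{SyntheticMethylome} or its \code{$truth}.
#' @param tissues tissue count (default from config).
#' @param seed integer seed.
#' @return TPM matrix (genes x tissues) with transcript rownames.
#' @export
simulateExpression <- function(truth, tissues = NULL, seed = 1L) {
    if (methods::is(truth, "SyntheticMethylome") ||
        (is.list(truth) && !is.null(truth$truth)))
        truth <- truth$truth
    cfg <- truth$config
    if (is.null(tissues)) tissues <- cfg$n_tissues
    genes <- truth$genes
    nG <- nrow(genes)
    base <- cfg$expr_intercept + cfg$expr_slope * genes$true_body_mean_pct
    .withSeed(seed, {
        m <- matrix(0, nrow = nG, ncol = tissues,
                    dimnames = list(genes$transcript_id,
                                    sprintf("tissue%02d", seq_len(tissues))))
        mp4 <- genes$archetype == 4L
        for (t in seq_len(tissues)) {
            e <- base + stats::rnorm(nG, 0, cfg$expr_noise_sd)
            if (any(mp4)) {
                burst <- base[mp4] + stats::rnorm(sum(mp4), 0, cfg$mp4_noise_sd)
                silent <- stats::runif(sum(mp4)) < cfg$mp4_zero_inflation
                e[mp4] <- ifelse(silent, 0, burst)
            }
            m[, t] <- pmax(2^pmax(e, 0) - 1, 0)
        }
        m
    })
}

#' Write a complete synthetic data set to disk
#'
#' Emits genome FASTA, GFF3 gene models, a RepeatMasker-style .out file, a
#' WGBS CGmap, an RRBS coverage file, a TPM matrix and the ground-truth
#' tables (TSV + config JSON) into one directory.
#'
#' @param sim a \code{SyntheticMethylome} from \code{\link{generateGenome}}.
#' @param dir output directory (created if needed).
#' @param seed seed for the methylome/expression draws.
#' @return named character vector of the files written, invisibly.
#' @export
writeSyntheticData <- function(sim, dir, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "genome.fa"),
               gff = file.path(dir, "genes.gff3"),
               rmout = file.path(dir, "repeats.out"),
               wgbs = file.path(dir, "wgbs.cgmap"),
               rrbs = file.path(dir, "rrbs.cov"),
               tpm = file.path(dir, "tpm.tsv"),
               truth_genes = file.path(dir, "truth_genes.tsv"),
               truth_cpgs = file.path(dir, "truth_cpgs.tsv"),
               config = file.path(dir, "config.json"))
    if (!is.null(sim$genome))
        Biostrings::writeXStringSet(sim$genome, paths["fasta"])
    writeGeneModels(sim$features, paths["gff"])
    writeRepeatMasker(sim$repeats, paths["rmout"])
    simulateMethylome(sim, "WGBS", "wgbs", seed = .deriveSeed(seed, 1L),
                      path = paths["wgbs"])
    simulateMethylome(sim, "RRBS", "rrbs", seed = .deriveSeed(seed, 2L),
                      path = paths["rrbs"])
    writeTpmMatrix(simulateExpression(sim, seed = .deriveSeed(seed, 3L)),
                   paths["tpm"])
    utils::write.table(sim$truth$genes, paths["truth_genes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$cpgs, paths["truth_cpgs"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$truth$config[setdiff(names(sim$truth$config),
                                                  character(0))],
                         paths["config"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
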