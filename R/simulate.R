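#' Plant motifs into a promoter sequence
#'
#' Writes concrete ABRE (and optionally CE) realizations into a background
#' sequence at evenly spaced, non-overlapping offsets. ABRE realizations are
#' drawn uniformly from the degenerate consensus; the CE realization is
#' [CE_MOTIF_DEFAULT]. Background occurrences that arise by chance are not
#' removed — callers recover the observable motif content by re-scanning.
#'
#' @param seq `DNAString` (or character) background sequence.
#' @param nAbre,nCe number of motifs to plant.
#' @param spacing distance between planted motif start positions (bp).
#' @return list: `seq` (`DNAString` with motifs), `positions` (data.frame
#'   `motif`, `start`, `realization`).
#' @export
plantMotifs <- function(seq, nAbre, nCe = 0L, spacing = 200L) {
    if (!is(seq, "DNAString")) seq <- Biostrings::DNAString(seq)
    need <- (nAbre + nCe) * spacing + 20L
    if (nAbre + nCe > 0L && length(seq) < need)
        stop("sequence too short to plant ", nAbre + nCe,
             " motifs at spacing ", spacing)
    pos <- integer(); motif <- character(); real <- character()
    slot <- 1L
    drawAbre <- function()
        paste0("CACG", sample(c("T", "C"), 1L), "G", sample(c("G", "T"), 1L),
               "C", sample(c("G", "C"), 1L))
    for (k in seq_len(nAbre)) {
        r <- drawAbre(); p <- (slot - 1L) * spacing + 50L
        Biostrings::subseq(seq, p, p + nchar(r) - 1L) <- Biostrings::DNAString(r)
        pos <- c(pos, p); motif <- c(motif, "ABRE"); real <- c(real, r)
        slot <- slot + 1L
    }
    for (k in seq_len(nCe)) {
        r <- CE_MOTIF_DEFAULT; p <- (slot - 1L) * spacing + 50L
        Biostrings::subseq(seq, p, p + nchar(r) - 1L) <- Biostrings::DNAString(r)
        pos <- c(pos, p); motif <- c(motif, "CE"); real <- c(real, r)
        slot <- slot + 1L
    }
    list(seq = seq,
         positions = data.frame(motif = motif, start = pos,
                                realization = real,
                                stringsAsFactors = FALSE))
}

.randomDNA <- function(n) {
    Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = ""))
}

# layout constants of the toy genome
.GENE_LEN <- 1000L
.GENE_OFFSET <- 2600L   # gene start within its slot
.CHLORO_NAME <- "chrC"
.CHLORO_LEN <- 100000L
# the conversion control pools many cytosines, as a real chloroplast does;
# a sparse control would propagate its sampling error into every adjusted
# methylation level
.CHLORO_SITES <- 20000L

# per-promoter methylation site spacing (bp between sites); CHH sites are
# dense in real promoters (H = A, T or C, so a sizeable fraction of bases)
.PROM_SPACING <- c(CG = 200L, CHG = 200L, CHH = 10L)

.simGeneLayout <- function(config) {
    perChrom <- ceiling(config@nGenes / config@nChroms)
    slot <- config@chromLen %/% perChrom
    if (slot < .GENE_LEN + 2L * 2000L + 200L)
        stop("chromLen too small for ", perChrom, " genes per chromosome; ",
             "need at least ", perChrom * (.GENE_LEN + 2L * 2000L + 200L), " bp")
    idx <- seq_len(config@nGenes)
    chromI <- ((idx - 1L) %/% perChrom) + 1L
    within <- ((idx - 1L) %% perChrom)
    start <- within * slot + .GENE_OFFSET
    GenomicRanges::GRanges(
        paste0("chr", chromI),
        IRanges::IRanges(start, width = .GENE_LEN),
        strand = ifelse(idx %% 2L == 1L, "+", "-"),
        gene_id = sprintf("gene%04d", idx),
        seqlengths = setNames(c(rep(config@chromLen, config@nChroms),
                                .CHLORO_LEN),
                              c(paste0("chr", seq_len(config@nChroms)),
                                .CHLORO_NAME)))
}

# truth classes and true per-comparison log2 fold changes
.simExpressionTruth <- function(config, geneIds) {
    n <- length(geneIds)
    abaWt <- runif(n) < config@fracAbaResponsive
    mop1Dep <- abaWt & runif(n) < config@fracMop1Dependent
    ampMut <- !abaWt & runif(n) < config@fracAmplifiedInMutant
    rddm <- runif(n) < config@fracRddmDeregulated
    eff <- function(active) ifelse(active,
        sample(c(-1, 1), n, replace = TRUE) *
            rnorm(n, config@effectLfcMean, config@effectLfcSd), 0)
    eAbaWt <- eff(abaWt)
    eAbaMut <- ifelse(abaWt & !mop1Dep, eAbaWt, 0) + eff(ampMut)
    eRddm <- eff(rddm)
    # latent log2 expression per condition, relative to WT control
    lvl <- cbind(WT_MS = 0, WT_ABA = eAbaWt, MUT_MS = eRddm,
                 MUT_ABA = eRddm + eAbaMut)
    data.frame(gene_id = geneIds,
               aba_responsive_wt = abaWt, mop1_dependent = mop1Dep,
               amplified_mutant = ampMut, rddm_deregulated = rddm,
               lfc_WTABA_vs_WTMS = lvl[, "WT_ABA"] - lvl[, "WT_MS"],
               lfc_MUTMS_vs_WTMS = lvl[, "MUT_MS"] - lvl[, "WT_MS"],
               lfc_MUTABA_vs_MUTMS = lvl[, "MUT_ABA"] - lvl[, "MUT_MS"],
               lfc_MUTABA_vs_WTABA = lvl[, "MUT_ABA"] - lvl[, "WT_ABA"],
               stringsAsFactors = FALSE)
}

# observed DE statistic tables from the truth
.simStatTables <- function(config, truth) {
    out <- list()
    for (cmp in COMPARISONS) {
        true <- truth[[paste0("lfc_", cmp)]]
        if (config@statNoiseSd > 0) {
            obs <- true + rnorm(length(true), 0, config@statNoiseSd)
            p <- 2 * pnorm(-abs(obs) / config@statNoiseSd)
        } else {
            obs <- true
            p <- ifelse(obs == 0, 1, 0)
        }
        out[[cmp]] <- data.frame(gene_id = truth$gene_id, comparison = cmp,
                                 log2fc = obs, pvalue = p,
                                 fdr = p.adjust(p, method = "BH"),
                                 stringsAsFactors = FALSE)
    }
    out
}

#' Simulate cytosine-call tables for the four conditions
#'
#' Background sites of each context are scattered over the chromosomes and
#' promoter sites are laid down on a regular grid (one CHH site per 25 bp, one
#' CG and one CHG site per 200 bp of promoter). Methylated counts are binomial
#' with context-specific success probabilities: the mutant's CHH probability
#' is multiplied genome-wide by `mutantChhScale`; wildtype-under-ABA promoter
#' CHH sites gain a factor `1 + wtAbaChhGain`. Coverage is Poisson around
#' `readDepth`; the chloroplast-like contig is unmethylated apart from the
#' non-conversion rate, which inflates the apparent methylation of every site.
#' Site positions and contexts are annotations of the toy methylome; they are
#' not derived from the genome sequence.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene models (`GRanges`) whose promoters carry the grid sites.
#' @return named list of cytosine-call data.frames:
#'   `WT_MS`, `WT_ABA`, `MUT_MS`, `MUT_ABA`, and metadata columns
#'   `compartment` (`"background"`/`"promoter"`/`"chloroplast"`).
#' @export
simulateMethylome <- function(config, genes) {
    chroms <- paste0("chr", seq_len(config@nChroms))
    baseline <- c(CG = config@baselineCG, CHG = config@baselineCHG,
                  CHH = config@baselineCHH)
    sites <- list()
    for (ctx in .methContexts) {
        nb <- config@nMethSitesPerContext
        sites[[ctx]] <- data.frame(
            chrom = sample(chroms, nb, replace = TRUE),
            pos = sample.int(config@chromLen, nb, replace = TRUE),
            strand = sample(c("+", "-"), nb, replace = TRUE),
            context = ctx, compartment = "background",
            stringsAsFactors = FALSE)
    }
    prom <- promoterRegion(genes, 2000L)
    promDF <- list()
    for (ctx in .methContexts) {
        sp <- .PROM_SPACING[[ctx]]
        offs <- seq(sp %/% 2L, 2000L - 1L, by = sp)
        nS <- length(offs)
        promDF[[ctx]] <- data.frame(
            chrom = rep(as.character(GenomeInfoDb::seqnames(prom)),
                        each = nS),
            pos = rep(BiocGenerics::start(prom), each = nS) +
                rep(offs, length(prom)),
            strand = sample(c("+", "-"), nS * length(prom), replace = TRUE),
            context = ctx, compartment = "promoter",
            stringsAsFactors = FALSE)
    }
    nc <- .CHLORO_SITES
    chloro <- data.frame(
        chrom = .CHLORO_NAME,
        pos = sort(sample.int(.CHLORO_LEN, nc)),
        strand = sample(c("+", "-"), nc, replace = TRUE),
        context = sample(.methContexts, nc, replace = TRUE),
        compartment = "chloroplast", stringsAsFactors = FALSE)
    all <- rbind(do.call(rbind, sites), do.call(rbind, promDF), chloro)
    all <- all[order(all$chrom, all$pos), , drop = FALSE]
    rownames(all) <- NULL
    # the ABA gain is positional: any CHH site lying in a promoter gets it,
    # including background sites that happen to fall there
    inProm <- IRanges::overlapsAny(
        GenomicRanges::GRanges(all$chrom, IRanges::IRanges(all$pos, width = 1L)),
        prom, ignore.strand = TRUE)

    pTrue <- function(condition) {
        p <- unname(baseline[all$context])
        p[all$compartment == "chloroplast"] <- 0
        if (condition %in% c("MUT_MS", "MUT_ABA")) {
            i <- all$context == "CHH" & all$compartment != "chloroplast"
            p[i] <- p[i] * config@mutantChhScale
        }
        if (condition == "WT_ABA") {
            i <- all$context == "CHH" & inProm &
                all$compartment != "chloroplast"
            p[i] <- p[i] * (1 + config@wtAbaChhGain)
        }
        pmin(p, 1)
    }
    out <- list()
    for (cond in c("WT_MS", "WT_ABA", "MUT_MS", "MUT_ABA")) {
        depth <- rpois(nrow(all), config@readDepth)
        p <- pTrue(cond)
        pObs <- p + (1 - p) * config@nonConversion
        df <- all
        df$n_total <- depth
        df$n_meth <- rbinom(nrow(all), depth, pObs)
        out[[cond]] <- df[, c("chrom", "pos", "strand", "context",
                              "n_meth", "n_total", "compartment")]
    }
    out
}

.simTEs <- function(config) {
    w <- config@teSuperfamilyWeights[TE_SUPERFAMILIES]
    fam <- sample(TE_SUPERFAMILIES, config@nTe, replace = TRUE,
                  prob = w / sum(w))
    len <- pmax(100L, as.integer(rpois(config@nTe, 400)))
    chroms <- paste0("chr", seq_len(config@nChroms))
    start <- sample.int(config@chromLen - max(len), config@nTe, replace = TRUE)
    GenomicRanges::GRanges(
        sample(chroms, config@nTe, replace = TRUE),
        IRanges::IRanges(start, width = len),
        strand = sample(c("+", "-"), config@nTe, replace = TRUE),
        te_id = sprintf("%s_%05d", fam, seq_len(config@nTe)),
        superfamily = fam)
}

.simGRN <- function(config, geneIds) {
    t1 <- max(3L, length(geneIds) %/% 75L)
    sizes <- pmin(t1 * 3L^(seq_len(config@grnNTiers) - 1L),
                  length(geneIds) %/% 4L)
    pool <- sample(geneIds)
    tiers <- list(); used <- 0L
    for (k in seq_along(sizes)) {
        tiers[[k]] <- pool[(used + 1L):(used + sizes[k])]
        used <- used + sizes[k]
    }
    edges <- list()
    tissues <- c("seed", "SAM", "root", "leaf")
    for (k in seq_along(tiers)) {
        nextPool <- if (k < length(tiers)) c(tiers[[k + 1L]], geneIds)
                    else geneIds
        for (reg in tiers[[k]]) {
            tg <- sample(setdiff(nextPool, reg), config@grnOutDegree)
            edges[[length(edges) + 1L]] <- data.frame(
                regulator = reg, target = tg,
                tissue = sample(tissues, length(tg), replace = TRUE),
                tier = k, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, edges)
}

.simSmallRNA <- function(config, geneIds) {
    profiled <- geneIds[seq_len(min(config@nSirnaRegions, length(geneIds)))]
    depleted <- runif(length(profiled)) < config@fracSirnaDepleted
    muWt <- stats::rlnorm(length(profiled), log(config@sirnaMeanCount), 0.6)
    libRep <- config@wtLibSize
    rows <- list()
    for (r in seq_len(config@nReps)) {
        cpmMut <- muWt * config@mirnaGlobalFactor *
            ifelse(depleted, config@mutantSirnaScale, 1)
        rows[[length(rows) + 1L]] <- data.frame(
            gene_id = profiled, genotype = "WT", replicate = r,
            count = rpois(length(profiled), muWt * libRep / 1e6))
        rows[[length(rows) + 1L]] <- data.frame(
            gene_id = profiled, genotype = "MUT", replicate = r,
            count = rpois(length(profiled), cpmMut * libRep / 1e6))
    }
    sirna <- do.call(rbind, rows)
    muMir <- stats::rlnorm(config@nMirna, log(config@mirnaMeanCount), 0.4)
    mirna <- data.frame(
        mirna_id = sprintf("zma-miR%03d", seq_len(config@nMirna)),
        count_wt = rpois(config@nMirna,
                         muMir * libRep * config@nReps / 1e6),
        count_mut = rpois(config@nMirna,
                          muMir * config@mirnaGlobalFactor *
                              libRep * config@nReps / 1e6),
        stringsAsFactors = FALSE)
    libsizes <- data.frame(genotype = c("WT", "MUT"),
                           libsize = rep(libRep * config@nReps, 2L))
    list(sirna = sirna, mirna = mirna, libsizes = libsizes,
         truth = data.frame(gene_id = profiled, sirna_depleted = depleted,
                            stringsAsFactors = FALSE))
}

#' Simulate a complete analysis bundle with known ground truth
#'
#' Generates, under one seed, a toy genome (uniform base composition plus an
#' unmethylated chloroplast-like contig), gene and TE annotations, planted
#' ABRE/CE promoter motifs, differential-expression statistic tables for the
#' four genotype-by-treatment comparisons, cytosine-call tables for the four
#' conditions, 24-nt siRNA and miRNA count tables for the two genotypes, a
#' tiered gene-regulatory network, and a per-gene truth table. All outputs are
#' deterministic given `config` (identical config and seed give byte-identical
#' files); nothing is written if the configuration is invalid.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory (created); `NULL` keeps everything
#'   in memory only.
#' @return list: `genes`, `genome`, `tes` (`GRanges`/`DNAStringSet`), `stats`
#'   (named list of DE tables), `methylome` (named list of call tables),
#'   `sirna`, `mirna`, `libsizes`, `grn`, `truth` (per-gene data.frame),
#'   `scan` (promoter motif counts), `dir`, `files`.
#' @export
simulateDataset <- function(config = simulationConfig(), outDir = NULL) {
    validObject(config)
    set.seed(config@seed)
    genes <- .simGeneLayout(config)
    geneIds <- genes$gene_id

    chroms <- setNames(
        c(rep(config@chromLen, config@nChroms), .CHLORO_LEN),
        c(paste0("chr", seq_len(config@nChroms)), .CHLORO_NAME))
    genome <- Biostrings::DNAStringSet(lapply(chroms, .randomDNA))

    truth <- .simExpressionTruth(config, geneIds)

    # motif planting in promoters: among ABA-responsive genes (either
    # genotype), plant 1-2 ABREs at rate abrePlantRate and a CE at cePlantRate
    responsive <- truth$aba_responsive_wt | truth$amplified_mutant
    getsAbre <- responsive & runif(length(geneIds)) < config@abrePlantRate
    nAbre <- ifelse(getsAbre, sample(1:2, length(geneIds), replace = TRUE), 0L)
    nCe <- as.integer(responsive & runif(length(geneIds)) < config@cePlantRate)
    prom <- promoterRegion(genes, 2000L)
    for (i in seq_along(geneIds)) {
        if (nAbre[i] + nCe[i] == 0L || BiocGenerics::width(prom)[i] < 2000L)
            next
        chrom <- as.character(GenomeInfoDb::seqnames(prom))[i]
        s <- BiocGenerics::start(prom)[i]; e <- BiocGenerics::end(prom)[i]
        planted <- plantMotifs(Biostrings::subseq(genome[[chrom]], s, e),
                               nAbre[i], nCe[i])
        Biostrings::subseq(genome[[chrom]], s, e) <- planted$seq
    }
    truth$planted_abre <- as.integer(nAbre)
    truth$planted_ce <- nCe

    # observable motif content: re-scan the finished genome
    scan <- scanPromoters(genome, genes, ceMotif = CE_MOTIF_DEFAULT)
    truth$scanned_abre <- scan$counts$n_abre[match(geneIds,
                                                   scan$counts$gene_id)]
    truth$scanned_ce <- scan$counts$n_ce[match(geneIds, scan$counts$gene_id)]
    motifRule <- truth$scanned_abre >= 2L |
        (truth$scanned_abre >= 1L & truth$scanned_ce >= 1L)
    truth$true_primary_wt <- abs(truth$lfc_WTABA_vs_WTMS) >= 0.95 & motifRule
    truth$true_primary_mut <- abs(truth$lfc_MUTABA_vs_MUTMS) >= 0.95 &
        motifRule

    stats <- .simStatTables(config, truth)
    methylome <- simulateMethylome(config, genes)
    tes <- .simTEs(config)
    grn <- .simGRN(config, geneIds)
    srna <- .simSmallRNA(config, geneIds)
    truth <- merge(truth, srna$truth, by = "gene_id", all.x = TRUE,
                   sort = TRUE)

    out <- list(genes = genes, genome = genome, tes = tes, stats = stats,
                methylome = methylome, sirna = srna$sirna,
                mirna = srna$mirna, libsizes = srna$libsizes, grn = grn,
                truth = truth, scan = scan, dir = outDir)
    if (!is.null(outDir)) out$files <- .writeBundle(out, config, outDir)
    out
}

.writeBundle <- function(bundle, config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outDir, x)
    files <- character()
    Biostrings::writeXStringSet(bundle$genome, fp("genome.fa"))
    files <- c(files, "genome.fa")
    writeGeneModelsGFF3(bundle$genes, fp("genes.gff3"))
    files <- c(files, "genes.gff3")
    teOut <- GenomicRanges::granges(bundle$tes)
    teOut$source <- "epiABA"; teOut$type <- "transposable_element"
    teOut$ID <- bundle$tes$te_id; teOut$superfamily <- bundle$tes$superfamily
    rtracklayer::export(teOut, fp("te.gff3"), format = "gff3")
    files <- c(files, "te.gff3")
    for (cmp in names(bundle$stats)) {
        f <- paste0("de_", cmp, ".tsv")
        writeTSV(bundle$stats[[cmp]][, c("gene_id", "log2fc", "pvalue",
                                         "fdr")], fp(f))
        files <- c(files, f)
    }
    for (cond in names(bundle$methylome)) {
        f <- paste0("meth_", cond, ".tsv")
        writeTSV(bundle$methylome[[cond]], fp(f))
        files <- c(files, f)
    }
    writeTSV(bundle$sirna, fp("sirna_counts.tsv"))
    writeTSV(bundle$mirna, fp("mirna_counts.tsv"))
    writeTSV(bundle$libsizes, fp("libsizes.tsv"))
    writeTSV(bundle$grn, fp("grn.tsv"))
    writeTSV(bundle$truth, fp("truth.tsv"))
    files <- c(files, "sirna_counts.tsv", "mirna_counts.tsv", "libsizes.tsv",
               "grn.tsv", "truth.tsv")
    cfgList <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfgList) <- slotNames(config)
    cfgList$teSuperfamilyWeights <- as.list(cfgList$teSuperfamilyWeights)
    yaml::write_yaml(cfgList, fp("config.yaml"))
    files <- c(files, "config.yaml")
    sums <- tools::md5sum(file.path(outDir, files))
    manifest <- list(files = setNames(as.list(unname(sums)), files),
                     seed = config@seed)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    c(files, "manifest.json")
}
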