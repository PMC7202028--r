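#' Run the full analysis pipeline on a dataset bundle
#'
#' Executes every stage in dependency order on a bundle directory as written
#' by [simulateDataset()] (or assembled by hand in the same formats):
#' DEG group classification and overlap accounting; genome-wide and promoter
#' methylation summaries with conversion-rate estimation and differential
#' promoter calls; ABRE scanning, primary-target classification and
#' regulatory-network cascade prediction; 24-nt siRNA depletion with
#' miRNA-anchored normalization; and TE superfamily context profiling.
#' Stages whose input files are missing are skipped and recorded; reruns on
#' the same inputs give identical reports.
#'
#' @param bundleDir directory containing the bundle files.
#' @param config an [AnalysisConfig-class].
#' @param outDir optional directory to write `report.json` and per-stage TSVs.
#' @param ceMotif coupling-element pattern for promoter scanning, or `NULL`
#'   (strict mode, ABRE-only).
#' @return the report, a nested list with elements `groups`, `methylation`,
#'   `cascade`, `sirna`, `te`, `provenance`, and `skipped`.
#' @export
runPipeline <- function(bundleDir, config = analysisConfig(), outDir = NULL,
                        ceMotif = NULL) {
    fp <- function(x) file.path(bundleDir, x)
    need <- function(x) {
        if (!file.exists(fp(x))) stop("missing bundle file: ", x)
        fp(x)
    }
    report <- list(skipped = character())
    genes <- readGeneModels(need("genes.gff3"))

    ## DEG groups
    stats <- do.call(rbind, lapply(COMPARISONS, function(cmp)
        readComparisonStats(need(paste0("de_", cmp, ".tsv")), cmp)))
    assignments <- classifyGroups(stats, config)
    ov <- overlapSummary(assignments)
    report$groups <- list(summary = ov[c("total_memberships", "total_genes",
                                         "shared", "unique",
                                         "shared_memberships")],
                          per_group = as.list(ov$per_group),
                          n_contra = length(ov$contra))

    ## Methylation
    methFiles <- paste0("meth_", c("WT_MS", "WT_ABA", "MUT_MS", "MUT_ABA"),
                        ".tsv")
    if (all(file.exists(fp(methFiles)))) {
        calls <- lapply(setNames(methFiles,
                                 c("WT_MS", "WT_ABA", "MUT_MS", "MUT_ABA")),
                        function(f) readCytosineCalls(fp(f)))
        nonConv <- vapply(calls, function(x)
            1 - conversionRate(x, contig = .CHLORO_NAME), numeric(1))
        poolAdj <- function(cond, ctx, regionCalls = NULL) {
            x <- calls[[cond]]
            x <- x[x$chrom != .CHLORO_NAME, , drop = FALSE]
            adjustForNonConversion(weightedMC(x, context = ctx)$mc,
                                   nonConv[[cond]])
        }
        gw <- list()
        for (ctx in .methContexts) {
            gw[[ctx]] <- list(
                aba_wt = relativeDiff(poolAdj("WT_ABA", ctx),
                                      poolAdj("WT_MS", ctx)),
                mutant_vs_wt = relativeDiff(poolAdj("MUT_MS", ctx),
                                            poolAdj("WT_MS", ctx)))
        }
        tiles <- lapply(calls, function(x)
            tilePromoters(genes, x[x$chrom != .CHLORO_NAME, ], "CHH", config))
        meta <- lapply(tiles, metageneProfile)
        pm <- lapply(calls, function(x)
            promoterMethylation(genes, x[x$chrom != .CHLORO_NAME, ], "CHH",
                                config))
        both <- pm$WT_ABA$evaluable & pm$WT_MS$evaluable
        dmCall <- callDifferentialPromoter(pm$WT_ABA$mc[both],
                                           pm$WT_MS$mc[both], "CHH", config)
        report$methylation <- list(
            conversion_rate = as.list(1 - nonConv),
            genome_wide_relative_diff = gw,
            metagene_chh = meta,
            n_promoters_evaluable = sum(both),
            n_differential_chh_promoters = sum(dmCall != "none"))
        report$methylation$differential_calls <- data.frame(
            gene_id = pm$WT_ABA$gene_id[both], call = dmCall,
            stringsAsFactors = FALSE)
    } else {
        report$skipped <- c(report$skipped, "methylation")
    }

    ## Motif scan + cascade (mutant ABA response)
    if (file.exists(fp("genome.fa")) && file.exists(fp("grn.tsv"))) {
        scan <- scanPromoters(fp("genome.fa"), genes, config,
                              ceMotif = ceMotif)
        m <- groupMembership(assignments)
        degMut <- rownames(m)[m[, "V"] | m[, "VI"]]
        sc <- scan$counts
        pc <- classifyPrimary(sc$gene_id, sc$n_abre, sc$n_ce,
                              sc$gene_id %in% degMut)
        primaries <- pc$gene_id[pc$is_primary]
        grn <- readGRN(fp("grn.tsv"))
        secondary <- predictSecondary(primaries, grn, degMut)
        report$cascade <- list(
            n_deg = length(degMut),
            n_primary = length(primaries),
            n_secondary = length(secondary),
            explained_pct = if (length(degMut))
                explainedFraction(length(primaries), length(secondary),
                                  length(degMut)) else NA_real_)
        report$cascade$primary_calls <- pc
    } else {
        report$skipped <- c(report$skipped, "cascade")
    }

    ## siRNA depletion
    sFiles <- c("sirna_counts.tsv", "mirna_counts.tsv", "libsizes.tsv")
    if (all(file.exists(fp(sFiles)))) {
        mir <- readTSV(fp("mirna_counts.tsv"),
                       required = c("mirna_id", "count_wt", "count_mut"))
        lib <- readTSV(fp("libsizes.tsv"),
                       required = c("genotype", "libsize"))
        libsizes <- setNames(lib$libsize, lib$genotype)
        nf <- mirnaNormFactor(setNames(mir$count_wt, mir$mirna_id),
                              setNames(mir$count_mut, mir$mirna_id),
                              libsizes[["WT"]], libsizes[["MUT"]])
        counts <- readTSV(fp("sirna_counts.tsv"),
                          required = c("gene_id", "genotype", "replicate",
                                       "count"))
        prof <- buildSiRNAProfiles(counts, libsizes, nf$value)
        dep <- callDepleted(prof, libsizes, nf$value, config)
        subsets <- c(as.list(setNames(GROUPS, GROUPS)),
                     list(up_in_mutant = c("III", "V", "VII"),
                          down_in_mutant = c("IV", "VI", "VIII")))
        tab <- suppressWarnings(
            groupDepletionTable(assignments, dep, subsets))
        report$sirna <- list(norm_factor = nf$value,
                             n_mirna_used = length(nf$ratios),
                             depletion_table = tab)
    } else {
        report$skipped <- c(report$skipped, "sirna")
    }

    ## TE context
    if (file.exists(fp("te.gff3")) && !is.null(report$cascade)) {
        tes <- readTEAnnotation(fp("te.gff3"))
        m <- groupMembership(assignments)
        pc <- report$cascade$primary_calls
        motifGenes <- pc$gene_id[pc$is_primary]
        upG <- intersect(motifGenes, rownames(m)[m[, "V"]])
        dnG <- intersect(motifGenes, rownames(m)[m[, "VI"]])
        bg <- superfamilyDistribution(tes$superfamily)
        teOne <- function(ids) {
            if (!length(ids)) return(NULL)
            rec <- flankingTEs(genes[ids], tes, config@flankLen)
            if (!nrow(rec)) return(NULL)
            fg <- superfamilyDistribution(rec)
            list(n_te = length(unique(rec$te_id)), pct = as.list(fg),
                 delta = as.list(distributionDelta(fg, bg)))
        }
        report$te <- list(background_pct = as.list(bg),
                          upregulated = teOne(upG),
                          downregulated = teOne(dnG))
    } else {
        report$skipped <- c(report$skipped, "te")
    }

    report$provenance <- list(
        bundle = normalizePath(bundleDir),
        config_seed = config@seed,
        package_version = as.character(utils::packageVersion("epiABA")))

    if (!is.null(outDir)) .writeReport(report, assignments, outDir)
    report
}

.writeReport <- function(report, assignments, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTSV(assignments, file.path(outDir, "group_assignments.tsv"))
    if (!is.null(report$methylation$differential_calls))
        writeTSV(report$methylation$differential_calls,
                 file.path(outDir, "differential_promoters_chh.tsv"))
    if (!is.null(report$cascade$primary_calls))
        writeTSV(report$cascade$primary_calls,
                 file.path(outDir, "primary_targets.tsv"))
    if (!is.null(report$sirna$depletion_table))
        writeTSV(report$sirna$depletion_table,
                 file.path(outDir, "sirna_depletion.tsv"))
    slim <- report
    slim$methylation$differential_calls <- NULL
    slim$cascade$primary_calls <- NULL
    slim$sirna$depletion_table <- NULL
    slim$methylation$metagene_chh <-
        lapply(slim$methylation$metagene_chh, as.list)
    jsonlite::write_json(slim, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(outDir)
}
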