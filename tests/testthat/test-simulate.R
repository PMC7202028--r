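smallCfg <- function(seed, ...)
    simulationConfig(seed = seed, nGenes = 80, nMethSitesPerContext = 500L,
                     nSirnaRegions = 80L, nTe = 100L, ...)

test_that("identical configuration and seed give byte-identical bundles", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    b1 <- simulateDataset(smallCfg(101), d1)
    b2 <- simulateDataset(smallCfg(101), d2)
    for (f in setdiff(b1$files, "manifest.json")) {
        expect_equal(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
    }
    b3 <- simulateDataset(smallCfg(102), withr::local_tempdir())
    expect_false(identical(b1$truth$lfc_WTABA_vs_WTMS,
                           b3$truth$lfc_WTABA_vs_WTMS))
})

test_that("invalid configurations fail before any file is written", {
    expect_error(simulationConfig(1, fracAbaResponsive = 1.2), "proportions")
    expect_error(simulationConfig(1, mutantChhScale = 0), "scale")
    expect_error(simulationConfig(1, bogus = 3), "unknown")
    d <- file.path(withr::local_tempdir(), "never")
    cfg <- smallCfg(1)
    cfg@chromLen <- 1000L   # too small for the gene layout
    expect_error(simulateDataset(cfg, d), "chromLen")
    expect_false(dir.exists(d))
})

test_that("a null configuration produces (almost) no significant calls", {
    b <- simulateDataset(simulationConfig(
        seed = 41, nGenes = 200, fracAbaResponsive = 0,
        fracMop1Dependent = 0, fracAmplifiedInMutant = 0,
        fracRddmDeregulated = 0, nMethSitesPerContext = 100L))
    a <- classifyGroups(do.call(rbind, b$stats), analysisConfig())
    # all true effects are zero; BH controls false positives at the 5% FDR
    expect_lte(nrow(a), ceiling(0.01 * 200 * 4))
})

test_that("truth-table fractions concentrate around configured rates", {
    b <- simulateDataset(simulationConfig(seed = 43, nGenes = 2000,
                                          chromLen = 6000000L,
                                          nMethSitesPerContext = 100L))
    expect_equal(nrow(b$truth), 2000L)
    expect_false(anyDuplicated(b$truth$gene_id) > 0)
    # binomial 3-sigma bands around the configured proportions
    f <- mean(b$truth$aba_responsive_wt)
    expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
    fa <- mean(b$truth$amplified_mutant[!b$truth$aba_responsive_wt])
    expect_lt(abs(fa - 0.30), 4 * sqrt(0.3 * 0.7 / sum(!b$truth$aba_responsive_wt)))
})

test_that("motif planting writes the requested occurrences into clean backgrounds", {
    set.seed(5)
    bg <- Biostrings::DNAString(paste(rep("A", 2000), collapse = ""))
    out <- plantMotifs(bg, nAbre = 2, nCe = 1)
    h <- scanMotif(out$seq, ABRE_MOTIF)
    expect_equal(nrow(h), 2L)
    expect_setequal(h$start, out$positions$start[out$positions$motif == "ABRE"])
    expect_equal(nrow(scanMotif(out$seq, CE_MOTIF_DEFAULT)), 1L)
    # negative control: a CACG-free alphabet holds no ABRE
    expect_equal(nrow(scanMotif(bg, ABRE_MOTIF)), 0L)
    expect_error(plantMotifs(Biostrings::DNAString("ACGT"), 2, 1),
                 "too short")
})

test_that("the methylome encodes the configured context-specific effects", {
    cfg <- simulationConfig(seed = 47, nGenes = 200,
                            nMethSitesPerContext = 4000L)
    genes <- epiABA:::.simGeneLayout(cfg)
    set.seed(cfg@seed)
    meth <- simulateMethylome(cfg, genes)
    # chloroplast-like contig shows only non-conversion
    nc <- 1 - conversionRate(meth$WT_MS, contig = "chrC")
    expect_lt(abs(nc - 0.005), 0.002)
    # mutant CHH reduction is genome-wide; CG/CHG untouched
    adjCHH <- function(calls) {
        ncC <- 1 - conversionRate(calls, contig = "chrC")
        adjustForNonConversion(
            weightedMC(calls[calls$chrom != "chrC", ], context = "CHH")$mc,
            ncC)
    }
    expect_lt(abs(adjCHH(meth$MUT_MS) / adjCHH(meth$WT_MS) - 0.32), 0.05)
    cgWt <- weightedMC(meth$WT_MS, context = "CG")$mc
    cgMut <- weightedMC(meth$MUT_MS, context = "CG")$mc
    expect_lt(abs(cgMut / cgWt - 1), 0.02)
    # the ABA CHH gain is confined to wildtype promoters
    cfg0 <- simulationConfig(seed = 47, nGenes = 200, wtAbaChhGain = 0,
                             nMethSitesPerContext = 4000L)
    set.seed(cfg0@seed)
    meth0 <- simulateMethylome(cfg0, genes)
    pm <- promoterMethylation(genes, meth0$WT_ABA, "CHH")
    pm0 <- promoterMethylation(genes, meth0$WT_MS, "CHH")
    d0 <- mean(pm$mc - pm0$mc, na.rm = TRUE)
    expect_lt(abs(d0), 0.004)   # null effect centres at zero
})

test_that("wildtype ABA promoter gain shows up tile by tile in the metagene", {
    b <- simulateDataset(simulationConfig(seed = 53, nGenes = 200,
                                          nMethSitesPerContext = 500L,
                                          readDepth = 20))
    cfgA <- analysisConfig()
    tAba <- tilePromoters(b$genes, b$methylome$WT_ABA, "CHH", cfgA)
    tCtl <- tilePromoters(b$genes, b$methylome$WT_MS, "CHH", cfgA)
    mAba <- metageneProfile(tAba); mCtl <- metageneProfile(tCtl)
    expect_gt(mean(mAba$mean_mc > mCtl$mean_mc), 0.5)
    # mutant lies below wildtype at (essentially) every tile
    tMut <- tilePromoters(b$genes, b$methylome$MUT_MS, "CHH", cfgA)
    mMut <- metageneProfile(tMut)
    expect_gt(mean(mMut$mean_mc < mCtl$mean_mc), 0.95)
})
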