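#' @import methods
#' @importFrom stats median p.adjust pnorm rbinom rnorm rpois runif setNames
#'   binom.test quantile
#' @importFrom utils read.delim write.table
NULL

#' Analysis configuration
#'
#' Holds every threshold the pipeline applies: differential-expression cutoffs,
#' promoter geometry, bisulfite coverage/site/level filters for genome-wide and
#' promoter modes, differential-methylation-call thresholds, and the 24-nt
#' siRNA depletion rule. All thresholds mirror the defaults used throughout
#' the analysis and are exposed so each rule is independently testable.
#'
#' @slot lfcMin minimum absolute log2 fold change for a DEG call (log2 units).
#' @slot fdrMax maximum FDR for a DEG call (inclusive).
#' @slot cpmMin counts-per-million floor for the low-abundance filter.
#' @slot promoterLen promoter length upstream of the TSS (bp).
#' @slot tileLen promoter tile length (bp).
#' @slot flankLen flank length for TE context search (bp).
#' @slot gwMinCoverage,gwMinSites genome-wide mode evaluability filters
#'   (mean reads per site; methylation-context sites per region).
#' @slot prMinCoverage,prMinSites promoter mode evaluability filters.
#' @slot levelMinCG,levelMinCHG,levelMinCHH minimum weighted methylation for a
#'   region to count as methylated, per context (proportions).
#' @slot diffAbsCGCHG absolute-difference threshold (percentage points) for a
#'   differential call in the CG/CHG contexts.
#' @slot diffAbsCHH absolute-difference threshold (percentage points) for the
#'   CHH context.
#' @slot chhLowMax CHH rule: the lower of the two samples must be at or below
#'   this methylation level (proportion).
#' @slot cgHyperMin minimum CG gain (percentage points) for a
#'   CG-hypermethylation call.
#' @slot sirnaLfcMax corrected log2 fold change at or below which a promoter
#'   is a depletion candidate.
#' @slot sirnaPMax binomial-test p-value cutoff for a depletion call.
#' @slot sirnaCpmMin pooled-CPM floor (in at least one genotype) for a promoter
#'   to be assessed at all.
#' @slot seed integer random seed recorded for provenance.
#' @export
setClass("AnalysisConfig", representation(
    lfcMin = "numeric", fdrMax = "numeric", cpmMin = "numeric",
    promoterLen = "integer", tileLen = "integer", flankLen = "integer",
    gwMinCoverage = "numeric", gwMinSites = "integer",
    prMinCoverage = "numeric", prMinSites = "integer",
    levelMinCG = "numeric", levelMinCHG = "numeric", levelMinCHH = "numeric",
    diffAbsCGCHG = "numeric", diffAbsCHH = "numeric",
    chhLowMax = "numeric", cgHyperMin = "numeric",
    sirnaLfcMax = "numeric", sirnaPMax = "numeric", sirnaCpmMin = "numeric",
    seed = "integer"
))

setValidity("AnalysisConfig", function(object) {
    msg <- character()
    lens <- c(promoterLen = object@promoterLen, tileLen = object@tileLen,
              flankLen = object@flankLen)
    if (any(lens <= 0L)) msg <- c(msg, "all lengths must be > 0")
    if (object@promoterLen %% object@tileLen != 0L)
        msg <- c(msg, "promoterLen must be a multiple of tileLen")
    props <- c(object@fdrMax, object@levelMinCG, object@levelMinCHG,
               object@levelMinCHH, object@chhLowMax, object@sirnaPMax)
    if (any(props < 0 | props > 1))
        msg <- c(msg, "proportion-valued thresholds must lie in [0, 1]")
    if (object@lfcMin < 0) msg <- c(msg, "lfcMin must be >= 0")
    if (object@cpmMin < 0) msg <- c(msg, "cpmMin must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an analysis configuration
#'
#' Defaults: |log2FC| >= 0.95 and FDR <= 0.05 for DEG calls, 0.58 CPM
#' low-abundance floor, 2-kb promoters in 100-bp tiles, genome-wide methylation
#' filters of 5x coverage / 2 sites (promoter mode 2x / 2 sites), context level
#' gates of 10% (CG/CHG) and 1% (CHH), differential-promoter thresholds of 40
#' points (CG/CHG) and 15 points with a 5% low-sample gate (CHH), 10-point CG
#' hypermethylation gain, and a siRNA depletion rule of corrected log2FC <= -1
#' with a binomial p <= 0.05.
#'
#' @param lfcMin,fdrMax,cpmMin DEG thresholds.
#' @param promoterLen,tileLen,flankLen geometry in bp.
#' @param gwMinCoverage,gwMinSites,prMinCoverage,prMinSites evaluability
#'   filters.
#' @param levelMinCG,levelMinCHG,levelMinCHH methylated-region level gates.
#' @param diffAbsCGCHG,diffAbsCHH,chhLowMax,cgHyperMin differential-call
#'   thresholds.
#' @param sirnaLfcMax,sirnaPMax,sirnaCpmMin siRNA depletion rule.
#' @param seed integer seed recorded for provenance.
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig()
#' lfcMin(cfg)
#' @export
analysisConfig <- function(lfcMin = 0.95, fdrMax = 0.05, cpmMin = 0.58,
                           promoterLen = 2000L, tileLen = 100L,
                           flankLen = 2000L,
                           gwMinCoverage = 5, gwMinSites = 2L,
                           prMinCoverage = 2, prMinSites = 2L,
                           levelMinCG = 0.10, levelMinCHG = 0.10,
                           levelMinCHH = 0.01,
                           diffAbsCGCHG = 40, diffAbsCHH = 15,
                           chhLowMax = 0.05, cgHyperMin = 10,
                           sirnaLfcMax = -1, sirnaPMax = 0.05,
                           sirnaCpmMin = 1,
                           seed = 1L) {
    new("AnalysisConfig",
        lfcMin = lfcMin, fdrMax = fdrMax, cpmMin = cpmMin,
        promoterLen = as.integer(promoterLen), tileLen = as.integer(tileLen),
        flankLen = as.integer(flankLen),
        gwMinCoverage = gwMinCoverage, gwMinSites = as.integer(gwMinSites),
        prMinCoverage = prMinCoverage, prMinSites = as.integer(prMinSites),
        levelMinCG = levelMinCG, levelMinCHG = levelMinCHG,
        levelMinCHH = levelMinCHH,
        diffAbsCGCHG = diffAbsCGCHG, diffAbsCHH = diffAbsCHH,
        chhLowMax = chhLowMax, cgHyperMin = cgHyperMin,
        sirnaLfcMax = sirnaLfcMax, sirnaPMax = sirnaPMax,
        sirnaCpmMin = sirnaCpmMin,
        seed = as.integer(seed))
}

#' @describeIn analysisConfig minimum absolute log2 fold change.
#' @param x an `AnalysisConfig`.
#' @export
lfcMin <- function(x) x@lfcMin
#' @describeIn analysisConfig maximum FDR.
#' @export
fdrMax <- function(x) x@fdrMax
#' @describeIn analysisConfig promoter length in bp.
#' @export
promoterLen <- function(x) x@promoterLen
#' @describeIn analysisConfig tile length in bp.
#' @export
tileLen <- function(x) x@tileLen

setMethod("show", "AnalysisConfig", function(object) {
    cat("AnalysisConfig\n")
    cat(sprintf("  DEG: |log2FC| >= %g, FDR <= %g, CPM >= %g\n",
                object@lfcMin, object@fdrMax, object@cpmMin))
    cat(sprintf("  promoter %d bp / %d bp tiles; TE flank %d bp\n",
                object@promoterLen, object@tileLen, object@flankLen))
    cat(sprintf("  mC filters: genome-wide %gx/%d sites; promoter %gx/%d sites\n",
                object@gwMinCoverage, object@gwMinSites,
                object@prMinCoverage, object@prMinSites))
    cat(sprintf("  differential: CG/CHG >= %g pts; CHH >= %g pts (low sample <= %g); CG hyper >= %g pts\n",
                object@diffAbsCGCHG, object@diffAbsCHH, object@chhLowMax,
                object@cgHyperMin))
    cat(sprintf("  siRNA: corrected log2FC <= %g, binomial p <= %g, CPM >= %g\n",
                object@sirnaLfcMax, object@sirnaPMax, object@sirnaCpmMin))
})

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' conditions: four genotype-by-treatment groups (wildtype and an RdDM-deficient
#' mop1-1 mutant, with and without ABA), a genotype-wide 68% CHH methylation
#' reduction in the mutant (`mutantChhScale = 0.32`), an ABA-induced 11.1%
#' relative CHH gain restricted to wildtype promoters (`wtAbaChhGain = 0.111`),
#' a global miRNA compositional fold change of 2.2 between mutant and wildtype
#' small-RNA libraries, and planted ABRE/CE promoter motifs.
#'
#' @slot seed integer seed; identical config + seed gives identical output.
#' @slot nGenes,nChroms,chromLen genome geometry.
#' @slot fracAbaResponsive fraction of genes truly ABA-responsive in wildtype.
#' @slot fracMop1Dependent fraction of the ABA-responsive genes whose response
#'   requires MOP1 (responsive in wildtype only).
#' @slot fracAmplifiedInMutant fraction of genes ABA-responsive only in the
#'   mutant (the amplified response).
#' @slot fracRddmDeregulated fraction of genes mis-regulated in the untreated
#'   mutant (loss-of-RdDM effect).
#' @slot effectLfcMean,effectLfcSd true log2 fold-change effect distribution.
#' @slot statNoiseSd sd of the Gaussian noise on observed log2FC (0 gives
#'   noiseless statistics).
#' @slot baselineCG,baselineCHG,baselineCHH per-context methylation levels.
#' @slot mutantChhScale multiplicative CHH factor in the mutant.
#' @slot wtAbaChhGain relative promoter CHH gain under ABA in wildtype.
#' @slot readDepth mean bisulfite coverage per cytosine.
#' @slot nMethSitesPerContext methylome size: background sites simulated per
#'   context (promoter sites are added on top).
#' @slot nonConversion bisulfite non-conversion rate (apparent methylation on
#'   the unmethylated chloroplast-like contig).
#' @slot nSirnaRegions number of promoters profiled for 24-nt siRNAs.
#' @slot fracSirnaDepleted fraction of profiled promoters truly depleted.
#' @slot mutantSirnaScale residual siRNA abundance factor at depleted
#'   promoters.
#' @slot mirnaGlobalFactor mutant/wildtype miRNA CPM compositional factor.
#' @slot nMirna,mirnaMeanCount miRNA panel size and mean count.
#' @slot sirnaMeanCount mean wildtype 24-nt read count per promoter.
#' @slot wtLibSize,nReps small-RNA library size and replicates per genotype.
#' @slot nTe,teSuperfamilyWeights TE annotation size and superfamily weights.
#' @slot grnNTiers,grnOutDegree regulatory-network shape.
#' @slot abrePlantRate,cePlantRate per-promoter motif planting probabilities
#'   among true ABA-responsive genes.
#' @export
setClass("SimulationConfig", representation(
    seed = "integer",
    nGenes = "integer", nChroms = "integer", chromLen = "integer",
    fracAbaResponsive = "numeric", fracMop1Dependent = "numeric",
    fracAmplifiedInMutant = "numeric", fracRddmDeregulated = "numeric",
    effectLfcMean = "numeric", effectLfcSd = "numeric", statNoiseSd = "numeric",
    baselineCG = "numeric", baselineCHG = "numeric", baselineCHH = "numeric",
    mutantChhScale = "numeric", wtAbaChhGain = "numeric",
    readDepth = "numeric", nMethSitesPerContext = "integer",
    nonConversion = "numeric",
    nSirnaRegions = "integer", fracSirnaDepleted = "numeric",
    mutantSirnaScale = "numeric", mirnaGlobalFactor = "numeric",
    nMirna = "integer", mirnaMeanCount = "numeric", sirnaMeanCount = "numeric",
    wtLibSize = "numeric", nReps = "integer",
    nTe = "integer", teSuperfamilyWeights = "numeric",
    grnNTiers = "integer", grnOutDegree = "integer",
    abrePlantRate = "numeric", cePlantRate = "numeric"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    props <- c(object@fracAbaResponsive, object@fracMop1Dependent,
               object@fracAmplifiedInMutant, object@fracRddmDeregulated,
               object@baselineCG, object@baselineCHG, object@baselineCHH,
               object@nonConversion, object@fracSirnaDepleted,
               object@abrePlantRate, object@cePlantRate)
    if (any(props < 0 | props > 1))
        msg <- c(msg, "proportions must lie in [0, 1]")
    scales <- c(object@mutantChhScale, object@mutantSirnaScale,
                object@mirnaGlobalFactor)
    if (any(scales <= 0)) msg <- c(msg, "scale factors must be > 0")
    if (object@wtAbaChhGain < 0) msg <- c(msg, "wtAbaChhGain must be >= 0")
    if (object@baselineCHH * (1 + object@wtAbaChhGain) > 1)
        msg <- c(msg, "baselineCHH * (1 + wtAbaChhGain) must be <= 1")
    if (any(c(object@nGenes, object@nChroms, object@chromLen, object@nTe,
              object@nMirna, object@nSirnaRegions, object@nReps) < 1L))
        msg <- c(msg, "counts must be >= 1")
    if (length(object@teSuperfamilyWeights) != length(TE_SUPERFAMILIES) ||
        is.null(names(object@teSuperfamilyWeights)) ||
        !identical(sort(names(object@teSuperfamilyWeights)),
                   sort(TE_SUPERFAMILIES)))
        msg <- c(msg, "teSuperfamilyWeights must be named by the 13 superfamily codes")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning of every field. Defaults give a
#' 1,000-gene toy genome on two 2-Mb chromosomes plus a 100-kb unmethylated
#' chloroplast-like contig, with the study's effect sizes: mutant CHH scale
#' 0.32 (a 68% reduction), wildtype ABA promoter CHH gain 0.111, miRNA global
#' factor 2.2, and a quarter of profiled promoters truly siRNA-depleted at a
#' residual scale of 0.25.
#'
#' @param seed integer seed.
#' @param ... any slot listed in [SimulationConfig-class], passed by name.
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(seed = 7, nGenes = 100)
#' @export
simulationConfig <- function(seed = 1L, ...) {
    defaults <- list(
        seed = 1L, nGenes = 1000L, nChroms = 2L, chromLen = 2000000L,
        fracAbaResponsive = 0.25, fracMop1Dependent = 0.20,
        fracAmplifiedInMutant = 0.30, fracRddmDeregulated = 0.05,
        effectLfcMean = 2.0, effectLfcSd = 0.6, statNoiseSd = 0.2,
        baselineCG = 0.80, baselineCHG = 0.65, baselineCHH = 0.04,
        mutantChhScale = 0.32, wtAbaChhGain = 0.111,
        readDepth = 10, nMethSitesPerContext = 20000L, nonConversion = 0.005,
        nSirnaRegions = 400L, fracSirnaDepleted = 0.25,
        mutantSirnaScale = 0.25, mirnaGlobalFactor = 2.2,
        nMirna = 50L, mirnaMeanCount = 500, sirnaMeanCount = 80,
        wtLibSize = 2e6, nReps = 2L,
        nTe = 500L, teSuperfamilyWeights = c(
            RLC = 0.15, RLG = 0.20, RLX = 0.05, RIL = 0.03, RIT = 0.02,
            RST = 0.02, DTA = 0.07, DTC = 0.08, DTH = 0.15, DTM = 0.08,
            DTT = 0.10, DTX = 0.02, DHH = 0.03),
        grnNTiers = 3L, grnOutDegree = 8L,
        abrePlantRate = 0.5, cePlantRate = 0.3)
    args <- list(...)
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(args)] <- args
    defaults$seed <- as.integer(seed)
    ints <- c("nGenes", "nChroms", "chromLen", "nMethSitesPerContext",
              "nSirnaRegions", "nMirna", "nReps", "nTe", "grnNTiers",
              "grnOutDegree")
    defaults[ints] <- lapply(defaults[ints], as.integer)
    do.call(new, c(list("SimulationConfig"), defaults))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig (seed", object@seed, ")\n")
    cat(sprintf("  genome: %d genes on %d x %d bp chromosomes + chloroplast-like contig\n",
                object@nGenes, object@nChroms, object@chromLen))
    cat(sprintf("  ABA-responsive %.0f%%, MOP1-dependent %.0f%%, mutant-amplified %.0f%%\n",
                100 * object@fracAbaResponsive, 100 * object@fracMop1Dependent,
                100 * object@fracAmplifiedInMutant))
    cat(sprintf("  mC baselines CG/CHG/CHH: %.2f/%.2f/%.3f; mutant CHH x%.2f; WT+ABA promoter CHH +%.1f%%\n",
                object@baselineCG, object@baselineCHG, object@baselineCHH,
                object@mutantChhScale, 100 * object@wtAbaChhGain))
    cat(sprintf("  siRNA: %d promoters, %.0f%% depleted (x%.2f); miRNA factor %.1f\n",
                object@nSirnaRegions, 100 * object@fracSirnaDepleted,
                object@mutantSirnaScale, object@mirnaGlobalFactor))
})
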