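#' Read per-cytosine bisulfite calls
#'
#' Expected columns: `chrom`, `pos` (1-based), `strand`, `context` (CG, CHG or
#' CHH), `n_meth` (reads read as C) and `n_total` (reads read as C or T).
#'
#' @param path TSV file.
#' @return data.frame of cytosine calls.
#' @export
readCytosineCalls <- function(path) {
    df <- readTSV(path, required = c("chrom", "pos", "strand", "context",
                                     "n_meth", "n_total"))
    .validateCalls(df)
    df
}

.validateCalls <- function(calls) {
    bad <- !calls$context %in% .methContexts
    if (any(bad))
        stop("unknown methylation context: ",
             paste(unique(calls$context[bad]), collapse = ", "))
    over <- calls$n_meth > calls$n_total | calls$n_meth < 0
    if (any(over)) {
        i <- which(over)[1L]
        stop("n_meth exceeds n_total at ", calls$chrom[i], ":", calls$pos[i])
    }
    invisible(calls)
}

#' Cytosine calls as genomic ranges
#'
#' @param calls data.frame of cytosine calls.
#' @return `GRanges` of width-1 sites carrying `context`, `n_meth`, `n_total`.
#' @export
callsAsGRanges <- function(calls) {
    GenomicRanges::GRanges(calls$chrom,
                           IRanges::IRanges(calls$pos, width = 1L),
                           strand = calls$strand,
                           context = calls$context,
                           n_meth = calls$n_meth, n_total = calls$n_total)
}

#' Weighted methylation of a region
#'
#' Pooled (weighted) methylation: the sum of methylated read counts over the
#' sum of total read counts across the in-region cytosines of one context —
#' not the mean of per-site ratios. A region with no covered site of the
#' context is non-evaluable and its `mc` is `NA`.
#'
#' @param calls data.frame of cytosine calls.
#' @param region optional single-range `GRanges` (or `NULL` for all sites).
#' @param context one of CG, CHG, CHH, or `NULL` to pool all contexts.
#' @return list: `mc` (proportion), `n_sites`, `coverage` (mean reads/site),
#'   `evaluable`.
#' @examples
#' calls <- data.frame(chrom = "chr1", pos = c(10, 20), strand = "+",
#'                     context = "CHH", n_meth = c(3, 0), n_total = c(4, 4))
#' weightedMC(calls)$mc  # 3/8
#' @export
weightedMC <- function(calls, region = NULL, context = NULL) {
    .validateCalls(calls)
    keep <- rep(TRUE, nrow(calls))
    if (!is.null(context)) {
        context <- match.arg(context, .methContexts)
        keep <- keep & calls$context == context
    }
    if (!is.null(region)) {
        stopifnot(length(region) == 1L)
        keep <- keep &
            calls$chrom == as.character(GenomeInfoDb::seqnames(region)) &
            calls$pos >= BiocGenerics::start(region) &
            calls$pos <= BiocGenerics::end(region)
    }
    sub <- calls[keep, , drop = FALSE]
    n <- nrow(sub)
    tot <- sum(sub$n_total)
    covered <- n > 0L && tot > 0L
    list(mc = if (covered) sum(sub$n_meth) / tot else NA_real_,
         n_sites = n,
         coverage = if (n > 0L) tot / n else 0,
         evaluable = covered)
}

#' Bisulfite conversion rate from an unmethylated contig
#'
#' All cytosines of the designated contig (chloroplast-like, biologically
#' unmethylated) are pooled across contexts; the conversion rate is one minus
#' the apparent weighted methylation.
#'
#' @param calls cytosine calls restricted to (or filtered for) the contig.
#' @param contig optional chromosome name to subset on.
#' @return proportion in `[0, 1]`.
#' @export
conversionRate <- function(calls, contig = NULL) {
    if (!is.null(contig)) calls <- calls[calls$chrom == contig, , drop = FALSE]
    .validateCalls(calls)
    tot <- sum(calls$n_total)
    if (tot == 0) stop("zero coverage on the unmethylated contig")
    1 - sum(calls$n_meth) / tot
}

#' Region evaluability filters
#'
#' Genome-wide mode requires a mean coverage of at least 5 reads per site and
#' at least 2 sites of the context; promoter mode relaxes coverage to 2x.
#' Both boundaries are inclusive. The separate context level minima (10% for
#' CG/CHG, 1% for CHH) gate whether an evaluable region *counts as
#' methylated*; see [isMethylated()].
#'
#' @param rm result of [weightedMC()].
#' @param mode `"genome_wide"` or `"promoter"`.
#' @param config an [AnalysisConfig-class].
#' @return logical.
#' @export
passesFilters <- function(rm, mode = c("genome_wide", "promoter"),
                          config = analysisConfig()) {
    mode <- match.arg(mode)
    if (!isTRUE(rm$evaluable)) return(FALSE)
    if (mode == "genome_wide")
        rm$coverage >= config@gwMinCoverage && rm$n_sites >= config@gwMinSites
    else
        rm$coverage >= config@prMinCoverage && rm$n_sites >= config@prMinSites
}

#' Level gate: does a region count as methylated?
#'
#' @param rm result of [weightedMC()].
#' @param context CG, CHG or CHH.
#' @param config an [AnalysisConfig-class].
#' @return logical; `NA` for non-evaluable regions.
#' @export
isMethylated <- function(rm, context, config = analysisConfig()) {
    context <- match.arg(context, .methContexts)
    if (!isTRUE(rm$evaluable)) return(NA)
    thr <- switch(context, CG = config@levelMinCG, CHG = config@levelMinCHG,
                  CHH = config@levelMinCHH)
    rm$mc >= thr
}

#' Relative methylation difference, in percent
#'
#' `100 * (mc_a - mc_b) / mc_b`: the percentage change of sample A relative to
#' sample B. Undefined when the reference is zero (returns `NA` with a
#' warning).
#'
#' @param mcA,mcB methylation proportions (vectorized).
#' @return percent change.
#' @examples
#' relativeDiff(0.0032, 0.0100)  # -68
#' @export
relativeDiff <- function(mcA, mcB) {
    out <- 100 * (mcA - mcB) / mcB
    if (any(mcB == 0, na.rm = TRUE)) {
        warning("relative difference undefined where the reference is 0")
        out[mcB == 0] <- NA_real_
    }
    out
}

#' Absolute methylation difference, in percentage points
#'
#' `100 * (mc_a - mc_b)`; exactly antisymmetric.
#'
#' @param mcA,mcB methylation proportions (vectorized).
#' @return percentage points.
#' @export
absoluteDiff <- function(mcA, mcB) 100 * (mcA - mcB)

#' Genome-wide pooled methylation difference between two samples
#'
#' Pools all sites of one context per sample with [weightedMC()] and returns
#' the relative (default) or absolute difference of sample A versus sample B.
#'
#' @param callsA,callsB cytosine-call data.frames for the two samples.
#' @param context CG, CHG or CHH.
#' @param type `"relative"` (percent) or `"absolute"` (percentage points).
#' @param excludeContig contig to drop first (e.g. the chloroplast-like
#'   conversion control).
#' @return one number.
#' @export
genomeWideContextDiff <- function(callsA, callsB, context,
                                  type = c("relative", "absolute"),
                                  excludeContig = NULL) {
    type <- match.arg(type)
    if (!is.null(excludeContig)) {
        callsA <- callsA[!callsA$chrom %in% excludeContig, , drop = FALSE]
        callsB <- callsB[!callsB$chrom %in% excludeContig, , drop = FALSE]
    }
    a <- weightedMC(callsA, context = context)$mc
    b <- weightedMC(callsB, context = context)$mc
    if (type == "relative") relativeDiff(a, b) else absoluteDiff(a, b)
}

#' Tile promoters and compute per-tile weighted methylation
#'
#' Each gene's promoter (see [promoterRegion()]) is divided into
#' `tileLen(config)`-bp tiles indexed 1 at the TSS and increasing upstream;
#' a 2-kb promoter in 100-bp tiles gives indices 1..20. Tiles with no covered
#' site of the context are marked non-evaluable (and are excluded from
#' per-gene averages downstream). Truncated promoters contribute only the
#' tiles they retain.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param calls cytosine-call data.frame.
#' @param context CG, CHG or CHH.
#' @param config an [AnalysisConfig-class].
#' @return data.frame: `gene_id`, `tile_index`, `context`, `mc`, `n_sites`,
#'   `coverage`, `evaluable` — one row per gene x tile.
#' @export
tilePromoters <- function(genes, calls, context, config = analysisConfig()) {
    context <- match.arg(context, .methContexts)
    .validateCalls(calls)
    nTiles <- as.integer(promoterLen(config) / tileLen(config))
    prom <- promoterRegion(genes, promoterLen(config))
    calls <- calls[calls$context == context, , drop = FALSE]
    sites <- callsAsGRanges(calls)
    hits <- GenomicRanges::findOverlaps(sites, prom, ignore.strand = TRUE)
    si <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
    tssAll <- tssPosition(genes)
    strandAll <- as.character(BiocGenerics::strand(genes))
    d <- ifelse(strandAll[pi] == "+",
                tssAll[pi] - calls$pos[si],
                calls$pos[si] - tssAll[pi])
    tile <- ceiling(d / tileLen(config))
    ok <- tile >= 1L & tile <= nTiles
    si <- si[ok]; pi <- pi[ok]; tile <- tile[ok]
    grid <- expand.grid(gene_id = genes$gene_id, tile_index = seq_len(nTiles),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(genes$gene_id[pi], tile, sep = "\r")
    gkey <- paste(grid$gene_id, grid$tile_index, sep = "\r")
    nm <- rowsum(calls$n_meth[si], key)
    nt <- rowsum(calls$n_total[si], key)
    ns <- rowsum(rep(1L, length(si)), key)
    idx <- match(gkey, rownames(nm))
    nMeth <- ifelse(is.na(idx), 0, nm[idx, 1L])
    nTot <- ifelse(is.na(idx), 0, nt[idx, 1L])
    nSites <- ifelse(is.na(idx), 0L, ns[idx, 1L])
    data.frame(gene_id = grid$gene_id, tile_index = grid$tile_index,
               context = context,
               mc = ifelse(nTot > 0, nMeth / nTot, NA_real_),
               n_sites = as.integer(nSites),
               coverage = ifelse(nSites > 0, nTot / nSites, 0),
               evaluable = nTot > 0,
               stringsAsFactors = FALSE)
}

#' Per-gene mean promoter methylation over evaluable tiles
#'
#' @param tiles result of [tilePromoters()].
#' @param tileRange optional integer range of tile indices to average over
#'   (e.g. `1:10` for the first kb above the TSS).
#' @return data.frame `gene_id`, `mc` (mean of evaluable tile mc; `NA` when no
#'   tile is evaluable), `n_tiles`.
#' @export
promoterMeanMC <- function(tiles, tileRange = NULL) {
    if (!is.null(tileRange))
        tiles <- tiles[tiles$tile_index %in% tileRange, , drop = FALSE]
    ev <- tiles[tiles$evaluable, , drop = FALSE]
    genes <- unique(tiles$gene_id)
    mc <- tapply(ev$mc, factor(ev$gene_id, levels = genes), mean)
    n <- tapply(ev$mc, factor(ev$gene_id, levels = genes), length)
    data.frame(gene_id = genes, mc = as.numeric(mc),
               n_tiles = ifelse(is.na(n), 0L, as.integer(n)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Metagene promoter methylation profile
#'
#' Arithmetic mean of evaluable per-tile weighted methylation across genes,
#' per tile index (1 = TSS-proximal), with the number of contributing genes.
#'
#' @param tiles result of [tilePromoters()].
#' @return data.frame `tile_index`, `mean_mc`, `n_genes`; empty input gives an
#'   empty profile.
#' @export
metageneProfile <- function(tiles) {
    ev <- tiles[tiles$evaluable, , drop = FALSE]
    if (nrow(ev) == 0L)
        return(data.frame(tile_index = integer(), mean_mc = numeric(),
                          n_genes = integer()))
    idx <- sort(unique(tiles$tile_index))
    f <- factor(ev$tile_index, levels = idx)
    data.frame(tile_index = idx,
               mean_mc = as.numeric(tapply(ev$mc, f, mean)),
               n_genes = as.integer(table(f)),
               row.names = NULL)
}

#' Pooled promoter methylation per gene
#'
#' Weighted (count-pooled) methylation of each gene's whole promoter, with
#' evaluability under the promoter-mode filters.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param calls cytosine-call data.frame.
#' @param context CG, CHG or CHH.
#' @param config an [AnalysisConfig-class].
#' @return data.frame: `gene_id`, `mc`, `n_sites`, `coverage`, `evaluable`
#'   (promoter filters applied).
#' @export
promoterMethylation <- function(genes, calls, context,
                                config = analysisConfig()) {
    context <- match.arg(context, .methContexts)
    .validateCalls(calls)
    prom <- promoterRegion(genes, promoterLen(config))
    calls <- calls[calls$context == context, , drop = FALSE]
    hits <- GenomicRanges::findOverlaps(callsAsGRanges(calls), prom,
                                        ignore.strand = TRUE)
    si <- S4Vectors::queryHits(hits); pi <- S4Vectors::subjectHits(hits)
    key <- factor(genes$gene_id[pi], levels = genes$gene_id)
    nMeth <- tapply(calls$n_meth[si], key, sum)
    nTot <- tapply(calls$n_total[si], key, sum)
    nSites <- tapply(si, key, length)
    nMeth[is.na(nMeth)] <- 0; nTot[is.na(nTot)] <- 0
    nSites[is.na(nSites)] <- 0L
    cov <- ifelse(nSites > 0, nTot / nSites, 0)
    data.frame(gene_id = genes$gene_id,
               mc = ifelse(nTot > 0, nMeth / nTot, NA_real_),
               n_sites = as.integer(nSites), coverage = as.numeric(cov),
               evaluable = nTot > 0 & cov >= config@prMinCoverage &
                   nSites >= config@prMinSites,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Correct a weighted methylation level for bisulfite non-conversion
#'
#' Incomplete conversion makes a fraction of unmethylated cytosines read as
#' methylated: observed `p_obs = p (1 - nc) + nc`, where `nc` is the
#' non-conversion rate estimated from the unmethylated chloroplast-like
#' contig (`nc = 1 - conversionRate(...)`). Inverts that relation, truncating
#' at zero.
#'
#' @param mc observed weighted methylation (vectorized).
#' @param nonConversion non-conversion rate in `[0, 1)`.
#' @return corrected methylation proportion.
#' @export
adjustForNonConversion <- function(mc, nonConversion) {
    stopifnot(nonConversion >= 0, nonConversion < 1)
    pmax(0, (mc - nonConversion) / (1 - nonConversion))
}

#' Differential-promoter methylation call
#'
#' Threshold rules, per context: CG and CHG promoters are differential when
#' the absolute methylation difference reaches 40 percentage points; CHH
#' promoters when the lower of the two samples is at or below 5% methylation
#' and the absolute difference reaches 15 points. Independently, a CG gain of
#' at least 10 points in sample A over sample B is flagged as CG
#' hypermethylation.
#'
#' @param mcA,mcB methylation proportions (vectorized; both from regions that
#'   passed the promoter filters).
#' @param context CG, CHG or CHH.
#' @param config an [AnalysisConfig-class].
#' @return character vector: `"none"`, `"differential"` or
#'   `"CG_hypermethylated"` (a CG call that is also differential reports
#'   `"CG_hypermethylated"` only when the gain rule fires; both labels are
#'   joined with `"+"` when both apply).
#' @examples
#' callDifferentialPromoter(0.55, 0.10, "CG")  # differential + hypermethylated
#' @export
callDifferentialPromoter <- function(mcA, mcB, context,
                                     config = analysisConfig()) {
    context <- match.arg(context, .methContexts)
    d <- absoluteDiff(mcA, mcB)
    diffCall <- if (context == "CHH") {
        pmin(mcA, mcB) <= config@chhLowMax & abs(d) >= config@diffAbsCHH
    } else {
        abs(d) >= config@diffAbsCGCHG
    }
    hyper <- context == "CG" & d >= config@cgHyperMin
    out <- ifelse(diffCall, "differential", "none")
    out[hyper & diffCall] <- "differential+CG_hypermethylated"
    out[hyper & !diffCall] <- "CG_hypermethylated"
    out
}
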