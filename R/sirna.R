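#' miRNA-anchored normalization factor
#'
#' In an RdDM-deficient mutant the global loss of 24-nt siRNAs shifts library
#' composition, so total-count normalization inflates mutant abundances.
#' miRNAs are biologically undisturbed between the genotypes and anchor the
#' correction: per miRNA, the mutant/wildtype CPM ratio is computed on
#' replicate-pooled counts, and the factor is the median ratio (or the ratio
#' of CPM sums with `method = "ratio_of_sums"`). miRNAs with a zero count in
#' either genotype are excluded and reported.
#'
#' @param countsWt,countsMut named numeric vectors of per-miRNA counts, pooled
#'   over replicates.
#' @param libsizeWt,libsizeMut total small-RNA library sizes.
#' @param method `"median"` (default) or `"ratio_of_sums"`.
#' @return list: `value` (fold change, > 0), `ratios` (per-miRNA mut/wt CPM
#'   ratios used), `excluded` (miRNA names dropped), `method`.
#' @export
mirnaNormFactor <- function(countsWt, countsMut, libsizeWt, libsizeMut,
                            method = c("median", "ratio_of_sums")) {
    method <- match.arg(method)
    stopifnot(length(countsWt) == length(countsMut))
    usable <- countsWt > 0 & countsMut > 0
    excluded <- names(countsWt)[!usable]
    if (!any(usable)) stop("no miRNA with nonzero counts in both genotypes")
    if (length(excluded))
        message(length(excluded), " miRNA(s) excluded (zero count in one genotype)")
    cw <- cpm(countsWt[usable], libsizeWt)
    cm <- cpm(countsMut[usable], libsizeMut)
    ratios <- cm / cw
    value <- if (method == "median") median(ratios) else sum(cm) / sum(cw)
    list(value = value, ratios = ratios, excluded = excluded, method = method)
}

#' Correct a fold change by the miRNA-anchored factor
#'
#' @param rawLfc raw log2 fold change (mutant/wildtype).
#' @param factor normalization fold change (> 0), e.g. the study-scale 2.2.
#' @return `rawLfc - log2(factor)`.
#' @export
correctedLfc <- function(rawLfc, factor) {
    stopifnot(factor > 0)
    rawLfc - log2(factor)
}

#' Build promoter siRNA profiles from per-region counts
#'
#' Pools replicate 24-nt read counts per promoter and genotype, computes CPM,
#' the raw log2 fold change (mutant/wildtype, pseudocount 0.5 on zero-count
#' sides), and the factor-corrected fold change.
#'
#' @param regionCounts data.frame with columns `gene_id`, `genotype`
#'   (`"WT"`/`"MUT"`), `replicate`, `count`.
#' @param libsizes named list/vector with elements `WT` and `MUT`: total
#'   library sizes pooled over replicates.
#' @param factor normalization fold change from [mirnaNormFactor()].
#' @return data.frame: `gene_id`, `count_wt`, `count_mut`, `cpm_wt`,
#'   `cpm_mut`, `raw_lfc`, `corrected_lfc`.
#' @export
buildSiRNAProfiles <- function(regionCounts, libsizes, factor) {
    stopifnot(all(c("WT", "MUT") %in% names(libsizes)))
    if (any(regionCounts$count < 0)) stop("counts must be >= 0")
    genes <- sort(unique(regionCounts$gene_id))
    pool <- function(gt) {
        sub <- regionCounts[regionCounts$genotype == gt, , drop = FALSE]
        v <- rowsum(sub$count, sub$gene_id)
        out <- setNames(rep(0, length(genes)), genes)
        out[rownames(v)] <- v[, 1L]
        out
    }
    wt <- pool("WT"); mut <- pool("MUT")
    ps <- function(x) ifelse(x > 0, x, 0.5)
    rawLfc <- log2((ps(mut) / libsizes[["MUT"]]) / (ps(wt) / libsizes[["WT"]]))
    data.frame(gene_id = genes,
               count_wt = wt, count_mut = mut,
               cpm_wt = cpm(wt, libsizes[["WT"]]),
               cpm_mut = cpm(mut, libsizes[["MUT"]]),
               raw_lfc = rawLfc,
               corrected_lfc = correctedLfc(rawLfc, factor),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Call 24-nt siRNA depletion per promoter
#'
#' A promoter is assessable when its pooled CPM reaches `sirnaCpmMin` in at
#' least one genotype; otherwise it is excluded as low-abundance (`NA`).
#' An assessable promoter is depleted when its corrected log2 fold change is
#' at or below `sirnaLfcMax` (default -1) and a two-sided binomial test of the
#' mutant count against the expectation implied by the library sizes and the
#' normalization factor gives p <= `sirnaPMax`. Under no depletion beyond the
#' global compositional shift, the mutant read count among the promoter's
#' pooled reads is binomial with success probability
#' `factor * libMut / (factor * libMut + libWt)`.
#'
#' @param profiles result of [buildSiRNAProfiles()].
#' @param libsizes named vector with `WT` and `MUT` library sizes.
#' @param factor normalization fold change.
#' @param config an [AnalysisConfig-class].
#' @return `profiles` with added columns `p_value` and `depleted` (logical,
#'   `NA` for low-abundance promoters).
#' @export
callDepleted <- function(profiles, libsizes, factor,
                         config = analysisConfig()) {
    assessable <- pmax(profiles$cpm_wt, profiles$cpm_mut) >= config@sirnaCpmMin
    p0 <- factor * libsizes[["MUT"]] /
        (factor * libsizes[["MUT"]] + libsizes[["WT"]])
    n <- profiles$count_wt + profiles$count_mut
    pv <- rep(NA_real_, nrow(profiles))
    idx <- which(assessable & n > 0)
    pv[idx] <- vapply(idx, function(i)
        binom.test(round(profiles$count_mut[i]), round(n[i]), p0)$p.value,
        numeric(1))
    profiles$p_value <- pv
    profiles$depleted <- ifelse(assessable,
                                profiles$corrected_lfc <= config@sirnaLfcMax &
                                    !is.na(pv) & pv <= config@sirnaPMax,
                                NA)
    profiles
}

#' Depletion rate
#'
#' @param nDepleted,nTotal counts, `0 <= nDepleted <= nTotal`, `nTotal > 0`.
#' @return percent, rounded to two decimals.
#' @examples
#' depletionRate(108, 470)  # 22.98
#' @export
depletionRate <- function(nDepleted, nTotal) {
    if (any(nTotal == 0)) stop("nTotal must be > 0")
    stopifnot(all(nDepleted >= 0), all(nDepleted <= nTotal))
    roundHalfUp(100 * nDepleted / nTotal, 2)
}

#' Per-group siRNA depletion summary
#'
#' For each requested group subset, counts the member genes that have a siRNA
#' promoter profile, those called depleted, and the depletion rate, plus a
#' genome-wide row over all profiled promoters. Group subsets with no
#' profiled gene are omitted with a warning.
#'
#' @param assignments result of [classifyGroups()].
#' @param calls result of [callDepleted()].
#' @param groupSubsets named list of group-label vectors, e.g.
#'   `list(I = "I", up_mut = c("III", "V", "VII"))`.
#' @return data.frame: `subset`, `n_genes` (profiled, non-`NA` call),
#'   `n_depleted`, `pct_depleted`.
#' @export
groupDepletionTable <- function(assignments, calls, groupSubsets) {
    m <- groupMembership(assignments)
    ok <- !is.na(calls$depleted)
    profiled <- calls$gene_id[ok]
    depleted <- calls$gene_id[ok][calls$depleted[ok]]
    rows <- list()
    for (nm in names(groupSubsets)) {
        members <- rownames(m)[rowSums(m[, groupSubsets[[nm]],
                                         drop = FALSE]) > 0]
        genes <- intersect(members, profiled)
        if (!length(genes)) {
            warning("no profiled genes in subset ", nm, "; row omitted")
            next
        }
        nd <- length(intersect(genes, depleted))
        rows[[nm]] <- data.frame(subset = nm, n_genes = length(genes),
                                 n_depleted = nd,
                                 pct_depleted = depletionRate(nd, length(genes)))
    }
    rows$genome_wide <- data.frame(
        subset = "genome_wide", n_genes = length(profiled),
        n_depleted = length(depleted),
        pct_depleted = depletionRate(length(depleted), length(profiled)))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
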