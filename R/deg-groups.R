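#' Read per-comparison differential-expression statistics
#'
#' Each table carries one named pairwise comparison: columns `gene_id`,
#' `log2fc`, `pvalue`, `fdr`. Fold-change model fitting is upstream of this
#' package; statistics are consumed as given.
#'
#' @param path TSV file.
#' @param comparison one of [COMPARISONS].
#' @return data.frame with columns `gene_id`, `comparison`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @export
readComparisonStats <- function(path, comparison) {
    comparison <- match.arg(comparison, COMPARISONS)
    df <- readTSV(path, required = c("gene_id", "log2fc", "pvalue", "fdr"))
    if (any(df$pvalue < 0 | df$pvalue > 1 | df$fdr < 0 | df$fdr > 1,
            na.rm = TRUE))
        stop("pvalue/fdr outside [0, 1] in ", basename(path))
    if (anyDuplicated(df$gene_id))
        stop("duplicated gene_id in ", basename(path))
    data.frame(gene_id = df$gene_id, comparison = comparison,
               log2fc = df$log2fc, pvalue = df$pvalue, fdr = df$fdr,
               stringsAsFactors = FALSE)
}

#' Low-abundance count filter
#'
#' Removes genes whose counts-per-million fall below `cpmMin` in all but a few
#' libraries. A gene is retained iff its CPM is at or above the threshold
#' (boundary inclusive) in at least `minSamples` libraries; by default
#' `minSamples` is the size of the smallest experimental group, or 2 when no
#' grouping is given.
#'
#' @param counts genes x samples count matrix with rownames.
#' @param libsizes per-sample library sizes.
#' @param cpmMin CPM threshold (default 0.58).
#' @param groups optional factor of sample group labels, used to derive
#'   `minSamples`.
#' @param minSamples explicit override of the at-least-k rule.
#' @return character vector of retained gene ids, with the removed ids in
#'   attribute `"removed"`.
#' @export
filterLowAbundance <- function(counts, libsizes, cpmMin = 0.58,
                               groups = NULL, minSamples = NULL) {
    if (!is.matrix(counts) || is.null(rownames(counts)))
        stop("counts must be a matrix with gene rownames")
    if (anyNA(counts)) stop("missing counts: every gene needs all sample columns")
    if (any(counts < 0)) stop("counts must be >= 0")
    if (is.null(minSamples)) {
        minSamples <- if (!is.null(groups)) min(table(groups)) else 2L
    }
    keep <- rowSums(cpm(counts, libsizes) >= cpmMin) >= minSamples
    retained <- rownames(counts)[keep]
    removed <- rownames(counts)[!keep]
    if (length(removed))
        message(length(removed), " gene(s) removed by the ", cpmMin,
                "-CPM filter")
    attr(retained, "removed") <- removed
    retained
}

#' Recompute FDR from p-values
#'
#' Benjamini-Hochberg adjustment per comparison, for synthetic tables whose
#' FDR column is to be rebuilt from raw p-values.
#'
#' @param stats long data.frame as from [readComparisonStats()].
#' @return the same data.frame with the `fdr` column replaced.
#' @export
recomputeFDR <- function(stats) {
    stats$fdr <- stats::ave(stats$pvalue, stats$comparison,
                            FUN = function(p) p.adjust(p, method = "BH"))
    stats
}

#' Classify genes into the eight analysis groups
#'
#' Per comparison, a gene with `log2fc >= lfcMin` and `fdr <= fdrMax` joins
#' the comparison's up-group, and with `log2fc <= -lfcMin` its down-group
#' (both boundaries inclusive). Comparisons map to group pairs:
#' wildtype ABA response I/II, loss-of-RdDM response III/IV, mutant ABA
#' response V/VI, differential ABA response mutant-vs-wildtype VII/VIII.
#'
#' @param stats long data.frame with columns `gene_id`, `comparison`,
#'   `log2fc`, `fdr` (rbind the four comparison tables).
#' @param config an [AnalysisConfig-class].
#' @return data.frame, one row per gene in at least one group: `gene_id`,
#'   `groups` (comma-joined roman numerals), `n_groups`, `unique` (exactly one
#'   group), `contra` (member of an up-group and a down-group). The full
#'   gene-by-group logical membership matrix is in attribute `"membership"`.
#' @examples
#' s <- data.frame(gene_id = "g1", comparison = "MUTABA_vs_MUTMS",
#'                 log2fc = 1.2, pvalue = 0.001, fdr = 0.01)
#' classifyGroups(s, analysisConfig())
#' @export
classifyGroups <- function(stats, config = analysisConfig()) {
    bad <- setdiff(unique(stats$comparison), COMPARISONS)
    if (length(bad))
        stop("unknown comparison label(s): ", paste(bad, collapse = ", "))
    up <- stats$log2fc >= lfcMin(config) & stats$fdr <= fdrMax(config)
    dn <- stats$log2fc <= -lfcMin(config) & stats$fdr <= fdrMax(config)
    grp <- rep(NA_character_, nrow(stats))
    for (cmp in COMPARISONS) {
        i <- stats$comparison == cmp
        grp[i & up] <- .groupMap[[cmp]]["up"]
        grp[i & dn] <- .groupMap[[cmp]]["down"]
    }
    hit <- !is.na(grp)
    genes <- sort(unique(stats$gene_id[hit]))
    membership <- matrix(FALSE, nrow = length(genes), ncol = length(GROUPS),
                         dimnames = list(genes, GROUPS))
    if (length(genes))
        membership[cbind(stats$gene_id[hit], grp[hit])] <- TRUE
    upG <- c("I", "III", "V", "VII"); dnG <- c("II", "IV", "VI", "VIII")
    n <- rowSums(membership)
    out <- data.frame(
        gene_id = genes,
        groups = vapply(genes, function(g)
            paste(GROUPS[membership[g, ]], collapse = ","), character(1)),
        n_groups = as.integer(n),
        unique = n == 1L,
        contra = rowSums(membership[, upG, drop = FALSE]) > 0 &
                 rowSums(membership[, dnG, drop = FALSE]) > 0,
        row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "membership") <- membership
    out
}

#' Gene-by-group membership matrix
#'
#' @param assignments result of [classifyGroups()].
#' @return logical matrix, genes x groups I..VIII.
#' @export
groupMembership <- function(assignments) {
    m <- attr(assignments, "membership")
    if (is.null(m)) stop("assignments lack a membership attribute; ",
                         "use classifyGroups()")
    m
}

#' Overlap and uniqueness summary of group assignments
#'
#' Accounts for genes appearing in more than one analysis group: the grand
#' total of group memberships, the number of distinct genes, how many genes
#' are shared between at least two groups, how many are unique to one, the
#' per-group sizes, and the contra-regulated genes (up in at least one
#' comparison and down in at least one other).
#'
#' @param assignments result of [classifyGroups()].
#' @return list with `total_memberships` (the grand total of group
#'   memberships, the sum of per-group sizes), `total_genes` (distinct genes),
#'   `shared` (genes in two or more groups), `unique` (genes in exactly one),
#'   `shared_memberships` (memberships held by multi-group genes, so that
#'   `unique == total_memberships - shared_memberships`), `per_group` (named
#'   integer vector) and `contra` (gene ids). Always
#'   `total_genes == unique + shared`.
#' @export
overlapSummary <- function(assignments) {
    m <- groupMembership(assignments)
    per <- colSums(m)
    k <- rowSums(m)
    list(total_memberships = as.integer(sum(per)),
         total_genes = nrow(m),
         shared = as.integer(sum(k >= 2L)),
         unique = as.integer(sum(k == 1L)),
         shared_memberships = as.integer(sum(k[k >= 2L])),
         per_group = setNames(as.integer(per), colnames(m)),
         contra = assignments$gene_id[assignments$contra])
}

#' Genes in one group set but not another
#'
#' Set difference on group membership, e.g. genes ABA-responsive in wildtype
#' (groups I/II) but not in the mutant (groups V/VI), with per-direction
#' splits.
#'
#' @param assignments result of [classifyGroups()].
#' @param groupsetA,groupsetB subsets of [GROUPS].
#' @return list with `genes` (in any group of A and none of B), `up` and
#'   `down` (the subset belonging to up-groups / down-groups of A).
#' @export
uniqueToComparison <- function(assignments, groupsetA, groupsetB) {
    stopifnot(all(groupsetA %in% GROUPS), all(groupsetB %in% GROUPS))
    m <- groupMembership(assignments)
    inA <- rowSums(m[, groupsetA, drop = FALSE]) > 0
    inB <- rowSums(m[, groupsetB, drop = FALSE]) > 0
    sel <- inA & !inB
    upG <- intersect(groupsetA, c("I", "III", "V", "VII"))
    dnG <- intersect(groupsetA, c("II", "IV", "VI", "VIII"))
    list(genes = rownames(m)[sel],
         up = rownames(m)[sel & rowSums(m[, upG, drop = FALSE]) > 0],
         down = rownames(m)[sel & rowSums(m[, dnG, drop = FALSE]) > 0])
}
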