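#' Transposable elements in gene flanks
#'
#' Reports every TE whose interval intersects a gene's 2-kb (configurable)
#' upstream-of-TSS or downstream-of-TTS flank. A TE near several genes is
#' reported once per gene; `distance` is the gap in bp between the TE and the
#' flank-adjacent gene boundary (0 when the TE overlaps the gene side of the
#' flank is irrelevant — distance is measured to the gene body, 0 for TEs
#' touching or overlapping it). A nearest-TE-only mode is available.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param tes `GRanges` of TEs with `te_id` and `superfamily`
#'   (see [readTEAnnotation()]).
#' @param flankLen flank length in bp.
#' @param nearestOnly keep only the closest TE per gene flank.
#' @return data.frame: `gene_id`, `te_id`, `superfamily`, `flank`
#'   (`"upstream"`/`"downstream"`), `distance`.
#' @export
flankingTEs <- function(genes, tes, flankLen = 2000L, nearestOnly = FALSE) {
    fl <- geneFlanks(genes, flankLen)
    one <- function(gr, label) {
        hits <- GenomicRanges::findOverlaps(tes, gr, ignore.strand = TRUE)
        if (length(hits) == 0L)
            return(data.frame(gene_id = character(), te_id = character(),
                              superfamily = character(), flank = character(),
                              distance = integer()))
        ti <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
        d <- GenomicRanges::distance(tes[ti], GenomicRanges::granges(genes)[gi],
                                     ignore.strand = TRUE)
        data.frame(gene_id = gr$gene_id[gi], te_id = tes$te_id[ti],
                   superfamily = tes$superfamily[ti], flank = label,
                   distance = as.integer(d), stringsAsFactors = FALSE)
    }
    out <- rbind(one(fl$upstream, "upstream"), one(fl$downstream, "downstream"))
    if (nearestOnly && nrow(out)) {
        key <- paste(out$gene_id, out$flank)
        out <- do.call(rbind, lapply(split(out, key), function(d) {
            d[d$distance == min(d$distance), , drop = FALSE]  # ties all kept
        }))
        rownames(out) <- NULL
    }
    out
}

#' Superfamily composition of a TE set
#'
#' Percentage of TEs in each superfamily of the closed code set; percentages
#' sum to 100.
#'
#' @param x either a `flankingTEs()` record data.frame (deduplicated on
#'   `te_id` by default) or a character vector of superfamily codes.
#' @param dedupe count each TE once even when reported for several genes.
#' @return named numeric vector over [TE_SUPERFAMILIES], in percent.
#' @export
superfamilyDistribution <- function(x, dedupe = TRUE) {
    fam <- if (is.data.frame(x)) {
        if (dedupe) x$superfamily[!duplicated(x$te_id)] else x$superfamily
    } else as.character(x)
    if (!length(fam)) stop("empty TE set")
    bad <- setdiff(unique(fam), TE_SUPERFAMILIES)
    if (length(bad))
        stop("unknown superfamily code(s): ", paste(bad, collapse = ", "))
    counts <- table(factor(fam, levels = TE_SUPERFAMILIES))
    setNames(100 * as.numeric(counts) / sum(counts), TE_SUPERFAMILIES)
}

#' Foreground-vs-background superfamily difference
#'
#' Percentage-point difference per superfamily between a foreground TE
#' distribution (e.g. TEs flanking ABRE-containing upregulated genes) and the
#' genome background.
#'
#' @param foreground,background named percent vectors over the same code set
#'   (as from [superfamilyDistribution()]).
#' @return named numeric vector of `foreground - background`, in points.
#' @export
distributionDelta <- function(foreground, background) {
    if (!identical(sort(names(foreground)), sort(names(background))))
        stop("distributions must cover the same superfamily code set")
    foreground - background[names(foreground)]
}
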