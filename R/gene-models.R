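#' Read gene models from GFF3
#'
#' Imports `gene` features from a GFF3 file into a `GRanges` with a `gene_id`
#' metadata column taken from the `ID` attribute. Coordinates follow the
#' Bioconductor convention (1-based, closed). Records with an unknown strand
#' are skipped with a warning; duplicated gene identifiers are an error.
#'
#' @param path GFF3 file with gene features (1-based closed coordinates).
#' @param seqlengths optional named vector of chromosome lengths; when the GFF3
#'   carries `##sequence-region` directives these are picked up automatically.
#' @return `GRanges`, one range per gene, metadata column `gene_id`.
#' @seealso [promoterRegion()], [geneFlanks()], [tssPosition()]
#' @export
readGeneModels <- function(path, seqlengths = NULL) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene features in ", path)
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids))
        stop("gene features must carry an ID attribute")
    unknown <- as.logical(BiocGenerics::strand(gr) == "*")
    if (any(unknown)) {
        warning("skipping ", sum(unknown), " gene(s) with unknown strand: ",
                paste(utils::head(ids[unknown], 5L), collapse = ", "))
        gr <- gr[!unknown]
        ids <- gr$ID
    }
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene_id in ", path, ": ", paste(dup, collapse = ", "))
    out <- GenomicRanges::granges(gr)
    out$gene_id <- ids
    names(out) <- ids
    if (!is.null(seqlengths))
        GenomeInfoDb::seqlengths(out) <-
            seqlengths[GenomeInfoDb::seqlevels(out)]
    out
}

#' Write gene models to GFF3
#'
#' Inverse of [readGeneModels()]: writing and re-reading reproduces identical
#' coordinates, strands and identifiers.
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGFF3 <- function(genes, path, source = "epiABA") {
    out <- GenomicRanges::granges(genes)
    out$source <- source
    out$type <- "gene"
    out$ID <- genes$gene_id
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Strand-aware TSS position
#'
#' The transcription start site is the 5' end of the gene: the start
#' coordinate on the plus strand and the end coordinate on the minus strand.
#'
#' @param genes `GRanges` of gene models.
#' @return integer vector of TSS positions, named by `gene_id` when present.
#' @export
tssPosition <- function(genes) {
    s <- as.character(BiocGenerics::strand(genes))
    if (any(s == "*")) stop("TSS undefined for unstranded genes")
    pos <- ifelse(s == "+", BiocGenerics::start(genes),
                  BiocGenerics::end(genes))
    if (!is.null(genes$gene_id)) names(pos) <- genes$gene_id
    pos
}

# trim to chromosome bounds and flag ranges that lost bases
.trimFlag <- function(gr) {
    trimmed <- suppressWarnings(IRanges::trim(gr))
    gr2 <- trimmed
    gr2$truncated <- BiocGenerics::width(trimmed) < BiocGenerics::width(gr) |
        BiocGenerics::width(trimmed) == 0L
    gr2
}

#' Promoter regions upstream of the TSS
#'
#' Returns the `length`-bp region immediately upstream of each gene's TSS,
#' strand-aware: on the plus strand the promoter ends one base before the gene
#' start, on the minus strand it begins one base after the gene end. Promoters
#' running off a chromosome edge are truncated (never extending below base 1)
#' and flagged via a `truncated` metadata column rather than dropped.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param length promoter length in bp (> 0).
#' @return `GRanges` parallel to `genes` with columns `gene_id`, `truncated`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000), "+",
#'                             gene_id = "g1")
#' promoterRegion(g, 2000)  # 3001-5000
#' @export
promoterRegion <- function(genes, length = 2000L) {
    if (length <= 0) stop("promoter length must be > 0")
    if (any(BiocGenerics::strand(genes) == "*"))
        stop("promoters undefined for unstranded genes")
    pr <- suppressWarnings(
        GenomicRanges::promoters(GenomicRanges::granges(genes),
                                 upstream = as.integer(length),
                                 downstream = 0L))
    pr <- .trimFlag(pr)
    pr$gene_id <- genes$gene_id
    names(pr) <- genes$gene_id
    pr
}

#' Upstream and downstream gene flanks
#'
#' Strand-aware flanks of each gene: the region upstream of the TSS and the
#' region downstream of the TTS, each of `length` bp, truncated at chromosome
#' boundaries and flagged. Reversing a gene's strand swaps the two flanks.
#'
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param length flank length in bp (> 0).
#' @return named list of two `GRanges` (`upstream`, `downstream`), each with
#'   `gene_id` and `truncated` columns; a flank fully off-chromosome has
#'   zero width.
#' @export
geneFlanks <- function(genes, length = 2000L) {
    if (length <= 0) stop("flank length must be > 0")
    if (any(BiocGenerics::strand(genes) == "*"))
        stop("flanks undefined for unstranded genes")
    core <- GenomicRanges::granges(genes)
    up <- suppressWarnings(GenomicRanges::flank(core, as.integer(length),
                                                start = TRUE))
    dn <- suppressWarnings(GenomicRanges::flank(core, as.integer(length),
                                                start = FALSE))
    up <- .trimFlag(up); dn <- .trimFlag(dn)
    up$gene_id <- dn$gene_id <- genes$gene_id
    names(up) <- names(dn) <- genes$gene_id
    list(upstream = up, downstream = dn)
}

#' Read a transposable-element annotation from GFF3
#'
#' TE features must carry the superfamily code in a `superfamily` attribute
#' (or, failing that, as the leading three letters of the `ID`). Codes are
#' validated against the closed set [TE_SUPERFAMILIES].
#'
#' @param path GFF3 file of TE features.
#' @return `GRanges` with metadata columns `te_id` and `superfamily`.
#' @export
readTEAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0L) stop("no TE features in ", path)
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) stop("TE features must carry an ID attribute")
    fam <- gr$superfamily
    if (is.null(fam)) fam <- substr(ids, 1L, 3L)
    bad <- !fam %in% TE_SUPERFAMILIES
    if (any(bad))
        stop("unknown TE superfamily code(s): ",
             paste(unique(fam[bad]), collapse = ", "))
    out <- GenomicRanges::granges(gr)
    out$te_id <- ids
    out$superfamily <- fam
    out
}
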