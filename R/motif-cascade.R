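#' ABRE consensus pattern
#'
#' The degenerate ABA-responsive-element consensus `CACG[TC]G[TG]C[GC]`,
#' stored as the IUPAC string `CACGYGKCS`.
#' @export
ABRE_MOTIF <- "CACGYGKCS"

#' Default coupling-element pattern
#'
#' A literature-derived CE1-like coupling-element consensus used when CE
#' scanning is enabled. No CE consensus is part of the core analysis
#' definition; in strict mode (the default elsewhere) CE scanning is off.
#' Chosen so that neither strand contains a `CACG` seed, so planted CEs can
#' never create spurious ABRE matches.
#' @export
CE_MOTIF_DEFAULT <- "TGCCACCGG"

# "CACG[TC]G[TG]C[GC]" -> "CACGYGKCS"
.bracketToIupac <- function(pattern) {
    if (!grepl("[", pattern, fixed = TRUE)) return(pattern)
    code <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                     vapply(Biostrings::IUPAC_CODE_MAP, function(x)
                         paste(sort(strsplit(x, "")[[1]]), collapse = ""),
                         character(1)))
    out <- character()
    i <- 1L; chars <- strsplit(pattern, "")[[1]]
    while (i <= length(chars)) {
        if (chars[i] == "[") {
            j <- i + 1L
            while (chars[j] != "]") j <- j + 1L
            key <- paste(sort(chars[(i + 1L):(j - 1L)]), collapse = "")
            if (is.na(code[key])) stop("unresolvable character class [", key, "]")
            out <- c(out, code[key])
            i <- j + 1L
        } else {
            out <- c(out, chars[i]); i <- i + 1L
        }
    }
    paste(out, collapse = "")
}

#' Scan a sequence for a degenerate motif
#'
#' Exact degenerate-string matching of an IUPAC pattern (bracket notation such
#' as `CACG[TC]G[TG]C[GC]` is accepted and converted). Subject bases are
#' literal: an `N` in the sequence never satisfies a constrained pattern
#' position. With `bothStrands` the reverse-complement matches are also
#' reported, in forward-strand coordinates. Overlapping matches are all
#' reported.
#'
#' @param sequence a character string or `DNAString` over A/C/G/T/N.
#' @param pattern IUPAC or bracket-notation motif.
#' @param bothStrands scan the minus strand too (default TRUE).
#' @return data.frame: `start`, `end` (1-based, forward coordinates),
#'   `strand`, `match` (forward-strand sequence of the site).
#' @examples
#' scanMotif("CACGTGTCG", ABRE_MOTIF)
#' @export
scanMotif <- function(sequence, pattern, bothStrands = TRUE) {
    pattern <- .bracketToIupac(toupper(pattern))
    bad <- setdiff(strsplit(pattern, "")[[1]],
                   names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid pattern character(s): ", paste(bad, collapse = ", "))
    subj <- if (is(sequence, "DNAString")) sequence
            else Biostrings::DNAString(toupper(as.character(sequence)))
    hit <- function(pat, strand) {
        m <- Biostrings::matchPattern(pat, subj, fixed = "subject")
        if (length(m) == 0L)
            return(data.frame(start = integer(), end = integer(),
                              strand = character(), match = character()))
        data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
                   strand = strand, match = as.character(m),
                   stringsAsFactors = FALSE)
    }
    out <- hit(pattern, "+")
    if (bothStrands) {
        rcpat <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
        out <- rbind(out, hit(rcpat, "-"))
    }
    out[order(out$start, out$strand), , drop = FALSE]
}

#' Count ABRE and CE hits in gene promoters
#'
#' Extracts each gene's promoter sequence from the genome and scans it for the
#' ABRE consensus and, when `ceMotif` is non-`NULL`, a coupling-element motif.
#' Offsets are reported relative to the TSS (negative upstream).
#'
#' @param genome `DNAStringSet` (or FASTA path) of the genome.
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param config an [AnalysisConfig-class] (promoter length).
#' @param abreMotif ABRE pattern (default [ABRE_MOTIF]).
#' @param ceMotif CE pattern, or `NULL` for strict ABRE-only scanning.
#' @return list: `counts` (data.frame `gene_id`, `n_abre`, `n_ce`) and `hits`
#'   (data.frame `gene_id`, `motif`, `offset`, `strand`).
#' @export
scanPromoters <- function(genome, genes, config = analysisConfig(),
                          abreMotif = ABRE_MOTIF, ceMotif = NULL) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    prom <- promoterRegion(genes, promoterLen(config))
    tss <- tssPosition(genes)
    strandG <- as.character(BiocGenerics::strand(genes))
    hits <- list(); counts <- list()
    for (i in seq_along(prom)) {
        if (BiocGenerics::width(prom)[i] == 0L) {
            counts[[i]] <- data.frame(gene_id = genes$gene_id[i],
                                      n_abre = 0L, n_ce = 0L)
            next
        }
        chrom <- as.character(GenomeInfoDb::seqnames(prom))[i]
        seq <- Biostrings::subseq(genome[[chrom]],
                                  BiocGenerics::start(prom)[i],
                                  BiocGenerics::end(prom)[i])
        perMotif <- list(ABRE = scanMotif(seq, abreMotif))
        if (!is.null(ceMotif)) perMotif$CE <- scanMotif(seq, ceMotif)
        counts[[i]] <- data.frame(
            gene_id = genes$gene_id[i],
            n_abre = nrow(perMotif$ABRE),
            n_ce = if (is.null(ceMotif)) 0L else nrow(perMotif$CE))
        for (mn in names(perMotif)) {
            h <- perMotif[[mn]]
            if (nrow(h) == 0L) next
            # genomic position of the match start, then offset from the TSS
            gpos <- BiocGenerics::start(prom)[i] + h$start - 1L
            offset <- if (strandG[i] == "+") gpos - tss[genes$gene_id[i]]
                      else tss[genes$gene_id[i]] - (gpos + nchar(h$match) - 1L)
            hits[[length(hits) + 1L]] <- data.frame(
                gene_id = genes$gene_id[i], motif = mn, offset = offset,
                strand = h$strand, stringsAsFactors = FALSE)
        }
    }
    list(counts = do.call(rbind, counts),
         hits = if (length(hits)) do.call(rbind, hits)
                else data.frame(gene_id = character(), motif = character(),
                                offset = integer(), strand = character()))
}

#' Primary ABA-target classification
#'
#' A gene is a primary ABA target when it is differentially expressed in
#' response to ABA and its promoter carries at least two ABRE sites, or one
#' ABRE site together with a coupling element. A curated override list can
#' force the call for literature-documented direct targets.
#'
#' @param geneIds character vector.
#' @param nAbre,nCe motif hit counts per gene.
#' @param isDeg logical per gene.
#' @param override gene ids whose primary status is forced (they must still be
#'   DEGs: the override asserts direct regulation, not differential
#'   expression).
#' @return data.frame `gene_id`, `n_abre`, `n_ce`, `is_deg`, `is_primary`.
#' @export
classifyPrimary <- function(geneIds, nAbre, nCe, isDeg,
                            override = character()) {
    stopifnot(all(nAbre >= 0), all(nCe >= 0))
    motifRule <- nAbre >= 2L | (nAbre >= 1L & nCe >= 1L)
    data.frame(gene_id = geneIds, n_abre = as.integer(nAbre),
               n_ce = as.integer(nCe), is_deg = isDeg,
               is_primary = isDeg & (motifRule | geneIds %in% override),
               stringsAsFactors = FALSE)
}

#' Read a gene-regulatory-network edge list
#'
#' @param path TSV with columns `regulator`, `target` and optionally `tissue`.
#' @return data.frame of edges.
#' @export
readGRN <- function(path) {
    df <- readTSV(path, required = c("regulator", "target"))
    if (is.null(df$tissue)) df$tissue <- NA_character_
    df
}

#' Predict secondary targets through the regulatory network
#'
#' Single-step propagation: the targets of network edges whose regulator is a
#' primary target, restricted to the differentially expressed set, minus the
#' primaries themselves. Primaries absent from the network's regulator column
#' simply contribute no edges. Multi-step closure is available but off by
#' default.
#'
#' @param primaries character vector of primary-target gene ids.
#' @param grn edge data.frame with `regulator`, `target` (and `tissue`).
#' @param degSet character vector of DEG ids the prediction is restricted to.
#' @param tissue optional tissue label(s) to filter edges (default: all).
#' @param excludeSelfLoops drop regulator==target edges (default TRUE).
#' @param steps propagation depth (default 1).
#' @return character vector of predicted secondary-target gene ids.
#' @export
predictSecondary <- function(primaries, grn, degSet, tissue = NULL,
                             excludeSelfLoops = TRUE, steps = 1L) {
    if (!is.null(tissue)) grn <- grn[grn$tissue %in% tissue, , drop = FALSE]
    if (excludeSelfLoops)
        grn <- grn[grn$regulator != grn$target, , drop = FALSE]
    frontier <- unique(primaries)
    seen <- character()
    for (k in seq_len(steps)) {
        nxt <- unique(grn$target[grn$regulator %in% frontier])
        nxt <- setdiff(intersect(nxt, degSet), c(primaries, seen))
        if (!length(nxt)) break
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    sort(seen)
}

#' Fraction of the ABA response explained by the cascade
#'
#' Percentage of all ABA-responsive DEGs accounted for as either primary
#' targets or their predicted secondary targets.
#'
#' @param nPrimary,nSecondary,nTotalDeg counts.
#' @return percent.
#' @examples
#' explainedFraction(244, 1362, 244 + 1542)  # ~90
#' @export
explainedFraction <- function(nPrimary, nSecondary, nTotalDeg) {
    stopifnot(nPrimary >= 0, nSecondary >= 0)
    if (nTotalDeg == 0) stop("nTotalDeg must be > 0")
    if (nPrimary + nSecondary > nTotalDeg)
        stop("primary + secondary cannot exceed the total DEG count")
    100 * (nPrimary + nSecondary) / nTotalDeg
}
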