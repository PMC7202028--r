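# Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

# gene models on a toy chromosome with known seqlengths
makeGenes <- function(starts, ends, strands, chrom = "chr1",
                      chromLen = 100000L) {
    GRanges(chrom, IRanges(starts, ends), strand = strands,
            gene_id = sprintf("g%02d", seq_along(starts)),
            seqlengths = setNames(chromLen, chrom))
}

# cytosine-call table builder
makeCalls <- function(pos, n_meth, n_total, context = "CHH", chrom = "chr1",
                      strand = "+") {
    data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
               n_meth = n_meth, n_total = n_total, stringsAsFactors = FALSE)
}

# one DE statistic row
statRow <- function(gene, cmp, lfc, fdr = 0.01, p = fdr) {
    data.frame(gene_id = gene, comparison = cmp, log2fc = lfc,
               pvalue = p, fdr = fdr, stringsAsFactors = FALSE)
}

# independent sliding-window motif oracle: IUPAC pattern vs character vector
IUPAC_SETS <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

naiveScan <- function(sequence, pattern, bothStrands = TRUE) {
    scanStrand <- function(seqChars, pat) {
        sets <- IUPAC_SETS[strsplit(pat, "")[[1]]]
        L <- length(seqChars); k <- length(sets)
        if (L < k) return(integer())
        ok <- rep(TRUE, L - k + 1L)
        for (j in seq_len(k))
            ok <- ok & seqChars[seq.int(j, L - k + j)] %in% sets[[j]]
        which(ok)
    }
    chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
    fwd <- scanStrand(chars, pattern)
    hits <- data.frame(start = fwd, strand = rep("+", length(fwd)))
    if (bothStrands) {
        rc <- as.character(reverseComplement(DNAString(pattern)))
        rev <- scanStrand(chars, rc)
        hits <- rbind(hits,
                      data.frame(start = rev, strand = rep("-", length(rev))))
    }
    hits[order(hits$start, hits$strand), , drop = FALSE]
}

randomDNAString <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
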