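#' TE superfamily code set
#'
#' The closed set of transposable-element superfamily codes used throughout:
#' LTR retrotransposons Copia (RLC), Gypsy (RLG) and unclassified (RLX),
#' LINEs L1 (RIL) and RTE (RIT), SINEs (RST), TIR DNA transposons hAT (DTA),
#' CACTA (DTC), Pif/Harbinger (DTH), Mutator (DTM), Tc1/Mariner (DTT) and
#' unclassified (DTX), and Helitrons (DHH).
#' @export
TE_SUPERFAMILIES <- c("RLC", "RLG", "RLX", "RIL", "RIT", "RST",
                      "DTA", "DTC", "DTH", "DTM", "DTT", "DTX", "DHH")

#' Pairwise comparison labels
#'
#' The four genotype-by-treatment pairwise comparisons, in the order their
#' up/down analysis-group pairs are numbered (I/II, III/IV, V/VI, VII/VIII).
#' @export
COMPARISONS <- c("WTABA_vs_WTMS", "MUTMS_vs_WTMS",
                 "MUTABA_vs_MUTMS", "MUTABA_vs_WTABA")

#' Analysis group labels
#' @export
GROUPS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")

# comparison -> (up group, down group)
.groupMap <- list(
    WTABA_vs_WTMS   = c(up = "I",   down = "II"),
    MUTMS_vs_WTMS   = c(up = "III", down = "IV"),
    MUTABA_vs_MUTMS = c(up = "V",   down = "VI"),
    MUTABA_vs_WTABA = c(up = "VII", down = "VIII"))

.methContexts <- c("CG", "CHG", "CHH")

#' Counts per million
#'
#' @param counts numeric vector or matrix of read counts (columns = libraries).
#' @param libsizes library sizes, recycled across columns for a matrix.
#' @return CPM on the same shape as `counts`.
#' @export
cpm <- function(counts, libsizes) {
    if (any(libsizes <= 0)) stop("libsizes must be > 0")
    if (is.matrix(counts)) {
        if (length(libsizes) != ncol(counts))
            stop("need one library size per column")
        sweep(counts, 2L, libsizes, "/") * 1e6
    } else {
        counts / libsizes * 1e6
    }
}

# TSV helpers: all tables are written with a header and read back strictly.
writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

readTSV <- function(path, required = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(required)) {
        miss <- setdiff(required, names(df))
        if (length(miss))
            stop("missing column(s) in ", basename(path), ": ",
                 paste(miss, collapse = ", "))
    }
    df
}

# round half away from zero, as tables print percentages
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}
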