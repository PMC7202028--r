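test_that("degenerate ABRE matching follows the consensus exactly", {
    h <- scanMotif("CACGTGTCG", ABRE_MOTIF)
    expect_equal(nrow(h), 1L)
    expect_equal(h$start, 1L)
    expect_equal(h$strand, "+")
    # position 5 must be T or C
    expect_equal(nrow(scanMotif("CACGAGTCG", ABRE_MOTIF)), 0L)
    # reverse complement is found on the minus strand, forward coordinates
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("CACGTGTCG")))
    hrc <- scanMotif(rc, ABRE_MOTIF)
    expect_equal(hrc$strand, "-")
    expect_equal(nrow(scanMotif(rc, ABRE_MOTIF, bothStrands = FALSE)), 0L)
    # N never satisfies a constrained position
    expect_equal(nrow(scanMotif("CACGNGTCG", ABRE_MOTIF)), 0L)
    expect_error(scanMotif("ACGT", "CAC!G"), "invalid pattern")
    # bracket notation is accepted
    expect_equal(nrow(scanMotif("CACGTGTCG", "CACG[TC]G[TG]C[GC]")), 1L)
})

test_that("scanner agrees with a naive sliding-window oracle", {
    set.seed(13)
    lens <- c(rep(1000L, 40), rep(5000L, 10))
    for (L in lens) {
        s <- randomDNAString(L)
        got <- scanMotif(s, ABRE_MOTIF)
        want <- naiveScan(s, ABRE_MOTIF)
        expect_equal(got$start, want$start)
        expect_equal(got$strand, want$strand)
        # motif count is invariant under reverse complement
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        expect_equal(nrow(scanMotif(rc, ABRE_MOTIF)), nrow(got))
    }
})

test_that("primary-target rule requires differential expression plus motifs", {
    pc <- classifyPrimary(c("a", "b", "c", "d", "e"),
                          nAbre = c(2, 1, 2, 0, 1),
                          nCe = c(0, 1, 3, 5, 0),
                          isDeg = c(TRUE, TRUE, FALSE, TRUE, TRUE))
    expect_equal(pc$is_primary, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_true(all(pc$is_deg[pc$is_primary]))
    # curated override forces the call for documented direct targets
    ov <- classifyPrimary("x", 0, 0, TRUE, override = "x")
    expect_true(ov$is_primary)
    expect_false(classifyPrimary("x", 0, 0, FALSE,
                                 override = "x")$is_primary)
})

test_that("secondary-target prediction is one-step, DEG-restricted propagation", {
    grn <- data.frame(regulator = c("A", "A", "B", "C", "A"),
                      target = c("x", "y", "y", "z", "A"),
                      tissue = "leaf")
    expect_setequal(predictSecondary(c("A", "B"), grn, c("x", "y", "z")),
                    c("x", "y"))
    expect_equal(predictSecondary(character(), grn, c("x")), character())
    expect_false("A" %in% predictSecondary("A", grn, c("A", "x", "y")))
    # multi-step closure only when requested
    grn2 <- data.frame(regulator = c("A", "x"), target = c("x", "w"),
                       tissue = "root")
    expect_setequal(predictSecondary("A", grn2, c("x", "w")), "x")
    expect_setequal(predictSecondary("A", grn2, c("x", "w"), steps = 2),
                    c("x", "w"))
})

test_that("propagation matches a breadth-first graph oracle on random networks", {
    set.seed(17)
    for (rep in 1:10) {
        genes <- sprintf("n%02d", 1:40)
        grn <- data.frame(regulator = sample(genes, 60, replace = TRUE),
                          target = sample(genes, 60, replace = TRUE),
                          tissue = "SAM")
        primaries <- sample(genes, 5)
        degSet <- sample(genes, 25)
        got <- predictSecondary(primaries, grn, degSet)
        adj <- grn[grn$regulator != grn$target, ]
        oracle <- setdiff(intersect(
            unique(adj$target[adj$regulator %in% primaries]), degSet),
            primaries)
        expect_setequal(got, oracle)
    }
})

test_that("explained fraction reproduces the cascade arithmetic", {
    expect_equal(explainedFraction(5, 5, 10), 100)
    expect_equal(explainedFraction(0, 0, 10), 0)
    expect_error(explainedFraction(1, 0, 0), "> 0")
    expect_error(explainedFraction(5, 6, 10), "exceed")
})

test_that("planted promoter motifs are recovered and classified exactly", {
    b <- simulateDataset(simulationConfig(seed = 23, nGenes = 150,
                                          statNoiseSd = 0,
                                          nMethSitesPerContext = 100L))
    sc <- b$scan$counts
    expect_equal(sc$gene_id, b$truth$gene_id)
    # every planted motif is found again (background hits may add more)
    expect_true(all(sc$n_abre >= b$truth$planted_abre))
    expect_true(all(sc$n_ce >= b$truth$planted_ce))
    # primary classification against noiseless DEG status recovers truth
    isDeg <- abs(b$truth$lfc_MUTABA_vs_MUTMS) >= 0.95
    pc <- classifyPrimary(sc$gene_id, sc$n_abre, sc$n_ce, isDeg)
    expect_equal(pc$is_primary, b$truth$true_primary_mut)
})

test_that("promoter scanning reports TSS-relative offsets within the promoter", {
    b <- simulateDataset(simulationConfig(seed = 29, nGenes = 60,
                                          statNoiseSd = 0,
                                          nMethSitesPerContext = 100L))
    h <- b$scan$hits
    expect_true(all(h$offset >= -2000 & h$offset <= -1))
})
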