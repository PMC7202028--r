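cfg <- analysisConfig()

test_that("miRNA-anchored factor is the median of per-miRNA CPM ratios", {
    wt <- c(m1 = 100, m2 = 200, m3 = 400)
    expect_equal(mirnaNormFactor(wt, wt * 2.2, 1e6, 1e6)$value, 2.2)
    expect_equal(mirnaNormFactor(wt, wt, 1e6, 1e6)$value, 1.0)
    # ratios {1, 2, 3} -> median 2; ratio of sums weighs by abundance
    mut <- c(m1 = 100, m2 = 400, m3 = 1200)
    expect_equal(mirnaNormFactor(wt, mut, 1e6, 1e6)$value, 2.0)
    expect_equal(mirnaNormFactor(wt, mut, 1e6, 1e6,
                                 method = "ratio_of_sums")$value, 1700 / 700)
    # library sizes enter through CPM
    expect_equal(mirnaNormFactor(wt, wt, 1e6, 2e6)$value, 0.5)
    # zero-count miRNAs are excluded and reported
    wt0 <- c(m1 = 100, m2 = 0)
    expect_message(nf <- mirnaNormFactor(wt0, c(m1 = 220, m2 = 50), 1e6, 1e6),
                   "excluded")
    expect_equal(nf$excluded, "m2")
    expect_error(mirnaNormFactor(c(a = 0), c(a = 5), 1e6, 1e6), "no miRNA")
})

test_that("fold-change correction subtracts the log factor", {
    expect_equal(correctedLfc(0, 2.2), -log2(2.2))
    expect_equal(correctedLfc(1.7, 1.0), 1.7)
    expect_equal(correctedLfc(log2(2.2), 2.2), 0)
})

test_that("profiles pool replicates and use a pseudocount for zeros", {
    rc <- data.frame(gene_id = rep(c("g1", "g2"), each = 4),
                     genotype = rep(c("WT", "WT", "MUT", "MUT"), 2),
                     replicate = rep(1:2, 4),
                     count = c(60, 40, 5, 5, 0, 0, 8, 2))
    libs <- c(WT = 1e6, MUT = 1e6)
    pr <- buildSiRNAProfiles(rc, libs, factor = 2.2)
    expect_equal(pr$count_wt, c(100, 0))
    expect_equal(pr$count_mut, c(10, 10))
    expect_equal(pr$raw_lfc[1], log2(10 / 100))
    expect_equal(pr$raw_lfc[2], log2(10 / 0.5))  # pseudocount on the zero side
    expect_equal(pr$corrected_lfc, pr$raw_lfc - log2(2.2))
})

test_that("depletion calls need both the fold-change and the binomial test", {
    rc <- data.frame(gene_id = rep(c("dep", "flat", "low"), each = 2),
                     genotype = rep(c("WT", "MUT"), 3), replicate = 1,
                     count = c(100, 10, 100, 220, 0, 0))
    libs <- c(WT = 1e6, MUT = 1e6)
    pr <- callDepleted(buildSiRNAProfiles(rc, libs, 2.2), libs, 2.2, cfg)
    expect_equal(pr$corrected_lfc[pr$gene_id == "dep"], log2(0.1) - log2(2.2))
    expect_true(pr$depleted[pr$gene_id == "dep"])
    # binomial oracle: mutant reads among pooled, null p = 2.2/(2.2+1)
    p0 <- 2.2 / 3.2
    expect_equal(pr$p_value[pr$gene_id == "dep"],
                 binom.test(10, 110, p0)$p.value)
    # a promoter tracking the compositional shift exactly is not depleted
    expect_false(pr$depleted[pr$gene_id == "flat"])
    expect_true(is.na(pr$depleted[pr$gene_id == "low"]))  # low-abundance
    # equal raw counts look flat but sit well below the 2.2 expectation:
    # the corrected fold change and the test both fire
    rc2 <- data.frame(gene_id = "equal", genotype = c("WT", "MUT"),
                      replicate = 1, count = c(100, 100))
    pr2 <- callDepleted(buildSiRNAProfiles(rc2, libs, 2.2), libs, 2.2, cfg)
    expect_equal(pr2$corrected_lfc, -log2(2.2))
    expect_true(pr2$depleted)
})

test_that("depletion rate is a rounded percentage, monotone in the numerator", {
    expect_equal(depletionRate(0, 50), 0.00)
    expect_equal(depletionRate(50, 50), 100.00)
    expect_error(depletionRate(1, 0), "> 0")
    expect_error(depletionRate(5, 4))
    r <- vapply(0:20, depletionRate, numeric(1), nTotal = 20)
    expect_true(all(diff(r) > 0))
})

test_that("group depletion table mirrors assignments and warns on empty groups", {
    s <- rbind(statRow(c("g1", "g2", "g3"), "MUTABA_vs_MUTMS", 2),
               statRow("g4", "WTABA_vs_WTMS", -2))
    a <- classifyGroups(s, cfg)
    calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                        cpm_wt = 10, cpm_mut = 1,
                        depleted = c(TRUE, FALSE, TRUE))
    expect_warning(tab <- groupDepletionTable(a, calls,
                                              list(V = "V", II = "II")),
                   "II")
    v <- tab[tab$subset == "V", ]
    expect_equal(v$n_genes, 3L)
    expect_equal(v$n_depleted, 2L)
    expect_equal(v$pct_depleted, depletionRate(2, 3))
    gw <- tab[tab$subset == "genome_wide", ]
    expect_equal(gw$pct_depleted, depletionRate(2, 3))
})

test_that("simulated depletion effects are recovered through the full path", {
    b <- simulateDataset(simulationConfig(seed = 31, nGenes = 400,
                                          nSirnaRegions = 400L,
                                          nMethSitesPerContext = 100L))
    libs <- setNames(b$libsizes$libsize, b$libsizes$genotype)
    nf <- mirnaNormFactor(setNames(b$mirna$count_wt, b$mirna$mirna_id),
                          setNames(b$mirna$count_mut, b$mirna$mirna_id),
                          libs[["WT"]], libs[["MUT"]])
    # the factor estimate recovers the configured global miRNA fold change
    expect_lt(abs(nf$value - 2.2), 0.15)
    pr <- callDepleted(buildSiRNAProfiles(b$sirna, libs, nf$value),
                       libs, nf$value, cfg)
    truth <- b$truth[match(pr$gene_id, b$truth$gene_id), ]
    dep <- truth$sirna_depleted
    # corrected fold change centres on log2(scale) for depleted promoters
    expect_lt(abs(mean(pr$corrected_lfc[dep]) - log2(0.25)), 0.15)
    # and on zero for undepleted ones
    expect_lt(abs(mean(pr$corrected_lfc[!dep])), 0.1)
    # calls separate the two classes cleanly at these depths
    expect_gt(mean(pr$depleted[dep], na.rm = TRUE), 0.9)
    expect_lt(mean(pr$depleted[!dep], na.rm = TRUE), 0.05)
})
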