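cfg <- analysisConfig()

test_that("weighted methylation pools counts, not per-site ratios", {
    calls <- makeCalls(c(10, 20), n_meth = c(3, 0), n_total = c(4, 4))
    expect_equal(weightedMC(calls)$mc, 3 / 8)  # mean of ratios would be 0.375 too:
    calls2 <- makeCalls(c(10, 20), n_meth = c(3, 0), n_total = c(4, 40))
    expect_equal(weightedMC(calls2)$mc, 3 / 44)  # != mean(3/4, 0)
    one <- makeCalls(5, 5, 5)
    expect_equal(weightedMC(one)$mc, 1.0)
    none <- weightedMC(calls, region = GRanges("chr2", IRanges(1, 100)))
    expect_false(none$evaluable)
    expect_true(is.na(none$mc))
    bad <- makeCalls(77, 6, 5)
    expect_error(weightedMC(bad), "chr1:77")
})

test_that("pooling over disjoint regions equals the count-weighted combination", {
    set.seed(5)
    for (rep in 1:10) {
        n <- 50
        calls <- makeCalls(sample.int(1000, n), context = "CG",
                           n_meth = rbinom(n, 10, 0.3),
                           n_total = 10)
        left <- GRanges("chr1", IRanges(1, 500))
        right <- GRanges("chr1", IRanges(501, 1000))
        a <- weightedMC(calls, left, "CG")
        b <- weightedMC(calls, right, "CG")
        whole <- weightedMC(calls, GRanges("chr1", IRanges(1, 1000)), "CG")
        na <- a$n_sites * a$coverage; nb <- b$n_sites * b$coverage
        combined <- (ifelse(na > 0, a$mc, 0) * na +
                     ifelse(nb > 0, b$mc, 0) * nb) / (na + nb)
        expect_equal(whole$mc, combined)
        expect_true(whole$mc >= 0 && whole$mc <= 1)
    }
})

test_that("conversion rate comes from the pooled chloroplast-like signal", {
    allT <- makeCalls(1:10, 0, 8, chrom = "chrC")
    expect_equal(conversionRate(allT), 1.0)
    some <- makeCalls(1:100, c(5, rep(0, 99)), 10, chrom = "chrC")
    expect_equal(conversionRate(some), 0.995)
    expect_error(conversionRate(makeCalls(1, 0, 0)), "zero coverage")
    # binomial sampling around a 0.005 non-conversion rate at 50x over 2 kb
    set.seed(9)
    sim <- makeCalls(seq(1, 2000, 10), chrom = "chrC",
                     n_meth = rbinom(200, 50, 0.005), n_total = 50)
    est <- conversionRate(sim)
    expect_lt(abs(est - 0.995), 3 * sqrt(0.005 * 0.995 / (200 * 50)))
})

test_that("evaluability filters use inclusive boundaries per mode", {
    rm5 <- list(mc = 0.2, n_sites = 2L, coverage = 5.0, evaluable = TRUE)
    rm49 <- list(mc = 0.2, n_sites = 10L, coverage = 4.9, evaluable = TRUE)
    rm3 <- list(mc = 0.2, n_sites = 2L, coverage = 3, evaluable = TRUE)
    expect_true(passesFilters(rm5, "genome_wide", cfg))
    expect_false(passesFilters(rm49, "genome_wide", cfg))
    expect_true(passesFilters(rm3, "promoter", cfg))
    expect_false(passesFilters(list(mc = NA, n_sites = 0L, coverage = 0,
                                    evaluable = FALSE), "promoter", cfg))
    expect_error(passesFilters(rm5, "tile", cfg))
    # level gates decide "methylated", separately from evaluability
    expect_true(isMethylated(list(mc = 0.011, evaluable = TRUE), "CHH", cfg))
    expect_false(isMethylated(list(mc = 0.05, evaluable = TRUE), "CG", cfg))
})

test_that("relative and absolute differences follow their formulas", {
    expect_equal(relativeDiff(0.0032, 0.0100), -68.0)
    expect_equal(relativeDiff(0.10, 0.10), 0.0)
    expect_equal(relativeDiff(0.0222, 0.0200), 11.0, tolerance = 1e-12)
    expect_warning(nd <- relativeDiff(0.1, 0), "reference")
    expect_true(is.na(nd))
    expect_equal(absoluteDiff(0.55, 0.10), 45.0)
    expect_equal(absoluteDiff(0.10, 0.55), -45.0)
    x <- runif(10)
    expect_equal(absoluteDiff(x, x), rep(0, 10))
    expect_equal(absoluteDiff(x, rev(x)), -absoluteDiff(rev(x), x))
})

test_that("non-conversion adjustment inverts the observation model", {
    p <- c(0, 0.01, 0.4, 1)
    nc <- 0.006
    pObs <- p * (1 - nc) + nc
    expect_equal(adjustForNonConversion(pObs, nc), p)
    expect_equal(adjustForNonConversion(0.001, 0.005), 0)  # truncated at zero
})

test_that("promoter tiling is TSS-anchored and matches per-site summation", {
    g <- makeGenes(5001, 6000, "+")
    # methylation only within 100 bp of the TSS -> only tile 1 has signal
    calls <- makeCalls(c(4950, 4990, 3500), n_meth = c(2, 3, 0),
                       n_total = c(4, 4, 0))
    tl <- tilePromoters(g, calls, "CHH", cfg)
    expect_equal(nrow(tl), 20L)
    t1 <- tl[tl$tile_index == 1, ]
    expect_equal(t1$mc, 5 / 8)
    expect_true(all(!tl$evaluable[tl$tile_index > 1]))
    # brute-force oracle: random sites, direct summation over tile bounds
    set.seed(21)
    for (strand in c("+", "-")) {
        gg <- makeGenes(30001, 32000, strand)
        tssP <- unname(tssPosition(gg))
        pos <- sample(seq(tssP - 2500, tssP + 2500), 300)
        cc <- makeCalls(pos, n_meth = rbinom(300, 6, 0.2), n_total = 6)
        tl <- tilePromoters(gg, cc, "CHH", cfg)
        for (k in c(1, 7, 20)) {
            d <- if (strand == "+") tssP - cc$pos else cc$pos - tssP
            inTile <- d >= (k - 1) * 100 + 1 & d <= k * 100
            row <- tl[tl$tile_index == k, ]
            expect_equal(row$n_sites, sum(inTile))
            if (sum(cc$n_total[inTile]) > 0)
                expect_equal(row$mc,
                             sum(cc$n_meth[inTile]) / sum(cc$n_total[inTile]))
        }
    }
})

test_that("metagene profiles average evaluable tiles and track the ABA gain", {
    tiles <- data.frame(gene_id = rep(c("a", "b"), each = 2),
                        tile_index = c(1, 2, 1, 2), context = "CHH",
                        mc = c(0.02, NA, 0.04, 0.10),
                        n_sites = c(3, 0, 3, 3), coverage = 5,
                        evaluable = c(TRUE, FALSE, TRUE, TRUE))
    mp <- metageneProfile(tiles)
    expect_equal(mp$mean_mc[mp$tile_index == 1], 0.03)
    expect_equal(mp$n_genes, c(2L, 1L))
    expect_equal(nrow(metageneProfile(tiles[0, ])), 0L)
})

test_that("differential-promoter calls implement the context rules", {
    expect_equal(callDifferentialPromoter(0.55, 0.10, "CG"),
                 "differential+CG_hypermethylated")
    expect_equal(callDifferentialPromoter(0.03, 0.20, "CHH"), "differential")
    expect_equal(callDifferentialPromoter(0.30, 0.10, "CHG"), "none")
    # CHH needs the low sample at or below 5%
    expect_equal(callDifferentialPromoter(0.07, 0.30, "CHH"), "none")
    # a 10-39 point CG gain is hypermethylated but not differential
    expect_equal(callDifferentialPromoter(0.30, 0.10, "CG"),
                 "CG_hypermethylated")
    expect_error(callDifferentialPromoter(0.1, 0.2, "CAA"))
})
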