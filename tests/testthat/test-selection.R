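mkPresence <- function(early, healthy, stroma, late = rep(0L, 11)) {
    m <- rbind(c(early, late, healthy, stroma))
    rownames(m) <- "P1"
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    storage.mode(m) <- "integer"
    SpectralCountExperiment(m, group = rep(c("early_cancer", "late_cancer",
                                             "healthy_epithelium", "stroma"),
                                           c(length(early), length(late),
                                             length(healthy), length(stroma))))
}

test_that("all-or-nothing enforces its three clauses", {
    p <- c(P1 = 1e-5)
    ## present 11/11 early, absent in both control tissues -> selected
    sce <- mkPresence(rep(1L, 11), rep(0L, 13), rep(0L, 13))
    expect_identical(allOrNothing(sce, p), "P1")
    ## presence in late cancer is permitted
    sce <- mkPresence(rep(1L, 11), rep(0L, 13), rep(0L, 13), late = rep(5L, 11))
    expect_identical(allOrNothing(sce, p), "P1")
    ## only 6 of 11 early -> below the presence floor
    sce <- mkPresence(c(rep(1L, 6), rep(0L, 5)), rep(0L, 13), rep(0L, 13))
    expect_identical(allOrNothing(sce, p), character(0))
    ## a single stroma count disqualifies
    sce <- mkPresence(c(rep(1L, 8), rep(0L, 3)), rep(0L, 13),
                      c(1L, rep(0L, 12)))
    expect_identical(allOrNothing(sce, p), character(0))
    ## p-value clause
    sce <- mkPresence(rep(1L, 11), rep(0L, 13), rep(0L, 13))
    expect_identical(allOrNothing(sce, c(P1 = 0.2)), character(0))
    expect_error(allOrNothing(sce, p, targetGroup = "stroma"),
                 "excluded")
})

test_that("group-exclusive selection respects the presence boundary", {
    sce <- mkPresence(rep(0L, 11), c(rep(1L, 6), rep(0L, 7)), rep(0L, 13))
    expect_identical(exclusiveInGroup(sce, "healthy_epithelium", 6), "P1")
    sce <- mkPresence(rep(0L, 11), c(rep(1L, 5), rep(0L, 8)), rep(0L, 13))
    expect_identical(exclusiveInGroup(sce, "healthy_epithelium", 6), character(0))
    ## one early-cancer count breaks exclusivity even at full presence
    sce <- mkPresence(c(1L, rep(0L, 10)), rep(1L, 13), rep(0L, 13))
    expect_identical(exclusiveInGroup(sce, "healthy_epithelium", 6), character(0))
})

test_that("Bonferroni thresholding is alpha over m, strict", {
    expect_equal(bonferroni(0.5, 0.05, 10)$threshold, 0.005)
    expect_equal(bonferroni(0.5, 0.05, 1)$threshold, 0.05)
    expect_equal(bonferroni(0.5, 0.05, 5061)$threshold, 9.88e-6, tolerance = 1e-3)
    b <- bonferroni(c(0.004, 0.005, 0.006), 0.05, 10)
    expect_identical(b$significant, c(TRUE, FALSE, FALSE))  # strict at the cutoff
})

test_that("Benjamini-Hochberg equals the brute-force step-up oracle", {
    expect_true(benjaminiHochberg(0.01, 0.05)$significant)
    allOnes <- benjaminiHochberg(rep(1, 5), 0.05)
    expect_false(any(allOnes$significant))
    expect_equal(allOnes$adjusted, rep(1, 5))
    stepUp <- benjaminiHochberg(c(0.01, 0.02, 0.03, 0.9), 0.05)
    expect_identical(stepUp$significant, c(TRUE, TRUE, TRUE, FALSE))

    set.seed(14)
    for (i in 1:200) {
        m <- sample(1:50, 1)
        p <- runif(m)^sample(1:3, 1)
        expect_identical(benjaminiHochberg(p, 0.05)$significant,
                         bhOracle(p, 0.05))
    }
})

test_that("selection regimes are nested: Bonferroni => BH => raw threshold", {
    set.seed(15)
    for (i in 1:50) {
        p <- runif(sample(5:80, 1))^2
        bf <- bonferroni(p, 0.05)$significant
        bh <- benjaminiHochberg(p, 0.05)$significant
        expect_true(all(!bf | bh))
        expect_true(all(!bh | (p < 0.05 + 1e-15)))
    }
})

test_that("all-or-nothing recovers the planted exclusive set exactly", {
    sim <- simulateStudy(smallConfig(23))
    ct <- contrastSpec("early_cancer", "healthy_epithelium",
                       testMethod = "fisher_presence")
    p <- differentialTest(sim$sce, ct)
    sel <- allOrNothing(sim$sce, p)
    planted <- sim$truth$protein_id[sim$truth$class == "tumor_exclusive"]
    expect_setequal(sel, planted)
})

test_that("selectionFlags annotates a differential table coherently", {
    sim <- simulateStudy(smallConfig(29))
    ct <- contrastSpec("early_cancer", "healthy_epithelium")
    tab <- differentialTable(sim$sce, ct)
    tab <- selectionFlags(tab, sim$sce)
    expect_true(all(c("all_or_nothing", "bonferroni", "bh") %in% colnames(tab)))
    expect_true(all(!tab$bonferroni | tab$bh))
    expect_true(all(tab$p_value[tab$bh] < 0.05 + 1e-12))
})
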