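mkSCE <- function(countsByGroup) {
    mats <- lapply(countsByGroup, as.matrix)
    m <- do.call(cbind, mats)
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    storage.mode(m) <- "integer"
    if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
    SpectralCountExperiment(m, group = rep(names(countsByGroup),
                                           vapply(mats, ncol, 0L)))
}

test_that("zero replacement touches only zeros", {
    expect_equal(replaceZeros(c(0, 3, 0)), c(0.125, 3, 0.125))
    expect_equal(replaceZeros(c(1, 2, 7)), c(1, 2, 7))
    expect_equal(replaceZeros(0, pseudocount = 1), 1)
    expect_error(replaceZeros(-1), "nonnegative")
})

test_that("log2 fold-change reproduces the pseudocount arithmetic", {
    sce <- mkSCE(list(early_cancer = matrix(c(4L, 0L, 5L), 3, 4),
                      healthy_epithelium = matrix(c(0L, 0L, 5L), 3, 4)))
    ct <- contrastSpec("early_cancer", "healthy_epithelium")
    fc <- log2FoldChange(sce, ct)
    expect_equal(unname(fc[1]), log2(4 / 0.125))   # = 5, a 32-fold increase
    expect_equal(unname(fc[1]), 5)
    expect_equal(unname(fc[2]), 0)                 # both groups all-zero
    expect_equal(unname(fc[3]), 0)                 # equal means
})

test_that("swapping contrast groups negates every fold-change", {
    sim <- simulateStudy(smallConfig(21))
    f1 <- log2FoldChange(sim$sce, contrastSpec("early_cancer", "healthy_epithelium"))
    f2 <- log2FoldChange(sim$sce, contrastSpec("healthy_epithelium", "early_cancer"))
    expect_equal(f1, -f2)
})

test_that("planted fold-change effects are recovered by the estimator", {
    cfg <- simulationConfig(nProteins = 5000, propFcUp = 0.1, propFcDown = 0,
                            propTumorExclusive = 0, propHealthyExclusive = 0,
                            log2Effect = 2, seed = 31)
    sim <- simulateStudy(cfg)
    up <- sim$truth$protein_id[sim$truth$class == "fc_up"]
    fc <- log2FoldChange(sim$sce, contrastSpec("early_cancer", "healthy_epithelium"))
    expect_lt(abs(median(fc[up]) - 2), 0.25)
})

test_that("welch test on log counts matches t.test and handles degeneracy", {
    ## degenerate: both groups constant and equal -> p = 1
    sce <- mkSCE(list(early_cancer = matrix(3L, 1, 4),
                      healthy_epithelium = matrix(3L, 1, 4)))
    ct <- contrastSpec("early_cancer", "healthy_epithelium")
    expect_equal(unname(differentialTest(sce, ct)), 1)

    ## constant but different -> tiny but positive
    sce2 <- mkSCE(list(early_cancer = matrix(8L, 1, 4),
                      healthy_epithelium = matrix(2L, 1, 4)))
    p2 <- unname(differentialTest(sce2, ct))
    expect_gt(p2, 0)
    expect_lt(p2, 1e-10)

    ## agreement with stats::t.test on random data
    set.seed(42)
    m <- matrix(rpois(50 * 24, 6), 50, 24,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:24)))
    sce3 <- SpectralCountExperiment(m, group = rep(c("early_cancer",
                                                     "healthy_epithelium"),
                                                   c(11, 13)))
    p <- differentialTest(sce3, ct)
    lg <- log2(replaceZeros(m))
    pRef <- apply(lg, 1, function(v)
        t.test(v[1:11], v[12:24])$p.value)
    expect_equal(unname(p), unname(pRef), tolerance = 1e-12)
})

test_that("presence-based Fisher test equals exhaustive enumeration", {
    ## full separation 11/11 vs 0/13
    sce <- mkSCE(list(early_cancer = matrix(2L, 1, 11),
                      healthy_epithelium = matrix(0L, 1, 13)))
    ct <- contrastSpec("early_cancer", "healthy_epithelium",
                       testMethod = "fisher_presence")
    p <- unname(differentialTest(sce, ct))
    expect_equal(p, fisherTwoSidedOracle(11, 11, 0, 13), tolerance = 1e-12)
    expect_equal(p, 1 / choose(24, 11), tolerance = 1e-9)

    ## balanced presence -> p = 1
    sceEq <- mkSCE(list(early_cancer = rbind(c(1L,1L,1L,1L,1L,0L,0L,0L,0L,0L)),
                        healthy_epithelium = rbind(c(1L,1L,1L,1L,1L,0L,0L,0L,0L,0L))))
    expect_equal(unname(differentialTest(sceEq, ct)), 1)

    ## random tables against the enumeration oracle
    set.seed(9)
    for (i in 1:25) {
        na <- sample(2:13, 1); nb <- sample(2:13, 1)
        pa <- sample(0:na, 1); pb <- sample(0:nb, 1)
        rowA <- c(rep(1L, pa), rep(0L, na - pa))
        rowB <- c(rep(1L, pb), rep(0L, nb - pb))
        sceR <- mkSCE(list(early_cancer = rbind(rowA),
                           healthy_epithelium = rbind(rowB)))
        expect_equal(unname(differentialTest(sceR, ct)),
                     fisherTwoSidedOracle(pa, na, pb, nb), tolerance = 1e-9)
    }
})

test_that("volcano table has the exact schema, sorted by significance", {
    sim <- simulateStudy(smallConfig(17))
    ct <- contrastSpec("early_cancer", "healthy_epithelium")
    v <- volcanoTable(sim$sce, ct)
    expect_identical(colnames(v), c("protein_id", "log2_fc", "neg_log10_p"))
    expect_identical(nrow(v), nrow(sim$sce))
    expect_true(!is.unsorted(rev(v$neg_log10_p)))
    ## -log10 identity at p = 0.05
    expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)
})

test_that("cell-line contrast classification follows the two filter rules", {
    fc <- data.frame(ec = c(3.1, 2.8, 0), lc = c(3.2, 3.3, 0),
                     hela = c(4.3, 0.0, 0), u87 = c(0.0, 0.0, 0),
                     hek293 = c(0.0, 0.0, 0))
    expect_identical(classifyFoldChanges(fc, 2.5),
                     c("tumor_and_HeLa", "tumor_only", "unclassified"))

    ## end-to-end from counts: one protein high in tumors+HeLa only
    groups <- list(early_cancer = matrix(c(8L, 0L), 2, 11),
                   late_cancer = matrix(c(8L, 0L), 2, 11),
                   healthy_epithelium = matrix(0L, 2, 13),
                   stroma = matrix(0L, 2, 13),
                   `cell_line:HeLa` = matrix(c(8L, 0L), 2, 1),
                   `cell_line:U87` = matrix(0L, 2, 1),
                   `cell_line:HEK293` = matrix(0L, 2, 1))
    sce <- mkSCE(groups)
    res <- cellLineContrast(sce, fcMin = 2.5)
    expect_identical(res$class, c("tumor_and_HeLa", "unclassified"))

    noHeLa <- sce[, sampleGroups(sce) != "cell_line:HeLa"]
    expect_error(cellLineContrast(noHeLa), "cell_line:HeLa")
})

test_that("replicate overlap is intersection over union", {
    expect_equal(replicateOverlap(list(c("A", "B"), c("A", "B")))$overall, 100)
    expect_equal(replicateOverlap(list(c("A", "B"), c("C", "D")))$overall, 0)
    r <- replicateOverlap(list(c("A", "B", "C"), c("B", "C", "D")))
    expect_equal(r$overall, 50)
    expect_equal(r$pairwise[1, 2], 50)
    r3 <- replicateOverlap(list(c("A", "B", "C"), c("B", "C", "D"), c("B", "C")))
    expect_equal(r3$overall, 100 * 2 / 4)
    expect_error(replicateOverlap(list(c("A"))), "two")
})
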