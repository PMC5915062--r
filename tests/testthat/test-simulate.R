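test_that("simulation is deterministic given its seed", {
    s1 <- simulateStudy(smallConfig(7))
    s2 <- simulateStudy(smallConfig(7))
    expect_identical(spectralCounts(s1$sce), spectralCounts(s2$sce))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateStudy(smallConfig(8))
    expect_false(identical(spectralCounts(s1$sce), spectralCounts(s3$sce)))
})

test_that("all-null configuration plants nothing", {
    cfg <- smallConfig(3, propFcUp = 0, propFcDown = 0,
                       propTumorExclusive = 0, propHealthyExclusive = 0)
    sim <- simulateStudy(cfg)
    expect_true(all(sim$truth$class == "null"))
})

test_that("planted tumor-exclusive proteins are exactly the all-zero rows in control tissue", {
    cfg <- simulationConfig(nProteins = 2500, propTumorExclusive = 31 / 2500,
                            propHealthyExclusive = 0, seed = 11)
    sim <- simulateStudy(cfg)
    planted <- sim$truth$protein_id[sim$truth$class == "tumor_exclusive"]
    expect_length(planted, 31)
    grp <- sampleGroups(sim$sce)
    ctl <- grp %in% c("healthy_epithelium", "stroma")
    expect_identical(sum(ctl), 26L)
    allZero <- rownames(sim$sce)[rowSums(spectralCounts(sim$sce)[, ctl]) == 0]
    expect_setequal(allZero, planted)
    ## presence floor in early cancer holds for every planted protein
    pres <- presenceCounts(sim$sce, "early_cancer")[planted]
    expect_true(all(pres >= cfg$tumorExclusiveMinPresent))
})

test_that("healthy-exclusive proteins are absent outside healthy epithelium", {
    sim <- simulateStudy(smallConfig(5))
    planted <- sim$truth$protein_id[sim$truth$class == "healthy_exclusive"]
    grp <- sampleGroups(sim$sce)
    other <- grp != "healthy_epithelium"
    expect_true(all(rowSums(spectralCounts(sim$sce)[planted, other, drop = FALSE]) == 0))
    expect_true(all(presenceCounts(sim$sce, "healthy_epithelium")[planted] >= 6))
})

test_that("class-conditional means follow the configured effect size", {
    cfg <- simulationConfig(nProteins = 5000, propFcUp = 0.25, propFcDown = 0,
                            propTumorExclusive = 0, propHealthyExclusive = 0,
                            dropout = 0, log2Effect = 2, seed = 13)
    sim <- simulateStudy(cfg)
    up <- sim$truth$protein_id[sim$truth$class == "fc_up"]
    cancer <- sampleGroups(sim$sce) %in% c("early_cancer", "late_cancer")
    mCancer <- mean(spectralCounts(sim$sce)[up, cancer])
    mHealthy <- mean(spectralCounts(sim$sce)[up, !cancer])
    expect_equal(mCancer, cfg$mu * 2^2, tolerance = 0.02)
    expect_equal(mHealthy, cfg$mu, tolerance = 0.02)
})

test_that("configuration validation rejects impossible settings", {
    expect_error(simulationConfig(seed = NULL), "seed")
    expect_error(simulationConfig(propFcUp = 0.9, propFcDown = 0.2, seed = 1),
                 "proportions")
    expect_error(simulationConfig(mu = -1, seed = 1), "positive")
    expect_error(simulationConfig(dropout = 1, seed = 1), "dropout")
})

test_that("simulated gene sets contain the planted members and respect the seed", {
    bg <- sprintf("G%04d", 1:3000)
    planted <- bg[1:14]
    gsc <- simulateGeneSets(nSets = 10, setSize = 35, background = bg,
                            plantedMembers = planted, seed = 2)
    expect_true(all(planted %in% geneSets(gsc)[["NET01"]]))
    expect_length(geneSets(gsc)[["NET01"]], 35)
    gsc2 <- simulateGeneSets(nSets = 10, setSize = 35, background = bg,
                             plantedMembers = planted, seed = 2)
    expect_identical(geneSets(gsc), geneSets(gsc2))
    ## a strong planted overlap produces an extreme right-tail score
    input <- c(planted, bg[2900:2915])  # 30 genes, 14 in the planted set
    p <- fisherEnrichment(input, geneSets(gsc)[["NET01"]], bg)
    expect_lt(p, 1e-20)
})

test_that("PRM series: zero noise is exactly linear, level 0 is intercept-only", {
    s <- simulatePRMSeries(slope = 1000, intercept = 50, cv = 0, seed = 1)
    expect_equal(s$area, 1000 * s$level + 50)
    expect_equal(unique(s$area[s$level == 0]), 50)
    fit <- fitCalibration(s)
    expect_equal(calibrationSummary(fit)$slope, 1000, tolerance = 1e-12)
})

test_that("expression simulation orders class means and respects its seed", {
    genes <- sprintf("G%03d", 1:300)
    e <- simulateExpression(genes, nSamples = 30, highSet = genes[1:30],
                            lowSet = genes[271:300], seed = 4)
    mu <- rowMeans(e)
    expect_gt(mean(mu[1:30]), mean(mu[31:270]))
    expect_gt(mean(mu[31:270]), mean(mu[271:300]))
    e2 <- simulateExpression(genes, nSamples = 30, highSet = genes[1:30],
                             lowSet = genes[271:300], seed = 4)
    expect_identical(e, e2)
})
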