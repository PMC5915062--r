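test_that("isotope-dilution arithmetic", {
    expect_equal(peptideAmountFmol(1000, 1000, 10, 1), 10)
    expect_equal(peptideAmountFmol(0, 1000, 10, 1), 0)
    ## half the SIL signal, 50 of 200 uL digested -> 20 fmol whole-lysate
    expect_equal(peptideAmountFmol(500, 1000, 10, 4), 20)
    ## zero SIL area: flagged not quantifiable, never infinite
    expect_true(is.na(peptideAmountFmol(500, 0)))
    expect_error(peptideAmountFmol(-1, 10), "nonnegative")
})

test_that("protein roll-up converts fmol to ng via molecular weight", {
    expect_equal(proteinAmountNg(10, 1e5), 1)
    expect_equal(proteinAmountNg(0, 1e5), 0)
    expect_equal(proteinAmountNg(c(8, 12), 5e4), 10 * 5e4 * 1e-6)  # median 10
    expect_equal(proteinAmountNg(c(8, 12, NA), 5e4, aggregate = "mean"), 0.5)
})

test_that("calibration: noise-free series fits exactly", {
    s <- simulatePRMSeries(slope = 12.5, intercept = 40, cv = 0, seed = 1)
    curve <- fitCalibration(s)
    cs <- calibrationSummary(curve)
    expect_equal(cs$slope, 12.5, tolerance = 1e-12)
    expect_equal(cs$intercept, 40, tolerance = 1e-10)
    expect_equal(cs$r_squared, 1)
    expect_equal(cs$lod_fmol_per_ul, 0)
    expect_equal(cs$loq_fmol_per_ul, 0)
    expect_true(cs$valid)
})

test_that("blank-based LOD and LOQ follow the 3.3/10 sigma convention", {
    ## construct a series whose blank sd is exactly 3 and slope exactly 10
    s <- data.frame(peptide = "PEP1",
                    level = rep(c(0, 1, 2, 4), each = 3),
                    replicate = rep(1:3, 4),
                    area = c(0, 3, 6, rep(10 * c(1, 2, 4), each = 3) + 3))
    curve <- fitCalibration(s)
    cs <- calibrationSummary(curve)
    expect_equal(sd(c(0, 3, 6)), 3)
    expect_equal(cs$slope, 10, tolerance = 1e-10)
    expect_equal(cs$lod_fmol_per_ul, 3.3 * 3 / 10, tolerance = 1e-9)
    expect_equal(cs$loq_fmol_per_ul, 10 * 3 / 10, tolerance = 1e-9)
    expect_lte(cs$lod_fmol_per_ul, cs$loq_fmol_per_ul)
})

test_that("per-level CV is 100*sd/mean", {
    s <- data.frame(level = rep(c(0, 1, 2), each = 3), replicate = rep(1:3, 3),
                    area = c(1, 1, 1, 9, 10, 11, 20, 20, 20))
    cv <- calibrationCV(fitCalibration(s))
    expect_equal(cv$cv_percent[cv$level == 1], 10)
    expect_equal(cv$cv_percent[cv$level == 2], 0)
})

test_that("a decreasing series is flagged invalid", {
    s <- data.frame(level = rep(c(0, 1, 2), each = 2), replicate = rep(1:2, 3),
                    area = c(100, 100, 50, 50, 10, 10))
    curve <- fitCalibration(s)
    expect_false(calibrationSummary(curve)$valid)
})

test_that("area rescaling leaves ratios, CVs, R^2 and LOD invariant", {
    s <- simulatePRMSeries(slope = 1000, intercept = 100, cv = 0.08, seed = 21)
    s10 <- s; s10$area <- s$area * 10
    c1 <- calibrationSummary(fitCalibration(s))
    c10 <- calibrationSummary(fitCalibration(s10))
    expect_equal(c10$slope, 10 * c1$slope)
    expect_equal(c10$sigma_blank, 10 * c1$sigma_blank)
    expect_equal(c10$r_squared, c1$r_squared)
    expect_equal(c10$lod_fmol_per_ul, c1$lod_fmol_per_ul)
    expect_equal(calibrationCV(fitCalibration(s10))$cv_percent,
                 calibrationCV(fitCalibration(s))$cv_percent)
    expect_equal(peptideAmountFmol(500, 250), peptideAmountFmol(5000, 2500))
})

test_that("slope is recovered within 2% at 5% noise (median over seeds)", {
    relErr <- vapply(1:100, function(s) {
        fit <- fitCalibration(simulatePRMSeries(slope = 1000, intercept = 0,
                                                cv = 0.05, seed = s))
        abs(calibrationSummary(fit)$slope - 1000) / 1000
    }, 0)
    expect_lt(median(relErr), 0.02)
})

test_that("measurement tables quantify per sample and protein", {
    meas <- data.frame(sample_id = rep("1218", 3),
                       peptide = c("p1", "p2", "p3"),
                       protein = rep("MCM3", 3),
                       endogenous_area = c(800, 1200, 0),
                       sil_area = c(1000, 1000, 0),
                       spike_fmol = 10, scale_factor = 4)
    q <- quantifyPRM(meas, c(MCM3 = 91000))
    ## p3 is not quantifiable; median of 32 and 48 fmol = 40 fmol
    expect_equal(q$amount_fmol, 40)
    expect_equal(q$amount_ng, 40 * 91000 * 1e-6)
    expect_equal(q$n_peptides, 2)
    expect_error(quantifyPRM(meas, c(OTHER = 1)), "MCM3")
})
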