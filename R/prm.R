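#' Endogenous peptide amount from a SIL spike ratio
#'
#' Standard isotope-dilution arithmetic: amount = (endogenous area / SIL
#' area) x spiked amount x scale factor, where the scale factor maps the
#' digested aliquot to the whole lysate (e.g. 4 when 50 of 200 uL were
#' digested). A zero SIL area makes the ratio undefined; the result is
#' \code{NA} (flagged not quantifiable), never infinity.
#'
#' @param endogenousArea integrated chromatographic peak area of the
#'   endogenous peptide (arbitrary units).
#' @param silArea peak area of the stable-isotope-labeled standard (same
#'   units).
#' @param spikeFmol amount of SIL peptide spiked (fmol; default 10).
#' @param scaleFactor unitless aliquot-to-lysate multiplier (default 1).
#' @return numeric vector of amounts in fmol, \code{NA} where not
#'   quantifiable.
#' @examples
#' peptideAmountFmol(500, 1000, spikeFmol = 10, scaleFactor = 4)  # 20 fmol
#' @export
peptideAmountFmol <- function(endogenousArea, silArea, spikeFmol = 10,
                              scaleFactor = 1) {
    if (any(endogenousArea < 0) || any(silArea < 0)) stop("areas must be nonnegative")
    if (any(spikeFmol <= 0) || any(scaleFactor <= 0))
        stop("spikeFmol and scaleFactor must be positive")
    out <- (endogenousArea / silArea) * spikeFmol * scaleFactor
    out[silArea == 0] <- NA_real_
    out
}

#' Protein amount in nanograms from peptide amounts
#'
#' Rolls peptide-level amounts up to the protein (median across peptides by
#' default, robust to a single interfered transition; mean available), then
#' converts moles to mass: ng = fmol x MW(Da) x 1e-6.
#'
#' @param peptideFmol numeric vector of peptide amounts in fmol (NAs from
#'   non-quantifiable peptides are dropped).
#' @param molecularWeightDa protein molecular weight in Daltons.
#' @param aggregate \code{"median"} (default) or \code{"mean"}.
#' @return protein amount in ng.
#' @examples
#' proteinAmountNg(10, 1e5)  # 1 ng
#' @export
proteinAmountNg <- function(peptideFmol, molecularWeightDa,
                            aggregate = c("median", "mean")) {
    aggregate <- match.arg(aggregate)
    stopifnot(molecularWeightDa > 0)
    v <- peptideFmol[!is.na(peptideFmol)]
    if (!length(v)) return(NA_real_)
    amt <- if (aggregate == "median") stats::median(v) else mean(v)
    amt * molecularWeightDa * 1e-6
}

#' Fit a PRM calibration curve
#'
#' Ordinary least squares of mean peak area on dilution level; R^2 on the
#' replicate means. Detection limits use the blank-based convention: LOD =
#' 3.3 sigma_blank / slope and LOQ = 10 sigma_blank / slope, with
#' sigma_blank the sd of level-0 replicate areas (falling back to the
#' residual sd of the fit when no blank replicates exist). Per-level CV\% =
#' 100 sd / mean of replicate areas. A non-positive slope flags the curve
#' invalid.
#'
#' @param series data.frame with columns \code{level}, \code{replicate},
#'   \code{area} (and optionally \code{peptide}, assumed homogeneous).
#' @return a \linkS4class{CalibrationCurve}.
#' @export
fitCalibration <- function(series) {
    req <- c("level", "replicate", "area")
    stopifnot(all(req %in% colnames(series)))
    peptide <- if ("peptide" %in% colnames(series))
        as.character(series$peptide[1L]) else "peptide"
    levels <- sort(unique(series$level))
    if (length(levels) < 3L) stop("at least 3 distinct levels are required")
    means <- vapply(levels, function(l) mean(series$area[series$level == l]), 0)
    fit <- stats::lm(means ~ levels)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((means - mean(means))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    blanks <- series$area[series$level == 0]
    sigmaBlank <- if (length(blanks) >= 2L) stats::sd(blanks)
                  else stats::sd(stats::residuals(fit))
    valid <- is.finite(slope) && slope > 0
    lod <- if (valid) 3.3 * sigmaBlank / slope else NA_real_
    loq <- if (valid) 10 * sigmaBlank / slope else NA_real_
    cv <- data.frame(level = levels,
                     cv_percent = vapply(levels, function(l) {
                         a <- series$area[series$level == l]
                         if (length(a) < 2L || mean(a) == 0) return(NA_real_)
                         100 * stats::sd(a) / mean(a)
                     }, 0))
    new("CalibrationCurve", peptide = peptide, levels = levels,
        areas = data.frame(level = series$level, replicate = series$replicate,
                           area = series$area),
        slope = slope, intercept = intercept, rSquared = r2,
        sigmaBlank = sigmaBlank, lod = lod, loq = loq, cv = cv, valid = valid)
}

#' Accessors for CalibrationCurve
#'
#' @param curve a \linkS4class{CalibrationCurve}.
#' @return \code{calibrationSummary}: one-row data.frame of the fit
#'   parameters; \code{calibrationCV}: per-level CV table.
#' @name calibration-accessors
NULL

#' @rdname calibration-accessors
#' @export
calibrationSummary <- function(curve) {
    data.frame(peptide = curve@peptide, slope = curve@slope,
               intercept = curve@intercept, r_squared = curve@rSquared,
               sigma_blank = curve@sigmaBlank, lod_fmol_per_ul = curve@lod,
               loq_fmol_per_ul = curve@loq, valid = curve@valid,
               stringsAsFactors = FALSE)
}

#' @rdname calibration-accessors
#' @export
calibrationCV <- function(curve) curve@cv

#' Quantify proteins from a PRM measurement table
#'
#' Applies \code{\link{peptideAmountFmol}} per measurement row and rolls up
#' to protein amounts per sample with \code{\link{proteinAmountNg}}.
#'
#' @param measurements data.frame as returned by
#'   \code{\link{readPRMMeasurements}}.
#' @param molecularWeights named numeric vector of protein molecular weights
#'   (Da), one per protein in the table.
#' @param aggregate roll-up across a protein's peptides, \code{"median"}
#'   (default) or \code{"mean"}.
#' @return data.frame with columns \code{sample_id}, \code{protein},
#'   \code{amount_fmol}, \code{amount_ng}, \code{n_peptides}.
#' @export
quantifyPRM <- function(measurements, molecularWeights,
                        aggregate = c("median", "mean")) {
    aggregate <- match.arg(aggregate)
    missingMW <- setdiff(unique(measurements$protein), names(molecularWeights))
    if (length(missingMW))
        stop("no molecular weight for protein(s): ",
             paste(missingMW, collapse = ", "))
    measurements$fmol <- peptideAmountFmol(measurements$endogenous_area,
                                           measurements$sil_area,
                                           measurements$spike_fmol,
                                           measurements$scale_factor)
    agg <- if (aggregate == "median") stats::median else mean
    keys <- unique(measurements[, c("sample_id", "protein")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
        sub <- measurements[measurements$sample_id == keys$sample_id[i] &
                            measurements$protein == keys$protein[i], ]
        v <- sub$fmol[!is.na(sub$fmol)]
        fmol <- if (length(v)) agg(v) else NA_real_
        data.frame(sample_id = keys$sample_id[i], protein = keys$protein[i],
                   amount_fmol = fmol,
                   amount_ng = if (is.na(fmol)) NA_real_ else
                       fmol * molecularWeights[[keys$protein[i]]] * 1e-6,
                   n_peptides = length(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
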