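#' @importFrom methods new validObject is callNextMethod setValidity show
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Closed vocabulary for tissue groups; cell lines carry a "cell_line:" prefix
## (e.g. "cell_line:HeLa") so the set stays open for arbitrary culture samples.
.TISSUE_GROUPS <- c("early_cancer", "late_cancer", "healthy_epithelium", "stroma")
.CANCER_GROUPS <- c("early_cancer", "late_cancer")

.isCellLine <- function(group) startsWith(group, "cell_line:")
.isValidGroup <- function(group) group %in% .TISSUE_GROUPS | .isCellLine(group)

#' SpectralCountExperiment: protein x sample spectral counts with annotations
#'
#' An S4 container for label-free spectral-count proteomics data, extending
#' \linkS4class{SummarizedExperiment}. Rows are proteins (keyed by gene
#' symbol), columns are samples. The single assay \code{"counts"} holds
#' nonnegative integer spectral counts (number of MS/MS spectra assigned to
#' peptides of a protein in a sample). Column data records the sample group
#' (one of \code{early_cancer}, \code{late_cancer}, \code{healthy_epithelium},
#' \code{stroma}, or \code{cell_line:<name>}), and optionally patient age
#' (years) and FIGO stage (cancer samples only).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @name SpectralCountExperiment-class
#' @aliases SpectralCountExperiment-class
#' @exportClass SpectralCountExperiment
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
    msgs <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (anyNA(cnt) || any(cnt < 0))
        msgs <- c(msgs, "counts must be nonnegative and non-missing")
    else if (any(cnt != round(cnt)))
        msgs <- c(msgs, "counts must be integral spectral counts")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "protein ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msgs <- c(msgs, "sample ids must be present and unique")
    cd <- colData(object)
    if (!"group" %in% colnames(cd)) {
        msgs <- c(msgs, "colData must contain a 'group' column")
    } else {
        grp <- as.character(cd$group)
        bad <- grp[!.isValidGroup(grp)]
        if (length(bad))
            msgs <- c(msgs, paste0("unknown sample group(s): ",
                                   paste(unique(bad), collapse = ", ")))
        if ("figo_stage" %in% colnames(cd)) {
            fig <- as.character(cd$figo_stage)
            offend <- !is.na(fig) & fig != "" & !(grp %in% .CANCER_GROUPS)
            if (any(offend))
                msgs <- c(msgs, "figo_stage may only be set for cancer samples")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SpectralCountExperiment
#'
#' @param counts numeric matrix of nonnegative integer spectral counts with
#'   protein ids as rownames and sample ids as colnames.
#' @param group character vector (one per sample) of group labels from the
#'   closed vocabulary \code{early_cancer}, \code{late_cancer},
#'   \code{healthy_epithelium}, \code{stroma}, or \code{cell_line:<name>}.
#' @param age optional numeric vector of patient ages in years.
#' @param figo_stage optional character vector of FIGO stages (e.g.
#'   \code{"Ib2"}); allowed only for cancer samples, \code{NA} elsewhere.
#' @return A \linkS4class{SpectralCountExperiment}.
#' @examples
#' m <- matrix(c(0L, 3L, 2L, 5L), 2, 2,
#'             dimnames = list(c("MCM4", "S100P"), c("s1", "s2")))
#' sce <- SpectralCountExperiment(m, group = c("early_cancer", "healthy_epithelium"))
#' spectralCounts(sce)
#' @export
SpectralCountExperiment <- function(counts, group, age = NULL, figo_stage = NULL) {
    counts <- as.matrix(counts)
    if (length(group) != ncol(counts))
        stop("'group' must have one entry per sample column")
    cd <- DataFrame(group = as.character(group), row.names = colnames(counts))
    if (!is.null(age)) cd$age <- as.numeric(age)
    if (!is.null(figo_stage)) cd$figo_stage <- as.character(figo_stage)
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("SpectralCountExperiment", se)
}

#' Combine a count matrix and a sample annotation table
#'
#' Joins a protein x sample count matrix (as returned by
#' \code{\link{readCountMatrix}}) with a sample annotation table (as returned
#' by \code{\link{readAnnotations}}). Every matrix sample must be annotated;
#' a missing annotation is a hard error, never a silent drop.
#'
#' @param counts integer matrix, proteins x samples.
#' @param annotations data.frame with columns \code{sample_id}, \code{group}
#'   and optionally \code{age}, \code{figo_stage}.
#' @return A \linkS4class{SpectralCountExperiment}.
#' @export
asSpectralCountExperiment <- function(counts, annotations) {
    stopifnot(is.data.frame(annotations),
              all(c("sample_id", "group") %in% colnames(annotations)))
    idx <- match(colnames(counts), annotations$sample_id)
    if (anyNA(idx))
        stop("no annotation for sample(s): ",
             paste(colnames(counts)[is.na(idx)], collapse = ", "))
    ann <- annotations[idx, , drop = FALSE]
    SpectralCountExperiment(counts, group = ann$group,
                            age = if ("age" %in% names(ann)) ann$age,
                            figo_stage = if ("figo_stage" %in% names(ann)) ann$figo_stage)
}

setMethod("show", "SpectralCountExperiment", function(object) {
    callNextMethod()
    tab <- table(sampleGroups(object))
    cat("groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

#' GeneSetCollection: named gene sets with a background universe
#'
#' Holds a collection of gene sets (by gene symbol) together with the
#' background universe against which over-representation is tested. Stands in
#' for proprietary pathway/network content: sets are plain GMT entries.
#'
#' @slot sets named list of character vectors, one per set; members unique
#'   within a set.
#' @slot descriptions named character vector of set descriptions.
#' @slot background character vector of background gene symbols, no
#'   duplicates.
#' @name GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character",
                        background = "character"))

setValidity("GeneSetCollection", function(object) {
    msgs <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msgs <- c(msgs, "sets must be uniquely named")
    if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
        msgs <- c(msgs, "set members must be unique within a set")
    if (anyDuplicated(object@background))
        msgs <- c(msgs, "background must contain no duplicates")
    if (!identical(sort(names(object@sets)), sort(names(object@descriptions))))
        msgs <- c(msgs, "descriptions must be named like sets")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param background character vector of background gene symbols; defaults to
#'   the union of all set members.
#' @param descriptions optional named character vector of descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
geneSetCollection <- function(sets, background = NULL, descriptions = NULL) {
    if (is.null(background)) background <- sort(unique(unlist(sets)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions[names(sets)],
        background = as.character(background))
}

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets over %d background genes\n",
                length(object@sets), length(object@background)))
    sizes <- lengths(object@sets)
    cat(sprintf("set sizes: %d-%d (median %.0f)\n",
                min(sizes), max(sizes), stats::median(sizes)))
})

#' PermutationNull: null distribution of maximum enrichment scores
#'
#' Result of a permutation experiment in which random gene lists of a fixed
#' size are scored against a gene-set collection; the per-repeat maximum score
#' forms the null. The significance threshold is the upper 95\% confidence
#' limit of the mean maximum score.
#'
#' @slot repeats integer number of permutation repeats.
#' @slot maxScores numeric, per-repeat maximum score (-log10 p).
#' @slot mean,sd,ciLower,ciUpper numeric summary of the max-score sample.
#' @slot threshold numeric, equal to \code{ciUpper}.
#' @slot listSize integer size of the random lists drawn.
#' @slot seed integer seed used for the draws (NA if constructed directly).
#' @name PermutationNull-class
#' @exportClass PermutationNull
setClass("PermutationNull",
         representation(repeats = "integer", maxScores = "numeric",
                        mean = "numeric", sd = "numeric",
                        ciLower = "numeric", ciUpper = "numeric",
                        threshold = "numeric", listSize = "integer",
                        seed = "integer"))

setValidity("PermutationNull", function(object) {
    msgs <- character()
    if (length(object@maxScores) != object@repeats)
        msgs <- c(msgs, "maxScores must have length equal to repeats")
    if (!(object@ciLower <= object@mean && object@mean <= object@ciUpper))
        msgs <- c(msgs, "confidence limits must bracket the mean")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf(paste0("PermutationNull: %d repeats of random lists of %d genes\n",
                       "mean max score %.3f (95%% CI %.3f-%.3f); threshold %.3f\n"),
                object@repeats, object@listSize, object@mean,
                object@ciLower, object@ciUpper, object@threshold))
})

#' Significance threshold of a PermutationNull
#' @param null a \linkS4class{PermutationNull}.
#' @return numeric threshold (upper 95\% confidence limit of the mean maximum
#'   score).
#' @export
nullThreshold <- function(null) {
    stopifnot(is(null, "PermutationNull"))
    null@threshold
}

#' CalibrationCurve: dilution-series fit for a PRM peptide
#'
#' Ordinary least-squares calibration of mean peak area against spiked
#' concentration, with blank-based detection limits and per-level
#' reproducibility.
#'
#' @slot peptide character peptide identifier.
#' @slot levels numeric dilution levels (fmol/uL).
#' @slot areas data.frame with columns \code{level}, \code{replicate},
#'   \code{area}.
#' @slot slope,intercept numeric OLS fit of mean area on level.
#' @slot rSquared numeric coefficient of determination on replicate means.
#' @slot sigmaBlank numeric sd of blank (level 0) replicate areas; falls back
#'   to the residual sd of the fit when no blank replicates exist.
#' @slot lod,loq numeric limits of detection/quantification (fmol/uL),
#'   3.3 and 10 times \code{sigmaBlank/slope}.
#' @slot cv data.frame with columns \code{level}, \code{cv_percent}.
#' @slot valid logical; FALSE when the fitted slope is not positive.
#' @name CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
         representation(peptide = "character", levels = "numeric",
                        areas = "data.frame", slope = "numeric",
                        intercept = "numeric", rSquared = "numeric",
                        sigmaBlank = "numeric", lod = "numeric",
                        loq = "numeric", cv = "data.frame",
                        valid = "logical"))

setValidity("CalibrationCurve", function(object) {
    if (object@valid && object@lod > object@loq + 1e-12)
        "lod must not exceed loq" else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf("CalibrationCurve [%s]: %d levels x %d replicates\n",
                object@peptide, length(object@levels),
                max(object@areas$replicate)))
    cat(sprintf("slope %.4g, intercept %.4g, R^2 %.5f%s\n",
                object@slope, object@intercept, object@rSquared,
                if (object@valid) "" else " (INVALID: slope <= 0)"))
    cat(sprintf("LOD %.4g fmol/uL, LOQ %.4g fmol/uL\n", object@lod, object@loq))
})
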