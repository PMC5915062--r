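#' "All-or-nothing" exclusivity selection
#'
#' The most restrictive selection regime: a protein is selected when it (1)
#' has zero spectral counts in every sample of every excluded group (default
#' healthy epithelium and stroma), (2) is present (count >= 1) in at least
#' \code{minPresent} samples of the target group (default 7 of the 11 early
#' cancer samples), and (3) has a raw p-value below \code{pMax}. Presence in
#' allowed groups (default late cancer) is ignored.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param pValues named numeric vector of per-protein p-values covering every
#'   protein of \code{x}.
#' @param targetGroup group in which presence is required.
#' @param excludeGroups groups in which any count disqualifies.
#' @param minPresent minimum presence count in the target group.
#' @param pMax raw p-value cutoff (strict \code{<}).
#' @return character vector of selected protein ids.
#' @export
allOrNothing <- function(x, pValues, targetGroup = "early_cancer",
                         excludeGroups = c("healthy_epithelium", "stroma"),
                         minPresent = 7, pMax = 0.05) {
    if (targetGroup %in% excludeGroups)
        stop("target group must not be an excluded group")
    if (!all(rownames(x) %in% names(pValues)))
        stop("pValues must cover every protein")
    p <- pValues[rownames(x)]
    presTarget <- presenceCounts(x, targetGroup)
    absentElsewhere <- rep(TRUE, nrow(x))
    for (g in excludeGroups)
        absentElsewhere <- absentElsewhere & presenceCounts(x, g) == 0L
    sel <- absentElsewhere & presTarget >= minPresent & p < pMax
    rownames(x)[sel]
}

#' Proteins exclusively present in one group
#'
#' Mirror of the all-or-nothing rule without a p-value clause: proteins with
#' zero counts in every sample of all other groups and presence in at least
#' \code{minPresent} samples of \code{group} (default 6 of 13).
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param group target group.
#' @param minPresent minimum presence count in \code{group}.
#' @param otherGroups groups that must be devoid of the protein; defaults to
#'   all other tissue groups in \code{x}.
#' @return character vector of protein ids.
#' @export
exclusiveInGroup <- function(x, group, minPresent = 6, otherGroups = NULL) {
    if (is.null(otherGroups))
        otherGroups <- setdiff(unique(sampleGroups(x)), group)
    if (group %in% otherGroups) stop("group must not be in otherGroups")
    pres <- presenceCounts(x, group)
    absent <- rep(TRUE, nrow(x))
    for (g in otherGroups) absent <- absent & presenceCounts(x, g) == 0L
    rownames(x)[absent & pres >= minPresent]
}

#' Bonferroni family-wise correction
#'
#' Flags p-values strictly below \code{alpha / m}. The family size defaults
#' to the number of supplied p-values but can be overridden when the test
#' family is defined externally.
#'
#' @param pValues numeric vector of raw p-values.
#' @param alpha family-wise error level.
#' @param m family size.
#' @return list with \code{threshold} (\code{alpha / m}) and
#'   \code{significant} (logical vector).
#' @examples
#' bonferroni(c(1e-7, 0.01), alpha = 0.05, m = 5061)$threshold  # 9.88e-6
#' @export
bonferroni <- function(pValues, alpha = 0.05, m = length(pValues)) {
    if (m < 1) stop("m must be at least 1")
    thr <- alpha / m
    list(threshold = thr, significant = pValues < thr)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure at FDR level \code{q}: sort p-values ascending,
#' find the largest i with p(i) <= i q / m and reject hypotheses 1..i (ties
#' rejected together). Adjusted p-values are the usual step-up minima,
#' computed with \code{stats::p.adjust(method = "BH")}; a hypothesis is
#' significant iff its adjusted p is at most \code{q}.
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @param q FDR level.
#' @return list with \code{significant} (logical) and \code{adjusted}
#'   (numeric adjusted p-values).
#' @export
benjaminiHochberg <- function(pValues, q = 0.05) {
    if (any(pValues <= 0 | pValues > 1)) stop("p-values must be in (0, 1]")
    adj <- stats::p.adjust(pValues, method = "BH")
    list(significant = adj <= q, adjusted = adj)
}

#' Annotate a differential table with the three selection flags
#'
#' Adds logical columns \code{all_or_nothing}, \code{bonferroni} and
#' \code{bh} to a \code{\link{differentialTable}} result.
#'
#' @param tab data.frame from \code{\link{differentialTable}}.
#' @param x the \linkS4class{SpectralCountExperiment} the table came from.
#' @param targetGroup,excludeGroups,minPresent,pMax passed to
#'   \code{\link{allOrNothing}}.
#' @param alpha,q levels for \code{\link{bonferroni}} and
#'   \code{\link{benjaminiHochberg}}.
#' @param m Bonferroni family size; defaults to the number of proteins
#'   present in at least one sample of either contrast group (the tested
#'   family).
#' @return the input table with three logical flag columns appended.
#' @export
selectionFlags <- function(tab, x, targetGroup = "early_cancer",
                           excludeGroups = c("healthy_epithelium", "stroma"),
                           minPresent = 7, pMax = 0.05,
                           alpha = 0.05, q = 0.05, m = NULL) {
    tested <- tab$presence_a > 0L | tab$presence_b > 0L
    if (is.null(m)) m <- sum(tested)
    p <- setNames(tab$p_value, tab$protein_id)
    aon <- allOrNothing(x, p, targetGroup, excludeGroups, minPresent, pMax)
    tab$all_or_nothing <- tab$protein_id %in% aon
    tab$bonferroni <- bonferroni(tab$p_value, alpha, m)$significant
    tab$bh <- FALSE
    tab$bh[tested] <- benjaminiHochberg(tab$p_value[tested], q)$significant
    tab
}
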