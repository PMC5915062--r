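#' Specify a two-group contrast
#'
#' @param groupA test group (e.g. \code{"early_cancer"}).
#' @param groupB reference group (e.g. \code{"healthy_epithelium"}).
#' @param pseudocount value substituted for zero counts before taking
#'   logarithms (default 0.125).
#' @param testMethod per-protein test: \code{"welch_log"} (two-sided
#'   unequal-variance t on log2 zero-replaced counts) or
#'   \code{"fisher_presence"} (two-sided exact test on the 2x2
#'   presence/absence table).
#' @return list of class \code{"ContrastSpec"}.
#' @export
contrastSpec <- function(groupA, groupB, pseudocount = 0.125,
                         testMethod = c("welch_log", "fisher_presence")) {
    testMethod <- match.arg(testMethod)
    if (identical(groupA, groupB)) stop("contrast groups must be disjoint")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    structure(list(groupA = groupA, groupB = groupB,
                   pseudocount = pseudocount, testMethod = testMethod),
              class = "ContrastSpec")
}

#' Replace zero counts by a pseudocount
#'
#' Zero spectral counts are converted to a small positive pseudocount
#' (default 0.125) to enable logarithm calculations; positive counts are
#' unchanged.
#'
#' @param counts numeric vector or matrix of nonnegative counts.
#' @param pseudocount replacement value for zeros.
#' @return same shape as \code{counts}.
#' @examples
#' replaceZeros(c(0, 3, 0))
#' @export
replaceZeros <- function(counts, pseudocount = 0.125) {
    if (any(counts < 0)) stop("counts must be nonnegative")
    counts[counts == 0] <- pseudocount
    counts
}

.groupCounts <- function(x, group) {
    idx <- which(sampleGroups(x) == group)
    if (!length(idx)) stop("no samples in group '", group, "'")
    spectralCounts(x)[, idx, drop = FALSE]
}

#' Per-protein log2 fold-change between two groups
#'
#' log2 of the ratio of group means of zero-replaced counts: a protein absent
#' from the reference group (all zeros, mean floored at the pseudocount
#' 0.125) with a test-group mean of 4 yields a 32-fold linear increase,
#' i.e. a log2 fold-change of 5.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param contrast a \code{\link{contrastSpec}}.
#' @return named numeric vector of log2 fold-changes (test over reference).
#' @export
log2FoldChange <- function(x, contrast) {
    a <- replaceZeros(.groupCounts(x, contrast$groupA), contrast$pseudocount)
    b <- replaceZeros(.groupCounts(x, contrast$groupB), contrast$pseudocount)
    log2(rowMeans(a) / rowMeans(b))
}

#' Per-group presence counts
#'
#' A protein is "present" in a sample when its spectral count is at least 1.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param group group label.
#' @return named integer vector: number of samples of \code{group} in which
#'   each protein is present.
#' @export
presenceCounts <- function(x, group) {
    rowSums(.groupCounts(x, group) >= 1L)
}

## vectorised two-sided Welch t on rows of log2 zero-replaced counts;
## zero pooled standard error: p = 1 for equal means (degenerate, no
## evidence), smallest positive double otherwise (limit of the test)
.rowWelch <- function(A, B) {
    n1 <- ncol(A); n2 <- ncol(B)
    if (n1 < 2L || n2 < 2L) stop("welch_log needs >= 2 samples per group")
    m1 <- rowMeans(A); m2 <- rowMeans(B)
    v1 <- rowSums((A - m1)^2) / (n1 - 1)
    v2 <- rowSums((B - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    p <- rep(NA_real_, nrow(A))
    zero <- se2 == 0
    p[zero & (m1 == m2)] <- 1
    p[zero & (m1 != m2)] <- .Machine$double.xmin
    ok <- !zero
    tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / (v1[ok]^2 / (n1^2 * (n1 - 1)) + v2[ok]^2 / (n2^2 * (n2 - 1)))
    p[ok] <- 2 * stats::pt(-abs(tstat), df)
    pmax(p, .Machine$double.xmin)
}

#' Per-protein two-group differential test
#'
#' \code{welch_log}: two-sided unequal-variance (Welch) t test on log2
#' zero-replaced counts, vectorised over proteins. \code{fisher_presence}:
#' two-sided Fisher exact test on the 2x2 table of samples with versus
#' without at least one spectral count in each group. When both groups are
#' constant and equal the Welch p-value is 1 (not NaN).
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param contrast a \code{\link{contrastSpec}}.
#' @return named numeric vector of p-values in (0, 1].
#' @export
differentialTest <- function(x, contrast) {
    a <- .groupCounts(x, contrast$groupA)
    b <- .groupCounts(x, contrast$groupB)
    if (contrast$testMethod == "welch_log") {
        p <- .rowWelch(log2(replaceZeros(a, contrast$pseudocount)),
                       log2(replaceZeros(b, contrast$pseudocount)))
    } else {
        pa <- rowSums(a >= 1L); pb <- rowSums(b >= 1L)
        na <- ncol(a); nb <- ncol(b)
        p <- vapply(seq_along(pa), function(i)
            stats::fisher.test(matrix(c(pa[i], na - pa[i], pb[i], nb - pb[i]),
                                      2L))$p.value, 0)
        p <- pmin(p, 1)
    }
    setNames(p, rownames(x))
}

#' Full differential table for a contrast
#'
#' One row per protein: log2 fold-change, raw p-value, per-group presence
#' counts. The building block for volcano plots and the selection regimes.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param contrast a \code{\link{contrastSpec}}.
#' @return data.frame with columns \code{protein_id}, \code{log2_fc},
#'   \code{p_value}, \code{presence_a}, \code{presence_b}.
#' @export
differentialTable <- function(x, contrast) {
    data.frame(protein_id = rownames(x),
               log2_fc = unname(log2FoldChange(x, contrast)),
               p_value = unname(differentialTest(x, contrast)),
               presence_a = unname(presenceCounts(x, contrast$groupA)),
               presence_b = unname(presenceCounts(x, contrast$groupB)),
               stringsAsFactors = FALSE)
}

#' Volcano table: log2 fold-change vs -log10 p
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param contrast a \code{\link{contrastSpec}}.
#' @return data.frame with columns \code{protein_id}, \code{log2_fc},
#'   \code{neg_log10_p}, rows sorted by ascending p-value.
#' @export
volcanoTable <- function(x, contrast) {
    tab <- differentialTable(x, contrast)
    out <- data.frame(protein_id = tab$protein_id, log2_fc = tab$log2_fc,
                      neg_log10_p = -log10(tab$p_value),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$neg_log10_p, out$protein_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify proteins by tumor / cell-line fold-change pattern
#'
#' Given per-protein log2 fold-changes of early cancer (EC), late cancer
#' (LC) and the HeLa, U87 and HEK293 cell lines, all relative to healthy
#' epithelium, labels each protein \code{tumor_and_HeLa} when EC, LC and
#' HeLa reach \code{fcMin} while U87 and HEK293 stay below it (cervical
#' specificity shared with the cervical cell line), \code{tumor_only} when
#' EC and LC reach \code{fcMin} but HeLa does not (specific to dissected
#' tumor tissue), and \code{unclassified} otherwise.
#'
#' @param fc data.frame with numeric columns \code{ec}, \code{lc},
#'   \code{hela}, \code{u87}, \code{hek293} (and optionally an id column).
#' @param fcMin log2 fold-change threshold (default 2.5).
#' @return character vector of classifications, one per row of \code{fc}.
#' @export
classifyFoldChanges <- function(fc, fcMin = 2.5) {
    req <- c("ec", "lc", "hela", "u87", "hek293")
    stopifnot(all(req %in% colnames(fc)))
    tumor <- fc$ec >= fcMin & fc$lc >= fcMin
    ifelse(tumor & fc$hela >= fcMin & fc$u87 < fcMin & fc$hek293 < fcMin,
           "tumor_and_HeLa",
           ifelse(tumor & fc$hela < fcMin, "tumor_only", "unclassified"))
}

#' Cell-line contrast filtering
#'
#' Computes log2 fold-changes of early cancer, late cancer and the HeLa, U87
#' and HEK293 cell-line samples against a reference group, then classifies
#' each protein with \code{\link{classifyFoldChanges}}.
#'
#' @param x a \linkS4class{SpectralCountExperiment} containing groups
#'   \code{early_cancer}, \code{late_cancer}, \code{cell_line:HeLa},
#'   \code{cell_line:U87} and \code{cell_line:HEK293}.
#' @param reference reference group (default \code{healthy_epithelium}).
#' @param fcMin log2 fold-change threshold (default 2.5).
#' @param pseudocount zero replacement for the fold-change arithmetic.
#' @return data.frame with columns \code{protein_id}, \code{ec}, \code{lc},
#'   \code{hela}, \code{u87}, \code{hek293}, \code{class}.
#' @export
cellLineContrast <- function(x, reference = "healthy_epithelium", fcMin = 2.5,
                             pseudocount = 0.125) {
    need <- c("early_cancer", "late_cancer", "cell_line:HeLa",
              "cell_line:U87", "cell_line:HEK293")
    missingGroups <- setdiff(need, unique(sampleGroups(x)))
    if (length(missingGroups))
        stop("missing group(s): ", paste(missingGroups, collapse = ", "))
    fcOf <- function(g) unname(log2FoldChange(x, contrastSpec(g, reference,
                                                              pseudocount)))
    fc <- data.frame(protein_id = rownames(x),
                     ec = fcOf("early_cancer"), lc = fcOf("late_cancer"),
                     hela = fcOf("cell_line:HeLa"), u87 = fcOf("cell_line:U87"),
                     hek293 = fcOf("cell_line:HEK293"),
                     stringsAsFactors = FALSE)
    fc$class <- classifyFoldChanges(fc, fcMin)
    fc
}

#' Replicate overlap of identified-protein sets
#'
#' Reproducibility readout for technical/methodological replicates: 100 x
#' size of the intersection of all sets over the size of their union, plus
#' the pairwise overlap matrix. An overlap above 50\% is conventionally
#' acceptable.
#'
#' @param proteinSets list of two or more character vectors of identified
#'   protein ids.
#' @return list with \code{overall} (percentage) and \code{pairwise}
#'   (numeric matrix of pairwise percentages).
#' @examples
#' replicateOverlap(list(c("A", "B", "C"), c("B", "C", "D")))$overall  # 50
#' @export
replicateOverlap <- function(proteinSets) {
    if (length(proteinSets) < 2L || any(lengths(proteinSets) == 0L))
        stop("need at least two nonempty protein sets")
    proteinSets <- lapply(proteinSets, unique)
    inter <- Reduce(intersect, proteinSets)
    uni <- Reduce(union, proteinSets)
    k <- length(proteinSets)
    pw <- matrix(100, k, k)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
        pw[i, j] <- pw[j, i] <-
            100 * length(intersect(proteinSets[[i]], proteinSets[[j]])) /
                  length(union(proteinSets[[i]], proteinSets[[j]]))
    }
    list(overall = 100 * length(inter) / length(uni), pairwise = pw)
}
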