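#' Per-gene mean expression across samples
#'
#' Arithmetic mean of log2 expression across all samples, for a requested
#' gene list. Genes absent from the table are reported in a dropped-genes
#' attribute (with a warning), never silently ignored.
#'
#' @param expr numeric matrix of log2 expression, genes x samples.
#' @param genes character vector of requested gene ids.
#' @return named numeric vector of means for the genes found; attribute
#'   \code{"dropped"} lists the missing genes.
#' @export
meanExpression <- function(expr, genes) {
    genes <- unique(genes)
    found <- intersect(genes, rownames(expr))
    dropped <- setdiff(genes, rownames(expr))
    if (length(dropped))
        warning(length(dropped), " requested gene(s) absent from the expression table")
    out <- rowMeans(expr[found, , drop = FALSE], na.rm = TRUE)
    attr(out, "dropped") <- dropped
    out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller sample has at most 8 values and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. Identical values throughout both samples give p = 1.
#'
#' @param valuesA,valuesB numeric vectors (both nonempty).
#' @return two-sided p-value.
#' @examples
#' wilcoxonRankSum(1:3, 4:6)  # 0.1
#' @export
wilcoxonRankSum <- function(valuesA, valuesB) {
    if (!length(valuesA) || !length(valuesB)) stop("both samples must be nonempty")
    all_vals <- c(valuesA, valuesB)
    if (length(unique(all_vals)) == 1L) return(1)
    ties <- anyDuplicated(all_vals) > 0L
    exact <- min(length(valuesA), length(valuesB)) <= 8L && !ties
    suppressWarnings(
        stats::wilcox.test(valuesA, valuesB, exact = exact,
                           correct = TRUE)$p.value)
}

#' Compare differential-gene expression to a background gene list
#'
#' Tests whether the mean RNA expression of differential-protein genes
#' differs from that of the proteome-identified background. Verdict
#' "significant" at p < 0.01 (strict), with the direction reported as the
#' difference of medians.
#'
#' @param diffGenes character vector of differential gene ids.
#' @param backgroundGenes character vector of background gene ids.
#' @param expr numeric matrix of log2 expression, genes x samples.
#' @param pCut significance level (default 0.01).
#' @return list with \code{p_value}, \code{median_diff},
#'   \code{median_background}, \code{significant}, \code{direction}, and
#'   \code{dropped} (genes absent from the table).
#' @export
compareToBackground <- function(diffGenes, backgroundGenes, expr, pCut = 0.01) {
    mDiff <- meanExpression(expr, diffGenes)
    mBg <- meanExpression(expr, backgroundGenes)
    if (!length(mDiff)) stop("no differential genes found in the expression table")
    if (!length(mBg)) stop("no background genes found in the expression table")
    p <- wilcoxonRankSum(as.numeric(mDiff), as.numeric(mBg))
    medD <- stats::median(mDiff); medB <- stats::median(mBg)
    list(p_value = p, median_diff = medD, median_background = medB,
         significant = p < pCut,
         direction = if (medD > medB) "higher" else if (medD < medB) "lower" else "equal",
         dropped = union(attr(mDiff, "dropped"), attr(mBg, "dropped")))
}
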