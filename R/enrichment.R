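#' Right-tailed Fisher (hypergeometric) over-representation p-value
#'
#' P(X >= observed overlap) for the hypergeometric distribution with
#' population size N = |background|, K = |set intersected with background|
#' successes and n = |input list| draws.
#'
#' @param inputList character vector of input gene symbols; must be a subset
#'   of the background.
#' @param geneSet character vector of set members (intersected with the
#'   background before testing).
#' @param background character vector of background gene symbols.
#' @return the right-tail p-value.
#' @examples
#' fisherEnrichment(letters[1:5], letters[1:5], letters[1:20])  # 1/choose(20,5)
#' @export
fisherEnrichment <- function(inputList, geneSet, background) {
    if (!length(background)) stop("background must be nonempty")
    background <- unique(background)
    inputList <- unique(inputList)
    if (!all(inputList %in% background))
        stop("input list must be a subset of the background")
    K <- length(intersect(unique(geneSet), background))
    n <- length(inputList)
    k <- length(intersect(inputList, geneSet))
    stats::phyper(k - 1L, K, length(background) - K, n, lower.tail = FALSE)
}

#' Score every gene set against an input list
#'
#' Over-representation score = -log10 of the right-tailed Fisher exact
#' (hypergeometric) p-value, reported unrounded.
#'
#' @param inputList character vector of input gene symbols (subset of the
#'   collection's background).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return data.frame with columns \code{set_id}, \code{overlap},
#'   \code{p_value}, \code{score}, sorted by descending score.
#' @export
scoreNetworks <- function(inputList, collection) {
    bg <- geneBackground(collection)
    sets <- geneSets(collection)
    inputList <- unique(inputList)
    res <- data.frame(set_id = names(sets),
                      overlap = vapply(sets, function(s)
                          length(intersect(inputList, s)), 0L),
                      p_value = vapply(sets, function(s)
                          fisherEnrichment(inputList, s, bg), 0),
                      stringsAsFactors = FALSE)
    res$score <- -log10(res$p_value)
    res <- res[order(-res$score, res$set_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Construct a PermutationNull from a vector of maximum scores
#'
#' Summarises per-repeat maximum scores into the significance threshold: the
#' upper 95\% confidence limit of the mean, mean + t(0.975, repeats-1) *
#' sd / sqrt(repeats) (a normal quantile is available as an option).
#'
#' @param maxScores numeric vector of per-repeat maximum scores (length >=
#'   2).
#' @param listSize size of the random lists that generated the scores.
#' @param seed seed used for the draws (NA when constructed directly).
#' @param ciMethod \code{"t"} (default) or \code{"normal"} quantile for the
#'   confidence limits.
#' @return a \linkS4class{PermutationNull}.
#' @examples
#' nullThreshold(permutationNull(1:10))  # 7.666
#' @export
permutationNull <- function(maxScores, listSize = NA_integer_,
                            seed = NA_integer_, ciMethod = c("t", "normal")) {
    ciMethod <- match.arg(ciMethod)
    r <- length(maxScores)
    if (r < 2L) stop("at least 2 repeats are required (CI undefined)")
    m <- mean(maxScores); s <- stats::sd(maxScores)
    qq <- if (ciMethod == "t") stats::qt(0.975, r - 1L) else stats::qnorm(0.975)
    half <- qq * s / sqrt(r)
    new("PermutationNull", repeats = as.integer(r),
        maxScores = as.numeric(maxScores), mean = m, sd = s,
        ciLower = m - half, ciUpper = m + half, threshold = m + half,
        listSize = as.integer(listSize), seed = as.integer(seed))
}

#' Permutation-derived enrichment-score threshold
#'
#' Draws \code{repeats} random gene lists of \code{listSize} uniformly
#' without replacement from the background, scores every set in the
#' collection for each draw and records the maximum score. The significance
#' threshold is the upper 95\% confidence limit of the mean maximum score.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param listSize number of genes per random list.
#' @param repeats number of permutation repeats (default 10).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param ciMethod \code{"t"} (default) or \code{"normal"}.
#' @return a \linkS4class{PermutationNull}.
#' @export
permutationThreshold <- function(collection, listSize, repeats = 10, seed,
                                 ciMethod = c("t", "normal")) {
    stopifnot(!missing(seed))
    if (repeats < 2L) stop("at least 2 repeats are required (CI undefined)")
    bg <- geneBackground(collection)
    if (listSize > length(bg)) stop("listSize exceeds the background size")
    set.seed(seed)
    maxScores <- vapply(seq_len(repeats), function(i) {
        draw <- sample(bg, listSize)
        max(scoreNetworks(draw, collection)$score)
    }, 0)
    permutationNull(maxScores, listSize = listSize, seed = seed,
                    ciMethod = ciMethod)
}

#' Gene sets exceeding the permutation threshold
#'
#' Strict exceedance: a set passes only when its score is greater than the
#' threshold; a score equal to the threshold fails.
#'
#' @param scores data.frame from \code{\link{scoreNetworks}}.
#' @param null a \linkS4class{PermutationNull}.
#' @return the scores table with logical \code{passes} and numeric
#'   \code{margin} (score minus threshold) columns appended, both passing
#'   and failing sets reported.
#' @export
significantNetworks <- function(scores, null) {
    thr <- nullThreshold(null)
    scores$passes <- scores$score > thr
    scores$margin <- scores$score - thr
    scores
}
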