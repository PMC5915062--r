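## Independent brute-force oracles used across the suite.

## Benjamini-Hochberg step-up by direct definition: sort ascending, find the
## largest i with p(i) <= i*q/m, reject hypotheses 1..i (ties together).
bhOracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    ok <- which(ps <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
    rej
}

## Right-tail hypergeometric by explicit summation of point masses.
hyperTailOracle <- function(k, K, N, n) {
    xs <- k:min(K, n)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

## Two-sided Fisher exact p for a 2x2 presence table by enumeration of all
## tables with the observed margins, summing point masses <= observed
## (minimum-likelihood convention, as stats::fisher.test).
fisherTwoSidedOracle <- function(pa, na, pb, nb) {
    K <- pa + pb
    xs <- max(0L, K - nb):min(K, na)
    f <- choose(na, xs) * choose(nb, K - xs) / choose(na + nb, K)
    obs <- f[match(pa, xs)]
    sum(f[f <= obs * (1 + 1e-7)])
}

## Naive O(n^3) Ward agglomeration on raw coordinates. Heights follow the
## ward.D2 convention: sqrt of twice the increase in within-cluster SS.
wardOracle <- function(x) {
    n <- nrow(x)
    clusters <- lapply(seq_len(n), function(i) i)
    heights <- numeric(0)
    memberSets <- list()
    cost <- function(a, b) {
        ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
        (length(a) * length(b)) / (length(a) + length(b)) * sum((ca - cb)^2)
    }
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestCost <- Inf
        for (i in seq_len(length(clusters) - 1L))
            for (j in seq(i + 1L, length(clusters))) {
                cc <- cost(clusters[[i]], clusters[[j]])
                if (cc < bestCost) { bestCost <- cc; best <- c(i, j) }
            }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        heights <- c(heights, sqrt(2 * bestCost))
        memberSets <- c(memberSets, list(merged))
        clusters <- c(clusters[-best], list(merged))
    }
    list(heights = heights, memberSets = memberSets)
}

## Leaf sets of every internal node of an hclust-style merge matrix.
mergeMemberSets <- function(merge) {
    sets <- vector("list", nrow(merge))
    for (s in seq_len(nrow(merge))) {
        grab <- function(v) if (v < 0) -v else sets[[v]]
        sets[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
    }
    sets
}

## Small, fast study configuration for simulation-driven tests.
smallConfig <- function(seed, ...) {
    args <- list(nProteins = 400, mu = 5, size = 2, dropout = 0.25,
                 propFcUp = 0.1, propFcDown = 0.05,
                 propTumorExclusive = 0.05, propHealthyExclusive = 0.025,
                 seed = seed)
    do.call(simulationConfig, utils::modifyList(args, list(...)))
}
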