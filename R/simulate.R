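#' Configuration for a synthetic spectral-count study
#'
#' Defines the statistical structure of a simulated LCM-style study: four
#' sample groups (defaults 11 early cancer, 11 late cancer, 13 healthy
#' epithelium, 13 stroma), negative-binomial baseline counts thinned by
#' independent detection dropout, and planted protein classes with known
#' ground truth (null, fold-change up/down, tumor-exclusive,
#' healthy-exclusive).
#'
#' Defaults emulate the scale of a deep LCM shotgun experiment: with
#' \code{nProteins = 2500}, \code{mu = 5}, \code{size = 2} and
#' \code{dropout = 0.25} the expected number of detected proteins per sample
#' is about 1,700.
#'
#' @param nProteins number of simulated proteins.
#' @param groupSizes named integer vector of samples per group.
#' @param mu baseline negative-binomial mean spectral count.
#' @param size negative-binomial dispersion parameter k (variance =
#'   mu + mu^2/k); large k approaches Poisson.
#' @param dropout probability that a detected count is zeroed per sample
#'   (independent detection dropout).
#' @param propFcUp,propFcDown,propTumorExclusive,propHealthyExclusive
#'   proportions of proteins planted in each non-null class (must sum to at
#'   most 1).
#' @param log2Effect planted log2 fold-change magnitude for fc_up/fc_down
#'   proteins (cancer groups vs healthy/stroma).
#' @param tumorExclusiveMinPresent minimum number of early-cancer samples in
#'   which a tumor-exclusive protein is present (default 8 of 11).
#' @param healthyExclusiveMinPresent minimum number of healthy-epithelium
#'   samples in which a healthy-exclusive protein is present (default 6 of
#'   13).
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nProteins = 2500,
                             groupSizes = c(early_cancer = 11, late_cancer = 11,
                                            healthy_epithelium = 13, stroma = 13),
                             mu = 5, size = 2, dropout = 0.25,
                             propFcUp = 0.05, propFcDown = 0.05,
                             propTumorExclusive = 0.0125,
                             propHealthyExclusive = 0.0125,
                             log2Effect = 2,
                             tumorExclusiveMinPresent = 8,
                             healthyExclusiveMinPresent = 6,
                             seed) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("'seed' is mandatory")
    props <- c(propFcUp, propFcDown, propTumorExclusive, propHealthyExclusive)
    if (any(props < 0) || sum(props) > 1)
        stop("class proportions must be nonnegative and sum to at most 1")
    if (mu <= 0 || size <= 0) stop("mu and size must be positive")
    if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
    stopifnot(all(c("early_cancer", "late_cancer", "healthy_epithelium",
                    "stroma") %in% names(groupSizes)))
    if (tumorExclusiveMinPresent > groupSizes[["early_cancer"]] ||
        healthyExclusiveMinPresent > groupSizes[["healthy_epithelium"]])
        stop("exclusive presence minimum exceeds group size")
    structure(list(nProteins = as.integer(nProteins), groupSizes = groupSizes,
                   mu = mu, size = size, dropout = dropout,
                   propFcUp = propFcUp, propFcDown = propFcDown,
                   propTumorExclusive = propTumorExclusive,
                   propHealthyExclusive = propHealthyExclusive,
                   log2Effect = log2Effect,
                   tumorExclusiveMinPresent = as.integer(tumorExclusiveMinPresent),
                   healthyExclusiveMinPresent = as.integer(healthyExclusiveMinPresent),
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

## zero-truncated negative binomial draws (for structurally present counts)
.rztnbinom <- function(n, mu, size) {
    x <- stats::rnbinom(n, mu = mu, size = size)
    x[x == 0L] <- 1L
    x
}

#' Simulate a spectral-count study with planted ground truth
#'
#' Draws nonnegative integer spectral counts for four sample groups from a
#' negative binomial thinned by independent detection dropout, and plants
#' protein classes: \code{fc_up}/\code{fc_down} (cancer-group mean shifted by
#' \code{2^log2Effect}), \code{tumor_exclusive} (zero in every healthy
#' epithelium and stroma sample, present in at least
#' \code{tumorExclusiveMinPresent} early-cancer samples) and
#' \code{healthy_exclusive} (the mirror: zero outside healthy epithelium,
#' present in at least \code{healthyExclusiveMinPresent} healthy samples).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{sce}
#'   (\linkS4class{SpectralCountExperiment}) and \code{truth} (data.frame
#'   with columns \code{protein_id}, \code{class}).
#' @export
simulateStudy <- function(config) {
    if (!inherits(config, "SimulationConfig")) stop("invalid config")
    set.seed(config$seed)
    n <- config$nProteins
    gs <- config$groupSizes
    groups <- rep(names(gs), gs)
    sampleIds <- unlist(lapply(names(gs), function(g) {
        pre <- c(early_cancer = "EC", late_cancer = "LC",
                 healthy_epithelium = "HE", stroma = "ST")[[g]]
        sprintf("%s%02d", pre, seq_len(gs[[g]]))
    }))
    nCls <- c(fc_up = round(n * config$propFcUp),
              fc_down = round(n * config$propFcDown),
              tumor_exclusive = round(n * config$propTumorExclusive),
              healthy_exclusive = round(n * config$propHealthyExclusive))
    cls <- rep("null", n)
    if (sum(nCls) > 0)
        cls[seq_len(sum(nCls))] <- rep(names(nCls), nCls)
    ids <- sprintf("SIM%04d", seq_len(n))
    counts <- matrix(0L, n, length(groups), dimnames = list(ids, sampleIds))
    isCancer <- groups %in% c("early_cancer", "late_cancer")
    isEarly <- groups == "early_cancer"
    isLate <- groups == "late_cancer"
    isHealthy <- groups == "healthy_epithelium"
    isBackgroundTissue <- groups %in% c("healthy_epithelium", "stroma")

    fill <- function(rows, colMask, mu) {
        if (!length(rows) || !any(colMask)) return()
        k <- length(rows) * sum(colMask)
        x <- stats::rnbinom(k, mu = mu, size = config$size)
        x[stats::runif(k) < config$dropout] <- 0L
        counts[rows, colMask] <<- x
    }
    fill(which(cls == "null"), rep(TRUE, length(groups)), config$mu)
    up <- which(cls == "fc_up")
    fill(up, isCancer, config$mu * 2^config$log2Effect)
    fill(up, !isCancer, config$mu)
    dn <- which(cls == "fc_down")
    fill(dn, isCancer, config$mu * 2^-config$log2Effect)
    fill(dn, !isCancer, config$mu)

    plantExclusive <- function(rows, targetMask, minPresent, alsoMask) {
        nT <- sum(targetMask)
        for (r in rows) {
            nPresent <- sample(seq(minPresent, nT), 1L)
            pos <- which(targetMask)[sample.int(nT, nPresent)]
            counts[r, pos] <<- .rztnbinom(nPresent, config$mu * 2^config$log2Effect,
                                          config$size)
            if (any(alsoMask)) {
                k <- sum(alsoMask)
                x <- stats::rnbinom(k, mu = config$mu * 2^config$log2Effect,
                                    size = config$size)
                x[stats::runif(k) < config$dropout] <- 0L
                counts[r, alsoMask] <<- x
            }
        }
    }
    ## tumor-exclusive: present in early cancer, allowed in late cancer,
    ## structurally absent from healthy epithelium and stroma
    plantExclusive(which(cls == "tumor_exclusive"), isEarly,
                   config$tumorExclusiveMinPresent, isLate)
    ## healthy-exclusive: present only in healthy epithelium
    plantExclusive(which(cls == "healthy_exclusive"), isHealthy,
                   config$healthyExclusiveMinPresent, rep(FALSE, length(groups)))

    sce <- SpectralCountExperiment(counts, group = groups)
    truth <- data.frame(protein_id = ids, class = cls, stringsAsFactors = FALSE)
    list(sce = sce, truth = truth)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' The first set (\code{"NET01"}) contains the supplied planted members,
#' padded with random background genes to \code{setSize}; remaining sets are
#' drawn uniformly from the background. Default set size 35 mirrors typical
#' curated interaction-network size.
#'
#' @param nSets number of sets.
#' @param setSize members per set.
#' @param background character vector of background gene symbols.
#' @param plantedMembers genes guaranteed to be members of the first set.
#' @param seed integer seed.
#' @return A \linkS4class{GeneSetCollection}; the planted set is named
#'   \code{"NET01"} with description \code{"planted"}.
#' @export
simulateGeneSets <- function(nSets = 10, setSize = 35, background,
                             plantedMembers = character(), seed) {
    stopifnot(!missing(seed), length(background) >= setSize)
    if (!all(plantedMembers %in% background))
        stop("plantedMembers must be drawn from the background")
    if (length(plantedMembers) > setSize)
        stop("more planted members than setSize")
    set.seed(seed)
    ids <- sprintf("NET%02d", seq_len(nSets))
    sets <- vector("list", nSets); names(sets) <- ids
    pad <- sample(setdiff(background, plantedMembers),
                  setSize - length(plantedMembers))
    sets[[1L]] <- c(plantedMembers, pad)
    for (i in seq_len(nSets)[-1L]) sets[[ids[i]]] <- sample(background, setSize)
    desc <- setNames(c("planted", rep("random", nSets - 1L)), ids)
    geneSetCollection(sets, background = background, descriptions = desc)
}

#' Simulate a PRM dilution series
#'
#' Peak areas follow \code{slope * level + intercept} multiplied by lognormal
#' noise with the requested coefficient of variation; \code{cv = 0} gives an
#' exactly linear series.
#'
#' @param slope area units per fmol/uL.
#' @param intercept area units at zero concentration.
#' @param cv fractional coefficient of variation of the multiplicative noise.
#' @param levels dilution levels in fmol/uL (default 0, 0.625, 1.25, 2.5, 5,
#'   10, 20).
#' @param replicates measurements per level (default triplicate).
#' @param seed integer seed.
#' @param peptide peptide label for the output table.
#' @return data.frame with columns \code{peptide}, \code{level},
#'   \code{replicate}, \code{area}.
#' @export
simulatePRMSeries <- function(slope, intercept = 0, cv = 0.05,
                              levels = c(0, 0.625, 1.25, 2.5, 5, 10, 20),
                              replicates = 3, seed, peptide = "PEP1") {
    stopifnot(!missing(seed), cv >= 0, replicates >= 1)
    set.seed(seed)
    grid <- expand.grid(replicate = seq_len(replicates), level = levels)
    meanArea <- slope * grid$level + intercept
    if (cv > 0) {
        sig2 <- log(1 + cv^2)
        noise <- exp(stats::rnorm(nrow(grid), -sig2 / 2, sqrt(sig2)))
    } else noise <- rep(1, nrow(grid))
    data.frame(peptide = peptide, level = grid$level,
               replicate = grid$replicate, area = meanArea * noise,
               stringsAsFactors = FALSE)
}

#' Simulate a log2 expression table with planted high/low genes
#'
#' Gene-level means are drawn around log2 FPKM 5 for \code{highSet}, around
#' -5 for \code{lowSet} (essentially undetectable transcripts) and around an
#' intermediate level (default 3.5) otherwise; per-sample values add Gaussian
#' noise.
#'
#' @param genes character vector of gene ids.
#' @param nSamples number of tumor samples (columns).
#' @param highSet,lowSet gene ids planted as high/low expressers.
#' @param seed integer seed.
#' @param highMean,midMean,lowMean class means on the log2 FPKM scale.
#' @param sdGene between-gene sd of the class means.
#' @param sdNoise within-gene, between-sample sd.
#' @return numeric matrix of log2 FPKM, genes x samples.
#' @export
simulateExpression <- function(genes, nSamples = 40, highSet = character(),
                               lowSet = character(), seed,
                               highMean = 5, midMean = 3.5, lowMean = -5,
                               sdGene = 1, sdNoise = 1) {
    stopifnot(!missing(seed), !anyDuplicated(genes))
    if (length(intersect(highSet, lowSet)))
        stop("highSet and lowSet must be disjoint")
    set.seed(seed)
    mu <- rep(midMean, length(genes))
    mu[genes %in% highSet] <- highMean
    mu[genes %in% lowSet] <- lowMean
    geneMean <- stats::rnorm(length(genes), mu, sdGene)
    m <- matrix(stats::rnorm(length(genes) * nSamples, rep(geneMean, nSamples),
                             sdNoise),
                nrow = length(genes), ncol = nSamples,
                dimnames = list(genes, sprintf("T%03d", seq_len(nSamples))))
    m
}

#' Write a full simulated study to a directory
#'
#' Convenience wrapper emitting \code{matrix.tsv}, \code{annotations.tsv},
#' \code{truth.tsv}, \code{sets.gmt}, \code{prm.tsv} and
#' \code{expression.tsv} into \code{dir}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
writeSimulatedStudy <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateStudy(config)
    ids <- rownames(sim$sce)
    diffIds <- sim$truth$protein_id[sim$truth$class != "null"]
    sets <- simulateGeneSets(background = ids,
                             plantedMembers = utils::head(diffIds, 14),
                             seed = config$seed + 1L)
    prm <- simulatePRMSeries(slope = 1e5, intercept = 2e3, cv = 0.05,
                             seed = config$seed + 2L)
    expr <- simulateExpression(genes = ids,
                               highSet = utils::head(diffIds, 50),
                               lowSet = utils::tail(ids, round(length(ids) / 10)),
                               seed = config$seed + 3L)
    paths <- list(matrix = file.path(dir, "matrix.tsv"),
                  annotations = file.path(dir, "annotations.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  sets = file.path(dir, "sets.gmt"),
                  prm = file.path(dir, "prm.tsv"),
                  expression = file.path(dir, "expression.tsv"))
    writeCountMatrix(sim$sce, paths$matrix)
    writeAnnotations(sampleAnnotations(sim$sce), paths$annotations)
    .writeTSV(sim$truth, paths$truth)
    writeGMT(sets, paths$sets)
    .writeTSV(prm, paths$prm)
    writeExpressionTable(expr, paths$expression)
    invisible(paths)
}
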