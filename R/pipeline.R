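#' Validate a pipeline configuration
#'
#' Checks a configuration list (or YAML file) before any computation:
#' exactly one of \code{simulate} / \code{inputs} must be given, referenced
#' files must exist, a seed is mandatory, and stage-specific requirements
#' (e.g. the network stage needs gene sets) are enforced.
#'
#' @param config a list, or the path to a YAML file.
#' @return the normalised configuration list, invisibly on success; errors
#'   otherwise.
#' @export
validatePipelineConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    if (is.null(config$seed)) stop("config error: 'seed' is required")
    hasSim <- !is.null(config$simulate)
    hasInp <- !is.null(config$inputs)
    if (hasSim == hasInp)
        stop("config error: exactly one of 'simulate' or 'inputs' must be given")
    if (hasInp) {
        req <- c("matrix", "annotations")
        miss <- setdiff(req, names(config$inputs))
        if (length(miss))
            stop("config error: inputs missing ", paste(miss, collapse = ", "))
        for (nm in names(config$inputs)) {
            if (!file.exists(config$inputs[[nm]]))
                stop("config error: input file not found: ", config$inputs[[nm]])
        }
    }
    if (is.null(config$contrast))
        config$contrast <- list(a = "early_cancer", b = "healthy_epithelium")
    if (isTRUE(config$stages$network) && hasInp &&
        is.null(config$inputs$gmt))
        stop("config error: network stage enabled but no 'gmt' input given")
    if (isTRUE(config$stages$transcriptome) && hasInp &&
        is.null(config$inputs$expression))
        stop("config error: transcriptome stage enabled but no 'expression' input")
    if (isTRUE(config$stages$prm) && hasInp && is.null(config$inputs$prm))
        stop("config error: prm stage enabled but no 'prm' input given")
    invisible(config)
}

.defaultSelection <- list(minPresent = 7, pMax = 0.05, alpha = 0.05, q = 0.05)

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate/read, differential testing, the three selection
#' regimes, gene-set scoring with a permutation threshold, Ward clustering,
#' and (when configured) PRM calibration and transcriptome comparison.
#' Outputs are staged in a temporary directory and copied to \code{outDir}
#' only on success, so a failing stage leaves no partial outputs. A
#' \code{manifest.json} records the package version, seed, parameters and
#' the row count of every table written. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config list or YAML path; see \code{\link{validatePipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
    config <- validatePipelineConfig(config)
    stage <- file.path(tempfile("pipeline_stage"))
    dir.create(stage, recursive = TRUE)
    on.exit(unlink(stage, recursive = TRUE), add = TRUE)
    seed <- as.integer(config$seed)
    sel <- utils::modifyList(.defaultSelection, config$selection %||% list())
    manifest <- list(package = "lcmProteomics",
                     version = as.character(utils::packageVersion("lcmProteomics")),
                     seed = seed, selection = sel, outputs = list())
    emit <- function(df, name) {
        .writeTSV(df, file.path(stage, name))
        manifest$outputs[[name]] <<- nrow(df)
    }

    ## --- inputs ---------------------------------------------------------
    collection <- NULL; expr <- NULL; prmSeries <- NULL
    if (!is.null(config$simulate)) {
        simArgs <- config$simulate
        simArgs$seed <- seed
        if (!is.null(simArgs$groupSizes)) simArgs$groupSizes <- unlist(simArgs$groupSizes)
        cfg <- do.call(simulationConfig, simArgs)
        sim <- simulateStudy(cfg)
        sce <- sim$sce
        emit(sim$truth, "truth.tsv")
        diffIds <- sim$truth$protein_id[sim$truth$class != "null"]
        collection <- simulateGeneSets(background = rownames(sce),
                                       plantedMembers = utils::head(diffIds, 14),
                                       seed = seed + 1L)
        expr <- simulateExpression(genes = rownames(sce),
                                   highSet = utils::head(diffIds, 50),
                                   lowSet = utils::tail(rownames(sce),
                                                        round(nrow(sce) / 10)),
                                   seed = seed + 3L)
        prmSeries <- simulatePRMSeries(slope = 1e5, intercept = 2e3, cv = 0.05,
                                       seed = seed + 2L)
    } else {
        counts <- readCountMatrix(config$inputs$matrix)
        ann <- readAnnotations(config$inputs$annotations)
        sce <- asSpectralCountExperiment(counts, ann)
        if (!is.null(config$inputs$gmt))
            collection <- readGMT(config$inputs$gmt, background = rownames(sce))
        if (!is.null(config$inputs$expression))
            expr <- readExpressionTable(config$inputs$expression)
        if (!is.null(config$inputs$prm))
            prmSeries <- readDilutionSeries(config$inputs$prm)
    }

    ## --- differential + selection --------------------------------------
    contrast <- contrastSpec(config$contrast$a, config$contrast$b,
                             testMethod = config$test %||% "welch_log")
    tab <- differentialTable(sce, contrast)
    tab <- selectionFlags(tab, sce, targetGroup = contrast$groupA,
                          minPresent = sel$minPresent, pMax = sel$pMax,
                          alpha = sel$alpha, q = sel$q)
    emit(tab, "differential.tsv")
    emit(volcanoTable(sce, contrast), "volcano.tsv")
    selected <- tab$protein_id[tab$all_or_nothing]

    ## --- network enrichment ---------------------------------------------
    if (!is.null(collection)) {
        inputList <- tab$protein_id[tab$bonferroni]
        if (!length(inputList)) inputList <- selected
        if (length(inputList)) {
            scores <- scoreNetworks(inputList, collection)
            null <- permutationThreshold(collection, listSize = length(inputList),
                                         repeats = config$network$repeats %||% 10,
                                         seed = seed + 10L)
            emit(significantNetworks(scores, null), "network_scores.tsv")
            emit(data.frame(repeat_ = seq_along(null@maxScores),
                            max_score = null@maxScores,
                            threshold = nullThreshold(null)), "network_null.tsv")
        }
    }

    ## --- clustering ------------------------------------------------------
    clusterIds <- if (length(selected) >= 2L) selected else
        utils::head(tab$protein_id[order(tab$p_value)], 14L)
    vals <- log2(replaceZeros(spectralCounts(sce)[clusterIds, , drop = FALSE]))
    cl <- wardCluster(vals)
    emit(data.frame(step = seq_len(nrow(cl$merge)), left = cl$merge[, 1L],
                    right = cl$merge[, 2L], height = cl$height), "cluster_merges.tsv")
    writeLines(clusterNewick(cl), file.path(stage, "cluster.nwk"))
    manifest$outputs[["cluster.nwk"]] <- length(clusterIds)

    ## --- PRM calibration -------------------------------------------------
    if (!is.null(prmSeries)) {
        curve <- fitCalibration(prmSeries)
        emit(calibrationSummary(curve), "prm_calibration.tsv")
        emit(calibrationCV(curve), "prm_cv.tsv")
    }

    ## --- transcriptome comparison ---------------------------------------
    if (!is.null(expr)) {
        diffGenes <- if (length(selected)) selected else
            tab$protein_id[tab$bonferroni]
        if (length(intersect(diffGenes, rownames(expr)))) {
            cmp <- compareToBackground(diffGenes, rownames(expr), expr)
            emit(data.frame(p_value = cmp$p_value, median_diff = cmp$median_diff,
                            median_background = cmp$median_background,
                            significant = cmp$significant,
                            direction = cmp$direction), "transcriptome.tsv")
        }
    }

    ## --- manifest + publish ---------------------------------------------
    jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (f in list.files(stage))
        file.copy(file.path(stage, f), file.path(outDir, f), overwrite = TRUE)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
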