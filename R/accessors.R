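#' Accessors for SpectralCountExperiment
#'
#' \code{spectralCounts} returns the integer count matrix;
#' \code{sampleGroups} the per-sample group labels; \code{sampleAge} ages;
#' \code{figoStage} FIGO stages; \code{groupSamples} the sample ids belonging
#' to one group; \code{sampleAnnotations} the annotation table in the layout
#' written by \code{\link{writeAnnotations}}.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param group a group label.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
spectralCounts <- function(x) assay(x, "counts")

#' @rdname accessors
#' @export
sampleGroups <- function(x) setNames(as.character(colData(x)$group), colnames(x))

#' @rdname accessors
#' @export
sampleAge <- function(x) {
    cd <- colData(x)
    if ("age" %in% colnames(cd)) setNames(cd$age, colnames(x))
    else setNames(rep(NA_real_, ncol(x)), colnames(x))
}

#' @rdname accessors
#' @export
figoStage <- function(x) {
    cd <- colData(x)
    if ("figo_stage" %in% colnames(cd)) setNames(as.character(cd$figo_stage), colnames(x))
    else setNames(rep(NA_character_, ncol(x)), colnames(x))
}

#' @rdname accessors
#' @export
groupSamples <- function(x, group) {
    colnames(x)[sampleGroups(x) == group]
}

#' @rdname accessors
#' @export
sampleAnnotations <- function(x) {
    data.frame(sample_id = colnames(x), group = unname(sampleGroups(x)),
               age = unname(sampleAge(x)), figo_stage = unname(figoStage(x)),
               stringsAsFactors = FALSE)
}

#' Accessors for GeneSetCollection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return \code{geneSets}: named list of member vectors;
#'   \code{setDescriptions}: named character; \code{geneBackground}:
#'   character vector of background symbols.
#' @name geneset-accessors
NULL

#' @rdname geneset-accessors
#' @export
geneSets <- function(x) x@sets

#' @rdname geneset-accessors
#' @export
setDescriptions <- function(x) x@descriptions

#' @rdname geneset-accessors
#' @export
geneBackground <- function(x) x@background
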