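## Tabular I/O. One dialect everywhere: UTF-8 TSV, '\t' separator, '.' decimal,
## header line; floats written with 6 significant digits.

.fmtNum <- function(x) {
    out <- ifelse(is.na(x), "NA",
           ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
                  formatC(x, digits = 6, format = "g")))
    out
}

.writeTSV <- function(df, path) {
    num <- vapply(df, is.numeric, TRUE)
    out <- df
    for (j in which(num)) out[[j]] <- .fmtNum(df[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

.readTSV <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read / write a spectral-count matrix
#'
#' TSV layout: first column \code{protein_id}, remaining columns one per
#' sample, header row carries sample ids. Cells must be nonnegative integers.
#' Row and column order are preserved.
#'
#' @param path file path.
#' @return \code{readCountMatrix}: integer matrix with protein ids as
#'   rownames and sample ids as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0L, 3L, 2L, 5L), 2, 2,
#'             dimnames = list(c("MCM4", "S100P"), c("s1", "s2")))
#' writeCountMatrix(m, tf)
#' identical(readCountMatrix(tf), m)
#' @export
readCountMatrix <- function(path) {
    df <- .readTSV(path)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("empty or malformed count matrix file: ", path)
    ids <- as.character(df[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated protein id(s): ", paste(unique(dup), collapse = ", "))
    sid <- colnames(df)[-1L]
    dupS <- sid[duplicated(sid)]
    if (length(dupS))
        stop("duplicated sample id(s): ", paste(unique(dupS), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("count cell is not a nonnegative integer at protein '%s', sample '%s'",
                     ids[bad[1L, 1L]], sid[bad[1L, 2L]]))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(ids, sid)
    m
}

#' @rdname readCountMatrix
#' @param counts integer matrix (or a \linkS4class{SpectralCountExperiment},
#'   whose counts assay is written).
#' @export
writeCountMatrix <- function(counts, path) {
    if (is(counts, "SpectralCountExperiment")) counts <- spectralCounts(counts)
    df <- data.frame(protein_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read / write sample annotations
#'
#' TSV with columns \code{sample_id}, \code{group}, and optionally \code{age}
#' (years) and \code{figo_stage}. Groups must come from the closed vocabulary
#' (\code{early_cancer}, \code{late_cancer}, \code{healthy_epithelium},
#' \code{stroma}, \code{cell_line:<name>}); a FIGO stage is only allowed on
#' cancer samples.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_id}, \code{group},
#'   \code{age}, \code{figo_stage}.
#' @export
readAnnotations <- function(path) {
    df <- .readTSV(path)
    req <- c("sample_id", "group")
    if (!all(req %in% colnames(df)))
        stop("annotation file must have columns sample_id and group: ", path)
    df$sample_id <- as.character(df$sample_id)
    df$group <- as.character(df$group)
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id(s): ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
    bad <- df$group[!.isValidGroup(df$group)]
    if (length(bad))
        stop("unknown group(s): ", paste(unique(bad), collapse = ", "))
    if (!"age" %in% names(df)) df$age <- NA_real_
    if (!"figo_stage" %in% names(df)) df$figo_stage <- NA_character_
    df$figo_stage[!is.na(df$figo_stage) & df$figo_stage == ""] <- NA_character_
    offend <- !is.na(df$figo_stage) & !(df$group %in% .CANCER_GROUPS)
    if (any(offend))
        stop("figo_stage set for non-cancer sample(s): ",
             paste(df$sample_id[offend], collapse = ", "))
    df[, c("sample_id", "group", "age", "figo_stage")]
}

#' @rdname readAnnotations
#' @param annotations data.frame as returned by \code{readAnnotations}.
#' @export
writeAnnotations <- function(annotations, path) {
    .writeTSV(annotations, path)
}

#' Classify a FIGO stage string as early or late
#'
#' Stages beginning with Roman numeral I or II are early; III or IV are late
#' (case-insensitive, optional sub-letter/digit such as "Ib2" or "IIIa").
#'
#' @param figo_stage character vector of FIGO stage strings.
#' @return character vector of \code{"early"} / \code{"late"}.
#' @examples
#' stageClass(c("Ib2", "IIb", "IIIb", "IVa"))
#' @export
stageClass <- function(figo_stage) {
    s <- toupper(trimws(as.character(figo_stage)))
    m <- regmatches(s, regexpr("^(IV|III|II|I)", s))
    ok <- lengths(regmatches(s, gregexpr("^(IV|III|II|I)[A-B0-9]*$", s))) == 1L
    if (any(!ok | !nzchar(s)))
        stop("unparseable FIGO stage string(s): ",
             paste(unique(figo_stage[!ok]), collapse = ", "))
    ifelse(m %in% c("I", "II"), "early", "late")
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, \code{set_id TAB description TAB
#' member1 TAB member2 ...}. Empty lines are ignored. Duplicate members
#' within a set are dropped with a warning. The background defaults to the
#' union of all members unless given.
#'
#' @param path file path.
#' @param background optional character vector of background gene symbols.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, background = NULL) {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d has fewer than 3 fields", lineno[i]))
        members <- f[-(1:2)]
        members <- members[nzchar(members)]
        if (anyDuplicated(members)) {
            warning(sprintf("duplicated member(s) in set '%s'; de-duplicated", f[1L]))
            members <- unique(members)
        }
        sets[[f[1L]]] <- members
        desc[f[1L]] <- f[2L]
    }
    geneSetCollection(sets, background = background, descriptions = desc)
}

#' @rdname readGMT
#' @param collection a \linkS4class{GeneSetCollection}.
#' @export
writeGMT <- function(collection, path) {
    sets <- geneSets(collection)
    desc <- setDescriptions(collection)
    lines <- vapply(names(sets), function(id)
        paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a log2 expression table
#'
#' TSV: first column \code{gene_id}, remaining columns samples; values are
#' log2-transformed expression (log2 FPKM). Missing values allowed as NA.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTable <- function(path) {
    df <- .readTSV(path)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("empty or malformed expression file: ", path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicated gene id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "numeric"
    if (any(is.infinite(m)))
        stop("expression values must be finite or NA")
    rownames(m) <- ids
    m
}

#' @rdname readExpressionTable
#' @param values numeric matrix of log2 expression, genes x samples.
#' @export
writeExpressionTable <- function(values, path) {
    df <- data.frame(gene_id = rownames(values), values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTSV(df, path)
}

#' Read a PRM dilution-series table
#'
#' TSV with columns \code{peptide}, \code{level} (fmol/uL),
#' \code{replicate}, \code{area}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readDilutionSeries <- function(path) {
    df <- .readTSV(path)
    req <- c("peptide", "level", "replicate", "area")
    if (!all(req %in% colnames(df)))
        stop("dilution series file must have columns: ", paste(req, collapse = ", "))
    df
}

#' Read a PRM measurement table
#'
#' TSV with columns \code{sample_id}, \code{peptide}, \code{protein},
#' \code{endogenous_area}, \code{sil_area}, \code{spike_fmol},
#' \code{scale_factor}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPRMMeasurements <- function(path) {
    df <- .readTSV(path)
    req <- c("sample_id", "peptide", "protein", "endogenous_area",
             "sil_area", "spike_fmol", "scale_factor")
    if (!all(req %in% colnames(df)))
        stop("PRM measurement file must have columns: ", paste(req, collapse = ", "))
    if (any(df$endogenous_area < 0 | df$sil_area < 0))
        stop("areas must be nonnegative")
    if (any(df$spike_fmol <= 0) || any(df$scale_factor <= 0))
        stop("spike_fmol and scale_factor must be positive")
    df
}

#' Estimate the number of cells in a microdissected area
#'
#' Converts a dissected tissue area and section thickness into an approximate
#' cell count assuming cubic cells of a given edge length: count =
#' area (mm^2) x 1e6 (um^2/mm^2) x thickness (um) / edge (um)^3, rounded to
#' the nearest integer.
#'
#' @param area_mm2 dissected area in mm^2.
#' @param section_thickness_um section thickness in um (cryosections are
#'   typically 10 um).
#' @param cell_edge_um assumed cell edge length in um (default 10, i.e. a
#'   10 x 10 x 10 um cell volume).
#' @return integer cell count.
#' @examples
#' estimateCellCount(0.8)  # ~8,000 cells
#' @export
estimateCellCount <- function(area_mm2, section_thickness_um = 10,
                              cell_edge_um = 10) {
    if (any(area_mm2 <= 0) || any(section_thickness_um <= 0) || any(cell_edge_um <= 0))
        stop("all arguments must be positive")
    round(area_mm2 * 1e6 * section_thickness_um / cell_edge_um^3)
}
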