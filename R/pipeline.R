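## ---- TSV I/O --------------------------------------------------------------

#' Read / write sample tables and occurrence matrices
#'
#' Sample tables are TSV with a header including a \code{sample} column;
#' occurrence matrices are TSV with lineages as rows (first column
#' \code{lineage}) and samples as columns, values 0/1.
#'
#' @param path file path.
#' @return \code{readSampleTable}: data.frame; \code{readOccurrenceMatrix}:
#'   integer matrix.
#' @export
readSampleTable <- function(path) {
    st <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample" %in% names(st))
        stop("sample table must have a 'sample' column", call. = FALSE)
    st
}

#' @rdname readSampleTable
#' @export
readOccurrenceMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
}

#' @rdname readSampleTable
#' @param occurrence lineage x sample matrix.
#' @export
writeOccurrenceMatrix <- function(occurrence, path) {
    df <- data.frame(lineage = rownames(occurrence), occurrence,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readSampleTable
#' @param d symmetric distance matrix with lineage ids as dimnames.
#' @export
writeDistanceMatrix <- function(d, path) {
    df <- data.frame(lineage = rownames(d), d, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname readSampleTable
#' @export
readDistanceMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}

## ---- lake summaries -------------------------------------------------------

#' Median and quartiles of lake variables
#'
#' Per-variable median, first and third quartile over lakes, using
#' linear-interpolation quantiles (sorted position 1 + p (n - 1)); this is
#' the convention that reproduces printed lake-table summary rows.
#'
#' @param sampleTable data.frame of lake metadata.
#' @param columns numeric columns to summarise; defaults to the numeric
#'   columns among the standard lake variables.
#' @return data.frame with rows \code{median}, \code{q1}, \code{q3}.
#' @export
summarizeLakes <- function(sampleTable,
                           columns = intersect(c("size_ha", "depth_m",
                                                 "secchi_m", "pH",
                                                 "conductivity", "hco3",
                                                 "lai", "larix_pct"),
                                               names(sampleTable))) {
    if (length(columns) == 0L)
        stop("no summary columns found in sample table", call. = FALSE)
    for (cl in columns)
        if (!is.numeric(sampleTable[[cl]]))
            stop("non-numeric values in column '", cl, "'", call. = FALSE)
    qs <- vapply(columns, function(cl)
        quantile(sampleTable[[cl]], c(0.5, 0.25, 0.75), type = 7,
                 names = FALSE), numeric(3L))
    out <- as.data.frame(qs)
    rownames(out) <- c("median", "q1", "q3")
    out
}

## ---- result-table helper --------------------------------------------------

resultRow <- function(data, explanatorySet, fs) {
    if (length(fs@selected)) {
        fm <- fs@finalModel
        data.frame(data = data, explanatory_set = explanatorySet,
                   selected = paste(fs@selected, collapse = " + "),
                   R2 = fm@R2, adjR2 = fm@adjR2, P = fm@pValue,
                   stringsAsFactors = FALSE)
    } else {
        ## nothing admitted: report the best rejected candidate diagnostics
        st <- fs@steps
        data.frame(data = data, explanatory_set = explanatorySet,
                   selected = "(none)",
                   R2 = if (nrow(st)) st$cum_R2[1L] else NA_real_,
                   adjR2 = if (nrow(st)) st$cum_adjR2[1L] else NA_real_,
                   P = if (nrow(st)) st$p[1L] else NA_real_,
                   stringsAsFactors = FALSE)
    }
}

## ---- spatial analysis -----------------------------------------------------

#' Spatial analysis: lineage occurrence and relatedness across lakes
#'
#' Runs the full modern-lake analysis: (i) NMDS of the samples on
#' Bray-Curtis dissimilarities of lineage presence/absence; (ii) RDA of the
#' occurrence table against transect dummies and against vegetation
#' dummies, each with forward selection; (iii) dbRDA of the lineages'
#' patristic distances against their transect-affinity columns and their
#' vegetation-affinity columns, each with forward selection. Abundances are
#' never used: the matrix is binarised on entry.
#'
#' @param occurrence binary lineage x lake matrix.
#' @param sampleTable lake metadata with \code{sample}, \code{transect},
#'   \code{vegetation} columns.
#' @param tree \code{phylo} covering the lineages (extra tips allowed;
#'   lineages missing from the tree are excluded with a warning).
#' @param nPerm,alpha,seed ordination settings (defaults 999, 0.1, 1).
#' @param negativePolicy PCoA negative-eigenvalue policy.
#' @return list with \code{nmds} (\code{NmdsResult}), \code{table} (one row
#'   per test: \code{data}, \code{explanatory_set}, \code{selected},
#'   \code{R2}, \code{adjR2}, \code{P}), and \code{details} (the underlying
#'   forward-selection objects and affinity tables).
#' @export
runSpatial <- function(occurrence, sampleTable, tree, nPerm = 999,
                       alpha = 0.1, seed = 1, negativePolicy = "drop") {
    stopifnot(is.matrix(occurrence))
    if (nrow(occurrence) == 0L || sum(occurrence) == 0L)
        stop("occurrence matrix is empty", call. = FALSE)
    occurrence <- (occurrence > 0) + 0L
    missing <- setdiff(rownames(occurrence), tree$tip.label)
    if (length(missing)) {
        warning("lineage(s) missing from tree excluded: ",
                paste(missing, collapse = ", "), call. = FALSE)
        occurrence <- occurrence[setdiff(rownames(occurrence), missing), ,
                                 drop = FALSE]
    }
    present <- rowSums(occurrence) > 0
    if (any(!present)) {
        warning("lineage(s) never observed excluded: ",
                paste(rownames(occurrence)[!present], collapse = ", "),
                call. = FALSE)
        occurrence <- occurrence[present, , drop = FALSE]
    }
    samples <- t(occurrence)                       # samples x lineages
    nmds <- nmdsFit(brayCurtis(samples), k = 2, seed = seed)
    trDum <- dummyCode(sampleTable, "transect")
    vgDum <- dummyCode(sampleTable, "vegetation")
    fsTr <- forwardSelect(samples, trDum, alpha, nPerm, seed,
                          isDistance = FALSE)
    fsVg <- forwardSelect(samples, vgDum, alpha, nPerm, seed,
                          isDistance = FALSE)
    pat <- patristicDistances(tree, rownames(occurrence))
    affTr <- categoryAffinity(occurrence, sampleTable, "transect")
    affVg <- categoryAffinity(occurrence, sampleTable, "vegetation")
    trCols <- affinityColumns(affTr, "transect")
    vgCols <- affinityColumns(affVg, "vegetation")
    fsPatTr <- forwardSelect(pat, trCols, alpha, nPerm, seed,
                             isDistance = TRUE,
                             negativePolicy = negativePolicy)
    fsPatVg <- forwardSelect(pat, vgCols, alpha, nPerm, seed,
                             isDistance = TRUE,
                             negativePolicy = negativePolicy)
    tab <- rbind(
        resultRow("occurrence", "transect dummies", fsTr),
        resultRow("occurrence", "vegetation dummies", fsVg),
        resultRow("patristic distance", "transect affinity", fsPatTr),
        resultRow("patristic distance", "vegetation affinity", fsPatVg))
    list(nmds = nmds, table = tab,
         details = list(rda_transect = fsTr, rda_vegetation = fsVg,
                        dbrda_transect = fsPatTr,
                        dbrda_vegetation = fsPatVg,
                        transect_affinity = affTr,
                        vegetation_affinity = affVg,
                        patristic = pat))
}

affinityColumns <- function(aff, prefix) {
    v <- affinityValues(aff)
    colnames(v) <- paste0(prefix, "_aff_", colnames(v))
    v
}

## ---- temporal analysis ----------------------------------------------------

#' Temporal analysis: core lineage relatedness vs Larix pollen
#'
#' Computes the \emph{Larix} pollen affinity of every core lineage and runs
#' the dbRDA of the lineages' patristic distances against that single
#' affinity column (forward selection over one candidate). Horizons without
#' a \emph{Larix} value are excluded with a warning; a constant
#' \emph{Larix} affinity is a degenerate explanatory variable and an error.
#'
#' @param occurrence binary lineage x horizon matrix.
#' @param sampleTable horizon metadata with \code{sample},
#'   \code{larix_pct}, and optionally \code{depth_cm}, \code{age_calBP}.
#' @param tree \code{phylo} covering the core lineages.
#' @param nPerm,alpha,seed,negativePolicy as in \code{\link{runSpatial}}.
#' @return list with \code{table} (one result row), \code{larixAffinity}
#'   (named numeric), \code{horizons} (per-horizon presence counts with
#'   \emph{Larix} percent, the down-core data layer) and \code{details}.
#' @export
runTemporal <- function(occurrence, sampleTable, tree, nPerm = 999,
                        alpha = 0.1, seed = 1, negativePolicy = "drop") {
    stopifnot(is.matrix(occurrence))
    occurrence <- (occurrence > 0) + 0L
    ok <- !is.na(sampleTable$larix_pct)
    if (any(!ok)) {
        warning("horizon(s) without Larix value excluded: ",
                paste(sampleTable$sample[!ok], collapse = ", "),
                call. = FALSE)
        sampleTable <- sampleTable[ok, , drop = FALSE]
        occurrence <- occurrence[, colnames(occurrence) %in%
                                       sampleTable$sample, drop = FALSE]
    }
    missing <- setdiff(rownames(occurrence), tree$tip.label)
    if (length(missing)) {
        warning("lineage(s) missing from tree excluded: ",
                paste(missing, collapse = ", "), call. = FALSE)
        occurrence <- occurrence[setdiff(rownames(occurrence), missing), ,
                                 drop = FALSE]
    }
    present <- rowSums(occurrence) > 0
    occurrence <- occurrence[present, , drop = FALSE]
    if (nrow(occurrence) < 4L)
        stop("too few lineages with occurrences (", nrow(occurrence),
             ") for dbRDA", call. = FALSE)
    la <- larixAffinity(occurrence, sampleTable)
    if (sd(la) < 1e-12)
        stop("Larix affinity has zero variance: degenerate explanatory ",
             "variable", call. = FALSE)
    pat <- patristicDistances(tree, names(la))
    X <- matrix(la, ncol = 1L,
                dimnames = list(names(la), "larix_affinity"))
    fs <- forwardSelect(pat, X, alpha, nPerm, seed, isDistance = TRUE,
                        negativePolicy = negativePolicy)
    tab <- resultRow("patristic distance (core)", "Larix pollen affinity",
                     fs)
    horizons <- data.frame(sampleTable[match(colnames(occurrence),
                                             sampleTable$sample), ,
                                       drop = FALSE],
                           n_lineages = colSums(occurrence),
                           row.names = NULL)
    list(table = tab, larixAffinity = la, horizons = horizons,
         details = list(dbrda_larix = fs, patristic = pat,
                        occurrence = occurrence))
}

## ---- modern vs ancient comparison -----------------------------------------

#' Compare modern and core lineage sets
#'
#' Partitions two lineage sets of the same fragment into shared (identical
#' sequence), modern-only and core-only lineages, and lists near-matches at
#' up to \code{maxMismatch} nucleotide differences, each with its partners'
#' affinity context when affinities are supplied (the modern lineage's
#' highest-affinity vegetation type and the core lineage's \emph{Larix}
#' affinity).
#'
#' @param modern,core \code{LineageSet}s trimmed to the same fragment.
#' @param maxMismatch near-match threshold (default 2).
#' @param modernAffinity optional \code{AffinityTable} of the modern
#'   lineages over vegetation types.
#' @param coreLarix optional named numeric \emph{Larix} affinity of core
#'   lineages.
#' @return list with \code{shared} (data.frame of identical pairs),
#'   \code{modern_only}, \code{core_only} (character vectors) and
#'   \code{near_matches} (data.frame with distances 1..maxMismatch and
#'   affinity context columns).
#' @export
runComparison <- function(modern, core, maxMismatch = 2,
                          modernAffinity = NULL, coreLarix = NULL) {
    pairs <- matchLineageSets(modern, core, maxMismatch)
    shared <- pairs[pairs$distance == 0L, c("idA", "idB"), drop = FALSE]
    names(shared) <- c("modern_id", "core_id")
    near <- pairs[pairs$distance > 0L, , drop = FALSE]
    names(near)[1:2] <- c("modern_id", "core_id")
    near$identical <- NULL
    if (!is.null(modernAffinity)) {
        v <- affinityValues(modernAffinity)
        am <- colnames(v)[max.col(v, ties.method = "first")]
        near$modern_top_vegetation <-
            am[match(near$modern_id, rownames(v))]
    }
    if (!is.null(coreLarix))
        near$core_larix_affinity <- unname(coreLarix[near$core_id])
    list(shared = shared,
         modern_only = setdiff(lineageIds(modern), shared$modern_id),
         core_only = setdiff(lineageIds(core), shared$core_id),
         near_matches = near)
}
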