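#' Per-lineage category affinity
#'
#' Occupancy proportion of each lineage within each category of a sample
#' classification (transect or vegetation type): presences of the lineage in
#' the category divided by the number of samples in the category. Dividing
#' by the category size is what corrects for unequal numbers of lakes per
#' transect / vegetation type; with presence/absence data the per-lake
#' relative frequency of a lineage is 0 or 1, so its within-category mean is
#' exactly this proportion.
#'
#' @param occurrence binary lineage x sample matrix (column names = sample
#'   ids); any positive entry counts as presence.
#' @param sampleTable data.frame with a \code{sample} column and the
#'   category column; every occurrence column must map to exactly one
#'   category.
#' @param categoryColumn name of the category column (default
#'   "vegetation").
#' @param normalizeRows if TRUE, rows are rescaled to sum to one (all-zero
#'   rows stay zero, with a warning).
#' @return An \code{\linkS4class{AffinityTable}}.
#' @examples
#' occ <- rbind(lin1 = c(1, 1, 0, 0), lin2 = c(0, 0, 1, 1))
#' colnames(occ) <- paste0("s", 1:4)
#' st <- data.frame(sample = paste0("s", 1:4),
#'                  vegetation = c("tundra", "tundra", "taiga", "taiga"))
#' affinityValues(categoryAffinity(occ, st))
#' @export
categoryAffinity <- function(occurrence, sampleTable,
                             categoryColumn = "vegetation",
                             normalizeRows = FALSE) {
    stopifnot(is.matrix(occurrence))
    if (!categoryColumn %in% names(sampleTable))
        stop("sampleTable has no column '", categoryColumn, "'",
             call. = FALSE)
    idx <- match(colnames(occurrence), sampleTable$sample)
    if (anyNA(idx))
        stop("samples missing from sampleTable: ",
             paste(colnames(occurrence)[is.na(idx)], collapse = ", "),
             call. = FALSE)
    cat <- sampleTable[[categoryColumn]][idx]
    if (anyNA(cat))
        stop("every sample must map to exactly one category", call. = FALSE)
    if (!is.factor(cat)) cat <- factor(cat)   # factors keep given levels
    if (any(tabulate(cat, nlevels(cat)) == 0L))
        stop("empty category level(s): ",
             paste(levels(cat)[tabulate(cat, nlevels(cat)) == 0L],
                   collapse = ", "), call. = FALSE)
    bin <- (occurrence > 0) + 0L
    sizes <- as.integer(table(cat))
    vals <- vapply(levels(cat), function(lv)
        rowSums(bin[, cat == lv, drop = FALSE]), numeric(nrow(bin)))
    if (nrow(bin) == 1L) vals <- matrix(vals, nrow = 1L,
                                        dimnames = list(rownames(bin),
                                                        levels(cat)))
    vals <- sweep(vals, 2L, sizes, "/")
    zero <- rowSums(bin) == 0L
    if (any(zero))
        warning("lineage(s) with zero occurrences retained with zero ",
                "affinity row: ",
                paste(rownames(bin)[zero], collapse = ", "), call. = FALSE)
    if (normalizeRows) {
        rs <- rowSums(vals)
        vals[rs > 0, ] <- vals[rs > 0, , drop = FALSE] / rs[rs > 0]
    }
    new("AffinityTable", values = vals, categorySizes = sizes,
        normalized = isTRUE(normalizeRows))
}

#' @rdname AffinityTable-class
#' @export
setMethod("affinityValues", "AffinityTable", function(x) x@values)

#' @rdname AffinityTable-class
#' @export
setMethod("categorySizes", "AffinityTable", function(x) x@categorySizes)

setMethod("show", "AffinityTable", function(object) {
    cat(sprintf("AffinityTable: %d lineages x %d categories%s\n",
                nrow(object@values), ncol(object@values),
                if (object@normalized) " (row-normalised)" else ""))
})

#' Larix pollen affinity
#'
#' The mean \emph{Larix} pollen percentage of the samples in which a lineage
#' occurs: a scalar environmental preference for each core lineage. It is a
#' convex combination of the occupied horizons' \emph{Larix} values, hence
#' bounded by their minimum and maximum. Lineages with no occurrences have
#' no defined affinity and are excluded with a warning.
#'
#' @param occurrence binary lineage x sample matrix.
#' @param sampleTable data.frame with \code{sample} and the \emph{Larix}
#'   percentage column.
#' @param larixColumn name of the percentage column (default "larix_pct").
#' @return named numeric vector over lineages with at least one occurrence.
#' @export
larixAffinity <- function(occurrence, sampleTable,
                          larixColumn = "larix_pct") {
    stopifnot(is.matrix(occurrence))
    if (!larixColumn %in% names(sampleTable))
        stop("sampleTable has no column '", larixColumn, "'", call. = FALSE)
    idx <- match(colnames(occurrence), sampleTable$sample)
    if (anyNA(idx))
        stop("samples missing from sampleTable: ",
             paste(colnames(occurrence)[is.na(idx)], collapse = ", "),
             call. = FALSE)
    p <- sampleTable[[larixColumn]][idx]
    if (anyNA(p))
        stop("missing ", larixColumn, " values for mapped samples",
             call. = FALSE)
    bin <- (occurrence > 0) + 0L
    tot <- rowSums(bin)
    if (any(tot == 0L))
        warning("lineage(s) with zero occurrences excluded from Larix ",
                "affinity: ",
                paste(rownames(bin)[tot == 0L], collapse = ", "),
                call. = FALSE)
    keep <- tot > 0L
    setNames(as.numeric(bin[keep, , drop = FALSE] %*% p) / tot[keep],
             rownames(bin)[keep])
}

#' Pairwise distances in affinity space
#'
#' Distances between lineages' affinity vectors (Euclidean by default,
#' optionally Manhattan); for a scalar affinity this is the absolute
#' difference. This is the "pairwise distances of lineages' affinity"
#' reading of the explanatory side of the distance-based analyses.
#'
#' @param x an \code{\linkS4class{AffinityTable}} or a named numeric vector
#'   (scalar affinity).
#' @param method "euclidean" (default) or "manhattan".
#' @return symmetric numeric matrix with zero diagonal.
#' @export
affinityDistance <- function(x, method = c("euclidean", "manhattan")) {
    method <- match.arg(method)
    v <- if (is(x, "AffinityTable")) x@values
         else matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
    if (is.null(rownames(v)))
        stop("affinity input must carry lineage ids", call. = FALSE)
    d <- as.matrix(dist(v, method = method))
    diag(d) <- 0
    d
}

#' Read / write affinity tables
#'
#' TSV with a \code{lineage} column and one column per category (or a
#' single \code{larix_affinity} column for the scalar affinity).
#'
#' @param x an \code{AffinityTable} or named numeric vector.
#' @param path file path.
#' @export
writeAffinityTable <- function(x, path) {
    if (is(x, "AffinityTable")) {
        df <- data.frame(lineage = rownames(x@values), x@values,
                         check.names = FALSE)
    } else {
        df <- data.frame(lineage = names(x), larix_affinity = unname(x))
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
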