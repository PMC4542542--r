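## ---- small linear-algebra helpers -----------------------------------------

centerCols <- function(m) sweep(m, 2L, colMeans(m), "-")

## R2 of the projection of centred Y onto span(centred X); also returns the
## qr object so callers can reuse fitted values.
projectionR2 <- function(Yc, Xc, ssY = sum(Yc^2)) {
    q <- qr(Xc)
    if (q$rank == 0L) return(list(r2 = 0, rank = 0L, qr = q))
    fit <- qr.fitted(q, Yc)
    list(r2 = sum(fit^2) / ssY, rank = q$rank, qr = q, fitted = fit)
}

asNumericMatrix <- function(X) {
    if (is.data.frame(X)) X <- as.matrix(X)
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                     dimnames = list(names(X), "x"))
    storage.mode(X) <- "double"
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
    X
}

checkDistanceMatrix <- function(d, tol = 1e-8) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    if (max(abs(d - t(d))) > tol)
        stop("distance matrix must be symmetric", call. = FALSE)
    if (any(abs(diag(d)) > tol))
        stop("distance matrix must have a zero diagonal", call. = FALSE)
    if (any(d < -tol))
        stop("distances must be nonnegative", call. = FALSE)
    d
}

## ---- Bray-Curtis ----------------------------------------------------------

#' Bray-Curtis dissimilarity
#'
#' Pairwise Bray-Curtis dissimilarity between the rows of a sample x lineage
#' matrix: BC(s,t) = 1 - 2 sum(min(x_s, x_t)) / sum(x_s + x_t). By default
#' the input is binarised first (the analyses here use presence/absence
#' only), on which Bray-Curtis equals the Sorensen dissimilarity. A pair of
#' all-zero rows has no shared or private lineages; its dissimilarity is
#' defined as 0, with a warning.
#'
#' @param m nonnegative numeric matrix, samples x lineages.
#' @param presenceAbsence binarise before computing (default TRUE).
#' @return symmetric matrix in [0, 1] with zero diagonal.
#' @examples
#' brayCurtis(rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 1)))
#' @export
brayCurtis <- function(m, presenceAbsence = TRUE) {
    stopifnot(is.matrix(m))
    if (any(m < 0))
        stop("abundance matrix must be nonnegative", call. = FALSE)
    if (presenceAbsence) m <- (m > 0) + 0
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    warned <- FALSE
    for (i in seq_len(max(n - 1L, 0L))) {
        for (j in (i + 1L):n) {
            denom <- sum(m[i, ]) + sum(m[j, ])
            if (denom == 0) {
                if (!warned) {
                    warning("pair(s) of empty samples: dissimilarity ",
                            "defined as 0", call. = FALSE)
                    warned <- TRUE
                }
                d[i, j] <- d[j, i] <- 0
            } else {
                d[i, j] <- d[j, i] <-
                    1 - 2 * sum(pmin(m[i, ], m[j, ])) / denom
            }
        }
    }
    d
}

## ---- dummy coding ---------------------------------------------------------

#' Dummy-code a categorical sample variable
#'
#' One 0/1 indicator column per level; with \code{dropReference = TRUE}
#' (default) the first level is dropped so the design is full rank alongside
#' an intercept. Row sums equal one before dropping.
#'
#' @param sampleTable data.frame of sample metadata.
#' @param column name of the categorical column.
#' @param dropReference drop the first level (default TRUE).
#' @param levels optional explicit level set; values outside it are an
#'   error.
#' @return numeric indicator matrix with columns named
#'   \code{<column>_<level>}.
#' @export
dummyCode <- function(sampleTable, column, dropReference = TRUE,
                      levels = NULL) {
    if (!column %in% names(sampleTable))
        stop("no column '", column, "' in sample table", call. = FALSE)
    x <- sampleTable[[column]]
    if (!is.null(levels)) {
        bad <- setdiff(unique(as.character(x)), levels)
        if (length(bad))
            stop("unknown level(s) in '", column, "': ",
                 paste(bad, collapse = ", "), call. = FALSE)
        f <- factor(x, levels = levels)
    } else f <- factor(x)
    if (nlevels(f) < 2L)
        stop("column '", column, "' has a single level; cannot be used ",
             "as a constraint", call. = FALSE)
    X <- vapply(base::levels(f), function(lv) as.numeric(f == lv),
                numeric(length(f)))
    colnames(X) <- paste(column, base::levels(f), sep = "_")
    rownames(X) <- sampleTable$sample
    if (dropReference) X <- X[, -1L, drop = FALSE]
    X
}

## ---- RDA ------------------------------------------------------------------

#' Redundancy analysis with a permutation test
#'
#' Classical RDA: the response matrix is column-centred and regressed on the
#' (centred) explanatory matrix; R2 is the fraction of total inertia (sum of
#' squares) captured by the fitted values, adjusted R2 is Ezekiel's
#' 1 - (1 - R2)(n - 1)/(n - m - 1) with m the rank of the constraints, and
#' the pseudo-F statistic (R2/m)/((1 - R2)/(n - m - 1)) is tested by
#' permuting the rows of the explanatory matrix (add-one p-value estimator).
#'
#' @param Y response matrix (n x p), e.g. a presence/absence community
#'   table with samples as rows.
#' @param X explanatory matrix or data.frame (n x m); typically dummy
#'   indicators or affinity columns.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A \code{\linkS4class{ConstrainedOrdination}}.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(40), 20)
#' X <- matrix(rnorm(20), 20, dimnames = list(NULL, "env"))
#' rdaFit(Y, X, nPerm = 99)
#' @export
rdaFit <- function(Y, X, nPerm = 999, seed = 1) {
    Y <- asNumericMatrix(Y); X <- asNumericMatrix(X)
    n <- nrow(Y)
    if (nrow(X) != n)
        stop("response and explanatory matrices must have aligned rows",
             call. = FALSE)
    Yc <- centerCols(Y); Xc <- centerCols(X)
    ssY <- sum(Yc^2)
    if (ssY == 0)
        stop("response has zero variance", call. = FALSE)
    obs <- projectionR2(Yc, Xc, ssY)
    m <- obs$rank
    if (m == 0L)
        stop("explanatory matrix has zero variance", call. = FALSE)
    if (m < ncol(X))
        warning("rank-deficient explanatory matrix: rank ", m, " < ",
                ncol(X), " columns", call. = FALSE)
    if (n <= m + 1L)
        stop("too few rows (n = ", n, ") for ", m, " constraints",
             call. = FALSE)
    R2 <- obs$r2
    adjR2 <- 1 - (1 - R2) * (n - 1) / (n - m - 1)
    pseudoF <- (R2 / m) / ((1 - R2) / (n - m - 1))
    set.seed(as.integer(seed))
    ge <- 0L
    for (b in seq_len(nPerm)) {
        perm <- sample.int(n)
        if (projectionR2(Yc, Xc[perm, , drop = FALSE], ssY)$r2 >= R2)
            ge <- ge + 1L
    }
    pValue <- (1 + ge) / (1 + nPerm)
    fit <- obs$fitted
    eigC <- svd(fit, nu = 0L, nv = 0L)$d^2
    eigC <- head(eigC[eigC > max(eigC[1], 1e-300) * 1e-12], m)
    eigU <- svd(Yc - fit, nu = 0L, nv = 0L)$d^2
    eigU <- eigU[eigU > 1e-12 * max(eigU[1], 1e-300)]
    new("ConstrainedOrdination", R2 = R2, adjR2 = adjR2, pseudoF = pseudoF,
        pValue = pValue, nPerm = as.integer(nPerm), rank = as.integer(m),
        nObs = as.integer(n), terms = colnames(X),
        eigConstrained = as.numeric(eigC), eigUnconstrained = as.numeric(eigU),
        totalInertia = ssY, method = "rda")
}

setMethod("show", "ConstrainedOrdination", function(object) {
    cat(sprintf("%s: n = %d, %d constraint(s) [%s]\n",
                toupper(object@method), object@nObs, object@rank,
                paste(object@terms, collapse = ", ")))
    cat(sprintf("  R2 = %.3f  adjR2 = %.3f  F = %.3f  P = %.4g (%d perms)\n",
                object@R2, object@adjR2, object@pseudoF, object@pValue,
                object@nPerm))
})

#' @rdname ConstrainedOrdination-class
#' @export
setMethod("ordinationSummary", "ConstrainedOrdination", function(object) {
    data.frame(R2 = object@R2, adjR2 = object@adjR2, F = object@pseudoF,
               P = object@pValue, n = object@nObs, rank = object@rank)
})

## ---- PCoA -----------------------------------------------------------------

#' Principal coordinates analysis
#'
#' Gower double-centring of the squared distances, G = -1/2 J D2 J with
#' J = I - 11'/n, followed by an eigendecomposition. Coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues.
#' Non-Euclidean matrices (Bray-Curtis, patristic) can produce negative
#' eigenvalues; policy \code{"drop"} (default) keeps the positive axes only,
#' \code{"lingoes"} adds the smallest constant to the squared distances and
#' \code{"cailliez"} to the distances that makes the matrix Euclidean.
#'
#' @param d distance matrix.
#' @param negativePolicy "drop", "lingoes" or "cailliez".
#' @return list with \code{coordinates} (n x k, k = number of positive
#'   axes), \code{eigenvalues} (all, of the possibly corrected matrix),
#'   \code{positiveEigenvalues}, \code{totalInertia} (their sum),
#'   \code{correction}, \code{constant}.
#' @export
pcoaFit <- function(d, negativePolicy = c("drop", "lingoes", "cailliez")) {
    negativePolicy <- match.arg(negativePolicy)
    d <- checkDistanceMatrix(d)
    n <- nrow(d)
    gower <- function(D2) {
        J <- diag(n) - matrix(1 / n, n, n)
        -0.5 * J %*% D2 %*% J
    }
    G <- gower(d^2)
    eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
    tol <- 1e-8 * max(abs(eig$values), 1e-300)
    constant <- 0
    if (min(eig$values) < -tol && negativePolicy != "drop") {
        if (negativePolicy == "lingoes") {
            constant <- -min(eig$values)
            D2 <- d^2 + 2 * constant
            diag(D2) <- 0
            G <- gower(D2)
        } else {                                # cailliez
            G2 <- gower(d)
            M <- rbind(cbind(matrix(0, n, n), 2 * G),
                       cbind(-diag(n), -4 * G2))
            constant <- max(Re(eigen(M, only.values = TRUE)$values))
            Dc <- d + constant
            diag(Dc) <- 0
            G <- gower(Dc^2)
        }
        eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
        tol <- 1e-8 * max(abs(eig$values), 1e-300)
    }
    pos <- eig$values > tol
    if (!any(pos))
        stop("degenerate input: no positive eigenvalues", call. = FALSE)
    coords <- eig$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(eig$values[pos]), sum(pos))
    rownames(coords) <- rownames(d)
    colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
    list(coordinates = coords, eigenvalues = eig$values,
         positiveEigenvalues = eig$values[pos],
         totalInertia = sum(eig$values[pos]),
         correction = negativePolicy, constant = constant)
}

## ---- dbRDA ----------------------------------------------------------------

#' Distance-based redundancy analysis
#'
#' RDA run on the principal coordinates of a distance matrix (all retained
#' axes), the standard two-stage construction: on Euclidean distances of a
#' raw matrix it reproduces the RDA of that matrix exactly. This is the
#' test used to relate lineages' patristic distances to their environmental
#' affinities.
#'
#' @param d distance matrix over the analysis units (e.g. lineages).
#' @param X explanatory matrix/data.frame with rows aligned to \code{d}
#'   (matched by rownames when present).
#' @param nPerm,seed permutation-test settings.
#' @param negativePolicy passed to \code{\link{pcoaFit}}.
#' @return A \code{\linkS4class{ConstrainedOrdination}} (method "dbrda");
#'   total inertia is the sum of positive PCoA eigenvalues.
#' @export
dbrdaFit <- function(d, X, nPerm = 999, seed = 1,
                     negativePolicy = c("drop", "lingoes", "cailliez")) {
    negativePolicy <- match.arg(negativePolicy)
    X <- asNumericMatrix(X)
    d <- checkDistanceMatrix(d)
    if (!is.null(rownames(d)) && !is.null(rownames(X))) {
        if (!setequal(rownames(d), rownames(X)))
            stop("labels of distance matrix and explanatory matrix differ",
                 call. = FALSE)
        X <- X[rownames(d), , drop = FALSE]
    } else if (nrow(X) != nrow(d))
        stop("explanatory matrix rows do not match distance matrix",
             call. = FALSE)
    pc <- pcoaFit(d, negativePolicy)
    res <- rdaFit(pc$coordinates, X, nPerm = nPerm, seed = seed)
    res@method <- "dbrda"
    res
}

## ---- forward selection ----------------------------------------------------

#' Greedy forward selection of constraints
#'
#' At each step every remaining candidate column is added to the current
#' model; the one with the largest added R2 (ties broken by label) is tested
#' by a conditional permutation test — the candidate's residuals off the
#' current model are permuted — and admitted if p < \code{alpha}. Selection
#' stops when no candidate qualifies. This is the "forward selection
#' (p < 0.1)" rule used to pick the final explanatory set of each RDA/dbRDA
#' model.
#'
#' @param response response matrix, or a distance matrix (detected by
#'   symmetry and zero diagonal, or forced with \code{isDistance}), in which
#'   case its principal coordinates are used.
#' @param candidates matrix/data.frame of candidate explanatory columns.
#' @param alpha admission threshold (default 0.1).
#' @param nPerm permutations per conditional test (default 999).
#' @param seed RNG seed.
#' @param isDistance override distance detection (logical or NULL).
#' @param negativePolicy PCoA policy when the response is a distance matrix.
#' @return A \code{\linkS4class{ForwardSelectionResult}}; when nothing
#'   qualifies the steps table records the best rejected candidate.
#' @export
forwardSelect <- function(response, candidates, alpha = 0.1, nPerm = 999,
                          seed = 1, isDistance = NULL,
                          negativePolicy = "drop") {
    stopifnot(alpha > 0, alpha < 1)
    candidates <- asNumericMatrix(candidates)
    if (is.null(isDistance))
        isDistance <- is.matrix(response) && nrow(response) == ncol(response) &&
            max(abs(response - t(response))) < 1e-8 &&
            all(abs(diag(response)) < 1e-8)
    if (isDistance) {
        if (!is.null(rownames(response)) && !is.null(rownames(candidates)))
            candidates <- candidates[rownames(response), , drop = FALSE]
        Y <- pcoaFit(response, negativePolicy)$coordinates
    } else Y <- asNumericMatrix(response)
    n <- nrow(Y)
    Yc <- centerCols(Y)
    ssY <- sum(Yc^2)
    set.seed(as.integer(seed))
    remaining <- colnames(candidates)
    selected <- character(0)
    r2cur <- 0
    steps <- data.frame(label = character(), added_R2 = numeric(),
                        cum_R2 = numeric(), cum_adjR2 = numeric(),
                        p = numeric(), selected = logical())
    r2of <- function(cols) {
        if (length(cols) == 0L) return(0)
        projectionR2(Yc, centerCols(candidates[, cols, drop = FALSE]),
                     ssY)$r2
    }
    repeat {
        if (length(remaining) == 0L) break
        if (n <= length(selected) + 2L) break    # no residual df left
        r2s <- vapply(remaining, function(lb) r2of(c(selected, lb)), 0)
        best <- remaining[order(-(r2s - r2cur), remaining)][1L]
        addedObs <- r2s[best] - r2cur
        ## conditional permutation: permute the candidate's residuals off
        ## the current model
        x <- candidates[, best]
        xc <- x - mean(x)
        if (length(selected)) {
            qcur <- qr(centerCols(candidates[, selected, drop = FALSE]))
            resid <- qr.resid(qcur, xc)
        } else resid <- xc
        if (sum(resid^2) < 1e-12 * max(sum(xc^2), 1e-300)) {
            ## candidate collinear with current model: cannot be tested
            steps <- rbind(steps, data.frame(
                label = best, added_R2 = addedObs, cum_R2 = r2s[best],
                cum_adjR2 = NA_real_, p = NA_real_, selected = FALSE))
            break
        }
        base <- if (length(selected))
            qr.fitted(qcur, xc) else rep(0, n)
        ge <- 0L
        for (b in seq_len(nPerm)) {
            xp <- base + resid[sample.int(n)]
            Xp <- if (length(selected))
                cbind(centerCols(candidates[, selected, drop = FALSE]),
                      xp - mean(xp))
            else matrix(xp - mean(xp), ncol = 1L)
            addedPerm <- projectionR2(Yc, Xp, ssY)$r2 - r2cur
            if (addedPerm >= addedObs) ge <- ge + 1L
        }
        p <- (1 + ge) / (1 + nPerm)
        m <- length(selected) + 1L
        adj <- 1 - (1 - r2s[best]) * (n - 1) / (n - m - 1)
        ok <- p < alpha
        steps <- rbind(steps, data.frame(
            label = best, added_R2 = addedObs, cum_R2 = r2s[best],
            cum_adjR2 = adj, p = p, selected = ok))
        if (!ok) break
        selected <- c(selected, best)
        remaining <- setdiff(remaining, best)
        r2cur <- r2s[best]
    }
    finalModel <- if (length(selected))
        rdaFit(Y, candidates[, selected, drop = FALSE], nPerm = nPerm,
               seed = as.integer(seed) + 1L)
    else NULL
    if (!is.null(finalModel) && isDistance) finalModel@method <- "dbrda"
    new("ForwardSelectionResult", selected = selected, steps = steps,
        finalModel = finalModel)
}

setMethod("show", "ForwardSelectionResult", function(object) {
    cat(sprintf("ForwardSelectionResult: %d selected [%s]\n",
                length(object@selected),
                paste(object@selected, collapse = ", ")))
    if (nrow(object@steps)) print(object@steps)
})
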