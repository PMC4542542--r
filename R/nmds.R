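## Kruskal stress-1 of a configuration against dissimilarities delta:
## disparities are the isotonic (PAVA) fit of the configuration distances on
## the rank order of delta, ties handled by the primary approach (within a
## tie block of delta, points are taken in order of the current distances,
## so the fit is free to follow them).
configStress <- function(delta, dvec) {
    ord <- order(delta, dvec)
    dhat <- numeric(length(dvec))
    dhat[ord] <- stats::isoreg(dvec[ord])$yf
    ss <- sum(dvec^2)
    if (ss == 0) return(list(stress = 1, dhat = dhat))
    list(stress = sqrt(sum((dvec - dhat)^2) / ss), dhat = dhat)
}

lowerVec <- function(m) m[lower.tri(m)]

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1,
#' sqrt(sum((d - dhat)^2) / sum(d^2)), where d are configuration distances
#' and dhat their monotone (isotonic) regression on the input
#' dissimilarities, by alternating the PAVA monotone-regression step with a
#' Guttman-transform (iterative majorization) configuration update. One
#' start uses the principal coordinates of the dissimilarities; the rest are
#' random. The lowest-stress solution is returned, centred and rotated to
#' its principal axes. Stress is scale-invariant, and with enough starts is
#' non-increasing in the dimension k.
#'
#' @param d dissimilarity matrix (symmetric, zero diagonal).
#' @param k target dimension (default 2); needs n >= k + 1.
#' @param nStarts number of starts (default 20; the first is the PCoA
#'   configuration).
#' @param maxIter iteration cap per start (default 300).
#' @param tol convergence: absolute stress change below this (default 1e-6).
#' @param seed RNG seed for the random starts.
#' @return An \code{\linkS4class{NmdsResult}}.
#' @examples
#' x <- matrix(rnorm(20), 10)
#' fit <- nmdsFit(as.matrix(dist(x)), k = 2, nStarts = 3)
#' fit@stress   # ~0: Euclidean input is perfectly representable
#' @export
nmdsFit <- function(d, k = 2, nStarts = 20, maxIter = 300, tol = 1e-6,
                    seed = 1) {
    d <- checkDistanceMatrix(d)
    n <- nrow(d)
    if (k < 1) stop("k must be >= 1", call. = FALSE)
    if (n < k + 1) stop("need at least k + 1 points", call. = FALSE)
    delta <- lowerVec(d)
    if (all(delta == 0))
        stop("all dissimilarities are zero", call. = FALSE)
    set.seed(as.integer(seed))
    starts <- vector("list", nStarts)
    pc <- tryCatch(pcoaFit(d, "drop")$coordinates, error = function(e) NULL)
    if (!is.null(pc)) {
        X0 <- matrix(0, n, k)
        take <- min(k, ncol(pc))
        X0[, seq_len(take)] <- pc[, seq_len(take)]
        if (take < k)
            X0[, (take + 1L):k] <- rnorm(n * (k - take), 0, 1e-4)
        starts[[1L]] <- X0
    } else starts[[1L]] <- matrix(rnorm(n * k), n, k)
    for (s in seq_len(nStarts)[-1L])
        starts[[s]] <- matrix(rnorm(n * k), n, k)
    best <- NULL
    for (s in seq_len(nStarts)) {
        X <- starts[[s]]
        stressPrev <- Inf
        converged <- FALSE
        res <- NULL
        for (it in seq_len(maxIter)) {
            dvec <- lowerVec(as.matrix(dist(X)))
            res <- configStress(delta, dvec)
            if (abs(stressPrev - res$stress) < tol) {
                converged <- TRUE
                break
            }
            stressPrev <- res$stress
            ## Guttman transform with weights 1
            Dm <- matrix(0, n, n)
            Dm[lower.tri(Dm)] <- dvec
            Dm <- Dm + t(Dm)
            Dh <- matrix(0, n, n)
            Dh[lower.tri(Dh)] <- res$dhat
            Dh <- Dh + t(Dh)
            ratio <- matrix(0, n, n)
            nz <- Dm > 0
            ratio[nz] <- Dh[nz] / Dm[nz]
            B <- -ratio
            diag(B) <- rowSums(ratio)
            X <- B %*% X / n
        }
        if (is.null(best) || res$stress < best$stress)
            best <- list(stress = res$stress, X = X, start = s,
                         converged = converged)
    }
    X <- scale(best$X, center = TRUE, scale = FALSE)
    sv <- svd(X)
    X <- sv$u %*% diag(sv$d, length(sv$d))
    rownames(X) <- rownames(d)
    colnames(X) <- sprintf("NMDS%d", seq_len(ncol(X)))
    if (!best$converged)
        warning("no NMDS start converged within maxIter; returning the ",
                "lowest-stress configuration", call. = FALSE)
    new("NmdsResult", points = X[, seq_len(k), drop = FALSE],
        stress = best$stress, converged = best$converged,
        nStarts = as.integer(nStarts), bestStart = as.integer(best$start))
}

setMethod("show", "NmdsResult", function(object) {
    cat(sprintf("NmdsResult: %d points in %d dimension(s), stress = %.4f%s\n",
                nrow(object@points), ncol(object@points), object@stress,
                if (object@converged) "" else " (not converged)"))
})
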