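#' Read / write a Newick tree with branch lengths
#'
#' Wrappers around \code{ape::read.tree} / \code{write.tree} that enforce
#' the contract the downstream analyses need: every edge must carry a finite
#' branch length (patristic distances are path sums over branch lengths), so
#' topology-only Newick is rejected.
#'
#' @param x a file path or a Newick string.
#' @return \code{readTree}: an \code{ape} \code{phylo}.
#' @examples
#' tr <- readTree("(A:1,B:2);")
#' writeTree(tr)
#' @export
readTree <- function(x) {
    tr <- tryCatch({
        if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
            ape::read.tree(x)
        else
            ape::read.tree(text = x)
    }, error = function(e)
        stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
       warning = function(w)
        stop("malformed Newick: ", conditionMessage(w), call. = FALSE))
    if (is.null(tr))
        stop("malformed Newick: could not parse input", call. = FALSE)
    if (is.null(tr$edge.length))
        stop("Newick tree has no branch lengths; lengths are required",
             call. = FALSE)
    if (length(tr$edge.length) != nrow(tr$edge) ||
        any(!is.finite(tr$edge.length)))
        stop("Newick tree has missing or non-finite branch lengths",
             call. = FALSE)
    if (anyDuplicated(tr$tip.label))
        stop("duplicate tip labels in tree", call. = FALSE)
    tr
}

#' @rdname readTree
#' @param tree a \code{phylo}.
#' @export
writeTree <- function(tree) ape::write.tree(tree)

#' Patristic distances between tree tips
#'
#' The patristic distance between two tips is the sum of branch lengths
#' along the unique path connecting them; it is the measure of evolutionary
#' relatedness the constrained-ordination analyses are run on. Rooting is
#' irrelevant to path sums, so rooted and unrooted trees give the same
#' matrix.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param tips optional character vector restricting (and ordering) the
#'   matrix to a subset of tips; the result equals the corresponding
#'   sub-matrix of the full matrix.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' patristicDistances(readTree("((A:1,B:1):1,C:3);"))
#' @export
patristicDistances <- function(tree, tips = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths", call. = FALSE)
    d <- ape::cophenetic.phylo(tree)
    if (!is.null(tips)) {
        bad <- setdiff(tips, rownames(d))
        if (length(bad))
            stop("unknown tip label(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        d <- d[tips, tips, drop = FALSE]
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}), provided as plumbing so
#' synthetic pipelines need no external tree-inference software. NJ is
#' consistent on additive matrices: run on exact patristic distances it
#' recovers the generating topology. Negative estimated branch lengths are
#' clamped to zero and flagged.
#'
#' @param d symmetric distance matrix with at least 3 taxa.
#' @return an unrooted \code{phylo}; attribute \code{"clamped"} gives the
#'   number of negative branch lengths set to zero.
#' @export
njTree <- function(d) {
    stopifnot(is.matrix(d))
    if (nrow(d) < 3L)
        stop("neighbor joining needs at least 3 taxa", call. = FALSE)
    if (max(abs(d - t(d))) > 1e-8)
        stop("distance matrix must be symmetric", call. = FALSE)
    tr <- ape::nj(stats::as.dist(d))
    neg <- tr$edge.length < 0
    if (any(neg)) tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- sum(neg)
    tr
}
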