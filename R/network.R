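## Union of all minimum spanning trees, Kruskal-style by weight class:
## an edge of weight w belongs to some MST iff its endpoints lie in
## different components of the graph built from all strictly lighter
## MST-usable edges. Returns edge data.frame with in_mst flag.
allMstEdges <- function(d) {
    n <- nrow(d)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    ed <- data.frame(i = pairs[, 1], j = pairs[, 2],
                     weight = d[pairs])
    ed <- ed[order(ed$weight), , drop = FALSE]
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    inMst <- logical(nrow(ed))
    for (w in unique(ed$weight)) {
        cls <- which(ed$weight == w)
        ## membership decided against components before this weight class
        comp <- vapply(seq_len(n), find, 0L)
        use <- cls[comp[ed$i[cls]] != comp[ed$j[cls]]]
        inMst[use] <- TRUE
        for (k in use) {        # then merge
            ra <- find(ed$i[k]); rb <- find(ed$j[k])
            if (ra != rb) parent[ra] <- rb
        }
    }
    ed$in_mst <- inMst
    ed
}

#' Build a haplotype network with inferred intermediates
#'
#' Minimum-spanning network over the Hamming distances of a set of aligned
#' haplotypes: the union of all minimum spanning trees, plus every edge not
#' longer than the longest MST edge plus \code{epsilon}. Edges spanning
#' d > 1 substitutions are expanded into chains of d - 1 inferred
#' ("missing") haplotype nodes so that every drawn edge is a single
#' substitution step.
#'
#' @param lineages a \code{\linkS4class{LineageSet}}.
#' @param epsilon relaxation beyond the longest MST edge (default 0).
#' @param sitePolicy passed to \code{\link{hammingMatrix}}.
#' @return A \code{\linkS4class{HaplotypeNetwork}} (connected by
#'   construction; a single lineage gives a single-node network).
#' @examples
#' buildHaplotypeNetwork(LineageSet(c(h1 = "AA", h2 = "AC", h3 = "CC")))
#' @export
buildHaplotypeNetwork <- function(lineages, epsilon = 0,
                                  sitePolicy = "skip_ambiguous") {
    stopifnot(is(lineages, "LineageSet"), epsilon >= 0)
    ids <- lineageIds(lineages)
    n <- length(ids)
    if (n == 1L)
        return(new("HaplotypeNetwork",
                   nodes = data.frame(id = ids, observed = TRUE),
                   edges = data.frame(from = character(),
                                      to = character()),
                   haplotypeEdges = data.frame(from = character(),
                                               to = character(),
                                               weight = integer(),
                                               in_mst = logical()),
                   annotations = NULL, annotationMode = character(0)))
    d <- hammingMatrix(lineages, sitePolicy)
    ed <- allMstEdges(d)
    maxUsed <- max(ed$weight[ed$in_mst])
    keep <- ed$in_mst | ed$weight <= maxUsed + epsilon
    hapEdges <- data.frame(from = ids[ed$i[keep]], to = ids[ed$j[keep]],
                           weight = as.integer(ed$weight[keep]),
                           in_mst = ed$in_mst[keep], row.names = NULL)
    ## expand multi-step edges through inferred intermediates
    nodes <- data.frame(id = ids, observed = TRUE)
    from <- character(); to <- character()
    for (k in seq_len(nrow(hapEdges))) {
        a <- hapEdges$from[k]; b <- hapEdges$to[k]
        w <- hapEdges$weight[k]
        if (w <= 1L) {
            from <- c(from, a); to <- c(to, b)
        } else {
            mids <- sprintf("med_%s_%s_%d", a, b, seq_len(w - 1L))
            nodes <- rbind(nodes,
                           data.frame(id = mids, observed = FALSE))
            chain <- c(a, mids, b)
            from <- c(from, chain[-length(chain)])
            to <- c(to, chain[-1L])
        }
    }
    new("HaplotypeNetwork", nodes = nodes,
        edges = data.frame(from = from, to = to),
        haplotypeEdges = hapEdges, annotations = NULL,
        annotationMode = character(0))
}

#' @rdname HaplotypeNetwork-class
#' @export
setMethod("networkNodes", "HaplotypeNetwork", function(x) x@nodes)

#' @rdname HaplotypeNetwork-class
#' @export
setMethod("networkEdges", "HaplotypeNetwork", function(x) x@edges)

setMethod("show", "HaplotypeNetwork", function(object) {
    cat(sprintf(paste0("HaplotypeNetwork: %d observed + %d inferred nodes, ",
                       "%d unit edges%s\n"),
                sum(object@nodes$observed), sum(!object@nodes$observed),
                nrow(object@edges),
                if (length(object@annotationMode))
                    paste0(" (annotated: ", object@annotationMode, ")")
                else ""))
})

#' Annotate a haplotype network
#'
#' Attaches per-node occurrence context: either the proportions of each
#' observed haplotype across the categories (vegetation types), normalised
#' to sum to one per node, or the scalar \emph{Larix} pollen affinity.
#' Inferred nodes carry no annotation.
#'
#' @param network a \code{\linkS4class{HaplotypeNetwork}}.
#' @param occurrence binary lineage x sample matrix covering all observed
#'   nodes.
#' @param sampleTable sample metadata (category column, or
#'   \code{larix_pct}).
#' @param mode "category_proportions" or "larix_affinity".
#' @param categoryColumn category column used in proportions mode.
#' @return the network with its \code{annotations} slot filled.
#' @export
annotateNetwork <- function(network, occurrence, sampleTable,
                            mode = c("category_proportions",
                                     "larix_affinity"),
                            categoryColumn = "vegetation") {
    mode <- match.arg(mode)
    stopifnot(is(network, "HaplotypeNetwork"))
    obs <- network@nodes$id[network@nodes$observed]
    missing <- setdiff(obs, rownames(occurrence))
    if (length(missing))
        stop("lineage(s) missing from occurrence matrix: ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (mode == "category_proportions") {
        aff <- categoryAffinity(occurrence[obs, , drop = FALSE],
                                sampleTable, categoryColumn)
        v <- affinityValues(aff)
        rs <- rowSums(v)
        prop <- v
        prop[rs > 0, ] <- v[rs > 0, , drop = FALSE] / rs[rs > 0]
        ann <- as.data.frame(prop)
    } else {
        la <- larixAffinity(occurrence[obs, , drop = FALSE], sampleTable)
        ann <- data.frame(larix_affinity = la[obs], row.names = obs)
    }
    network@annotations <- ann
    network@annotationMode <- mode
    network
}

#' Export a haplotype network as TSV
#'
#' Writes \code{nodes.tsv} (id, observed flag, annotation columns when
#' present) and \code{edges.tsv} (from, to) to a directory.
#'
#' @param network a \code{HaplotypeNetwork}.
#' @param dir output directory.
#' @export
writeNetwork <- function(network, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    nodes <- network@nodes
    if (!is.null(network@annotations)) {
        ann <- network@annotations
        idx <- match(nodes$id, rownames(ann))
        nodes <- cbind(nodes, ann[idx, , drop = FALSE])
        rownames(nodes) <- NULL
    }
    write.table(nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(network@edges, file.path(dir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
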