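## Shared fixture builders. Everything is generated in code; no data files.

randomLineageSet <- function(n, L, seed, label = "random") {
    set.seed(seed)
    repeat {
        sq <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), "")
        if (!anyDuplicated(sq)) break
    }
    LineageSet(setNames(sq, sprintf("lin_%02d", seq_len(n))), label)
}

## brute-force Hamming distance over comparable sites (independent of the
## vectorised implementation)
bruteHamming <- function(a, b, skipAmbiguous = TRUE) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    d <- 0L
    for (k in seq_along(ca)) {
        if (skipAmbiguous &&
            !(ca[k] %in% c("A", "C", "G", "T") &&
              cb[k] %in% c("A", "C", "G", "T"))) next
        if (ca[k] != cb[k]) d <- d + 1L
    }
    d
}

## shortest-path patristic oracle over the tree graph
igraphPatristic <- function(tree) {
    g <- igraph::graph_from_data_frame(
        data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
        directed = FALSE)
    w <- tree$edge.length
    nt <- length(tree$tip.label)
    ids <- as.character(seq_len(nt))
    d <- igraph::distances(g, v = ids, to = ids, weights = w)
    dimnames(d) <- list(tree$tip.label, tree$tip.label)
    d
}

## a small lake table matching the default simulated layout
toySampleTable <- function() {
    data.frame(sample = paste0("s", 1:8),
               transect = rep(c("T1", "T2"), each = 4),
               vegetation = rep(c("tundra", "taiga"), 4),
               larix_pct = c(1, 2, 3, 4, 5, 6, 7, 8))
}
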