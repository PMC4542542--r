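#' Build a simulation configuration
#'
#' See \code{\linkS4class{SimulationConfig}} for the meaning of every field.
#' All generators are pure functions of (config, seed): rerunning with the
#' same values gives bit-identical output.
#'
#' @param nLineages,seqLength,nTransects,nVegetationTypes,nLakes,nCoreSamples
#'   design sizes; defaults 14, 67, 3, 4, 21, 20.
#' @param mutationRate substitutions per site per unit branch length
#'   (default 0.015, tuned to give a few percent pairwise divergence on a
#'   unit-rate Yule tree, the level seen between closely related
#'   \emph{Staurosira} fragments).
#' @param nicheSignal phylogenetic-signal weight of the niche trait in
#'   [0, 1] (default 0.85); see \code{\linkS4class{SimulationConfig}}.
#' @param occupancyBaseline,nicheWidth Gaussian niche occupancy parameters;
#'   defaults 0.9 and 0.5 are the strong-signal preset.
#' @param cloneCount,cloneErrorRate,nPcrReplicates clone-library parameters
#'   (defaults 20 clones, 0.002 errors/site, 2 independent PCRs).
#' @param larixStart,larixEnd,larixNoiseSd declining core pollen curve
#'   (defaults 6 percent -> 1 percent with SD 0.5 noise, clipped at 0).
#' @param scenario "environment" (occupancy structured by vegetation type),
#'   "geography" (by transect) or "null" (unstructured).
#' @param seed integer RNG seed.
#' @return A validated \code{SimulationConfig}.
#' @export
simulationConfig <- function(nLineages = 14, seqLength = 67, nTransects = 3,
                             nVegetationTypes = 4, nLakes = 21,
                             nCoreSamples = 20, mutationRate = 0.015,
                             nicheSignal = 0.85, occupancyBaseline = 0.9,
                             nicheWidth = 0.5, cloneCount = 20,
                             cloneErrorRate = 0.002, nPcrReplicates = 2,
                             larixStart = 6, larixEnd = 1,
                             larixNoiseSd = 0.5,
                             scenario = c("environment", "geography", "null"),
                             seed = 1) {
    scenario <- match.arg(scenario)
    new("SimulationConfig",
        nLineages = as.integer(nLineages), seqLength = as.integer(seqLength),
        nTransects = as.integer(nTransects),
        nVegetationTypes = as.integer(nVegetationTypes),
        nLakes = as.integer(nLakes), nCoreSamples = as.integer(nCoreSamples),
        mutationRate = mutationRate, nicheSignal = nicheSignal,
        occupancyBaseline = occupancyBaseline, nicheWidth = nicheWidth,
        cloneCount = as.integer(cloneCount), cloneErrorRate = cloneErrorRate,
        nPcrReplicates = as.integer(nPcrReplicates), larixStart = larixStart,
        larixEnd = larixEnd, larixNoiseSd = larixNoiseSd,
        scenario = scenario, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d lineages x %d bp, %d lakes ",
                       "(%d transects x %d vegetation types), %d horizons, ",
                       "scenario '%s', seed %d\n"),
                object@nLineages, object@seqLength, object@nLakes,
                object@nTransects, object@nVegetationTypes,
                object@nCoreSamples, object@scenario, object@seed))
})

## ---- tree -----------------------------------------------------------------

#' Simulate an ultrametric Yule lineage tree
#'
#' Pure-birth tree conditioned on the number of tips (via
#' \code{ape::rphylo}, birth rate 1, death rate 0), tips relabelled
#' \code{lineage_01 ...}. Stands in for a Bayesian gene tree of closely
#' related lineages.
#'
#' @param nLineages number of tips (>= 2).
#' @param seed RNG seed.
#' @return an \code{ape} \code{phylo}, ultrametric, branch lengths > 0.
#' @export
simulateTree <- function(nLineages, seed = 1) {
    if (nLineages < 2)
        stop("nLineages must be >= 2", call. = FALSE)
    set.seed(as.integer(seed))
    tr <- ape::rphylo(as.integer(nLineages), birth = 1, death = 0)
    tr$tip.label <- sprintf("lineage_%02d", seq_len(nLineages))
    tr
}

## ---- sequences ------------------------------------------------------------

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' A uniform-random root sequence evolves down the tree; on a branch of
#' length t each site substitutes to a uniformly chosen different base with
#' probability p = 3/4 (1 - exp(-4 mu t / 3)), the Jukes-Cantor transition
#' probability.
#'
#' @param tree \code{phylo} with finite branch lengths.
#' @param seqLength number of sites.
#' @param mutationRate mu, substitutions per site per unit branch length.
#' @param seed RNG seed.
#' @return A \code{\linkS4class{LineageSet}} with one sequence per tip.
#' @export
evolveSequences <- function(tree, seqLength, mutationRate, seed = 1) {
    stopifnot(inherits(tree, "phylo"))
    if (mutationRate < 0)
        stop("mutationRate must be >= 0", call. = FALSE)
    if (seqLength < 1)
        stop("seqLength must be >= 1", call. = FALSE)
    if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
        stop("tree must have finite branch lengths", call. = FALSE)
    set.seed(as.integer(seed))
    bases <- c("A", "C", "G", "T")
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- matrix(NA_integer_, nnode, seqLength)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(4L, seqLength, replace = TRUE)
    ## cladewise edge order lists every parent before its children
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
        t <- tr$edge.length[e]
        p <- 0.75 * (1 - exp(-4 * mutationRate * t / 3))
        s <- seqs[par, ]
        hit <- which(runif(seqLength) < p)
        if (length(hit))
            s[hit] <- (s[hit] + sample.int(3L, length(hit),
                                           replace = TRUE) - 1L) %% 4L + 1L
        seqs[child, ] <- s
    }
    tipSeqs <- vapply(seq_len(ntip),
                      function(i) paste(bases[seqs[i, ]], collapse = ""), "")
    LineageSet(setNames(tipSeqs, tree$tip.label), "simulated")
}

## ---- niche truth ----------------------------------------------------------

brownianTips <- function(tree, variance) {
    ntip <- length(tree$tip.label)
    vals <- numeric(ntip + tree$Nnode)
    vals[ntip + 1L] <- 0
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
        par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
        vals[child] <- vals[par] +
            rnorm(1L, 0, sqrt(variance * tr$edge.length[e]))
    }
    setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Generate the ground truth of a synthetic study
#'
#' Draws the true lineage tree, evolves niche optima along it by Brownian
#' motion (so closely related lineages have similar optima, the pattern the
#' analyses are meant to detect), lays out the lakes (transect blocks, each
#' spanning the ordered vegetation gradient so the two factors are crossed),
#' and fixes the noise-free declining \emph{Larix} curve of the core.
#'
#' Optima are expressed on the category-index scale of the active scenario:
#' centred on the mid category, spread set by the Brownian variance
#' (\code{nicheSignal}).
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return A \code{\linkS4class{ScenarioTruth}}.
#' @export
simulateTruth <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    tree <- simulateTree(config@nLineages, config@seed)
    set.seed(config@seed + 1L)
    ## niche trait: weighted blend of the deterministic leading axis of
    ## patristic divergence (tip scores on the first principal coordinate)
    ## and one standardized Brownian realization on the tree; the weight is
    ## the phylogenetic-signal knob. A pure Brownian draw (weight 0) only
    ## sometimes realizes tree-structured niche similarity, so the
    ## deterministic component is what makes relatedness -> niche
    ## similarity reliably built in.
    z <- brownianTips(tree, 1)
    zb <- (z - mean(z)) / max(sd(z), 1e-12)
    pc1 <- pcoaFit(ape::cophenetic.phylo(tree))$coordinates[, 1L]
    zs <- (pc1 - mean(pc1)) / max(sd(pc1), 1e-12)
    lam <- config@nicheSignal
    trait <- sqrt(lam) * zs[names(z)] + sqrt(1 - lam) * zb
    K <- if (config@scenario == "geography") config@nTransects
         else config@nVegetationTypes
    ## niches live on the bounded gradient: squash the trait onto [1, K]
    ## through a logistic
    optima <- 1 + (K - 1) * stats::plogis(trait)
    nLakes <- config@nLakes
    transect <- sort(rep_len(seq_len(config@nTransects), nLakes))
    perTransect <- tabulate(transect, config@nTransects)
    vegetation <- unlist(lapply(perTransect, function(m)
        rep_len(seq_len(config@nVegetationTypes), m)))
    lakeTable <- data.frame(
        sample = sprintf("lake_%02d", seq_len(nLakes)),
        transect = transect,
        vegetation = vegetation)
    larixCurve <- seq(config@larixStart, config@larixEnd,
                      length.out = config@nCoreSamples)
    new("ScenarioTruth", tree = tree, optima = optima,
        lakeTable = lakeTable, larixCurve = larixCurve,
        scenario = config@scenario)
}

setMethod("show", "ScenarioTruth", function(object) {
    cat(sprintf("ScenarioTruth ('%s'): %d lineages, %d lakes, %d horizons\n",
                object@scenario, length(object@optima),
                nrow(object@lakeTable), length(object@larixCurve)))
})

## ---- occurrences ----------------------------------------------------------

nicheProbability <- function(optimum, category, baseline, width) {
    baseline * exp(-(optimum - category)^2 / (2 * width^2))
}

#' Simulate the lake occurrence matrix
#'
#' Presence/absence of every lineage in every lake. Under the environment
#' scenario the presence probability follows a Gaussian niche over the
#' vegetation-type index; under geography, over the transect index; under
#' null it is a constant baseline. Lineages that end up absent everywhere
#' are redrawn (a lineage never observed cannot enter any analysis), up to
#' \code{maxRetries} times per lineage.
#'
#' @param truth a \code{\linkS4class{ScenarioTruth}}.
#' @param config the matching \code{SimulationConfig}.
#' @param seed RNG seed (default derived from the config).
#' @param maxRetries bound on per-lineage redraws (default 100).
#' @return binary integer matrix, lineages x lakes.
#' @export
simulateOccurrences <- function(truth, config, seed = config@seed + 2L,
                                maxRetries = 100L) {
    stopifnot(is(truth, "ScenarioTruth"), is(config, "SimulationConfig"))
    set.seed(as.integer(seed))
    lakes <- truth@lakeTable
    category <- switch(config@scenario,
                       environment = lakes$vegetation,
                       geography = lakes$transect,
                       null = NULL)
    n <- length(truth@optima); m <- nrow(lakes)
    occ <- matrix(0L, n, m,
                  dimnames = list(names(truth@optima), lakes$sample))
    for (i in seq_len(n)) {
        p <- if (config@scenario == "null")
            rep(config@occupancyBaseline, m)
        else nicheProbability(truth@optima[i], category,
                              config@occupancyBaseline, config@nicheWidth)
        row <- rbinom(m, 1L, p)
        tries <- 0L
        while (sum(row) == 0L && tries < maxRetries) {
            row <- rbinom(m, 1L, p)
            tries <- tries + 1L
        }
        if (sum(row) == 0L)
            stop("simulation failure: lineage ", names(truth@optima)[i],
                 " absent from all lakes after ", maxRetries,
                 " retries (max presence probability ",
                 signif(max(p), 3), ")", call. = FALSE)
        occ[i, ] <- row
    }
    occ
}

#' Simulate the sediment core
#'
#' A monotone depth/age grid with a declining noisy \emph{Larix} pollen
#' curve, and lineage presence per horizon from the same Gaussian niche rule
#' with \emph{Larix} percent as the environmental axis (lineage optima are
#' rescaled from the category-index scale onto the observed \emph{Larix}
#' range; the niche width is rescaled by the same factor). Horizons with no
#' lineages are allowed and kept as all-zero columns.
#'
#' @param truth a \code{\linkS4class{ScenarioTruth}}.
#' @param config the matching \code{SimulationConfig}.
#' @param seed RNG seed (default derived from the config).
#' @return list with \code{occurrence} (lineages x horizons binary matrix)
#'   and \code{sampleTable} (\code{sample}, \code{depth_cm},
#'   \code{age_calBP}, \code{larix_pct}).
#' @export
simulateCore <- function(truth, config, seed = config@seed + 3L) {
    stopifnot(is(truth, "ScenarioTruth"), is(config, "SimulationConfig"))
    set.seed(as.integer(seed))
    nh <- config@nCoreSamples
    depth <- seq(2, 132, length.out = nh)
    age <- depth * 7000 / 132          # ~0.019 cm/yr, mid-Holocene core
    larix <- rev(truth@larixCurve)     # oldest (deepest) horizons highest
    larix <- pmax(0, larix + rnorm(nh, 0, config@larixNoiseSd))
    st <- data.frame(sample = sprintf("horizon_%02d", seq_len(nh)),
                     depth_cm = depth, age_calBP = age, larix_pct = larix)
    ## map optima from category-index scale onto the larix axis
    K <- if (truth@scenario == "geography") config@nTransects
         else config@nVegetationTypes
    lr <- range(larix)
    scale <- if (diff(lr) > 0) diff(lr) / (K - 1) else 1
    optL <- lr[1] + (truth@optima - 1) * scale
    widthL <- config@nicheWidth * scale
    n <- length(optL)
    occ <- matrix(0L, n, nh,
                  dimnames = list(names(truth@optima), st$sample))
    for (i in seq_len(n)) {
        p <- if (config@scenario == "null")
            rep(config@occupancyBaseline, nh)
        else nicheProbability(optL[i], larix, config@occupancyBaseline,
                              widthL)
        occ[i, ] <- rbinom(nh, 1L, p)
    }
    list(occurrence = occ, sampleTable = st)
}

## ---- clone libraries ------------------------------------------------------

#' Simulate a clone library with polymerase errors
#'
#' Each clone is the template with every site independently substituted to a
#' uniformly chosen different base with probability \code{cloneErrorRate}.
#' Clones are tagged with a PCR-replicate id, round-robin over
#' \code{nPcr} independent PCRs, so the authenticity filter can be exercised
#' on data with known ground truth.
#'
#' @param template template sequence (character or \code{DNAString}).
#' @param cloneCount number of clones (>= 1).
#' @param cloneErrorRate per-site error probability in [0, 1).
#' @param seed RNG seed.
#' @param nPcr number of independent PCRs (default 2).
#' @param sampleId sample id for the returned library.
#' @return A \code{\linkS4class{CloneLibrary}}.
#' @export
simulateCloneLibrary <- function(template, cloneCount, cloneErrorRate,
                                 seed = 1, nPcr = 2, sampleId = "sample_01") {
    if (cloneCount < 1) stop("cloneCount must be >= 1", call. = FALSE)
    if (cloneErrorRate < 0 || cloneErrorRate >= 1)
        stop("cloneErrorRate must be in [0, 1)", call. = FALSE)
    set.seed(as.integer(seed))
    bases <- c("A", "C", "G", "T")
    tpl <- match(strsplit(toupper(as.character(template)), "")[[1]], bases)
    L <- length(tpl)
    clones <- vapply(seq_len(cloneCount), function(k) {
        s <- tpl
        hit <- which(runif(L) < cloneErrorRate)
        if (length(hit))
            s[hit] <- (s[hit] + sample.int(3L, length(hit),
                                           replace = TRUE) - 1L) %% 4L + 1L
        paste(bases[s], collapse = "")
    }, "")
    names(clones) <- sprintf("%s_clone_%03d", sampleId, seq_len(cloneCount))
    pcr <- sprintf("pcr_%d", rep_len(seq_len(nPcr), cloneCount))
    CloneLibrary(clones, sampleId, pcr)
}

## ---- full dataset ---------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing everything the spatial and temporal
#' analyses consume: truth, tree, aligned lineage sequences, the lake
#' occurrence matrix with its sample table, and the core occurrence matrix
#' with its horizon table.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return list with elements \code{truth}, \code{tree}, \code{lineages},
#'   \code{occurrence}, \code{sampleTable}, \code{core} (list of
#'   \code{occurrence}, \code{sampleTable}).
#' @examples
#' sim <- simulateDataset(simulationConfig(seed = 7))
#' dim(sim$occurrence)
#' @export
simulateDataset <- function(config = simulationConfig()) {
    truth <- simulateTruth(config)
    lineages <- evolveSequences(truth@tree, config@seqLength,
                                config@mutationRate, config@seed + 4L)
    occ <- simulateOccurrences(truth, config)
    core <- simulateCore(truth, config)
    veg <- c("arctic_tundra", "single_tree_tundra", "forest_tundra",
             "light_northern_taiga")
    st <- truth@lakeTable
    st$vegetation_label <- if (config@nVegetationTypes == 4L)
        veg[st$vegetation] else sprintf("veg_%d", st$vegetation)
    st$transect_label <- sprintf("transect_%d", st$transect)
    list(truth = truth, tree = truth@tree, lineages = lineages,
         occurrence = occ, sampleTable = st, core = core)
}

#' Write a synthetic study to disk
#'
#' Writes the FASTA, Newick and TSV files (occurrence matrices, sample
#' tables, truth table) of a simulated dataset into a directory.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeDataset <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLineageFasta(sim$lineages, file.path(dir, "lineages.fasta"))
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
    writeOccurrenceMatrix(sim$occurrence, file.path(dir, "occurrence.tsv"))
    write.table(sim$sampleTable, file.path(dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeOccurrenceMatrix(sim$core$occurrence,
                          file.path(dir, "core_occurrence.tsv"))
    write.table(sim$core$sampleTable, file.path(dir, "core_samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truthTab <- data.frame(lineage = names(sim$truth@optima),
                           optimum = unname(sim$truth@optima),
                           scenario = sim$truth@scenario)
    write.table(truthTab, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}
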