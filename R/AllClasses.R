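#' @import methods
#' @importFrom stats dist quantile rnorm runif rbinom setNames sd cor
#' @importFrom utils read.delim write.table combn head
NULL

#' Aligned lineage sequences
#'
#' A \code{LineageSet} holds the aligned, equal-length nucleotide sequences of
#' a set of verified sedimentary-DNA lineages (e.g. the 67-bp or 191-bp
#' \emph{rbcL} fragments of closely related \emph{Staurosira} lineages). It is
#' the unit all distance, network and affinity computations operate on.
#'
#' Sequences are stored as a \link[Biostrings]{DNAStringSet}; ids are the
#' element names and must be unique. Equal width is enforced; sequence
#' distinctness is not (trimming a longer fragment can create duplicates,
#' which \code{\link{collapseIdentical}} removes).
#'
#' @slot seqs A \code{DNAStringSet} of equal-width sequences with unique names.
#' @slot fragmentLabel Single string naming the fragment (e.g. "rbcL_67").
#' @export
setClass("LineageSet",
    representation(seqs = "DNAStringSet", fragmentLabel = "character"))

setValidity("LineageSet", function(object) {
    s <- object@seqs
    if (length(s) == 0L)
        return("LineageSet must contain at least one sequence")
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
        return("sequence ids must be present and unique")
    if (length(unique(Biostrings::width(s))) != 1L)
        return("all sequences must have equal length (aligned fragments)")
    if (length(object@fragmentLabel) != 1L)
        return("fragmentLabel must be a single string")
    TRUE
})

#' Clone library from a single sample
#'
#' Raw cloned PCR products from one sediment sample, before dereplication.
#' Each clone carries the id of the independent PCR replicate it came from;
#' the authenticity filter (\code{\link{verifySequenceTypes}}) uses these tags
#' to require observation in more than one PCR.
#'
#' @slot seqs A \code{DNAStringSet} of clone reads (equal width).
#' @slot sampleId Single string; the sample all clones share.
#' @slot pcrId Character vector parallel to \code{seqs}: PCR replicate ids.
#' @export
setClass("CloneLibrary",
    representation(seqs = "DNAStringSet", sampleId = "character",
                   pcrId = "character"))

setValidity("CloneLibrary", function(object) {
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    if (length(object@pcrId) != length(object@seqs))
        return("pcrId must have one entry per clone")
    if (length(object@seqs) > 0L &&
        length(unique(Biostrings::width(object@seqs))) != 1L)
        return("clone sequences must have equal length")
    TRUE
})

#' Dereplicated sequence types
#'
#' One row per distinct clone sequence, with tallies used by the
#' authenticity filter: total clone count, number of samples, and number of
#' independent PCRs the type was observed in. Rows are ordered by
#' descending clone count, ties broken by sequence lexicographic order.
#'
#' @slot table data.frame with columns \code{id}, \code{sequence},
#'   \code{clone_count}, \code{n_samples}, \code{n_pcrs}.
#' @export
setClass("SequenceTypeSet", representation(table = "data.frame"))

setValidity("SequenceTypeSet", function(object) {
    tb <- object@table
    need <- c("id", "sequence", "clone_count", "n_samples", "n_pcrs")
    if (!all(need %in% names(tb)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    if (nrow(tb) > 0L && any(tb$clone_count < 1L))
        return("clone_count must be >= 1")
    if (anyDuplicated(tb$sequence))
        return("sequences must be unique within a SequenceTypeSet")
    TRUE
})

#' Per-lineage category affinities
#'
#' Occupancy-based affinity of each lineage for each category (transect or
#' vegetation type): the proportion of samples of that category in which the
#' lineage occurs. Dividing by the category size is what corrects for
#' unequal numbers of lakes per transect / vegetation type.
#'
#' @slot values numeric matrix, lineages x categories, entries in [0, 1].
#' @slot categorySizes integer vector of samples per category.
#' @slot normalized logical; TRUE if rows were rescaled to sum to one.
#' @export
setClass("AffinityTable",
    representation(values = "matrix", categorySizes = "integer",
                   normalized = "logical"))

setValidity("AffinityTable", function(object) {
    v <- object@values
    if (length(object@categorySizes) != ncol(v))
        return("one category size per column required")
    if (any(object@categorySizes < 1L))
        return("category sizes must be >= 1")
    if (any(v < -1e-12 | v > 1 + 1e-12))
        return("affinities must lie in [0, 1]")
    TRUE
})

#' Haplotype network with inferred intermediates
#'
#' Minimum-spanning network over a set of aligned haplotypes. All edges that
#' belong to some minimum spanning tree of the Hamming distance matrix are
#' kept (plus optionally slightly longer ones); multi-step edges are expanded
#' into chains of single-substitution steps through inferred (unobserved)
#' intermediate nodes, the "missing haplotypes" drawn as dots in published
#' networks.
#'
#' @slot nodes data.frame with columns \code{id}, \code{observed}.
#' @slot edges data.frame with columns \code{from}, \code{to}; every edge is
#'   one substitution step.
#' @slot haplotypeEdges data.frame of the pre-expansion lineage-to-lineage
#'   edges: \code{from}, \code{to}, \code{weight}, \code{in_mst}.
#' @slot annotations \code{NULL}, or a data.frame of per-observed-node
#'   annotation columns added by \code{\link{annotateNetwork}}.
#' @slot annotationMode character; empty until annotated.
#' @export
setClass("HaplotypeNetwork",
    representation(nodes = "data.frame", edges = "data.frame",
                   haplotypeEdges = "data.frame", annotations = "ANY",
                   annotationMode = "character"))

#' NMDS solution
#'
#' Best configuration over random starts of non-metric multidimensional
#' scaling, with Kruskal stress-1.
#'
#' @slot points numeric matrix (n x k), centred and rotated to principal axes.
#' @slot stress Kruskal stress-1 of the best start, in [0, 1].
#' @slot converged logical; FALSE if no start met the tolerance.
#' @slot nStarts number of starts used.
#' @slot bestStart index of the winning start.
#' @export
setClass("NmdsResult",
    representation(points = "matrix", stress = "numeric",
                   converged = "logical", nStarts = "integer",
                   bestStart = "integer"))

#' Constrained ordination (RDA / dbRDA) result
#'
#' Holds the variance-explained and permutation-test summary of a redundancy
#' analysis or distance-based redundancy analysis: the quantities reported as
#' R2, adjusted R2 and P in the study's result tables.
#'
#' @slot R2 fraction of total inertia explained by the constraints.
#' @slot adjR2 Ezekiel-adjusted R2.
#' @slot pseudoF permutation test statistic.
#' @slot pValue permutation p-value (add-one estimator).
#' @slot nPerm number of permutations.
#' @slot rank rank of the explanatory matrix after centring.
#' @slot nObs number of rows.
#' @slot terms labels of the explanatory columns used.
#' @slot eigConstrained constrained eigenvalues (sums of squares).
#' @slot eigUnconstrained residual eigenvalues.
#' @slot totalInertia total inertia of the response.
#' @slot method "rda" or "dbrda".
#' @export
setClass("ConstrainedOrdination",
    representation(R2 = "numeric", adjR2 = "numeric", pseudoF = "numeric",
                   pValue = "numeric", nPerm = "integer", rank = "integer",
                   nObs = "integer", terms = "character",
                   eigConstrained = "numeric", eigUnconstrained = "numeric",
                   totalInertia = "numeric", method = "character"))

#' Forward-selection result
#'
#' Greedy forward selection of explanatory columns for (db)RDA, each
#' candidate admitted only if its conditional permutation p-value is below
#' \code{alpha}.
#'
#' @slot selected labels of the admitted columns, in selection order.
#' @slot steps data.frame with one row per step actually taken (plus, when
#'   nothing qualified, the best rejected candidate): \code{label},
#'   \code{added_R2}, \code{cum_R2}, \code{cum_adjR2}, \code{p},
#'   \code{selected}.
#' @slot finalModel \code{ConstrainedOrdination} for the selected set, or
#'   \code{NULL} if the selection is empty.
#' @export
setClass("ForwardSelectionResult",
    representation(selected = "character", steps = "data.frame",
                   finalModel = "ANY"))

#' Synthetic-study configuration
#'
#' All knobs of the synthetic sedimentary-DNA generator. Defaults emulate
#' the study design the package targets: 14 closely related lineages of a
#' 67-bp fragment, 21 lakes in 3 transects crossing 4 ordered vegetation
#' types (tundra to taiga), a 20-horizon sediment core with declining
#' \emph{Larix} pollen, and clone libraries with rare polymerase errors.
#' The default niche parameters (\code{nicheWidth} 0.5,
#' \code{occupancyBaseline} 0.9) are the "strong signal" preset.
#'
#' @slot nLineages,seqLength,nTransects,nVegetationTypes,nLakes,nCoreSamples
#'   integer design sizes.
#' @slot mutationRate expected substitutions per site per unit branch length.
#' @slot nicheSignal phylogenetic-signal weight of the niche trait in
#'   [0, 1]: 1 means the trait is fully determined by the leading axis of
#'   patristic divergence, 0 means a single standardized Brownian
#'   realization on the tree.
#' @slot occupancyBaseline maximum presence probability, in [0, 1].
#' @slot nicheWidth Gaussian niche width, in category-index units.
#' @slot cloneCount clones per sample per lineage.
#' @slot cloneErrorRate per-site polymerase error probability, in [0, 1).
#' @slot nPcrReplicates independent PCRs clones are tagged with.
#' @slot larixStart,larixEnd,larixNoiseSd declining core pollen curve: percent
#'   at the oldest and youngest horizon and Gaussian noise SD.
#' @slot scenario one of "environment", "geography", "null".
#' @slot seed integer RNG seed; same config + seed gives identical output.
#' @export
setClass("SimulationConfig",
    representation(nLineages = "integer", seqLength = "integer",
                   nTransects = "integer", nVegetationTypes = "integer",
                   nLakes = "integer", nCoreSamples = "integer",
                   mutationRate = "numeric", nicheSignal = "numeric",
                   occupancyBaseline = "numeric", nicheWidth = "numeric",
                   cloneCount = "integer", cloneErrorRate = "numeric",
                   nPcrReplicates = "integer", larixStart = "numeric",
                   larixEnd = "numeric", larixNoiseSd = "numeric",
                   scenario = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    cnt <- c(nLineages = object@nLineages, nTransects = object@nTransects,
             nVegetationTypes = object@nVegetationTypes,
             nLakes = object@nLakes, nCoreSamples = object@nCoreSamples)
    if (any(cnt < 2L))
        return(paste("counts must all be >= 2; offending:",
                     paste(names(cnt)[cnt < 2L], collapse = ", ")))
    if (object@seqLength < 1L) return("seqLength must be >= 1")
    if (object@mutationRate < 0) return("mutationRate must be >= 0")
    if (object@nicheSignal < 0 || object@nicheSignal > 1)
        return("nicheSignal must be in [0, 1]")
    if (object@occupancyBaseline < 0 || object@occupancyBaseline > 1)
        return("occupancyBaseline must be in [0, 1]")
    if (object@nicheWidth <= 0) return("nicheWidth must be > 0")
    if (object@cloneCount < 1L) return("cloneCount must be >= 1")
    if (object@cloneErrorRate < 0 || object@cloneErrorRate >= 1)
        return("cloneErrorRate must be in [0, 1)")
    if (!object@scenario %in% c("environment", "geography", "null"))
        return("scenario must be environment, geography or null")
    TRUE
})

#' Ground truth of a simulated study
#'
#' Retained alongside generator output so parameter-recovery tests can
#' compare inferred affinities and relatedness patterns with the truth.
#'
#' @slot tree the true ultrametric lineage tree (\code{ape} phylo).
#' @slot optima named numeric; niche optimum per lineage on the
#'   category-index scale of the active scenario.
#' @slot lakeTable data.frame: \code{sample}, \code{transect},
#'   \code{vegetation} (ordered category index and label).
#' @slot larixCurve numeric; noise-free \emph{Larix} percent per core horizon.
#' @slot scenario character; the scenario the truth was generated under.
#' @export
setClass("ScenarioTruth",
    representation(tree = "ANY", optima = "numeric", lakeTable = "data.frame",
                   larixCurve = "numeric", scenario = "character"))
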