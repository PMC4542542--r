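#' Construct a CloneLibrary
#'
#' @param seqs named character vector or \code{DNAStringSet} of clone reads.
#' @param sampleId the sample the clones come from.
#' @param pcrId character vector of PCR replicate ids, one per clone.
#' @return A \code{\linkS4class{CloneLibrary}}.
#' @export
CloneLibrary <- function(seqs, sampleId, pcrId) {
    if (is.character(seqs)) {
        if (is.null(names(seqs)))
            names(seqs) <- sprintf("%s_clone_%03d", sampleId,
                                   seq_along(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    }
    new("CloneLibrary", seqs = seqs, sampleId = sampleId,
        pcrId = as.character(pcrId))
}

setMethod("show", "CloneLibrary", function(object) {
    cat(sprintf("CloneLibrary '%s': %d clones from %d PCR replicate(s)\n",
                object@sampleId, length(object@seqs),
                length(unique(object@pcrId))))
})

setMethod("length", "CloneLibrary", function(x) length(x@seqs))

#' @rdname SequenceTypeSet-class
#' @param x a \code{SequenceTypeSet}.
#' @export
typeTable <- function(x) x@table

setMethod("show", "SequenceTypeSet", function(object) {
    cat(sprintf("SequenceTypeSet: %d types, %d clones total\n",
                nrow(object@table), sum(object@table$clone_count)))
})

#' Dereplicate clone libraries into sequence types
#'
#' Groups identical clone sequences across libraries into sequence types and
#' tallies, per type, the total clone count, the number of samples and the
#' number of independent PCRs in which the type was seen. Type ids are
#' assigned deterministically: descending clone count, ties broken by
#' sequence lexicographic order.
#'
#' @param libraries list of \code{\linkS4class{CloneLibrary}} objects (all
#'   clones equal length, pre-aligned / trimmed).
#' @return A \code{\linkS4class{SequenceTypeSet}}. The sum of clone counts
#'   equals the number of input clones.
#' @export
dereplicateClones <- function(libraries) {
    if (is(libraries, "CloneLibrary")) libraries <- list(libraries)
    stopifnot(all(vapply(libraries, is, TRUE, "CloneLibrary")))
    seqs <- unlist(lapply(libraries, function(l) as.character(l@seqs)),
                   use.names = FALSE)
    if (length(seqs) == 0L)
        return(new("SequenceTypeSet",
                   table = data.frame(id = character(),
                                      sequence = character(),
                                      clone_count = integer(),
                                      n_samples = integer(),
                                      n_pcrs = integer())))
    if (length(unique(nchar(seqs))) != 1L)
        stop("clone sequences must all have equal length", call. = FALSE)
    samp <- unlist(lapply(libraries,
                          function(l) rep(l@sampleId, length(l@seqs))),
                   use.names = FALSE)
    pcr <- unlist(lapply(libraries,
                         function(l) paste(l@sampleId, l@pcrId, sep = "/")),
                  use.names = FALSE)
    uniq <- unique(seqs)
    cnt <- vapply(uniq, function(s) sum(seqs == s), 0L)
    nsamp <- vapply(uniq, function(s) length(unique(samp[seqs == s])), 0L)
    npcr <- vapply(uniq, function(s) length(unique(pcr[seqs == s])), 0L)
    ord <- order(-cnt, uniq)
    tb <- data.frame(id = sprintf("type_%02d", seq_along(uniq)),
                     sequence = uniq[ord], clone_count = cnt[ord],
                     n_samples = nsamp[ord], n_pcrs = npcr[ord],
                     row.names = NULL)
    new("SequenceTypeSet", table = tb)
}

#' Authenticity filter for sequence types
#'
#' Stringent verification step excluding sequence types likely derived from
#' polymerase errors: a type is retained only if it was observed in at least
#' \code{minClones} clones AND in at least \code{minPcrs} independent PCRs.
#' A true template amplified in several PCRs passes; a polymerase error,
#' arising in one molecule of one reaction, is overwhelmingly a singleton
#' and is discarded.
#'
#' @param types a \code{\linkS4class{SequenceTypeSet}}.
#' @param minClones minimum clone count (default 2).
#' @param minPcrs minimum number of independent PCRs (default 2).
#' @param fragmentLabel label and id prefix for the retained lineages.
#' @return list with \code{lineages} (a \code{LineageSet}, retained types
#'   renumbered \code{<prefix>_01 ...}; \code{NULL} if nothing passes) and
#'   \code{discarded} (data.frame \code{type_id}, \code{clone_count},
#'   \code{n_pcrs}, \code{reason}).
#' @export
verifySequenceTypes <- function(types, minClones = 2, minPcrs = 2,
                                fragmentLabel = "lineage") {
    stopifnot(is(types, "SequenceTypeSet"))
    tb <- types@table
    keep <- tb$clone_count >= minClones & tb$n_pcrs >= minPcrs
    reason <- character(nrow(tb))
    reason[tb$clone_count < minClones] <- "too_few_clones"
    reason[tb$n_pcrs < minPcrs] <-
        ifelse(tb$clone_count[tb$n_pcrs < minPcrs] < minClones,
               "too_few_clones_and_pcrs", "too_few_pcrs")
    discarded <- data.frame(type_id = tb$id[!keep],
                            clone_count = tb$clone_count[!keep],
                            n_pcrs = tb$n_pcrs[!keep],
                            reason = reason[!keep], row.names = NULL)
    if (!any(keep))
        return(list(lineages = NULL, discarded = discarded))
    kept <- tb[keep, , drop = FALSE]
    ids <- sprintf("%s_%02d", fragmentLabel, seq_len(nrow(kept)))
    lin <- LineageSet(setNames(kept$sequence, ids), fragmentLabel)
    list(lineages = lin, discarded = discarded)
}

#' Write the discarded-type report
#'
#' @param discarded data.frame from \code{\link{verifySequenceTypes}}.
#' @param path output TSV path.
#' @export
writeDiscardedReport <- function(discarded, path) {
    write.table(discarded, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
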