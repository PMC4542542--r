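#' Construct a LineageSet
#'
#' @param seqs named character vector or \code{DNAStringSet} of aligned,
#'   equal-length sequences; names are the lineage ids.
#' @param fragmentLabel fragment name, e.g. "rbcL_67".
#' @return A \code{\linkS4class{LineageSet}}.
#' @examples
#' ls67 <- LineageSet(c(a = "ACGTACG", b = "ACGTACC"), "toy_7")
#' lineageIds(ls67)
#' @export
LineageSet <- function(seqs, fragmentLabel = "fragment") {
    if (is.character(seqs))
        seqs <- Biostrings::DNAStringSet(seqs)
    new("LineageSet", seqs = seqs, fragmentLabel = fragmentLabel)
}

#' @rdname LineageSet-class
#' @export
setMethod("lineageIds", "LineageSet", function(x) names(x@seqs))

#' @rdname LineageSet-class
#' @export
setMethod("sequences", "LineageSet", function(x) x@seqs)

#' @rdname LineageSet-class
#' @export
setMethod("fragmentLabel", "LineageSet", function(x) x@fragmentLabel)

#' @rdname LineageSet-class
#' @export
setMethod("length", "LineageSet", function(x) length(x@seqs))

#' @rdname LineageSet-class
#' @param i index (numeric, logical or id character) of lineages to keep.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LineageSet", function(x, i, j, ..., drop = FALSE) {
    new("LineageSet", seqs = x@seqs[i], fragmentLabel = x@fragmentLabel)
})

setMethod("show", "LineageSet", function(object) {
    cat(sprintf("LineageSet '%s': %d lineages x %d bp\n",
                object@fragmentLabel, length(object@seqs),
                Biostrings::width(object@seqs)[1]))
    ids <- names(object@seqs)
    cat("  ids:", paste(head(ids, 6L), collapse = ", "),
        if (length(ids) > 6L) "..." else "", "\n")
})

## ---- FASTA I/O ------------------------------------------------------------

#' Read / write aligned lineage FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O with the checks the pipeline
#' relies on: non-empty file, unique ids, IUPAC characters only (lowercase is
#' normalised to uppercase by the DNA alphabet). Reading and writing
#' round-trip exactly, up to line wrapping.
#'
#' @param path file path.
#' @param fragmentLabel label for the returned \code{LineageSet}.
#' @return \code{readLineageFasta}: a \code{LineageSet}.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLineageFasta(LineageSet(c(a = "ACGT", b = "ACGA")), tf)
#' readLineageFasta(tf)
#' @export
readLineageFasta <- function(path, fragmentLabel = "fragment") {
    recs <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                         stop("malformed FASTA '", path, "': ",
                              conditionMessage(e), call. = FALSE))
    if (length(recs) == 0L)
        stop("empty FASTA file: ", path, call. = FALSE)
    ## keep only the first whitespace-delimited token of each header
    names(recs) <- sub("\\s.*$", "", names(recs))
    if (anyDuplicated(names(recs)))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(names(recs)[duplicated(names(recs))]),
                   collapse = ", "), call. = FALSE)
    LineageSet(recs, fragmentLabel)
}

#' @rdname readLineageFasta
#' @param x a \code{LineageSet} (or \code{DNAStringSet}).
#' @export
writeLineageFasta <- function(x, path) {
    if (is(x, "LineageSet")) x <- x@seqs
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

## ---- trimming and collapsing ----------------------------------------------

#' Trim aligned lineages to a sub-fragment window
#'
#' Slices every sequence identically using 0-based half-open coordinates
#' \code{[start, end)}; this is how a longer amplicon set is shortened to the
#' window of a nested shorter amplicon so modern and core lineage sets become
#' comparable.
#'
#' @param x a \code{LineageSet}.
#' @param start,end 0-based half-open window within the alignment.
#' @param fragmentLabel label for the trimmed set.
#' @return A \code{LineageSet} of width \code{end - start}; trimmed sequences
#'   may be duplicated (collapse with \code{\link{collapseIdentical}}).
#' @examples
#' trimToSubfragment(LineageSet(c(a = "ACGTACGT")), 2, 5)
#' @export
trimToSubfragment <- function(x, start, end, fragmentLabel = NULL) {
    stopifnot(is(x, "LineageSet"))
    L <- Biostrings::width(x@seqs)[1]
    if (!(start >= 0 && end > start && end <= L))
        stop("window [", start, ", ", end, ") out of range for length ", L,
             call. = FALSE)
    if (is.null(fragmentLabel))
        fragmentLabel <- sprintf("%s[%d,%d)", x@fragmentLabel, start, end)
    new("LineageSet",
        seqs = Biostrings::subseq(x@seqs, start + 1L, end),
        fragmentLabel = fragmentLabel)
}

#' Collapse identical sequences
#'
#' Reduces a \code{LineageSet} to its distinct sequences (e.g. the 23-to-14
#' reduction that trimming a longer fragment to a shorter window induces).
#' The first occurrence's id names each collapsed lineage; the returned
#' mapping is total and surjective.
#'
#' @param x a \code{LineageSet}.
#' @return list with \code{lineages} (distinct \code{LineageSet}, first-
#'   occurrence order) and \code{mapping} (named character, old id -> new id).
#' @examples
#' collapseIdentical(LineageSet(c(s1 = "AAA", s2 = "AAA", s3 = "AAC")))
#' @export
collapseIdentical <- function(x) {
    stopifnot(is(x, "LineageSet"))
    sq <- as.character(x@seqs)
    keep <- !duplicated(sq)
    newIds <- names(sq)[keep][match(sq, sq[keep])]
    mapping <- setNames(newIds, names(sq))
    list(lineages = new("LineageSet", seqs = x@seqs[keep],
                        fragmentLabel = x@fragmentLabel),
         mapping = mapping)
}

## ---- Hamming distances ----------------------------------------------------

charMatrix <- function(x) {
    sq <- if (is(x, "LineageSet")) as.character(x@seqs) else x
    do.call(rbind, strsplit(sq, "", fixed = TRUE))
}

#' Uncorrected pairwise nucleotide distances
#'
#' Counts of differing sites between every pair of aligned sequences. Under
#' the default \code{"skip_ambiguous"} policy a site contributes only when
#' both characters are unambiguous bases (A, C, G, T); under \code{"strict"}
#' every site is compared literally.
#'
#' @param x a \code{LineageSet} (or named equal-length character vector).
#' @param sitePolicy "skip_ambiguous" (default) or "strict".
#' @return symmetric integer matrix with zero diagonal, dimnames = ids.
#' @examples
#' hammingMatrix(LineageSet(c(a = "ACGT", b = "ACGA")))
#' @export
hammingMatrix <- function(x, sitePolicy = c("skip_ambiguous", "strict")) {
    sitePolicy <- match.arg(sitePolicy)
    cm <- charMatrix(x)
    n <- nrow(cm)
    ids <- if (is(x, "LineageSet")) lineageIds(x) else names(x)
    d <- matrix(0L, n, n, dimnames = list(ids, ids))
    if (n < 2L) return(d)
    ok <- cm == "A" | cm == "C" | cm == "G" | cm == "T"
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            diff <- cm[i, ] != cm[j, ]
            if (sitePolicy == "skip_ambiguous")
                diff <- diff & ok[i, ] & ok[j, ]
            d[i, j] <- d[j, i] <- sum(diff)
        }
    }
    d
}

#' Summarise pairwise nucleotide distances
#'
#' Mean and maximum over the n(n-1)/2 distinct pairs, as counts and as
#' percentages of the fragment length (reported to one decimal, the
#' convention used when quoting e.g. "3.4 substitutions out of 67").
#'
#' @param d integer distance matrix from \code{\link{hammingMatrix}}.
#' @param L alignment length used as the percentage denominator.
#' @return list with \code{mean_count}, \code{max_count}, \code{mean_pct},
#'   \code{max_pct}.
#' @export
distanceSummary <- function(d, L) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    if (nrow(d) < 2L)
        stop("need at least two lineages to summarise distances",
             call. = FALSE)
    up <- d[upper.tri(d)]
    list(mean_count = round(mean(up), 1),
         max_count  = max(up),
         mean_pct   = round(mean(up) / L * 100, 1),
         max_pct    = round(max(up) / L * 100, 1))
}

#' Match lineages across two sets
#'
#' All cross-set pairs at Hamming distance at most \code{maxMismatch},
#' used to align modern and core lineage sets of the same fragment (shared
#' lineages at distance 0, near-matches at 1-2 nucleotides).
#'
#' @param setA,setB \code{LineageSet}s trimmed to the same fragment length.
#' @param maxMismatch maximum Hamming distance (default 2).
#' @param sitePolicy passed to the site comparison.
#' @return data.frame with columns \code{idA}, \code{idB}, \code{distance},
#'   \code{identical}, sorted by distance then ids.
#' @export
matchLineageSets <- function(setA, setB, maxMismatch = 2,
                             sitePolicy = c("skip_ambiguous", "strict")) {
    sitePolicy <- match.arg(sitePolicy)
    stopifnot(is(setA, "LineageSet"), is(setB, "LineageSet"),
              maxMismatch >= 0)
    if (Biostrings::width(setA@seqs)[1] != Biostrings::width(setB@seqs)[1])
        stop("fragment lengths differ between the two sets", call. = FALSE)
    ca <- charMatrix(setA); cb <- charMatrix(setB)
    oka <- ca == "A" | ca == "C" | ca == "G" | ca == "T"
    okb <- cb == "A" | cb == "C" | cb == "G" | cb == "T"
    out <- list()
    for (i in seq_len(nrow(ca))) {
        for (j in seq_len(nrow(cb))) {
            diff <- ca[i, ] != cb[j, ]
            if (sitePolicy == "skip_ambiguous")
                diff <- diff & oka[i, ] & okb[j, ]
            dd <- sum(diff)
            if (dd <= maxMismatch)
                out[[length(out) + 1L]] <-
                    data.frame(idA = lineageIds(setA)[i],
                               idB = lineageIds(setB)[j],
                               distance = dd, identical = dd == 0L)
        }
    }
    if (length(out) == 0L)
        return(data.frame(idA = character(), idB = character(),
                          distance = integer(), identical = logical()))
    res <- do.call(rbind, out)
    res[order(res$distance, res$idA, res$idB), , drop = FALSE]
}
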