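test_that("FASTA I/O round-trips and normalises input", {
    tf <- tempfile(fileext = ".fasta")

    ## order and ids preserved
    writeLineageFasta(LineageSet(c(b = "ACGT", a = "ACGA")), tf)
    ls <- readLineageFasta(tf)
    expect_identical(lineageIds(ls), c("b", "a"))

    ## round trip of many random records
    orig <- randomLineageSet(100, 67, seed = 1)
    writeLineageFasta(orig, tf)
    back <- readLineageFasta(tf)
    expect_identical(as.character(sequences(back)),
                     as.character(sequences(orig)))

    ## lowercase bases uppercased on read
    writeLines(c(">x", "acgt"), tf)
    expect_identical(as.character(sequences(readLineageFasta(tf)))[["x"]],
                     "ACGT")

    ## duplicate ids rejected
    writeLines(c(">x", "ACGT", ">x", "ACGA"), tf)
    expect_error(readLineageFasta(tf), "duplicate")

    ## empty file rejected
    writeLines(character(0), tf)
    expect_error(readLineageFasta(tf), "empty|malformed")
})

test_that("dereplication tallies clones and conserves counts", {
    lib <- CloneLibrary(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAC",
                          e = "AAAC"),
                        sampleId = "s1",
                        pcrId = c("p1", "p1", "p2", "p1", "p2"))
    ty <- dereplicateClones(lib)
    tb <- typeTable(ty)
    expect_identical(nrow(tb), 2L)
    expect_identical(tb$clone_count, c(3L, 2L))
    expect_identical(tb$sequence, c("AAAA", "AAAC"))
    expect_identical(tb$n_pcrs, c(2L, 2L))

    ## all identical
    one <- dereplicateClones(CloneLibrary(rep("ACGT", 7), "s", rep("p1", 7)))
    expect_identical(typeTable(one)$clone_count, 7L)

    ## empty input
    expect_identical(nrow(typeTable(dereplicateClones(list()))), 0L)

    ## ties in clone count broken by sequence lexicographic order
    tie <- dereplicateClones(CloneLibrary(c("TTTT", "AAAA"), "s",
                                          c("p1", "p2")))
    expect_identical(typeTable(tie)$sequence, c("AAAA", "TTTT"))

    ## count conservation on random libraries
    for (s in 1:5) {
        set.seed(s)
        libs <- lapply(1:3, function(i) {
            n <- sample(5:30, 1)
            CloneLibrary(vapply(seq_len(n), function(k)
                paste(sample(c("A", "C"), 8, replace = TRUE),
                      collapse = ""), ""),
                sprintf("s%d", i),
                sample(c("p1", "p2"), n, replace = TRUE))
        })
        tb <- typeTable(dereplicateClones(libs))
        expect_identical(sum(tb$clone_count),
                         sum(vapply(libs, length, 0L)))
    }

    ## unequal lengths rejected
    expect_error(dereplicateClones(CloneLibrary(c("AA", "AAA"), "s",
                                                c("p1", "p1"))))
})

test_that("authenticity filter keeps replicated types and discards error variants", {
    ## singleton excluded under defaults; thresholds of 1 disable the filter
    ty <- dereplicateClones(CloneLibrary(c("AAAA", "AAAA", "AAAC"), "s",
                                         c("p1", "p2", "p1")))
    v <- verifySequenceTypes(ty)
    expect_identical(lineageIds(v$lineages), "lineage_01")
    expect_identical(v$discarded$reason, "too_few_clones_and_pcrs")

    v1 <- verifySequenceTypes(ty, minClones = 1, minPcrs = 1)
    expect_identical(length(v1$lineages), 2L)
    expect_identical(nrow(v1$discarded), 0L)

    ## retention is monotone in clone_count: nothing failing a threshold
    ## is ever retained
    expect_true(all(typeTable(ty)$clone_count[
        typeTable(ty)$id %in% v$discarded$type_id] < 2 |
        typeTable(ty)$n_pcrs[
            typeTable(ty)$id %in% v$discarded$type_id] < 2))

    ## Monte-Carlo with known templates: templates retained, polymerase
    ## error variants overwhelmingly discarded
    templates <- as.character(sequences(randomLineageSet(10, 191, seed = 42)))
    keptTemplates <- 0L; totalVariants <- 0L; keptVariants <- 0L
    nRuns <- 40
    for (s in seq_len(nRuns)) {
        libs <- lapply(seq_along(templates), function(i)
            simulateCloneLibrary(templates[i], 20, 0.002,
                                 seed = s * 100 + i, nPcr = 2,
                                 sampleId = sprintf("s%d", i)))
        ty <- dereplicateClones(libs)
        v <- verifySequenceTypes(ty)
        kept <- as.character(sequences(v$lineages))
        keptTemplates <- keptTemplates + sum(templates %in% kept)
        variants <- setdiff(typeTable(ty)$sequence, templates)
        totalVariants <- totalVariants + length(variants)
        keptVariants <- keptVariants + sum(variants %in% kept)
    }
    expect_identical(keptTemplates, as.integer(nRuns * length(templates)))
    expect_gte(1 - keptVariants / totalVariants, 0.95)
})

test_that("trimming slices all sequences identically and collapse removes duplicates", {
    ls <- LineageSet(c(a = "ACGTACGT"))
    expect_identical(as.character(sequences(trimToSubfragment(ls, 2, 5)))[[1]],
                     "GTA")
    expect_identical(as.character(sequences(trimToSubfragment(ls, 0, 8)))[[1]],
                     "ACGTACGT")
    expect_error(trimToSubfragment(ls, 3, 9), "out of range")
    expect_error(trimToSubfragment(ls, -1, 4), "out of range")

    cl <- collapseIdentical(LineageSet(c(s1 = "AAA", s2 = "AAA",
                                         s3 = "AAC")))
    expect_identical(length(cl$lineages), 2L)
    expect_identical(unname(cl$mapping[c("s1", "s2", "s3")]),
                     c("s1", "s1", "s3"))

    ## identity mapping when there are no duplicates
    ls2 <- randomLineageSet(20, 30, seed = 3)
    cl2 <- collapseIdentical(ls2)
    expect_identical(unname(cl2$mapping), lineageIds(ls2))

    ## idempotence, and trim -> collapse never increases lineage count
    for (s in 1:10) {
        x <- randomLineageSet(15, 40, seed = s)
        tr <- trimToSubfragment(x, 5, 12)
        c1 <- collapseIdentical(tr)
        c2 <- collapseIdentical(c1$lineages)
        expect_identical(length(c2$lineages), length(c1$lineages))
        expect_lte(length(c1$lineages), length(x))
    }
})

test_that("Hamming distances respect the site policy and the metric axioms", {
    expect_identical(hammingMatrix(LineageSet(c(a = "ACGT",
                                                b = "ACGA")))["a", "b"], 1L)

    ## ambiguous site skipped by default, compared literally under strict
    lsN <- LineageSet(c(a = "ACGT", b = "ACNT"))
    expect_identical(hammingMatrix(lsN)["a", "b"], 0L)
    expect_identical(hammingMatrix(lsN, "strict")["a", "b"], 1L)

    ## brute-force oracle and metric axioms on random sets
    for (s in 1:5) {
        ls <- randomLineageSet(8, 25, seed = s + 50)
        d <- hammingMatrix(ls)
        sq <- as.character(sequences(ls))
        for (i in 1:7) for (j in (i + 1):8)
            expect_identical(d[i, j], bruteHamming(sq[i], sq[j]))
        expect_identical(d, t(d))
        expect_true(all(diag(d) == 0L))
        ## triangle inequality
        n <- nrow(d)
        for (i in 1:n) for (j in 1:n) for (k in 1:n)
            expect_lte(d[i, j], d[i, k] + d[k, j])
        ## identity of indiscernibles under strict policy
        ds <- hammingMatrix(ls, "strict")
        expect_true(all(ds[upper.tri(ds)] >= 1L))
    }
})

test_that("distance summaries report counts and percentages of fragment length", {
    d2 <- matrix(c(0, 4, 4, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    s <- distanceSummary(d2, 67)
    expect_equal(s$mean_count, 4)
    expect_equal(s$mean_pct, 6.0)

    d3 <- matrix(0, 3, 3)
    d3[upper.tri(d3)] <- c(1, 2, 3)
    d3 <- d3 + t(d3)
    expect_equal(distanceSummary(d3, 67)$mean_count, 2.0)

    expect_error(distanceSummary(matrix(0, 1, 1), 67), "two lineages")
})

test_that("cross-set lineage matching equals a brute-force all-pairs scan", {
    a <- LineageSet(c(x1 = "ACGT", x2 = "TTTT"))
    b <- LineageSet(c(y1 = "ACGT", y2 = "ACGA", y3 = "GGGG"))
    m <- matchLineageSets(a, b, maxMismatch = 1)
    expect_identical(m$idA, c("x1", "x1"))
    expect_identical(m$idB, c("y1", "y2"))
    expect_identical(m$distance, c(0L, 1L))
    expect_identical(m$identical, c(TRUE, FALSE))

    ## maxMismatch = 0 is exactly the sequence intersection
    m0 <- matchLineageSets(a, b, maxMismatch = 0)
    expect_identical(nrow(m0), 1L)

    ## oracle equivalence on random 67-mers
    for (s in 1:3) {
        A <- randomLineageSet(6, 67, seed = s)
        B <- randomLineageSet(6, 67, seed = s + 100)
        got <- matchLineageSets(A, B, maxMismatch = 40)
        sa <- as.character(sequences(A)); sb <- as.character(sequences(B))
        want <- 0L
        for (i in 1:6) for (j in 1:6)
            if (bruteHamming(sa[i], sb[j]) <= 40) want <- want + 1L
        expect_identical(nrow(got), want)
        for (r in seq_len(nrow(got)))
            expect_identical(got$distance[r],
                             bruteHamming(sa[[got$idA[r]]],
                                          sb[[got$idB[r]]]))
    }

    expect_error(matchLineageSets(a, LineageSet(c(z = "ACGTT"))),
                 "lengths differ")
})
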