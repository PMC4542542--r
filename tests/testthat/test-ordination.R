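test_that("Bray-Curtis equals the Sorensen form on presence/absence data", {
    m <- rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 1), s3 = c(1, 1, 0),
               s4 = c(0, 0, 1))
    d <- brayCurtis(m)
    expect_equal(unname(d["s1", "s2"]), 0.5)
    expect_equal(unname(d["s1", "s3"]), 0)      # identical rows
    expect_equal(unname(d["s1", "s4"]), 1)      # disjoint rows
    expect_true(all(d >= 0 & d <= 1))

    ## a pair of empty samples is defined as 0, with a warning
    m0 <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
    expect_warning(d0 <- brayCurtis(m0), "empty samples")
    expect_equal(unname(d0["a", "b"]), 0)

    expect_error(brayCurtis(rbind(c(-1, 2), c(0, 1))), "nonnegative")

    ## independent implementation oracle
    skip_if_not_installed("vegan")
    set.seed(9)
    mm <- matrix(rbinom(120, 1, 0.4), 10)
    expect_equal(brayCurtis(mm),
                 as.matrix(vegan::vegdist(mm, "bray")),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dummy coding produces full-rank indicator designs", {
    st <- data.frame(sample = paste0("l", 1:21),
                     vegetation = rep_len(c("at", "stt", "ft", "lnt"), 21))
    X <- dummyCode(st, "vegetation")
    expect_identical(ncol(X), 3L)                 # k - 1 columns
    Xfull <- dummyCode(st, "vegetation", dropReference = FALSE)
    expect_equal(unname(rowSums(Xfull)), rep(1, 21))

    expect_error(dummyCode(st, "vegetation", levels = c("at", "stt")),
                 "unknown level")
    st1 <- data.frame(sample = "a", vegetation = "at")
    expect_error(dummyCode(st1, "vegetation"), "single level")
})

test_that("RDA matches closed-form regression and is reference-level invariant", {
    set.seed(4)
    n <- 24
    ## univariate response, single numeric constraint: R2 is the squared
    ## Pearson correlation
    x <- rnorm(n); y <- 2 * x + rnorm(n)
    f <- rdaFit(matrix(y), matrix(x, dimnames = list(NULL, "x")),
                nPerm = 99)
    expect_equal(f@R2, cor(x, y)^2, tolerance = 1e-10)

    ## constructed orthogonal constraint: R2 exactly 0, p high
    xo <- residuals(lm(rnorm(n) ~ y))
    f0 <- rdaFit(matrix(y), matrix(xo, dimnames = list(NULL, "xo")),
                 nPerm = 199, seed = 2)
    expect_lt(f0@R2, 1e-3)
    expect_gt(f0@pValue, 0.2)

    ## perfect fit: R2 = adjusted R2 = 1
    X <- cbind(a = rnorm(n), b = rnorm(n))
    Y <- X %*% rbind(c(1, 2), c(3, -1))
    fp <- rdaFit(Y, X, nPerm = 49)
    expect_equal(fp@R2, 1, tolerance = 1e-12)
    expect_equal(fp@adjR2, 1, tolerance = 1e-12)

    ## adjusted R2 never exceeds R2
    for (s in 1:10) {
        set.seed(s)
        fr <- rdaFit(matrix(rnorm(3 * n), n),
                     matrix(rnorm(2 * n), n), nPerm = 9, seed = s)
        expect_lte(fr@adjR2, fr@R2)
    }

    ## reference-level choice does not change R2
    st <- data.frame(sample = paste0("l", 1:20),
                     veg = rep_len(c("a", "b", "c", "d"), 20))
    set.seed(11)
    Y2 <- matrix(rnorm(60), 20)
    Xa <- dummyCode(st, "veg")
    Xb <- dummyCode(st, "veg", levels = c("d", "b", "c", "a"))
    expect_equal(rdaFit(Y2, Xa, nPerm = 9)@R2,
                 rdaFit(Y2, Xb, nPerm = 9)@R2, tolerance = 1e-12)

    ## independent oracle: vegan's rda
    skip_if_not_installed("vegan")
    ra <- vegan::RsquareAdj(vegan::rda(Y2 ~ Xa))
    ours <- rdaFit(Y2, Xa, nPerm = 9)
    expect_equal(ours@R2, ra$r.squared, tolerance = 1e-12)
    expect_equal(ours@adjR2, ra$adj.r.squared, tolerance = 1e-12)

    expect_error(rdaFit(matrix(rnorm(8), 4), matrix(rnorm(12), 4)),
                 "too few rows")
    expect_error(rdaFit(Y2, matrix(1, 20, 1)), "zero variance")
})

test_that("PCoA reproduces Euclidean geometry and handles negative eigenvalues", {
    ## classical-scaling exactness: distances of recovered coordinates
    ## equal the input distances
    set.seed(6)
    pts <- matrix(rnorm(24), 12)
    d <- as.matrix(dist(pts))
    pc <- pcoaFit(d)
    expect_equal(as.matrix(dist(pc$coordinates)), d, tolerance = 1e-8,
                 ignore_attr = TRUE)

    ## three equidistant points: two equal positive eigenvalues, third ~ 0
    d3 <- matrix(1, 3, 3); diag(d3) <- 0
    e3 <- pcoaFit(d3)$eigenvalues
    expect_equal(e3[1], e3[2], tolerance = 1e-10)
    expect_lt(abs(e3[3]), 1e-10)

    ## bookkeeping: total inertia is the sum of positive eigenvalues
    occ <- matrix(rbinom(100, 1, 0.5), 10)
    db <- brayCurtis(occ)
    pcb <- pcoaFit(db)
    expect_equal(pcb$totalInertia, sum(pcb$positiveEigenvalues))

    ## corrections make the matrix Euclidean (minimum eigenvalue ~ 0)
    for (policy in c("lingoes", "cailliez")) {
        pcc <- pcoaFit(db, policy)
        expect_gt(min(pcc$eigenvalues), -1e-6 * max(pcc$eigenvalues))
        expect_gt(pcc$constant, 0)
    }

    ## independent oracle for the corrected eigenvalues
    skip_if_not_installed("vegan")
    ## ape::pcoa implements the same Lingoes/Cailliez corrections
    ref <- ape::pcoa(as.dist(db), correction = "lingoes")
    ours <- pcoaFit(db, "lingoes")
    refVal <- ref$values$Corr_eig[seq_along(ours$positiveEigenvalues)]
    expect_equal(ours$positiveEigenvalues, refVal, tolerance = 1e-8)
})

test_that("dbRDA on Euclidean distances equals RDA on the raw coordinates", {
    for (s in 1:10) {
        set.seed(s)
        n <- sample(10:30, 1)
        Y <- matrix(rnorm(n * 3), n)
        X <- matrix(rnorm(n * sample(2:5, 1)), n)
        colnames(X) <- paste0("v", seq_len(ncol(X)))
        d <- as.matrix(dist(Y))
        expect_equal(dbrdaFit(d, X, nPerm = 9, seed = s)@R2,
                     rdaFit(Y, X, nPerm = 9, seed = s)@R2,
                     tolerance = 1e-9)
    }

    ## label alignment: rows of X matched to the distance labels
    set.seed(3)
    Y <- matrix(rnorm(30), 10)
    rownames(Y) <- paste0("u", 1:10)
    X <- matrix(rnorm(10), 10, dimnames = list(paste0("u", 1:10), "x"))
    d <- as.matrix(dist(Y))
    shuffled <- X[sample(1:10), , drop = FALSE]
    expect_equal(dbrdaFit(d, shuffled, nPerm = 9)@R2,
                 dbrdaFit(d, X, nPerm = 9)@R2, tolerance = 1e-12)

    ## degenerate constant explanatory column
    expect_error(dbrdaFit(d, matrix(1, 10, 1), nPerm = 9),
                 "zero variance")

    ## independent oracle: vegan's capscale on a non-Euclidean matrix
    skip_if_not_installed("vegan")
    occ <- matrix(rbinom(200, 1, 0.5), 20)
    db <- brayCurtis(occ)
    Xc <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
    cs <- vegan::RsquareAdj(vegan::capscale(as.dist(db) ~ Xc))
    expect_equal(dbrdaFit(db, Xc, nPerm = 9)@R2, cs$r.squared,
                 tolerance = 1e-6)
})

test_that("NMDS minimises Kruskal stress-1", {
    ## perfectly representable input: near-zero stress
    set.seed(2)
    pts <- matrix(rnorm(20), 10)
    fit <- nmdsFit(as.matrix(dist(pts)), k = 2, nStarts = 5)
    expect_lt(fit@stress, 0.01)

    ## 4-point instance at k = 1: dense grid-search oracle
    d4 <- matrix(c(0, 1, 3, 2,
                   1, 0, 1, 3,
                   3, 1, 0, 1,
                   2, 3, 1, 0), 4, 4)
    fit1 <- nmdsFit(d4, k = 1, nStarts = 20, seed = 5)
    gridStress <- function(x2, x3, x4) {
        X <- matrix(c(0, x2, x3, x4), 4, 1)
        dv <- X[c(2, 3, 4, 3, 4, 4)] - X[c(1, 1, 1, 2, 2, 3)]
        dv <- abs(dv)
        delta <- c(d4[2, 1], d4[3, 1], d4[4, 1], d4[3, 2], d4[4, 2],
                   d4[4, 3])
        ord <- order(delta, dv)
        dh <- numeric(6); dh[ord] <- stats::isoreg(dv[ord])$yf
        if (sum(dv^2) == 0) return(1)
        sqrt(sum((dv - dh)^2) / sum(dv^2))
    }
    g <- seq(-1, 1, by = 0.05)
    best <- Inf; bestArg <- NULL
    for (a in g) for (b in g) for (cc in g) {
        s <- gridStress(a, b, cc)
        if (s < best) { best <- s; bestArg <- c(a, b, cc) }
    }
    fine <- lapply(bestArg, function(v) seq(v - 0.05, v + 0.05, by = 0.004))
    for (a in fine[[1]]) for (b in fine[[2]]) for (cc in fine[[3]]) {
        s <- gridStress(a, b, cc)
        if (s < best) best <- s
    }
    expect_lt(abs(fit1@stress - best), 1e-3)

    ## nested-dimension monotonicity (best of starts)
    set.seed(8)
    dd <- as.matrix(dist(matrix(runif(36), 12)))
    s1 <- nmdsFit(dd, k = 1, nStarts = 10, seed = 3)@stress
    s2 <- nmdsFit(dd, k = 2, nStarts = 10, seed = 3)@stress
    expect_lte(s2, s1 + 1e-8)

    ## scale invariance of stress
    sA <- nmdsFit(dd, k = 2, nStarts = 5, seed = 4)@stress
    sB <- nmdsFit(dd * 7.3, k = 2, nStarts = 5, seed = 4)@stress
    expect_equal(sA, sB, tolerance = 1e-8)

    ## sanity against an independent optimiser: our best stress should
    ## not be clearly worse
    skip_if_not_installed("vegan")
    mm <- vegan::monoMDS(as.dist(dd), k = 2, model = "global")
    expect_lt(nmdsFit(dd, k = 2, nStarts = 20, seed = 1)@stress,
              mm$stress + 0.02)
})

test_that("forward selection admits true constraints and respects the alpha rule", {
    set.seed(10)
    n <- 25
    cand <- matrix(rnorm(n * 3), n,
                   dimnames = list(NULL, c("c1", "c2", "c3")))

    ## response built from c1 only, no noise: c1 selected at step 1
    Y <- cbind(2 * cand[, "c1"], -cand[, "c1"])
    fs <- forwardSelect(Y, cand, nPerm = 99, seed = 1)
    expect_identical(fs@selected[1], "c1")
    expect_equal(fs@steps$cum_R2[1], 1, tolerance = 1e-10)

    ## two collinear significant candidates: exactly one selected
    cand2 <- cbind(g1 = cand[, "c1"], g2 = cand[, "c1"])
    fs2 <- forwardSelect(Y, cand2, nPerm = 99, seed = 1)
    expect_identical(fs2@selected, "g1")   # tie broken lexicographically

    ## orthogonal single candidate under the null: selection rate ~ alpha
    nRuns <- 200; hits <- 0L
    for (s in seq_len(nRuns)) {
        set.seed(1000 + s)
        Yn <- matrix(rnorm(15 * 2), 15)
        xn <- matrix(rnorm(15), 15, dimnames = list(NULL, "x"))
        fsN <- forwardSelect(Yn, xn, alpha = 0.1, nPerm = 99,
                             seed = 2000 + s)
        if (length(fsN@selected)) hits <- hits + 1L
    }
    ## binomial 99% band around 0.1 at 200 runs
    expect_gt(hits / nRuns, 0.1 - 2.576 * sqrt(0.1 * 0.9 / nRuns))
    expect_lt(hits / nRuns, 0.1 + 2.576 * sqrt(0.1 * 0.9 / nRuns))

    ## empty selection still reports best-candidate diagnostics
    set.seed(12)
    fsE <- forwardSelect(matrix(rnorm(30), 15),
                         matrix(rnorm(15), 15,
                                dimnames = list(NULL, "noise")),
                         alpha = 0.001, nPerm = 99, seed = 3)
    expect_identical(length(fsE@selected), 0L)
    expect_identical(nrow(fsE@steps), 1L)
    expect_false(fsE@steps$selected[1])
})
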