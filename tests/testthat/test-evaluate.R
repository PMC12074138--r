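test_that("projection is the exact matrix product", {
    set.seed(1)
    X <- matrix(rnorm(8 * 5), 8, 5)
    W <- matrix(rnorm(8 * 3), 8, 3)
    P <- projectFeatures(X, W)
    # naive per-entry dot products
    for (i in 1:5) for (j in 1:3)
        expect_lt(abs(P[i, j] - sum(X[, i] * W[, j])), 1e-12)
    expect_identical(projectFeatures(matrix(0, 8, 2), W), matrix(0, 2, 3))
    expect_error(projectFeatures(matrix(0, 7, 2), W), "mismatch")
})

test_that("identification picks the nearest row with documented tie-breaking", {
    gal <- makeGallery(rbind(c(0, 0), c(3, 0), c(0, 3)), c("a", "b", "c"))
    # query equal to a gallery row
    expect_identical(as.character(identifyQueries(rbind(c(3, 0)), gal)), "b")
    # equidistant rows: lowest gallery index wins and the tie is counted
    pred <- identifyQueries(rbind(c(1.5, 1.5)), makeGallery(
        rbind(c(3, 0), c(0, 3)), c("b", "c")))
    expect_identical(as.character(pred), "b")
    expect_identical(attr(pred, "nTies"), 1L)
    # brute-force oracle on a random instance
    set.seed(2)
    G <- matrix(rnorm(40), 10, 4); gl <- sample(letters[1:4], 10, TRUE)
    Q <- matrix(rnorm(24), 6, 4)
    gal2 <- makeGallery(G, gl)
    pred2 <- as.character(identifyQueries(Q, gal2))
    for (i in 1:6) {
        dd <- apply(G, 1, function(g) sqrt(sum((Q[i, ] - g)^2)))
        expect_identical(pred2[i], gl[which.min(dd)])
    }
    expect_error(identifyQueries(Q, makeGallery(matrix(0, 0, 4),
        character(0))), "empty")
})

test_that("identification accuracy is a percentage of exact matches", {
    expect_identical(identificationAccuracy(c("a", "b"), c("a", "b")), 100)
    expect_identical(identificationAccuracy(c("a", "b"), c("b", "a")), 0)
    expect_identical(identificationAccuracy(c("a", "b", "c", "d"),
                                            c("a", "b", "c", "x")), 75)
    expect_error(identificationAccuracy(character(0), character(0)), "empty")
})

test_that("EER follows the threshold-sweep definition with interpolation", {
    # perfect separation
    expect_identical(computeEER(c(1, 2), c(5, 6, 7))$eer, 0)
    # the interleaved four-score case crosses at 25%
    res <- computeEER(c(1, 3), c(2, 4))
    expect_equal(res$eer, 25)
    expect_equal(res$threshold, 2.5)
    # same distribution: EER ~ 50% over seeds
    eers <- vapply(1:10, function(s) {
        set.seed(s)
        computeEER(rexp(400), rexp(400))$eer
    }, numeric(1))
    expect_lt(max(abs(eers - 50)), 8)
    # bounds and degenerate input
    expect_true(all(eers >= 0 & eers <= 100))
    expect_warning(res0 <- computeEER(rep(1, 5), rep(1, 5)), "degenerate")
    expect_error(computeEER(numeric(0), 1), "required")
})

test_that("matching is invariant to joint isometries", {
    set.seed(4)
    G <- matrix(rnorm(60), 15, 4); gl <- sample(letters[1:5], 15, TRUE)
    Q <- matrix(rnorm(32), 8, 4)
    Qrot <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    shift <- matrix(rnorm(4), 1, 4)
    p1 <- as.character(identifyQueries(Q, makeGallery(G, gl)))
    p2 <- as.character(identifyQueries(
        Q %*% Qrot + shift[rep(1, 8), ],
        makeGallery(G %*% Qrot + shift[rep(1, 15), ], gl)))
    expect_identical(p1, p2)
    s1 <- verificationScores(Q, sample(letters[1:5], 8, TRUE),
                             makeGallery(G, gl))
    expect_true(all(s1$genuine >= 0) && all(s1$impostor >= 0))
})

test_that("per-class-mean galleries average within individuals", {
    reps <- rbind(c(0, 0), c(2, 2), c(10, 10))
    gal <- makeGallery(reps, c("a", "a", "b"), mode = "per-class-mean")
    expect_identical(gal@labels, c("a", "b"))
    expect_equal(gal@reps[1, ], c(1, 1))
})

test_that("per-round accuracy reduces to a single evaluation for one chunk", {
    st <- simulateFeatureStream(nIndividuals = 6, chunkSizes = 30L, d = 16,
        seed = 6)
    hy <- OnlineHyper(r = 8L, seed = 6)
    fit <- trainStream(st$chunks, hy, test = st$test)
    expect_identical(nrow(fit$perRound), 1L)
    ev <- evaluateModel(fit$model, chunkFeatures(st$chunks[[1]]),
        chunkLabels(st$chunks[[1]]), chunkFeatures(st$test),
        chunkLabels(st$test))
    expect_identical(fit$perRound$accuracy, ev$accuracy)
    expect_identical(fit$final$accuracy, ev$accuracy)
})

test_that("zero-information features score near chance", {
    set.seed(7)
    nCls <- 8
    chunks <- lapply(1:3, function(t) FeatureChunk(
        matrix(rnorm(24 * 60), 24, 60),
        sample(letters[1:nCls], 60, replace = TRUE), t))
    test <- FeatureChunk(matrix(rnorm(24 * 80), 24, 80),
        rep(letters[1:nCls], each = 10), 4L)
    accs <- vapply(1:5, function(s) {
        trainStream(chunks, OnlineHyper(r = 8L, seed = s),
                    test = test)$final$accuracy
    }, numeric(1))
    # chance is 12.5%; allow generous sampling noise around it
    expect_lt(abs(mean(accs) - 100 / nCls), 10)
})
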