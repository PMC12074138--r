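test_that("pairwise label matrix encodes same-individual structure", {
    expect_identical(pairwiseLabelMatrix(c("a", "a", "b")),
                     rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
    expect_identical(pairwiseLabelMatrix(letters[1:4]), diag(4))
    expect_identical(pairwiseLabelMatrix(rep("z", 3)), matrix(1, 3, 3))
    A <- pairwiseLabelMatrix(sample(letters[1:5], 30, replace = TRUE))
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 1))
    expect_error(pairwiseLabelMatrix(character(0)), "non-empty")
})

test_that("memory similarity matrix marks remembered individuals only", {
    expect_identical(memorySimilarityMatrix(c("b", "c"), c("a", "b")),
                     rbind(c(0, 0), c(1, 0)))
    # empty memory: 0 x n matrix
    S <- memorySimilarityMatrix(c("a", "b"), character(0))
    expect_identical(dim(S), c(0L, 2L))
    # all labels remembered: every column sums to 1, never more
    S2 <- memorySimilarityMatrix(c("a", "b", "a"), c("a", "b", "c"))
    expect_identical(colSums(S2), c(1, 1, 1))
    expect_error(memorySimilarityMatrix("a", c("x", "x")), "distinct")
})

test_that("regression updates solve canonical cases exactly", {
    # identity regression: X = V = I, no history, vanishing ridge -> W = I
    hy <- OnlineHyper(delta = 1e-12, r = 6L)
    st0 <- emptyStats(6, 6)
    W <- updateW(st0, diag(6), diag(6), hy)
    expect_lt(max(abs(W - diag(6))), 1e-10)
    # exact reconstruction: X = B V' with orthonormal V -> G V' = X
    set.seed(1)
    V <- qr.Q(qr(matrix(rnorm(10 * 4), 10, 4)))
    B <- matrix(rnorm(7 * 4), 7, 4)
    X <- B %*% t(V)
    G <- updateG(emptyStats(7, 4), X, V, OnlineHyper(delta = 1e-12, r = 4L))
    expect_lt(max(abs(G %*% t(V) - X)), 1e-8)
    expect_error(updateW(st0, matrix(NaN, 6, 6), diag(6), hy), "non-finite")
})

test_that("prototype update collapses and solves least squares as expected", {
    set.seed(2)
    V <- matrix(rnorm(12 * 4), 12, 4)
    lab <- rep(letters[1:4], each = 3)   # all 4 code rows -> H'H full rank
    A <- pairwiseLabelMatrix(lab)
    cb <- assignCodes(hadamardCodebook(2), letters[1:4])
    H <- chunkCodeMatrix(cb, lab)
    # gamma = 0: the sub-problem collapses to R = V
    expect_identical(updateR(V, A, H, OnlineHyper(gamma = 0, r = 4L)), V)
    # theta = 0: pure least squares R = A'H (H'H)^-1
    Rls <- updateR(V, A, H, OnlineHyper(theta = 0, r = 4L))
    expect_lt(max(abs(Rls - t(A) %*% H %*% solve(crossprod(H)))), 1e-10)
    # converged prototypes are shared within an individual
    hy <- OnlineHyper(r = 4L)
    R <- updateR(V, A, H, hy)
    # R rows of one individual agree once V rows agree
    Vt <- H / 4
    Rt <- updateR(Vt, A, H, hy)
    expect_lt(max(abs(Rt[1, ] - Rt[2, ])), 1e-12)
})

test_that("representation update obeys dominant-term limits and memory modes", {
    set.seed(3)
    d <- 9; n <- 8; r <- 4
    X <- matrix(rnorm(d * n), d, n)
    W <- matrix(rnorm(d * r), d, r); G <- matrix(rnorm(d * r), d, r)
    R <- matrix(rnorm(n * r), n, r)
    Vm0 <- matrix(0, 0, r); S0 <- matrix(0, 0, n)
    # beta = eta = 0, huge theta: V -> R
    hy <- OnlineHyper(beta = 0, eta = 0, theta = 1e6, r = r)
    V <- updateV(X, W, G, R, S0, Vm0, hy)
    expect_lt(max(abs(V - R)), 1e-4)
    # with empty memory the derived and printed brackets coincide
    hyA <- OnlineHyper(r = r)
    hyB <- OnlineHyper(r = r, paperFormulaV = TRUE)
    expect_identical(updateV(X, W, G, R, S0, Vm0, hyA),
                     updateV(X, W, G, R, S0, Vm0, hyB))
    # and differ once memory rows exist
    Vm <- matrix(rnorm(2 * r), 2, r)
    S <- memorySimilarityMatrix(rep(c("a", "b"), 4), c("a", "b"))
    expect_false(identical(updateV(X, W, G, R, S, Vm, hyA),
                           updateV(X, W, G, R, S, Vm, hyB)))
})

test_that("each closed-form update is the exact minimiser of its sub-problem", {
    for (seed in 1:6) {
        inst <- randomInstance(seed)
        probs <- subProblems(inst)
        for (nm in names(probs)) {
            p <- probs[[nm]]
            closed <- as.vector(p$closed())
            # independent iterative minimiser on the explicit sub-objective
            cg <- cgQuadMin(p$fn, p$gr, rnorm(p$dim))
            expect_lt(max(abs(cg - closed)) / (1 + max(abs(closed))), 1e-8)
            # analytic stationarity at the closed form
            expect_lt(sqrt(sum(p$gr(closed)^2)),
                      1e-10 * (1 + abs(p$fn(closed))))
        }
    }
})

test_that("objective equals a naive term-by-term recomputation", {
    inst <- randomInstance(99)
    lat <- new("ChunkLatents", V = inst$V, R = inst$R, H = inst$H,
               A = inst$A, S = inst$S)
    got <- chunkObjective(inst$X, inst$W, inst$G, lat, inst$Vm, inst$hyper,
                          inst$stats)
    h <- inst$hyper
    # naive: explicit norms, with the old-data residuals materialised from
    # the explicit old chunk that built the statistics
    Xp <- inst$oldX
    Vp <- inst$oldV
    naive <- h@alpha * (sum((inst$V - t(inst$X) %*% inst$W)^2) +
                        sum((Vp - t(Xp) %*% inst$W)^2)) +
        h@beta * (sum((inst$X - inst$G %*% t(inst$V))^2) +
                  sum((Xp - inst$G %*% t(Vp))^2)) +
        h@gamma * sum((inst$A - inst$H %*% t(inst$R))^2) +
        h@theta * sum((inst$R - inst$V)^2) +
        h@eta * sum((inst$S - inst$Vm %*% t(inst$V))^2) +
        h@delta * (sum(inst$W^2) + sum(inst$G^2))
    expect_lt(abs(got - naive) / (1 + naive), 1e-10)
    # zero everything -> zero objective
    z <- new("ChunkLatents", V = matrix(0, 2, 2), R = matrix(0, 2, 2),
             H = matrix(0, 2, 2), A = matrix(0, 2, 2), S = matrix(0, 0, 2))
    expect_identical(chunkObjective(matrix(0, 3, 2), matrix(0, 3, 2),
        matrix(0, 3, 2), z, matrix(0, 0, 2), OnlineHyper(r = 2L)), 0)
})

test_that("the full streaming objective is monotone within every chunk", {
    st <- simulateFeatureStream(nIndividuals = 8, chunkSizes = rep(30, 3),
        d = 24, seed = 13)
    fit <- trainStream(st$chunks, OnlineHyper(r = 8L, seed = 13))
    expect_lte(maxRelIncrease(fit$model), 1e-8)
    # also with the memory module exercising the eta term across rounds
    st2 <- simulateFeatureStream(nIndividuals = 8, chunkSizes = rep(30, 3),
        d = 24, incrementalFraction = 0.25, seed = 14)
    fit2 <- trainStream(st2$chunks, OnlineHyper(r = 8L, seed = 14))
    expect_lte(maxRelIncrease(fit2$model), 1e-8)
})

test_that("online sufficient statistics and W equal their batch counterparts", {
    st <- simulateFeatureStream(nIndividuals = 8, chunkSizes = rep(25, 4),
        d = 20, seed = 21)
    hy <- OnlineHyper(r = 8L, seed = 21)
    m <- newOnlineModel(20, hy)
    Xs <- list(); Vs <- list()
    for (ch in st$chunks) {
        out <- trainChunk(m, ch)
        m <- out$model
        Xs <- c(Xs, list(chunkFeatures(ch)))
        Vs <- c(Vs, list(latentV(out$latents)))
        C1 <- Reduce(`+`, lapply(Xs, tcrossprod))
        C2 <- Reduce(`+`, mapply(function(X, V) X %*% V, Xs, Vs,
                                 SIMPLIFY = FALSE))
        C3 <- Reduce(`+`, lapply(Vs, crossprod))
        s <- modelStats(m)
        expect_lt(max(abs(s@C1 - C1)), 1e-10)
        expect_lt(max(abs(s@C2 - C2)), 1e-10)
        expect_lt(max(abs(s@C3 - C3)), 1e-10)
        # online W = batch ridge on the concatenated frozen data
        Wb <- solve(C1 + (hy@delta / hy@alpha) * diag(20), C2)
        expect_lt(max(abs(modelProjection(m) - Wb)), 1e-9)
    }
})

test_that("training is deterministic given seed and stream", {
    st <- simulateFeatureStream(nIndividuals = 6, chunkSizes = rep(20, 3),
        d = 16, seed = 8)
    hy <- OnlineHyper(r = 8L, seed = 8)
    m1 <- trainStream(st$chunks, hy)$model
    m2 <- trainStream(st$chunks, hy)$model
    expect_identical(modelProjection(m1), modelProjection(m2))
    expect_identical(memoryMatrix(modelMemory(m1)),
                     memoryMatrix(modelMemory(m2)))
    # a different seed gives a different W
    m3 <- trainStream(st$chunks, OnlineHyper(r = 8L, seed = 9))$model
    expect_false(identical(modelProjection(m1), modelProjection(m3)))
})

test_that("module toggles run the ablation paths", {
    st <- simulateFeatureStream(nIndividuals = 6, chunkSizes = rep(24, 2),
        d = 16, seed = 30)
    for (hy in list(
        OnlineHyper(r = 8L, seed = 30, bidirectional = FALSE),
        OnlineHyper(r = 8L, seed = 30, prototypes = FALSE),
        OnlineHyper(r = 8L, seed = 30, memory = FALSE))) {
        fit <- trainStream(st$chunks, hy, test = st$test)
        expect_true(all(is.finite(modelProjection(fit$model))))
        expect_lte(maxRelIncrease(fit$model), 1e-8)
        expect_gte(fit$final$accuracy, 0)
    }
    # dimension drift across chunks is refused
    m <- newOnlineModel(16, OnlineHyper(r = 8L))
    bad <- FeatureChunk(matrix(rnorm(10 * 4), 10, 4), letters[1:4], 1L)
    expect_error(trainChunk(m, bad), "does not match")
})

test_that("warm statistics help on a repeated chunk", {
    # absorbing the identical chunk a second time: with warmed W, G and
    # statistics, the second round's current-chunk objective part ends below
    # the first (cold) round's final value. The memory module is switched
    # off here because its term only exists from round 2 on, which would
    # make the two rounds' objectives incomparable.
    st <- simulateFeatureStream(nIndividuals = 8, chunkSizes = c(30, 30),
        d = 24, seed = 11)
    ch <- st$chunks[[1]]
    for (s in c(11L, 12L, 13L)) {
        hy <- OnlineHyper(r = 8L, seed = s, memory = FALSE)
        out1 <- trainChunk(newOnlineModel(24, hy), ch)
        coldFinal <- utils::tail(objectiveLog(out1$model)$objective, 1)
        out2 <- trainChunk(out1$model,
            FeatureChunk(chunkFeatures(ch), chunkLabels(ch), 2L))
        bd <- chunkObjective(chunkFeatures(ch), modelProjection(out2$model),
            modelReconstruction(out2$model), out2$latents,
            matrix(0, 0, 8), hy, modelStats(out1$model), breakdown = TRUE)
        expect_lt(sum(bd) - bd[["old"]], coldFinal)
    }
})
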