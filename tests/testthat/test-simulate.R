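test_that("stream schedules and label bookkeeping are exact", {
    # five-round protocol: 4 x 70 + 49
    st <- simulateFeatureStream(nIndividuals = 20,
        chunkSizes = c(70, 70, 70, 70, 49), d = 64, seed = 1)
    expect_identical(vapply(st$chunks,
        function(ch) ncol(chunkFeatures(ch)), integer(1)),
        c(70L, 70L, 70L, 70L, 49L))
    # six-round protocol: 5 x 108 + 27
    st6 <- simulateFeatureStream(nIndividuals = 25,
        chunkSizes = c(rep(108, 5), 27), d = 64, seed = 1)
    expect_identical(length(st6$chunks), 6L)
    expect_identical(ncol(chunkFeatures(st6$chunks[[6]])), 27L)
    # label marginals match the generator's own bookkeeping
    lab <- unlist(lapply(st$chunks, chunkLabels))
    expect_identical(as.integer(table(factor(lab,
        levels = names(st$trainCounts)))), as.integer(st$trainCounts))
    # held-out test chunk: 5 per individual
    expect_identical(ncol(chunkFeatures(st$test)), 100L)
    expect_true(all(table(chunkLabels(st$test)) == 5))
    # feature dimension constant and finite
    expect_true(all(vapply(st$chunks,
        function(ch) nrow(chunkFeatures(ch)), integer(1)) == 64L))
})

test_that("class-incremental schedules withhold individuals from round 1", {
    st <- simulateFeatureStream(nIndividuals = 20,
        chunkSizes = c(70, 70, 70, 70, 49), d = 64,
        incrementalFraction = 0.3, introRound = 3, seed = 2)
    withheld <- names(st$firstRound)[st$firstRound > 1]
    expect_identical(length(withheld), 6L)
    expect_true(all(st$firstRound[withheld] >= 3))
    # rounds 1 and 2 never contain withheld individuals
    expect_false(any(withheld %in% chunkLabels(st$chunks[[1]])))
    expect_false(any(withheld %in% chunkLabels(st$chunks[[2]])))
    # every withheld individual appears exactly from its first round
    for (id in withheld) {
        seenAt <- which(vapply(st$chunks,
            function(ch) id %in% chunkLabels(ch), logical(1)))
        expect_identical(min(seenAt), as.integer(st$firstRound[id]))
    }
    # capacity errors
    expect_error(simulateFeatureStream(nIndividuals = 30,
        chunkSizes = c(10, 10), d = 64, seed = 1), "too small")
    expect_error(simulateFeatureStream(nIndividuals = 80, d = 64, seed = 1),
        "nIndividuals <= d")
})

test_that("streams are reproducible and respect the separation contract", {
    a <- simulateFeatureStream(nIndividuals = 8, chunkSizes = c(30, 30),
        d = 20, seed = 5)
    b <- simulateFeatureStream(nIndividuals = 8, chunkSizes = c(30, 30),
        d = 20, seed = 5)
    expect_identical(chunkFeatures(a$chunks[[2]]), chunkFeatures(b$chunks[[2]]))
    expect_identical(chunkLabels(a$test), chunkLabels(b$test))
    # min pairwise mean distance equals classSeparation * withinSd
    st <- simulateFeatureStream(nIndividuals = 10, chunkSizes = 40L, d = 16,
        classSeparation = 7, withinSd = 0.3, seed = 6)
    D <- as.matrix(dist(st$means))
    expect_equal(min(D[D > 0]), 7 * 0.3, tolerance = 1e-10)
})

test_that("noiseless streams are perfectly identifiable end to end", {
    st <- simulateFeatureStream(nIndividuals = 10, chunkSizes = c(40, 40),
        d = 40, withinSd = 0, seed = 3)
    fit <- trainStream(st$chunks, OnlineHyper(r = 16L, seed = 3),
                       test = st$test)
    expect_identical(fit$final$accuracy, 100)
    expect_identical(fit$final$eer, 0)
})

test_that("identification accuracy is non-decreasing in class separation", {
    acc <- sapply(c(2, 6, 12), function(sep) {
        median(vapply(1:5, function(s) {
            st <- simulateFeatureStream(nIndividuals = 10,
                chunkSizes = c(40, 40), d = 32, classSeparation = sep,
                seed = s)
            trainStream(st$chunks, OnlineHyper(r = 16L, seed = s),
                        test = st$test)$final$accuracy
        }, numeric(1)))
    })
    # allow small sampling noise between adjacent levels
    expect_true(all(diff(acc) > -2))
})

test_that("pseudo-ECG generator plants QRS maxima at the declared indices", {
    sim <- simulateEcgRecord(fs = 360, nBeats = 25, noiseSd = 0, seed = 9)
    x <- sim$record@samples
    # with no noise the signal maximum around each ground-truth index is the
    # index itself (QRS amplitude dominates P and T)
    for (p in sim$rPeaks) {
        win <- max(1, p - 30):min(length(x), p + 30)
        expect_identical(win[which.max(x[win])], as.integer(p))
    }
    # record length follows the generator's own arithmetic
    sim2 <- simulateEcgRecord(fs = 360, nBeats = 100, rrMean = 0.8, seed = 10)
    expect_lt(abs(length(sim2$record@samples) - 100 * 0.8 * 360),
              2 * 0.8 * 360)
    # fixed seed -> identical record
    sim3 <- simulateEcgRecord(fs = 360, nBeats = 25, noiseSd = 0.1, seed = 9)
    sim4 <- simulateEcgRecord(fs = 360, nBeats = 25, noiseSd = 0.1, seed = 9)
    expect_identical(sim3$record@samples, sim4$record@samples)
    expect_error(simulateEcgRecord(rrMean = 0.01, seed = 1), "exceed")
})

test_that("full pipeline from pseudo-ECG to features holds its contracts", {
    sim <- simulateEcgRecord(fs = 360, nBeats = 40, noiseSd = 0.03, seed = 12)
    peaks <- detectRPeaks(sim$record)
    beats <- segmentHeartbeats(sim$record, peaks, windowLength = 260)
    expect_gte(ncol(beatMatrix(beats)), 38L)
    cfg <- LbpConfig()
    fc <- extractLbpFeatures(beats, cfg)
    expect_identical(nrow(chunkFeatures(fc)), lbpFeatureDim(cfg, 260L))
    expect_false(anyNA(chunkFeatures(fc)))
})
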