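#' Simulate a labeled feature stream
#'
#' Generates a class-incremental stream of [FeatureChunk-class]s with
#' controllable class structure: individual means are the vertices of a
#' regular simplex, randomly rotated, scaled so that the minimum pairwise
#' mean distance equals `classSeparation * withinSd`; samples are the mean
#' plus isotropic Gaussian noise of standard deviation `withinSd`. A
#' fraction of individuals can be withheld from round 1 and introduced at
#' later rounds (the class-incremental case). Five samples per individual
#' (configurable) are generated separately as a held-out test chunk.
#'
#' The default chunk schedule is the five-round protocol with four chunks
#' of 70 samples and a final chunk of 49; a six-round schedule of five
#' 108-sample chunks plus a final 27 is the other reference protocol.
#'
#' @param nIndividuals number of individuals (must be <= d for the simplex
#'   construction).
#' @param chunkSizes per-round sample counts; round 1 must be able to hold
#'   every non-withheld individual at least once.
#' @param d feature dimension.
#' @param classSeparation minimum distance between class means, in units of
#'   `withinSd`.
#' @param withinSd within-class standard deviation.
#' @param incrementalFraction fraction of individuals withheld from round 1.
#' @param introRound earliest round at which withheld individuals appear
#'   (they are spread over rounds `introRound, ..., length(chunkSizes)`).
#' @param nTest held-out test samples per individual.
#' @param seed RNG seed; the stream is fully reproducible from it.
#' @return List with `chunks` (list of [FeatureChunk-class]), `test`
#'   (a [FeatureChunk-class]), `means` (nIndividuals x d), `firstRound`
#'   (named integer vector, first training round of each individual) and
#'   `trainCounts` (named per-individual training sample counts).
#' @examples
#' st <- simulateFeatureStream(nIndividuals = 10, d = 20, seed = 1)
#' length(st$chunks)
#' @export
simulateFeatureStream <- function(nIndividuals = 20L,
                                  chunkSizes = c(70L, 70L, 70L, 70L, 49L),
                                  d = 64L, classSeparation = 12,
                                  withinSd = 0.05, incrementalFraction = 0,
                                  introRound = 2L, nTest = 5L, seed = 1L) {
    nIndividuals <- as.integer(nIndividuals)
    chunkSizes <- as.integer(chunkSizes)
    d <- as.integer(d)
    stopifnot(nIndividuals >= 2L, all(chunkSizes >= 1L), d >= 2L,
              classSeparation >= 0, withinSd >= 0,
              incrementalFraction >= 0, incrementalFraction < 1)
    if (nIndividuals > d)
        stop("the simplex mean construction requires nIndividuals <= d")
    nRounds <- length(chunkSizes)
    introRound <- max(2L, min(as.integer(introRound), nRounds))

    set.seed(as.integer(seed))
    ids <- sprintf("id%02d", seq_len(nIndividuals))
    # regular simplex: scaled standard-basis rows have all pairwise
    # distances equal to scale * sqrt(2); a random rotation hides the axes.
    # In the noiseless limit the separation is taken in absolute units so
    # the class means do not collapse.
    unit <- if (withinSd > 0) withinSd else 1
    scale <- classSeparation * unit / sqrt(2)
    M0 <- diag(scale, nIndividuals, d)
    Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    means <- M0 %*% Q
    rownames(means) <- ids

    nWithheld <- floor(incrementalFraction * nIndividuals)
    withheld <- if (nWithheld > 0) utils::tail(ids, nWithheld) else character(0)
    base <- setdiff(ids, withheld)
    if (length(base) > chunkSizes[1L])
        stop(sprintf(paste0("chunk sizes too small to cover individuals: ",
            "round 1 has %d slots for %d individuals"),
            chunkSizes[1L], length(base)))
    firstRound <- stats::setNames(rep(1L, nIndividuals), ids)
    if (nWithheld > 0) {
        slots <- rep(seq(introRound, nRounds), length.out = nWithheld)
        firstRound[withheld] <- sort(slots)
        nAtRound <- table(factor(firstRound[withheld],
                                 levels = seq_len(nRounds)))
        short <- which(as.integer(nAtRound) > chunkSizes)
        if (length(short))
            stop("chunk sizes too small to cover newly introduced individuals")
    }

    sampleChunk <- function(lab, t) {
        X <- t(means[lab, , drop = FALSE]) +
            matrix(stats::rnorm(d * length(lab), 0, withinSd), d, length(lab))
        FeatureChunk(X, lab, t)
    }

    chunks <- vector("list", nRounds)
    for (t in seq_len(nRounds)) {
        pool <- ids[firstRound <= t]
        newcomers <- ids[firstRound == t]
        lab <- newcomers
        extra <- chunkSizes[t] - length(lab)
        if (extra < 0) stop("chunk sizes too small to cover individuals")
        if (extra > 0)
            lab <- c(lab, sample(rep(pool, length.out = extra)))
        lab <- sample(lab)
        chunks[[t]] <- sampleChunk(lab, t)
    }

    testLab <- rep(ids, each = nTest)
    test <- sampleChunk(testLab, nRounds + 1L)

    trainLab <- unlist(lapply(chunks, chunkLabels))
    list(chunks = chunks, test = test, means = means,
         firstRound = firstRound,
         trainCounts = table(factor(trainLab, levels = ids)))
}

# one Gaussian bump per wave, clipped to +/- 5 sigma for speed
.addBump <- function(sig, fs, center, amp, width) {
    n <- length(sig)
    lo <- max(1L, floor((center - 5 * width) * fs))
    hi <- min(n, ceiling((center + 5 * width) * fs))
    if (lo > hi) return(sig)
    tt <- (lo:hi) / fs
    sig[lo:hi] <- sig[lo:hi] + amp * exp(-((tt - center)^2) / (2 * width^2))
    sig
}

#' Simulate a pseudo-ECG record with known R peaks
#'
#' Concatenates heartbeats, each the sum of three Gaussian bumps (P wave,
#' QRS complex, T wave) at per-record amplitudes/offsets/widths, with
#' jittered RR intervals and additive white Gaussian noise. Ground-truth
#' R-peak sample indices (the QRS bump centres) are returned alongside the
#' record, making the generator the test bed for the Pan-Tompkins detector
#' and the segmentation step.
#'
#' @param fs sampling rate in Hz.
#' @param nBeats number of beats.
#' @param rrMean,rrSd mean and standard deviation of the RR interval in
#'   seconds (jitter is truncated at 0.5 * rrMean).
#' @param waves list of three lists `P`, `QRS`, `T`, each with `amp`
#'   (amplitude), `mu` (centre offset from the R peak in seconds) and
#'   `sigma` (Gaussian width in seconds). Defaults approximate a normal
#'   beat morphology.
#' @param noiseSd standard deviation of additive Gaussian noise, in the
#'   same units as the waveform (R amplitude defaults to 1).
#' @param seed RNG seed.
#' @return List with `record` (an [EcgRecord-class]) and `rPeaks`
#'   (ground-truth integer sample indices).
#' @examples
#' sim <- simulateEcgRecord(fs = 360, nBeats = 20, noiseSd = 0.05, seed = 7)
#' sim$record
#' @export
simulateEcgRecord <- function(fs = 360, nBeats = 100L, rrMean = 0.8,
                              rrSd = 0.04,
                              waves = list(
                                  P = list(amp = 0.15, mu = -0.2, sigma = 0.025),
                                  QRS = list(amp = 1, mu = 0, sigma = 0.012),
                                  T = list(amp = 0.3, mu = 0.25, sigma = 0.05)),
                              noiseSd = 0, seed = 1L) {
    stopifnot(fs > 0, nBeats >= 1, rrMean > 0)
    for (wv in waves)
        if (rrMean <= wv$sigma)
            stop("rrMean must exceed every wave width")
    set.seed(as.integer(seed))
    rr <- pmax(rrMean + stats::rnorm(nBeats, 0, rrSd), 0.5 * rrMean)
    rTimes <- cumsum(c(0.6 * rrMean, rr[-1L]))
    n <- ceiling((rTimes[nBeats] + 0.6 * rrMean) * fs)
    sig <- numeric(n)
    for (k in seq_len(nBeats))
        for (wv in waves)
            sig <- .addBump(sig, fs, rTimes[k] + wv$mu, wv$amp, wv$sigma)
    if (noiseSd > 0) sig <- sig + stats::rnorm(n, 0, noiseSd)
    list(record = EcgRecord(sig, fs, recordId = sprintf("sim%d", seed)),
         rPeaks = as.integer(round(rTimes * fs)))
}

#' Noise level for a target signal-to-noise ratio
#'
#' Helper mapping an SNR in dB to the additive-noise standard deviation for
#' a given clean signal: `sd(signal) / 10^(snrDb / 20)`.
#'
#' @param signal clean signal vector.
#' @param snrDb target SNR in decibels.
#' @return Noise standard deviation.
#' @export
noiseSdForSnr <- function(signal, snrDb) {
    stats::sd(signal) / 10^(snrDb / 20)
}
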