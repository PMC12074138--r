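#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic Pan-Tompkins QRS detection: band-pass filtering of the raw trace,
#' differentiation, squaring, moving-window integration, then adaptive dual
#' thresholds with RR-interval search-back. The band-pass and integration
#' stages are applied zero-phase (forward-backward Butterworth, centred
#' windows), so detected integration peaks align with the underlying QRS and
#' the final R position is the band-passed maximum in a +/-100 ms
#' neighbourhood.
#'
#' @param record an [EcgRecord-class].
#' @param bandEdges band-pass corner frequencies in Hz (default 5-15 Hz).
#' @param integrationWindow moving-window integration length in seconds
#'   (default 0.15).
#' @param refractory minimum spacing between accepted peaks in seconds
#'   (default 0.2); the returned indices are guaranteed at least this far
#'   apart.
#' @param searchBackFactor multiple of the running average RR interval after
#'   which a missed beat is searched for below the primary threshold
#'   (default 1.66).
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based). A signal with no energy (constant trace) yields
#'   `integer(0)`.
#' @examples
#' sim <- simulateEcgRecord(fs = 360, nBeats = 12, seed = 1)
#' peaks <- detectRPeaks(sim$record)
#' @export
detectRPeaks <- function(record, bandEdges = c(5, 15),
                         integrationWindow = 0.15, refractory = 0.2,
                         searchBackFactor = 1.66) {
    stopifnot(is(record, "EcgRecord"))
    validObject(record)
    x <- record@samples
    fs <- record@fs
    if (fs < 100)
        warning(sprintf("sampling rate %g Hz is low for QRS detection; >= 100 Hz recommended", fs))
    if (!all(is.finite(x))) stop("record contains non-finite samples")
    if (diff(range(x)) == 0) return(integer(0))
    nWarm <- ceiling(2 * fs)
    if (length(x) < nWarm)
        stop(sprintf("record too short for filter warm-up: %d samples, need at least %d (2 s at %g Hz)",
                     length(x), nWarm, fs))

    bf <- signal::butter(3, pmin(bandEdges / (fs / 2), 0.99), type = "pass")
    bp <- as.numeric(signal::filtfilt(bf, x))

    # centred 5-point derivative (zero phase), then squaring
    dkern <- c(1, 2, 0, -2, -1) / 8
    dv <- as.numeric(stats::filter(bp, dkern, sides = 2))
    dv[is.na(dv)] <- 0
    sq <- dv^2

    nw <- max(3L, round(integrationWindow * fs))
    if (nw %% 2L == 0L) nw <- nw + 1L
    mwi <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 2))
    mwi[is.na(mwi)] <- 0

    refr <- round(refractory * fs)
    cand <- .localMaxima(mwi, minGap = refr)
    cand <- cand[mwi[cand] > 0]
    if (!length(cand)) return(integer(0))

    # adaptive dual thresholds over the candidate sequence
    init <- mwi[seq_len(min(length(mwi), nWarm))]
    spki <- 0.25 * max(init)
    npki <- 0.5 * mean(init)
    accepted <- integer(0)
    rejected <- integer(0)
    rrBuf <- numeric(0)
    for (p in cand) {
        th1 <- npki + 0.25 * (spki - npki)
        # search-back for a missed beat when the gap grows too large
        if (length(accepted) && length(rrBuf)) {
            rrAvg <- mean(rrBuf)
            if (p - accepted[length(accepted)] > searchBackFactor * rrAvg &&
                length(rejected)) {
                gap <- rejected[rejected > accepted[length(accepted)] + refr &
                                rejected < p - refr]
                gap <- gap[mwi[gap] > 0.5 * th1]
                if (length(gap)) {
                    best <- gap[which.max(mwi[gap])]
                    accepted <- c(accepted, best)
                    spki <- 0.25 * mwi[best] + 0.75 * spki
                    rrBuf <- .pushRR(rrBuf, diff(utils::tail(accepted, 2L)))
                    rejected <- setdiff(rejected, best)
                }
            }
        }
        if (mwi[p] > th1 &&
            (!length(accepted) || p - accepted[length(accepted)] > refr)) {
            accepted <- c(accepted, p)
            spki <- 0.125 * mwi[p] + 0.875 * spki
            if (length(accepted) > 1L)
                rrBuf <- .pushRR(rrBuf, diff(utils::tail(accepted, 2L)))
        } else {
            npki <- 0.125 * mwi[p] + 0.875 * npki
            rejected <- c(rejected, p)
        }
    }
    if (!length(accepted)) return(integer(0))

    # refine to the band-passed maximum near each integration peak
    half <- round(0.1 * fs)
    n <- length(x)
    peaks <- vapply(sort(accepted), function(p) {
        lo <- max(1L, as.integer(p - half))
        hi <- min(n, as.integer(p + half))
        lo + which.max(bp[lo:hi]) - 1L
    }, integer(1))
    peaks <- sort(unique(peaks))

    # enforce the refractory period on the refined positions: keep the
    # stronger of any two peaks closer than 0.2 s
    if (length(peaks) > 1L) {
        keep <- rep(TRUE, length(peaks))
        last <- 1L
        for (i in 2L:length(peaks)) {
            if (peaks[i] - peaks[last] < refr) {
                if (bp[peaks[i]] > bp[peaks[last]]) {
                    keep[last] <- FALSE
                    last <- i
                } else keep[i] <- FALSE
            } else last <- i
        }
        peaks <- peaks[keep]
    }
    as.integer(peaks)
}

# local maxima of y at least minGap apart (greedy on height within plateaus)
.localMaxima <- function(y, minGap) {
    n <- length(y)
    if (n < 3L) return(integer(0))
    idx <- which(y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
    if (!length(idx)) return(integer(0))
    # thin maxima closer than minGap, keeping the higher one
    keep <- integer(0)
    for (i in idx) {
        if (length(keep) && i - keep[length(keep)] < minGap) {
            if (y[i] > y[keep[length(keep)]]) keep[length(keep)] <- i
        } else keep <- c(keep, i)
    }
    keep
}

.pushRR <- function(buf, rr, maxLen = 8L) {
    buf <- c(buf, rr)
    if (length(buf) > maxLen) buf <- utils::tail(buf, maxLen)
    buf
}

#' Segment heartbeats around detected R peaks
#'
#' Cuts one fixed-length window per R peak, placing
#' `floor(offsetFraction * windowLength)` samples before the peak and the
#' remainder from the peak onward. Windows that would cross a record
#' boundary are dropped (not padded) and counted, so every retained column
#' is a verbatim contiguous slice of the source record.
#'
#' @param record an [EcgRecord-class].
#' @param peaks integer R-peak indices (e.g. from [detectRPeaks()]).
#' @param windowLength samples per beat (260 is customary at 360 Hz,
#'   600 at higher-rate off-the-person recordings).
#' @param offsetFraction fraction of the window placed before the R peak,
#'   in (0, 1); default 0.5 (symmetric).
#' @return A [HeartbeatMatrix-class]; `nDropped()` reports boundary drops.
#' @examples
#' sim <- simulateEcgRecord(fs = 360, nBeats = 12, seed = 1)
#' beats <- segmentHeartbeats(sim$record, sim$rPeaks, windowLength = 260)
#' @export
segmentHeartbeats <- function(record, peaks, windowLength = 260L,
                              offsetFraction = 0.5) {
    stopifnot(is(record, "EcgRecord"))
    windowLength <- as.integer(windowLength)
    if (windowLength < 2L) stop("'windowLength' must be >= 2")
    if (!(offsetFraction > 0 && offsetFraction < 1))
        stop("'offsetFraction' must lie strictly between 0 and 1")
    n <- length(record@samples)
    if (windowLength > n)
        stop(sprintf("windowLength (%d) exceeds record length (%d)",
                     windowLength, n))
    peaks <- sort(as.integer(peaks))
    pre <- floor(offsetFraction * windowLength)
    starts <- peaks - pre
    ends <- starts + windowLength - 1L
    ok <- starts >= 1L & ends <= n
    kept <- peaks[ok]
    seg <- vapply(starts[ok],
        function(s) record@samples[s:(s + windowLength - 1L)],
        numeric(windowLength))
    if (!is.matrix(seg)) seg <- matrix(seg, nrow = windowLength)
    new("HeartbeatMatrix", segments = seg, rPeaks = kept,
        windowLength = windowLength, nDropped = sum(!ok), fs = record@fs)
}

#' Write heartbeat segments to disk
#'
#' One column per beat in a comma-delimited matrix, plus a JSON sidecar
#' recording the R-peak indices, sampling rate and window length.
#'
#' @param beats a [HeartbeatMatrix-class].
#' @param file path of the delimited matrix; the sidecar gets `.json`
#'   appended.
#' @return Invisibly, the sidecar path.
#' @export
writeHeartbeats <- function(beats, file) {
    stopifnot(is(beats, "HeartbeatMatrix"))
    utils::write.table(beats@segments, file, sep = ",", row.names = FALSE,
        col.names = FALSE)
    side <- paste0(file, ".json")
    jsonlite::write_json(list(r_peak_indices = beats@rPeaks, fs = beats@fs,
        window_length = beats@windowLength, n_dropped = beats@nDropped),
        side, auto_unbox = TRUE, digits = NA)
    invisible(side)
}
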