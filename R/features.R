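#' 1-D local binary pattern codes at one radius
#'
#' For every interior sample, the `2 * neighborsPerSide` neighbours at
#' offsets `-neighborsPerSide*radius, ..., -radius, +radius, ...,
#' +neighborsPerSide*radius` are compared with the centre value; a neighbour
#' greater than or equal to the centre (ties count as 1) contributes bit 1,
#' otherwise 0. Bits are packed left-to-right (most negative offset is the
#' most significant bit). Boundary samples without a full neighbourhood are
#' truncated, so the code series is shorter than the segment by
#' `2 * radius * neighborsPerSide`.
#'
#' Because the comparison is relative to the centre sample, adding a
#' constant to the whole segment leaves every code unchanged.
#'
#' @param segment numeric vector.
#' @param radius positive integer sample offset between neighbours.
#' @param neighborsPerSide neighbours per side (code alphabet size is
#'   `2^(2*neighborsPerSide)`).
#' @return Integer vector of codes, length
#'   `length(segment) - 2 * radius * neighborsPerSide`.
#' @examples
#' lbpCodes1d(1:10, radius = 1, neighborsPerSide = 1)  # all 1 on a ramp
#' @export
lbpCodes1d <- function(segment, radius = 1L, neighborsPerSide = 1L) {
    radius <- as.integer(radius)
    nps <- as.integer(neighborsPerSide)
    stopifnot(radius >= 1L, nps >= 1L)
    span <- radius * nps
    L <- length(segment)
    if (L <= 2L * span)
        stop(sprintf("segment too short for LBP: %d samples, need more than %d (2 * radius * neighborsPerSide)",
                     L, 2L * span))
    centers <- (span + 1L):(L - span)
    ctr <- segment[centers]
    offsets <- c(-(nps:1L) * radius, (1L:nps) * radius)
    code <- integer(length(centers))
    for (off in offsets)
        code <- code * 2L + as.integer(segment[centers + off] >= ctr)
    code
}

# window start positions over a code series of length L: full windows with
# the given stride; a window longer than the series collapses to one window
# spanning everything
.lbpWindows <- function(L, window, stride) {
    if (window >= L) return(list(starts = 1L, width = L))
    list(starts = seq(1L, L - window + 1L, by = stride), width = window)
}

#' Feature dimension implied by an LbpConfig
#'
#' `d = sum over radii of nWindows(radius) * 2^(2*neighborsPerSide)`, where
#' the code series at radius R has length
#' `segmentLength - 2 * R * neighborsPerSide` and windows of the configured
#' length are tiled with the configured stride (one whole-series window when
#' the series is shorter than the window). The dimension depends only on
#' the configuration and the segment length, never on data values.
#'
#' @param cfg an [LbpConfig-class].
#' @param segmentLength samples per heartbeat.
#' @return Integer feature dimension.
#' @export
lbpFeatureDim <- function(cfg, segmentLength) {
    stopifnot(is(cfg, "LbpConfig"))
    nbins <- as.integer(2^(2 * cfg@neighborsPerSide))
    sum(vapply(cfg@radii, function(rad) {
        L <- segmentLength - 2L * rad * cfg@neighborsPerSide
        if (L < 1L)
            stop(sprintf("segment length %d too short for radius %d", segmentLength, rad))
        length(.lbpWindows(L, cfg@window, cfg@stride)$starts) * nbins
    }, integer(1L)))
}

#' Extract 1DMRLBP histogram features from heartbeat segments
#'
#' Per beat and per radius, the LBP code series is computed, split into
#' (possibly overlapping) windows, and each window is histogrammed over the
#' `2^(2*neighborsPerSide)` possible codes. All histograms are concatenated
#' into one feature column, giving the base feature matrix X consumed by
#' the online learner. With `normalize = TRUE`, each histogram block sums
#' to 1.
#'
#' @param beats a [HeartbeatMatrix-class] or a plain numeric matrix with one
#'   beat per column (all of equal length).
#' @param cfg an [LbpConfig-class].
#' @param labels optional per-beat individual identifiers to attach.
#' @param roundIndex arrival round recorded on the resulting chunk.
#' @return A [FeatureChunk-class] (labels default to "" per column when not
#'   supplied).
#' @examples
#' sim <- simulateEcgRecord(fs = 360, nBeats = 12, seed = 1)
#' beats <- segmentHeartbeats(sim$record, sim$rPeaks, windowLength = 260)
#' fc <- extractLbpFeatures(beats, LbpConfig())
#' @export
extractLbpFeatures <- function(beats, cfg = LbpConfig(), labels = NULL,
                               roundIndex = 1L) {
    seg <- if (is(beats, "HeartbeatMatrix")) beatMatrix(beats) else as.matrix(beats)
    if (!is.numeric(seg)) stop("beats must be numeric")
    Lseg <- nrow(seg)
    if (cfg@window > Lseg)
        stop("histogram window exceeds the segment length")
    nbins <- as.integer(2^(2 * cfg@neighborsPerSide))
    d <- lbpFeatureDim(cfg, Lseg)
    n <- ncol(seg)
    X <- matrix(0, d, n)
    for (j in seq_len(n)) {
        col <- numeric(0)
        for (rad in cfg@radii) {
            codes <- lbpCodes1d(seg[, j], rad, cfg@neighborsPerSide)
            w <- .lbpWindows(length(codes), cfg@window, cfg@stride)
            for (s in w$starts) {
                h <- tabulate(codes[s:(s + w$width - 1L)] + 1L, nbins)
                if (cfg@normalize) h <- h / sum(h)
                col <- c(col, h)
            }
        }
        X[, j] <- col
    }
    if (is.null(labels)) labels <- rep("", n)
    FeatureChunk(X, labels, roundIndex)
}
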