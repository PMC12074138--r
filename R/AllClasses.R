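#' @import methods
#' @importFrom stats rnorm sd
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' EcgRecord: a single-lead ECG trace
#'
#' Container for one raw ECG voltage series together with its sampling rate.
#' Units of the samples are arbitrary; all downstream processing is
#' amplitude-shift tolerant.
#'
#' @slot samples numeric vector of sampled voltages.
#' @slot fs sampling rate in Hz (> 0).
#' @slot recordId opaque identifier, used only for reporting.
#'
#' @seealso [EcgRecord()], [detectRPeaks()], [segmentHeartbeats()]
#' @exportClass EcgRecord
setClass("EcgRecord",
    representation(samples = "numeric", fs = "numeric", recordId = "character"),
    prototype(recordId = "record"))

setValidity("EcgRecord", function(object) {
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        return("'fs' must be a single positive number (Hz)")
    if (length(object@samples) < 2L)
        return("'samples' must contain at least 2 values")
    TRUE
})

#' Construct an EcgRecord
#'
#' @param samples numeric vector of sampled voltages.
#' @param fs sampling rate in Hz.
#' @param recordId identifier string.
#' @return An [EcgRecord-class] object.
#' @examples
#' rec <- EcgRecord(sin(seq(0, 10, by = 1 / 360)), fs = 360)
#' @export
EcgRecord <- function(samples, fs, recordId = "record") {
    new("EcgRecord", samples = as.numeric(samples), fs = as.numeric(fs),
        recordId = as.character(recordId))
}

#' HeartbeatMatrix: fixed-length heartbeat segments
#'
#' One column per retained heartbeat, each a verbatim window of the source
#' record centred (up to the configured offset) on a detected R peak.
#'
#' @slot segments numeric matrix, windowLength x nBeats.
#' @slot rPeaks integer vector of R-peak sample indices into the source
#'   record, one per retained beat, strictly increasing.
#' @slot windowLength samples per beat.
#' @slot nDropped number of beats discarded because their window crossed a
#'   record boundary.
#' @slot fs sampling rate of the source record (Hz).
#'
#' @exportClass HeartbeatMatrix
setClass("HeartbeatMatrix",
    representation(segments = "matrix", rPeaks = "integer",
        windowLength = "integer", nDropped = "integer", fs = "numeric"))

setValidity("HeartbeatMatrix", function(object) {
    if (nrow(object@segments) != object@windowLength)
        return("segment rows must equal windowLength")
    if (ncol(object@segments) != length(object@rPeaks))
        return("one rPeak per segment column required")
    if (length(object@rPeaks) > 1L && any(diff(object@rPeaks) <= 0L))
        return("rPeaks must be strictly increasing")
    TRUE
})

#' LbpConfig: 1-D multi-resolution LBP settings
#'
#' @slot radii distinct positive integer sample offsets (one code series per
#'   radius).
#' @slot neighborsPerSide number of neighbours compared on each side of the
#'   centre sample, at multiples of the radius.
#' @slot window histogram window length, in code samples.
#' @slot stride window step, in code samples.
#' @slot normalize if TRUE each histogram block is scaled to sum to 1.
#'
#' @exportClass LbpConfig
setClass("LbpConfig",
    representation(radii = "integer", neighborsPerSide = "integer",
        window = "integer", stride = "integer", normalize = "logical"))

setValidity("LbpConfig", function(object) {
    if (length(object@radii) < 1L || any(object@radii < 1L))
        return("all radii must be >= 1")
    if (anyDuplicated(object@radii)) return("radii must be distinct")
    if (object@neighborsPerSide < 1L) return("neighborsPerSide must be >= 1")
    if (object@window < 1L || object@stride < 1L)
        return("window and stride must be >= 1")
    TRUE
})

#' Construct an LbpConfig
#'
#' Defaults follow the multi-resolution convention: three radii, two
#' neighbours per side (16-bin histograms), 64-sample windows with 50%
#' overlap, normalised blocks.
#'
#' @param radii integer vector of radii.
#' @param neighborsPerSide neighbours per side.
#' @param window histogram window length.
#' @param stride histogram window step.
#' @param normalize normalise each histogram block to sum 1.
#' @return An [LbpConfig-class] object.
#' @export
LbpConfig <- function(radii = c(1L, 2L, 4L), neighborsPerSide = 2L,
                      window = 64L, stride = 32L, normalize = TRUE) {
    new("LbpConfig", radii = as.integer(radii),
        neighborsPerSide = as.integer(neighborsPerSide),
        window = as.integer(window), stride = as.integer(stride),
        normalize = isTRUE(normalize))
}

#' FeatureChunk: one round of labeled feature columns
#'
#' The unit of arrival in the streaming protocol: a d x n feature matrix
#' whose columns are samples, with one individual label per column.
#'
#' @slot X numeric matrix, d x n (columns are samples).
#' @slot labels character vector of individual identifiers, length n.
#' @slot roundIndex arrival round, >= 1.
#'
#' @exportClass FeatureChunk
setClass("FeatureChunk",
    representation(X = "matrix", labels = "character", roundIndex = "integer"))

setValidity("FeatureChunk", function(object) {
    if (anyNA(object@X) || !all(is.finite(object@X)))
        return("feature matrix must be finite with no missing values")
    if (ncol(object@X) != length(object@labels))
        return("one label per feature column required")
    if (object@roundIndex < 1L) return("roundIndex must be >= 1")
    TRUE
})

#' Construct a FeatureChunk
#'
#' @param X numeric matrix, features in rows, samples in columns.
#' @param labels per-column individual identifiers.
#' @param roundIndex arrival round (>= 1).
#' @return A [FeatureChunk-class] object.
#' @export
FeatureChunk <- function(X, labels, roundIndex = 1L) {
    X <- as.matrix(X)
    dimnames(X) <- NULL
    new("FeatureChunk", X = X, labels = as.character(labels),
        roundIndex = as.integer(roundIndex))
}

#' HadamardCodebook: fixed class codes for prototype learning
#'
#' Rows of a Sylvester Hadamard matrix serve as maximally separated,
#' mutually orthogonal target codes, one per enrolled individual. Codes are
#' assigned in first-appearance order, so replaying the same labeled stream
#' reproduces the same codebook without any seed.
#'
#' @slot H full 2^k x 2^k Hadamard matrix (+1/-1).
#' @slot k log2 of the Hadamard order.
#' @slot r code dimension actually used; when r < 2^k the first r columns of
#'   each row are taken (orthogonality then holds only approximately).
#' @slot assignment named integer vector mapping individual id to row index
#'   (1-based).
#'
#' @exportClass HadamardCodebook
setClass("HadamardCodebook",
    representation(H = "matrix", k = "integer", r = "integer",
        assignment = "integer"))

setValidity("HadamardCodebook", function(object) {
    n <- 2L^object@k
    if (nrow(object@H) != n || ncol(object@H) != n)
        return("H must be 2^k x 2^k")
    if (object@r < 1L || object@r > n)
        return("code dimension r must lie in [1, 2^k]")
    if (anyDuplicated(object@assignment))
        return("assignment must be injective (one row per individual)")
    if (length(object@assignment) &&
        (max(object@assignment) > n || min(object@assignment) < 1L))
        return("assigned rows out of range")
    TRUE
})

#' MemoryBank: per-individual running means of representations
#'
#' The memory-enhancement store: one row per individual ever seen, holding
#' the running mean of all latent representations that individual has
#' produced, together with the count it is based on. Memory size therefore
#' scales with the number of individuals, never with the number of samples.
#'
#' @slot ids individual identifiers in first-appearance order.
#' @slot counts number of representations absorbed per individual.
#' @slot means numeric matrix, length(ids) x r, row i = running mean for
#'   ids[i].
#'
#' @exportClass MemoryBank
setClass("MemoryBank",
    representation(ids = "character", counts = "numeric", means = "matrix"))

setValidity("MemoryBank", function(object) {
    if (length(object@ids) != length(object@counts) ||
        length(object@ids) != nrow(object@means))
        return("ids, counts and mean rows must align")
    if (anyDuplicated(object@ids)) return("ids must be distinct")
    if (length(object@counts) && any(object@counts < 1))
        return("counts must all be >= 1")
    TRUE
})

#' Create an empty MemoryBank
#'
#' @param r latent dimension of the stored means.
#' @return A [MemoryBank-class] with zero rows.
#' @export
emptyMemoryBank <- function(r) {
    new("MemoryBank", ids = character(0), counts = numeric(0),
        means = matrix(0, 0L, as.integer(r)))
}

#' OnlineHyper: hyperparameters of the online learner
#'
#' Trade-off weights and control settings for the per-chunk alternating
#' optimisation. Defaults are the reference operating point: all weights 1
#' except the ridge weight delta = 0.01, latent dimension r = 128 (tied to a
#' 2^7 Hadamard codebook), T = 6 alternating iterations per chunk.
#'
#' @slot alpha weight of the forward regression (features -> latent).
#' @slot beta weight of the backward regression (latent -> features).
#' @slot gamma weight of the prototype/code agreement term.
#' @slot theta weight pulling representations toward their prototypes.
#' @slot eta weight of the memory-enhancement term.
#' @slot delta ridge regularisation weight on W and G.
#' @slot r latent dimension.
#' @slot iterations alternating iterations per chunk (T).
#' @slot seed base RNG seed; each round derives its own sub-seed.
#' @slot bidirectional enable the bidirectional-regression module.
#' @slot prototypes enable the prototype-learning module.
#' @slot memory enable the memory-enhancement module.
#' @slot paperFormulaV if TRUE the V update uses the printed bracket
#'   (alpha+theta+eta)I; the default FALSE uses the exact minimiser bracket
#'   (alpha+theta)I + eta Vm'Vm (see the methods vignette).
#'
#' @exportClass OnlineHyper
setClass("OnlineHyper",
    representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
        theta = "numeric", eta = "numeric", delta = "numeric",
        r = "integer", iterations = "integer", seed = "integer",
        bidirectional = "logical", prototypes = "logical",
        memory = "logical", paperFormulaV = "logical"))

setValidity("OnlineHyper", function(object) {
    w <- c(object@alpha, object@beta, object@gamma, object@theta,
           object@eta, object@delta)
    if (any(!is.finite(w)) || any(w < 0))
        return("all trade-off weights must be finite and non-negative")
    if (object@bidirectional && object@alpha + object@beta <= 0)
        return("alpha + beta must be > 0 when the bidirectional module is on")
    if (object@r < 1L) return("latent dimension r must be >= 1")
    if (object@iterations < 1L) return("iterations (T) must be >= 1")
    TRUE
})

#' Construct an OnlineHyper
#'
#' @param alpha,beta,gamma,theta,eta,delta non-negative trade-off weights.
#' @param r latent dimension.
#' @param iterations alternating iterations per chunk.
#' @param seed base RNG seed for the random initialisation.
#' @param bidirectional,prototypes,memory module toggles.
#' @param paperFormulaV use the printed V-update bracket instead of the
#'   exact sub-problem minimiser (for comparison only).
#' @return An [OnlineHyper-class] object.
#' @export
OnlineHyper <- function(alpha = 1, beta = 1, gamma = 1, theta = 1, eta = 1,
                        delta = 0.01, r = 128L, iterations = 6L, seed = 1L,
                        bidirectional = TRUE, prototypes = TRUE,
                        memory = TRUE, paperFormulaV = FALSE) {
    new("OnlineHyper", alpha = alpha, beta = beta, gamma = gamma,
        theta = theta, eta = eta, delta = delta, r = as.integer(r),
        iterations = as.integer(iterations), seed = as.integer(seed),
        bidirectional = isTRUE(bidirectional),
        prototypes = isTRUE(prototypes), memory = isTRUE(memory),
        paperFormulaV = isTRUE(paperFormulaV))
}

#' SufficientStats: frozen cumulative cross-products
#'
#' The entire influence of past rounds on the regression updates flows
#' through three cumulative matrices: C1 = sum_t X_t X_t', C2 = sum_t X_t
#' V_t, C3 = sum_t V_t' V_t, with the per-round V frozen at its converged
#' value. Storage is O(d^2 + d r + r^2) regardless of stream length.
#'
#' @slot C1 d x d cumulative feature Gram matrix.
#' @slot C2 d x r cumulative feature-latent cross-product.
#' @slot C3 r x r cumulative latent Gram matrix.
#' @slot roundsAbsorbed number of rounds folded in.
#'
#' @exportClass SufficientStats
setClass("SufficientStats",
    representation(C1 = "matrix", C2 = "matrix", C3 = "matrix",
        roundsAbsorbed = "integer"))

setValidity("SufficientStats", function(object) {
    if (nrow(object@C1) != ncol(object@C1)) return("C1 must be square")
    if (nrow(object@C3) != ncol(object@C3)) return("C3 must be square")
    if (nrow(object@C2) != nrow(object@C1) || ncol(object@C2) != nrow(object@C3))
        return("C2 must be d x r, consistent with C1 and C3")
    TRUE
})

#' Create zeroed SufficientStats
#'
#' @param d feature dimension.
#' @param r latent dimension.
#' @return A [SufficientStats-class] object with all-zero matrices.
#' @export
emptyStats <- function(d, r) {
    new("SufficientStats", C1 = matrix(0, d, d), C2 = matrix(0, d, r),
        C3 = matrix(0, r, r), roundsAbsorbed = 0L)
}

#' OnlineModel: state of the online learner
#'
#' Everything the learner carries between rounds: the bidirectional
#' projection matrices, the frozen sufficient statistics, the Hadamard
#' codebook, the memory bank, and a per-iteration objective log.
#'
#' @slot W d x r projection matrix (features -> latent space).
#' @slot G d x r reconstruction matrix (latent -> features).
#' @slot stats [SufficientStats-class] accumulated over all absorbed rounds.
#' @slot codebook [HadamardCodebook-class] with the id -> code assignment.
#' @slot memory [MemoryBank-class] of per-individual mean representations.
#' @slot hyper [OnlineHyper-class] settings the model was trained with.
#' @slot round number of rounds absorbed so far.
#' @slot d,r dimensions.
#' @slot log data.frame of per-update objective values
#'   (round, iter, step, objective).
#'
#' @exportClass OnlineModel
setClass("OnlineModel",
    representation(W = "matrix", G = "matrix", stats = "SufficientStats",
        codebook = "HadamardCodebook", memory = "MemoryBank",
        hyper = "OnlineHyper", round = "integer", d = "integer",
        r = "integer", log = "data.frame"))

setValidity("OnlineModel", function(object) {
    if (nrow(object@W) != object@d || ncol(object@W) != object@r)
        return("W must be d x r")
    if (nrow(object@G) != object@d || ncol(object@G) != object@r)
        return("G must be d x r")
    if (!all(is.finite(object@W)) || !all(is.finite(object@G)))
        return("W and G must be finite")
    TRUE
})

#' ChunkLatents: per-round working matrices
#'
#' The latent quantities produced while absorbing one chunk: learned
#' representations V, prototype rows R, Hadamard code rows H, the pairwise
#' same-individual matrix A, and the memory similarity matrix S. Old-round
#' matrices are deliberately never kept; their influence lives entirely in
#' [SufficientStats-class].
#'
#' @slot V n x r learned representations.
#' @slot R n x r prototype rows (rows equal within an individual).
#' @slot H n x r assigned Hadamard code rows.
#' @slot A n x n 0/1 same-individual matrix (symmetric, unit diagonal).
#' @slot S cOld x n 0/1 memory similarity matrix (at most one 1 per column).
#'
#' @exportClass ChunkLatents
setClass("ChunkLatents",
    representation(V = "matrix", R = "matrix", H = "matrix",
        A = "matrix", S = "matrix"))

#' Gallery: enrolled representations for matching
#'
#' @slot reps m x r matrix of registered-sample representations.
#' @slot labels per-row individual identifiers.
#' @slot mode "per-sample" (every registered sample kept) or
#'   "per-class-mean" (one averaged row per individual).
#'
#' @exportClass Gallery
setClass("Gallery",
    representation(reps = "matrix", labels = "character", mode = "character"))

setValidity("Gallery", function(object) {
    if (nrow(object@reps) != length(object@labels))
        return("one label per gallery row required")
    if (!all(is.finite(object@reps))) return("gallery must be finite")
    if (!object@mode %in% c("per-sample", "per-class-mean"))
        return("mode must be 'per-sample' or 'per-class-mean'")
    TRUE
})
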