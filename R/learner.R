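#' @section Online learner:
#' The learner maintains projection matrices W (features to latent space)
#' and G (latent space back to features) plus three cumulative sufficient
#' statistics; each arriving chunk is absorbed by T alternating closed-form
#' updates of W, G, the prototype rows R and the representations V. Past
#' raw data are never revisited: their whole influence is carried by the
#' statistics.
#' @name learner-internal
#' @keywords internal
NULL

# Symmetric positive-definite solve A X = B via Cholesky; optional jitter
# fallback (+ scaled 1e-10 on the diagonal) when the factorisation fails.
.solveSPD <- function(A, B, allowJitter = TRUE) {
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
        if (!allowJitter)
            stop("bracket matrix is singular and no regulariser applies")
        jit <- 1e-10 * (mean(abs(diag(A))) + 1)
        ch <- chol(A + jit * diag(nrow(A)))
    }
    backsolve(ch, forwardsolve(t(ch), B))
}

# module toggles applied to the trade-off weights
.effWeights <- function(hyper) {
    list(
        alpha = if (hyper@bidirectional) hyper@alpha else 0,
        beta  = if (hyper@bidirectional) hyper@beta else 0,
        gamma = if (hyper@prototypes) hyper@gamma else 0,
        theta = if (hyper@prototypes) hyper@theta else 0,
        eta   = if (hyper@memory) hyper@eta else 0,
        delta = hyper@delta)
}

.checkFinite <- function(...) {
    args <- list(...)
    for (nm in names(args))
        if (!all(is.finite(args[[nm]])))
            stop(sprintf("non-finite values in '%s'", nm))
    invisible(TRUE)
}

#' Pairwise same-individual matrix
#'
#' A[i, j] = 1 when samples i and j carry the same label, else 0;
#' symmetric with unit diagonal.
#'
#' @param labels per-sample individual identifiers.
#' @return An n x n 0/1 matrix.
#' @examples
#' pairwiseLabelMatrix(c("a", "a", "b"))
#' @export
pairwiseLabelMatrix <- function(labels) {
    labels <- as.character(labels)
    if (!length(labels)) stop("labels must be non-empty")
    outer(labels, labels, "==") * 1
}

#' Memory similarity matrix
#'
#' S[c, i] = 1 when the i-th new sample belongs to the c-th remembered
#' individual; columns of brand-new individuals are all zero, so each
#' column holds at most one 1.
#'
#' @param labels per-sample identifiers of the new chunk.
#' @param memoryIds distinct identifiers already in the memory bank, in
#'   bank order.
#' @return A `length(memoryIds)` x `length(labels)` 0/1 matrix (0 rows when
#'   the memory is empty).
#' @export
memorySimilarityMatrix <- function(labels, memoryIds) {
    labels <- as.character(labels)
    memoryIds <- as.character(memoryIds)
    if (anyDuplicated(memoryIds)) stop("memoryIds must be distinct")
    if (!length(memoryIds)) return(matrix(0, 0L, length(labels)))
    outer(memoryIds, labels, "==") * 1
}

#' Closed-form update of the projection matrix W
#'
#' Exact minimiser of the forward-regression sub-problem over old and new
#' data, `alpha * sum_t ||V_t - X_t' W||_F^2 + delta * ||W||_F^2`, via the
#' ridge normal equations `W = (C1 + (delta/alpha) I)^-1 C2` with
#' `C1 = C1_prev + X X'` and `C2 = C2_prev + X V` (prior-round parts come
#' frozen in `stats`). Solved by a symmetric positive-definite
#' factorisation, never an explicit inverse.
#'
#' @param stats [SufficientStats-class] frozen up to the previous round.
#' @param X d x n feature matrix of the current chunk.
#' @param V n x r current representations of the chunk.
#' @param hyper an [OnlineHyper-class]; requires `alpha > 0`.
#' @return The d x r matrix W.
#' @export
updateW <- function(stats, X, V, hyper) {
    if (hyper@alpha <= 0) stop("updateW requires alpha > 0")
    .checkFinite(X = X, V = V)
    C1 <- stats@C1 + tcrossprod(X)
    C2 <- stats@C2 + X %*% V
    .solveSPD(C1 + (hyper@delta / hyper@alpha) * diag(nrow(C1)), C2)
}

#' Closed-form update of the reconstruction matrix G
#'
#' Exact minimiser of `beta * sum_t ||X_t - G V_t'||_F^2 +
#' delta * ||G||_F^2`: `G = C2 (C3 + (delta/beta) I)^-1` with
#' `C3 = C3_prev + V'V`.
#'
#' @inheritParams updateW
#' @return The d x r matrix G.
#' @export
updateG <- function(stats, X, V, hyper) {
    if (hyper@beta <= 0) stop("updateG requires beta > 0")
    .checkFinite(X = X, V = V)
    C2 <- stats@C2 + X %*% V
    C3 <- stats@C3 + crossprod(V)
    t(.solveSPD(C3 + (hyper@delta / hyper@beta) * diag(nrow(C3)), t(C2)))
}

#' Closed-form update of the prototype rows R
#'
#' Exact minimiser of `theta * ||R - V||_F^2 + gamma * ||A - H R'||_F^2`:
#' `R = (theta V + gamma A' H) (theta I + gamma H'H)^-1`. With `gamma = 0`
#' this collapses to `R = V`; with `theta = 0` the bracket must be full
#' rank, otherwise an error is raised.
#'
#' @param V n x r representations.
#' @param A n x n same-individual matrix.
#' @param H n x r Hadamard code rows.
#' @param hyper an [OnlineHyper-class].
#' @return The n x r prototype matrix R.
#' @export
updateR <- function(V, A, H, hyper) {
    theta <- hyper@theta
    gamma <- hyper@gamma
    if (theta + gamma <= 0) stop("updateR requires theta + gamma > 0")
    .checkFinite(V = V, A = A, H = H)
    if (gamma == 0) return(V)
    r <- ncol(V)
    bracket <- theta * diag(r) + gamma * crossprod(H)
    t(.solveSPD(bracket, t(theta * V + gamma * crossprod(A, H)),
                allowJitter = theta > 0))
}

#' Closed-form update of the representations V
#'
#' Exact minimiser of the per-chunk sub-problem
#' `alpha ||V - X'W||^2 + beta ||X - G V'||^2 + theta ||R - V||^2 +
#' eta ||S - Vm V'||^2`:
#' `V = (alpha X'W + beta X'G + theta R + eta S'Vm) *
#' ((alpha + theta) I + beta G'G + eta Vm'Vm)^-1`.
#' With `paperFormulaV = TRUE` the bracket carries an additional `eta * I`
#' (the printed closed form); both modes coincide whenever the memory is
#' empty. Weights honour the module toggles in `hyper`.
#'
#' @param X d x n feature matrix of the chunk.
#' @param W,G current d x r projection and reconstruction matrices.
#' @param R n x r prototype rows.
#' @param S cOld x n memory similarity matrix (0 rows when memory empty).
#' @param Vm cOld x r memory matrix of stored means.
#' @param hyper an [OnlineHyper-class].
#' @return The n x r representation matrix V.
#' @export
updateV <- function(X, W, G, R, S, Vm, hyper) {
    w <- .effWeights(hyper)
    .checkFinite(X = X, W = W, G = G, R = R)
    r <- ncol(W)
    n <- ncol(X)
    useMem <- w$eta > 0 && nrow(Vm) > 0L
    num <- matrix(0, n, r)
    bracket <- (w$alpha + w$theta) * diag(r)
    if (w$alpha > 0) num <- num + w$alpha * crossprod(X, W)
    if (w$beta > 0) {
        num <- num + w$beta * crossprod(X, G)
        bracket <- bracket + w$beta * crossprod(G)
    }
    if (w$theta > 0) num <- num + w$theta * R
    if (useMem) {
        num <- num + w$eta * crossprod(S, Vm)
        bracket <- bracket + w$eta * crossprod(Vm)
        if (hyper@paperFormulaV) bracket <- bracket + w$eta * diag(r)
    }
    t(.solveSPD(bracket, t(num)))
}

#' Per-round objective value
#'
#' Evaluates the overall objective for the current round:
#' `alpha ||V - X'W||^2 + beta ||X - G V'||^2 + gamma ||A - H R'||^2 +
#' theta ||R - V||^2 + eta ||S - Vm V'||^2 + delta (||W||^2 + ||G||^2)`
#' (squared Frobenius norms throughout, weights after module toggles).
#' When `statsPrev` is supplied, the old-data regression residuals --
#' constant in this round's V and R but not in W and G -- are added from
#' the frozen statistics:
#' `alpha (tr C3p - 2 tr(W'C2p) + tr(W'C1p W)) +
#'  beta (tr C1p - 2 tr(G'C2p) + tr(G C3p G'))`,
#' which makes the returned value the full streaming objective and hence a
#' quantity that every one of the four closed-form updates can only
#' decrease.
#'
#' @param X d x n chunk features.
#' @param W,G current projection/reconstruction matrices.
#' @param latents a [ChunkLatents-class] (V, R, H, A, S).
#' @param Vm cOld x r memory matrix.
#' @param hyper an [OnlineHyper-class].
#' @param statsPrev optional [SufficientStats-class] frozen before this
#'   round.
#' @param breakdown if TRUE, return a named vector of per-term values
#'   (whose sum is the objective) instead of the scalar.
#' @return Scalar objective value (or named breakdown).
#' @export
chunkObjective <- function(X, W, G, latents, Vm, hyper, statsPrev = NULL,
                           breakdown = FALSE) {
    w <- .effWeights(hyper)
    V <- latents@V; R <- latents@R; H <- latents@H
    A <- latents@A; S <- latents@S
    useMem <- w$eta > 0 && nrow(Vm) > 0L
    terms <- c(
        alpha = w$alpha * sum((V - crossprod(X, W))^2),
        beta  = w$beta * sum((X - G %*% t(V))^2),
        gamma = w$gamma * sum((A - H %*% t(R))^2),
        theta = w$theta * sum((R - V)^2),
        eta   = if (useMem) w$eta * sum((S - Vm %*% t(V))^2) else 0,
        delta = w$delta * (sum(W^2) + sum(G^2)),
        old   = 0)
    if (!is.null(statsPrev) && statsPrev@roundsAbsorbed > 0L) {
        C1p <- statsPrev@C1; C2p <- statsPrev@C2; C3p <- statsPrev@C3
        oldA <- w$alpha * (sum(diag(C3p)) - 2 * sum(W * C2p) +
                           sum(W * (C1p %*% W)))
        oldB <- w$beta * (sum(diag(C1p)) - 2 * sum(G * C2p) +
                          sum(G * (G %*% C3p)))
        terms["old"] <- oldA + oldB
    }
    if (breakdown) terms else sum(terms)
}

#' Create a fresh OnlineModel
#'
#' Initialises zeroed projection matrices and sufficient statistics, an
#' empty memory bank, and (unless supplied) a Hadamard codebook of the
#' smallest order with at least `r` columns.
#'
#' @param d feature dimension of the stream.
#' @param hyper an [OnlineHyper-class].
#' @param codebook optional [HadamardCodebook-class]; its code dimension
#'   must equal `hyper@r`.
#' @return An [OnlineModel-class] at round 0.
#' @examples
#' m <- newOnlineModel(d = 40, hyper = OnlineHyper(r = 16))
#' m
#' @export
newOnlineModel <- function(d, hyper = OnlineHyper(), codebook = NULL) {
    d <- as.integer(d)
    r <- hyper@r
    if (is.null(codebook)) {
        k <- as.integer(ceiling(log2(max(r, 1L))))
        codebook <- suppressWarnings(hadamardCodebook(k, r))
    }
    if (codebook@r != r)
        stop("codebook code dimension must equal hyper@r")
    new("OnlineModel", W = matrix(0, d, r), G = matrix(0, d, r),
        stats = emptyStats(d, r), codebook = codebook,
        memory = emptyMemoryBank(r), hyper = hyper, round = 0L,
        d = d, r = r,
        log = data.frame(round = integer(0), iter = integer(0),
            step = character(0), objective = numeric(0)))
}

# deterministic per-round sub-seed, kept inside 32-bit integer range
.roundSeed <- function(seed, round) {
    as.integer((as.double(seed) * 48271 + as.double(round) * 16807) %%
               2147483647)
}

#' Absorb one chunk: the per-round online optimisation
#'
#' Runs the four-step alternating optimisation for one arriving chunk:
#' the pairwise matrix A, Hadamard code rows H and memory similarity S are
#' built, V and R are randomly initialised (Normal(0, 0.01), seeded from
#' the model seed and the round number), then T iterations update, in
#' order, W, G, R and V -- each the exact closed-form minimiser of its
#' sub-problem, so the full streaming objective is non-increasing after
#' every step. Within a round, the chunk's contribution to C1 is fixed
#' while its contributions to C2 and C3 are recomputed from the latest V;
#' prior-round statistics are immutable. On exit the statistics are frozen
#' with the converged V, the memory bank absorbs the new representations,
#' and the round counter advances.
#'
#' When the bidirectional-regression module is toggled off, V is driven by
#' prototypes and memory only; W is then fitted once after convergence as a
#' ridge regression from features to representations, purely so that
#' matching still has a projection to use (G stays zero).
#'
#' @param model an [OnlineModel-class].
#' @param chunk a [FeatureChunk-class] with `nrow(X) == model d`.
#' @return A list with elements `model` (updated) and `latents`
#'   ([ChunkLatents-class]).
#' @examples
#' stream <- simulateFeatureStream(nIndividuals = 5, chunkSizes = c(20, 20),
#'                                 d = 12, seed = 1)
#' m <- newOnlineModel(d = 12, hyper = OnlineHyper(r = 8, seed = 1))
#' m <- trainChunk(m, stream$chunks[[1]])$model
#' @export
trainChunk <- function(model, chunk) {
    stopifnot(is(model, "OnlineModel"), is(chunk, "FeatureChunk"))
    X <- chunk@X
    labels <- chunk@labels
    if (nrow(X) != model@d)
        stop(sprintf("chunk dimension %d does not match model dimension %d",
                     nrow(X), model@d))
    hyper <- model@hyper
    w <- .effWeights(hyper)
    n <- ncol(X)
    r <- model@r
    round <- model@round + 1L

    model@codebook <- assignCodes(model@codebook, labels)
    A <- pairwiseLabelMatrix(labels)
    H <- chunkCodeMatrix(model@codebook, labels)
    mem <- memoryMatrix(model@memory)
    S <- memorySimilarityMatrix(labels, mem$ids)
    Vm <- mem$Vm

    set.seed(.roundSeed(hyper@seed, round))
    V <- matrix(stats::rnorm(n * r, 0, 0.01), n, r)
    R <- matrix(stats::rnorm(n * r, 0, 0.01), n, r)
    W <- model@W
    G <- model@G
    if (model@round == 0L) {
        W <- matrix(stats::rnorm(model@d * r, 0, 0.01), model@d, r)
        G <- matrix(stats::rnorm(model@d * r, 0, 0.01), model@d, r)
    }

    statsPrev <- model@stats
    C1cur <- statsPrev@C1 + tcrossprod(X)  # chunk part fixed for the round

    logRows <- list()
    obj <- function(iter, step) {
        lat <- new("ChunkLatents", V = V, R = R, H = H, A = A, S = S)
        val <- chunkObjective(X, W, G, lat, Vm, hyper, statsPrev)
        logRows[[length(logRows) + 1L]] <<- data.frame(round = round,
            iter = iter, step = step, objective = val)
        val
    }
    obj(0L, "init")

    for (iter in seq_len(hyper@iterations)) {
        if (w$alpha > 0) {
            C2cur <- statsPrev@C2 + X %*% V
            W <- .solveSPD(C1cur + (w$delta / w$alpha) * diag(model@d), C2cur)
            obj(iter, "W")
        }
        if (w$beta > 0) {
            C2cur <- statsPrev@C2 + X %*% V
            C3cur <- statsPrev@C3 + crossprod(V)
            G <- t(.solveSPD(C3cur + (w$delta / w$beta) * diag(r), t(C2cur)))
            obj(iter, "G")
        }
        if (hyper@prototypes) {
            R <- updateR(V, A, H, hyper)
            obj(iter, "R")
        }
        V <- updateV(X, W, G, R, S, Vm, hyper)
        obj(iter, "V")
    }

    # refresh W and G against the converged V so the stored model satisfies
    # the ridge normal equations of the frozen statistics (online = batch);
    # each refresh is an exact sub-problem minimiser, so the objective can
    # only decrease further
    if (w$alpha > 0) {
        C2cur <- statsPrev@C2 + X %*% V
        W <- .solveSPD(C1cur + (w$delta / w$alpha) * diag(model@d), C2cur)
        obj(hyper@iterations + 1L, "W")
    }
    if (w$beta > 0) {
        C2cur <- statsPrev@C2 + X %*% V
        C3cur <- statsPrev@C3 + crossprod(V)
        G <- t(.solveSPD(C3cur + (w$delta / w$beta) * diag(r), t(C2cur)))
        obj(hyper@iterations + 1L, "G")
    }
    if (w$alpha == 0) {
        # matching needs a projection even without the forward regression:
        # fit W once, after convergence, as a ridge from features to V
        C2cur <- statsPrev@C2 + X %*% V
        W <- .solveSPD(C1cur + w$delta * diag(model@d), C2cur)
        if (w$beta == 0) G <- matrix(0, model@d, r)
    }

    model@W <- W
    model@G <- G
    model@stats <- new("SufficientStats", C1 = C1cur,
        C2 = statsPrev@C2 + X %*% V, C3 = statsPrev@C3 + crossprod(V),
        roundsAbsorbed = statsPrev@roundsAbsorbed + 1L)
    model@memory <- updateMemory(model@memory, V, labels)
    model@round <- round
    model@log <- rbind(model@log, do.call(rbind, logRows))
    validObject(model)
    list(model = model,
         latents = new("ChunkLatents", V = V, R = R, H = H, A = A, S = S))
}
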