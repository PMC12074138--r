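# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: brute-force loops, naive norm summations,
# and a conjugate-gradient minimiser that only ever sees an objective
# function and its gradient.

# Fletcher-Reeves conjugate gradient with exact line search for quadratic
# objectives; Hessian-vector products come from gradient differences, so the
# minimiser is independent of any closed-form solution.
cgQuadMin <- function(fn, gr, x0, maxit = NULL, tol = 1e-14) {
    x <- x0
    g <- gr(x)
    p <- -g
    n <- length(x0)
    if (is.null(maxit)) maxit <- 3L * n + 20L
    g0norm <- sqrt(sum(g^2)) + 1e-300
    for (k in seq_len(maxit)) {
        Hp <- gr(x + p) - gr(x)          # exact for quadratics
        denom <- sum(p * Hp)
        if (denom <= 0) break
        alpha <- -sum(g * p) / denom
        x <- x + alpha * p
        gNew <- gr(x)
        if (sqrt(sum(gNew^2)) / g0norm < tol) return(x)
        beta <- sum(gNew^2) / sum(g^2)
        p <- -gNew + beta * p
        g <- gNew
        if (k %% n == 0) p <- -g          # periodic restart
    }
    x
}

# central-difference gradient norm of fn at x
fdGradNorm <- function(fn, x, h = 1e-5) {
    g <- vapply(seq_along(x), function(i) {
        e <- numeric(length(x)); e[i] <- h
        (fn(x + e) - fn(x - e)) / (2 * h)
    }, numeric(1))
    sqrt(sum(g^2))
}

# naive double-loop 1-D LBP oracle (documented convention: offsets sorted
# ascending, MSB first, ties >= count as 1)
naiveLbp <- function(segment, radius, nps) {
    span <- radius * nps
    out <- integer(0)
    for (i in (span + 1):(length(segment) - span)) {
        bits <- integer(0)
        for (off in c(-(nps:1) * radius, (1:nps) * radius))
            bits <- c(bits, as.integer(segment[i + off] >= segment[i]))
        code <- 0L
        for (b in bits) code <- code * 2L + b
        out <- c(out, code)
    }
    out
}

# random instance of the per-chunk optimisation problem, with previous-round
# statistics built from an explicit fake old chunk
randomInstance <- function(seed, dMax = 15, nMax = 25, rMax = 8) {
    set.seed(seed)
    d <- sample(5:dMax, 1); n <- sample(6:nMax, 1); r <- sample(2:rMax, 1)
    lab <- sample(letters[1:3], n, replace = TRUE)
    cb <- assignCodes(suppressWarnings(hadamardCodebook(3, r)), letters[1:3])
    Xp <- matrix(rnorm(d * 10), d, 10)
    Vp <- matrix(rnorm(10 * r), 10, r)
    list(d = d, n = n, r = r,
         X = matrix(rnorm(d * n), d, n), V = matrix(rnorm(n * r), n, r),
         W = matrix(rnorm(d * r), d, r), G = matrix(rnorm(d * r), d, r),
         R = matrix(rnorm(n * r), n, r), labels = lab,
         A = pairwiseLabelMatrix(lab), H = chunkCodeMatrix(cb, lab),
         S = memorySimilarityMatrix(lab, c("a", "b")),
         Vm = matrix(rnorm(2 * r), 2, r),
         oldX = Xp, oldV = Vp,
         stats = new("SufficientStats", C1 = tcrossprod(Xp), C2 = Xp %*% Vp,
                     C3 = crossprod(Vp), roundsAbsorbed = 1L),
         hyper = OnlineHyper(alpha = runif(1, 0.3, 2), beta = runif(1, 0.3, 2),
             gamma = runif(1, 0.3, 2), theta = runif(1, 0.3, 2),
             eta = runif(1, 0.3, 2), delta = 0.05, r = r, seed = seed))
}

# explicit sub-objectives and residual-form gradients (never the normal
# equations), shared by the optimality tests
subProblems <- function(inst) {
    with(inst, {
        a <- hyper@alpha; b <- hyper@beta; g0 <- hyper@gamma
        th <- hyper@theta; et <- hyper@eta; de <- hyper@delta
        C1p <- stats@C1; C2p <- stats@C2; C3p <- stats@C3
        list(
        W = list(
            fn = function(w) {
                Wm <- matrix(w, d, r)
                a * (sum((V - crossprod(X, Wm))^2) + sum(diag(C3p)) -
                     2 * sum(Wm * C2p) + sum(Wm * (C1p %*% Wm))) +
                de * sum(Wm^2)
            },
            gr = function(w) {
                Wm <- matrix(w, d, r)
                as.vector(2 * a * (X %*% (crossprod(X, Wm) - V) +
                          C1p %*% Wm - C2p) + 2 * de * Wm)
            },
            closed = function() updateW(stats, X, V, hyper), dim = d * r),
        G = list(
            fn = function(x) {
                Gm <- matrix(x, d, r)
                b * (sum((X - Gm %*% t(V))^2) + sum(diag(C1p)) -
                     2 * sum(Gm * C2p) + sum(Gm * (Gm %*% C3p))) +
                de * sum(Gm^2)
            },
            gr = function(x) {
                Gm <- matrix(x, d, r)
                as.vector(2 * b * ((Gm %*% t(V) - X) %*% V + Gm %*% C3p -
                          C2p) + 2 * de * Gm)
            },
            closed = function() updateG(stats, X, V, hyper), dim = d * r),
        R = list(
            fn = function(x) {
                Rm <- matrix(x, n, r)
                th * sum((Rm - V)^2) + g0 * sum((A - H %*% t(Rm))^2)
            },
            gr = function(x) {
                Rm <- matrix(x, n, r)
                as.vector(2 * th * (Rm - V) +
                          2 * g0 * (Rm %*% crossprod(H) - crossprod(A, H)))
            },
            closed = function() updateR(V, A, H, hyper), dim = n * r),
        V = list(
            fn = function(v) {
                Vv <- matrix(v, n, r)
                a * sum((Vv - crossprod(X, W))^2) +
                b * sum((X - G %*% t(Vv))^2) + th * sum((R - Vv)^2) +
                et * sum((S - Vm %*% t(Vv))^2)
            },
            gr = function(v) {
                Vv <- matrix(v, n, r)
                as.vector(2 * a * (Vv - crossprod(X, W)) +
                    2 * b * (Vv %*% crossprod(G) - crossprod(X, G)) +
                    2 * th * (Vv - R) +
                    2 * et * (Vv %*% crossprod(Vm) - crossprod(S, Vm)))
            },
            closed = function() updateV(X, W, G, R, S, Vm, hyper),
            dim = n * r))
    })
}

# maximum relative objective increase over the per-round log (negative or
# ~0 means monotone descent)
maxRelIncrease <- function(model) {
    lg <- objectiveLog(model)
    max(unlist(tapply(lg$objective, lg$round, function(x)
        diff(x) / pmax(abs(x[-length(x)]), 1e-300))))
}
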