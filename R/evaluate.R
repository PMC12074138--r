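#' Project features into the learned latent space
#'
#' Computes `t(X) %*% W`, one representation row per sample.
#'
#' @param X d x n feature matrix (samples in columns).
#' @param W d x r projection matrix.
#' @return An n x r matrix of representations.
#' @export
projectFeatures <- function(X, W) {
    X <- as.matrix(X); W <- as.matrix(W)
    if (nrow(X) != nrow(W))
        stop(sprintf("feature dimension mismatch: X has %d rows, W has %d",
                     nrow(X), nrow(W)))
    crossprod(X, W)
}

#' Build a matching gallery
#'
#' Registers sample representations for matching, either one row per
#' registered sample ("per-sample", the default) or one averaged row per
#' individual ("per-class-mean").
#'
#' @param reps m x r representation matrix (e.g. from [projectFeatures()]).
#' @param labels per-row individual identifiers.
#' @param mode "per-sample" or "per-class-mean".
#' @return A [Gallery-class].
#' @export
makeGallery <- function(reps, labels, mode = c("per-sample", "per-class-mean")) {
    mode <- match.arg(mode)
    reps <- as.matrix(reps)
    labels <- as.character(labels)
    if (mode == "per-class-mean") {
        ids <- unique(labels)
        reps <- t(vapply(ids,
            function(id) colMeans(reps[labels == id, , drop = FALSE]),
            numeric(ncol(reps))))
        labels <- ids
    }
    new("Gallery", reps = reps, labels = labels, mode = mode)
}

# full Euclidean distance matrix, queries x gallery
.distMatrix <- function(Q, Gal) {
    d2 <- outer(rowSums(Q^2), rowSums(Gal^2), "+") - 2 * tcrossprod(Q, Gal)
    sqrt(pmax(d2, 0))
}

#' Identify queries by nearest gallery neighbour
#'
#' Each query receives the label of the gallery row at the smallest
#' Euclidean distance; exact ties go to the lowest gallery index, and the
#' number of tied queries is reported in the `"nTies"` attribute.
#'
#' @param queryReps nQ x r matrix of query representations.
#' @param gallery a [Gallery-class] (non-empty).
#' @return Character vector of predicted labels, with attribute `nTies`.
#' @export
identifyQueries <- function(queryReps, gallery) {
    stopifnot(is(gallery, "Gallery"))
    if (!nrow(gallery@reps)) stop("gallery is empty")
    queryReps <- as.matrix(queryReps)
    D <- .distMatrix(queryReps, gallery@reps)
    nn <- apply(D, 1L, which.min)           # which.min takes the lowest index
    ties <- sum(apply(D, 1L, function(row) sum(row == min(row)) > 1L))
    pred <- gallery@labels[nn]
    attr(pred, "nTies") <- ties
    pred
}

#' Identification accuracy
#'
#' Percentage of correctly identified samples: `100 * mean(pred == truth)`.
#'
#' @param pred predicted labels.
#' @param truth true labels, same length.
#' @return Accuracy in percent.
#' @export
identificationAccuracy <- function(pred, truth) {
    if (!length(pred)) stop("empty input")
    if (length(pred) != length(truth)) stop("pred and truth lengths differ")
    100 * mean(as.character(pred) == as.character(truth))
}

#' Equal error rate from genuine and impostor distances
#'
#' Sweeps every candidate threshold (the pooled sorted distances). At a
#' threshold tau the false acceptance rate is the fraction of impostor
#' distances strictly below tau and the false rejection rate is the
#' fraction of genuine distances strictly above tau; FAR is non-decreasing
#' and FRR non-increasing in tau, and the EER is their common value at the
#' crossing, linearly interpolated between the bracketing thresholds.
#'
#' @param genuine distances of same-individual comparisons.
#' @param impostor distances of different-individual comparisons.
#' @return List with `eer` (percent) and `threshold`.
#' @examples
#' computeEER(c(1, 3), c(2, 4))$eer   # 25
#' @export
computeEER <- function(genuine, impostor) {
    genuine <- as.numeric(genuine); impostor <- as.numeric(impostor)
    if (!length(genuine) || !length(impostor))
        stop("both genuine and impostor scores are required")
    if (any(c(genuine, impostor) < 0)) stop("distances must be >= 0")
    if (diff(range(c(genuine, impostor))) == 0)
        warning("degenerate scores: all distances equal")
    taus <- sort(unique(c(genuine, impostor)))
    sImp <- sort(impostor); sGen <- sort(genuine)
    far <- findInterval(taus, sImp, left.open = TRUE) / length(impostor)
    frr <- 1 - findInterval(taus, sGen) / length(genuine)
    dif <- far - frr
    i <- which(dif >= 0)[1L]
    if (is.na(i)) {                 # FRR stays above FAR over the whole sweep
        return(list(eer = 100 * frr[length(taus)],
                    threshold = taus[length(taus)]))
    }
    if (dif[i] == 0 || i == 1L)
        return(list(eer = 100 * far[i], threshold = taus[i]))
    # linear interpolation of both rates between the bracketing thresholds
    t1 <- taus[i - 1L]; t2 <- taus[i]
    f1 <- far[i - 1L]; f2 <- far[i]
    g1 <- frr[i - 1L]; g2 <- frr[i]
    s <- (g1 - f1) / ((f2 - f1) - (g2 - g1))
    list(eer = 100 * (f1 + s * (f2 - f1)), threshold = t1 + s * (t2 - t1))
}

#' Verification scores between queries and a gallery
#'
#' Euclidean distances between every query and every gallery row, split
#' into genuine (same individual) and impostor (different individual)
#' score lists for [computeEER()].
#'
#' @param queryReps nQ x r query representations.
#' @param queryLabels per-query identifiers.
#' @param gallery a [Gallery-class].
#' @return List with numeric vectors `genuine` and `impostor`.
#' @export
verificationScores <- function(queryReps, queryLabels, gallery) {
    stopifnot(is(gallery, "Gallery"))
    D <- .distMatrix(as.matrix(queryReps), gallery@reps)
    same <- outer(as.character(queryLabels), gallery@labels, "==")
    list(genuine = D[same], impostor = D[!same])
}

#' Evaluate a trained model on a query set
#'
#' Projects registered and query features with the model's current
#' projection matrix, identifies each query by nearest neighbour, and
#' computes identification accuracy plus verification EER.
#'
#' @param model an [OnlineModel-class].
#' @param galleryX d x m registered feature matrix.
#' @param galleryLabels per-column identifiers of the registered samples.
#' @param queryX d x nQ query feature matrix.
#' @param queryLabels per-column identifiers of the queries.
#' @param galleryMode "per-sample" or "per-class-mean".
#' @return List with `accuracy` (percent), `eer` (percent), `threshold`,
#'   `nQuery`, `nGallery`.
#' @export
evaluateModel <- function(model, galleryX, galleryLabels, queryX, queryLabels,
                          galleryMode = "per-sample") {
    stopifnot(is(model, "OnlineModel"))
    W <- modelProjection(model)
    gal <- makeGallery(projectFeatures(galleryX, W), galleryLabels,
                       galleryMode)
    qr <- projectFeatures(queryX, W)
    pred <- identifyQueries(qr, gal)
    sc <- verificationScores(qr, queryLabels, gal)
    eer <- computeEER(sc$genuine, sc$impostor)
    list(accuracy = identificationAccuracy(pred, queryLabels),
         eer = eer$eer, threshold = eer$threshold,
         nQuery = ncol(as.matrix(queryX)), nGallery = nrow(gal@reps))
}
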