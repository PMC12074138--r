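#' Train on a whole stream of chunks
#'
#' Feeds a list of [FeatureChunk-class]s through [trainChunk()] in arrival
#' order. When a held-out test chunk is supplied, identification accuracy
#' is evaluated after every round with the then-current projection matrix,
#' against a gallery of all training samples seen so far, yielding the
#' accuracy-per-round curve of the streaming protocol.
#'
#' The evaluation gallery re-projects stored registered features; the
#' learner itself touches each chunk only in its own round.
#'
#' @param chunks list of [FeatureChunk-class] in arrival order.
#' @param hyper an [OnlineHyper-class].
#' @param test optional held-out [FeatureChunk-class].
#' @param model optional existing [OnlineModel-class] to continue training.
#' @param galleryMode gallery construction for the per-round evaluation.
#' @return List with `model`, and when `test` is given `perRound`
#'   (data.frame round/accuracy/eer) plus `final` (the last round's
#'   evaluation list).
#' @examples
#' st <- simulateFeatureStream(nIndividuals = 6, chunkSizes = c(24, 24),
#'                             d = 16, seed = 2)
#' fit <- trainStream(st$chunks, OnlineHyper(r = 8, seed = 2),
#'                    test = st$test)
#' fit$perRound
#' @export
trainStream <- function(chunks, hyper = OnlineHyper(), test = NULL,
                        model = NULL, galleryMode = "per-sample") {
    stopifnot(length(chunks) >= 1L)
    d <- nrow(chunkFeatures(chunks[[1L]]))
    if (is.null(model)) model <- newOnlineModel(d, hyper)
    galX <- NULL; galLab <- character(0)
    perRound <- NULL
    final <- NULL
    for (chunk in chunks) {
        model <- trainChunk(model, chunk)$model
        if (!is.null(test)) {
            galX <- cbind(galX, chunkFeatures(chunk))
            galLab <- c(galLab, chunkLabels(chunk))
            ev <- evaluateModel(model, galX, galLab,
                chunkFeatures(test), chunkLabels(test), galleryMode)
            perRound <- rbind(perRound, data.frame(round = model@round,
                accuracy = ev$accuracy, eer = ev$eer))
            final <- ev
        }
    }
    out <- list(model = model)
    if (!is.null(test)) {
        out$perRound <- perRound
        out$final <- final
    }
    out
}

#' Train from an on-disk stream, one chunk file at a time
#'
#' Streaming counterpart of [trainStream()]: chunk files listed in the
#' manifest are opened strictly in order and exactly once each (the online
#' contract); a checkpoint is written after every round when `checkpointDir`
#' is given. The vector of files actually read, in open order, is returned
#' for auditing.
#'
#' @param dir directory holding `manifest.json` and chunk files.
#' @param hyper an [OnlineHyper-class].
#' @param checkpointDir optional directory for per-round checkpoints
#'   (`round_01`, `round_02`, ...).
#' @return List with `model`, `filesRead` and, when the manifest has a test
#'   chunk, `perRound` and `final`.
#' @export
trainStreamFromDisk <- function(dir, hyper = OnlineHyper(),
                                checkpointDir = NULL) {
    ms <- openFeatureStream(dir)
    filesRead <- character(0)
    model <- NULL
    galX <- NULL; galLab <- character(0)
    test <- if (!is.null(ms$testFile)) readFeatureChunk(ms$testFile) else NULL
    perRound <- NULL; final <- NULL
    for (t in seq_along(ms$chunkFiles)) {
        f <- ms$chunkFiles[t]
        chunk <- readFeatureChunk(f)
        filesRead <- c(filesRead, f)
        if (is.null(model))
            model <- newOnlineModel(nrow(chunkFeatures(chunk)), hyper)
        model <- trainChunk(model, chunk)$model
        if (!is.null(checkpointDir))
            saveCheckpoint(model,
                file.path(checkpointDir, sprintf("round_%02d", model@round)))
        if (!is.null(test)) {
            galX <- cbind(galX, chunkFeatures(chunk))
            galLab <- c(galLab, chunkLabels(chunk))
            ev <- evaluateModel(model, galX, galLab,
                chunkFeatures(test), chunkLabels(test))
            perRound <- rbind(perRound, data.frame(round = model@round,
                accuracy = ev$accuracy, eer = ev$eer))
            final <- ev
        }
    }
    out <- list(model = model, filesRead = filesRead)
    if (!is.null(test)) {
        out$perRound <- perRound
        out$final <- final
    }
    out
}
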