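#' Write a feature stream to disk
#'
#' Each chunk becomes a comma-delimited matrix file (d rows x n columns, no
#' headers) plus a JSON sidecar `{round_index, labels, d, n}`; a
#' `manifest.json` lists the chunk files in arrival order together with the
#' optional held-out test chunk and a spec echo.
#'
#' @param stream list with elements `chunks` (list of
#'   [FeatureChunk-class]) and optionally `test`, as returned by
#'   [simulateFeatureStream()].
#' @param dir output directory (created if needed).
#' @param meta optional named list echoed into the manifest.
#' @return Invisibly, the manifest path.
#' @export
writeFeatureStream <- function(stream, dir, meta = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeOne <- function(chunk, stem) {
        mat <- file.path(dir, paste0(stem, ".csv"))
        utils::write.table(chunk@X, mat, sep = ",", row.names = FALSE,
            col.names = FALSE)
        jsonlite::write_json(list(round_index = chunk@roundIndex,
            labels = chunk@labels, d = nrow(chunk@X), n = ncol(chunk@X)),
            file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE,
            digits = NA)
        basename(mat)
    }
    files <- vapply(seq_along(stream$chunks), function(t)
        writeOne(stream$chunks[[t]], sprintf("chunk_%02d", t)), character(1))
    testFile <- if (!is.null(stream$test)) writeOne(stream$test, "test") else NULL
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(c(list(chunks = files, test = testFile,
        n_rounds = length(files)), meta), manifest, auto_unbox = TRUE,
        digits = NA, null = "null")
    invisible(manifest)
}

#' Read one feature chunk from disk
#'
#' @param file path to the delimited matrix written by
#'   [writeFeatureStream()]; the `.json` sidecar must sit next to it.
#' @return A [FeatureChunk-class].
#' @export
readFeatureChunk <- function(file) {
    side <- sub("\\.csv$", ".json", file)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    X <- as.matrix(utils::read.table(file, sep = ",", header = FALSE))
    dimnames(X) <- NULL
    FeatureChunk(X, meta$labels, meta$round_index)
}

#' Open a feature stream manifest
#'
#' Returns the manifest contents with chunk paths resolved; chunks
#' themselves are not read here, so a streaming consumer can open each one
#' exactly once, in order.
#'
#' @param dir directory containing `manifest.json`.
#' @return List with `chunkFiles`, `testFile` (or NULL) and the raw
#'   manifest.
#' @export
openFeatureStream <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
        simplifyVector = TRUE)
    list(chunkFiles = file.path(dir, manifest$chunks),
         testFile = if (!is.null(manifest$test) && length(manifest$test))
             file.path(dir, manifest$test) else NULL,
         manifest = manifest)
}

#' Save a model checkpoint
#'
#' One directory holding W, G and the sufficient statistics as delimited
#' matrices plus a JSON file with the round counter, hyperparameters,
#' codebook assignment and memory contents.
#'
#' @param model an [OnlineModel-class].
#' @param dir checkpoint directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
saveCheckpoint <- function(model, dir) {
    stopifnot(is(model, "OnlineModel"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wm <- function(M, f) utils::write.table(M, file.path(dir, f), sep = ",",
        row.names = FALSE, col.names = FALSE)
    wm(model@W, "W.csv"); wm(model@G, "G.csv")
    wm(model@stats@C1, "C1.csv"); wm(model@stats@C2, "C2.csv")
    wm(model@stats@C3, "C3.csv")
    if (length(model@memory@ids)) wm(model@memory@means, "memory_means.csv")
    h <- model@hyper
    jsonlite::write_json(list(
        format_version = 1L, round = model@round, d = model@d, r = model@r,
        rounds_absorbed = model@stats@roundsAbsorbed,
        hyper = list(alpha = h@alpha, beta = h@beta, gamma = h@gamma,
            theta = h@theta, eta = h@eta, delta = h@delta, r = h@r,
            iterations = h@iterations, seed = h@seed,
            bidirectional = h@bidirectional, prototypes = h@prototypes,
            memory = h@memory, paperFormulaV = h@paperFormulaV),
        codebook = list(k = model@codebook@k, r = model@codebook@r,
            assignment = as.list(model@codebook@assignment)),
        memory = list(ids = model@memory@ids, counts = model@memory@counts)),
        file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir directory written by [saveCheckpoint()].
#' @return An [OnlineModel-class] (objective log not retained).
#' @export
loadCheckpoint <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "meta.json"),
        simplifyVector = TRUE)
    rm <- function(f) {
        M <- as.matrix(utils::read.table(file.path(dir, f), sep = ",",
            header = FALSE))
        dimnames(M) <- NULL
        M
    }
    h <- meta$hyper
    hyper <- OnlineHyper(alpha = h$alpha, beta = h$beta, gamma = h$gamma,
        theta = h$theta, eta = h$eta, delta = h$delta, r = h$r,
        iterations = h$iterations, seed = h$seed,
        bidirectional = h$bidirectional, prototypes = h$prototypes,
        memory = h$memory, paperFormulaV = h$paperFormulaV)
    cb <- suppressWarnings(hadamardCodebook(meta$codebook$k, meta$codebook$r))
    asg <- unlist(meta$codebook$assignment)
    if (length(asg))
        cb@assignment <- stats::setNames(as.integer(asg), names(asg))
    memIds <- as.character(unlist(meta$memory$ids))
    mem <- emptyMemoryBank(meta$r)
    if (length(memIds)) {
        mem@ids <- memIds
        mem@counts <- as.numeric(unlist(meta$memory$counts))
        mem@means <- rm("memory_means.csv")
    }
    new("OnlineModel", W = rm("W.csv"), G = rm("G.csv"),
        stats = new("SufficientStats", C1 = rm("C1.csv"), C2 = rm("C2.csv"),
            C3 = rm("C3.csv"),
            roundsAbsorbed = as.integer(meta$rounds_absorbed)),
        codebook = cb, memory = mem, hyper = hyper,
        round = as.integer(meta$round), d = as.integer(meta$d),
        r = as.integer(meta$r),
        log = data.frame(round = integer(0), iter = integer(0),
            step = character(0), objective = numeric(0)))
}
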