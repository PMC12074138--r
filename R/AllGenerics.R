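#' Accessors for ecgStream classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an ecgStream S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chunkFeatures", function(object) standardGeneric("chunkFeatures"))
#' @rdname accessors
#' @export
setGeneric("chunkLabels", function(object) standardGeneric("chunkLabels"))
#' @rdname accessors
#' @export
setGeneric("chunkRound", function(object) standardGeneric("chunkRound"))
#' @rdname accessors
#' @export
setGeneric("beatMatrix", function(object) standardGeneric("beatMatrix"))
#' @rdname accessors
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
#' @rdname accessors
#' @export
setGeneric("nDropped", function(object) standardGeneric("nDropped"))
#' @rdname accessors
#' @export
setGeneric("modelProjection", function(object) standardGeneric("modelProjection"))
#' @rdname accessors
#' @export
setGeneric("modelReconstruction",
           function(object) standardGeneric("modelReconstruction"))
#' @rdname accessors
#' @export
setGeneric("modelStats", function(object) standardGeneric("modelStats"))
#' @rdname accessors
#' @export
setGeneric("modelRound", function(object) standardGeneric("modelRound"))
#' @rdname accessors
#' @export
setGeneric("modelMemory", function(object) standardGeneric("modelMemory"))
#' @rdname accessors
#' @export
setGeneric("modelCodebook", function(object) standardGeneric("modelCodebook"))
#' @rdname accessors
#' @export
setGeneric("modelHyper", function(object) standardGeneric("modelHyper"))
#' @rdname accessors
#' @export
setGeneric("objectiveLog", function(object) standardGeneric("objectiveLog"))
#' @rdname accessors
#' @export
setGeneric("memoryIds", function(object) standardGeneric("memoryIds"))
#' @rdname accessors
#' @export
setGeneric("memoryCounts", function(object) standardGeneric("memoryCounts"))
#' @rdname accessors
#' @export
setGeneric("codeAssignment", function(object) standardGeneric("codeAssignment"))
#' @rdname accessors
#' @export
setGeneric("latentV", function(object) standardGeneric("latentV"))
#' @rdname accessors
#' @export
setGeneric("latentR", function(object) standardGeneric("latentR"))

setMethod("chunkFeatures", "FeatureChunk", function(object) object@X)
setMethod("chunkLabels", "FeatureChunk", function(object) object@labels)
setMethod("chunkRound", "FeatureChunk", function(object) object@roundIndex)
setMethod("beatMatrix", "HeartbeatMatrix", function(object) object@segments)
setMethod("rPeaks", "HeartbeatMatrix", function(object) object@rPeaks)
setMethod("nDropped", "HeartbeatMatrix", function(object) object@nDropped)
setMethod("modelProjection", "OnlineModel", function(object) object@W)
setMethod("modelReconstruction", "OnlineModel", function(object) object@G)
setMethod("modelStats", "OnlineModel", function(object) object@stats)
setMethod("modelRound", "OnlineModel", function(object) object@round)
setMethod("modelMemory", "OnlineModel", function(object) object@memory)
setMethod("modelCodebook", "OnlineModel", function(object) object@codebook)
setMethod("modelHyper", "OnlineModel", function(object) object@hyper)
setMethod("objectiveLog", "OnlineModel", function(object) object@log)
setMethod("memoryIds", "MemoryBank", function(object) object@ids)
setMethod("memoryCounts", "MemoryBank",
    function(object) stats::setNames(object@counts, object@ids))
setMethod("codeAssignment", "HadamardCodebook", function(object) object@assignment)
setMethod("latentV", "ChunkLatents", function(object) object@V)
setMethod("latentR", "ChunkLatents", function(object) object@R)

setMethod("show", "EcgRecord", function(object) {
    cat(sprintf("EcgRecord '%s': %d samples at %g Hz (%.1f s)\n",
        object@recordId, length(object@samples), object@fs,
        length(object@samples) / object@fs))
})

setMethod("show", "HeartbeatMatrix", function(object) {
    cat(sprintf("HeartbeatMatrix: %d beats x %d samples (fs %g Hz), %d dropped at boundaries\n",
        ncol(object@segments), object@windowLength, object@fs, object@nDropped))
})

setMethod("show", "FeatureChunk", function(object) {
    cat(sprintf("FeatureChunk round %d: d = %d features x n = %d samples, %d individuals\n",
        object@roundIndex, nrow(object@X), ncol(object@X),
        length(unique(object@labels))))
})

setMethod("show", "HadamardCodebook", function(object) {
    cat(sprintf("HadamardCodebook: order 2^%d = %d, code dimension %d, %d/%d rows assigned\n",
        object@k, 2L^object@k, object@r, length(object@assignment),
        2L^object@k))
})

setMethod("show", "MemoryBank", function(object) {
    cat(sprintf("MemoryBank: %d individuals, latent dimension %d\n",
        length(object@ids), ncol(object@means)))
    if (length(object@ids)) {
        shown <- utils::head(object@ids, 5L)
        cat("  ids:", paste(shown, collapse = ", "),
            if (length(object@ids) > 5L) "..." else "", "\n")
    }
})

setMethod("show", "OnlineModel", function(object) {
    cat(sprintf("OnlineModel: d = %d -> r = %d, %d round(s) absorbed, %d individuals enrolled\n",
        object@d, object@r, object@round, length(object@memory@ids)))
    mods <- c(if (object@hyper@bidirectional) "bidirectional-regressions",
              if (object@hyper@prototypes) "prototype-learning",
              if (object@hyper@memory) "memory-enhancement")
    cat("  modules:", paste(mods, collapse = " + "), "\n")
})

setMethod("show", "OnlineHyper", function(object) {
    cat(sprintf("OnlineHyper: alpha=%g beta=%g gamma=%g theta=%g eta=%g delta=%g | r=%d T=%d seed=%d\n",
        object@alpha, object@beta, object@gamma, object@theta, object@eta,
        object@delta, object@r, object@iterations, object@seed))
})
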