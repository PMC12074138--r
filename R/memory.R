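#' Absorb one round of representations into the memory bank
#'
#' Implements the two update scenarios of the memory-enhancement store:
#' (1) class-incremental expansion — an unseen individual is appended with
#' the mean of its rows in this round; (2) running-mean update — a seen
#' individual's stored mean is replaced by the count-weighted mean
#' `(count * mean + sum of new rows) / (count + nNew)`, the unique rule
#' under which every stored mean equals the arithmetic mean of all
#' representations that individual has ever produced. Order of ids is
#' first-appearance order; shuffling rows within a round does not change
#' the result.
#'
#' @param bank a [MemoryBank-class].
#' @param V n x r matrix of this round's learned representations.
#' @param labels per-row individual identifiers (length n).
#' @return The updated [MemoryBank-class].
#' @examples
#' b <- emptyMemoryBank(4)
#' V <- matrix(rnorm(12), 3, 4)
#' b <- updateMemory(b, V, c("a", "a", "b"))
#' memoryCounts(b)
#' @export
updateMemory <- function(bank, V, labels) {
    stopifnot(is(bank, "MemoryBank"))
    V <- as.matrix(V)
    labels <- as.character(labels)
    if (nrow(V) != length(labels))
        stop("one label per representation row required")
    if (ncol(bank@means) != ncol(V))
        stop("latent dimension of V does not match the memory bank")
    for (id in unique(labels)) {
        rows <- V[labels == id, , drop = FALSE]
        k <- nrow(rows)
        i <- match(id, bank@ids)
        if (is.na(i)) {
            bank@ids <- c(bank@ids, id)
            bank@counts <- c(bank@counts, k)
            bank@means <- rbind(bank@means, colMeans(rows))
        } else {
            cnt <- bank@counts[i]
            bank@means[i, ] <- (cnt * bank@means[i, ] + colSums(rows)) / (cnt + k)
            bank@counts[i] <- cnt + k
        }
    }
    rownames(bank@means) <- NULL
    validObject(bank)
    bank
}

#' Memory matrix and id order
#'
#' Returns the aligned cOld x r matrix of stored means together with the id
#' order, which is the order used to build the memory similarity matrix S.
#' Stable across calls.
#'
#' @param bank a [MemoryBank-class].
#' @return A list with elements `Vm` (cOld x r matrix) and `ids`.
#' @export
memoryMatrix <- function(bank) {
    stopifnot(is(bank, "MemoryBank"))
    list(Vm = bank@means, ids = bank@ids)
}
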