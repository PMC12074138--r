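#' Sylvester Hadamard matrix
#'
#' Builds the 2^k x 2^k Hadamard matrix by the Sylvester doubling
#' construction: H_0 = [1], H_{k} = [[H, H], [H, -H]]. Rows (and columns)
#' are mutually orthogonal: H %*% t(H) == 2^k * I exactly, in integer
#' arithmetic.
#'
#' @param k non-negative integer; the matrix has order 2^k.
#' @return A 2^k x 2^k matrix with entries in {+1, -1}.
#' @examples
#' hadamardMatrix(1)
#' H <- hadamardMatrix(7)            # 128 x 128
#' all(H %*% t(H) == 128 * diag(128))
#' @export
hadamardMatrix <- function(k) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 0L)
        stop("'k' must be a single non-negative integer")
    H <- matrix(1, 1L, 1L)
    if (k == 0L) return(H)
    for (i in seq_len(k))
        H <- rbind(cbind(H, H), cbind(H, -H))
    H
}

#' Construct a HadamardCodebook
#'
#' Creates an empty codebook over a Sylvester Hadamard matrix of order 2^k.
#' The code dimension r defaults to 2^k (the reference configuration is
#' k = 7, r = 128). Setting r < 2^k truncates each code to its first r
#' entries; exact mutual orthogonality then no longer holds and a warning is
#' given.
#'
#' @param k log2 of the Hadamard order; capacity is 2^k individuals.
#' @param r code dimension (defaults to 2^k).
#' @return A [HadamardCodebook-class] with no assignments.
#' @examples
#' cb <- hadamardCodebook(7)
#' cb
#' @export
hadamardCodebook <- function(k = 7L, r = 2L^as.integer(k)) {
    k <- as.integer(k)
    r <- as.integer(r)
    if (r < 2L^k && r >= 1L)
        warning("r < 2^k: truncated codes are not exactly orthogonal")
    new("HadamardCodebook", H = hadamardMatrix(k), k = k, r = r,
        assignment = stats::setNames(integer(0), character(0)))
}

#' Assign code rows to individuals
#'
#' Previously unseen identifiers receive consecutive Hadamard rows in
#' first-appearance order; already-assigned identifiers keep their rows, so
#' the operation is idempotent and reproducible from the label stream alone.
#'
#' @param codebook a [HadamardCodebook-class].
#' @param ids character vector of individual identifiers (repeats allowed).
#' @return The updated codebook.
#' @examples
#' cb <- assignCodes(hadamardCodebook(3), c("a", "b", "a"))
#' codeAssignment(cb)
#' @export
assignCodes <- function(codebook, ids) {
    stopifnot(is(codebook, "HadamardCodebook"))
    ids <- as.character(ids)
    newIds <- setdiff(unique(ids), names(codebook@assignment))
    if (!length(newIds)) return(codebook)
    capacity <- as.integer(2^codebook@k)
    nextRow <- length(codebook@assignment) + 1L
    if (nextRow + length(newIds) - 1L > capacity)
        stop(sprintf(paste0(
            "Hadamard codebook capacity exceeded: %d individuals cannot fit ",
            "in 2^%d = %d code rows; rebuild the codebook with a larger k"),
            length(codebook@assignment) + length(newIds), codebook@k, capacity))
    add <- stats::setNames(seq(nextRow, length.out = length(newIds)), newIds)
    codebook@assignment <- c(codebook@assignment, add)
    validObject(codebook)
    codebook
}

#' Code matrix for one chunk
#'
#' Stacks the assigned code row of each sample's individual into the n x r
#' target matrix used by the prototype-learning term: samples sharing a
#' label share identical rows.
#'
#' @param codebook a [HadamardCodebook-class] covering all labels.
#' @param labels per-sample individual identifiers.
#' @return An n x r matrix with entries in {+1, -1}.
#' @export
chunkCodeMatrix <- function(codebook, labels) {
    stopifnot(is(codebook, "HadamardCodebook"))
    labels <- as.character(labels)
    rows <- codebook@assignment[labels]
    if (anyNA(rows))
        stop("unassigned labels: ",
             paste(unique(labels[is.na(rows)]), collapse = ", "),
             " (call assignCodes() first)")
    codebook@H[rows, seq_len(codebook@r), drop = FALSE]
}
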