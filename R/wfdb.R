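#' Read a WFDB-format ECG record
#'
#' Minimal reader for PhysioNet WFDB records: parses the `.hea` header and
#' decodes the signal file for the common storage formats 212 (two 12-bit
#' samples packed in 3 bytes, as in the MIT-BIH arrhythmia recordings) and
#' 16 (little-endian 16-bit integers). One channel is extracted and
#' converted to physical units via `(adc - baseline) / gain`.
#'
#' @param header path to the `.hea` header file; the signal file named in
#'   the header is resolved relative to it.
#' @param channel 1-based signal channel to extract (MIT-BIH records have
#'   two).
#' @param n maximum number of samples to read (default: all).
#' @return An [EcgRecord-class].
#' @export
readWfdbRecord <- function(header, channel = 1L, n = Inf) {
    lines <- readLines(header, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    top <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
    recName <- sub("/.*$", "", top[1L])
    nsig <- as.integer(top[2L])
    fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
    nsamp <- if (length(top) >= 4L) as.numeric(top[4L]) else NA_real_
    if (channel < 1L || channel > nsig)
        stop(sprintf("channel %d out of range; record has %d signal(s)", channel, nsig))

    sig <- lapply(lines[1L + seq_len(nsig)], function(l)
        strsplit(trimws(l), "[[:space:]]+")[[1L]])
    fileName <- sig[[channel]][1L]
    fmt <- sub("x.*$|:.*$|\\+.*$", "", sig[[channel]][2L])
    gainField <- if (length(sig[[channel]]) >= 3L) sig[[channel]][3L] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gainField))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- 0
    if (grepl("\\(", gainField))
        baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainField))
    # ADC zero is field 6 when present and no explicit (baseline) given
    if (!grepl("\\(", gainField) && length(sig[[channel]]) >= 6L) {
        z <- suppressWarnings(as.numeric(sig[[channel]][6L]))
        if (is.finite(z)) baseline <- z
    }

    datPath <- file.path(dirname(header), fileName)
    raw <- readBin(datPath, "raw", n = file.size(datPath))
    adc <- switch(fmt,
        "212" = .decode212(raw),
        "16"  = {
            v <- readBin(datPath, "integer", n = length(raw) %/% 2L,
                         size = 2L, signed = TRUE, endian = "little")
            matrix(v, nrow = nsig)  # interleaved frames
        },
        stop(sprintf("unsupported WFDB storage format '%s' (only 212 and 16)", fmt)))
    if (fmt == "212") adc <- matrix(adc[seq_len((length(adc) %/% nsig) * nsig)],
                                    nrow = nsig)
    x <- adc[channel, ]
    if (is.finite(nsamp)) x <- x[seq_len(min(length(x), nsamp))]
    if (is.finite(n)) x <- x[seq_len(min(length(x), n))]
    EcgRecord((x - baseline) / gain, fs = fs, recordId = recName)
}

# format 212: 3 bytes hold two 12-bit two's-complement samples
.decode212 <- function(raw) {
    nTriple <- length(raw) %/% 3L
    b <- as.integer(raw[seq_len(3L * nTriple)])
    b1 <- b[seq(1L, by = 3L, length.out = nTriple)]
    b2 <- b[seq(2L, by = 3L, length.out = nTriple)]
    b3 <- b[seq(3L, by = 3L, length.out = nTriple)]
    s1 <- b1 + 256L * (b2 %% 16L)
    s2 <- b3 + 256L * (b2 %/% 16L)
    fix <- function(v) ifelse(v > 2047L, v - 4096L, v)
    as.integer(rbind(fix(s1), fix(s2)))
}
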