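#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Sequence names are the first
#' whitespace-delimited token of each header; lowercase input is accepted
#' and uppercased; ambiguity characters (N etc.) are preserved.
#'
#' @param path path of the FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
    if (!file.exists(path)) stop("cannot read FASTA file: ", path)
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(names(seqs)))
        stop("duplicate sequence names in ", path)
    seqs
}

#' Write LC intervals as 3-column BED
#'
#' Emits one `seqid<TAB>start<TAB>end` line per interval (0-based half-open,
#' the package's only coordinate dialect). Byte output is deterministic for
#' a fixed input.
#'
#' @param intervals data frame with `seqid`, `start`, `end` columns, sorted
#'   by sequence and start (as returned by [longdust()]).
#' @param path output file path, or `""` for standard output.
#' @return Invisibly, the number of lines written.
#' @export
write_bed <- function(intervals, path = "") {
    lines <- sprintf("%s\t%d\t%d", intervals$seqid,
                     as.integer(intervals$start), as.integer(intervals$end))
    writeLines(lines, con = if (nzchar(path)) file(path) else stdout())
    invisible(length(lines))
}

#' Write a masked FASTA
#'
#' Writes the sequences with every base covered by an interval soft-masked
#' (lowercased) or hard-masked (replaced by `N`); all other bases are
#' unchanged. Lines are wrapped at 60 columns.
#'
#' @param seqs named character vector of sequences.
#' @param intervals data frame with `seqid`, `start`, `end` (0-based
#'   half-open); every `seqid` must name an input sequence.
#' @param path output file path.
#' @param hard hard-mask with `N` instead of lowercasing.
#' @return Invisibly, the total number of masked bases.
#' @export
write_masked_fasta <- function(seqs, intervals, path, hard = FALSE) {
    if (!all(intervals$seqid %in% names(seqs)))
        stop("interval refers to an unknown sequence id")
    total <- 0L
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
        ch <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1]]
        iv <- intervals[intervals$seqid == nm, , drop = FALSE]
        for (z in seq_len(nrow(iv))) {
            if (iv$start[z] < 0 || iv$end[z] > length(ch))
                stop("interval out of bounds for ", nm)
            idx <- (iv$start[z] + 1L):iv$end[z]
            ch[idx] <- if (hard) "N" else tolower(ch[idx])
            total <- total + length(idx)
        }
        writeLines(paste0(">", nm), con)
        s <- paste(ch, collapse = "")
        starts <- seq(1L, max(nchar(s), 1L), by = 60L)
        writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
    invisible(total)
}
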