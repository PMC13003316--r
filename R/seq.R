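# Sequence encoding helpers. Internal coordinate convention throughout the
# package: 0-based positions, BED-style half-open intervals at the surface.

# Encode a DNA string as integer codes A=0, C=1, G=2, T=3; any other
# character (ambiguity codes, N) becomes NA.
.encode <- function(seq) {
    b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    c(A = 0L, C = 1L, G = 2L, T = 3L)[b]
}

# 2-bit k-mer codes of an ACGT-only code vector; entry i is the code of the
# k-mer ending at 0-based position (i - 1 + k - 1).
.kmer_codes <- function(codes, k) {
    n <- length(codes)
    if (n < k) return(integer(0))
    if (k == 1L) return(codes)
    # embed() row i holds codes[i+k-1], ..., codes[i], so weighting the
    # first column with 4^0 makes the first base the most significant digit
    as.integer(embed(codes, k) %*% 4^(0:(k - 1)))
}

#' Reverse complement of DNA strings
#'
#' @param seq character vector of DNA strings (IUPAC codes supported, case
#'   preserved).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Genome-wide G+C fraction
#'
#' Computes the G+C fraction over one or more sequences jointly, counting
#' only unambiguous A/C/G/T bases, as used for the default frequency model.
#'
#' @param seqs character vector of DNA strings.
#' @return G+C fraction in `[0, 1]` (`NaN` if no A/C/G/T base is present).
#' @examples
#' gc_fraction(c("ACGT", "GGCC"))
#' @export
gc_fraction <- function(seqs) {
    counts <- colSums(Biostrings::alphabetFrequency(
        Biostrings::DNAStringSet(toupper(seqs))))
    acgt <- counts[c("A", "C", "G", "T")]
    sum(acgt[c("C", "G")]) / sum(acgt)
}

#' Count k-mers of a DNA string
#'
#' Tallies the k-mers of a contiguous ACGT-only string into a sparse count
#' vector. A string of `n` bases holds `ell = n - k + 1` k-mers.
#'
#' @param seq a single DNA string over A/C/G/T (case-insensitive).
#' @param k k-mer length.
#' @return An object of class `kmer_counts`: list with `counts` (named
#'   integer vector of nonzero counts, names are 2-bit k-mer codes), `ell`
#'   (total k-mer count) and `k`.
#' @examples
#' kc <- kmer_counts("AAAAAAAA", k = 7)
#' kc$ell
#' @export
kmer_counts <- function(seq, k) {
    k <- as.integer(k)
    stopifnot(length(seq) == 1L, k >= 1L, k <= 12L)
    codes <- .encode(seq)
    if (anyNA(codes)) stop("'seq' must contain only A/C/G/T")
    kc <- .kmer_codes(codes, k)
    counts <- integer(0)
    if (length(kc)) {
        tb <- table(kc)
        counts <- as.integer(tb)
        names(counts) <- names(tb)
    }
    structure(list(counts = counts, ell = length(kc), k = k),
              class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
    cat(sprintf("kmer_counts: %d k-mers (k = %d), %d distinct\n",
                x$ell, x$k, length(x$counts)))
    invisible(x)
}
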