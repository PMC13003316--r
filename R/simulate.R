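#' Simulate a sequence with planted tandem arrays
#'
#' Generates an i.i.d. random background at a given G+C fraction
#' (`P(G) = P(C) = gc/2`) and plants tandem repeat arrays into it: each
#' array is `copies` concatenated copies of a repeat unit, optionally
#' degraded by per-base substitutions and indels. This emulates the LC
#' regimes of real genomes -- from microsatellites (units of a few bases)
#' to alpha-satellite-like arrays (~170 bp units) -- for benchmarking the
#' scan against a known truth.
#'
#' Each planted array replaces a background slice of its nominal
#' (mutation-free) length at the requested position; indels change the
#' array's realised length, shifting all downstream coordinates, and the
#' returned truth intervals refer to the emitted sequence. Arrays must not
#' overlap. Output is fully determined by `seed`.
#'
#' @param length total background length in bases (before indel shifts).
#' @param gc background G+C fraction in (0, 1).
#' @param repeats list of planted repeats; each element is a list with
#'   `unit` (unit length, or an explicit unit string), `copies`, `at`
#'   (0-based insert position) and optional `sub` / `indel` per-base rates
#'   in `[0, 1)`. Random units are drawn from the background composition.
#' @param seed integer random seed, or `NULL` to use the current RNG state.
#' @return A list with `seq` (the sequence string), `truth` (data frame of
#'   planted-array intervals: `start`, `end` 0-based half-open on the
#'   emitted sequence) and `gc` (the requested background G+C).
#' @examples
#' sim <- simulate_genome(2000, repeats = list(
#'     list(unit = 170, copies = 5, sub = 0.05, at = 500)), seed = 1)
#' sim$truth
#' @export
simulate_genome <- function(length, gc = 0.5, repeats = list(), seed = NULL) {
    stopifnot(length >= 0, gc > 0, gc < 1)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(as.integer(seed))
    }
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- c("A", "C", "G", "T")
    bg <- sample(bases, length, replace = TRUE, prob = prob)
    at <- vapply(repeats, function(r) as.integer(r$at), integer(1))
    if (base::length(repeats)) {
        o <- order(at)
        repeats <- repeats[o]
        at <- at[o]
    }
    pieces <- character(0)
    truth_s <- integer(0); truth_e <- integer(0)
    cursor <- 0L   # position in the background
    out_len <- 0L  # length emitted so far
    for (z in seq_along(repeats)) {
        r <- repeats[[z]]
        unit <- if (is.character(r$unit)) toupper(r$unit)
                else paste(sample(bases, as.integer(r$unit), replace = TRUE,
                                  prob = prob), collapse = "")
        copies <- as.integer(r$copies)
        sub <- if (is.null(r$sub)) 0 else r$sub
        indel <- if (is.null(r$indel)) 0 else r$indel
        stopifnot(sub >= 0, sub < 1, indel >= 0, indel < 1)
        nominal <- nchar(unit) * copies
        if (at[z] < cursor) stop("planted repeats overlap")
        if (at[z] + nominal > length) stop("planted repeat exceeds the sequence")
        arr <- .mutate_array(strrep(unit, copies), sub, indel, bases)
        gap <- if (at[z] > cursor) paste(bg[(cursor + 1L):at[z]], collapse = "") else ""
        pieces <- c(pieces, gap, arr)
        out_len <- out_len + nchar(gap)
        truth_s <- c(truth_s, out_len)
        out_len <- out_len + nchar(arr)
        truth_e <- c(truth_e, out_len)
        cursor <- at[z] + nominal
    }
    if (cursor < length)
        pieces <- c(pieces, paste(bg[(cursor + 1L):length], collapse = ""))
    list(seq = paste(pieces, collapse = ""),
         truth = data.frame(start = truth_s, end = truth_e),
         gc = gc)
}

# Apply per-base substitutions and indels to an array. Substitution picks a
# different base uniformly; an indel event is a deletion or a random-base
# insertion (before the site) with equal probability.
.mutate_array <- function(s, sub, indel, bases) {
    if (sub == 0 && indel == 0) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    ev <- indel > 0 & runif(n) < indel
    del <- ev & runif(n) < 0.5
    ins <- ev & !del
    smut <- !del & sub > 0 & runif(n) < sub
    if (any(smut)) {
        shift <- sample(1:3, sum(smut), replace = TRUE)
        ch[smut] <- bases[(match(ch[smut], bases) - 1L + shift) %% 4L + 1L]
    }
    if (any(ins))
        ch[ins] <- paste0(sample(bases, sum(ins), replace = TRUE), ch[ins])
    ch[del] <- ""
    paste(ch, collapse = "")
}
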