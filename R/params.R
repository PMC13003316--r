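#' Longdust model parameters
#'
#' Bundles the tunable parameters of the longdust model and scan. All scores
#' are in nats (natural logarithms).
#'
#' @param k k-mer length. Complexity is measured on counts of `k`-mers;
#'   larger `k` sharpens the null (fewer chance collisions) but weakens
#'   sensitivity to very short repeat units. Must be in `1..12`.
#' @param w context window size in k-mers. An individual good LC interval
#'   holds at most `w` k-mers (`w + k - 1` bases); longer LC regions arise by
#'   merging. Must satisfy `w >= k`.
#' @param threshold complexity threshold `T` per k-mer, in nats. A string is
#'   LC-containing iff `S = Q - T * ell > 0`. Must satisfy
#'   `0 < threshold < log(4)` so that the per-base score can go negative on
#'   random sequence.
#' @param gc genome G+C fraction in (0, 1) used to derive k-mer frequencies,
#'   or `NULL` to compute it from the input sequences (A/C/G/T bases only).
#' @param xdrop X-drop threshold in nats, or `NULL` to disable. When set,
#'   reported intervals are split wherever the running prefix score falls
#'   more than `xdrop` below its running maximum, excluding non-repetitive
#'   spacers between adjacent repeats. 25 is a reasonable value when enabled.
#' @param both_strands run the scan on both strands and report the union
#'   (strand-symmetric output, the default). With `FALSE` only the forward
#'   strand is scanned and output may differ between a sequence and its
#'   reverse complement.
#' @param use_extension use the window-sliding extension heuristic: a good
#'   interval spanning the whole window at `j - 1` is extended to `j` without
#'   a fresh candidate search when the incoming k-mer repeats in the window.
#' @param fast_start restrict the candidate search to the smallest candidate
#'   start only. This guarantees O(w) work per position but is slightly
#'   further from the exact interval definition; off by default.
#'
#' @return An object of class `longdust_params`.
#' @examples
#' p <- ld_params()
#' p$k
#' @export
ld_params <- function(k = 7L, w = 5000L, threshold = 0.6, gc = NULL,
                      xdrop = NULL, both_strands = TRUE, use_extension = TRUE,
                      fast_start = FALSE) {
    k <- as.integer(k)
    w <- as.integer(w)
    if (length(k) != 1L || is.na(k) || k < 1L || k > 12L)
        stop("'k' must be a single integer in 1..12")
    if (length(w) != 1L || is.na(w) || w < k)
        stop("'w' must be a single integer >= k")
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= log(4))
        stop("'threshold' must be in (0, log 4)")
    if (!is.null(gc)) {
        if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1)
            stop("'gc' must be a single value in (0, 1)")
    }
    if (!is.null(xdrop)) {
        if (!is.numeric(xdrop) || length(xdrop) != 1L || xdrop <= 0)
            stop("'xdrop' must be a single positive value (or NULL to disable)")
    }
    structure(list(k = k, w = w, threshold = as.numeric(threshold),
                   gc = if (is.null(gc)) NULL else as.numeric(gc),
                   xdrop = if (is.null(xdrop)) NULL else as.numeric(xdrop),
                   both_strands = isTRUE(both_strands),
                   use_extension = isTRUE(use_extension),
                   fast_start = isTRUE(fast_start)),
              class = "longdust_params")
}

#' @export
print.longdust_params <- function(x, ...) {
    cat("longdust parameters\n")
    cat(sprintf("  k = %d, w = %d k-mers, T = %g nats\n", x$k, x$w, x$threshold))
    cat(sprintf("  gc = %s, xdrop = %s\n",
                if (is.null(x$gc)) "auto" else format(x$gc),
                if (is.null(x$xdrop)) "off" else format(x$xdrop)))
    cat(sprintf("  both_strands = %s, use_extension = %s, fast_start = %s\n",
                x$both_strands, x$use_extension, x$fast_start))
    invisible(x)
}

#' Minimum number of exact repeat copies detectable
#'
#' Closed-form approximation to the smallest number of exact copies of a
#' tandem repeat unit that can yield a positive complexity score under
#' threshold `T`:
#' \deqn{3 + \frac{k-1}{r} + \frac{3T - \log 2 - \log 3}{\log 4 - T}.}
#' The approximation assumes the unit length `r` exceeds `k`, that all
#' k-mers within a unit are distinct, and that `f` is negligible at the
#' relevant lengths. At the default `T = 0.6` the unit-length-independent
#' part is about 3.01 copies.
#'
#' @param params a [ld_params()] object (uses `k` and `threshold`).
#' @param r repeat unit length in bases; must exceed `k` (may be `Inf` for
#'   the limiting constant).
#' @return Minimum copy number (a positive real, not rounded).
#' @examples
#' min_exact_copies(ld_params(), r = 20)   # ~3.31
#' min_exact_copies(ld_params(), r = Inf)  # ~3.01
#' @export
min_exact_copies <- function(params, r) {
    stopifnot(inherits(params, "longdust_params"))
    if (!is.numeric(r) || length(r) != 1L || r <= params$k)
        stop("'r' must be a single unit length greater than k")
    T <- params$threshold
    3 + (params$k - 1) / r + (3 * T - log(2) - log(3)) / (log(4) - T)
}
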