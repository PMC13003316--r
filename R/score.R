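#' Longdust complexity scores
#'
#' `score_q()` evaluates the centred complexity statistic
#' \eqn{Q = \sum_t \log c(t)! - f(\ell)}: near zero on random sequence of any
#' length, positive on compositionally repetitive sequence. `score_s()`
#' applies the per-k-mer threshold, \eqn{S = Q - T \ell}; a string contains a
#' low-complexity substring iff `S > 0`.
#'
#' @param x a [kmer_counts()] object, or a single ACGT string which is
#'   counted with the model's `k`.
#' @param model a [ld_model()] object; the counts' `ell` must not exceed the
#'   model's window `w` (the range of the precomputed scaling table).
#' @return Score in nats. For `ell = 0`, `Q = S = 0`.
#' @examples
#' m <- ld_model(ld_params(k = 7, w = 100, gc = 0.5))
#' score_s(strrep("A", 50), m)   # positive: homopolymer
#' score_s("ACGTACGG", m) < 0    # all k-mers distinct
#' @export
score_q <- function(x, model) {
    stopifnot(inherits(model, "longdust_model"))
    x <- .as_counts(x, model)
    if (x$ell > model$params$w)
        stop("counts hold more k-mers than the model window w")
    sum(model$logfact[x$counts + 1L]) - model$f[x$ell + 1L]
}

#' @rdname score_q
#' @export
score_s <- function(x, model) {
    stopifnot(inherits(model, "longdust_model"))
    x <- .as_counts(x, model)
    score_q(x, model) - model$params$threshold * x$ell
}

.as_counts <- function(x, model) {
    if (inherits(x, "kmer_counts")) {
        if (x$k != model$params$k)
            stop("k of the counts does not match the model")
        return(x)
    }
    kmer_counts(x, model$params$k)
}

#' Comparison scoring functions: SDUST and Shannon entropy
#'
#' `score_sdust()` is the SDUST complexity score
#' \eqn{S_S = \frac{1}{\ell} \sum_t \binom{c(t)}{2} - T}, which grows
#' linearly with string length for a fixed-period repeat (and for any string
#' once \eqn{\ell \ge 4^k}). `score_entropy()` is the entropy-based score
#' \eqn{S_E = \log\ell - H - T = \frac{1}{\ell} \sum_t c(t) \log c(t) - T},
#' defined for \eqn{\ell \le 4^k}. `shannon_entropy()` returns the Shannon
#' entropy \eqn{H = -\sum_t p(t) \log p(t)} with \eqn{p(t) = c(t)/\ell}, in
#' nats. Both scorers share the drop-in interface of the longdust score and
#' can drive the interval scan (see the `scorer` argument of [ld_scan()]).
#'
#' @param x a [kmer_counts()] object, or a single ACGT string (then `k` must
#'   be given).
#' @param threshold score threshold `T` per k-mer.
#' @param k k-mer length used when `x` is a string (SDUST's own convention
#'   is `k = 3`).
#' @return Score (or entropy) in nats. By convention `score_sdust()` of an
#'   empty count set is `-threshold`.
#' @examples
#' score_sdust(kmer_counts("AAAAA", 3), threshold = 0.6)  # (ell-1)/2 - T
#' shannon_entropy(kmer_counts("ACGTAC", 3))              # log(4): all distinct
#' @export
score_sdust <- function(x, threshold = 0.6, k = 3L) {
    x <- .as_counts_k(x, k)
    if (x$ell == 0L) return(-threshold)
    sum(x$counts * (x$counts - 1) / 2) / x$ell - threshold
}

#' @rdname score_sdust
#' @export
score_entropy <- function(x, threshold = 0.6, k = 3L) {
    x <- .as_counts_k(x, k)
    if (x$ell > 4^x$k)
        stop("the entropy score is defined for ell <= 4^k")
    if (x$ell == 0L) return(-threshold)
    sum(x$counts * log(x$counts)) / x$ell - threshold
}

#' @rdname score_sdust
#' @export
shannon_entropy <- function(x, k = 3L) {
    x <- .as_counts_k(x, k)
    if (x$ell == 0L) stop("entropy of an empty k-mer set is undefined")
    p <- x$counts / x$ell
    -sum(p * log(p))
}

.as_counts_k <- function(x, k) {
    if (inherits(x, "kmer_counts")) x else kmer_counts(x, k)
}
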