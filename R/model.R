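#' Build a longdust scoring model
#'
#' Derives the k-mer frequency model from the G+C fraction and precomputes
#' the scaling table used by all scoring operations. Under the
#' independent-base background, the frequency of a k-mer `t` containing `m`
#' G/C bases is \eqn{q_t = (gc/2)^m ((1-gc)/2)^{k-m}}, so `q_t` takes only
#' `k + 1` distinct values. The scaling function
#' \deqn{f(\ell) = \sum_t e^{-\ell q_t} \sum_{n \ge 2} \log(n!)
#'       \frac{(\ell q_t)^n}{n!}}
#' is the Poisson-approximated expectation of \eqn{\sum_t \log c(t)!} for a
#' random string of `ell` k-mers; it is tabulated for integer
#' `ell = 0..w` at build time, together with a log-factorial table.
#'
#' @param params a [ld_params()] object. `params$gc` must be set (the
#'   higher-level [longdust()] fills it in from the input when `NULL`);
#'   `gc = 0.5` is used here if missing.
#' @return An object of class `longdust_model`: the resolved `params`, the
#'   per-group frequencies `q_group` (G/C count `0..k`), the group sizes,
#'   the scaling table `f` (`f[ell + 1]` is \eqn{f(\ell)}) and the
#'   log-factorial table `logfact` (`logfact[n + 1]` is \eqn{\log n!}).
#' @examples
#' m <- ld_model(ld_params(k = 3, w = 100, gc = 0.5))
#' m$f[1]  # f(0) = 0
#' @export
ld_model <- function(params = ld_params()) {
    stopifnot(inherits(params, "longdust_params"))
    if (is.null(params$gc)) params$gc <- 0.5
    k <- params$k
    m <- 0:k
    q_group <- (params$gc / 2)^m * ((1 - params$gc) / 2)^(k - m)
    n_group <- choose(k, m) * 2^k
    f <- .ld_ftable_cpp(params$w, k, params$gc, 1e-12)
    structure(list(params = params,
                   q_group = q_group,
                   n_group = n_group,
                   f = f,
                   logfact = lfactorial(0:params$w)),
              class = "longdust_model")
}

#' @export
print.longdust_model <- function(x, ...) {
    cat("longdust model\n")
    print(x$params)
    cat(sprintf("  f(w) = %.4f nats at ell = %d\n",
                x$f[x$params$w + 1], x$params$w))
    invisible(x)
}

#' Per-k-mer background frequencies
#'
#' Expands the grouped frequency model into the full vector of `4^k` k-mer
#' frequencies `q_t` (and scaled frequencies `r_t = 4^k q_t`), indexed by the
#' 2-bit k-mer code (A=0, C=1, G=2, T=3; the first base is the most
#' significant digit).
#'
#' @param model a [ld_model()] object with `k <= 10` (the full vector has
#'   `4^k` entries).
#' @return A data frame with columns `kmer`, `q` and `r`; `sum(q)` is 1.
#' @examples
#' fq <- kmer_frequencies(ld_model(ld_params(k = 2, w = 10, gc = 0.3)))
#' sum(fq$q)
#' @export
kmer_frequencies <- function(model) {
    stopifnot(inherits(model, "longdust_model"))
    k <- model$params$k
    if (k > 10L) stop("full frequency vectors are only materialised for k <= 10")
    codes <- 0:(4^k - 1)
    gc_count <- integer(length(codes))
    kmer <- character(length(codes))
    bases <- c("A", "C", "G", "T")
    rem <- codes
    for (pos in seq_len(k)) {  # least-significant digit = last base
        digit <- rem %% 4L
        rem <- rem %/% 4L
        gc_count <- gc_count + (digit == 1L | digit == 2L)
        kmer <- paste0(bases[digit + 1L], kmer)
    }
    q <- model$q_group[gc_count + 1L]
    data.frame(kmer = kmer, q = q, r = 4^k * q, stringsAsFactors = FALSE)
}
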