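# Brute-force reference implementations. These deliberately avoid the
# compiled scan path: scores are recomputed from scratch so the fast
# incremental implementation can be validated against them.

#' Complexity score of one interval, recomputed from scratch
#'
#' Counts the k-mers of `seq[start, end)` into a fresh table and evaluates
#' `S = sum(log c!) - T * ell - f(ell)`. Ground truth for the incremental
#' scan implementation.
#'
#' @param seq a single ACGT-only DNA string.
#' @param start,end 0-based half-open base coordinates; the interval must
#'   hold at least one k-mer and at most the model window `w`.
#' @param model a [ld_model()] object.
#' @return Score `S` in nats.
#' @examples
#' m <- ld_model(ld_params(k = 5, w = 60, gc = 0.5))
#' oracle_score(strrep("A", 30), 0, 30, m)
#' @export
oracle_score <- function(seq, start, end, model) {
    stopifnot(inherits(model, "longdust_model"))
    n <- nchar(seq)
    if (start < 0 || end > n || end - start < model$params$k)
        stop("interval out of range or shorter than k")
    sub <- substr(seq, start + 1L, end)
    score_s(kmer_counts(sub, model$params$k), model)
}

# Dense matrix of interval scores: M[s + 1, e + 1] = S of base interval
# [s, e] (0-based inclusive) for all intervals holding <= w k-mers.
.score_matrix <- function(seq, model) {
    p <- model$params
    codes <- .chk_codes(seq)
    n <- length(codes)
    kc <- .kmer_codes(codes, p$k)
    M <- matrix(NA_real_, n, n)
    if (n < p$k) return(M)
    cnt <- integer(4^p$k)
    lf <- model$logfact
    f <- model$f
    T <- p$threshold
    for (s in 1:(n - p$k + 1L)) {      # 1-based base start
        emax <- min(n, s + p$w + p$k - 2L)  # at most w k-mers
        touched <- integer(0)
        u <- 0
        for (e in (s + p$k - 1L):emax) {  # 1-based base end
            t <- kc[e - p$k + 1L] + 1L
            cnt[t] <- cnt[t] + 1L
            touched <- c(touched, t)
            u <- u + lf[cnt[t] + 1L] - lf[cnt[t]] - T
            M[s, e] <- u - f[e - s - p$k + 3L]  # ell = e - s - k + 2
        }
        cnt[touched] <- 0L
    }
    M
}

#' Exhaustively enumerate good and perfect LC intervals
#'
#' Scores every interval of up to `w` k-mers from scratch (O(w^2 n)) and
#' applies the interval definitions directly: an interval is *good* if
#' `S > 0` and no proper prefix or suffix scores strictly higher, and
#' *perfect* if additionally no substring scores strictly higher (ties do
#' not disqualify). Intended as the test oracle for the scanning algorithm;
#' inputs are capped at 2000 bases and `w <= 200`.
#'
#' @param seq a single ACGT-only DNA string (at most 2000 bases).
#' @param model a [ld_model()] object with `w <= 200`.
#' @return A list with `good`: data frame of all good intervals (`start`,
#'   `end` 0-based half-open, `score`, logical `perfect`), and `coverage`:
#'   logical vector marking bases covered by the union of good intervals.
#' @examples
#' m <- ld_model(ld_params(k = 3, w = 60, gc = 0.5))
#' oracle_good_intervals(strrep("AT", 30), m)$good
#' @export
oracle_good_intervals <- function(seq, model) {
    stopifnot(inherits(model, "longdust_model"))
    n <- nchar(seq)
    if (n > 2000L) stop("oracle enumeration is capped at 2000 bases")
    if (model$params$w > 200L) stop("oracle enumeration is capped at w = 200")
    k <- model$params$k
    M <- .score_matrix(seq, model)
    gs <- integer(0); ge <- integer(0); gv <- numeric(0); gp <- logical(0)
    cov <- logical(n)
    if (n >= k) {
        for (s in 1:(n - k + 1L)) {
            for (e in which(!is.na(M[s, ]) & M[s, ] > 0)) {
                S <- M[s, e]
                # proper prefixes end before e; proper suffixes start after s
                pref <- if (e - 1L >= s + k - 1L) M[s, (s + k - 1L):(e - 1L)]
                        else numeric(0)
                suff <- if (s + 1L <= e - k + 1L) M[(s + 1L):(e - k + 1L), e]
                        else numeric(0)
                ps <- c(pref, suff)
                ps <- ps[!is.na(ps)]
                if (any(ps > S)) next
                sub <- M[s:e, s:e]
                sub <- sub[!is.na(sub)]
                gs <- c(gs, s - 1L); ge <- c(ge, e); gv <- c(gv, S)
                gp <- c(gp, !any(sub > S))
                cov[s:e] <- TRUE
            }
        }
    }
    list(good = data.frame(start = gs, end = ge, score = gv, perfect = gp),
         coverage = cov)
}
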