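# Shared fixtures and independent mini-oracles used across the test files.

rand_dna <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# Direct evaluation of the Poisson-form scaling function, summing over all
# 4^k k-mers individually (no G/C grouping): independent oracle for the
# grouped table. Suitable for small k and ell only.
f_direct <- function(ell, k, gc, nmax = 200) {
    codes <- 0:(4^k - 1)
    gc_count <- integer(length(codes))
    rem <- codes
    for (pos in seq_len(k)) {
        d <- rem %% 4L
        rem <- rem %/% 4L
        gc_count <- gc_count + (d == 1L | d == 2L)
    }
    q <- (gc / 2)^gc_count * ((1 - gc) / 2)^(k - gc_count)
    n <- 2:nmax
    sum(vapply(q, function(qt)
        sum(lfactorial(n) * stats::dpois(n, ell * qt)), numeric(1)))
}

# Brute-force suffix scores S(i - k + 1, j) for all k-mer end positions i
# in [max(k-1, j-w+1), j], computed from scratch via the oracle scorer.
suffix_scores <- function(seq, j, model) {
    k <- model$params$k
    ilo <- max(k - 1, j - model$params$w + 1)
    pos <- ilo:j
    v <- vapply(pos, function(i) oracle_score(seq, i - k + 1, j + 1, model),
                numeric(1))
    data.frame(pos = pos, v = v)
}

# The seeded 300 bp planted-repeat suite (k = 5, w = 60) shared by the
# soundness and oracle-coverage checks. Heuristics off, single strand.
suite_model <- function() {
    ld_model(ld_params(k = 5, w = 60, threshold = 0.6, gc = 0.5,
                       both_strands = FALSE, use_extension = FALSE))
}

suite_seq <- function(i) {
    set.seed(1000 + i)
    unit <- sample(3:8, 1)
    copies <- sample(5:12, 1)
    sub <- sample(c(0, 0, 0.05), 1)
    at <- sample(0:(300 - unit * copies), 1)
    simulate_genome(300, gc = 0.5,
                    repeats = list(list(unit = unit, copies = copies,
                                        sub = sub, at = at)),
                    seed = 2000 + i)$seq
}

# Good-LC-interval predicate applied to one interval (0-based half-open)
# using a precomputed oracle score matrix (1-based [start, end] indexing).
is_good_interval <- function(M, start, end, k) {
    s <- start + 1L
    e <- end
    S <- M[s, e]
    if (is.na(S) || S <= 0) return(FALSE)
    pref <- if (e - 1L >= s + k - 1L) M[s, (s + k - 1L):(e - 1L)] else numeric(0)
    suff <- if (s + 1L <= e - k + 1L) M[(s + 1L):(e - k + 1L), e] else numeric(0)
    ps <- c(pref, suff)
    ps <- ps[!is.na(ps)]
    !any(ps > S + 1e-9)
}

interval_coverage <- function(df, n) {
    cov <- logical(n)
    for (z in seq_len(nrow(df))) cov[(df$start[z] + 1L):df$end[z]] <- TRUE
    cov
}
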