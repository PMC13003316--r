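test_that("SDUST score: closed-form cases", {
    T <- 0.6
    # all k-mers distinct
    expect_equal(score_sdust("ACGTA", T, k = 3), -T)
    # homopolymer with k = 3: one 3-mer counted ell times
    n <- 20
    ell <- n - 2
    expect_equal(score_sdust(strrep("A", n), T, k = 3), (ell - 1) / 2 - T)
    # two k-mers each counted twice, ell = 4
    kc <- kmer_counts("AAAA", 3)   # placeholder counts, then by hand
    counts <- structure(list(counts = c(`0` = 2L, `1` = 2L), ell = 4L, k = 3L),
                        class = "kmer_counts")
    expect_equal(score_sdust(counts, T), (1 + 1) / 4 - T)
    # empty-sum convention
    empty <- structure(list(counts = integer(0), ell = 0L, k = 3L),
                       class = "kmer_counts")
    expect_equal(score_sdust(empty, T), -T)
})

test_that("entropy score and Shannon entropy", {
    T <- 0.6
    expect_equal(score_entropy("ACGTA", T, k = 3), -T)    # all distinct
    # single k-mer repeated ell times
    kc <- kmer_counts(strrep("A", 12), 3)
    expect_equal(score_entropy(kc, T), log(10) - T)
    expect_equal(shannon_entropy(kc), 0)
    # uniform counts of 2 over ell/2 k-mers
    counts <- structure(list(counts = c(a = 2L, b = 2L, c = 2L), ell = 6L,
                             k = 3L), class = "kmer_counts")
    expect_equal(score_entropy(counts, T), log(2) - T)
    # maximal entropy at all-distinct counts
    kc2 <- kmer_counts("ACGTAC", 3)
    expect_equal(shannon_entropy(kc2), log(4))
    # algebraic identity H + S_E + T = log(ell)
    set.seed(31)
    for (z in 1:20) {
        s <- rand_dna(sample(10:60, 1))
        kc <- kmer_counts(s, 3)
        expect_equal(shannon_entropy(kc) + score_entropy(kc, T) + T,
                     log(kc$ell), tolerance = 1e-9)
    }
    # defined only up to ell = 4^k
    expect_error(score_entropy(rand_dna(100), T, k = 3), "4\\^k")
    expect_error(shannon_entropy(structure(list(counts = integer(0), ell = 0L,
                                                k = 3L),
                                          class = "kmer_counts")), "empty")
})

test_that("all scorers return -T on strings with distinct k-mers", {
    m <- ld_model(ld_params(k = 3, w = 60, gc = 0.5))
    s <- "ACGTTGA"   # distinct 3-mers
    kc <- kmer_counts(s, 3)
    expect_true(all(kc$counts == 1L))
    expect_equal(score_sdust(kc, 0.6), -0.6)
    expect_equal(score_entropy(kc, 0.6), -0.6)
    # longdust per-string analogue: S = -T*ell - f(ell), i.e. -T per k-mer
    # before scaling; check the Q part vanishes up to f
    expect_equal(score_s(kc, m) + m$f[kc$ell + 1], -0.6 * kc$ell)
})

test_that("SDUST score grows linearly while the longdust score flattens per base", {
    m <- ld_model(ld_params(k = 7, w = 1000, gc = 0.5))
    ns <- seq(50, 500, by = 50)
    ell <- numeric(0); ss <- numeric(0); s_ld <- numeric(0)
    raw_sdust <- numeric(0); raw_q <- numeric(0)
    for (n in ns) {
        s <- strrep("AC", n)
        kc <- kmer_counts(s, 7)
        ell <- c(ell, kc$ell)
        ss <- c(ss, score_sdust(kc, 0.6, k = 7))
        s_ld <- c(s_ld, score_s(kc, m))
        raw_sdust <- c(raw_sdust, sum(kc$counts * (kc$counts - 1) / 2))
        raw_q <- c(raw_q, sum(lfactorial(kc$counts)))
    }
    # unnormalised statistics: quadratic (SDUST) vs ~ ell log ell (longdust)
    expect_gt(coef(lm(log(raw_sdust) ~ log(ell)))[2], 1.9)
    expect_lt(coef(lm(log(raw_q) ~ log(ell)))[2], 1.3)
    # per-base SDUST score is approximately constant in length...
    expect_lt(max(ss / ell) / min(ss / ell) - 1, 0.1)
    # ...while SDUST's total grows linearly
    expect_gt(coef(lm(ss ~ ell))[2], 0)
    # the longdust per-base score flattens: its increments shrink
    expect_true(all(diff(diff(s_ld / ell)) < 0))
})

test_that("alternative scorers drive the interval scan", {
    sim <- simulate_genome(2000, repeats = list(
        list(unit = 4, copies = 20, at = 1000)), seed = 32)
    m <- ld_model(ld_params(k = 3, w = 60, gc = 0.5))
    for (scorer in c("sdust", "entropy")) {
        iv <- ld_scan(sim$seq, m, scorer = scorer)
        cov <- interval_coverage(iv, nchar(sim$seq))
        expect_gte(mean(cov[1001:1080]), 0.8)
    }
    # entropy scorer refuses windows beyond its defined range
    m_big <- ld_model(ld_params(k = 3, w = 100, gc = 0.5))
    expect_error(ld_scan(sim$seq, m_big, scorer = "entropy"), "4\\^k")
})
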