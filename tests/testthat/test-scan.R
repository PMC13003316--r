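m200 <- ld_model(ld_params(k = 7, w = 200, gc = 0.5))

test_that("backward pass matches brute-force suffix scores", {
    # random window with all k-mers unique: no candidate
    set.seed(11)
    rnd <- rand_dna(150)
    if (max(kmer_counts(rnd, 7)$counts) == 1L)
        expect_equal(nrow(ld_backward(rnd, 149, m200)), 0)

    # tandem repeat: smallest candidate maps to (or before) the first unit
    m5 <- ld_model(ld_params(k = 5, w = 200, gc = 0.5))
    rep5 <- strrep("AACGT", 30)
    b <- ld_backward(rep5, 149, m5)
    expect_gt(nrow(b), 0)
    expect_lte(min(b$pos) - 5 + 1, 5)
    expect_true(all(b$vbound > 0))
    # the recorded bound is the brute-force maximum suffix score
    ss <- suffix_scores(rep5, 149, m5)
    expect_equal(max(b$vbound), max(ss$v), tolerance = 1e-9)

    # homopolymer behind a random flank: the suffix-score argmax is emitted
    set.seed(12)
    s <- paste0(rand_dna(200), strrep("A", 60))
    b2 <- ld_backward(s, 259, m200)
    ss2 <- suffix_scores(s, 259, m200)
    best <- min(ss2$pos[ss2$v >= max(ss2$v) - 1e-12])
    expect_true(best %in% b2$pos)
    expect_equal(max(b2$vbound), max(ss2$v), tolerance = 1e-9)
})

test_that("forward pass returns the prefix-score argmax", {
    # full homopolymer: the whole run is its own maximum
    polyA <- strrep("A", 60)
    expect_equal(ld_forward(polyA, 6, 59, m200)$imax, 59)
    # degenerate single k-mer scan never reaches a positive score
    expect_equal(ld_forward(polyA, 6, 6, m200)$imax, -1)

    # repeat followed by random tail: argmax sits at/near the repeat end
    set.seed(13)
    s <- paste0(strrep("A", 60), rand_dna(140))
    r <- ld_forward(s, 6, 199, m200)
    expect_lt(r$imax, 199)
    profile <- vapply(6:199, function(e) oracle_score(s, 0, e + 1, m200),
                      numeric(1))
    brute <- max((6:199)[profile >= max(profile) - 1e-12])
    expect_equal(r$imax, brute)
})

test_that("find_start reports good intervals and nothing on random input", {
    set.seed(14)
    rnd <- rand_dna(300)
    expect_equal(nrow(ld_find_start(rnd, 299, m200)), 0)

    m5 <- ld_model(ld_params(k = 5, w = 200, gc = 0.5))
    s <- strrep("ACGGT", 40)
    hit <- ld_find_start(s, 199, m5)
    expect_equal(nrow(hit), 1)
    expect_lte(hit$start, 5)  # starts within the first repeat unit
    # independently verify the good-interval predicate
    M <- longdustr:::.score_matrix(s, m5)
    expect_true(is_good_interval(M, hit$start, hit$end, 5))
})

test_that("incremental scores agree with from-scratch recomputation", {
    set.seed(15)
    s <- paste0(rand_dna(80), strrep("ATG", 20), rand_dna(80))
    m <- ld_model(ld_params(k = 5, w = 150, gc = 0.5))
    for (z in 1:50) {
        j <- sample(4:(nchar(s) - 1), 1)
        lo <- max(4, j - 140)  # at most w k-mers
        i0 <- lo + sample.int(j - lo + 1, 1) - 1L
        r <- ld_forward(s, i0, j, m)
        expect_equal(r$score_at_j, oracle_score(s, i0 - 4, j + 1, m),
                     tolerance = 1e-9)
    }
})

test_that("scan masks planted repeats and stays quiet on random sequence", {
    set.seed(16)
    rnd <- rand_dna(10000)
    mdef <- ld_model(ld_params(gc = 0.5))
    iv <- ld_scan(rnd, mdef)
    expect_lt(sum(iv$end - iv$start), 0.005 * 10000)

    sim <- simulate_genome(6000, repeats = list(
        list(unit = "ACGGT", copies = 40, at = 2000)), seed = 17)
    iv2 <- ld_scan(sim$seq, mdef)
    cov <- interval_coverage(iv2, 6000)
    expect_gte(sum(cov[2001:2200]) / 200, 0.95)
    expect_lt(sum(cov[c(1:2000, 2201:6000)]), 0.01 * 5800)
})

test_that("arrays below the minimum copy number are not called", {
    # random 20-mer unit, k = 7: formula needs ~3.31 copies
    hits <- function(copies, seed) {
        sim <- simulate_genome(1200, repeats = list(
            list(unit = 20, copies = copies, at = 600)), seed = seed)
        iv <- longdust(c(s = sim$seq))
        arr <- sim$truth
        sum(pmax(0, pmin(iv$end, arr$end) - pmax(iv$start, arr$start)))
    }
    expect_equal(hits(3, 181), 0)
    expect_gte(hits(4, 181), 0.9 * 80)
})

test_that("raw intervals never exceed the window and merging is maximal", {
    sim <- simulate_genome(4000, repeats = list(
        list(unit = 171, copies = 18, sub = 0.05, at = 500)), seed = 18)
    # w must admit > 3 copies of the 171-mer unit for the array to score
    m <- ld_model(ld_params(k = 7, w = 2000, gc = 0.5, use_extension = FALSE))
    raw <- ld_scan(sim$seq, m, merge = FALSE)
    expect_gt(nrow(raw), 0)
    expect_true(all(raw$end - raw$start <= 2000 + 7 - 1))
    merged <- ld_scan(sim$seq, m)
    expect_true(all(merged$start[-1] > merged$end[-nrow(merged)]))
    expect_gt(max(merged$end - merged$start), 2000 + 6)  # merging spans > w
    # the satellite array is essentially fully masked
    cov <- interval_coverage(merged, nchar(sim$seq))
    arr <- sim$truth
    expect_gte(mean(cov[(arr$start + 1):arr$end]), 0.95)
})

test_that("raising the threshold never increases masked bases", {
    sim <- simulate_genome(5000, repeats = list(
        list(unit = 10, copies = 12, sub = 0.05, at = 1000),
        list(unit = 51, copies = 6, sub = 0.08, at = 2500)), seed = 19)
    masked <- vapply(c(0.4, 0.6, 0.8, 1.0), function(T) {
        iv <- ld_scan(sim$seq, ld_model(ld_params(threshold = T, gc = 0.5)))
        sum(iv$end - iv$start)
    }, numeric(1))
    expect_true(all(diff(masked) <= 0))
})

test_that("ambiguous bases split the scan and are never covered", {
    left <- strrep("AT", 30)
    right <- strrep("CAG", 20)
    s <- paste0(left, "N", right, "RY", strrep("A", 30))
    m <- ld_model(ld_params(k = 5, w = 100, gc = 0.5))
    iv <- ld_scan(s, m)
    expect_gt(nrow(iv), 0)
    ch <- strsplit(s, "")[[1]]
    cov <- interval_coverage(iv, nchar(s))
    expect_true(all(ch[cov] %in% c("A", "C", "G", "T")))
    # each repeat block is recovered despite the splits
    expect_gte(mean(cov[1:60]), 0.9)
    expect_gte(mean(cov[62:121]), 0.9)
})

test_that("X-drop splits spacer-joined intervals and is off by default", {
    set.seed(20)
    spacer <- rand_dna(300)
    s <- paste0(strrep("A", 40), spacer, strrep("A", 40))
    m <- ld_model(ld_params(k = 7, w = 500, gc = 0.5))
    # force a single candidate interval spanning both runs
    joined <- data.frame(start = 0L, end = nchar(s))
    mx <- ld_model(ld_params(k = 7, w = 500, gc = 0.5, xdrop = 25))
    split <- xdrop_filter(joined, s, mx)
    expect_gte(nrow(split), 2)
    cov <- interval_coverage(split, nchar(s))
    expect_true(all(cov[1:34]))            # first run kept (k-mer ends)
    expect_true(all(cov[341:380]))         # second run kept
    expect_lt(mean(cov[61:320]), 0.2)      # spacer excluded
    # infinite / unset xdrop is the identity
    expect_identical(xdrop_filter(joined, s, m), joined)

    # minor effect on realistic satellite input
    sim <- simulate_genome(20000, repeats = list(
        list(unit = 171, copies = 60, sub = 0.05, at = 3000),
        list(unit = 5, copies = 80, sub = 0.02, at = 16000)), seed = 21)
    tot <- function(mm) {
        iv <- ld_scan(sim$seq, mm)
        sum(iv$end - iv$start)
    }
    t_off <- tot(ld_model(ld_params(gc = 0.5)))
    t_on <- tot(ld_model(ld_params(gc = 0.5, xdrop = 25)))
    expect_lte(t_on, t_off)
    expect_lt((t_off - t_on) / t_off, 0.02)
})

test_that("strand union output is invariant under reverse complement", {
    for (seed in 22:24) {
        sim <- simulate_genome(4000, repeats = list(
            list(unit = 13, copies = 15, sub = 0.03, at = 1200)), seed = seed)
        bed_f <- longdust(c(x = sim$seq), w = 1000)
        bed_r <- longdust(c(x = revcomp(sim$seq)), w = 1000)
        n <- nchar(sim$seq)
        mapped <- data.frame(seqid = bed_r$seqid, start = n - bed_r$end,
                             end = n - bed_r$start)
        mapped <- mapped[order(mapped$start), ]
        rownames(mapped) <- NULL
        expect_equal(bed_f, mapped)
    }
    # coordinate mapping of a reverse-strand interval
    rc_iv <- data.frame(start = 100L, end = 200L)
    n <- 1000L
    expect_equal(data.frame(start = n - rc_iv$end, end = n - rc_iv$start),
                 data.frame(start = 800L, end = 900L))
})

test_that("extension heuristic preserves satellite coverage", {
    sim <- simulate_genome(15000, repeats = list(
        list(unit = 171, copies = 50, sub = 0.05, at = 2000)), seed = 25)
    m_on <- ld_model(ld_params(w = 2000, gc = 0.5))
    m_off <- ld_model(ld_params(w = 2000, gc = 0.5, use_extension = FALSE))
    cov_on <- sum(with(ld_scan(sim$seq, m_on), end - start))
    cov_off <- sum(with(ld_scan(sim$seq, m_off), end - start))
    expect_lt(abs(cov_on - cov_off) / cov_off, 0.02)
})

test_that("fast-start variant stays close to the default scan", {
    sim <- simulate_genome(6000, repeats = list(
        list(unit = 20, copies = 10, sub = 0.02, at = 3000)), seed = 26)
    iv_def <- ld_scan(sim$seq, ld_model(ld_params(gc = 0.5)))
    iv_fast <- ld_scan(sim$seq, ld_model(ld_params(gc = 0.5, fast_start = TRUE)))
    cov_d <- interval_coverage(iv_def, 6000)
    cov_f <- interval_coverage(iv_fast, 6000)
    expect_gt(sum(cov_d & cov_f) / max(1, sum(cov_d | cov_f)), 0.9)
})
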