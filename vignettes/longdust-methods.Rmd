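---
title: "How longdustr defines and finds low-complexity DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How longdustr defines and finds low-complexity DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdustr)
```

## The statistical model

Low-complexity (LC) DNA -- homopolymers, short tandem repeats, satellite
arrays -- is compositionally repetitive: some k-mers occur far more often
than a random string of the same length would allow. `longdustr` turns this
into a score through a bag-of-words model. For a string $x$ holding
$\ell = |x| - k + 1$ k-mers with counts $c(t)$, the count vector is
multinomial with per-k-mer frequencies $q_t$, and the log-probability of the
counts decomposes into a length term, a k-mer-usage term, and the
repetitiveness term $-\sum_t \log c(t)!$. Only the last one is kept: a
string of rare-but-unique k-mers should not count as low complexity.

To compare strings of different lengths the statistic is centred by its
null expectation. Under a Poisson approximation to the per-k-mer counts,

$$f(\ell) \;=\; \sum_t e^{-\ell q_t} \sum_{n \ge 2} \log(n!)\,
   \frac{(\ell q_t)^n}{n!}$$

is the expected value of $\sum_t \log c(t)!$ for a random string, so

$$Q = \sum_t \log c(t)! - f(\ell)$$

approaches zero on random sequence regardless of length (verified by
simulation in the test suite) and grows on repetitive sequence. A
per-k-mer threshold $T$ then defines the decision score

$$S = Q - T\ell,$$

and a string *contains* an LC substring iff $S > 0$.

### Background frequencies from GC content

$q_t$ is derived from the genome-wide G+C fraction alone, with bases
independent: $q_t = (gc/2)^m\,((1-gc)/2)^{k-m}$ where $m$ is the number of
G/C bases in $t$. This is the only background under which $q_t$ is a
function of GC alone; it collapses the $4^k$ frequencies to $k+1$ distinct
values, which makes the $f$ table cheap (a sum over $k+1$ groups of sizes
$\binom{k}{m}2^k$ instead of $4^k$ terms). Biased GC raises $f$, since
counts of GC-skewed k-mers inflate faster; $f$ is symmetric in
$gc \leftrightarrow 1-gc$. The GC fraction is computed once over all input
records jointly (A/C/G/T bases only) and can be overridden (`gc=` / `-g`).
Richer backgrounds (dinucleotide or Markov models) are deliberately out of
scope.

## Parameters

* `k = 7` -- complexity is measured on 7-mer counts. Larger `k` sharpens
  the null but misses repeats whose unit structure only shows at short
  k-mers; `k` up to 12 is supported.
* `w = 5000` (k-mers) -- the context window. A single good interval holds
  at most `w` k-mers; longer LC regions (megabase satellite arrays) arise
  by merging overlapping calls. The speedups also rely on
  $\ell \ll 4^k$, so very large `w` with small `k` is both slow and
  statistically strained.
* `threshold = 0.6` nats per k-mer, below $\log 2$: a k-mer pair
  ($\log 2!$) does not by itself pay for its length. The score of a random
  string drifts down at $-T$ per k-mer, so calls end quickly outside
  repeats. Validity requires $0 < T < \log 4$.
* `xdrop` -- optional (off by default; 25 nats is a reasonable setting).
  Splits a reported interval where the running prefix score falls more
  than `xdrop` below its running maximum, removing random spacers between
  adjacent repeat blocks. Its effect on total masked length is small
  (percent-level on satellite-rich input, tested).
* `both_strands = TRUE` -- scan both strands and output the union, making
  the output invariant under reverse complementation (see below).

## Finding good LC intervals

An interval is a *good LC interval* if $S > 0$ and no proper prefix or
suffix scores strictly higher (ties tolerated); it is *perfect* if no
substring scores higher. The union of all good intervals defines the LC
regions; enumerating them naively costs $O(w^2 L)$, which the scan reduces
to approximately $O(wL)$:

1. **Backward pass.** From each end position $j$, scan starts backwards,
   updating the suffix score incrementally
   ($u \leftarrow u + \log c(t) - T$, $v = u - f(\ell)$). A start is a
   candidate only if its suffix score matched the running maximum before
   dropping; the final global argmax is appended last. Candidates with a
   non-positive score bound are discarded -- they can never head an
   interval with $S > 0$. While no candidate has been seen, a second
   accumulator reads counts from the full window and aborts the pass once
   it goes negative (a suffix enriched with window-unique k-mers cannot be
   extended to reach $j$).
2. **Forward pass.** Each candidate is rescanned forward with fresh
   counts; the candidate heads a good interval ending at $j$ iff the
   prefix-score argmax is $j$ itself. Candidates contained in a previous
   forward reach are skipped (an approximation), and the pass stops early
   once the score exceeds the candidate's recorded suffix bound.
3. **Genome scan.** Position $j$ is skipped outright when the k-mer ending
   at $j$ is unique in the window (the forward pass could not reach $j$).
   When the previous position produced a good interval spanning the whole
   window, the *extension heuristic* slides its end to $j$ without a new
   candidate search, provided the incoming k-mer repeats in the window --
   this is what keeps deep satellite arrays close to $O(L)$.
   Overlapping or directly adjacent calls are merged into maximal regions.

With the heuristics disabled, every emitted interval satisfies the
good-interval predicate checked by the independent brute-force oracle
(`oracle_good_intervals()`), and the emitted union covers at least 99% of
the oracle's union on the seeded planted-repeat suite; the scan is
approximate, so exact equality is not guaranteed.

Because the heuristics are not exactly strand symmetric, the default
pipeline scans both strands, maps reverse-complement calls back
($[s,e) \mapsto [n-e, n-s)$) and merges; the result is invariant under
reverse complementation by construction. Single-strand mode (`-f`-style)
may differ slightly between strands.

## Numerical choices

* The inner Poisson sum of $f$ starts at $n = 2$ ($\log 0! = \log 1! =
  0$), accumulates terms computed in log space (so large Poisson means do
  not underflow), and stops past the mode once a term falls below
  $10^{-12}$ of the running sum, with a hard cap at
  $\lceil\lambda\rceil + 20\sqrt\lambda + 50$. The table is computed once
  per model for integer $\ell \in [0, w]$; $\ell$ is always an integer,
  so no interpolation is needed.
* $f$ is monotone in $\ell$ by construction; the implementation clamps
  truncation-level wiggles so the invariant holds exactly.
* $\log n!$ comes from a precomputed table up to $w$ (counts cannot
  exceed $\ell \le w$), avoiding transcendental calls in inner loops.
* Ties: a later position attaining the running maximum replaces the
  earlier one ($v \ge v_{max}$), in both passes; correspondingly the
  good/perfect predicates treat equal-scoring prefixes/suffixes as
  non-disqualifying.
* Ambiguous bases (anything outside A/C/G/T) split the input; each
  segment is scanned independently and no interval spans a split. The
  2-bit k-mer encoding never sees ambiguity codes.
* In X-drop splitting of extension-grown intervals longer than the
  window, the scaling term is capped at $f(w)$. This is conservative
  (drops deep inside long arrays are slightly under-reported) and only
  affects the opt-in X-drop path.
* Reported coordinates follow the scoring definition: a candidate k-mer
  ending at $i$ opens the base interval $[i-k+1, j]$, emitted as 0-based
  half-open BED.

## The synthetic generator

`simulate_genome()` emulates the regimes the scanner is meant for:
i.i.d. background at a chosen GC, with planted tandem arrays
(`unit^copies`) degraded by per-base substitutions and indels -- from
microsatellites (units of a few bases) to alpha-satellite-like arrays with
~170 bp units. Indels shift downstream coordinates and the returned truth
intervals refer to the emitted sequence. It does **not** emulate diverged
higher-order repeat structure, nested or interrupted repeats, segmental
duplications, or real base-composition heterogeneity, so passing tests on
synthetic data demonstrate correctness of the algorithm under its own
model, not genome-wide accuracy claims.

Test problem sizes are chosen to keep the brute-force oracle exact and the
suite quick: the planted-repeat suite uses 100 seeded 300 bp sequences at
`k = 5, w = 60`; null specificity uses 100 seeded 10 kb sequences at
defaults; copy-number behaviour uses 20 seeded trials with random 20-mer
units, where the closed form predicts a ~3.31-copy detection threshold
(arrays of 3 exact copies score negative, 4 copies positive).

## Design decisions at genuinely open points

* The extension heuristic is specified here as: extend when the previous
  position's good interval spans the entire window **and** the incoming
  k-mer occurs at least twice in the window. This is the cheapest test
  consistent with sliding a window-saturated interval; the soundness
  checks run with it disabled.
* Candidate emission requires a strictly positive score bound (inference
  from the $S > 0$ requirement, not an extra heuristic).
* The guaranteed-$O(w)$ variant of the candidate search (forward from the
  smallest candidate only) is available as `fast_start = TRUE` but is not
  the default, being further from the exact interval definition.
* The SDUST scoring function is provided as a drop-in scorer (default
  `k = 3` on the command line, matching its own convention), and the
  entropy scorer likewise (defined only for $\ell \le 4^k$, enforced).
  Both plug into the same scan machinery; the entropy scorer lacks the
  longdust-specific backward early-exit and is therefore slower.

## Known limitations

* No repeat units or copy numbers are reported -- only intervals.
* Repeats whose unit exceeds the window (tens of kb) are missed at
  defaults; raising `w` is possible but increasingly slow.
* The scan is approximate: rarely, a good interval starting inside
  another good interval can be missed (quantified by the oracle-coverage
  bound, not eliminated).
* The Poisson-approximated centring is derived for $\ell \ll 4^k$;
  with small `k` and large `w` the null is less well centred.
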