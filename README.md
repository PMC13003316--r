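# longdustr

Statistical detection of low-complexity (LC) DNA with the longdust
algorithm: homopolymers, short tandem repeats and long satellite arrays
(alpha-satellite-scale units included), reported as BED intervals or masked
FASTA. LC regions cause spurious homology matches and variant-calling
artifacts; masking them is routine in alignment and variant filtration
pipelines. Classic DUST-family tools score 3-mer counts in small windows
and cannot see repeats with long units; `longdustr` scores k-mer counts
under an explicit statistical model in windows of thousands of bases, so
centromeric satellite comes out as long contiguous blocks.

## The model in brief

For a string holding `ell` k-mers with counts `c(t)`, complexity is scored
as

    Q = sum_t log c(t)!  -  f(ell)          (nats)
    S = Q - T * ell

where `f(ell) = sum_t exp(-ell q_t) sum_{n>=2} log(n!) (ell q_t)^n / n!`
is the Poisson-approximated expectation of the first term for random
sequence with k-mer frequencies `q_t` derived from genome GC content. `Q`
stays near 0 on random sequence of any length; `S > 0` flags an LC
substring under the per-k-mer threshold `T` (default 0.6, k = 7, window
w = 5000 k-mers). An interval is reported when it is a *good LC interval*:
`S > 0` and no prefix or suffix scores higher. Good intervals are located
by an efficient backward/forward candidate scan, merged into maximal
regions, and the union over both strands makes the output invariant under
reverse complement. The SDUST and Shannon-entropy scoring functions are
included as drop-in alternatives for comparison, and a brute-force oracle
(`oracle_good_intervals()`) provides ground truth for validation.

## Worked example

Simulate a 6 kb sequence with an alpha-satellite-like array (171 bp unit,
20 copies, 5% substitution divergence) planted at position 1500, then mask
it:

```r
library(longdustr)
sim <- simulate_genome(6000, repeats = list(
    list(unit = 171, copies = 20, sub = 0.05, at = 1500)), seed = 7)
sim$truth
#>   start  end
#> 1  1500 4920
longdust(c(chr_sim = sim$seq), w = 2000)
#>     seqid start  end
#> 1 chr_sim  1500 4911
```

The single reported interval covers the planted 3420 bp array (99.7% of
it, nothing of the random flanks) even though it is longer than the
2000-k-mer window: overlapping good intervals are merged. Coordinates are
0-based half-open (BED). `write_bed()` and `write_masked_fasta()` produce
the standard output files.

The same pipeline is available from the shell (see `inst/cli/longdust`):

```sh
longdust simulate --length 6000 --unit 171 --copies 20 --sub 0.05 \
    --at 1500 --seed 7 --out-fasta sim.fa --out-bed truth.bed
longdust mask -w 2000 sim.fa -o lc.bed --fasta-out sim.masked.fa
```

Useful knobs: `-k` (k-mer size), `-w` (window), `-t` (threshold, nats),
`-g` (GC override), `--xdrop` (split intervals across random spacers),
`--single-strand`, `--scorer sdust|entropy`.

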