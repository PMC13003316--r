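#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scorer codes shared with the R wrappers (see R/scan.R).
enum { SC_LONGDUST = 0, SC_SDUST = 1, SC_ENTROPY = 2 };

// n * log(n) with the 0 * log(0) = 0 convention.
static inline double xlogx(double n) { return n > 0.0 ? n * std::log(n) : 0.0; }

// Poisson-approximated expectation of sum_t log c(t)! for a random string
// holding l k-mers.  k-mers are grouped by their G+C count m: all k-mers in a
// group share the frequency q_m = (gc/2)^m ((1-gc)/2)^(k-m) and there are
// choose(k,m) * 2^k of them.  The inner Poisson sum starts at n = 2
// (log 0! = log 1! = 0), is evaluated with log-space terms so that large
// Poisson means do not underflow, and stops past the mode once a term drops
// below rel_tol of the accumulated sum (hard cap: mean + 20*sd + 50).
// [[Rcpp::export(name = ".ld_ftable_cpp")]]
NumericVector ld_ftable_cpp(int lmax, int k, double gc, double rel_tol = 1e-12) {
    NumericVector f(lmax + 1);
    std::vector<double> q(k + 1), ngrp(k + 1);
    for (int m = 0; m <= k; ++m) {
        q[m] = std::pow(gc / 2.0, m) * std::pow((1.0 - gc) / 2.0, k - m);
        ngrp[m] = Rf_choose((double)k, (double)m) * std::pow(2.0, (double)k);
    }
    for (int l = 1; l <= lmax; ++l) {
        double s = 0.0;
        for (int m = 0; m <= k; ++m) {
            double lam = (double)l * q[m];
            if (lam <= 0.0) continue;
            double llam = std::log(lam);
            int ncap = (int)std::ceil(lam + 20.0 * std::sqrt(lam) + 50.0);
            double acc = 0.0;
            for (int n = 2; n <= ncap; ++n) {
                double lognfact = std::lgamma((double)n + 1.0);
                double term = std::exp(-lam + n * llam - lognfact) * lognfact;
                acc += term;
                if ((double)n > lam && term < rel_tol * acc) break;
            }
            s += ngrp[m] * acc;
        }
        f[l] = s;
        // f is monotone in l by construction of the model; guard against
        // truncation-level wiggles so downstream code can rely on it.
        if (f[l] < f[l - 1]) f[l] = f[l - 1];
    }
    return f;
}

// ---- shared scan machinery ---------------------------------------------

struct Cand { int pos; double v; };

// Incremental per-step score update.  For the longdust score the running
// statistic is u = sum_t log c(t)! - T*l and v = u - f(l); for the SDUST and
// entropy scorers the statistic is the unnormalised numerator and
// v = u / l - T.  cnew is the count of the current k-mer after insertion.
static inline double step_v(int scorer, double &u, int cnew, int l, double T,
                            const double *f) {
    if (scorer == SC_LONGDUST) {
        u += std::log((double)cnew) - T;
        return u - f[l];
    } else if (scorer == SC_SDUST) {
        u += (double)(cnew - 1);
        return u / (double)l - T;
    } else {
        u += xlogx((double)cnew) - xlogx((double)(cnew - 1));
        return u / (double)l - T;
    }
}

// Build 2-bit k-mer codes; kc[i] is the code of the k-mer ending at i
// (valid for i >= k-1).
static void build_kmer_codes(const IntegerVector &codes, int k,
                             std::vector<int> &kc) {
    int n = codes.size();
    kc.assign(n, -1);
    int mask = (1 << (2 * k)) - 1;
    int cur = 0;
    for (int i = 0; i < n; ++i) {
        int b = codes[i];
        if (b < 0 || b > 3) stop("sequence codes must be in 0..3 (A,C,G,T)");
        cur = ((cur << 2) | b) & mask;
        if (i >= k - 1) kc[i] = cur;
    }
}

static void reset_counts(std::vector<int> &c, std::vector<int> &touched) {
    for (size_t z = 0; z < touched.size(); ++z) c[touched[z]] = 0;
    touched.clear();
}

// Backward pass: scan start positions i from j down to max(j-w+1, k-1),
// maintaining the suffix score v = S(i-k+1, j), and collect candidate start
// positions.  cp holds the k-mer counts of the current full window
// [j-w+1, j] and drives the early-termination test (a suffix enriched with
// window-unique k-mers cannot head a good interval).  Candidates are pushed
// in descending position order; the final (global-argmax) candidate, if any,
// is pushed last and is the smallest.  Only positive score bounds are kept:
// a non-positive suffix maximum can never yield S > 0.
static void backward_pass(const std::vector<int> &kc, int j, int k, int w,
                          double T, const double *f, int scorer,
                          const std::vector<int> &cp, std::vector<int> &c,
                          std::vector<int> &touched, std::vector<Cand> &B) {
    B.clear();
    double u = 0.0, v0 = -1.0, up = 0.0, vmax = 0.0;
    int imax = -1;
    int ilo = std::max(j - w + 1, k - 1);
    for (int i = j; i >= ilo; --i) {
        int t = kc[i];
        int cn = ++c[t];
        touched.push_back(t);
        double v = step_v(scorer, u, cn, j - i + 1, T, f);
        if (v < v0 && v0 == vmax) {
            if (vmax > 0.0) { Cand cd = { i + 1, vmax }; B.push_back(cd); }
        } else if (v >= vmax) {
            vmax = v; imax = i;
        } else if (imax < 0 && scorer == SC_LONGDUST) {
            // u' accumulates the would-be forward score of [i, j] read from
            // the full-window counts; once negative, Forward() from any
            // earlier start could not reach j.
            int cw = cp[t];
            if (cw <= 0) break;  // k-mer absent from the window: log 0
            up += std::log((double)cw) - T;
            if (up < 0.0) break;
        }
        v0 = v;
    }
    if (imax >= 0 && vmax > 0.0) { Cand cd = { imax, vmax }; B.push_back(cd); }
    reset_counts(c, touched);
}

// Forward pass from candidate start i0 (a k-mer end position): returns the
// argmax end position of S(i0-k+1, .) in [i0, j], breaking early once the
// score exceeds the candidate's recorded suffix bound.  On ties the latest
// position attaining the maximum wins (v >= vmax).  score_j receives the
// score at i == j when reached (NaN otherwise).
static int forward_pass(const std::vector<int> &kc, int i0, int j, double vbound,
                        double T, const double *f, int scorer,
                        std::vector<int> &c, std::vector<int> &touched,
                        double &score_j) {
    double u = 0.0, vmax = 0.0;
    int imax = -1;
    score_j = std::numeric_limits<double>::quiet_NaN();
    for (int i = i0; i <= j; ++i) {
        int t = kc[i];
        int cn = ++c[t];
        touched.push_back(t);
        double v = step_v(scorer, u, cn, i - i0 + 1, T, f);
        if (i == j) score_j = v;
        if (v >= vmax) { vmax = v; imax = i; }
        if (v > vbound) break;
    }
    reset_counts(c, touched);
    return imax;
}

// FindStart: return the smallest candidate start whose forward argmax is j
// (then [start-k+1, j] is a good LC interval), or -1.  Candidates are taken
// in ascending position order; one contained in a previous forward reach is
// skipped (an approximation).  fast_start restricts to the smallest
// candidate only, which guarantees O(w) per call.
static int find_start(const std::vector<int> &kc, int j, int k, int w, double T,
                      const double *f, int scorer, bool fast_start,
                      const std::vector<int> &cp, std::vector<int> &c,
                      std::vector<int> &touched, double &score_out) {
    std::vector<Cand> B;
    backward_pass(kc, j, k, w, T, f, scorer, cp, c, touched, B);
    int jmaxp = -1;
    for (int bi = (int)B.size() - 1; bi >= 0; --bi) {
        int i = B[bi].pos;
        if (i < jmaxp) continue;
        double sj;
        int j2 = forward_pass(kc, i, j, B[bi].v, T, f, scorer, c, touched, sj);
        if (j2 == j) { score_out = sj; return i; }
        if (fast_start) break;
        jmaxp = std::max(jmaxp, j2);
    }
    return -1;
}

// ---- exported entry points ---------------------------------------------

// Full single-strand scan of an ACGT-only segment.  Returns the raw good LC
// intervals (base coordinates, 0-based inclusive) in scan order, with the
// interval score where it was computed (NA for extension-grown ends).
// [[Rcpp::export(name = ".ld_scan_cpp")]]
List ld_scan_cpp(IntegerVector codes, int k, int w, double T, NumericVector f,
                 bool use_extension, bool fast_start, int scorer) {
    int n = codes.size();
    std::vector<int> kc;
    std::vector<int> rs, re;
    std::vector<double> rv;
    if (n >= k) {
        build_kmer_codes(codes, k, kc);
        int nk = 1 << (2 * k);
        std::vector<int> c(nk, 0), cp(nk, 0), touched;
        const double *fp = REAL(f);
        int last_s = -1, last_e = -2, last_idx = -1;
        for (int j = k - 1; j < n; ++j) {
            ++cp[kc[j]];
            int ev = j - w + k - 1;  // k-mer end leaving window [j-w+1, j]
            if (ev >= k - 1) --cp[kc[ev]];
            if (cp[kc[j]] == 1) continue;  // k-mer unique in window: skip j
            if (use_extension && last_e == j - 1 && last_s <= j - w) {
                // window-saturated good interval at j-1: slide it to j
                re[last_idx] = j;
                rv[last_idx] = NA_REAL;
                last_e = j;
                continue;
            }
            double sc;
            int i = find_start(kc, j, k, w, T, fp, scorer, fast_start,
                               cp, c, touched, sc);
            if (i >= 0) {
                rs.push_back(i - k + 1);
                re.push_back(j);
                rv.push_back(sc);
                last_idx = (int)rs.size() - 1;
                last_s = i - k + 1;
                last_e = j;
            }
        }
    }
    return List::create(_["start"] = wrap(rs), _["end"] = wrap(re),
                        _["score"] = wrap(rv));
}

// X-drop splitting of intervals (base coordinates, 0-based half-open,
// ACGT-only sequence).  The prefix score profile v(p) = S(start, p) is
// recomputed across each interval; when the running maximum exceeds the
// current score by more than xdrop, the interval is truncated at the
// running-max position and scanning restarts, with fresh counts, after the
// drop position.  For intervals longer than the window (possible after the
// extension heuristic) the scaling term is capped at f(w), which is
// conservative: it can only under-report drops deep inside long intervals.
// [[Rcpp::export(name = ".ld_xdrop_cpp")]]
DataFrame ld_xdrop_cpp(IntegerVector codes, IntegerVector starts,
                       IntegerVector ends, int k, double T, NumericVector f,
                       double xdrop, int scorer) {
    std::vector<int> kc;
    build_kmer_codes(codes, k, kc);
    int nk = 1 << (2 * k);
    int fmax = f.size() - 1;
    const double *fp = REAL(f);
    std::vector<int> c(nk, 0), touched;
    std::vector<int> out_s, out_e;
    for (int z = 0; z < starts.size(); ++z) {
        int s0 = starts[z], e0 = ends[z];  // half-open
        int cur = s0;                       // current sub-interval base start
        while (cur + k <= e0) {
            double u = 0.0, vbest = -1e300;
            int pbest = cur + k - 1, drop_at = -1;
            reset_counts(c, touched);
            for (int i = cur + k - 1; i < e0; ++i) {  // k-mer end positions
                int t = kc[i];
                int cn = ++c[t];
                touched.push_back(t);
                int l = i - (cur + k - 1) + 1;
                double v;
                if (scorer == SC_LONGDUST) {
                    u += std::log((double)cn) - T;
                    v = u - fp[l > fmax ? fmax : l];
                } else if (scorer == SC_SDUST) {
                    u += (double)(cn - 1);
                    v = u / (double)l - T;
                } else {
                    u += xlogx((double)cn) - xlogx((double)(cn - 1));
                    v = u / (double)l - T;
                }
                if (v >= vbest) { vbest = v; pbest = i; }
                if (vbest - v > xdrop) { drop_at = i; break; }
            }
            reset_counts(c, touched);
            if (drop_at < 0) {  // no drop: keep the remainder
                out_s.push_back(cur);
                out_e.push_back(e0);
                break;
            }
            out_s.push_back(cur);
            out_e.push_back(pbest + 1);
            cur = drop_at + 1;
        }
    }
    return DataFrame::create(_["start"] = wrap(out_s), _["end"] = wrap(out_e));
}

// [[Rcpp::export(name = ".ld_backward_cpp")]]
DataFrame ld_backward_cpp(IntegerVector codes, int j, int k, int w, double T,
                          NumericVector f, int scorer) {
    int n = codes.size();
    if (j < k - 1 || j >= n) stop("j out of range");
    std::vector<int> kc;
    build_kmer_codes(codes, k, kc);
    int nk = 1 << (2 * k);
    std::vector<int> c(nk, 0), cp(nk, 0), touched;
    for (int i = std::max(k - 1, j - w + k); i <= j; ++i) ++cp[kc[i]];
    std::vector<Cand> B;
    backward_pass(kc, j, k, w, T, REAL(f), scorer, cp, c, touched, B);
    int m = (int)B.size();
    IntegerVector pos(m);
    NumericVector vb(m);
    for (int z = 0; z < m; ++z) {  // ascending position order
        pos[z] = B[m - 1 - z].pos;
        vb[z] = B[m - 1 - z].v;
    }
    return DataFrame::create(_["pos"] = pos, _["vbound"] = vb);
}

// [[Rcpp::export(name = ".ld_forward_cpp")]]
List ld_forward_cpp(IntegerVector codes, int i0, int j, double vbound, int k,
                    double T, NumericVector f, int scorer) {
    int n = codes.size();
    if (i0 < k - 1 || i0 > j || j >= n) stop("positions out of range");
    std::vector<int> kc;
    build_kmer_codes(codes, k, kc);
    int nk = 1 << (2 * k);
    std::vector<int> c(nk, 0), touched;
    double sj;
    int imax = forward_pass(kc, i0, j, vbound, T, REAL(f), scorer, c, touched, sj);
    return List::create(_["imax"] = imax, _["score_at_j"] = sj);
}

// [[Rcpp::export(name = ".ld_find_start_cpp")]]
List ld_find_start_cpp(IntegerVector codes, int j, int k, int w, double T,
                       NumericVector f, bool fast_start, int scorer) {
    int n = codes.size();
    if (j < k - 1 || j >= n) stop("j out of range");
    std::vector<int> kc;
    build_kmer_codes(codes, k, kc);
    int nk = 1 << (2 * k);
    std::vector<int> c(nk, 0), cp(nk, 0), touched;
    for (int i = std::max(k - 1, j - w + k); i <= j; ++i) ++cp[kc[i]];
    double sc = NA_REAL;
    int i = find_start(kc, j, k, w, T, REAL(f), scorer, fast_start, cp, c,
                       touched, sc);
    return List::create(_["start"] = i, _["score"] = sc);
}
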