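// Core simulation engine: Wright-Fisher allele-frequency trajectories under
// piecewise-constant demography, and a structured coalescent with
// recombination conditioned on a frequency trajectory.
//
// Conventions used throughout:
//  * time is measured in (possibly fractional) generations before present;
//  * a trajectory is a numeric vector indexed by generation before present
//    (element 0 = present), oldest element = origin of the derived allele;
//  * genotype fitnesses are 1 : 1+2hs : 1+2s, so with h = 0.5 the
//    heterozygote advantage equals s (additive, per-allele selection);
//  * all randomness comes from R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ----------------------------------------------------------------- demography

struct Demog {
    std::vector<double> t0;  // epoch start times, ascending, t0[0] == 0
    std::vector<double> N;   // diploid sizes
    double size_at(double t) const {
        int i = (int)t0.size() - 1;
        while (i > 0 && t < t0[i]) --i;
        return N[i];
    }
    // end of the epoch containing time t (start of the next older epoch);
    // +Inf for the oldest epoch
    double epoch_end(double t) const {
        for (size_t i = 0; i < t0.size(); ++i)
            if (t < t0[i]) return t0[i];
        return std::numeric_limits<double>::infinity();
    }
};

static Demog make_demog(const NumericVector& ep_t, const NumericVector& ep_N) {
    if (ep_t.size() != ep_N.size() || ep_t.size() == 0)
        stop("epoch time and size vectors must have equal positive length");
    Demog d;
    d.t0 = as<std::vector<double>>(ep_t);
    d.N  = as<std::vector<double>>(ep_N);
    if (d.t0[0] != 0.0) stop("first epoch must start at time 0");
    for (size_t i = 1; i < d.t0.size(); ++i)
        if (d.t0[i] <= d.t0[i - 1]) stop("epoch start times must be increasing");
    for (double N : d.N) if (N < 2) stop("population sizes must be >= 2");
    return d;
}

// ------------------------------------------------------------------ selection

// Deterministic selection step: expected frequency in the offspring
// generation given parental frequency p. Fitnesses 1 : 1+2hs : 1+2s.
static inline double sel_pstar(double p, double s, double h) {
    if (p <= 0.0) return 0.0;
    if (p >= 1.0) return 1.0;
    double w2 = 1.0 + 2.0 * s, w1 = 1.0 + 2.0 * h * s;
    double q = 1.0 - p;
    double num = p * p * w2 + p * q * w1;
    double den = num + p * q * w1 + q * q;
    return num / den;
}

// Reversed-fitness step used by the backward-in-time accelerator: the derived
// allele is disfavoured with the reciprocal genotype weights, which keeps the
// weights positive for any s >= 0. With s = 0 this is plain neutral drift.
static inline double sel_pstar_rev(double p, double s, double h) {
    if (p <= 0.0) return 0.0;
    if (p >= 1.0) return 1.0;
    double w2 = 1.0 / (1.0 + 2.0 * s), w1 = 1.0 / (1.0 + 2.0 * h * s);
    double q = 1.0 - p;
    double num = p * p * w2 + p * q * w1;
    double den = num + p * q * w1 + q * q;
    return num / den;
}

// One Wright-Fisher generation forward in time: binomial sampling of
// 2*N_child offspring alleles around the post-selection frequency.
// [[Rcpp::export]]
double cpp_wf_step(double p, double N_child, double s, double h) {
    if (p < 0.0 || p > 1.0) stop("allele frequency must lie in [0, 1]");
    if (N_child < 1) stop("population size must be positive");
    if (p == 0.0 || p == 1.0) return p;  // absorbing states
    double twoN = 2.0 * N_child;
    double k = R::rbinom(twoN, sel_pstar(p, s, h));
    return k / twoN;
}

// ---------------------------------------------------- forward SDN trajectories

// Simulate one accepted trajectory for selection on a de novo mutation that
// arose t_age generations before present, by rejection on the survival
// condition (non-lost, optionally still segregating).
// [[Rcpp::export]]
List cpp_sdn_trajectory(NumericVector ep_t, NumericVector ep_N,
                        double s, double h, int t_age,
                        bool require_segregating, double max_attempts) {
    Demog dem = make_demog(ep_t, ep_N);
    if (t_age < 1) stop("t_age must be >= 1");
    std::vector<double> fr(t_age + 1);
    double attempts = 0;
    while (attempts < max_attempts) {
        attempts += 1;
        double N0 = dem.size_at((double)t_age);
        double p = 1.0 / (2.0 * N0);
        fr[t_age] = p;
        bool lost = false;
        for (int g = t_age; g >= 1; --g) {
            double twoN = 2.0 * dem.size_at((double)(g - 1));
            double k = R::rbinom(twoN, sel_pstar(p, s, h));
            p = k / twoN;
            fr[g - 1] = p;
            if (p == 0.0) { lost = true; break; }
            if (p == 1.0) { for (int gg = g - 2; gg >= 0; --gg) fr[gg] = 1.0; break; }
        }
        if (lost) continue;
        if (require_segregating && fr[0] >= 1.0) continue;
        return List::create(_["freqs"] = NumericVector(fr.begin(), fr.end()),
                            _["attempts"] = attempts);
    }
    stop("no trajectory accepted after %.0f attempts (SDN, s=%g, t_age=%d)",
         max_attempts, s, t_age);
}

// Count how many of n_attempts de novo trajectories satisfy the survival
// condition (used for acceptance-probability diagnostics).
// [[Rcpp::export]]
double cpp_sdn_acceptance(NumericVector ep_t, NumericVector ep_N,
                          double s, double h, int t_age,
                          bool require_segregating, double n_attempts) {
    Demog dem = make_demog(ep_t, ep_N);
    double acc = 0;
    for (double a = 0; a < n_attempts; a += 1) {
        double p = 1.0 / (2.0 * dem.size_at((double)t_age));
        for (int g = t_age; g >= 1; --g) {
            double twoN = 2.0 * dem.size_at((double)(g - 1));
            double k = R::rbinom(twoN, sel_pstar(p, s, h));
            p = k / twoN;
            if (p == 0.0 || p == 1.0) break;  // absorbed; frequency persists
        }
        if (p == 0.0) continue;
        if (require_segregating && p >= 1.0) continue;
        acc += 1;
    }
    return acc;
}

// ------------------------------------------------------- backward trajectories

// Backward-in-time path from frequency p_start at generation t_start,
// stepping to older generations with binomial resampling (reversed fitness
// weights when s > 0; plain neutral drift when s = 0) until absorption at 0.
// Paths absorbed at 1 are rejected: the derived allele must originate as a
// mutation. Returns frequencies for generations t_start, t_start+1, ...,
// origin (all positive; the origin is the oldest positive-frequency
// generation).
// [[Rcpp::export]]
List cpp_backward_path(NumericVector ep_t, NumericVector ep_N,
                       double s, double h, double p_start, double t_start,
                       double max_attempts, double max_len) {
    Demog dem = make_demog(ep_t, ep_N);
    if (p_start <= 0.0 || p_start >= 1.0)
        stop("backward path must start from a polymorphic frequency");
    double attempts = 0;
    std::vector<double> fr;
    while (attempts < max_attempts) {
        attempts += 1;
        fr.clear();
        fr.push_back(p_start);
        double p = p_start, t = t_start;
        bool ok = false;
        while ((double)fr.size() < max_len) {
            t += 1.0;
            double twoN = 2.0 * dem.size_at(t);
            double k = R::rbinom(twoN, sel_pstar_rev(p, s, h));
            p = k / twoN;
            if (p == 0.0) { ok = true; break; }   // origin reached
            if (p == 1.0) { break; }              // fixed backward: reject
            fr.push_back(p);
        }
        if (!ok) continue;
        return List::create(_["freqs"] = NumericVector(fr.begin(), fr.end()),
                            _["attempts"] = attempts);
    }
    stop("no backward path accepted after %.0f attempts (p_start=%g)",
         max_attempts, p_start);
}

// -------------------------------------------- current-frequency conditioning

// Baseline rejection sampler: forward simulation from a de novo mutation at a
// uniformly drawn origin time in [1, t_max], accepted when the present-day
// frequency falls in [lo, hi].
// [[Rcpp::export]]
List cpp_current_freq_forward(NumericVector ep_t, NumericVector ep_N,
                              double s, double h, double lo, double hi,
                              int t_max, double max_attempts) {
    Demog dem = make_demog(ep_t, ep_N);
    if (!(lo > 0.0 && hi <= 1.0 && lo <= hi)) stop("invalid frequency bin");
    std::vector<double> fr(t_max + 1);
    double attempts = 0;
    while (attempts < max_attempts) {
        attempts += 1;
        int t_age = 1 + (int)(unif_rand() * t_max);
        if (t_age > t_max) t_age = t_max;
        double p = 1.0 / (2.0 * dem.size_at((double)t_age));
        fr[t_age] = p;
        bool lost = false;
        for (int g = t_age; g >= 1; --g) {
            double twoN = 2.0 * dem.size_at((double)(g - 1));
            double k = R::rbinom(twoN, sel_pstar(p, s, h));
            p = k / twoN;
            fr[g - 1] = p;
            if (p == 0.0) { lost = true; break; }
            if (p == 1.0) { for (int gg = g - 2; gg >= 0; --gg) fr[gg] = 1.0; break; }
        }
        if (lost) continue;
        if (fr[0] < lo || fr[0] > hi) continue;
        return List::create(
            _["freqs"] = NumericVector(fr.begin(), fr.begin() + t_age + 1),
            _["attempts"] = attempts);
    }
    stop("no trajectory accepted after %.0f attempts (current-frequency bin [%g, %g])",
         max_attempts, lo, hi);
}

// Constant-population accelerator: draw the present-day lattice frequency
// uniformly within the bin and extend the path into the past with the
// reversed-fitness backward sampler. Requires hi < 1.
// [[Rcpp::export]]
List cpp_current_freq_backward(double N, double s, double h,
                               double lo, double hi,
                               double max_attempts, double max_len) {
    if (!(lo > 0.0 && hi < 1.0 && lo <= hi)) stop("backward accelerator needs 0 < lo <= hi < 1");
    double twoN = 2.0 * N;
    int klo = (int)std::ceil(lo * twoN), khi = (int)std::floor(hi * twoN);
    if (klo < 1) klo = 1;
    if (khi > (int)twoN - 1) khi = (int)twoN - 1;
    if (khi < klo) stop("frequency bin contains no lattice value at 2N=%g", twoN);
    NumericVector ep_t = NumericVector::create(0.0);
    NumericVector ep_N = NumericVector::create(N);
    double attempts = 0;
    while (attempts < max_attempts) {
        attempts += 1;
        int k = klo + (int)(unif_rand() * (khi - klo + 1));
        if (k > khi) k = khi;
        double p0 = k / twoN;
        List bw;
        try {
            bw = cpp_backward_path(ep_t, ep_N, s, h, p0, 0.0, 1.0, max_len);
        } catch (Rcpp::exception& e) {
            continue;  // single backward attempt rejected; redraw p0
        }
        NumericVector fr = bw["freqs"];
        return List::create(_["freqs"] = fr, _["attempts"] = attempts);
    }
    stop("no trajectory accepted after %.0f attempts (backward, bin [%g, %g])",
         max_attempts, lo, hi);
}

// --------------------------------------------------------- SSV trajectories

// Standing-variation trajectory: neutral backward segment from (the lattice
// value nearest) p1 at generation t_sel back to the origin, spliced to a
// forward selected segment from p1 at t_sel down to the present.
// [[Rcpp::export]]
List cpp_ssv_trajectory(NumericVector ep_t, NumericVector ep_N,
                        double s, double h, double p1, int t_sel,
                        bool require_segregating, double max_attempts,
                        double max_len) {
    Demog dem = make_demog(ep_t, ep_N);
    if (t_sel < 1) stop("t_sel must be >= 1");
    if (!(p1 > 0.0 && p1 < 1.0)) stop("p1 must lie in (0, 1)");
    double twoN_sel = 2.0 * dem.size_at((double)t_sel);
    double k1 = std::llround(p1 * twoN_sel);
    if (k1 < 1) k1 = 1;
    if (k1 > twoN_sel - 1) k1 = twoN_sel - 1;
    double p1l = k1 / twoN_sel;

    // forward selected segment, rejected on the survival condition
    std::vector<double> fwd(t_sel + 1);
    double attempts_fwd = 0;
    bool have_fwd = false;
    while (attempts_fwd < max_attempts) {
        attempts_fwd += 1;
        double p = p1l;
        fwd[t_sel] = p;
        bool lost = false;
        for (int g = t_sel; g >= 1; --g) {
            double twoN = 2.0 * dem.size_at((double)(g - 1));
            double k = R::rbinom(twoN, sel_pstar(p, s, h));
            p = k / twoN;
            fwd[g - 1] = p;
            if (p == 0.0) { lost = true; break; }
            if (p == 1.0) { for (int gg = g - 2; gg >= 0; --gg) fwd[gg] = 1.0; break; }
        }
        if (lost) continue;
        if (require_segregating && fwd[0] >= 1.0) continue;
        have_fwd = true;
        break;
    }
    if (!have_fwd)
        stop("no forward SSV segment accepted after %.0f attempts", max_attempts);

    // ancestral neutral segment
    List bw = cpp_backward_path(ep_t, ep_N, 0.0, h, p1l, (double)t_sel,
                                max_attempts, max_len);
    NumericVector bfr = bw["freqs"];  // index 0 == generation t_sel

    int origin = t_sel + (int)bfr.size() - 1;
    NumericVector out(origin + 1);
    for (int g = 0; g <= t_sel; ++g) out[g] = fwd[g];
    for (int j = 1; j < (int)bfr.size(); ++j) out[t_sel + j] = bfr[j];
    return List::create(_["freqs"] = out,
                        _["attempts_forward"] = attempts_fwd,
                        _["attempts_backward"] = bw["attempts"]);
}

// ================================================== structured coalescent ===

namespace {

struct Seg {
    double l, r;
    uint64_t m0, m1;  // descendant-leaf mask (bits 0..63 / 64..127)
};

static inline int seg_pop(const Seg& s) {
    return __builtin_popcountll(s.m0) + __builtin_popcountll(s.m1);
}

struct Lin {
    std::vector<Seg> segs;  // sorted, disjoint, within [0, L]
    int cls;                // 1 = derived, 0 = ancestral / unstructured
    double birth;           // time (gen before present) the lineage arose
};

// Union of two sorted disjoint segment lists with OR'd leaf masks; portions
// whose mask becomes complete (all n leaves) have reached their MRCA and are
// dropped.
static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B, int n) {
    std::vector<double> bp;
    bp.reserve(2 * (A.size() + B.size()));
    for (const Seg& s : A) { bp.push_back(s.l); bp.push_back(s.r); }
    for (const Seg& s : B) { bp.push_back(s.l); bp.push_back(s.r); }
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
    std::vector<Seg> out;
    size_t ia = 0, ib = 0;
    for (size_t i = 0; i + 1 < bp.size(); ++i) {
        double l = bp[i], r = bp[i + 1], mid = 0.5 * (l + r);
        while (ia < A.size() && A[ia].r <= l) ++ia;
        while (ib < B.size() && B[ib].r <= l) ++ib;
        uint64_t m0 = 0, m1 = 0;
        bool cov = false;
        if (ia < A.size() && A[ia].l <= l && mid < A[ia].r) {
            m0 |= A[ia].m0; m1 |= A[ia].m1; cov = true;
        }
        if (ib < B.size() && B[ib].l <= l && mid < B[ib].r) {
            m0 |= B[ib].m0; m1 |= B[ib].m1; cov = true;
        }
        if (!cov) continue;
        int pc = __builtin_popcountll(m0) + __builtin_popcountll(m1);
        if (pc >= n) continue;  // resolved: MRCA reached for this stretch
        if (!out.empty() && out.back().r == l &&
            out.back().m0 == m0 && out.back().m1 == m1) {
            out.back().r = r;
        } else {
            out.push_back(Seg{l, r, m0, m1});
        }
    }
    return out;
}

static void split_at(const std::vector<Seg>& S, double x,
                     std::vector<Seg>& left, std::vector<Seg>& right) {
    for (const Seg& s : S) {
        if (s.r <= x) left.push_back(s);
        else if (s.l >= x) right.push_back(s);
        else {
            left.push_back(Seg{s.l, x, s.m0, s.m1});
            right.push_back(Seg{x, s.r, s.m0, s.m1});
        }
    }
}

// Accumulator for genealogy edge records. Every lineage, once it terminates
// (by coalescing, recombining, or being forced to merge at the trajectory
// origin), contributes one record spanning [birth, end) with its material.
struct RecOut {
    std::vector<double> t0, t1;
    std::vector<int> srec;
    std::vector<double> sl, sr;
    std::vector<int> w1, w2, w3, w4;  // mask words (int32 bit patterns)
    int nrec = 0;
    void emit(const Lin& L, double tend) {
        ++nrec;
        t0.push_back(L.birth);
        t1.push_back(tend);
        for (const Seg& s : L.segs) {
            srec.push_back(nrec);
            sl.push_back(s.l);
            sr.push_back(s.r);
            int32_t w[4];
            std::memcpy(w, &s.m0, 8);
            std::memcpy(w + 2, &s.m1, 8);
            w1.push_back(w[0]); w2.push_back(w[1]);
            w3.push_back(w[2]); w4.push_back(w[3]);
        }
    }
};

}  // namespace

// Structured coalescent with recombination, conditioned on a derived-allele
// frequency trajectory. traj is indexed by generation before present; an
// empty traj simulates the unconditioned neutral coalescent. Event scheduling
// is discrete-generation Bernoulli: at most one coalescence per allelic class
// per (sub-)generation, with generations subdivided so that no coalescence
// probability exceeds 0.1. Per-lineage recombination probabilities (r times
// the bp span, at most r*L) are far below 0.1 for the region sizes used here,
// so they never force subdivision on their own.
// [[Rcpp::export]]
List cpp_structured_genealogy(NumericVector ep_t, NumericVector ep_N,
                              NumericVector traj, int n_der, int n_anc,
                              double L, double rrate, double focal_pos,
                              double max_generations) {
    const int n = n_der + n_anc;
    if (n < 2 || n > 128) stop("sample size must be in [2, 128]");
    if (L <= 0) stop("region length must be positive");
    if (focal_pos < 0 || focal_pos > L) stop("focal position outside region");
    Demog dem = make_demog(ep_t, ep_N);
    const bool focal = traj.size() > 0;
    const long long G = focal ? (long long)traj.size() - 1 : -1;
    if (focal) {
        for (double p : traj)
            if (p <= 0.0 || p > 1.0)
                stop("trajectory frequencies must lie in (0, 1]");
        if (n_der > 0 && traj[0] <= 0.0)
            stop("derived lineages sampled but the trajectory ends at frequency 0");
    }

    std::vector<Lin> lin;
    lin.reserve(2 * n);
    for (int i = 0; i < n; ++i) {
        Seg s{0.0, L, 0, 0};
        if (i < 64) s.m0 = 1ULL << i; else s.m1 = 1ULL << (i - 64);
        Lin li;
        li.segs.push_back(s);
        li.cls = (focal && i < n_der) ? 1 : 0;
        li.birth = 0.0;
        lin.push_back(li);
    }
    RecOut out;
    double t = 0.0;

    auto coalesce = [&](int i, int j, double tev) {
        out.emit(lin[i], tev);
        out.emit(lin[j], tev);
        std::vector<Seg> m = merge_segs(lin[i].segs, lin[j].segs, n);
        int cls = lin[i].cls;
        if (i > j) std::swap(i, j);
        lin.erase(lin.begin() + j);
        lin.erase(lin.begin() + i);
        if (!m.empty()) {
            Lin nl;
            nl.segs = std::move(m);
            nl.cls = cls;
            nl.birth = tev;
            lin.push_back(std::move(nl));
        }
    };

    // Attempt a recombination on lineage i at time tev. Returns true if the
    // lineage set changed. Breakpoint uniform on the span from the leftmost
    // to the rightmost of the material endpoints (and the focal site during
    // the structured phase); the fragment not containing the focal site joins
    // a derived background with probability p_par.
    auto recomb = [&](int i, double tev, double p_par, bool focal_phase) -> bool {
        Lin& Lc = lin[i];
        double ml = Lc.segs.front().l, mr = Lc.segs.back().r;
        double sl_ = focal_phase ? std::min(ml, focal_pos) : ml;
        double sr_ = focal_phase ? std::max(mr, focal_pos) : mr;
        if (sr_ <= sl_) return false;
        double x = R::runif(sl_, sr_);
        std::vector<Seg> left, right;
        split_at(Lc.segs, x, left, right);
        if (!focal_phase) {
            if (left.empty() || right.empty()) return false;
            out.emit(Lc, tev);
            Lin a{std::move(left), 0, tev};
            Lin b{std::move(right), 0, tev};
            lin.erase(lin.begin() + i);
            lin.push_back(std::move(a));
            lin.push_back(std::move(b));
            return true;
        }
        bool focal_left = focal_pos < x;
        std::vector<Seg>& F = focal_left ? left : right;  // keeps the class
        std::vector<Seg>& O = focal_left ? right : left;  // redraws its class
        if (O.empty()) return false;  // nothing separated from the focal site
        int ocls = (unif_rand() < p_par) ? 1 : 0;
        out.emit(Lc, tev);
        int pcls = Lc.cls;
        bool f_empty = F.empty();
        Lin a{std::move(F), pcls, tev};
        Lin b{std::move(O), ocls, tev};
        lin.erase(lin.begin() + i);
        if (!f_empty) lin.push_back(std::move(a));
        lin.push_back(std::move(b));
        return true;
    };

    auto pick_pair = [&](const std::vector<int>& idx, int& a, int& b) {
        int k = (int)idx.size();
        int i1 = (int)(unif_rand() * k); if (i1 >= k) i1 = k - 1;
        int i2 = (int)(unif_rand() * (k - 1)); if (i2 >= k - 1) i2 = k - 2;
        if (i2 >= i1) ++i2;
        a = idx[i1]; b = idx[i2];
    };

    // one structured WF generation looking back (parents at time t + 1)
    auto focal_generation = [&](double N_par, double p_par) {
        double twoN = 2.0 * N_par;
        int kD = 0, kA = 0;
        for (const Lin& l : lin) (l.cls ? kD : kA)++;
        double nD = std::max((double)std::llround(twoN * p_par), (double)kD);
        double nA = std::max(twoN - nD, (double)kA);
        double qD = kD >= 2 ? (double)kD * (kD - 1) / 2.0 / nD : 0.0;
        double qA = kA >= 2 ? (double)kA * (kA - 1) / 2.0 / nA : 0.0;
        int m = (int)std::ceil(std::max(qD, qA) / 0.1);
        if (m < 1) m = 1;
        for (int sub = 0; sub < m; ++sub) {
            double tev = t + (double)(sub + 1) / m;
            // recombination, one Bernoulli per (pre-existing) lineage
            int k0 = (int)lin.size();
            for (int i = 0; i < k0 && i < (int)lin.size();) {
                const Lin& Lc = lin[i];
                double span = std::max(Lc.segs.back().r, focal_pos) -
                              std::min(Lc.segs.front().l, focal_pos);
                double q = rrate * span / m;
                if (q > 0 && unif_rand() < q) {
                    if (recomb(i, tev, p_par, true)) { --k0; continue; }
                }
                ++i;
            }
            // at most one coalescence per class per sub-generation
            int cD = 0, cA = 0;
            for (const Lin& l : lin) (l.cls ? cD : cA)++;
            double nDs = std::max((double)std::llround(twoN * p_par), (double)cD);
            double nAs = std::max(twoN - nDs, (double)cA);
            double pD = cD >= 2 ? std::min(1.0, (double)cD * (cD - 1) / 2.0 / nDs / m) : 0.0;
            double pA = cA >= 2 ? std::min(1.0, (double)cA * (cA - 1) / 2.0 / nAs / m) : 0.0;
            bool doD = pD > 0 && unif_rand() < pD;
            bool doA = pA > 0 && unif_rand() < pA;
            if (doD) {
                std::vector<int> idx;
                for (int i = 0; i < (int)lin.size(); ++i) if (lin[i].cls == 1) idx.push_back(i);
                if ((int)idx.size() >= 2) { int a, b; pick_pair(idx, a, b); coalesce(a, b, tev); }
            }
            if (doA) {
                std::vector<int> idx;
                for (int i = 0; i < (int)lin.size(); ++i) if (lin[i].cls == 0) idx.push_back(i);
                if ((int)idx.size() >= 2) { int a, b; pick_pair(idx, a, b); coalesce(a, b, tev); }
            }
        }
    };

    // the mutation event: all remaining derived lineages merge into the
    // single copy present at the origin, and the merged lineage joins the
    // ancestral class
    auto force_merge_derived = [&](double tev) {
        std::vector<int> D;
        for (int i = 0; i < (int)lin.size(); ++i) if (lin[i].cls == 1) D.push_back(i);
        if (D.size() >= 2) {
            std::vector<Seg> acc = lin[D[0]].segs;
            out.emit(lin[D[0]], tev);
            for (size_t j = 1; j < D.size(); ++j) {
                out.emit(lin[D[j]], tev);
                acc = merge_segs(acc, lin[D[j]].segs, n);
            }
            for (int j = (int)D.size() - 1; j >= 0; --j)
                lin.erase(lin.begin() + D[j]);
            if (!acc.empty()) {
                Lin nl;
                nl.segs = std::move(acc);
                nl.cls = 0;
                nl.birth = tev;
                lin.push_back(std::move(nl));
            }
        } else if (D.size() == 1) {
            lin[D[0]].cls = 0;
        }
    };

    while (!lin.empty()) {
        if (t > max_generations)
            stop("structured coalescent exceeded %g generations", max_generations);

        if (focal && t < (double)G) {
            double t_par = t + 1.0;
            double N_par = dem.size_at(t_par);
            if ((long long)t_par >= G) {
                force_merge_derived((double)G);
            } else {
                focal_generation(N_par, traj[(int)t_par]);
            }
            t = t_par;
            continue;
        }

        // unstructured phase (pre-origin, or no focal site at all)
        int k = (int)lin.size();
        if (k == 1)
            stop("internal error: single lineage left with unresolved material");
        double t_par = t + 1.0;
        double twoN = 2.0 * dem.size_at(t_par);
        double qc = (double)k * (k - 1) / 2.0 / twoN;

        if (qc > 0.1) {
            int m = (int)std::ceil(qc / 0.1);
            for (int sub = 0; sub < m; ++sub) {
                double tev = t + (double)(sub + 1) / m;
                int k0 = (int)lin.size();
                for (int i = 0; i < k0 && i < (int)lin.size();) {
                    double span = lin[i].segs.back().r - lin[i].segs.front().l;
                    double q = rrate * span / m;
                    if (q > 0 && unif_rand() < q) {
                        if (recomb(i, tev, 0.0, false)) { --k0; continue; }
                    }
                    ++i;
                }
                int kk = (int)lin.size();
                if (kk >= 2) {
                    double q = std::min(1.0, (double)kk * (kk - 1) / 2.0 / twoN / m);
                    if (unif_rand() < q) {
                        int i1 = (int)(unif_rand() * kk); if (i1 >= kk) i1 = kk - 1;
                        int i2 = (int)(unif_rand() * (kk - 1)); if (i2 >= kk - 1) i2 = kk - 2;
                        if (i2 >= i1) ++i2;
                        coalesce(i1, i2, tev);
                    }
                }
            }
            t = t_par;
            continue;
        }

        // rates are generation-invariant until the next event or epoch
        // boundary, so sample the waiting time to the first event-bearing
        // generation directly (geometric), then the event configuration of
        // that generation conditioned on at least one event
        double te = dem.epoch_end(t_par);
        long long jmax = std::isfinite(te)
            ? (long long)std::ceil(te - t - 1e-9) - 1
            : std::numeric_limits<long long>::max() / 4;
        if (jmax < 1) jmax = 1;

        std::vector<double> q(k + 1);
        q[0] = qc;
        double log_qnone = std::log1p(-qc);
        for (int i = 0; i < k; ++i) {
            double span = lin[i].segs.back().r - lin[i].segs.front().l;
            q[i + 1] = rrate * span;
            if (q[i + 1] > 0) log_qnone += std::log1p(-q[i + 1]);
        }
        double u = unif_rand();
        long long T = 1 + (long long)std::floor(std::log(u) / log_qnone);
        if (T < 1) T = 1;
        if (T > jmax) {  // no event before the epoch boundary
            t = t + (double)jmax;
            continue;
        }
        double tev = t + (double)T;
        // suffix products of the no-event probabilities
        std::vector<double> S(k + 2);
        S[k + 1] = 1.0;
        for (int i = k; i >= 0; --i) S[i] = S[i + 1] * (1.0 - q[i]);
        bool any = false;
        std::vector<char> fire(k + 1, 0);
        for (int i = 0; i <= k; ++i) {
            if (!any) {
                double denom = 1.0 - (1.0 - q[i]) * S[i + 1];
                double pe = denom > 0 ? q[i] / denom : 1.0;
                if (unif_rand() < pe) { fire[i] = 1; any = true; }
            } else {
                if (q[i] > 0 && unif_rand() < q[i]) fire[i] = 1;
            }
        }
        // apply recombinations (descending index keeps pending indices valid)
        for (int i = k; i >= 1; --i)
            if (fire[i]) recomb(i - 1, tev, 0.0, false);
        if (fire[0]) {
            int kk = (int)lin.size();
            if (kk >= 2) {
                int i1 = (int)(unif_rand() * kk); if (i1 >= kk) i1 = kk - 1;
                int i2 = (int)(unif_rand() * (kk - 1)); if (i2 >= kk - 1) i2 = kk - 2;
                if (i2 >= i1) ++i2;
                coalesce(i1, i2, tev);
            }
        }
        t = tev;
    }

    return List::create(
        _["rec_t0"] = NumericVector(out.t0.begin(), out.t0.end()),
        _["rec_t1"] = NumericVector(out.t1.begin(), out.t1.end()),
        _["seg_rec"] = IntegerVector(out.srec.begin(), out.srec.end()),
        _["seg_l"] = NumericVector(out.sl.begin(), out.sl.end()),
        _["seg_r"] = NumericVector(out.sr.begin(), out.sr.end()),
        _["seg_w1"] = IntegerVector(out.w1.begin(), out.w1.end()),
        _["seg_w2"] = IntegerVector(out.w2.begin(), out.w2.end()),
        _["seg_w3"] = IntegerVector(out.w3.begin(), out.w3.end()),
        _["seg_w4"] = IntegerVector(out.w4.begin(), out.w4.end()),
        _["n"] = n,
        _["end_time"] = t);
}
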