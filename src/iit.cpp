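// Exact IIT 3.0 engine over binary systems described by a state-by-node TPM.
//
// Conventions (fixed package-wide):
//  * States are little-endian: node 1 (R label) is bit 0 / the least
//    significant bit. Row s+1 of the TPM is system state s.
//  * tpm is a (2^n x n) matrix: P(node j on at t+tau | system state s at t).
//  * Node sets are bit masks over the n system nodes.
//  * Repertoires over a purview P are vectors of length 2^|P| indexed by the
//    purview-local state (bit k = state of the k-th smallest purview node).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
const double PHI_TIE_TOL = 1e-12;

inline int popcnt(unsigned x) { return __builtin_popcount(x); }

// extract bits of x at positions set in m, packed densely (LSB first)
inline int pext_mask(unsigned x, unsigned m) {
  int r = 0, b = 0;
  while (m) {
    unsigned lb = m & (~m + 1u);
    if (x & lb) r |= (1 << b);
    ++b;
    m &= m - 1;
  }
  return r;
}

// deposit dense bits of x into positions set in m
inline int pdep_mask(unsigned x, unsigned m) {
  int r = 0, b = 0;
  while (m) {
    unsigned lb = m & (~m + 1u);
    if (x & (1 << b)) r |= lb;
    ++b;
    m &= m - 1;
  }
  return r;
}

// labels of set bits, ascending
inline std::vector<int> mask_nodes(unsigned m) {
  std::vector<int> v;
  for (int b = 0; m; ++b, m >>= 1)
    if (m & 1) v.push_back(b);
  return v;
}

// lexicographic order on the ascending label sequences of two masks
inline bool lex_less(unsigned a, unsigned b) {
  while (a && b) {
    int la = __builtin_ctz(a), lb = __builtin_ctz(b);
    if (la != lb) return la < lb;
    a &= a - 1;
    b &= b - 1;
  }
  return a == 0 && b != 0;
}

// Exact earth mover's distance between two same-length distributions over
// bit-states, ground metric = Hamming distance. Successive shortest paths
// (min-cost flow); exact for real-valued masses.
double emd_hamming_states(const double* p, const double* q, int ns) {
  const double tol = 1e-12;
  std::vector<double> rp(p, p + ns), rq(q, q + ns);
  for (int i = 0; i < ns; ++i) {  // shared mass moves for free
    double m = std::min(rp[i], rq[i]);
    rp[i] -= m;
    rq[i] -= m;
  }
  std::vector<double> F((size_t)ns * ns, 0.0);
  std::vector<double> du(ns), dv(ns);
  std::vector<int> pv(ns), pu(ns);
  while (true) {
    double sup = 0;
    for (double v : rp) sup += v;
    if (sup <= tol) break;
    for (int i = 0; i < ns; ++i) { du[i] = (rp[i] > tol) ? 0.0 : INF; pu[i] = -1; }
    for (int j = 0; j < ns; ++j) { dv[j] = INF; pv[j] = -1; }
    bool changed = true;
    while (changed) {
      changed = false;
      for (int j = 0; j < ns; ++j)
        for (int i = 0; i < ns; ++i) {
          if (du[i] == INF) continue;
          double c = du[i] + popcnt((unsigned)(i ^ j));
          if (c < dv[j] - 1e-15) { dv[j] = c; pv[j] = i; changed = true; }
        }
      for (int i = 0; i < ns; ++i)
        for (int j = 0; j < ns; ++j) {
          if (F[(size_t)i * ns + j] > tol && dv[j] != INF) {
            double c = dv[j] - popcnt((unsigned)(i ^ j));
            if (c < du[i] - 1e-15) { du[i] = c; pu[i] = j; changed = true; }
          }
        }
    }
    int jbest = -1;
    double dbest = INF;
    for (int j = 0; j < ns; ++j)
      if (rq[j] > tol && dv[j] < dbest) { dbest = dv[j]; jbest = j; }
    if (jbest < 0) break;
    std::vector<int> pis, pjs;
    int cj = jbest;
    while (true) {
      int ci = pv[cj];
      pis.insert(pis.begin(), ci);
      pjs.insert(pjs.begin(), cj);
      if (pu[ci] < 0) break;
      cj = pu[ci];
      if ((int)pis.size() > 2 * ns) stop("emd: augmenting-path trace failed");
    }
    double bott = std::min(rp[pis.front()], rq[jbest]);
    for (size_t k = 1; k < pis.size(); ++k)
      bott = std::min(bott, F[(size_t)pis[k] * ns + pjs[k - 1]]);
    for (size_t k = 0; k < pis.size(); ++k)
      F[(size_t)pis[k] * ns + pjs[k]] += bott;
    for (size_t k = 1; k < pis.size(); ++k)
      F[(size_t)pis[k] * ns + pjs[k - 1]] -= bott;
    rp[pis.front()] -= bott;
    rq[jbest] -= bott;
  }
  double cost = 0;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j)
      cost += F[(size_t)i * ns + j] * popcnt((unsigned)(i ^ j));
  return cost;
}

// ---------------------------------------------------------------------------

struct ConceptSide {
  double phi;
  unsigned purview;                 // core purview mask
  std::vector<double> cause_full;   // cause only: repertoire expanded to 2^n
  std::vector<double> eff_marg;     // effect only: n on-marginals (0.5 off-purview)
};

struct MechEntry {            // one (mechanism, mechanism-state)
  ConceptSide cause, effect;
  double phi;                 // min of the two sides
};

struct Engine {
  int n, ns;
  std::vector<double> tpm;    // row-major: tpm[s * n + j]
  // cond[mask] : (2^|mask|) x n, mean of column j over rows with (s&mask)==state
  std::vector<std::vector<double> > cond;

  Engine(const NumericMatrix& m) {
    n = m.ncol();
    ns = 1 << n;
    if (m.nrow() != ns) stop("tpm must have 2^n rows");
    if (n < 1 || n > 8) stop("engine supports 1..8 nodes");
    tpm.resize((size_t)ns * n);
    for (int s = 0; s < ns; ++s)
      for (int j = 0; j < n; ++j) {
        double v = m(s, j);
        if (!(v >= 0.0 && v <= 1.0)) stop("tpm entries must lie in [0, 1]");
        tpm[(size_t)s * n + j] = v;
      }
    cond.resize(ns);
    for (unsigned M = 0; M < (unsigned)ns; ++M) {
      int k = popcnt(M), nl = 1 << k;
      cond[M].assign((size_t)nl * n, 0.0);
      int nfree = 1 << (n - k);
      unsigned Mc = (~M) & (unsigned)(ns - 1);
      for (int loc = 0; loc < nl; ++loc) {
        int base = pdep_mask(loc, M);
        for (int u = 0; u < nfree; ++u) {
          int s = base | pdep_mask(u, Mc);
          for (int j = 0; j < n; ++j)
            cond[M][(size_t)loc * n + j] += tpm[(size_t)s * n + j];
        }
        for (int j = 0; j < n; ++j) cond[M][(size_t)loc * n + j] /= nfree;
      }
    }
  }

  // on-marginal of node j at t+tau given mechanism M in local state msl
  inline double eff_marginal(unsigned M, int msl, int j) const {
    return cond[M][(size_t)msl * n + j];
  }

  // effect repertoire over purview P (local indexing), mechanism M state msl
  std::vector<double> effect_rep(unsigned M, int msl, unsigned P) const {
    std::vector<int> pn = mask_nodes(P);
    int np = pn.size(), nl = 1 << np;
    std::vector<double> r(nl, 1.0);
    for (int z = 0; z < nl; ++z)
      for (int k = 0; k < np; ++k) {
        double pj = eff_marginal(M, msl, pn[k]);
        r[z] *= (z >> k & 1) ? pj : 1.0 - pj;
      }
    return r;
  }

  // cause repertoire over purview P given mechanism M in local state msl;
  // product of per-mechanism-node likelihoods (non-purview past uniform),
  // normalized; zero normalizer -> uniform (flag via out arg)
  std::vector<double> cause_rep(unsigned M, int msl, unsigned P, bool* degenerate = 0) const {
    int np = popcnt(P), nl = 1 << np;
    std::vector<double> r(nl, 1.0);
    std::vector<int> mn = mask_nodes(M);
    for (int z = 0; z < nl; ++z)
      for (size_t k = 0; k < mn.size(); ++k) {
        double on = cond[P][(size_t)z * n + mn[k]];
        r[z] *= (msl >> k & 1) ? on : 1.0 - on;
      }
    double tot = 0;
    for (double v : r) tot += v;
    if (degenerate) *degenerate = (tot <= 0);
    if (tot <= 0) {
      for (int z = 0; z < nl; ++z) r[z] = 1.0 / nl;
    } else {
      for (int z = 0; z < nl; ++z) r[z] /= tot;
    }
    return r;
  }

  // combine part repertoires over P1, P2 (disjoint, union P) into purview-local order
  std::vector<double> combine(const std::vector<double>& r1, unsigned P1,
                              const std::vector<double>& r2, unsigned P2) const {
    unsigned P = P1 | P2;
    int nl = 1 << popcnt(P);
    std::vector<double> out(nl);
    for (int z = 0; z < nl; ++z) {
      int emb = pdep_mask(z, P);
      double v = 1.0;
      if (P1) v *= r1[pext_mask(emb, P1)];
      if (P2) v *= r2[pext_mask(emb, P2)];
      out[z] = v;
    }
    return out;
  }

  // phi over the minimum-information partition of (M, P); direction: true=cause
  double phi_mip(unsigned M, int msl, unsigned P, bool cause_dir,
                 unsigned* bM1 = 0, unsigned* bP1 = 0) const {
    int mstate = pdep_mask(msl, M);  // embedded mechanism state
    std::vector<int> pn = mask_nodes(P);
    int np = pn.size();
    double best = INF;
    unsigned bestM1 = 0, bestP1 = 0;
    std::vector<double> whole;
    std::vector<double> wm(np);
    if (cause_dir) {
      whole = cause_rep(M, msl, P);
    } else {
      for (int k = 0; k < np; ++k) wm[k] = eff_marginal(M, msl, pn[k]);
    }
    // all unordered bipartitions {(M1,P1),(M2,P2)}, trivial part (0,0) excluded
    for (unsigned M1 = M;; M1 = (M1 - 1) & M) {
      for (unsigned P1 = P;; P1 = (P1 - 1) & P) {
        unsigned M2 = M & ~M1, P2 = P & ~P1;
        bool skip = (M1 == 0 && P1 == 0) || (M2 == 0 && P2 == 0);
        // count each unordered pair once, in a fixed enumeration order
        unsigned key1 = (M1 << n) | P1, key2 = (M2 << n) | P2;
        if (!skip && key1 < key2) {
          double d;
          if (!cause_dir) {
            d = 0;
            int l1 = pext_mask(mstate, M1) , l2 = pext_mask(mstate, M2);
            for (int k = 0; k < np; ++k) {
              unsigned bit = 1u << pn[k];
              double pm = (P1 & bit) ? eff_marginal(M1, l1, pn[k])
                                     : eff_marginal(M2, l2, pn[k]);
              d += std::fabs(wm[k] - pm);
            }
          } else {
            std::vector<double> r1, r2;
            if (P1) r1 = M1 ? cause_rep(M1, pext_mask(mstate, M1), P1)
                            : std::vector<double>(1 << popcnt(P1), 1.0 / (1 << popcnt(P1)));
            if (P2) r2 = M2 ? cause_rep(M2, pext_mask(mstate, M2), P2)
                            : std::vector<double>(1 << popcnt(P2), 1.0 / (1 << popcnt(P2)));
            std::vector<double> part = combine(r1, P1, r2, P2);
            d = emd_hamming_states(whole.data(), part.data(), 1 << np);
          }
          if (d < best) { best = d; bestM1 = M1; bestP1 = P1; }
        }
        if (P1 == 0) break;
      }
      if (M1 == 0) break;
    }
    if (bM1) *bM1 = bestM1;
    if (bP1) *bP1 = bestP1;
    return best < INF ? std::max(best, 0.0) : 0.0;
  }

  // core purview search; ties -> larger purview, then lexicographically first
  ConceptSide core(unsigned M, int msl, bool cause_dir) const {
    ConceptSide cs;
    cs.phi = -1;
    cs.purview = 0;
    for (unsigned P = 1; P < (unsigned)ns; ++P) {
      double ph = phi_mip(M, msl, P, cause_dir);
      bool take = false;
      if (ph > cs.phi + PHI_TIE_TOL) {
        take = true;
      } else if (ph > cs.phi - PHI_TIE_TOL) {
        int szP = popcnt(P), szB = popcnt(cs.purview);
        if (szP > szB || (szP == szB && lex_less(P, cs.purview))) take = true;
      }
      if (take) { cs.phi = ph; cs.purview = P; }
    }
    if (cs.phi < 0) cs.phi = 0;
    unsigned P = cs.purview;
    if (cause_dir) {
      std::vector<double> r = cause_rep(M, msl, P);
      cs.cause_full.assign(ns, 0.0);
      double fill = 1.0 / (1 << (n - popcnt(P)));
      for (int x = 0; x < ns; ++x)
        cs.cause_full[x] = r[pext_mask(x, P)] * fill;
    } else {
      cs.eff_marg.assign(n, 0.5);
      for (int j = 0; j < n; ++j)
        if (P >> j & 1) cs.eff_marg[j] = eff_marginal(M, msl, j);
    }
    return cs;
  }

  // all (mechanism, mechanism-state) concepts; table[M-1][msl]
  std::vector<std::vector<MechEntry> > concept_table() const {
    std::vector<std::vector<MechEntry> > tab(ns - 1);
    for (unsigned M = 1; M < (unsigned)ns; ++M) {
      int nms = 1 << popcnt(M);
      tab[M - 1].resize(nms);
      for (int msl = 0; msl < nms; ++msl) {
        MechEntry& e = tab[M - 1][msl];
        e.cause = core(M, msl, true);
        e.effect = core(M, msl, false);
        e.phi = std::min(e.cause.phi, e.effect.phi);
      }
    }
    return tab;
  }

  // unidirectional cut: inputs from `from` into its complement are noised by
  // uniform marginalization over the from-part's current-state bits
  NumericMatrix apply_cut(unsigned from) const {
    unsigned all = (unsigned)(ns - 1);
    unsigned to = all & ~from;
    NumericMatrix out(ns, n);
    int nf = 1 << popcnt(from);
    for (int s = 0; s < ns; ++s)
      for (int j = 0; j < n; ++j) {
        if (!(to >> j & 1)) {
          out(s, j) = tpm[(size_t)s * n + j];
        } else {
          double acc = 0;
          int keep = s & ~from;
          for (int u = 0; u < nf; ++u)
            acc += tpm[(size_t)(keep | pdep_mask(u, from)) * n + j];
          out(s, j) = acc / nf;
        }
      }
    return out;
  }
};

// expanded effect repertoire (2^n) from n on-marginals
std::vector<double> marg_to_rep(const std::vector<double>& m) {
  int n = m.size(), ns = 1 << n;
  std::vector<double> r(ns, 1.0);
  for (int x = 0; x < ns; ++x)
    for (int j = 0; j < n; ++j)
      r[x] *= (x >> j & 1) ? m[j] : 1.0 - m[j];
  return r;
}

// phi-weighted distance between a full and a cut cause-effect structure at
// one system state. Residual phi mass is transported to the maximally
// uninformative (unconstrained) repertoires of the larger-phi side.
double ces_distance_tables(const Engine& engF, const std::vector<std::vector<MechEntry> >& tf,
                           const Engine& engC, const std::vector<std::vector<MechEntry> >& tc,
                           int state) {
  int n = engF.n, ns = engF.ns;
  double total = 0;
  std::vector<double> unifc(ns, 1.0 / ns);
  for (unsigned M = 1; M < (unsigned)ns; ++M) {
    int msl = pext_mask(state & M, M);
    const MechEntry& ef = tf[M - 1][msl];
    const MechEntry& ec = tc[M - 1][msl];
    double w = std::min(ef.phi, ec.phi);
    if (w > 0) {
      double dc = emd_hamming_states(ef.cause.cause_full.data(),
                                     ec.cause.cause_full.data(), ns);
      double de = 0;
      for (int j = 0; j < n; ++j)
        de += std::fabs(ef.effect.eff_marg[j] - ec.effect.eff_marg[j]);
      total += w * (dc + de);
    }
    double resid = std::fabs(ef.phi - ec.phi);
    if (resid > 0) {
      const MechEntry& eb = (ef.phi >= ec.phi) ? ef : ec;
      const Engine& engB = (ef.phi >= ec.phi) ? engF : engC;
      double dc = emd_hamming_states(eb.cause.cause_full.data(), unifc.data(), ns);
      double de = 0;
      for (int j = 0; j < n; ++j)
        de += std::fabs(eb.effect.eff_marg[j] - engB.eff_marginal(0, 0, j));
      total += resid * (dc + de);
    }
  }
  return total;
}

List side_to_list(const ConceptSide& cs, int n) {
  List out = List::create(_["phi"] = cs.phi, _["purview"] = (int)cs.purview);
  if (!cs.cause_full.empty()) out["repertoire_full"] = NumericVector(cs.cause_full.begin(), cs.cause_full.end());
  if (!cs.eff_marg.empty()) out["marginals"] = NumericVector(cs.eff_marg.begin(), cs.eff_marg.end());
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_emd_hamming(NumericVector p, NumericVector q) {
  int ns = p.size();
  if (q.size() != ns) stop("distributions must share a state space");
  int nb = 0;
  while ((1 << nb) < ns) ++nb;
  if ((1 << nb) != ns) stop("length must be a power of two");
  return emd_hamming_states(REAL(p), REAL(q), ns);
}

// [[Rcpp::export]]
NumericVector cpp_effect_rep(NumericMatrix tpm, int mech, int mech_state, int purview) {
  Engine eng(tpm);
  std::vector<double> r = eng.effect_rep((unsigned)mech, mech_state, (unsigned)purview);
  return NumericVector(r.begin(), r.end());
}

// [[Rcpp::export]]
List cpp_cause_rep(NumericMatrix tpm, int mech, int mech_state, int purview) {
  Engine eng(tpm);
  bool degen = false;
  std::vector<double> r = eng.cause_rep((unsigned)mech, mech_state, (unsigned)purview, &degen);
  return List::create(_["probs"] = NumericVector(r.begin(), r.end()),
                      _["degenerate"] = degen);
}

// [[Rcpp::export]]
List cpp_phi_mip(NumericMatrix tpm, int mech, int mech_state, int purview, bool cause_dir) {
  Engine eng(tpm);
  unsigned m1 = 0, p1 = 0;
  double phi = eng.phi_mip((unsigned)mech, mech_state, (unsigned)purview, cause_dir, &m1, &p1);
  return List::create(_["phi"] = phi, _["part1_mech"] = (int)m1,
                      _["part1_purview"] = (int)p1,
                      _["part2_mech"] = (int)(mech & ~m1),
                      _["part2_purview"] = (int)(purview & ~p1));
}

// [[Rcpp::export]]
List cpp_core(NumericMatrix tpm, int mech, int mech_state, bool cause_dir) {
  Engine eng(tpm);
  ConceptSide cs = eng.core((unsigned)mech, mech_state, cause_dir);
  List out = side_to_list(cs, eng.n);
  // purview-local repertoire as well
  if (cause_dir) {
    std::vector<double> r = eng.cause_rep((unsigned)mech, mech_state, cs.purview);
    out["repertoire"] = NumericVector(r.begin(), r.end());
  } else {
    std::vector<double> r = eng.effect_rep((unsigned)mech, mech_state, cs.purview);
    out["repertoire"] = NumericVector(r.begin(), r.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_concept_table(NumericMatrix tpm) {
  Engine eng(tpm);
  std::vector<std::vector<MechEntry> > tab = eng.concept_table();
  List mechs(eng.ns - 1);
  for (int M = 1; M < eng.ns; ++M) {
    List states(tab[M - 1].size());
    for (size_t msl = 0; msl < tab[M - 1].size(); ++msl) {
      const MechEntry& e = tab[M - 1][msl];
      states[msl] = List::create(
          _["phi"] = e.phi,
          _["cause"] = side_to_list(e.cause, eng.n),
          _["effect"] = side_to_list(e.effect, eng.n));
    }
    mechs[M - 1] = states;
  }
  return mechs;
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_cut(NumericMatrix tpm, int from_mask) {
  Engine eng(tpm);
  return eng.apply_cut((unsigned)from_mask);
}

// [[Rcpp::export]]
double cpp_ces_distance(NumericMatrix tpm_full, NumericMatrix tpm_cut, int state) {
  Engine engF(tpm_full), engC(tpm_cut);
  std::vector<std::vector<MechEntry> > tf = engF.concept_table();
  std::vector<std::vector<MechEntry> > tc = engC.concept_table();
  return ces_distance_tables(engF, tf, engC, tc, state);
}

// Per-state system-level integrated information for every system state at
// once: Phi, the minimal cut, and the mechanism phi table (IIS per state).
// [[Rcpp::export]]
List cpp_big_phi_all(NumericMatrix tpm) {
  Engine engF(tpm);
  int n = engF.n, ns = engF.ns;
  if (n < 2) stop("system-level integrated information needs >= 2 nodes");
  std::vector<std::vector<MechEntry> > tf = engF.concept_table();

  NumericVector bigphi(ns, INF);
  IntegerVector mincut(ns, -1);
  NumericMatrix phimat(ns - 1, ns);       // mechanism x state, full-system phi
  NumericMatrix cutdist(ns - 2, ns);      // cut x state distances
  for (int s = 0; s < ns; ++s)
    for (unsigned M = 1; M < (unsigned)ns; ++M)
      phimat(M - 1, s) = tf[M - 1][pext_mask(s & M, M)].phi;

  int ci = 0;
  for (unsigned from = 1; from < (unsigned)(ns - 1); ++from, ++ci) {
    bool all_zero = true;
    for (int s = 0; s < ns; ++s)
      if (bigphi[s] > 0) { all_zero = false; break; }
    if (all_zero && ci > 0) {              // min already 0 everywhere; first wins ties
      for (int s = 0; s < ns; ++s) cutdist(ci, s) = NA_REAL;
      continue;
    }
    NumericMatrix cut_tpm = engF.apply_cut(from);
    double delta = 0;
    for (int s = 0; s < ns; ++s)
      for (int j = 0; j < n; ++j)
        delta = std::max(delta, std::fabs(cut_tpm(s, j) - tpm(s, j)));
    if (delta < 1e-15) {                   // cut severs no actual connection
      for (int s = 0; s < ns; ++s) {
        cutdist(ci, s) = 0.0;
        if (0.0 < bigphi[s]) { bigphi[s] = 0.0; mincut[s] = from; }
      }
      continue;
    }
    Engine engC(cut_tpm);
    std::vector<std::vector<MechEntry> > tc = engC.concept_table();
    for (int s = 0; s < ns; ++s) {
      double d = ces_distance_tables(engF, tf, engC, tc, s);
      cutdist(ci, s) = d;
      if (d < bigphi[s]) { bigphi[s] = d; mincut[s] = from; }
    }
  }
  return List::create(_["big_phi"] = bigphi, _["min_cut"] = mincut,
                      _["phi_matrix"] = phimat, _["cut_distances"] = cutdist);
}
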