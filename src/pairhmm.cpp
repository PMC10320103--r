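// Banded pair-HMM (3 states: M, I, D) for read-given-chunk likelihoods and
// the perturbation matrix P[r][i][e].
//
// Model (conditional on the chunk):
//   M emits a read base given the chunk base: match_prob if equal, else
//     (1 - match_prob)/3.  I emits a read base uniformly (1/4).  D is silent.
//   Transitions: M->I = M->D = gap_open, M->M = 1 - 2*gap_open,
//     I->I = D->D = gap_extend, I->M = D->M = 1 - gap_extend.  No I<->D.
//   The start state behaves like M; the model ends with probability 1 once
//   both sequences are consumed.
//
// The DP is banded around the diagonal j ~ i * l / L with half-width `band`
// and scaled per chunk-column, so everything stays in double range.
//
// Perturbation entries are obtained from stored forward/backward columns:
// every alignment path consumes chunk base p exactly once (in M or D), which
// gives an exact O(band) cut formula per edit rather than a full
// recomputation per edit.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

const double TINY = 1e-300;

struct Params {
  double match;    // emission agreement probability in M
  double q;        // per-base mismatch emission = (1 - match) / 3
  double eI;       // insertion emission = 0.25
  double tMM, tMI, tMD, tII, tIM, tDD, tDM;
  Params(double match_prob, double gap_open, double gap_extend) {
    match = match_prob;
    q = (1.0 - match_prob) / 3.0;
    eI = 0.25;
    tMI = gap_open;
    tMD = gap_open;
    tMM = 1.0 - 2.0 * gap_open;
    tII = gap_extend;
    tDD = gap_extend;
    tIM = 1.0 - gap_extend;
    tDM = 1.0 - gap_extend;
  }
  inline double eM(int a, int b) const { return a == b ? match : q; }
};

std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: stop("non-ACGT symbol in sequence");
    }
  }
  return v;
}

// Forward/backward tables for one (chunk, read) pair.
struct BandedFB {
  int L, l, W, width;
  std::vector<int> jlo, jhi;          // inclusive band per chunk column i=0..L
  // state tables, index (i, j - jlo[i]); width = 2W+1; shared workspace
  // reused across instances (single-threaded use, one instance at a time)
  static std::vector<double> FM, FI, FD, BM, BI, BD;
  std::vector<double> cumF, cumB;     // per-column log scale factors (cumulative)
  double ll;                          // forward log-likelihood

  inline double& at(std::vector<double>& T, int i, int j) { return T[(size_t)i * width + (j - jlo[i])]; }
  inline double get(const std::vector<double>& T, int i, int j) const {
    if (j < jlo[i] || j > jhi[i]) return 0.0;
    return T[(size_t)i * width + (j - jlo[i])];
  }

  BandedFB(const std::vector<int>& chunk, const std::vector<int>& read,
           const Params& pp, int band) {
    L = (int)chunk.size();
    l = (int)read.size();
    W = band;
    width = 2 * W + 1;
    jlo.resize(L + 1);
    jhi.resize(L + 1);
    for (int i = 0; i <= L; ++i) {
      int c = (int)std::llround((double)i * l / (double)L);
      jlo[i] = std::max(0, c - W);
      jhi[i] = std::min(l, c + W);
    }
    // every in-band cell is written before it is read, so reused buffers
    // need no zeroing beyond their initial growth
    size_t n = (size_t)(L + 1) * width;
    if (FM.size() < n) {
      FM.resize(n); FI.resize(n); FD.resize(n);
      BM.resize(n); BI.resize(n); BD.resize(n);
    }
    cumF.assign(L + 1, 0.0);
    cumB.assign(L + 1, 0.0);
    forward(chunk, read, pp);
    backward(chunk, read, pp);
  }

  // rescale a column and record the cumulative log scale; called every
  // SCALE_EVERY columns (doubles hold ~1e±308, per-column mass shrinks by
  // only a few e-folds, so sparse rescaling is safe)
  static constexpr int SCALE_EVERY = 16;

  void scale_col(std::vector<double>& A, std::vector<double>& Bv, std::vector<double>& C,
                 int i, std::vector<double>& cum, double prev, bool force) {
    if (!force && (i % SCALE_EVERY) != 0) {
      cum[i] = prev;
      return;
    }
    double s = 0.0;
    for (int j = jlo[i]; j <= jhi[i]; ++j)
      s += at(A, i, j) + at(Bv, i, j) + at(C, i, j);
    if (s < TINY) s = TINY;
    double inv = 1.0 / s;
    for (int j = jlo[i]; j <= jhi[i]; ++j) {
      at(A, i, j) *= inv; at(Bv, i, j) *= inv; at(C, i, j) *= inv;
    }
    cum[i] = prev + std::log(s);
  }

  void forward(const std::vector<int>& chunk, const std::vector<int>& read, const Params& pp) {
    // column 0 (all three states written explicitly: buffers are reused)
    for (int j = jlo[0]; j <= jhi[0]; ++j) {
      at(FM, 0, j) = (j == 0) ? 1.0 : 0.0;
      at(FD, 0, j) = 0.0;
      at(FI, 0, j) = (j >= 1)
        ? pp.eI * (pp.tMI * get(FM, 0, j - 1) + pp.tII * get(FI, 0, j - 1))
        : 0.0;
    }
    scale_col(FM, FI, FD, 0, cumF, 0.0, true);
    for (int i = 1; i <= L; ++i) {
      const int ci = chunk[i - 1];
      const double *pM = &FM[(size_t)(i - 1) * width], *pI = &FI[(size_t)(i - 1) * width],
                   *pD = &FD[(size_t)(i - 1) * width];
      double *cM = &FM[(size_t)i * width], *cI = &FI[(size_t)i * width],
             *cD = &FD[(size_t)i * width];
      const int lo = jlo[i], hi = jhi[i], plo = jlo[i - 1], phi = jhi[i - 1];
      const int s = lo - plo;  // prev index of j = idx + s
      for (int j = lo; j <= hi; ++j) {
        const int idx = j - lo;
        const int pd = idx + s;      // (i-1, j)
        const int pm = pd - 1;       // (i-1, j-1)
        double m = 0.0;
        if (j >= 1 && j - 1 >= plo && j - 1 <= phi) {
          m = pp.eM(ci, read[j - 1]) *
              (pp.tMM * pM[pm] + pp.tIM * pI[pm] + pp.tDM * pD[pm]);
        }
        cM[idx] = m;
        cD[idx] = (j >= plo && j <= phi) ? pp.tMD * pM[pd] + pp.tDD * pD[pd] : 0.0;
        cI[idx] = (idx >= 1) ? pp.eI * (pp.tMI * cM[idx - 1] + pp.tII * cI[idx - 1]) : 0.0;
      }
      scale_col(FM, FI, FD, i, cumF, cumF[i - 1], false);
    }
    double fin = get(FM, L, l) + get(FI, L, l) + get(FD, L, l);
    if (fin < TINY) fin = TINY;
    ll = std::log(fin) + cumF[L];
  }

  void backward(const std::vector<int>& chunk, const std::vector<int>& read, const Params& pp) {
    // column L
    if (jhi[L] == l) { at(BM, L, l) = 1.0; at(BI, L, l) = 1.0; at(BD, L, l) = 1.0; }
    for (int j = std::min(l - 1, jhi[L]); j >= jlo[L]; --j) {
      double bi = get(BI, L, j + 1);
      at(BM, L, j) = pp.tMI * pp.eI * bi;
      at(BI, L, j) = pp.tII * pp.eI * bi;
      at(BD, L, j) = 0.0;
    }
    scale_col(BM, BI, BD, L, cumB, 0.0, true);
    for (int i = L - 1; i >= 0; --i) {
      const int ci1 = chunk[i];  // chunk base i+1 (0-based i)
      const double *nM = &BM[(size_t)(i + 1) * width], *nD = &BD[(size_t)(i + 1) * width];
      double *cM = &BM[(size_t)i * width], *cI = &BI[(size_t)i * width],
             *cD = &BD[(size_t)i * width];
      const int lo = jlo[i], hi = jhi[i], nlo = jlo[i + 1], nhi = jhi[i + 1];
      const int s = lo - nlo;  // next-column index of j = idx + s
      for (int j = hi; j >= lo; --j) {
        const int idx = j - lo;
        const int nd = idx + s;       // (i+1, j)
        const int nm = nd + 1;        // (i+1, j+1)
        double em_bm1 = 0.0;
        if (j + 1 <= l && j + 1 >= nlo && j + 1 <= nhi)
          em_bm1 = pp.eM(ci1, read[j]) * nM[nm];
        const double bi0 = (j + 1 <= l && idx + 1 <= hi - lo) ? cI[idx + 1] : 0.0;
        const double bd1 = (j >= nlo && j <= nhi) ? nD[nd] : 0.0;
        cM[idx] = pp.tMM * em_bm1 + pp.tMI * pp.eI * bi0 + pp.tMD * bd1;
        cI[idx] = pp.tIM * em_bm1 + pp.tII * pp.eI * bi0;
        cD[idx] = pp.tDM * em_bm1 + pp.tDD * bd1;
      }
      scale_col(BM, BI, BD, i, cumB, cumB[i + 1], false);
    }
    // cross-check value available as log(BM(0,0)) + cumB[0]
  }

  double ll_backward() const {
    double v = get(BM, 0, 0);
    if (v < TINY) v = TINY;
    return std::log(v) + cumB[0];
  }
};

std::vector<double> BandedFB::FM; std::vector<double> BandedFB::FI;
std::vector<double> BandedFB::FD; std::vector<double> BandedFB::BM;
std::vector<double> BandedFB::BI; std::vector<double> BandedFB::BD;

inline double safelog(double x) { return std::log(x < TINY ? TINY : x); }

// Fill the 9 perturbation entries for every chunk position for one read.
// out must have room for L*9 doubles laid out out[pos * 9 + e].
// Edits e: 0..3 sub A/C/G/T, 4..7 ins A/C/G/T before pos, 8 del at pos.
void perturb_one(const std::vector<int>& chunk, const std::vector<int>& read,
                 const Params& pp, int band, double* out, double* ll_out) {
  BandedFB fb(chunk, read, pp, band);
  const int L = fb.L, l = fb.l;
  const int W = fb.width;
  *ll_out = fb.ll;
  for (int p = 1; p <= L; ++p) {
    const int cp = chunk[p - 1];
    const int lo_p = fb.jlo[p], hi_p = fb.jhi[p];
    const int lo1 = fb.jlo[p - 1], hi1 = fb.jhi[p - 1];
    const double *FMp = &fb.FM[(size_t)p * W], *FDp = &fb.FD[(size_t)p * W];
    const double *BMp = &fb.BM[(size_t)p * W], *BDp = &fb.BD[(size_t)p * W];
    const double *FM1 = &fb.FM[(size_t)(p - 1) * W], *FI1 = &fb.FI[(size_t)(p - 1) * W],
                 *FD1 = &fb.FD[(size_t)(p - 1) * W];
    const double *BM1 = &fb.BM[(size_t)(p - 1) * W], *BD1 = &fb.BD[(size_t)(p - 1) * W];
    // --- substitutions: cut at column p ---
    double A[4] = {0, 0, 0, 0}, DBp = 0.0;
    for (int j = lo_p; j <= hi_p; ++j) {
      const int idx = j - lo_p;
      if (j >= 1) A[read[j - 1]] += FMp[idx] * BMp[idx];
      DBp += FDp[idx] * BDp[idx];
    }
    double scale_p = fb.cumF[p] + fb.cumB[p];
    for (int b = 0; b < 4; ++b) {
      if (b == cp) { out[(size_t)(p - 1) * 9 + b] = 0.0; continue; }
      double s = DBp;
      for (int rb = 0; rb < 4; ++rb)
        s += (pp.eM(b, rb) / pp.eM(cp, rb)) * A[rb];
      out[(size_t)(p - 1) * 9 + b] = safelog(s) + scale_p - fb.ll;
    }
    // --- incoming vectors from column p-1 (shared by ins and del) ---
    double H[4] = {0, 0, 0, 0}, GDB = 0.0;
    for (int j = lo1; j <= hi1; ++j) {
      const int idx = j - lo1;
      if (idx >= 1 && j >= 1) {
        double gm = pp.tMM * FM1[idx - 1] + pp.tIM * FI1[idx - 1] + pp.tDM * FD1[idx - 1];
        H[read[j - 1]] += gm * BM1[idx];
      }
      double gd = pp.tMD * FM1[idx] + pp.tDD * FD1[idx];
      GDB += gd * BD1[idx];
    }
    double Htot = H[0] + H[1] + H[2] + H[3];
    double scale_ins = fb.cumF[p - 1] + fb.cumB[p - 1];
    for (int b = 0; b < 4; ++b) {
      double s = pp.match * H[b] + pp.q * (Htot - H[b]) + GDB;
      out[(size_t)(p - 1) * 9 + 4 + b] = safelog(s) + scale_ins - fb.ll;
    }
    // --- deletion of chunk base p ---
    double del;
    if (p < L) {
      const int cnext = chunk[p];
      const int lo2 = fb.jlo[p + 1], hi2 = fb.jhi[p + 1];
      const double *BM2 = &fb.BM[(size_t)(p + 1) * W], *BD2 = &fb.BD[(size_t)(p + 1) * W];
      double s = 0.0;
      int lo = std::max(lo1, lo2);
      int hi = std::min(hi1 + 1, hi2);
      for (int j = lo; j <= hi; ++j) {
        const int i1 = j - lo1, i2 = j - lo2;
        double gm = 0.0;
        if (j >= 1 && j - 1 >= lo1 && j - 1 <= hi1)
          gm = pp.tMM * FM1[i1 - 1] + pp.tIM * FI1[i1 - 1] + pp.tDM * FD1[i1 - 1];
        double gd = (j <= hi1) ? pp.tMD * FM1[i1] + pp.tDD * FD1[i1] : 0.0;
        s += (gm > 0 ? pp.eM(cnext, read[j - 1]) * gm * BM2[i2] : 0.0) + gd * BD2[i2];
      }
      del = safelog(s) + fb.cumF[p - 1] + fb.cumB[p + 1] - fb.ll;
    } else {
      // deleting the last chunk base: the edited chunk's forward table equals
      // columns 0..L-1 of the original, so its likelihood is the final-cell
      // sum there (tail insertions are already accumulated in FI).
      double s = fb.get(fb.FM, L - 1, l) + fb.get(fb.FI, L - 1, l) +
                 fb.get(fb.FD, L - 1, l);
      del = safelog(s) + fb.cumF[L - 1] - fb.ll;
    }
    out[(size_t)(p - 1) * 9 + 8] = del;
  }
}

}  // namespace

// [[Rcpp::export(name = ".ca_loglik_cpp")]]
double ca_loglik_cpp(std::string chunk, std::string read, double match_prob,
                     double gap_open, double gap_extend, int band) {
  Params pp(match_prob, gap_open, gap_extend);
  std::vector<int> c = encode(chunk), r = encode(read);
  if (c.empty() || r.empty()) stop("empty sequence");
  BandedFB fb(c, r, pp, band);
  return fb.ll;
}

// [[Rcpp::export(name = ".ca_loglik_fb_cpp")]]
NumericVector ca_loglik_fb_cpp(std::string chunk, std::string read, double match_prob,
                               double gap_open, double gap_extend, int band) {
  Params pp(match_prob, gap_open, gap_extend);
  std::vector<int> c = encode(chunk), r = encode(read);
  BandedFB fb(c, r, pp, band);
  return NumericVector::create(fb.ll, fb.ll_backward());
}

// Per-read perturbation matrices for one chunk.
// Returns list(P = array N x L x 9, loglik = numeric N).
// [[Rcpp::export(name = ".ca_perturbation_cpp")]]
List ca_perturbation_cpp(std::string chunk, CharacterVector reads, double match_prob,
                         double gap_open, double gap_extend, int band, bool sum_only) {
  Params pp(match_prob, gap_open, gap_extend);
  std::vector<int> c = encode(chunk);
  const int L = (int)c.size();
  const int N = reads.size();
  NumericVector lls(N);
  std::vector<double> buf((size_t)L * 9);
  if (sum_only) {
    NumericMatrix Ps(L, 9);
    for (int r = 0; r < N; ++r) {
      std::vector<int> rd = encode(as<std::string>(reads[r]));
      perturb_one(c, rd, pp, band, buf.data(), &lls[r]);
      for (int i = 0; i < L; ++i)
        for (int e = 0; e < 9; ++e) Ps(i, e) += buf[(size_t)i * 9 + e];
      Rcpp::checkUserInterrupt();
    }
    return List::create(_["Ps"] = Ps, _["loglik"] = lls);
  }
  NumericVector P((size_t)N * L * 9);  // index r + N*i + N*L*e
  for (int r = 0; r < N; ++r) {
    std::vector<int> rd = encode(as<std::string>(reads[r]));
    perturb_one(c, rd, pp, band, buf.data(), &lls[r]);
    for (int i = 0; i < L; ++i)
      for (int e = 0; e < 9; ++e)
        P[(size_t)r + (size_t)N * i + (size_t)N * L * e] = buf[(size_t)i * 9 + e];
    Rcpp::checkUserInterrupt();
  }
  P.attr("dim") = IntegerVector::create(N, L, 9);
  return List::create(_["P"] = P, _["loglik"] = lls);
}
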