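// Forward-time individual-based engine for the dominance-modifier network.
// Mirrors the R-level operations in R/population.R exactly (fitness model,
// soft selection within sexes, independent assortment of the alpha-A and
// beta-B linked units, per-nucleotide site mutation); equivalence of the two
// paths is covered by the test suite. Uses R's RNG, so runs are reproducible
// from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr int NCOL_REC = 18;

inline int hamming(const int* a, const int* b, int L) {
  int d = 0;
  for (int i = 0; i < L; ++i) d += (a[i] != b[i]);
  return d;
}

// weighted index draw from cumulative weights
inline int drawIndex(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return static_cast<int>(
      std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
}

struct Engine {
  int N, L;
  std::vector<int> a1, a2, b1, b2;       // N x L, row-major
  std::vector<char> cod1, cod2, female;  // cod: 1 = A2
  std::vector<int> stimF, stimM, recogA1, recogA2;
  double Dconc, k, Amax, effA1, effA2, Bmax;
  int fitnessShape;  // 0 linear, 1 gaussian
  double sF, sM, thetaF, thetaM, omega;
  double muSite;
  bool modifierOn;
  std::vector<double> kpow;  // k^{-d/L} for d = 0..L

  // per-generation scratch
  std::vector<double> conc1, conc2, mst1, mst2, phi, fit;

  void init_scratch() {
    kpow.resize(L + 1);
    for (int d = 0; d <= L; ++d) {
      kpow[d] = std::pow(k, -static_cast<double>(d) / L);
    }
    conc1.resize(N); conc2.resize(N);
    mst1.resize(N); mst2.resize(N);
    phi.resize(N); fit.resize(N);
  }

  double occupancy(int d) const {
    double x = Dconc * kpow[d];
    return x / (1.0 + 2.0 * x);
  }

  void computeState() {
    for (int i = 0; i < N; ++i) {
      const int* stim = female[i] ? stimF.data() : stimM.data();
      int d1 = hamming(&a1[i * L], stim, L);
      int d2 = hamming(&a2[i * L], stim, L);
      mst1[i] = static_cast<double>(d1) / L;
      mst2[i] = static_cast<double>(d2) / L;
      double c1 = Amax * occupancy(d1);
      double c2 = Amax * occupancy(d2);
      conc1[i] = c1;
      conc2[i] = c2;
      const int* r1 = cod1[i] ? recogA2.data() : recogA1.data();
      const int* r2 = cod2[i] ? recogA2.data() : recogA1.data();
      double e1 = cod1[i] ? effA2 : effA1;
      double e2 = cod2[i] ? effA2 : effA1;
      double B = 0.0;
      const int* betas[2] = {&b1[i * L], &b2[i * L]};
      for (int s = 0; s < 2; ++s) {
        double w1 = c1 * kpow[hamming(r1, betas[s], L)];
        double w2 = c2 * kpow[hamming(r2, betas[s], L)];
        double tot = w1 + w2;
        if (tot > 0.0) B += (w1 * e1 + w2 * e2) / tot;
      }
      double ph = (Bmax > 0.0) ? B / Bmax : 0.0;
      if (ph > 1.0) ph = 1.0;
      phi[i] = ph;
      if (fitnessShape == 0) {
        fit[i] = female[i] ? 1.0 - sF * (1.0 - ph) : 1.0 - sM * ph;
      } else {
        double th = female[i] ? thetaF : thetaM;
        double dz = ph - th;
        fit[i] = std::exp(-dz * dz / (2.0 * omega * omega));
      }
    }
  }

  double freqA2() const {
    long s = 0;
    for (int i = 0; i < N; ++i) s += cod1[i] + cod2[i];
    return static_cast<double>(s) / (2.0 * N);
  }

  // trajectory row; assumes computeState() has run on the current state
  void record(int gen, std::vector<double>& out) const {
    double phiSum[2][3] = {{0}}, wSum[2] = {0};
    int phiN[2][3] = {{0}}, sexN[2] = {0};
    double aseSum[2] = {0};
    int aseN[2] = {0}, hetN[2] = {0};
    double mSum[2][2] = {{0}};
    int mN[2][2] = {{0}};
    for (int i = 0; i < N; ++i) {
      int sx = female[i] ? 0 : 1;
      int n2 = cod1[i] + cod2[i];
      phiSum[sx][n2] += phi[i];
      ++phiN[sx][n2];
      wSum[sx] += fit[i];
      ++sexN[sx];
      if (n2 == 1) {
        ++hetN[sx];
        double cA1 = cod1[i] ? conc2[i] : conc1[i];
        double cA2 = cod1[i] ? conc1[i] : conc2[i];
        double tot = cA1 + cA2;
        if (tot > 0.0) {
          aseSum[sx] += cA1 / tot;
          ++aseN[sx];
        }
      }
      mSum[sx][cod1[i] ? 1 : 0] += mst1[i];
      ++mN[sx][cod1[i] ? 1 : 0];
      mSum[sx][cod2[i] ? 1 : 0] += mst2[i];
      ++mN[sx][cod2[i] ? 1 : 0];
    }
    auto avg = [](double s, int n) { return n ? s / n : NA_REAL; };
    out.push_back(gen);
    out.push_back(freqA2());
    for (int sx = 0; sx < 2; ++sx) {
      for (int n2 = 0; n2 < 3; ++n2) out.push_back(avg(phiSum[sx][n2], phiN[sx][n2]));
    }
    out.push_back(avg(wSum[0], sexN[0]));
    out.push_back(avg(wSum[1], sexN[1]));
    out.push_back(avg(aseSum[0], aseN[0]));
    out.push_back(avg(aseSum[1], aseN[1]));
    for (int sx = 0; sx < 2; ++sx) {
      for (int al = 0; al < 2; ++al) out.push_back(avg(mSum[sx][al], mN[sx][al]));
    }
    out.push_back(hetN[0]);
    out.push_back(hetN[1]);
  }

  void mutateMatrix(std::vector<int>& m) {
    const std::size_t n = m.size();
    for (std::size_t j = 0; j < n; ++j) {
      if (unif_rand() < muSite) {
        int step = 1 + static_cast<int>(unif_rand() * 3.0);
        m[j] = (m[j] - 1 + step) % 4 + 1;
      }
    }
  }

  // one Wright-Fisher generation; assumes computeState() current
  void reproduce() {
    std::vector<int> fIdx, mIdx;
    fIdx.reserve(N); mIdx.reserve(N);
    for (int i = 0; i < N; ++i) (female[i] ? fIdx : mIdx).push_back(i);
    std::vector<double> fCum(fIdx.size()), mCum(mIdx.size());
    double acc = 0.0;
    for (std::size_t i = 0; i < fIdx.size(); ++i) { acc += fit[fIdx[i]]; fCum[i] = acc; }
    if (acc <= 0.0) stop("degenerate selection: total fitness is zero in females");
    acc = 0.0;
    for (std::size_t i = 0; i < mIdx.size(); ++i) { acc += fit[mIdx[i]]; mCum[i] = acc; }
    if (acc <= 0.0) stop("degenerate selection: total fitness is zero in males");

    std::vector<int> na1(N * L), na2(N * L), nb1(N * L), nb2(N * L);
    std::vector<char> nc1(N), nc2(N), nf(N);
    for (int i = 0; i < N; ++i) nf[i] = (i < N / 2) ? 1 : 0;
    for (int i = N - 1; i > 0; --i) {  // Fisher-Yates shuffle of sexes
      int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(nf[i], nf[j]);
    }
    for (int i = 0; i < N; ++i) {
      int mom = fIdx[drawIndex(fCum)];
      int dad = mIdx[drawIndex(mCum)];
      bool am = unif_rand() < 0.5;  // take mother's second A haplotype?
      bool ap = unif_rand() < 0.5;
      bool bm = unif_rand() < 0.5;
      bool bp = unif_rand() < 0.5;
      nc1[i] = am ? cod2[mom] : cod1[mom];
      nc2[i] = ap ? cod2[dad] : cod1[dad];
      const int* srcA1 = (am ? a2 : a1).data() + mom * L;
      const int* srcA2 = (ap ? a2 : a1).data() + dad * L;
      const int* srcB1 = (bm ? b2 : b1).data() + mom * L;
      const int* srcB2 = (bp ? b2 : b1).data() + dad * L;
      std::copy(srcA1, srcA1 + L, na1.begin() + i * L);
      std::copy(srcA2, srcA2 + L, na2.begin() + i * L);
      std::copy(srcB1, srcB1 + L, nb1.begin() + i * L);
      std::copy(srcB2, srcB2 + L, nb2.begin() + i * L);
    }
    a1.swap(na1); a2.swap(na2); b1.swap(nb1); b2.swap(nb2);
    cod1.swap(nc1); cod2.swap(nc2); female.swap(nf);
    if (muSite > 0.0) {
      if (modifierOn) {
        mutateMatrix(a1);
        mutateMatrix(a2);
      }
      mutateMatrix(b1);
      mutateMatrix(b2);
    }
  }
};

std::vector<int> flattenRows(const IntegerMatrix& m) {
  std::vector<int> out(m.nrow() * m.ncol());
  for (int i = 0; i < m.nrow(); ++i) {
    for (int j = 0; j < m.ncol(); ++j) out[i * m.ncol() + j] = m(i, j);
  }
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cppSimulate")]]
List cppSimulate(IntegerMatrix alpha1, IntegerMatrix alpha2,
                 IntegerMatrix beta1, IntegerMatrix beta2,
                 LogicalVector cod1, LogicalVector cod2, LogicalVector female,
                 IntegerVector stimF, IntegerVector stimM,
                 IntegerVector recogA1, IntegerVector recogA2,
                 double Dconc, double k, double Amax,
                 double effA1, double effA2, double Bmax,
                 int fitnessShape, double sF, double sM,
                 double thetaF, double thetaM, double omega,
                 double muSite, bool modifierOn,
                 int nGen, int recordEvery) {
  Engine e;
  e.N = alpha1.nrow();
  e.L = alpha1.ncol();
  e.a1 = flattenRows(alpha1);
  e.a2 = flattenRows(alpha2);
  e.b1 = flattenRows(beta1);
  e.b2 = flattenRows(beta2);
  e.cod1.assign(cod1.begin(), cod1.end());
  e.cod2.assign(cod2.begin(), cod2.end());
  e.female.assign(female.begin(), female.end());
  e.stimF = as<std::vector<int>>(stimF);
  e.stimM = as<std::vector<int>>(stimM);
  e.recogA1 = as<std::vector<int>>(recogA1);
  e.recogA2 = as<std::vector<int>>(recogA2);
  e.Dconc = Dconc; e.k = k; e.Amax = Amax;
  e.effA1 = effA1; e.effA2 = effA2; e.Bmax = Bmax;
  e.fitnessShape = fitnessShape;
  e.sF = sF; e.sM = sM;
  e.thetaF = thetaF; e.thetaM = thetaM; e.omega = omega;
  e.muSite = muSite; e.modifierOn = modifierOn;
  e.init_scratch();

  std::vector<double> rows;
  int lossGen = -1;
  e.computeState();
  e.record(0, rows);
  double f = e.freqA2();
  if (f == 0.0 || f == 1.0) {
    lossGen = 0;
  } else {
    for (int g = 1; g <= nGen; ++g) {
      e.reproduce();
      e.computeState();
      f = e.freqA2();
      bool lost = (f == 0.0 || f == 1.0);
      if (g % recordEvery == 0 || g == nGen || lost) e.record(g, rows);
      if (lost) {
        lossGen = g;
        break;
      }
      if (g % 512 == 0) checkUserInterrupt();
    }
  }
  int nrow = static_cast<int>(rows.size()) / NCOL_REC;
  NumericMatrix rec(nrow, NCOL_REC);
  for (int i = 0; i < nrow; ++i) {
    for (int j = 0; j < NCOL_REC; ++j) rec(i, j) = rows[i * NCOL_REC + j];
  }
  return List::create(_["records"] = rec, _["lossGen"] = lossGen);
}
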