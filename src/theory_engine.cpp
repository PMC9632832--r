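// Discrete-grid evaluation of the per-cycle expected STDP updates for a
// synapse whose pre- and postsynaptic populations receive periodic stimulus
// trains lagged by a phase phi.
//
// All spike-time statistics live on a grid of bin width `delta` ms covering
// one cycle [0, T). Masses (not densities) are used throughout: Lm[, m] is
// the sub-normalised distribution of the mth spike bin; lam1[b] the first
// spike bin; lamc[[l]] (l >= 2) the conditional ISI mass (row e = ISI in
// bins, col x = previous spike bin); Llast the last-spike bin. Spike times
// are taken at bin centres, and the STDP kernel is evaluated analytically.
//
// The post-triggered (positive-lag) term W_m^+ integrates the mth
// postsynaptic arrival over the gap (0, eps] after each presynaptic arrival;
// the pre-triggered (negative-lag) term W_m^- integrates the mth presynaptic
// arrival over the gap (0, eps) after each postsynaptic arrival, evaluating
// the kernel at the negated lag. The asymmetric inclusion of the gap's far
// end mirrors the simulator's tie-break (simultaneous arrivals: post first).
// The mth-spike distribution is normalised by P(>= m spikes); re-weighting
// the m-sum by the spike-count distribution then reproduces the expectation
// of the nearest-neighbour pairing sum.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SparseVec { std::vector<int> idx; std::vector<double> val; };

SparseVec sparsify(const NumericVector &v) {
  SparseVec s;
  for (int i = 0; i < v.size(); ++i) {
    if (v[i] > 0) { s.idx.push_back(i); s.val.push_back(v[i]); }
  }
  return s;
}

const double EPS = 1e-7;  // window boundaries, in units of bins

// Sum over one gap window using the prefix sums S of Lnorm * exp(-t/tau):
// sum_{j: lo_excl < j+off <= / < up} Lnorm[j] * exp(-((j+0.5)*delta - C)/tau)
double window_sum(const std::vector<double> &S, int nb, double a, double up,
                  bool inclusive_upper, double expC) {
  int jlo = (int) std::floor(a + EPS) + 1;
  int jhi = inclusive_upper ? (int) std::floor(up + EPS)
                            : (int) std::floor(up - EPS);
  if (jlo < 0) jlo = 0;
  if (jhi > nb - 1) jhi = nb - 1;
  if (jhi < jlo) return 0.0;
  double lo = (jlo > 0) ? S[jlo - 1] : 0.0;
  return expC * (S[jhi] - lo);
}

}  // namespace

// [[Rcpp::export]]
List theory_percycle_cpp(NumericMatrix Lm, NumericVector lam1, List lamc,
                         NumericVector Llast, NumericVector Pk,
                         double phi, double T, double xi, double delta,
                         int kmin, int kmax,
                         double eta, double beta, double tau_R, double tau_plus) {
  const int nb = Lm.nrow();
  const int nmax = Lm.ncol();
  const double tau_minus = tau_plus * tau_R;
  const double amp_neg = eta * beta / tau_R;
  const double Tb = T / delta;  // cycle length in bins

  // sparse chain structures shared by both branches
  std::vector<SparseVec> Ln(nmax);
  for (int n = 0; n < nmax; ++n) Ln[n] = sparsify(Lm(_, n));
  SparseVec l1 = sparsify(lam1);
  SparseVec Ll = sparsify(Llast);
  // lamc[[l]] is the conditional ISI mass for spike order l (l >= 2);
  // store per x-bin sparse columns
  int n_lam = lamc.size();
  std::vector<std::vector<SparseVec>> lam_cols(n_lam);
  for (int l = 0; l < n_lam; ++l) {
    if (Rf_isNull(lamc[l])) continue;
    NumericMatrix m = lamc[l];
    lam_cols[l].resize(nb);
    for (int x = 0; x < nb; ++x) {
      for (int r = 0; r < m.nrow(); ++r) {
        if (m(r, x) > 0) {
          lam_cols[l][x].idx.push_back(r + 1);   // row r = ISI of r+1 bins
          lam_cols[l][x].val.push_back(m(r, x));
        }
      }
    }
  }

  std::vector<double> PgeM(nmax, 0.0);
  {
    double acc = 0.0;
    for (int m = nmax - 1; m >= 0; --m) { acc += Pk[m]; PgeM[m] = acc; }
  }

  NumericVector Wm_plus(nmax), Wm_minus(nmax);

  for (int m = 0; m < nmax; ++m) {
    if (PgeM[m] <= 0) { Wm_plus[m] = 0; Wm_minus[m] = 0; continue; }
    // normalised mth-spike distribution and its exponential prefix sums
    std::vector<double> Sp(nb, 0.0), Sm(nb, 0.0);
    {
      double accP = 0.0, accM = 0.0;
      for (int j = 0; j < nb; ++j) {
        double lj = Lm(j, m) / PgeM[m];
        accP += lj * std::exp(-((j + 0.5) * delta) / tau_plus);
        accM += lj * std::exp(-((j + 0.5) * delta) / tau_minus);
        Sp[j] = accP; Sm[j] = accM;
      }
    }

    for (int branch = 0; branch < 2; ++branch) {
      const bool plus = (branch == 0);
      const double tau = plus ? tau_plus : tau_minus;
      const double amp = plus ? eta : amp_neg;
      const std::vector<double> &S = plus ? Sp : Sm;
      // gap-window base offset: pre arrivals for the + branch, post for -
      const double offC = plus ? (-phi * T + xi) : (phi * T - xi);
      double tot = 0.0;

      for (int k = kmin; k <= kmax; ++k) {
        const double base = k * T + offC;
        // chain term: gap between the nth and (n+1)th spike of a cycle
        for (int n = 1; n <= nmax; ++n) {
          int li = n + 1 - 2;  // index of lambda_{n+1} in lam_cols
          if (li >= n_lam || lam_cols[li].empty()) continue;
          const SparseVec &L_n = Ln[n - 1];
          for (size_t a = 0; a < L_n.idx.size(); ++a) {
            int i = L_n.idx[a];
            double Ci = (i + 0.5) * delta + base;
            double lo = Ci / delta - 0.5;
            double expC = amp * std::exp(Ci / tau);
            const SparseVec &col = lam_cols[li][i];
            for (size_t b = 0; b < col.idx.size(); ++b) {
              double up = lo + col.idx[b];
              double sum = window_sum(S, nb, lo, up, plus, expC);
              if (sum != 0) tot += L_n.val[a] * col.val[b] * sum;
            }
          }
        }
        // boundary term: gap between a cycle's last spike and the first
        // spike of the next cycle
        for (size_t a = 0; a < Ll.idx.size(); ++a) {
          int i = Ll.idx[a];
          double Ci = (i + 0.5) * delta + base;
          double lo = Ci / delta - 0.5;
          double expC = amp * std::exp(Ci / tau);
          for (size_t b = 0; b < l1.idx.size(); ++b) {
            double up = lo + Tb + (l1.idx[b] - i);
            double sum = window_sum(S, nb, lo, up, plus, expC);
            if (sum != 0) tot += Ll.val[a] * l1.val[b] * sum;
          }
        }
      }
      if (plus) Wm_plus[m] = tot; else Wm_minus[m] = -tot;
    }
  }

  return List::create(_["Wm_plus"] = Wm_plus, _["Wm_minus"] = Wm_minus,
                      _["P_ge_m"] = wrap(PgeM));
}
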