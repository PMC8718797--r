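#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoidc(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Draw a node index from the cumulative noise distribution of one type
// (inverse-CDF on R's uniform stream, so results follow set.seed()).
static int draw_negative(const IntegerVector& nodes,
                         const NumericVector& cum) {
  double u = unif_rand();
  int lo = 0, hi = cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return nodes[lo];
}

// Skip-gram with type-constrained negative sampling over a walk corpus.
// psi/phi are d x n (column per node). Learning rate decays linearly from
// lr0 to lr_min over all scheduled updates. Returns updated matrices and
// the mean pair loss per epoch.
// [[Rcpp::export]]
List sgns_train_cpp(List walks, IntegerVector type, List type_nodes,
                    List type_cum, NumericMatrix psi, NumericMatrix phi,
                    int window, int negative, double lr0, double lr_min,
                    int epochs) {
  const int d = psi.nrow();
  const int nw = walks.size();
  // total number of (center, context) updates for the lr schedule
  double total = 0;
  for (int w = 0; w < nw; ++w) {
    IntegerVector wk = walks[w];
    int L = wk.size();
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      total += hi - lo;  // window minus the center itself
    }
  }
  total *= epochs;
  if (total <= 0) stop("corpus yields no context pairs");

  std::vector<double> grad(d);
  NumericVector epoch_loss(epochs);
  double done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0; double npairs = 0;
    for (int w = 0; w < nw; ++w) {
      IntegerVector wk = walks[w];
      int L = wk.size();
      for (int i = 0; i < L; ++i) {
        int vi = wk[i];
        int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int vj = wk[j];
          double lr = lr0 + (lr_min - lr0) * (done / total);
          done += 1;
          int tj = type[vj];
          IntegerVector tn = type_nodes[tj];
          NumericVector tc = type_cum[tj];
          double* pi = &psi(0, vi);
          std::fill(grad.begin(), grad.end(), 0.0);
          // positive context
          double s = 0;
          double* pj = &phi(0, vj);
          for (int k = 0; k < d; ++k) s += pj[k] * pi[k];
          double sg = sigmoidc(s);
          loss_sum += -std::log(std::max(1e-300, sg));
          for (int k = 0; k < d; ++k) {
            grad[k] -= (1 - sg) * pj[k];
            pj[k] += lr * (1 - sg) * pi[k];
          }
          // negatives of the context's type
          for (int u = 0; u < negative; ++u) {
            int vn = draw_negative(tn, tc);
            if (vn == vj) continue;
            double* pu = &phi(0, vn);
            double su = 0;
            for (int k = 0; k < d; ++k) su += pu[k] * pi[k];
            su = sigmoidc(su);
            loss_sum += -std::log(std::max(1e-300, 1 - su));
            for (int k = 0; k < d; ++k) {
              grad[k] += su * pu[k];
              pu[k] -= lr * su * pi[k];
            }
          }
          for (int k = 0; k < d; ++k) pi[k] -= lr * grad[k];
          npairs += 1;
        }
      }
    }
    epoch_loss[ep] = loss_sum / npairs;
  }
  return List::create(_["psi"] = psi, _["phi"] = phi,
                      _["epoch_loss"] = epoch_loss);
}

// Best axis-aligned split of a node by squared-error reduction on the
// residuals. Ties broken by lowest feature index, then lowest threshold.
// Returns (feature 1-based, threshold, gain) or feature = 0 when no valid
// split exists.
// [[Rcpp::export]]
NumericVector best_split_cpp(NumericMatrix X, NumericVector r,
                             IntegerVector rows, int min_leaf) {
  const int n = rows.size(), p = X.ncol();
  double best_gain = 0; int best_f = -1; double best_thr = 0;
  if (n < 2 * min_leaf)
    return NumericVector::create(0, NA_REAL, 0);
  std::vector<int> ord(n);
  std::vector<double> xv(n), rv(n);
  double rsum = 0;
  for (int i = 0; i < n; ++i) rsum += r[rows[i] - 1];
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) {
      ord[i] = i;
      xv[i] = X(rows[i] - 1, f);
      rv[i] = r[rows[i] - 1];
    }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xv[a] < xv[b]; });
    double cl = 0;
    for (int pos = 0; pos < n - 1; ++pos) {
      cl += rv[ord[pos]];
      int nl = pos + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double xl = xv[ord[pos]], xr = xv[ord[pos + 1]];
      if (xl >= xr) continue;  // no distinct threshold here
      double cr = rsum - cl;
      double gain = cl * cl / nl + cr * cr / nr - rsum * rsum / n;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = f;
        best_thr = (xl + xr) / 2;
      }
    }
  }
  if (best_f < 0) return NumericVector::create(0, NA_REAL, 0);
  return NumericVector::create(best_f + 1, best_thr, best_gain);
}
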