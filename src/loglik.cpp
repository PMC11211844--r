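#include <Rcpp.h>
using namespace Rcpp;

// Gaussian (Brownian) pruning over a rooted tree, both axes at once.
// Leaves carry displacement-adjusted observations z; internal entries are NA.
// Each node sends its parent the message N(m, V + sigma2 * brlen) scaled by
// an accumulated log factor; sibling messages combine by Gaussian product.
// The root (one child) evaluates the incoming message at (x0, y0).
// [[Rcpp::export]]
double bm_prune_cpp(IntegerVector postorder, IntegerVector parent,
                    NumericVector brlen, NumericVector zx, NumericVector zy,
                    double sigma2, double x0, double y0, int root) {
  const int n = parent.size();
  std::vector<double> mx(n), my(n), V(n), ll(n, 0.0);
  std::vector<int> nmsg(n, 0);
  const double LOG2PI = 1.8378770664093454836;

  for (int i = 0; i < n; ++i) {
    int v = postorder[i] - 1;
    if (nmsg[v] == 0) { // leaf
      if (NumericVector::is_na(zx[v])) return NA_REAL;
      mx[v] = zx[v];
      my[v] = zy[v];
      V[v] = 0.0;
    }
    if (v == root - 1) break;
    int u = parent[v] - 1;
    double Vmsg = V[v] + sigma2 * brlen[v];
    if (nmsg[u] == 0) {
      mx[u] = mx[v];
      my[u] = my[v];
      V[u] = Vmsg;
      ll[u] = ll[v];
    } else {
      double Vt = V[u] + Vmsg;
      if (Vt <= 0.0) return R_NegInf;
      double dx = mx[u] - mx[v];
      double dy = my[u] - my[v];
      ll[u] += ll[v] - LOG2PI - std::log(Vt) - 0.5 * (dx * dx + dy * dy) / Vt;
      double w = Vmsg / Vt;
      mx[u] = mx[u] * w + mx[v] * (1.0 - w);
      my[u] = my[u] * w + my[v] * (1.0 - w);
      V[u] = V[u] * Vmsg / Vt;
    }
    nmsg[u] += 1;
  }
  int rt = root - 1;
  if (nmsg[rt] == 0 || V[rt] <= 0.0) return R_NegInf;
  double dx = x0 - mx[rt];
  double dy = y0 - my[rt];
  return ll[rt] - LOG2PI - std::log(V[rt]) -
         0.5 * (dx * dx + dy * dy) / V[rt];
}

// Discrete pruning for the irreversible barcode model.
// Hidden states per site k: 0 (unmutated), 1..M(k) (mutated), M(k)+1
// (silenced). Transitions: mutation 0 -> a at rate lambda * pi_a, silencing
// h -> silent at rate nu from any non-silent state, silent absorbing.
// Observations: -2 = missing '?', 0..M observed state. Dropout: an unsilenced
// state is seen as '?' with probability phi; the silenced state is always '?'.
// obsidx maps node -> row of obs (0-based) or -1 for internal nodes.
// pioff/pivals hold per-site mutated-state priors (concatenated).
// Root state is fixed at 0 (unedited progenitor).
// [[Rcpp::export]]
NumericVector pmm_prune_cpp(IntegerVector postorder, IntegerVector parent,
                            NumericVector brlen, IntegerVector obsidx,
                            IntegerMatrix obs, IntegerVector Mk,
                            NumericVector pivals, IntegerVector pioff,
                            double lambda, double nu, double phi, int root) {
  const int n = parent.size();
  const int K = Mk.size();
  NumericVector out(K);

  for (int k = 0; k < K; ++k) {
    const int M = Mk[k];
    const int ns = M + 2; // 0, 1..M, silent at index M+1
    const double* pi = &pivals[pioff[k]];
    std::vector<double> part(n * ns, 1.0);
    std::vector<bool> seen(n, false);
    double logscale = 0.0;
    bool dead = false;

    for (int i = 0; i < n && !dead; ++i) {
      int v = postorder[i] - 1;
      double* pv = &part[v * ns];
      if (obsidx[v] >= 0) { // leaf emission
        int o = obs(obsidx[v], k);
        if (o == -2) { // missing
          for (int h = 0; h <= M; ++h) pv[h] = phi;
          pv[M + 1] = 1.0;
        } else {
          for (int h = 0; h < ns; ++h) pv[h] = 0.0;
          pv[o] = 1.0 - phi;
        }
      }
      if (v == root - 1) break;
      int u = parent[v] - 1;
      double el = std::exp(-lambda * brlen[v]);
      double en = std::exp(-nu * brlen[v]);
      // message to parent: msg[h] = sum_j P(h -> j; brlen) * pv[j]
      double summut = 0.0;
      for (int a = 1; a <= M; ++a) summut += pi[a - 1] * pv[a];
      double msg0 = el * en * pv[0] + (1.0 - el) * en * summut +
                    (1.0 - en) * pv[M + 1];
      double* pu = &part[u * ns];
      if (!seen[u]) {
        for (int h = 0; h < ns; ++h) pu[h] = 1.0;
        seen[u] = true;
      }
      pu[0] *= msg0;
      for (int a = 1; a <= M; ++a) {
        pu[a] *= en * pv[a] + (1.0 - en) * pv[M + 1];
      }
      pu[M + 1] *= pv[M + 1];
      // rescale the parent partial once all messages may have shrunk it
      double mx = 0.0;
      for (int h = 0; h < ns; ++h) mx = std::max(mx, pu[h]);
      if (mx > 0.0 && mx < 1e-280) {
        for (int h = 0; h < ns; ++h) pu[h] /= mx;
        logscale += std::log(mx);
      } else if (mx == 0.0) {
        dead = true;
      }
    }
    double L0 = part[(root - 1) * ns + 0];
    out[k] = dead || L0 <= 0.0 ? R_NegInf : std::log(L0) + logscale;
  }
  return out;
}
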