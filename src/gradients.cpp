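#include <Rcpp.h>
using namespace Rcpp;

// Analytic gradient of the spatial (SD) log-likelihood by Gaussian belief
// propagation. Edge factors are N(x_v ; x_u + D_e, W_e) with W_e = sigma^2 *
// floored branch length and D_e the signed division displacement (per axis).
// An upward (pruning) pass gives subtree messages, a downward pass gives
// posterior marginals; per-edge first/second moments of the innovation
// x_v - x_u - D_e yield d ll / d W_e and d ll / d D_e.
// dx, dy: leaf observations (NA internally); Dx, Dy: per-edge displacement.
// Returns ll plus per-edge gradients and the root-location gradient.
// [[Rcpp::export]]
List bm_bp_grad_cpp(IntegerVector postorder, IntegerVector preorder,
                    IntegerVector parent, NumericVector W,
                    NumericVector Dx, NumericVector Dy,
                    NumericVector zx, NumericVector zy,
                    double x0, double y0, int root) {
  const int n = parent.size();
  const double LOG2PI = 1.8378770664093454836;
  // upward: (mx, my, V) = combination of children messages at each node
  // (likelihood of strict-subtree data given the node value), leaves pinned
  std::vector<double> mx(n), my(n), V(n), ll(n, 0.0);
  std::vector<int> nmsg(n, 0);
  double loglik = 0.0;
  for (int i = 0; i < n; ++i) {
    int v = postorder[i] - 1;
    if (nmsg[v] == 0) { // leaf
      mx[v] = zx[v];
      my[v] = zy[v];
      V[v] = 0.0;
    }
    if (v == root - 1) break;
    int u = parent[v] - 1;
    double mmx = mx[v] + /* message mean for x_u: x_v - D */ 0.0;
    mmx = mx[v] - Dx[v];
    double mmy = my[v] - Dy[v];
    double Vm = V[v] + W[v];
    if (nmsg[u] == 0) {
      mx[u] = mmx; my[u] = mmy; V[u] = Vm; ll[u] = ll[v];
    } else {
      double Vt = V[u] + Vm;
      if (Vt <= 0.0) return List::create(Named("ll") = R_NegInf);
      double ddx = mx[u] - mmx, ddy = my[u] - mmy;
      ll[u] += ll[v] - LOG2PI - std::log(Vt) -
               0.5 * (ddx * ddx + ddy * ddy) / Vt;
      double w = Vm / Vt;
      mx[u] = mx[u] * w + mmx * (1.0 - w);
      my[u] = my[u] * w + mmy * (1.0 - w);
      V[u] = V[u] * Vm / Vt;
    }
    nmsg[u] += 1;
  }
  int rt = root - 1;
  if (nmsg[rt] == 0 || V[rt] <= 0.0)
    return List::create(Named("ll") = R_NegInf);
  {
    double ddx = x0 - mx[rt], ddy = y0 - my[rt];
    loglik = ll[rt] - LOG2PI - std::log(V[rt]) -
             0.5 * (ddx * ddx + ddy * ddy) / V[rt];
  }
  if (!R_finite(loglik)) return List::create(Named("ll") = loglik);

  // downward: posterior marginals (pmx, pmy, S) with the root pinned
  std::vector<double> pmx(n), pmy(n), S(n);
  pmx[rt] = x0; pmy[rt] = y0; S[rt] = 0.0;
  NumericVector gW(n), gDx(n), gDy(n);
  double gx0 = (mx[rt] - x0) / V[rt];
  double gy0 = (my[rt] - y0) / V[rt];
  for (int i = 0; i < n; ++i) {
    int v = preorder[i] - 1;
    if (v == rt) continue;
    int u = parent[v] - 1;
    double We = W[v];
    double alpha = V[v] / (We + V[v]); // 0 at leaves
    // x_v | x_u ~ N(alpha*m_v-part...) : mean a*(x_u + D) + (1-a)*m_below
    double sx = We * V[v] / (We + V[v]);
    double mvx = alpha * (pmx[u] + Dx[v]) + (1.0 - alpha) * mx[v];
    double mvy = alpha * (pmy[u] + Dy[v]) + (1.0 - alpha) * my[v];
    double Sv = alpha * alpha * S[u] + sx;
    // innovation d = x_v - x_u - D
    double edx = mvx - pmx[u] - Dx[v];
    double edy = mvy - pmy[u] - Dy[v];
    double vd = (alpha - 1.0) * (alpha - 1.0) * S[u] + sx;
    gW[v] = (edx * edx + vd - We) / (2.0 * We * We) +
            (edy * edy + vd - We) / (2.0 * We * We);
    gDx[v] = edx / We;
    gDy[v] = edy / We;
    pmx[v] = mvx; pmy[v] = mvy; S[v] = Sv;
  }
  return List::create(Named("ll") = loglik, Named("gW") = gW,
                      Named("gDx") = gDx, Named("gDy") = gDy,
                      Named("gx0") = gx0, Named("gy0") = gy0);
}

// Analytic gradient of the barcode log-likelihood by the inside-outside
// algorithm, summed over sites. Same model and encoding as pmm_prune_cpp.
// Returns total ll and gradients w.r.t. lambda, nu, phi, and each branch
// length. A site with zero likelihood makes the total -Inf (gradients 0).
// [[Rcpp::export]]
List pmm_grad_cpp(IntegerVector postorder, IntegerVector preorder,
                  IntegerVector parent, NumericVector brlen,
                  IntegerVector obsidx, IntegerMatrix obs, IntegerVector Mk,
                  NumericVector pivals, IntegerVector pioff,
                  double lambda, double nu, double phi, int root) {
  const int n = parent.size();
  const int K = Mk.size();
  const int rt = root - 1;
  double total = 0.0, gl = 0.0, gn = 0.0, gp = 0.0;
  NumericVector gd(n); // d ll / d brlen per edge (child-indexed)

  // children lists (binary or single)
  std::vector<int> c1(n, -1), c2(n, -1);
  for (int v = 0; v < n; ++v) {
    int u = parent[v] - 1;
    if (u >= 0) {
      if (c1[u] < 0) c1[u] = v; else c2[u] = v;
    }
  }

  for (int k = 0; k < K; ++k) {
    const int M = Mk[k];
    const int ns = M + 2;
    const double* pi = &pivals[pioff[k]];
    std::vector<double> P(n * ns, 1.0), O(n * ns, 0.0);
    std::vector<double> lin(n, 0.0), lout(n, 0.0);
    std::vector<double> msg(n * ns, 0.0); // message from v to its parent
    bool dead = false;

    // inside pass with per-node scaling
    for (int i = 0; i < n && !dead; ++i) {
      int v = postorder[i] - 1;
      double* pv = &P[v * ns];
      if (obsidx[v] >= 0) {
        int o = obs(obsidx[v], k);
        if (o == -2) {
          for (int h = 0; h <= M; ++h) pv[h] = phi;
          pv[M + 1] = 1.0;
        } else {
          for (int h = 0; h < ns; ++h) pv[h] = 0.0;
          pv[o] = 1.0 - phi;
        }
      } else {
        for (int c : {c1[v], c2[v]}) {
          if (c < 0) continue;
          for (int h = 0; h < ns; ++h) pv[h] *= msg[c * ns + h];
        }
        double mxv = 0.0;
        for (int h = 0; h < ns; ++h) mxv = std::max(mxv, pv[h]);
        if (mxv <= 0.0) { dead = true; break; }
        for (int h = 0; h < ns; ++h) pv[h] /= mxv;
        lin[v] = std::log(mxv);
        for (int c : {c1[v], c2[v]}) if (c >= 0) lin[v] += lin[c];
      }
      if (v == rt) break;
      double el = std::exp(-lambda * brlen[v]);
      double en = std::exp(-nu * brlen[v]);
      double summut = 0.0;
      for (int a = 1; a <= M; ++a) summut += pi[a - 1] * pv[a];
      double* mv = &msg[v * ns];
      mv[0] = el * en * pv[0] + (1.0 - el) * en * summut +
              (1.0 - en) * pv[M + 1];
      for (int a = 1; a <= M; ++a)
        mv[a] = en * pv[a] + (1.0 - en) * pv[M + 1];
      mv[M + 1] = pv[M + 1];
    }
    double L0 = dead ? 0.0 : P[rt * ns + 0];
    if (L0 <= 0.0) { total = R_NegInf; continue; }
    double logL = std::log(L0) + lin[rt];
    total += logL;

    // outside pass; O_v has the same per-site meaning scaled by exp(lout)
    for (int h = 0; h < ns; ++h) O[rt * ns + h] = 0.0;
    O[rt * ns + 0] = 1.0;
    lout[rt] = 0.0;
    for (int i = 0; i < n; ++i) {
      int u = preorder[i] - 1;
      if (obsidx[u] >= 0) continue; // leaves have no children
      for (int c : {c1[u], c2[u]}) {
        if (c < 0) continue;
        int sib = (c == c1[u]) ? c2[u] : c1[u];
        // outside at u excluding child c's message
        std::vector<double> op(ns);
        double lop = lout[u];
        for (int h = 0; h < ns; ++h) op[h] = O[u * ns + h];
        if (sib >= 0) {
          for (int h = 0; h < ns; ++h) op[h] *= msg[sib * ns + h];
          lop += lin[sib];
        }
        double el = std::exp(-lambda * brlen[c]);
        double en = std::exp(-nu * brlen[c]);
        const double* pc = &P[c * ns];
        // gradient contributions of edge (u, c): sum over (h, j) of
        // op[h] * pc[j] * dPsi(h,j)/dx, scaled by exp(lop + lin[c] - logL)
        double sc = std::exp(lop + lin[c] - logL);
        double summut = 0.0, sumpid = 0.0;
        for (int a = 1; a <= M; ++a) {
          summut += pi[a - 1] * pc[a];
          sumpid += pi[a - 1] * pc[a];
        }
        double t = brlen[c];
        // from state 0
        double c0 = op[0] * sc;
        gl += c0 * (-t * el * en * pc[0] + t * el * en * summut);
        gn += c0 * (-t * el * en * pc[0] - t * (1.0 - el) * en * summut +
                    t * en * pc[M + 1]);
        gd[c] += c0 * (-(lambda + nu) * el * en * pc[0] +
                       (lambda * el * en - nu * (1.0 - el) * en) * sumpid +
                       nu * en * pc[M + 1]);
        // from mutated states
        for (int a = 1; a <= M; ++a) {
          double ca = op[a] * sc;
          gn += ca * (-t * en * pc[a] + t * en * pc[M + 1]);
          gd[c] += ca * (-nu * en * pc[a] + nu * en * pc[M + 1]);
        }
        // silent state: Psi row constant, no gradient
        // propagate outside to child c
        double* oc = &O[c * ns];
        oc[0] = op[0] * el * en;
        for (int a = 1; a <= M; ++a)
          oc[a] = op[0] * pi[a - 1] * (1.0 - el) * en + op[a] * en;
        oc[M + 1] = op[0] * (1.0 - en);
        for (int a = 1; a <= M; ++a) oc[M + 1] += op[a] * (1.0 - en);
        oc[M + 1] += op[M + 1];
        double mxo = 0.0;
        for (int h = 0; h < ns; ++h) mxo = std::max(mxo, oc[h]);
        if (mxo > 0.0) {
          for (int h = 0; h < ns; ++h) oc[h] /= mxo;
          lout[c] = lop + std::log(mxo);
        } else {
          lout[c] = R_NegInf;
        }
      }
    }
    // phi gradient via leaf emissions
    for (int v = 0; v < n; ++v) {
      if (obsidx[v] < 0) continue;
      int o = obs(obsidx[v], k);
      double sc = std::exp(lout[v] - logL);
      if (!R_finite(sc)) continue;
      const double* ov = &O[v * ns];
      if (o == -2) {
        for (int h = 0; h <= M; ++h) gp += sc * ov[h]; // dE/dphi = 1
      } else {
        gp -= sc * ov[o]; // dE/dphi = -1
      }
    }
  }
  if (!R_finite(total)) {
    return List::create(Named("ll") = total);
  }
  return List::create(Named("ll") = total, Named("glambda") = gl,
                      Named("gnu") = gn, Named("gphi") = gp,
                      Named("gdelta") = gd);
}
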