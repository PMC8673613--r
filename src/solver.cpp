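// Incomplete-Cholesky (IC0) preconditioned conjugate gradients for the
// symmetric positive definite FE systems. Matrix passed in CSC arrays
// (full symmetric pattern); the factor is built on the lower triangle.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// IC(0) on lower-triangular CSC pattern. Returns false on breakdown.
static bool ic0(const std::vector<int>& Lp, const std::vector<int>& Li,
                std::vector<double>& Lx, int n) {
  std::vector<int> ptr(n), head(n, -1), nxt(n, -1), marker(n, -1);
  std::vector<double> w(n, 0.0);
  for (int j = 0; j < n; ++j) {
    // scatter column j
    for (int q = Lp[j]; q < Lp[j + 1]; ++q) {
      w[Li[q]] = Lx[q];
      marker[Li[q]] = j;
    }
    // updates from earlier columns with an entry in row j
    int k = head[j];
    while (k != -1) {
      int knext = nxt[k];
      double ljk = Lx[ptr[k]];
      for (int q = ptr[k]; q < Lp[k + 1]; ++q) {
        int i = Li[q];
        if (marker[i] == j) w[i] -= ljk * Lx[q];
      }
      ++ptr[k];
      if (ptr[k] < Lp[k + 1]) {
        int r = Li[ptr[k]];
        nxt[k] = head[r]; head[r] = k;
      }
      k = knext;
    }
    double d = w[j];
    if (!(d > 0.0)) return false;
    double dj = std::sqrt(d);
    Lx[Lp[j]] = dj;
    for (int q = Lp[j] + 1; q < Lp[j + 1]; ++q) Lx[q] = w[Li[q]] / dj;
    ptr[j] = Lp[j] + 1;
    if (ptr[j] < Lp[j + 1]) {
      int r = Li[ptr[j]];
      nxt[j] = head[r]; head[r] = j;
    }
  }
  return true;
}

static void solve_LLt(const std::vector<int>& Lp, const std::vector<int>& Li,
                      const std::vector<double>& Lx, int n,
                      const std::vector<double>& r, std::vector<double>& z,
                      std::vector<double>& y) {
  // forward: L y = r (column-oriented)
  for (int i = 0; i < n; ++i) y[i] = r[i];
  for (int j = 0; j < n; ++j) {
    y[j] /= Lx[Lp[j]];
    double yj = y[j];
    for (int q = Lp[j] + 1; q < Lp[j + 1]; ++q) y[Li[q]] -= Lx[q] * yj;
  }
  // backward: L^T z = y
  for (int i = 0; i < n; ++i) z[i] = y[i];
  for (int j = n - 1; j >= 0; --j) {
    double acc = z[j];
    for (int q = Lp[j] + 1; q < Lp[j + 1]; ++q) acc -= Lx[q] * z[Li[q]];
    z[j] = acc / Lx[Lp[j]];
  }
}

// [[Rcpp::export]]
List sparse_pcg(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                NumericVector b, double tol, int maxit) {
  const int n = b.size();
  // symmetric Jacobi scaling A' = D^{-1/2} A D^{-1/2} absorbs the large
  // conductivity contrast before the incomplete factorization
  std::vector<double> dscale(n, 1.0);
  for (int j = 0; j < n; ++j)
    for (int q = Ap[j]; q < Ap[j + 1]; ++q)
      if (Ai[q] == j && Ax[q] > 0.0) dscale[j] = 1.0 / std::sqrt(Ax[q]);
  std::vector<double> Axs(Ax.size());
  for (int j = 0; j < n; ++j)
    for (int q = Ap[j]; q < Ap[j + 1]; ++q)
      Axs[q] = Ax[q] * dscale[Ai[q]] * dscale[j];
  std::vector<double> bs(n);
  for (int i = 0; i < n; ++i) bs[i] = b[i] * dscale[i];
  // build lower triangle (row >= col), diagonal first per column
  std::vector<int> Lp(n + 1, 0), Li;
  std::vector<double> Lx;
  std::vector<double> diag(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int q = Ap[j]; q < Ap[j + 1]; ++q)
      if (Ai[q] >= j) Lp[j + 1]++;
  for (int j = 0; j < n; ++j) Lp[j + 1] += Lp[j];
  Li.resize(Lp[n]); Lx.resize(Lp[n]);
  {
    std::vector<int> pos(n);
    for (int j = 0; j < n; ++j) pos[j] = Lp[j];
    for (int j = 0; j < n; ++j) {
      // diagonal entry first
      for (int q = Ap[j]; q < Ap[j + 1]; ++q)
        if (Ai[q] == j) { Li[pos[j]] = j; Lx[pos[j]] = Axs[q];
                          diag[j] = Axs[q]; pos[j]++; }
      for (int q = Ap[j]; q < Ap[j + 1]; ++q)
        if (Ai[q] > j) { Li[pos[j]] = Ai[q]; Lx[pos[j]] = Axs[q]; pos[j]++; }
    }
  }
  // IC(0) with diagonal shift retries on breakdown
  std::vector<double> L0(Lx);
  double shift = 0.0;
  bool ok = ic0(Lp, Li, Lx, n);
  int tries = 0;
  while (!ok && tries < 12) {
    shift = (shift == 0.0) ? 1e-4 : shift * 10.0;
    Lx = L0;
    for (int j = 0; j < n; ++j) Lx[Lp[j]] = L0[Lp[j]] * (1.0 + shift);
    ok = ic0(Lp, Li, Lx, n);
    ++tries;
  }
  // CG
  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Apv(n), work(n);
  for (int i = 0; i < n; ++i) r[i] = bs[i];
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += bs[i] * bs[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iters"] = 0,
                        _["rel_res"] = 0.0, _["converged"] = true);
  auto precond = [&](const std::vector<double>& rr, std::vector<double>& zz) {
    if (ok) solve_LLt(Lp, Li, Lx, n, rr, zz, work);
    else for (int i = 0; i < n; ++i) zz[i] = rr[i] / diag[i];
  };
  precond(r, z);
  for (int i = 0; i < n; ++i) p[i] = z[i];
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  double relres = 1.0;
  int it = 0;
  for (; it < maxit; ++it) {
    // A p (full symmetric CSC)
    std::fill(Apv.begin(), Apv.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double pj = p[j];
      if (pj != 0.0)
        for (int q = Ap[j]; q < Ap[j + 1]; ++q) Apv[Ai[q]] += Axs[q] * pj;
    }
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Apv[i];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Apv[i];
      rnorm += r[i] * r[i];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres < tol) { ++it; break; }
    precond(r, z);
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) rz_new += r[i] * z[i];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  for (int i = 0; i < n; ++i) x[i] *= dscale[i];   // unscale
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iters"] = it,
                      _["rel_res"] = relres,
                      _["converged"] = relres < tol,
                      _["ic_shift"] = shift,
                      _["ic_ok"] = ok);
}
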