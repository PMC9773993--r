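#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// 3D connected-component labelling on a logical mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels start at 1;
// voxels outside the mask get 0. Deterministic scan order (column-major).
// [[Rcpp::export(name = "cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> offs_x, offs_y, offs_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_x.push_back(dx); offs_y.push_back(dy); offs_z.push_back(dz);
      }
  int lab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++lab;
    stack.clear();
    stack.push_back(s);
    out[s] = lab;
    while (!stack.empty()) {
      R_xlen_t c = stack.back(); stack.pop_back();
      int cx = (int)(c % nx);
      int cy = (int)((c / nx) % ny);
      int cz = (int)(c / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < offs_x.size(); ++k) {
        int x = cx + offs_x[k], y = cy + offs_y[k], z = cz + offs_z[k];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        R_xlen_t t = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (mask[t] && out[t] == 0) { out[t] = lab; stack.push_back(t); }
      }
    }
  }
  return out;
}

// ---- incomplete-Cholesky preconditioned conjugate gradients ---------------
//
// A is a symmetric positive-definite sparse matrix in compressed sparse
// column form (both triangles stored, rows sorted within columns, as in
// Matrix::dgCMatrix). The preconditioner is IC(0): an incomplete Cholesky
// factor on the lower-triangular sparsity pattern of A, with a Manteuffel
// diagonal shift retried on breakdown. Fully serial and deterministic.

struct CscLower {
  std::vector<int> p;       // column pointers, size n+1
  std::vector<int> i;       // row indices (>= column), sorted
  std::vector<double> x;    // values
  std::vector<int> diag;    // position of the diagonal entry per column
};

static void extract_lower(const IntegerVector &Ap, const IntegerVector &Ai,
                          const NumericVector &Ax, int n, CscLower &L) {
  L.p.assign(n + 1, 0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] >= j) ++L.p[j + 1];
  for (int j = 0; j < n; ++j) L.p[j + 1] += L.p[j];
  L.i.resize(L.p[n]);
  L.x.resize(L.p[n]);
  L.diag.assign(n, -1);
  std::vector<int> pos(L.p.begin(), L.p.end() - 1);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] >= j) {
        int q = pos[j]++;
        L.i[q] = Ai[k];
        L.x[q] = Ax[k];
        if (Ai[k] == j) L.diag[j] = q;
      }
}

// In-place IC(0) on L (values initialized from A's lower triangle, with the
// diagonal scaled by (1 + shift)). Returns false on breakdown.
static bool ic0_factor(CscLower &L, int n, double shift) {
  if (shift > 0.0)
    for (int j = 0; j < n; ++j) L.x[L.diag[j]] *= (1.0 + shift);
  for (int k = 0; k < n; ++k) {
    int dk = L.diag[k];
    if (dk < 0) return false;
    double d = L.x[dk];
    if (!(d > 0.0) || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    L.x[dk] = d;
    for (int p = dk + 1; p < L.p[k + 1]; ++p) L.x[p] /= d;
    // Update later columns that have an entry in column k.
    for (int p1 = dk + 1; p1 < L.p[k + 1]; ++p1) {
      int j = L.i[p1];
      double ljk = L.x[p1];
      // subtract ljk * L(i,k) from L(i,j) for i >= j in pattern of col j
      for (int p2 = p1; p2 < L.p[k + 1]; ++p2) {
        int i = L.i[p2];
        // binary search for row i in column j
        int lo = L.p[j], hi = L.p[j + 1] - 1, found = -1;
        while (lo <= hi) {
          int mid = (lo + hi) / 2;
          if (L.i[mid] == i) { found = mid; break; }
          if (L.i[mid] < i) lo = mid + 1; else hi = mid - 1;
        }
        if (found >= 0) L.x[found] -= ljk * L.x[p2];
      }
    }
  }
  return true;
}

// Solve L y = r, then L^T z = y (z overwrites work vector).
static void ic0_solve(const CscLower &L, int n, const double *r, double *z,
                      double *work) {
  for (int j = 0; j < n; ++j) work[j] = r[j];
  for (int j = 0; j < n; ++j) {           // forward: L y = r
    double yj = work[j] / L.x[L.diag[j]];
    work[j] = yj;
    for (int p = L.diag[j] + 1; p < L.p[j + 1]; ++p)
      work[L.i[p]] -= L.x[p] * yj;
  }
  for (int j = n - 1; j >= 0; --j) {      // backward: L^T z = y
    double s = work[j];
    for (int p = L.diag[j] + 1; p < L.p[j + 1]; ++p)
      s -= L.x[p] * work[L.i[p]];
    work[j] = s / L.x[L.diag[j]];
  }
  for (int j = 0; j < n; ++j) z[j] = work[j];
}

static void spmv(const IntegerVector &Ap, const IntegerVector &Ai,
                 const NumericVector &Ax, int n, const double *v, double *y) {
  for (int j = 0; j < n; ++j) y[j] = 0.0;
  for (int j = 0; j < n; ++j) {
    double vj = v[j];
    if (vj == 0.0) continue;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * vj;
  }
}

// [[Rcpp::export(name = "ic0_pcg_cpp")]]
List ic0_pcg_cpp(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                 NumericVector b, double tol, int maxit) {
  const int n = b.size();
  CscLower L;
  double shift = 0.0;
  bool ok = false;
  for (int attempt = 0; attempt < 8; ++attempt) {
    extract_lower(Ap, Ai, Ax, n, L);
    ok = ic0_factor(L, n, shift);
    if (ok) break;
    shift = (shift == 0.0) ? 1e-3 : shift * 10.0;
  }
  if (!ok) stop("IC(0) factorization failed even with diagonal shift.");

  NumericVector x(n, 0.0);
  std::vector<double> r(n), z(n), p(n), q(n), work(n);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) { r[j] = b[j]; bnorm += b[j] * b[j]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = x, _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true,
                        _["shift"] = shift);
  }
  ic0_solve(L, n, r.data(), z.data(), work.data());
  for (int j = 0; j < n; ++j) p[j] = z[j];
  double rz = 0.0;
  for (int j = 0; j < n; ++j) rz += r[j] * z[j];
  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    spmv(Ap, Ai, Ax, n, p.data(), q.data());
    double pq = 0.0;
    for (int j = 0; j < n; ++j) pq += p[j] * q[j];
    if (pq <= 0.0) stop("PCG breakdown: matrix not positive definite.");
    double alpha = rz / pq;
    double rn = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * q[j];
      rn += r[j] * r[j];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres <= tol) break;
    ic0_solve(L, n, r.data(), z.data(), work.data());
    double rz_new = 0.0;
    for (int j = 0; j < n; ++j) rz_new += r[j] * z[j];
    double beta = rz_new / rz;
    rz = rz_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  bool converged = relres <= tol;
  return List::create(_["x"] = x, _["iterations"] = std::min(it, maxit),
                      _["relres"] = relres, _["converged"] = converged,
                      _["shift"] = shift);
}
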