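// Sparse ILU(0)-preconditioned Krylov solvers (CG / BiCGStab) for the
// structured finite-volume systems assembled on the R side.  Matrices arrive
// in dgCMatrix (CSC) form and are converted to CSR once; the ILU(0) factor
// is cached behind an external pointer so repeated solves (Uzawa pressure
// iterations, Picard transport iterations) reuse it.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct CsrIlu {
  int n;
  std::vector<int> rowptr, colind, diagptr;
  std::vector<double> val;   // original matrix values
  std::vector<double> lu;    // ILU(0) factor values (same pattern)
};

// CSC (Ap, Ai, Ax) -> CSR of the same matrix.
static void csc_to_csr(int n, const IntegerVector& Ap, const IntegerVector& Ai,
                       const NumericVector& Ax, CsrIlu& M) {
  int nnz = Ax.size();
  M.n = n;
  M.rowptr.assign(n + 1, 0);
  M.colind.resize(nnz);
  M.val.resize(nnz);
  for (int k = 0; k < nnz; ++k) M.rowptr[Ai[k] + 1]++;
  for (int i = 0; i < n; ++i) M.rowptr[i + 1] += M.rowptr[i];
  std::vector<int> next(M.rowptr.begin(), M.rowptr.end() - 1);
  for (int col = 0; col < n; ++col) {
    for (int k = Ap[col]; k < Ap[col + 1]; ++k) {
      int row = Ai[k];
      int dst = next[row]++;
      M.colind[dst] = col;   // columns come out sorted because rows in CSC are
      M.val[dst] = Ax[k];
    }
  }
}

// ILU(0); with milu = true the dropped fill is lumped onto the diagonal
// (modified ILU), which roughly halves CG iteration counts on Poisson-type
// systems.
static void ilu0(CsrIlu& M, bool milu) {
  int n = M.n;
  M.lu = M.val;
  M.diagptr.assign(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int k = M.rowptr[i]; k < M.rowptr[i + 1]; ++k) {
      if (M.colind[k] == i) { M.diagptr[i] = k; break; }
    }
    if (M.diagptr[i] < 0) stop("ilu0: missing diagonal entry in row %d", i);
  }
  std::vector<int> iw(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int k = M.rowptr[i]; k < M.rowptr[i + 1]; ++k) iw[M.colind[k]] = k;
    double dropped = 0.0;
    for (int k = M.rowptr[i]; k < M.rowptr[i + 1]; ++k) {
      int col = M.colind[k];
      if (col >= i) break;
      double piv = M.lu[M.diagptr[col]];
      if (piv == 0.0) piv = 1e-300;
      double mult = M.lu[k] / piv;
      M.lu[k] = mult;
      for (int kk = M.diagptr[col] + 1; kk < M.rowptr[col + 1]; ++kk) {
        int pos = iw[M.colind[kk]];
        if (pos >= 0) M.lu[pos] -= mult * M.lu[kk];
        else if (milu) dropped += mult * M.lu[kk];
      }
    }
    if (milu) M.lu[M.diagptr[i]] -= dropped;
    if (M.lu[M.diagptr[i]] == 0.0) M.lu[M.diagptr[i]] = 1e-300;
    for (int k = M.rowptr[i]; k < M.rowptr[i + 1]; ++k) iw[M.colind[k]] = -1;
  }
}

static void matvec(const CsrIlu& M, const double* x, double* y) {
  for (int i = 0; i < M.n; ++i) {
    double s = 0.0;
    for (int k = M.rowptr[i]; k < M.rowptr[i + 1]; ++k)
      s += M.val[k] * x[M.colind[k]];
    y[i] = s;
  }
}

// z = (LU)^{-1} r
static void ilu_apply(const CsrIlu& M, const double* r, double* z) {
  int n = M.n;
  // forward solve L z = r (unit lower)
  for (int i = 0; i < n; ++i) {
    double s = r[i];
    for (int k = M.rowptr[i]; k < M.diagptr[i]; ++k)
      s -= M.lu[k] * z[M.colind[k]];
    z[i] = s;
  }
  // backward solve U z = z
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = M.diagptr[i] + 1; k < M.rowptr[i + 1]; ++k)
      s -= M.lu[k] * z[M.colind[k]];
    z[i] = s / M.lu[M.diagptr[i]];
  }
}

static double dot(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

static double nrm2(const std::vector<double>& a) { return std::sqrt(dot(a, a)); }

// [[Rcpp::export]]
SEXP cpp_make_solver(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                     int n, bool milu) {
  XPtr<CsrIlu> ptr(new CsrIlu(), true);
  csc_to_csr(n, Ap, Ai, Ax, *ptr);
  ilu0(*ptr, milu);
  return ptr;
}

// [[Rcpp::export]]
List cpp_solve(SEXP solver, NumericVector b, NumericVector x0,
               double tol, int maxit, std::string method) {
  XPtr<CsrIlu> M(solver);
  int n = M->n;
  if ((int)b.size() != n) stop("cpp_solve: rhs length mismatch");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), z(n), tmp(n);
  matvec(*M, x.data(), tmp.data());
  for (int i = 0; i < n; ++i) r[i] = b[i] - tmp[i];
  double bnrm = nrm2(std::vector<double>(b.begin(), b.end()));
  if (bnrm == 0.0) bnrm = 1.0;
  double rn = nrm2(r);
  int it = 0;
  bool conv = rn <= tol * bnrm;

  if (!conv && method == "cg") {
    std::vector<double> p(n), Ap_(n);
    ilu_apply(*M, r.data(), z.data());
    p = z;
    double rz = dot(r, z);
    for (it = 1; it <= maxit; ++it) {
      matvec(*M, p.data(), Ap_.data());
      double pAp = dot(p, Ap_);
      if (pAp == 0.0) break;
      double alpha = rz / pAp;
      for (int i = 0; i < n; ++i) { x[i] += alpha * p[i]; r[i] -= alpha * Ap_[i]; }
      rn = nrm2(r);
      if (rn <= tol * bnrm) { conv = true; break; }
      ilu_apply(*M, r.data(), z.data());
      double rz_new = dot(r, z);
      double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    }
  } else if (!conv) {  // BiCGStab, ILU left-preconditioned
    std::vector<double> r0(r), p(n, 0.0), v(n, 0.0), s(n), t(n), ph(n), sh(n);
    double rho = 1.0, alpha = 1.0, omega = 1.0;
    for (it = 1; it <= maxit; ++it) {
      double rho_new = dot(r0, r);
      if (rho_new == 0.0) break;
      if (it == 1) {
        p = r;
      } else {
        double beta = (rho_new / rho) * (alpha / omega);
        for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * v[i]);
      }
      rho = rho_new;
      ilu_apply(*M, p.data(), ph.data());
      matvec(*M, ph.data(), v.data());
      double r0v = dot(r0, v);
      if (r0v == 0.0) break;
      alpha = rho / r0v;
      for (int i = 0; i < n; ++i) s[i] = r[i] - alpha * v[i];
      if (nrm2(s) <= tol * bnrm) {
        for (int i = 0; i < n; ++i) x[i] += alpha * ph[i];
        r = s; rn = nrm2(r); conv = true; break;
      }
      ilu_apply(*M, s.data(), sh.data());
      matvec(*M, sh.data(), t.data());
      double tt = dot(t, t);
      if (tt == 0.0) break;
      omega = dot(t, s) / tt;
      for (int i = 0; i < n; ++i) {
        x[i] += alpha * ph[i] + omega * sh[i];
        r[i] = s[i] - omega * t[i];
      }
      rn = nrm2(r);
      if (rn <= tol * bnrm) { conv = true; break; }
      if (omega == 0.0) break;
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iters"] = it,
                      _["relres"] = rn / bnrm,
                      _["converged"] = conv);
}

// [[Rcpp::export]]
NumericVector cpp_matvec(SEXP solver, NumericVector x) {
  XPtr<CsrIlu> M(solver);
  NumericVector y(M->n);
  matvec(*M, REAL(x), REAL(y));
  return y;
}
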