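#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Finite-volume solver for the periodic unit-cell corrector problem on an
// n^3 grid.  Face transmissibilities Tx/Ty/Tz (stored at the cell on the
// minus side of the face, periodic wrap) define the flux-conservative
// 7-point stencil; zero transmissibility across a face realises the
// staircase Neumann (reflecting) condition on obstacle surfaces.
//
// The corrector omega_j solves  sum_Q T_PQ (omega_P - omega_Q) =
// h (T_{+j}(P) - T_{-j}(P)),  i.e. the discrete Laplace problem with the
// inhomogeneous Neumann data folded into the right-hand side via
// chi_j = omega_j + x_j.  The system is singular (constants on the fluid
// component); consistency holds because the forcing sums to zero.

static inline int wrap_up(int i, int n) { return (i + 1 == n) ? 0 : i + 1; }
static inline int wrap_dn(int i, int n) { return (i == 0) ? n - 1 : i - 1; }

// y = A x for the stencil above; diag-zero (isolated/solid) cells act as
// identity rows so the system is nonsingular outside the fluid component.
static void stencil_matvec(const std::vector<double>& Tx,
                           const std::vector<double>& Ty,
                           const std::vector<double>& Tz,
                           const std::vector<double>& diag,
                           int n, const std::vector<double>& x,
                           std::vector<double>& y) {
  const size_t N = x.size();
  for (size_t p = 0; p < N; ++p) y[p] = (diag[p] == 0.0) ? x[p] : 0.0;
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      const size_t base = (size_t)n * (j + (size_t)n * k);
      const size_t basej = (size_t)n * (wrap_up(j, n) + (size_t)n * k);
      const size_t basek = (size_t)n * (j + (size_t)n * wrap_up(k, n));
      for (int i = 0; i < n; ++i) {
        const size_t p = base + i;
        double t = Tx[p];
        if (t != 0.0) {
          const size_t q = base + wrap_up(i, n);
          const double f = t * (x[p] - x[q]);
          y[p] += f; y[q] -= f;
        }
        t = Ty[p];
        if (t != 0.0) {
          const size_t q = basej + i;
          const double f = t * (x[p] - x[q]);
          y[p] += f; y[q] -= f;
        }
        t = Tz[p];
        if (t != 0.0) {
          const size_t q = basek + i;
          const double f = t * (x[p] - x[q]);
          y[p] += f; y[q] -= f;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List solve_corrector_cpp(NumericVector Tx_, NumericVector Ty_, NumericVector Tz_,
                         int n, int axis, double tol, int maxit) {
  const size_t N = (size_t)n * n * n;
  if ((size_t)Tx_.size() != N || (size_t)Ty_.size() != N || (size_t)Tz_.size() != N)
    stop("transmissibility arrays must have n^3 entries");
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  std::vector<double> Tx(Tx_.begin(), Tx_.end());
  std::vector<double> Ty(Ty_.begin(), Ty_.end());
  std::vector<double> Tz(Tz_.begin(), Tz_.end());
  const double h = 1.0 / n;

  // diagonal: sum of face transmissibilities around each cell
  std::vector<double> diag(N, 0.0);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        const size_t p = i + (size_t)n * (j + (size_t)n * k);
        const size_t qx = wrap_up(i, n) + (size_t)n * (j + (size_t)n * k);
        const size_t qy = i + (size_t)n * (wrap_up(j, n) + (size_t)n * k);
        const size_t qz = i + (size_t)n * (j + (size_t)n * wrap_up(k, n));
        diag[p] += Tx[p] + Ty[p] + Tz[p];
        diag[qx] += Tx[p]; diag[qy] += Ty[p]; diag[qz] += Tz[p];
      }

  // rhs: b_P = h (T_{+axis}(P) - T_{-axis}(P))
  std::vector<double> b(N, 0.0);
  const std::vector<double>& Ta = (axis == 1) ? Tx : (axis == 2 ? Ty : Tz);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        const size_t p = i + (size_t)n * (j + (size_t)n * k);
        size_t pm;
        if (axis == 1)      pm = wrap_dn(i, n) + (size_t)n * (j + (size_t)n * k);
        else if (axis == 2) pm = i + (size_t)n * (wrap_dn(j, n) + (size_t)n * k);
        else                pm = i + (size_t)n * (j + (size_t)n * wrap_dn(k, n));
        b[p] = h * (Ta[p] - Ta[pm]);
      }

  // Jacobi-preconditioned CG on the singular consistent system; the
  // iterates stay orthogonal to the null space because b does, so a final
  // zero-mean projection over fluid cells fixes the gauge.
  std::vector<double> x(N, 0.0), r(b), z(N), p(N), Ap(N);
  std::vector<double> dinv(N);
  for (size_t q = 0; q < N; ++q) dinv[q] = (diag[q] == 0.0) ? 1.0 : 1.0 / diag[q];

  double bnorm = 0.0;
  for (size_t q = 0; q < N; ++q) bnorm += b[q] * b[q];
  bnorm = std::sqrt(bnorm);
  double relres = 0.0;
  int it = 0;
  bool converged = true;
  if (bnorm > 0.0) {
    converged = false;
    for (size_t q = 0; q < N; ++q) z[q] = dinv[q] * r[q];
    p = z;
    double rz = 0.0;
    for (size_t q = 0; q < N; ++q) rz += r[q] * z[q];
    for (it = 1; it <= maxit; ++it) {
      stencil_matvec(Tx, Ty, Tz, diag, n, p, Ap);
      double pAp = 0.0;
      for (size_t q = 0; q < N; ++q) pAp += p[q] * Ap[q];
      const double alpha = rz / pAp;
      double rn = 0.0;
      for (size_t q = 0; q < N; ++q) {
        x[q] += alpha * p[q];
        r[q] -= alpha * Ap[q];
        rn += r[q] * r[q];
      }
      relres = std::sqrt(rn) / bnorm;
      if (relres <= tol) { converged = true; break; }
      double rz_new = 0.0;
      for (size_t q = 0; q < N; ++q) {
        z[q] = dinv[q] * r[q];
        rz_new += r[q] * z[q];
      }
      const double beta = rz_new / rz;
      rz = rz_new;
      for (size_t q = 0; q < N; ++q) p[q] = z[q] + beta * p[q];
    }
  }

  // zero-mean gauge over fluid cells (diag > 0)
  double mean = 0.0; size_t nf = 0;
  for (size_t q = 0; q < N; ++q) if (diag[q] > 0.0) { mean += x[q]; ++nf; }
  if (nf > 0) mean /= nf;
  for (size_t q = 0; q < N; ++q) x[q] = (diag[q] > 0.0) ? x[q] - mean : 0.0;

  // face-flux sums for the effective-diffusivity quadrature:
  // S[d] = sum over d-faces of T * (omega_Q - omega_P + h * delta(d, axis))
  NumericVector S(3);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        const size_t pp = i + (size_t)n * (j + (size_t)n * k);
        const size_t qx = wrap_up(i, n) + (size_t)n * (j + (size_t)n * k);
        const size_t qy = i + (size_t)n * (wrap_up(j, n) + (size_t)n * k);
        const size_t qz = i + (size_t)n * (j + (size_t)n * wrap_up(k, n));
        S[0] += Tx[pp] * (x[qx] - x[pp] + (axis == 1 ? h : 0.0));
        S[1] += Ty[pp] * (x[qy] - x[pp] + (axis == 2 ? h : 0.0));
        S[2] += Tz[pp] * (x[qz] - x[pp] + (axis == 3 ? h : 0.0));
      }

  return List::create(_["omega"] = NumericVector(x.begin(), x.end()),
                      _["flux_sums"] = S,
                      _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = converged,
                      _["n_fluid"] = (double)nf);
}

// Periodic flood fill: is the fluid phase a single face-connected component?
// [[Rcpp::export]]
bool fluid_connected_cpp(LogicalVector fluid, int n) {
  const size_t N = (size_t)n * n * n;
  if ((size_t)fluid.size() != N) stop("mask must have n^3 entries");
  size_t nf = 0, seed = N;
  for (size_t q = 0; q < N; ++q) if (fluid[q]) { ++nf; if (seed == N) seed = q; }
  if (nf == 0) return false;
  std::vector<char> seen(N, 0);
  std::vector<size_t> stack;
  stack.reserve(nf);
  stack.push_back(seed);
  seen[seed] = 1;
  size_t count = 0;
  while (!stack.empty()) {
    const size_t p = stack.back(); stack.pop_back();
    ++count;
    const int i = p % n, j = (p / n) % n, k = p / ((size_t)n * n);
    const size_t nb[6] = {
      (size_t)wrap_up(i, n) + (size_t)n * (j + (size_t)n * k),
      (size_t)wrap_dn(i, n) + (size_t)n * (j + (size_t)n * k),
      (size_t)i + (size_t)n * (wrap_up(j, n) + (size_t)n * k),
      (size_t)i + (size_t)n * (wrap_dn(j, n) + (size_t)n * k),
      (size_t)i + (size_t)n * (j + (size_t)n * wrap_up(k, n)),
      (size_t)i + (size_t)n * (j + (size_t)n * wrap_dn(k, n))
    };
    for (int d = 0; d < 6; ++d)
      if (fluid[nb[d]] && !seen[nb[d]]) { seen[nb[d]] = 1; stack.push_back(nb[d]); }
  }
  return count == nf;
}
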