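#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tension-only constitutive law f(eps) = A*eps + B*eps^p for eps > 0, else 0.
// Linear springs are the special case B = 0, A = k. The per-spring stiffness
// multiplier kmul scales the whole law. `form` is the exponent m on the rest
// length: tension T = kmul * L0^(m-1) * f(eps), energy = kmul * L0^m * F(eps)
// with F the antiderivative of f. m = 2 gives the extension-based quadratic
// (k/2)(L - L0)^2 for linear springs; m = 1 the strain-based (k/2) L0 eps^2.

static inline double law_f(double eps, double A, double B, double p) {
  if (eps <= 0.0) return 0.0;
  return A * eps + (B != 0.0 ? B * std::pow(eps, p) : 0.0);
}

static inline double law_F(double eps, double A, double B, double p) {
  if (eps <= 0.0) return 0.0;
  double e = 0.5 * A * eps * eps;
  if (B != 0.0) e += B * std::pow(eps, p + 1.0) / (p + 1.0);
  return e;
}

// Spring energy + gradient of the total energy wrt node positions.
// pos is n x 3; from/to are 0-based spring endpoint indices.
// ext (n x 3 or 0 x 0) holds constant external nodal forces; their potential
// -sum(ext . x) is included in the returned energy and gradient.
static double energy_grad(const NumericMatrix& pos,
                          const IntegerVector& from, const IntegerVector& to,
                          const NumericVector& L0, const NumericVector& kmul,
                          const LogicalVector& broken,
                          double A, double B, double p, int form,
                          const NumericMatrix& ext,
                          std::vector<double>* grad) {
  const int n = pos.nrow(), ns = from.size();
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  double E = 0.0;
  for (int s = 0; s < ns; ++s) {
    if (broken[s]) continue;
    const int i = from[s], j = to[s];
    const double dx = pos(j, 0) - pos(i, 0);
    const double dy = pos(j, 1) - pos(i, 1);
    const double dz = pos(j, 2) - pos(i, 2);
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double l0 = L0[s];
    const double eps = (L - l0) / l0;
    if (eps <= 0.0) continue;
    const double scale = kmul[s] * (form == 2 ? l0 * l0 : l0);
    E += scale * law_F(eps, A, B, p);
    if (grad && L > 0.0) {
      // dE/dL = scale * f(eps) / l0 = tension
      const double T = scale * law_f(eps, A, B, p) / l0;
      const double c = T / L;
      (*grad)[i * 3 + 0] -= c * dx; (*grad)[j * 3 + 0] += c * dx;
      (*grad)[i * 3 + 1] -= c * dy; (*grad)[j * 3 + 1] += c * dy;
      (*grad)[i * 3 + 2] -= c * dz; (*grad)[j * 3 + 2] += c * dz;
    }
  }
  if (ext.nrow() == n) {
    for (int i = 0; i < n; ++i) {
      E -= ext(i, 0) * pos(i, 0) + ext(i, 1) * pos(i, 1) + ext(i, 2) * pos(i, 2);
      if (grad) {
        (*grad)[i * 3 + 0] -= ext(i, 0);
        (*grad)[i * 3 + 1] -= ext(i, 1);
        (*grad)[i * 3 + 2] -= ext(i, 2);
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
double net_energy_cpp(const NumericMatrix& pos,
                      const IntegerVector& from, const IntegerVector& to,
                      const NumericVector& L0, const NumericVector& kmul,
                      const LogicalVector& broken,
                      double A, double B, double p, int form,
                      const NumericMatrix& ext) {
  return energy_grad(pos, from, to, L0, kmul, broken, A, B, p, form, ext, NULL);
}

// Net nodal forces (-grad of total energy, including external forces).
// [[Rcpp::export]]
NumericMatrix net_forces_cpp(const NumericMatrix& pos,
                             const IntegerVector& from, const IntegerVector& to,
                             const NumericVector& L0, const NumericVector& kmul,
                             const LogicalVector& broken,
                             double A, double B, double p, int form,
                             const NumericMatrix& ext) {
  const int n = pos.nrow();
  std::vector<double> grad(3 * n, 0.0);
  energy_grad(pos, from, to, L0, kmul, broken, A, B, p, form, ext, &grad);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) F(i, d) = -grad[i * 3 + d];
  return F;
}

// Per-spring current length, engineering strain and tension.
// [[Rcpp::export]]
List spring_state_cpp(const NumericMatrix& pos,
                      const IntegerVector& from, const IntegerVector& to,
                      const NumericVector& L0, const NumericVector& kmul,
                      const LogicalVector& broken,
                      double A, double B, double p, int form) {
  const int ns = from.size();
  NumericVector len(ns), strain(ns), tension(ns);
  for (int s = 0; s < ns; ++s) {
    const int i = from[s], j = to[s];
    const double dx = pos(j, 0) - pos(i, 0);
    const double dy = pos(j, 1) - pos(i, 1);
    const double dz = pos(j, 2) - pos(i, 2);
    const double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    len[s] = L;
    const double eps = (L - L0[s]) / L0[s];
    strain[s] = eps;
    if (broken[s] || eps <= 0.0) {
      tension[s] = 0.0;
    } else {
      const double scale = kmul[s] * (form == 2 ? L0[s] * L0[s] : L0[s]);
      tension[s] = scale * law_f(eps, A, B, p) / L0[s];
    }
  }
  return List::create(_["length"] = len, _["strain"] = strain,
                      _["tension"] = tension);
}

// Gradient-based energy minimization of the node positions: limited-memory
// BFGS directions with Armijo backtracking (so the energy sequence is
// strictly non-increasing), falling back to steepest descent whenever the
// quasi-Newton direction is not a descent direction. Nodes with
// movable = FALSE never move; the two force criteria (max and mean
// resultant-force magnitude) are evaluated over nodes with active = TRUE.
// [[Rcpp::export]]
List minimize_net_cpp(NumericMatrix pos,
                      const IntegerVector& from, const IntegerVector& to,
                      const NumericVector& L0, const NumericVector& kmul,
                      const LogicalVector& broken,
                      double A, double B, double p, int form,
                      const NumericMatrix& ext,
                      const LogicalVector& movable, const LogicalVector& active,
                      double tol_max, double tol_mean,
                      int max_iter, double step0, double armijo_c,
                      bool trace_energy) {
  const int n = pos.nrow();
  const int N = 3 * n;
  const int M = 8; // L-BFGS memory
  NumericMatrix x = clone(pos);
  std::vector<double> g(N), g_old(N), x_old(N), dir(N);
  std::vector<std::vector<double>> S(M, std::vector<double>(N)),
      Y(M, std::vector<double>(N));
  std::vector<double> rho(M), alpha_lb(M);
  int n_mem = 0, mem_pos = 0;
  std::vector<double> etrace;
  if (trace_energy) etrace.reserve(512);

  double E = energy_grad(x, from, to, L0, kmul, broken, A, B, p, form, ext, &g);
  for (int i = 0; i < n; ++i)
    if (!movable[i]) g[i * 3] = g[i * 3 + 1] = g[i * 3 + 2] = 0.0;
  if (trace_energy) etrace.push_back(E);

  double max_force = 0.0, mean_force = 0.0;
  bool converged = false;
  int iter = 0, n_active = 0;
  for (int i = 0; i < n; ++i) if (active[i]) ++n_active;

  for (iter = 0; iter < max_iter; ++iter) {
    // force criteria over active nodes
    max_force = 0.0; mean_force = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      const double fn = std::sqrt(g[i * 3] * g[i * 3] +
                                  g[i * 3 + 1] * g[i * 3 + 1] +
                                  g[i * 3 + 2] * g[i * 3 + 2]);
      if (fn > max_force) max_force = fn;
      mean_force += fn;
    }
    if (n_active > 0) mean_force /= n_active;
    if (max_force < tol_max && mean_force < tol_mean) { converged = true; break; }

    double gg = 0.0;
    for (int k = 0; k < N; ++k) gg += g[k] * g[k];
    if (gg == 0.0) { converged = true; break; }

    // two-loop recursion for the L-BFGS direction
    for (int k = 0; k < N; ++k) dir[k] = -g[k];
    if (n_mem > 0) {
      for (int j = 0; j < n_mem; ++j) {
        const int idx = (mem_pos - 1 - j + M * 4) % M;
        double sd = 0.0;
        for (int k = 0; k < N; ++k) sd += S[idx][k] * dir[k];
        alpha_lb[idx] = rho[idx] * sd;
        for (int k = 0; k < N; ++k) dir[k] -= alpha_lb[idx] * Y[idx][k];
      }
      const int last = (mem_pos - 1 + M) % M;
      double yy = 0.0, sy = 0.0;
      for (int k = 0; k < N; ++k) {
        yy += Y[last][k] * Y[last][k];
        sy += S[last][k] * Y[last][k];
      }
      const double gamma = (yy > 0.0) ? sy / yy : 1.0;
      for (int k = 0; k < N; ++k) dir[k] *= gamma;
      for (int j = n_mem - 1; j >= 0; --j) {
        const int idx = (mem_pos - 1 - j + M * 4) % M;
        double yd = 0.0;
        for (int k = 0; k < N; ++k) yd += Y[idx][k] * dir[k];
        const double beta = rho[idx] * yd;
        for (int k = 0; k < N; ++k) dir[k] += S[idx][k] * (alpha_lb[idx] - beta);
      }
    }
    double gd = 0.0;
    for (int k = 0; k < N; ++k) gd += g[k] * dir[k];
    if (!(gd < 0.0) || !std::isfinite(gd)) {
      // not a descent direction: reset to steepest descent
      for (int k = 0; k < N; ++k) dir[k] = -g[k];
      gd = -gg;
      n_mem = 0;
    }

    std::copy(g.begin(), g.end(), g_old.begin());
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) x_old[i * 3 + d] = x(i, d);

    // Armijo backtracking along dir: E_new <= E + c * alpha * g.dir
    double alpha = (n_mem > 0) ? 1.0 : step0 / std::max(1e-12, max_force);
    bool ok = false;
    double E_new = 0.0;
    for (int bt = 0; bt < 60; ++bt) {
      for (int i = 0; i < n; ++i) {
        if (!movable[i]) continue;
        x(i, 0) = x_old[i * 3] + alpha * dir[i * 3];
        x(i, 1) = x_old[i * 3 + 1] + alpha * dir[i * 3 + 1];
        x(i, 2) = x_old[i * 3 + 2] + alpha * dir[i * 3 + 2];
      }
      E_new = energy_grad(x, from, to, L0, kmul, broken, A, B, p, form, ext, NULL);
      if (E_new <= E + armijo_c * alpha * gd) { ok = true; break; }
      alpha *= 0.5;
    }
    if (!ok) {
      if (n_mem > 0) { // distrust the quasi-Newton memory and retry
        n_mem = 0;
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d) x(i, d) = x_old[i * 3 + d];
        continue;
      }
      // steepest descent cannot decrease at machine precision: stop
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) x(i, d) = x_old[i * 3 + d];
      break;
    }

    E = energy_grad(x, from, to, L0, kmul, broken, A, B, p, form, ext, &g);
    for (int i = 0; i < n; ++i)
      if (!movable[i]) g[i * 3] = g[i * 3 + 1] = g[i * 3 + 2] = 0.0;
    if (trace_energy) etrace.push_back(E);

    // curvature update
    double sy = 0.0, snorm2 = 0.0, ynorm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      for (int d = 0; d < 3; ++d) {
        const int k = i * 3 + d;
        const double s = x(i, d) - x_old[k];
        const double y = g[k] - g_old[k];
        S[mem_pos][k] = s; Y[mem_pos][k] = y;
        sy += s * y; snorm2 += s * s; ynorm2 += y * y;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (movable[i]) continue;
      for (int d = 0; d < 3; ++d) {
        S[mem_pos][i * 3 + d] = 0.0; Y[mem_pos][i * 3 + d] = 0.0;
      }
    }
    if (sy > 1e-10 * std::sqrt(snorm2 * ynorm2) && sy > 0.0) {
      rho[mem_pos] = 1.0 / sy;
      mem_pos = (mem_pos + 1) % M;
      if (n_mem < M) ++n_mem;
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["pos"] = x, _["energy"] = E,
                      _["energy_trace"] = wrap(etrace),
                      _["iterations"] = iter, _["converged"] = converged,
                      _["max_force"] = max_force, _["mean_force"] = mean_force);
}
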