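#include <Rcpp.h>
using namespace Rcpp;

// Moore neighbourhood offsets
static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// phases: 1 = G1, 2 = S, 3 = G2, 4 = M

// [[Rcpp::export]]
IntegerMatrix cpp_simulate_abm(int L,
                               IntegerMatrix init_cells, // n x 3: x, y, phase (1-based)
                               NumericVector rates,      // rho_G1_S, rho_S_G2, rho_G2_M, rho_M_G1
                               double s,
                               double K_A,
                               int T_con,
                               double dt,
                               NumericVector record_times,
                               double t_end) {
  const int n_rec = record_times.size();
  IntegerMatrix out(n_rec, 2);

  std::vector<int> occ((size_t)L * L, 0); // 0 empty, else cell index + 1
  std::vector<int> cx, cy, ph;
  const int n0 = init_cells.nrow();
  cx.reserve(4096); cy.reserve(4096); ph.reserve(4096);
  for (int i = 0; i < n0; ++i) {
    int x = init_cells(i, 0) - 1, y = init_cells(i, 1) - 1;
    if (x < 0 || x >= L || y < 0 || y >= L) stop("initial cell off lattice");
    size_t idx = (size_t)x * L + y;
    if (occ[idx] != 0) stop("two initial cells on one site");
    cx.push_back(x); cy.push_back(y); ph.push_back(init_cells(i, 2));
    occ[idx] = (int)cx.size();
  }

  // per-step event probabilities
  double p_tr[4];
  for (int k = 0; k < 4; ++k) p_tr[k] = 1.0 - std::exp(-rates[k] * dt);
  const double p_mig = 1.0 - std::exp(-s * dt);

  const int n_steps = (int)std::lround(t_end / dt);
  int rec = 0;
  std::vector<int> order;
  int nbr_empty[8];

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    while (rec < n_rec && record_times[rec] <= t + 1e-9) {
      int g1s = 0, g2m = 0;
      for (size_t i = 0; i < ph.size(); ++i) {
        if (ph[i] <= 2) ++g1s; else ++g2m;
      }
      out(rec, 0) = g1s; out(rec, 1) = g2m;
      ++rec;
    }
    if (step == n_steps) break;

    const int n_now = (int)cx.size(); // daughters born this step are not updated this step
    order.resize(n_now);
    for (int i = 0; i < n_now; ++i) order[i] = i;
    for (int i = n_now - 1; i > 0; --i) { // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int oi = 0; oi < n_now; ++oi) {
      const int i = order[oi];
      const int x = cx[i], y = cy[i], phase = ph[i];

      // phase-transition attempt
      if (unif_rand() < p_tr[phase - 1]) {
        if (phase == 1) {
          // restriction point: G1 -> S arrested by contact inhibition
          int n_occ = 0;
          for (int k = 0; k < 8; ++k) {
            int nx = x + DX[k], ny = y + DY[k];
            if (nx < 0 || nx >= L || ny < 0 || ny >= L) continue;
            if (occ[(size_t)nx * L + ny]) ++n_occ;
          }
          if (n_occ <= T_con) ph[i] = 2;
        } else if (phase < 4) {
          ph[i] = phase + 1;
        } else {
          // M -> G1 always proceeds; a daughter G1 cell is produced only if
          // the parent is not contact-inhibited (occupied <= T_con), an
          // empty Moore neighbour exists, and the division survives the
          // global logistic thinning (blocked with probability N/K_A)
          int n_occ = 0, n_empty = 0;
          for (int k = 0; k < 8; ++k) {
            int nx = x + DX[k], ny = y + DY[k];
            if (nx < 0 || nx >= L || ny < 0 || ny >= L) continue;
            if (occ[(size_t)nx * L + ny]) ++n_occ; else nbr_empty[n_empty++] = k;
          }
          ph[i] = 1;
          double n_tot = (double)cx.size();
          if (n_occ <= T_con && n_empty > 0 && unif_rand() >= n_tot / K_A) {
            int k = nbr_empty[(int)(unif_rand() * n_empty)];
            int nx = x + DX[k], ny = y + DY[k];
            cx.push_back(nx); cy.push_back(ny); ph.push_back(1);
            occ[(size_t)nx * L + ny] = (int)cx.size();
          }
        }
      }

      // migration attempt
      if (p_mig > 0 && unif_rand() < p_mig) {
        int n_empty = 0;
        for (int k = 0; k < 8; ++k) {
          int nx = cx[i] + DX[k], ny = cy[i] + DY[k];
          if (nx < 0 || nx >= L || ny < 0 || ny >= L) continue;
          if (!occ[(size_t)nx * L + ny]) nbr_empty[n_empty++] = k;
        }
        if (n_empty > 0) {
          int k = nbr_empty[(int)(unif_rand() * n_empty)];
          int nx = cx[i] + DX[k], ny = cy[i] + DY[k];
          occ[(size_t)cx[i] * L + cy[i]] = 0;
          cx[i] = nx; cy[i] = ny;
          occ[(size_t)nx * L + ny] = i + 1;
        }
      }
    }
  }
  return out;
}

// two-compartment cell-cycle surrogate, classic RK4 on a fixed grid
static inline void cc_deriv(double lambda, double alpha, double K,
                            double n1, double n2, double &d1, double &d2) {
  d1 = -lambda * n1 + alpha * (2.0 - (n1 + n2) / K) * n2;
  d2 = lambda * n1 - alpha * n2;
}

// [[Rcpp::export]]
NumericMatrix cpp_solve_cellcycle(double lambda, double alpha, double K,
                                  double N1S0, double N2M0,
                                  NumericVector times, double dt) {
  const int nt = times.size();
  NumericMatrix out(nt, 2);
  double n1 = N1S0, n2 = N2M0, t = times[0];
  out(0, 0) = n1; out(0, 1) = n2;
  for (int j = 1; j < nt; ++j) {
    double span = times[j] - t;
    int m = (int)std::ceil(span / dt - 1e-12);
    if (m < 1) m = 1;
    double h = span / m;
    for (int k = 0; k < m; ++k) {
      double k11, k12, k21, k22, k31, k32, k41, k42;
      cc_deriv(lambda, alpha, K, n1, n2, k11, k12);
      cc_deriv(lambda, alpha, K, n1 + 0.5 * h * k11, n2 + 0.5 * h * k12, k21, k22);
      cc_deriv(lambda, alpha, K, n1 + 0.5 * h * k21, n2 + 0.5 * h * k22, k31, k32);
      cc_deriv(lambda, alpha, K, n1 + h * k31, n2 + h * k32, k41, k42);
      n1 += h / 6.0 * (k11 + 2 * k21 + 2 * k31 + k41);
      n2 += h / 6.0 * (k12 + 2 * k22 + 2 * k32 + k42);
    }
    t = times[j];
    out(j, 0) = n1; out(j, 1) = n2;
  }
  return out;
}

// weighted-RSS objective for the cell-cycle surrogate (hot path: profiling)
// obs, sd: nt x 2 matrices (N_G1S, N_G2M ensemble mean and floored SD)
// [[Rcpp::export]]
double cpp_rss_cellcycle(double lambda, double alpha, double K,
                         double N1S0, double N2M0,
                         NumericVector times, double dt,
                         NumericMatrix obs, NumericMatrix sd_) {
  NumericMatrix sol = cpp_solve_cellcycle(lambda, alpha, K, N1S0, N2M0, times, dt);
  const int nt = times.size();
  double acc = 0.0;
  for (int j = 0; j < nt; ++j) {
    for (int v = 0; v < 2; ++v) {
      double r = (sol(j, v) - obs(j, v)) / sd_(j, v);
      acc += r * r;
    }
  }
  if (!std::isfinite(acc)) return 1e300;
  return acc / (2.0 * nt);
}

// von Bertalanffy growth dN/dt = alpha*N^theta - beta*N, theta = 1 - 1/nu
// [[Rcpp::export]]
NumericVector cpp_solve_vonb(double alpha, double beta, double nu, double N0,
                             NumericVector times, double dt) {
  const double theta = 1.0 - 1.0 / nu;
  const int nt = times.size();
  NumericVector out(nt);
  double n = N0, t = times[0];
  out[0] = n;
  for (int j = 1; j < nt; ++j) {
    double span = times[j] - t;
    int m = (int)std::ceil(span / dt - 1e-12);
    if (m < 1) m = 1;
    double h = span / m;
    for (int k = 0; k < m; ++k) {
      double y0 = n > 0 ? n : 0.0;
      double k1 = alpha * std::pow(y0, theta) - beta * y0;
      double y1 = std::max(n + 0.5 * h * k1, 0.0);
      double k2 = alpha * std::pow(y1, theta) - beta * y1;
      double y2 = std::max(n + 0.5 * h * k2, 0.0);
      double k3 = alpha * std::pow(y2, theta) - beta * y2;
      double y3 = std::max(n + h * k3, 0.0);
      double k4 = alpha * std::pow(y3, theta) - beta * y3;
      n += h / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      if (n < 0) n = 0;
    }
    t = times[j];
    out[j] = n;
  }
  return out;
}
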