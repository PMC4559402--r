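#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Circular (wrap-around) angular distance, [.] = pi - |pi - |a| mod 2pi|.
static inline double circ_dist(double a) {
  double aa = std::fabs(a);
  double m = aa - 2.0 * M_PI * std::floor(aa / (2.0 * M_PI));
  return M_PI - std::fabs(M_PI - m);
}

// One litter's contact field and per-step state update, iterated for
// settle_steps (kinematics frozen) + steps (full dynamics). All pups are
// updated synchronously from the start-of-step state; the contact field
// computed at the start of a step drives both the movement and the
// body-temperature update of that step.
//
// Variants: 0 = endothermic (Tb clamped), 1 = ectothermic (identity transfer),
// 2 = homeothermotaxic (sigmoidal transfer gated by Tp - Tb).
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector y0, NumericVector th0,
                  NumericVector tb0, List cfg) {
  const int p = x0.size();
  const int n = as<int>(cfg["n_thermometers"]);
  const int steps = as<int>(cfg["steps"]);
  const int settle = as<int>(cfg["settle_steps"]);
  const double dt = as<double>(cfg["dt"]);
  const double k1 = as<double>(cfg["k1"]);
  const double k2 = as<double>(cfg["k2"]);
  const double g = as<double>(cfg["g"]);
  const double ta = as<double>(cfg["t_a"]);
  const double tp = as<double>(cfg["t_p"]);
  const double sigma = as<double>(cfg["sigma"]);
  const double v1 = as<double>(cfg["v1"]);
  const double v2 = as<double>(cfg["v2"]);
  const double r = as<double>(cfg["r"]);
  const double arena = as<double>(cfg["arena_radius"]);
  const double scal = as<double>(cfg["contact_scaling"]);
  const double noise_sd = std::sqrt(as<double>(cfg["noise_variance"]));
  const bool boundary = as<bool>(cfg["boundary"]);
  const int variant = as<int>(cfg["variant_code"]);
  const double tb_endo = as<double>(cfg["tb_endo"]);

  // thermometer angular offsets from heading: (k - 1/2) * 2pi / n
  std::vector<double> off(n), cos_off(n), sin_off(n);
  for (int k = 0; k < n; ++k) {
    off[k] = (k + 0.5) * 2.0 * M_PI / n;
    cos_off[k] = std::cos(off[k]);
    sin_off[k] = std::sin(off[k]);
  }

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end()), tb(tb0.begin(), tb0.end());
  std::vector<double> nx(p), ny(p), nth(p), ntb(p);

  NumericMatrix rec_x(steps, p), rec_y(steps, p), rec_th(steps, p),
      rec_tb(steps, p), rec_eta(steps, p);

  std::vector<char> eps(n);
  std::vector<double> chi(n), best_d2(n);
  std::vector<double> dmat(p * p), phimat(p * p);
  std::vector<double> eta(p), tc(p), tl(p), tr(p);

  const int total = settle + steps;
  for (int stp = 0; stp < total; ++stp) {
    const bool kinematics = stp >= settle;

    // pairwise distances and bearings (phi undefined at d = 0: drawn uniform)
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j) {
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d = std::sqrt(dx * dx + dy * dy);
        dmat[i * p + j] = dmat[j * p + i] = d;
        double ph;
        if (d < 1e-12) {
          ph = R::runif(0.0, 2.0 * M_PI);
        } else {
          ph = std::atan2(dy, dx);
        }
        phimat[i * p + j] = ph;
        phimat[j * p + i] = (d < 1e-12) ? ph + M_PI : std::atan2(-dy, -dx);
      }
      dmat[i * p + i] = 0.0;
      phimat[i * p + i] = 0.0;
    }

    // contact field, sensors, motors, kinematics, temperature per pup
    for (int i = 0; i < p; ++i) {
      std::fill(eps.begin(), eps.end(), 1);
      std::fill(chi.begin(), chi.end(), 0.0);
      std::fill(best_d2.begin(), best_d2.end(), R_PosInf);
      const double ci = std::cos(th[i]), si = std::sin(th[i]);

      for (int j = 0; j < p; ++j) {
        if (j == i) continue;
        double d = dmat[i * p + j];
        if (d > 2.0 * r) continue;
        double halfw = std::acos(d / (2.0 * r));
        double phi = phimat[i * p + j];
        for (int k = 0; k < n; ++k) {
          if (circ_dist(th[i] + off[k] - phi) < halfw) {
            eps[k] = 0;
            // thermometer coordinates via angle-sum identity
            double txk = x[i] + r * (ci * cos_off[k] - si * sin_off[k]);
            double tyk = y[i] + r * (si * cos_off[k] + ci * sin_off[k]);
            double ddx = x[j] - txk, ddy = y[j] - tyk;
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best_d2[k]) { // ties keep the lowest pup index
              best_d2[k] = d2;
              chi[k] = tb[j];
            }
          }
        }
      }

      int n_exposed = 0;
      double sum_chi = 0.0;
      double sl = 0.0, sr = 0.0;
      for (int k = 0; k < n; ++k) {
        if (eps[k]) ++n_exposed;
        sum_chi += chi[k];
        double tau = (eps[k] ? ta : 0.0) + scal * chi[k];
        if (noise_sd > 0.0 && kinematics) tau += R::rnorm(0.0, noise_sd);
        if (k < n / 2) sl += tau; else sr += tau;
      }
      eta[i] = (double)n_exposed / n;
      int n_contact = n - n_exposed;
      // mean over contacted thermometers; Tb itself when fully exposed so the
      // exchange term is exactly zero
      tc[i] = (n_contact > 0) ? sum_chi / n_contact : tb[i];
      tl[i] = 2.0 * sl / n;
      tr[i] = 2.0 * sr / n;
    }

    for (int i = 0; i < p; ++i) {
      if (kinematics) {
        double fl, fr;
        if (variant == 2) {
          fl = 1.0 / (1.0 + std::exp(-(tp - tb[i]) * tl[i] / sigma));
          fr = 1.0 / (1.0 + std::exp(-(tp - tb[i]) * tr[i] / sigma));
        } else {
          fl = tl[i];
          fr = tr[i];
        }
        double s = fl + fr;
        double ml, mr;
        if (s > 0.0) { ml = fr / s; mr = fl / s; } else { ml = mr = 0.5; }
        // contralateral drive; turn toward the warmer side (ML > MR turns
        // the heading clockwise)
        nth[i] = th[i] + dt * std::atan(v1 * (mr - ml));

        double fx = v2 * std::cos(th[i]);
        double fy = v2 * std::sin(th[i]);
        double norm = std::sqrt(x[i] * x[i] + y[i] * y[i]);
        if (boundary && norm + r >= arena && norm > 0.0) {
          double beta = arena - norm - r; // <= 0: inward radial push
          fx += beta * x[i] / norm;
          fy += beta * y[i] / norm;
        }
        for (int j = 0; j < p; ++j) {
          if (j == i) continue;
          double d = dmat[i * p + j];
          if (d > 2.0 * r) continue;
          double mag = r - d / 2.0;
          double phi = phimat[i * p + j]; // bearing of j from i
          fx += mag * (-std::cos(phi));
          fy += mag * (-std::sin(phi));
        }
        nx[i] = x[i] + dt * fx;
        ny[i] = y[i] + dt * fy;
      } else {
        nx[i] = x[i];
        ny[i] = y[i];
        nth[i] = th[i];
      }

      if (variant == 0) {
        ntb[i] = tb_endo;
      } else {
        ntb[i] = tb[i] + dt * (-k1 * eta[i] * (tb[i] - ta)
                               - k2 * (1.0 - eta[i]) * (tb[i] - tc[i]) + g);
      }
      if (!std::isfinite(nx[i]) || !std::isfinite(ny[i]) ||
          !std::isfinite(nth[i]) || !std::isfinite(ntb[i])) {
        stop("non-finite state at step %d, pup %d: check dt and parameters",
             stp + 1, i + 1);
      }
    }

    std::swap(x, nx);
    std::swap(y, ny);
    std::swap(th, nth);
    std::swap(tb, ntb);

    if (kinematics) {
      int row = stp - settle;
      for (int i = 0; i < p; ++i) {
        rec_x(row, i) = x[i];
        rec_y(row, i) = y[i];
        rec_th(row, i) = th[i];
        rec_tb(row, i) = tb[i];
        rec_eta(row, i) = eta[i]; // start-of-step field that produced this state
      }
    }
  }

  return List::create(_["x"] = rec_x, _["y"] = rec_y, _["theta"] = rec_th,
                      _["tb"] = rec_tb, _["eta"] = rec_eta);
}

// Connected components of the contact graph (edge iff centre distance <= 2r)
// for each recorded step; returns the component count and the largest
// component size per step.
// [[Rcpp::export]]
List cpp_component_stats(NumericMatrix x, NumericMatrix y, double r) {
  const int steps = x.nrow(), p = x.ncol();
  IntegerVector ncomp(steps), largest(steps);
  std::vector<int> parent(p);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };

  for (int s = 0; s < steps; ++s) {
    for (int i = 0; i < p; ++i) parent[i] = i;
    for (int i = 0; i < p; ++i) {
      for (int j = i + 1; j < p; ++j) {
        double dx = x(s, j) - x(s, i), dy = y(s, j) - y(s, i);
        if (dx * dx + dy * dy <= 4.0 * r * r) {
          int ra = find(i), rb = find(j);
          if (ra != rb) parent[ra] = rb;
        }
      }
    }
    std::vector<int> size(p, 0);
    int nc = 0, big = 0;
    for (int i = 0; i < p; ++i) {
      int rt = find(i);
      if (size[rt] == 0) ++nc;
      if (++size[rt] > big) big = size[rt];
    }
    ncomp[s] = nc;
    largest[s] = big;
  }
  return List::create(_["n_subgroups"] = ncomp, _["largest"] = largest);
}
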