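#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the five-species cascade on the cell graph.
//
// Species per cell: miR171, HAM mRNA, HAM protein, GFP mRNA, GFP protein.
// Only miR171 diffuses; its graph Laplacian uses the (possibly weighted)
// edge list, which realizes the no-flux boundary implicitly because
// boundary cells just have fewer neighbours.
//
// par order: k_mirp, k_mirn, D_mir171, k_hrp, k_hrnm, k_hrnh,
//            k_hpp, k_hpn, k_grp, k_grn, k_gpp, k_gpn
//
// Stops when the max |derivative| over all cells and species drops below
// `tol` (if early_stop), else runs to t_max. Errors on divergence. The
// convergence test runs every `check_every` steps (the reported final
// state always satisfies it when `converged` is true).
// [[Rcpp::export(name = ".euler_kernel")]]
List euler_kernel(NumericVector m, NumericVector par,
                  IntegerVector e1, IntegerVector e2, NumericVector w,
                  double dt, double t_max, double tol, double ceiling,
                  bool early_stop, int record_every, int check_every) {
  const int n = m.size();
  const int ne = e1.size();
  const double k_mirp = par[0], k_mirn = par[1], D = par[2];
  const double k_hrp = par[3], k_hrnm = par[4], k_hrnh = par[5];
  const double k_hpp = par[6], k_hpn = par[7];
  const double k_grp = par[8], k_grn = par[9], k_gpp = par[10], k_gpn = par[11];

  std::vector<double> mir(n, 0.0), hr(n, 0.0), hp(n, 0.0), gr(n, 0.0), gp(n, 0.0);
  std::vector<double> lap(n), dmir(n), dhr(n), dhp(n), dgr(n), dgp(n);

  long max_steps = (long)std::ceil(t_max / dt - 1e-9);
  long step = 0;
  double maxder = 0.0;
  bool converged = false;

  std::vector<double> rec_t;
  List rec_states;

  for (;;) {
    // graph Laplacian of miR171 (weighted, no-flux by construction)
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int k = 0; k < ne; ++k) {
      const int a = e1[k], b = e2[k];
      const double d = w[k] * (mir[b] - mir[a]);
      lap[a] += d;
      lap[b] -= d;
    }
    // all derivatives from the current state; track the max magnitude
    // only on convergence-check steps
    const bool check = (early_stop && step % check_every == 0) ||
                       step >= max_steps;
    if (check) {
      maxder = 0.0;
      for (int i = 0; i < n; ++i) {
        dmir[i] = k_mirp * m[i] - k_mirn * mir[i] + D * lap[i];
        dhr[i]  = k_hrp - k_hrnm * hr[i] * mir[i] - k_hrnh * hr[i];
        dhp[i]  = k_hpp * hr[i] - k_hpn * hp[i];
        dgr[i]  = k_grp * m[i] - k_grn * gr[i];
        dgp[i]  = k_gpp * gr[i] - k_gpn * gp[i];
        double mx = std::fabs(dmir[i]);
        if (std::fabs(dhr[i]) > mx) mx = std::fabs(dhr[i]);
        if (std::fabs(dhp[i]) > mx) mx = std::fabs(dhp[i]);
        if (std::fabs(dgr[i]) > mx) mx = std::fabs(dgr[i]);
        if (std::fabs(dgp[i]) > mx) mx = std::fabs(dgp[i]);
        if (mx > maxder) maxder = mx;
      }
      if (early_stop && maxder < tol) { converged = true; break; }
      if (step >= max_steps) break;
    } else {
      for (int i = 0; i < n; ++i) {
        dmir[i] = k_mirp * m[i] - k_mirn * mir[i] + D * lap[i];
        dhr[i]  = k_hrp - k_hrnm * hr[i] * mir[i] - k_hrnh * hr[i];
        dhp[i]  = k_hpp * hr[i] - k_hpn * hp[i];
        dgr[i]  = k_grp * m[i] - k_grn * gr[i];
        dgp[i]  = k_gpp * gr[i] - k_gpn * gp[i];
      }
    }

    for (int i = 0; i < n; ++i) {
      mir[i] += dt * dmir[i];
      hr[i]  += dt * dhr[i];
      hp[i]  += dt * dhp[i];
      gr[i]  += dt * dgr[i];
      gp[i]  += dt * dgp[i];
    }
    ++step;
    if (step % check_every == 0 || step >= max_steps) {
      bool bad = false;
      for (int i = 0; i < n; ++i) {
        if (!(mir[i] < ceiling) || !(hr[i] < ceiling) || !(hp[i] < ceiling) ||
            !(gr[i] < ceiling) || !(gp[i] < ceiling) ||
            !std::isfinite(mir[i]) || !std::isfinite(hr[i])) { bad = true; break; }
      }
      if (bad) {
        stop("simulation diverged by t = %g h (concentration non-finite or above ceiling); the forward-Euler step is unstable for these parameters", step * dt);
      }
    }
    if (record_every > 0 && step % record_every == 0) {
      NumericMatrix snap(n, 5);
      for (int i = 0; i < n; ++i) {
        snap(i, 0) = mir[i]; snap(i, 1) = hr[i]; snap(i, 2) = hp[i];
        snap(i, 3) = gr[i];  snap(i, 4) = gp[i];
      }
      rec_states.push_back(snap);
      rec_t.push_back(step * dt);
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix state(n, 5);
  for (int i = 0; i < n; ++i) {
    state(i, 0) = mir[i]; state(i, 1) = hr[i]; state(i, 2) = hp[i];
    state(i, 3) = gr[i];  state(i, 4) = gp[i];
  }
  return List::create(_["state"] = state,
                      _["t_final"] = step * dt,
                      _["steps"] = (double)step,
                      _["max_deriv"] = maxder,
                      _["converged"] = converged || (maxder < tol),
                      _["trajectory"] = rec_states,
                      _["trajectory_times"] = rec_t);
}
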