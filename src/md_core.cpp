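// Bead-spring molecular dynamics: velocity-Verlet integration with an
// Andersen thermostat. Forces: harmonic springs 3kT/l^2 between successive
// beads, WCA excluded volume and Gaussian pair attractions between all
// pairs. Uses R's RNG so trajectories are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;

static void compute_forces(const mat& X, const mat& E, double kappa_s,
                           double r0, double sigma, double eps,
                           bool use_pairs, mat& F) {
  const arma::uword N = X.n_rows;
  F.zeros();
  // springs
  for (arma::uword i = 0; i + 1 < N; ++i) {
    for (int d = 0; d < 3; ++d) {
      double b = X(i + 1, d) - X(i, d);
      F(i, d) += kappa_s * b;
      F(i + 1, d) -= kappa_s * b;
    }
  }
  if (!use_pairs) return;
  const double rc2 = std::pow(2.0, 1.0 / 3.0) * sigma * sigma;
  const double inv2r02 = 1.0 / (2.0 * r0 * r0);
  const double invr02 = 1.0 / (r0 * r0);
  for (arma::uword i = 0; i + 1 < N; ++i) {
    for (arma::uword j = i + 1; j < N; ++j) {
      double dx = X(i, 0) - X(j, 0);
      double dy = X(i, 1) - X(j, 1);
      double dz = X(i, 2) - X(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double coef = 0.0;
      double e = E(i, j);
      if (e != 0.0)
        coef += e * invr02 * std::exp(-r2 * inv2r02);
      if (eps > 0 && r2 < rc2) {
        double sr2 = sigma * sigma / r2;
        double sr6 = sr2 * sr2 * sr2;
        coef += 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
      }
      if (coef != 0.0) {
        F(i, 0) += coef * dx; F(j, 0) -= coef * dx;
        F(i, 1) += coef * dy; F(j, 1) -= coef * dy;
        F(i, 2) += coef * dz; F(j, 2) -= coef * dz;
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List md_run_cpp(const arma::mat& X0, const arma::mat& V0,
                      const arma::mat& E, double kappa_s, double r0,
                      double sigma, double eps, double kT, double mass,
                      double dt, int n_steps, int sample_every, double nu) {
  const arma::uword N = X0.n_rows;
  mat X = X0, V = V0;
  bool use_pairs = (arma::abs(E).max() > 0.0) || (eps > 0.0);
  mat F(N, 3);
  compute_forces(X, E, kappa_s, r0, sigma, eps, use_pairs, F);

  const int n_frames = n_steps / sample_every;
  arma::cube pos(N, 3, n_frames), vel(N, 3, n_frames);
  arma::vec times(n_frames);
  int frame = 0;
  const double half = 0.5 * dt / mass;
  const double p_collide = (nu > 0) ? 1.0 - std::exp(-nu * dt) : 0.0;
  const double v_sd = std::sqrt(kT / mass);

  for (int step = 1; step <= n_steps; ++step) {
    V += half * F;
    X += dt * V;
    compute_forces(X, E, kappa_s, r0, sigma, eps, use_pairs, F);
    V += half * F;
    if (p_collide > 0.0) {
      for (arma::uword i = 0; i < N; ++i) {
        if (R::unif_rand() < p_collide) {
          V(i, 0) = R::norm_rand() * v_sd;
          V(i, 1) = R::norm_rand() * v_sd;
          V(i, 2) = R::norm_rand() * v_sd;
        }
      }
    }
    if (!X.is_finite())
      Rcpp::stop("force overflow (bead overlap blow-up): reduce dt");
    if (step % sample_every == 0 && frame < n_frames) {
      pos.slice(frame) = X;
      vel.slice(frame) = V;
      times(frame) = step * dt;
      ++frame;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("positions") = pos, Rcpp::Named("velocities") = vel,
      Rcpp::Named("times") = times, Rcpp::Named("X") = X,
      Rcpp::Named("V") = V);
}

// Contact frequency over frames [first_frame, nF): fraction with r < cutoff.
// [[Rcpp::export]]
arma::mat traj_contact_map_cpp(const arma::cube& pos, double cutoff,
                               int first_frame) {
  const arma::uword N = pos.n_rows, nF = pos.n_slices;
  arma::mat P(N, N, arma::fill::zeros);
  const double c2 = cutoff * cutoff;
  arma::uword used = 0;
  for (arma::uword f = (arma::uword)first_frame; f < nF; ++f) {
    const arma::mat& X = pos.slice(f);
    for (arma::uword i = 0; i + 1 < N; ++i) {
      for (arma::uword j = i + 1; j < N; ++j) {
        double dx = X(i, 0) - X(j, 0);
        double dy = X(i, 1) - X(j, 1);
        double dz = X(i, 2) - X(j, 2);
        if (dx * dx + dy * dy + dz * dz < c2) {
          P(i, j) += 1.0;
          P(j, i) += 1.0;
        }
      }
    }
    ++used;
  }
  if (used > 0) P /= (double)used;
  P.diag().ones();
  return P;
}

// Time-averaged squared distances <(X_m - X_n)^2> over frames.
// [[Rcpp::export]]
arma::mat traj_mean_sq_cpp(const arma::cube& pos, int first_frame) {
  const arma::uword N = pos.n_rows, nF = pos.n_slices;
  arma::mat M(N, N, arma::fill::zeros);
  arma::uword used = 0;
  for (arma::uword f = (arma::uword)first_frame; f < nF; ++f) {
    const arma::mat& X = pos.slice(f);
    for (arma::uword i = 0; i + 1 < N; ++i) {
      for (arma::uword j = i + 1; j < N; ++j) {
        double dx = X(i, 0) - X(j, 0);
        double dy = X(i, 1) - X(j, 1);
        double dz = X(i, 2) - X(j, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        M(i, j) += r2;
        M(j, i) += r2;
      }
    }
    ++used;
  }
  if (used > 0) M /= (double)used;
  return M;
}

// Per-frame root mean squared pairwise distance over a set of bead indices.
// [[Rcpp::export]]
arma::vec traj_rmsd_group_cpp(const arma::cube& pos,
                              const arma::uvec& idx0) {
  const arma::uword nF = pos.n_slices, n = idx0.n_elem;
  arma::vec out(nF);
  for (arma::uword f = 0; f < nF; ++f) {
    const arma::mat& X = pos.slice(f);
    double acc = 0.0;
    arma::uword cnt = 0;
    for (arma::uword a = 0; a + 1 < n; ++a) {
      for (arma::uword b = a + 1; b < n; ++b) {
        arma::uword i = idx0(a), j = idx0(b);
        double dx = X(i, 0) - X(j, 0);
        double dy = X(i, 1) - X(j, 1);
        double dz = X(i, 2) - X(j, 2);
        acc += dx * dx + dy * dy + dz * dz;
        ++cnt;
      }
    }
    out(f) = std::sqrt(acc / (double)cnt);
  }
  return out;
}
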