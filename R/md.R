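#' Self-avoiding random-walk initial configuration
#'
#' Places beads sequentially at bond length `l` in random directions,
#' redrawing a step when the new bead comes within `min_dist` of any
#' previous bead. Used as the starting configuration of MD runs.
#'
#' @param N number of beads.
#' @param l bond length.
#' @param min_dist minimal allowed distance to previously placed beads.
#' @param max_tries redraw attempts per bead before accepting the best so
#'   far.
#' @return an `N x 3` matrix.
#' @export
saw_initial_config <- function(N, l = 1, min_dist = 0.8 * l,
                               max_tries = 200) {
  X <- matrix(0, N, 3)
  if (N == 1) return(X)
  for (i in 2:N) {
    best <- NULL
    best_d <- -Inf
    for (try in seq_len(max_tries)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- X[i - 1, ] + l * u
      d <- sqrt(min(rowSums((X[seq_len(i - 1), , drop = FALSE] -
                               matrix(cand, i - 1, 3, byrow = TRUE))^2)))
      if (d >= min_dist) { best <- cand; break }
      if (d > best_d) { best_d <- d; best <- cand }
    }
    X[i, ] <- best
  }
  X
}

#' Exact equilibrium configuration of the ideal chain
#'
#' Draws bead positions as a random walk with independent Gaussian bond
#' components of variance `l^2/3`: the exact Boltzmann sample of the
#' harmonic chain without pair interactions. The natural starting state for
#' ideal-chain runs, which then need no conformational equilibration.
#'
#' @param N number of beads.
#' @param l bond length.
#' @return an `N x 3` matrix.
#' @export
gaussian_chain_config <- function(N, l = 1) {
  steps <- matrix(rnorm(N * 3, sd = l / sqrt(3)), N, 3)
  steps[1, ] <- 0
  apply(steps, 2, cumsum)
}

#' Molecular dynamics of the copolymer
#'
#' Velocity-Verlet integration of the bead-spring chain with harmonic bonds
#' (stiffness \eqn{3kT/l^2}), WCA excluded volume, Gaussian pair attractions
#' \eqn{E_{mn} e^{-r^2/(2 r_0^2)}}, and an Andersen thermostat that
#' redraws each bead's velocity from the Maxwell-Boltzmann distribution at
#' collision rate `thermostat_nu`. Time is in units of
#' \eqn{\tau = l\sqrt{m/kT}}. Trajectories are bitwise reproducible for a
#' fixed `seed`.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param n_steps number of integration steps (>= 1).
#' @param dt timestep (default 0.005 tau).
#' @param thermostat_nu Andersen collision frequency (0 = NVE).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param sample_every store every this-many steps.
#' @param X0 optional `N x 3` starting configuration; defaults to a
#'   self-avoiding random walk.
#' @param mass bead mass (default 1).
#' @return an object of class `md_trajectory`: `list(times, positions,
#'   velocities, dt, seed, thermostat_nu, sample_every, states, model)`
#'   with `positions` and `velocities` as `N x 3 x n_frames` arrays.
#' @export
simulate_md <- function(seq, model, n_steps, dt = 0.005, thermostat_nu = 1,
                        seed = NULL, sample_every = 100, X0 = NULL,
                        mass = 1) {
  stopifnot(inherits(seq, "epi_sequence"), inherits(model, "interaction_model"),
            n_steps >= 1, dt > 0, sample_every >= 1, thermostat_nu >= 0)
  if (!is.null(seed)) set.seed(seed)
  N <- length(seq)
  cp <- model$chain
  if (is.null(X0)) X0 <- saw_initial_config(N, cp$l, 0.8 * cp$sigma)
  V0 <- matrix(rnorm(N * 3, sd = sqrt(cp$kT / mass)), N, 3)
  E <- interaction_matrix(seq, model)
  res <- md_run_cpp(X0, V0, E, 3 * cp$kT / cp$l^2, model$r0, cp$sigma,
                    cp$epsilon, cp$kT, mass, dt, as.integer(n_steps),
                    as.integer(sample_every), thermostat_nu)
  structure(list(times = as.numeric(res$times),
                 positions = res$positions,
                 velocities = res$velocities,
                 dt = dt, seed = seed, thermostat_nu = thermostat_nu,
                 sample_every = sample_every, mass = mass,
                 states = seq$states, model = model),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf(
    "md_trajectory: N = %d beads, %d frames to t = %.4g tau (dt = %g, nu = %g)\n",
    dim(x$positions)[1], length(x$times),
    if (length(x$times)) max(x$times) else 0, x$dt, x$thermostat_nu))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[3]

# First frame index (1-based) strictly after the burn-in time.
first_frame_after <- function(traj, burn_in) {
  idx <- which(traj$times > burn_in)
  if (length(idx) == 0L) stop("no frames after burn_in")
  idx[1]
}

#' Equilibration time from the end-to-end autocorrelation
#'
#' Estimates the burn-in as the time at which the autocorrelation of the
#' end-to-end vector first decays below 1/e.
#'
#' @param traj an `md_trajectory`.
#' @return a time (same units as `traj$times`).
#' @export
estimate_burn_in <- function(traj) {
  nF <- n_frames(traj)
  if (nF < 10) return(0)
  N <- dim(traj$positions)[1]
  e2e <- t(vapply(seq_len(nF), function(f)
    traj$positions[N, , f] - traj$positions[1, , f], numeric(3)))
  e2e <- sweep(e2e, 2, colMeans(e2e))
  lag_max <- min(nF - 1, 2000)
  ac <- rowSums(vapply(1:3, function(d)
    acf(e2e[, d], lag.max = lag_max, plot = FALSE,
        demean = FALSE)$acf[, 1, 1] * var(e2e[, d]), numeric(lag_max + 1)))
  ac <- ac / ac[1]
  below <- which(ac < exp(-1))
  if (length(below) == 0L) return(traj$times[nF] / 2)
  traj$times[min(below)]
}

#' Contact map from an MD trajectory
#'
#' \eqn{P_{mn}} = fraction of post-burn-in frames in which beads `m` and `n`
#' lie within `cutoff`; the diagonal is set to 1.
#'
#' @param traj an `md_trajectory`.
#' @param cutoff contact distance (default 1.5 l).
#' @param burn_in time discarded as equilibration; `NULL` estimates it with
#'   [estimate_burn_in()].
#' @param bin_size genomic bin size recorded in the map.
#' @return a [contact_map()].
#' @export
contact_map_from_trajectory <- function(traj, cutoff = 1.5, burn_in = 0,
                                        bin_size = 10000) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0)
  if (is.null(burn_in)) burn_in <- estimate_burn_in(traj)
  f0 <- first_frame_after(traj, burn_in)
  P <- traj_contact_map_cpp(traj$positions, cutoff, f0 - 1L)
  contact_map(P, A = NA_real_, bin_size = bin_size)
}

#' Time-averaged squared distances from an MD trajectory
#'
#' The MD estimate of \eqn{\langle (X_m - X_n)^2 \rangle} (note: this is
#' `3 D_mn` in the convention of the self-consistent solver, whose `D` is a
#' per-component variance).
#'
#' @inheritParams contact_map_from_trajectory
#' @return an `N x N` matrix.
#' @export
mean_sq_distances <- function(traj, burn_in = 0) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(burn_in)) burn_in <- estimate_burn_in(traj)
  f0 <- first_frame_after(traj, burn_in)
  traj_mean_sq_cpp(traj$positions, f0 - 1L)
}

#' Root mean squared distance between same-state monomers
#'
#' Per frame, the root mean squared pairwise distance over all monomer pairs
#' of one chromatin state; the observable whose joint dynamics for two
#' states reveals jumps between metastable families.
#'
#' @param traj an `md_trajectory`.
#' @param seq the [epi_sequence()] the trajectory was run with.
#' @param type_label state label.
#' @param window optional sliding-window width (frames) for smoothing.
#' @return numeric vector, one value per frame.
#' @export
rmsd_same_type <- function(traj, seq, type_label, window = 1) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(seq, "epi_sequence"))
  idx <- which(seq$states == type_label)
  if (length(idx) < 2)
    stop("fewer than 2 monomers of type ", type_label)
  out <- as.numeric(traj_rmsd_group_cpp(traj$positions, idx - 1L))
  if (window > 1) {
    k <- rep(1 / window, window)
    out <- as.numeric(stats::filter(out, k, sides = 2))
  }
  out
}

#' Distance between the centres of mass of two domains
#'
#' @param traj an `md_trajectory`.
#' @param seq the [epi_sequence()] the trajectory was run with.
#' @param domain_a,domain_b disjoint, non-empty monomer index ranges.
#' @return numeric vector, one distance per frame.
#' @export
domain_com_distance <- function(traj, seq, domain_a, domain_b) {
  stopifnot(inherits(traj, "md_trajectory"))
  N <- dim(traj$positions)[1]
  domain_a <- as.integer(domain_a)
  domain_b <- as.integer(domain_b)
  if (length(domain_a) == 0L || length(domain_b) == 0L)
    stop("domains must be non-empty")
  if (any(c(domain_a, domain_b) < 1) || any(c(domain_a, domain_b) > N))
    stop("domain indices outside the chain")
  if (length(intersect(domain_a, domain_b)) > 0L)
    stop("domains must be disjoint")
  nF <- n_frames(traj)
  vapply(seq_len(nF), function(f) {
    X <- traj$positions[, , f]
    sqrt(sum((colMeans(X[domain_a, , drop = FALSE]) -
                colMeans(X[domain_b, , drop = FALSE]))^2))
  }, numeric(1))
}

#' Export a trajectory in XYZ format
#'
#' One block per frame; the element column carries the chromatin-state
#' label. A sidecar metadata file records dt, seed, thermostat frequency and
#' the interaction parameters.
#'
#' @param traj an `md_trajectory`.
#' @param path output XYZ path.
#' @param metadata_path sidecar path (default `paste0(path, ".meta")`).
#' @return the path, invisibly.
#' @export
write_xyz <- function(traj, path, metadata_path = paste0(path, ".meta")) {
  stopifnot(inherits(traj, "md_trajectory"))
  N <- dim(traj$positions)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(N),
                 sprintf("t = %.6g", traj$times[f])), con)
    X <- traj$positions[, , f]
    writeLines(sprintf("%s %.8g %.8g %.8g", traj$states,
                       X[, 1], X[, 2], X[, 3]), con)
  }
  md <- traj$model
  meta <- c(sprintf("dt = %g", traj$dt),
            sprintf("seed = %s",
                    if (is.null(traj$seed)) "NA" else traj$seed),
            sprintf("thermostat_nu = %g", traj$thermostat_nu),
            sprintf("sample_every = %d", traj$sample_every),
            sprintf("mass = %g", traj$mass),
            sprintf("U_ns = %g", md$U_ns),
            sprintf("U_s = %s", if (is.matrix(md$U_s)) "matrix" else md$U_s),
            sprintf("r0 = %g", md$r0))
  writeLines(meta, metadata_path)
  invisible(path)
}

#' Kinetic energy per frame
#'
#' @param traj an `md_trajectory`.
#' @return numeric vector of kinetic energies (kT units).
#' @export
kinetic_energy <- function(traj) {
  vapply(seq_len(n_frames(traj)), function(f)
    0.5 * traj$mass * sum(traj$velocities[, , f]^2), numeric(1))
}
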