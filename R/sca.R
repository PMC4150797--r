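#' Parameters of the self-consistent distance dynamics
#'
#' Controls integration of the coupled ODEs for the mean squared distance
#' matrix `D`. Time is measured in units of \eqn{\xi l^2 / kT}. Stationarity
#' is declared on the dimensionless residual
#' \eqn{\max_{mn} |\xi\, dD_{mn}/dt| / (4 kT) <} `steady_tol`.
#'
#' @param xi friction coefficient (> 0; sets the time unit).
#' @param rtol,atol relative and absolute tolerances of the embedded
#'   Dormand-Prince 5(4) integrator. The stationarity residual cannot fall
#'   below a floor of about `2.5 * rtol` (each accepted step perturbs `D`
#'   by its local error), so `rtol` defaults one decade below `steady_tol`.
#' @param steady_tol stationarity threshold on the scaled residual.
#' @param t_max integration horizon; runs hitting it without reaching
#'   `steady_tol` are reported as non-converged.
#' @param noise_scale multiplier on the `4 kT` noise term. The discrete
#'   Rouse profile is an exact fixed point at the default 1 (see the methods
#'   vignette); the knob exists to probe that consistency.
#' @param max_D divergence bound: any entry of `D` exceeding it flags the
#'   run as diverged.
#' @param fp_tol relative Frobenius distance below which two stationary
#'   solutions are considered the same fixed point.
#' @param max_steps hard cap on accepted integrator steps.
#' @return an object of class `sca_params`.
#' @export
sca_params <- function(xi = 1, rtol = 1e-7, atol = 1e-9, steady_tol = 1e-6,
                       t_max = 5000, noise_scale = 1, max_D = 1e8,
                       fp_tol = 1e-2, max_steps = 2e6) {
  stopifnot(xi > 0, rtol > 0, atol > 0, steady_tol > 0, t_max >= 0,
            noise_scale > 0, max_D > 0, fp_tol > 0)
  structure(list(xi = xi, rtol = rtol, atol = atol, steady_tol = steady_tol,
                 t_max = t_max, noise_scale = noise_scale, max_D = max_D,
                 fp_tol = fp_tol, max_steps = as.integer(max_steps)),
            class = "sca_params")
}

# Validate a mean squared distance matrix.
check_dist_matrix <- function(D, N = NULL) {
  D <- as.matrix(D)
  if (!is.null(N) && !all(dim(D) == N))
    stop("distance matrix does not match the sequence length")
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("non-finite entries in distance matrix")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D))))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distance matrix entries must be non-negative")
  D
}

#' Ideal-chain (Rouse) distance profile
#'
#' \eqn{D_{mn} = |m - n|\, l^2 / 3}: the exact equilibrium mean squared
#' distance (per component) of the discrete Gaussian chain.
#'
#' @param N number of monomers.
#' @param l bond length.
#' @return an `N x N` matrix.
#' @export
ideal_chain_profile <- function(N, l = 1) {
  i <- seq_len(N)
  abs(outer(i, i, "-")) * l^2 / 3
}

# Gram matrix of a distance matrix by double centering: G = -C D C / 2.
gram_from_dist <- function(D) {
  N <- nrow(D)
  Cc <- diag(N) - matrix(1 / N, N, N)
  -0.5 * Cc %*% D %*% Cc
}

#' Check that a distance matrix admits a Gaussian embedding
#'
#' `D` derives from a covariance matrix iff the double-centred Gram matrix
#' \eqn{-\tfrac12 C D C} is positive semidefinite.
#'
#' @param D distance matrix.
#' @param tol relative eigenvalue tolerance.
#' @return logical.
#' @export
is_embeddable <- function(D, tol = 1e-8) {
  ev <- eigen(gram_from_dist(as.matrix(D)), symmetric = TRUE,
              only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1e-300)
}

#' Project a distance matrix to the nearest valid Gaussian embedding
#'
#' Clips negative eigenvalues of the double-centred Gram matrix to zero and
#' rebuilds `D` from the repaired Gram matrix.
#'
#' @param D distance matrix.
#' @return a symmetric, zero-diagonal, embeddable distance matrix.
#' @export
project_embeddable <- function(D) {
  D <- as.matrix(D)
  e <- eigen(gram_from_dist(D), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  G <- e$vectors %*% (lam * t(e$vectors))
  g <- diag(G)
  out <- outer(g, g, "+") - 2 * G
  out <- (out + t(out)) / 2
  out[out < 0] <- 0
  diag(out) <- 0
  out
}

#' Coil (ideal chain) initial condition
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @return the Rouse profile \eqn{D_{mn} = |m-n| l^2/3}.
#' @export
init_coil <- function(seq, model = interaction_model()) {
  ideal_chain_profile(length(seq), model$chain$l)
}

#' Globule initial condition
#'
#' The coil profile capped at a plateau variance, mimicking a collapsed
#' compact chain whose long-range distances saturate. The default plateau
#' \eqn{N^{2/3} l^2 / 3} is the geometric scale of a dense globule of `N`
#' monomers.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param plateau variance scale (> 0) of long-range entries.
#' @return a distance matrix (projected to a valid embedding).
#' @export
init_globule <- function(seq, model = interaction_model(), plateau = NULL) {
  N <- length(seq)
  l <- model$chain$l
  if (is.null(plateau)) plateau <- N^(2 / 3) * l^2 / 3
  if (plateau <= 0) stop("plateau must be positive")
  D <- pmin(ideal_chain_profile(N, l), plateau)
  if (is_embeddable(D)) D else project_embeddable(D)
}

#' Microphase-separated initial condition
#'
#' Same-state pairs get a small variance `intra`, cross-state pairs a large
#' variance `inter`; short-range chain structure is preserved by taking the
#' elementwise minimum with the coil profile, and the result is projected to
#' a valid Gaussian embedding. Defaults scale `intra` with the size of a
#' type's monomer pool and set `inter` to the coil long-range scale.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param intra variance for same-state pairs (0 < intra < inter).
#' @param inter variance for cross-state pairs.
#' @return a distance matrix.
#' @export
init_mps <- function(seq, model = interaction_model(), intra = NULL,
                     inter = NULL) {
  N <- length(seq)
  l <- model$chain$l
  n_types <- length(unique(seq$states))
  if (is.null(intra)) intra <- (N / n_types)^(2 / 3) * l^2 / 3
  if (is.null(inter)) inter <- N * l^2 / 6
  if (!(intra > 0) || intra >= inter)
    stop("need 0 < intra < inter")
  same <- same_state_indicator(seq)
  B <- ifelse(same == 1, intra, inter)
  D <- pmin(ideal_chain_profile(N, l), B)
  diag(D) <- 0
  project_embeddable(D)
}

#' Initial condition from a contact map
#'
#' Inverts the Gaussian contact formula \eqn{P_{mn} = A D_{mn}^{-3/2}} to
#' \eqn{D_{mn} = (A / P_{mn})^{2/3}}. Entries where `P` is zero or missing
#' are imputed from the coil profile; the result is projected to a valid
#' Gaussian embedding. This builds "experimental-like" starting states from
#' Hi-C-style maps.
#'
#' @param P a [contact_map()] or plain matrix of contact frequencies.
#' @param model an [interaction_model()] (for the coil imputation scale).
#' @param A proportionality constant; defaults to the map's recorded `A`,
#'   else to the value that makes the mean nearest-neighbour distance equal
#'   to the coil bond variance.
#' @return a distance matrix.
#' @export
init_from_contact_map <- function(P, model = interaction_model(), A = NULL) {
  Pm <- if (inherits(P, "contact_map")) P$P else as.matrix(P)
  if (all(Pm == 0)) stop("all-zero contact map")
  if (is.null(A) && inherits(P, "contact_map") && is.finite(P$A)) A <- P$A
  l <- model$chain$l
  N <- nrow(Pm)
  nn <- cbind(seq_len(N - 1), 2:N)
  if (is.null(A)) {
    # choose A so the mean nearest-neighbour D is the bond variance l^2/3
    p_nn <- Pm[nn]
    p_nn <- p_nn[p_nn > 0]
    if (length(p_nn) == 0L) stop("no positive nearest-neighbour contacts")
    A <- mean(p_nn) * (l^2 / 3)^1.5
  }
  D <- matrix(NA_real_, N, N)
  pos <- Pm > 0
  D[pos] <- (A / Pm[pos])^(2 / 3)
  coil <- ideal_chain_profile(N, l)
  D[!pos] <- coil[!pos]
  diag(D) <- 0
  D <- (D + t(D)) / 2
  project_embeddable(D)
}

# Pack solver inputs for the compiled core.
sca_core_args <- function(seq, model, params) {
  cp <- model$chain
  list(E = interaction_matrix(seq, model),
       kappa = 3 * cp$kT / cp$l^2,
       kT = cp$kT, xi = params$xi, r0 = model$r0,
       Uhc0 = cp$U_hc0, rhc = cp$r_hc, noise = params$noise_scale)
}

#' Right-hand side of the self-consistent distance dynamics
#'
#' \deqn{\xi \frac{dD_{mn}}{dt} = 4 kT -
#'   \sum_k (\langle J_{mk}\rangle - \langle J_{nk}\rangle)(D_{mk} - D_{nk})}
#' for \eqn{m \neq n}; the diagonal is identically zero. `<J>` is the mean
#' Hessian from [mean_hessian()] evaluated at the current `D`. This is the
#' reference R implementation; [evolve()] uses an equivalent compiled path.
#'
#' @param D distance matrix.
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param params an [sca_params()].
#' @return the matrix `dD/dt` (symmetric, zero diagonal).
#' @export
sca_rhs <- function(D, seq, model, params = sca_params()) {
  D <- check_dist_matrix(D, length(seq))
  J <- mean_hessian(D, seq, model)
  s <- rowSums(J * D)
  M <- J %*% D
  kT <- model$chain$kT
  R <- params$noise_scale * 4 * kT - (outer(s, s, "+") - M - t(M))
  diag(R) <- 0
  R <- (R + t(R)) / 2
  R / params$xi
}

#' Evolve the distance matrix to stationarity
#'
#' Integrates the self-consistent distance dynamics with an adaptive
#' embedded Dormand-Prince 5(4) scheme until the scaled residual drops below
#' `params$steady_tol`, the horizon `t_max` is reached, or the run diverges.
#' Snapshots of `D` at requested times support time-resolved contact maps.
#'
#' @param D0 initial distance matrix (symmetric, zero diagonal).
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param params an [sca_params()].
#' @param snapshot_times optional increasing vector of times at which to
#'   record `D`.
#' @param absorb optional list of known stationary distance matrices: a run
#'   entering the fixed-point clustering ball of one of them (relative
#'   Frobenius distance below `absorb_tol`) is stopped early and reported as
#'   converged to it (`report$absorbed` gives its index, 0 otherwise).
#' @param absorb_tol radius of the absorption ball (default
#'   `params$fp_tol / 2`).
#' @return an object of class `sca_result`: `list(D, report, snapshots,
#'   snapshot_times)` where `report` carries `converged`, `diverged`,
#'   `t_end`, `residual` and `n_steps`.
#' @export
evolve <- function(D0, seq, model, params = sca_params(),
                   snapshot_times = NULL, absorb = NULL,
                   absorb_tol = NULL) {
  D0 <- check_dist_matrix(D0, length(seq))
  if (is.null(snapshot_times)) snapshot_times <- numeric(0)
  if (is.unsorted(snapshot_times, strictly = TRUE) && length(snapshot_times) > 1)
    stop("snapshot_times must be strictly increasing")
  if (is.null(absorb)) absorb <- list()
  if (is.null(absorb_tol)) absorb_tol <- params$fp_tol / 2
  a <- sca_core_args(seq, model, params)
  res <- sca_evolve_cpp(D0, a$E, a$kappa, a$kT, a$xi, a$r0, a$Uhc0, a$rhc,
                        a$noise, params$rtol, params$atol, params$steady_tol,
                        params$t_max, params$max_D,
                        as.numeric(snapshot_times), params$max_steps,
                        absorb, absorb_tol)
  structure(list(
    D = res$D,
    report = list(converged = res$converged, diverged = res$diverged,
                  t_end = res$t_end, residual = res$residual,
                  n_steps = res$n_steps, n_rejected = res$n_rejected,
                  absorbed = res$absorbed),
    snapshots = res$snapshots,
    snapshot_times = snapshot_times[seq_along(res$snapshots)]),
    class = "sca_result")
}

#' @export
print.sca_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "sca_result: N = %d, %s at t = %.4g (residual %.3g, %d steps)\n",
    nrow(x$D),
    if (r$diverged) "DIVERGED" else if (r$converged) "converged" else
      "NOT converged", r$t_end, r$residual, r$n_steps))
  invisible(x)
}

#' Canonical set of initial conditions
#'
#' The coil, globule and microphase-separated starting states used by
#' [find_fixed_points()] and the phase classifier.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @return named list of distance matrices.
#' @export
canonical_inits <- function(seq, model) {
  out <- list(coil = init_coil(seq, model),
              globule = init_globule(seq, model))
  if (length(unique(seq$states)) >= 2)
    out$mps <- init_mps(seq, model)
  out
}

#' Find the distinct stationary solutions reachable from a set of starts
#'
#' Runs [evolve()] from each initial condition and clusters the converged
#' stationary matrices by relative Frobenius distance (`params$fp_tol`).
#' Multiple clusters signal multistability: several metastable chain
#' organisations coexist at one parameter set, selected by the start.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param params an [sca_params()].
#' @param inits named list of initial distance matrices; defaults to
#'   [canonical_inits()].
#' @return `list(fixed_points, multiplicity, assignment, reports,
#'   n_unconverged)`; `assignment` maps each converged init to its cluster.
#' @export
find_fixed_points <- function(seq, model, params = sca_params(),
                              inits = NULL) {
  if (is.null(inits)) inits <- canonical_inits(seq, model)
  if (length(inits) < 1L) stop("need at least one initial condition")
  if (is.null(names(inits)))
    names(inits) <- paste0("init", seq_along(inits))
  reps <- list()
  assignment <- rep(NA_integer_, length(inits))
  names(assignment) <- names(inits)
  reports <- vector("list", length(inits))
  names(reports) <- names(inits)
  n_unconverged <- 0L
  for (i in seq_along(inits)) {
    # runs are absorbed early once they enter the clustering ball of an
    # already-found fixed point
    fit <- evolve(inits[[i]], seq, model, params, absorb = reps,
                  absorb_tol = params$fp_tol / 2)
    reports[[i]] <- fit$report
    if (!fit$report$converged || fit$report$diverged) {
      n_unconverged <- n_unconverged + 1L
      next
    }
    if (fit$report$absorbed > 0) {
      assignment[i] <- fit$report$absorbed
      next
    }
    Di <- fit$D
    placed <- FALSE
    for (k in seq_along(reps)) {
      rel <- norm(Di - reps[[k]], "F") / max(norm(reps[[k]], "F"), 1e-300)
      if (rel < params$fp_tol) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- Di
      assignment[i] <- length(reps)
    }
  }
  list(fixed_points = reps,
       multiplicity = length(reps),
       assignment = assignment,
       reports = reports,
       n_unconverged = n_unconverged)
}

#' Self-avoiding coil state of the non-interacting chain
#'
#' The stationary distance matrix of the model with `U_ns = U_s = 0` (chain
#' connectivity plus excluded volume only), evolved from the ideal-chain
#' profile. This is the physically equilibrated coil of the model and the
#' recommended "coil" member of the canonical init set for phase scans:
#' unlike the ideal profile it already carries the excluded-volume swelling,
#' so weak-interaction nodes start close to their fixed point.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()] supplying `r0` and chain
#'   parameters (its `U_ns`/`U_s` are ignored).
#' @param params an [sca_params()].
#' @return a distance matrix.
#' @export
coil_state <- function(seq, model = interaction_model(),
                       params = sca_params()) {
  m0 <- interaction_model(U_ns = 0, U_s = 0, r0 = model$r0,
                          chain = model$chain)
  fit <- evolve(init_coil(seq, m0), seq, m0, params)
  fit$D
}

#' Write / read a distance matrix
#'
#' Dense whitespace-delimited text with a one-line header recording `N`,
#' `bin_size` and `l`; or an RDS container keyed by `D`, `times`,
#' `snapshots` when `format = "rds"`.
#'
#' @param D distance matrix (or an `sca_result` for the RDS container).
#' @param path file path.
#' @param bin_size,l metadata recorded in the header.
#' @param format `"text"` or `"rds"`.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(D, path, bin_size = 10000, l = 1,
                                  format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    obj <- if (inherits(D, "sca_result"))
      list(D = D$D, times = D$snapshot_times, snapshots = D$snapshots)
    else list(D = as.matrix(D), times = numeric(0), snapshots = list())
    saveRDS(obj, path)
    return(invisible(path))
  }
  Dm <- if (inherits(D, "sca_result")) D$D else as.matrix(D)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epifold distance-matrix N=%d bin_size=%g l=%g",
                     nrow(Dm), bin_size, l), con)
  write.table(Dm, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  header <- readLines(path, n = 1)
  if (!grepl("^#", header)) stop("missing distance-matrix header line")
  D <- as.matrix(read.table(path, skip = 1))
  dimnames(D) <- NULL
  attr(D, "bin_size") <-
    as.numeric(sub(".*bin_size=([0-9.eE+-]+).*", "\\1", header))
  attr(D, "l") <- as.numeric(sub(".*l=([0-9.eE+-]+).*", "\\1", header))
  D
}
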