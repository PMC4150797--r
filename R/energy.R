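#' Chain mechanical parameters
#'
#' Parameters of the bead-spring backbone and of excluded volume, in reduced
#' simulation units: `l` (bond length of the pure Gaussian chain) is the
#' length unit and `kT` the energy unit. Excluded volume enters twice, in two
#' forms suited to the two solvers:
#' * molecular dynamics uses a Weeks-Chandler-Andersen (WCA) potential, the
#'   purely repulsive Lennard-Jones truncated and shifted at
#'   \eqn{2^{1/6}\sigma}, with range `sigma` and amplitude `epsilon`;
#' * the Gaussian self-consistent solver uses a repulsive Gaussian surrogate
#'   \eqn{+U_{hc0}\exp(-r^2/(2 r_{hc}^2))}, which averages in closed form
#'   over a Gaussian chain ensemble.
#'
#' @param l bond length (> 0, default 1).
#' @param kT thermal energy (> 0, default 1).
#' @param sigma WCA range (> 0, default `l`).
#' @param epsilon WCA amplitude (>= 0, default `kT`).
#' @param U_hc0 amplitude of the repulsive Gaussian surrogate (>= 0,
#'   default `3 * kT`).
#' @param r_hc range of the repulsive Gaussian surrogate (> 0,
#'   default `sigma`).
#' @return an object of class `chain_params`.
#' @export
chain_params <- function(l = 1, kT = 1, sigma = l, epsilon = kT,
                         U_hc0 = 3 * kT, r_hc = sigma) {
  stopifnot(l > 0, kT > 0, sigma > 0, epsilon >= 0, U_hc0 >= 0, r_hc > 0)
  structure(list(l = l, kT = kT, sigma = sigma, epsilon = epsilon,
                 U_hc0 = U_hc0, r_hc = r_hc),
            class = "chain_params")
}

#' Interaction model of the copolymer
#'
#' Holds the two control parameters of the model: the non-specific attraction
#' `U_ns` acting between every monomer pair (effective compaction, e.g. due
#' to nuclear confinement) and the specific attraction `U_s` acting only
#' between monomers of the same chromatin state, plus the range `r0` of the
#' Gaussian pair potential and the chain parameters. The pairwise interaction
#' strength is \eqn{E_{mn} = U_{ns} + U_s[\mathrm{state}_m, \mathrm{state}_n]}.
#'
#' `U_s` may be a single number (uniform same-state attraction: diagonal of
#' the per-type-pair matrix, zero off-diagonal) or a symmetric matrix with
#' state labels as dimnames, allowing e.g. Polycomb-Polycomb interactions
#' stronger than black-black ones.
#'
#' @param U_ns non-specific pair strength (attractive when negative), in kT.
#' @param U_s uniform specific strength (scalar) or symmetric per-type-pair
#'   matrix with labelled dimnames, in kT.
#' @param r0 interaction range of the Gaussian pair potential (> 0), in
#'   units of `l`.
#' @param chain a [chain_params()].
#' @return an object of class `interaction_model`.
#' @export
interaction_model <- function(U_ns = 0, U_s = 0, r0 = 1.5,
                              chain = chain_params()) {
  stopifnot(r0 > 0, inherits(chain, "chain_params"))
  if (is.matrix(U_s)) {
    if (is.null(rownames(U_s)) || !identical(rownames(U_s), colnames(U_s)))
      stop("a U_s matrix needs identical row and column state labels")
    if (!isSymmetric(unname(U_s)))
      stop("U_s matrix must be symmetric")
  } else {
    stopifnot(is.numeric(U_s), length(U_s) == 1L)
  }
  structure(list(U_ns = U_ns, U_s = U_s, r0 = r0, chain = chain),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  us <- if (is.matrix(x$U_s)) "per-type-pair matrix" else sprintf("%g", x$U_s)
  cat(sprintf("interaction_model: U_ns = %g kT, U_s = %s, r0 = %g l\n",
              x$U_ns, us, x$r0))
  invisible(x)
}

# Per-type-pair specific-strength matrix resolved against an alphabet.
us_matrix_for <- function(model, alphabet) {
  if (is.matrix(model$U_s)) {
    missing <- setdiff(alphabet, rownames(model$U_s))
    if (length(missing) > 0L)
      stop("state label(s) absent from U_s matrix: ",
           paste(missing, collapse = ", "))
    model$U_s[alphabet, alphabet, drop = FALSE]
  } else {
    m <- diag(model$U_s, length(alphabet))
    dimnames(m) <- list(alphabet, alphabet)
    m
  }
}

#' Pairwise interaction-strength matrix
#'
#' \eqn{E_{mn} = U_{ns} + U_s[\mathrm{state}_m, \mathrm{state}_n]}, the
#' amplitude of the Gaussian pair potential between monomers `m` and `n`.
#' The diagonal (self-interaction) is unused and set to 0.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @return a symmetric `N x N` matrix.
#' @export
interaction_matrix <- function(seq, model) {
  stopifnot(inherits(seq, "epi_sequence"), inherits(model, "interaction_model"))
  us <- us_matrix_for(model, seq$alphabet)
  E <- model$U_ns + us[seq$states, seq$states, drop = FALSE]
  dimnames(E) <- NULL
  diag(E) <- 0
  E
}

# WCA pair energy for squared distances r2 (vectorised).
wca_energy <- function(r2, sigma, epsilon) {
  if (epsilon == 0) return(rep(0, length(r2)))
  rc2 <- 2^(1 / 3) * sigma^2
  out <- numeric(length(r2))
  in_core <- r2 < rc2
  if (any(in_core)) {
    sr6 <- (sigma^2 / r2[in_core])^3
    out[in_core] <- 4 * epsilon * (sr6^2 - sr6) + epsilon
  }
  out
}

#' Total potential energy of a chain configuration
#'
#' \eqn{H = H_\mathrm{chain} + H_\mathrm{inter}}: harmonic springs with
#' prefactor \eqn{3 kT / (2 l^2)} between successive beads, WCA excluded
#' volume between all pairs, and the Gaussian attraction
#' \eqn{E_{mn}\exp(-r_{mn}^2/(2 r_0^2))}.
#'
#' @param positions `N x 3` matrix of bead coordinates.
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @return the potential energy (scalar, in kT units).
#' @export
total_energy <- function(positions, seq, model) {
  stopifnot(inherits(seq, "epi_sequence"), inherits(model, "interaction_model"))
  X <- as.matrix(positions)
  N <- length(seq)
  if (!is.numeric(X) || ncol(X) != 3L || nrow(X) != N)
    stop("positions must be an N x 3 numeric matrix matching the sequence")
  if (any(!is.finite(X))) stop("non-finite coordinates")
  if (N < 2L) stop("need at least 2 monomers")
  cp <- model$chain
  bond2 <- rowSums((X[-1, , drop = FALSE] - X[-N, , drop = FALSE])^2)
  e_spring <- 3 * cp$kT / (2 * cp$l^2) * sum(bond2)
  idx <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  d2 <- rowSums((X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE])^2)
  E <- interaction_matrix(seq, model)
  e_pair <- sum(E[idx] * exp(-d2 / (2 * model$r0^2)))
  e_hc <- sum(wca_energy(d2, cp$sigma, cp$epsilon))
  e_spring + e_pair + e_hc
}

#' Gaussian-ensemble averages of the pair potential and its Hessian
#'
#' For a pair potential \eqn{u(r) = E\,e^{-r^2/(2a^2)}} and a separation
#' vector drawn from a centred isotropic 3-D Gaussian with per-component
#' variance `D` (so \eqn{\langle r^2\rangle = 3D}), the exact averages are
#' \deqn{\langle u \rangle = E\,\alpha^{3/2}, \qquad
#'   \tfrac{1}{3}\langle \mathrm{tr}\,\nabla^2 u \rangle =
#'   -\frac{E}{a^2}\,\alpha^{5/2}, \qquad \alpha = \frac{a^2}{a^2 + D}.}
#' The second quantity is the isotropic (trace/3) reduction of the averaged
#' Hessian used to assemble the mean Hessian of the Hamiltonian.
#'
#' @param E_pair pair amplitude (energy).
#' @param a interaction range (> 0).
#' @param D per-component separation variance (>= 0); vectorised.
#' @return `list(potential =, hessian =)`, each the same shape as `D`.
#' @export
gaussian_pair_averages <- function(E_pair, a, D) {
  if (a <= 0) stop("range a must be positive")
  if (any(D < 0)) stop("variance D must be non-negative")
  alpha <- a^2 / (a^2 + D)
  list(potential = E_pair * alpha^1.5,
       hessian = -E_pair / a^2 * alpha^2.5)
}

# Path-graph Laplacian of an N-bead chain.
chain_laplacian <- function(N) {
  L <- diag(c(1, rep(2, max(N - 2, 0)), 1)[seq_len(N)])
  if (N >= 2)
    for (i in seq_len(N - 1)) { L[i, i + 1] <- -1; L[i + 1, i] <- -1 }
  L
}

#' Mean Hessian of the Hamiltonian under the Gaussian ansatz
#'
#' \eqn{\langle J\rangle_{mn}} is minus the Gaussian-ensemble average of the
#' Hessian blocks of `H`, reduced to isotropic scalars (trace/3). It is the
#' sum of the exact harmonic-chain contribution \eqn{-(3kT/l^2) L} (path
#' Laplacian `L`) and of pair contributions from the attractive Gaussian
#' potential and the repulsive Gaussian excluded-volume surrogate, each
#' evaluated at the current mean squared distances via
#' [gaussian_pair_averages()]. Rows sum to zero (translation invariance of
#' all pair and bond terms).
#'
#' @param D symmetric `N x N` matrix of per-component separation variances
#'   (zero diagonal, non-negative).
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @return the symmetric `N x N` matrix `J`.
#' @export
mean_hessian <- function(D, seq, model) {
  N <- length(seq)
  D <- as.matrix(D)
  dimnames(D) <- NULL
  if (!all(dim(D) == N)) stop("D does not match the sequence length")
  if (any(!is.finite(D))) stop("non-finite entries in D")
  if (any(D < 0)) stop("negative entries in D")
  cp <- model$chain
  E <- interaction_matrix(seq, model)
  J <- gaussian_pair_averages(1, model$r0, D)$hessian * E
  if (cp$U_hc0 > 0)
    J <- J + gaussian_pair_averages(cp$U_hc0, cp$r_hc, D)$hessian
  diag(J) <- 0
  kappa <- 3 * cp$kT / cp$l^2
  J <- J - kappa * chain_laplacian(N)
  diag(J) <- 0
  diag(J) <- -rowSums(J)
  J
}

#' Serialize an interaction model to a flat key-value config file
#'
#' Keys: `U_ns`, `U_s` (scalar) or `U_s.<type1>.<type2>` (per-type-pair),
#' `r0`, `l`, `kT`, `hardcore.sigma`, `hardcore.epsilon`, `hardcore.U0`,
#' `hardcore.range`.
#'
#' @param model an [interaction_model()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_model_config <- function(model, path) {
  cp <- model$chain
  lines <- c(sprintf("U_ns = %.17g", model$U_ns))
  if (is.matrix(model$U_s)) {
    labs <- rownames(model$U_s)
    for (i in seq_along(labs))
      for (j in i:length(labs))
        lines <- c(lines, sprintf("U_s.%s.%s = %.17g", labs[i], labs[j],
                                  model$U_s[i, j]))
  } else {
    lines <- c(lines, sprintf("U_s = %.17g", model$U_s))
  }
  lines <- c(lines,
             sprintf("r0 = %.17g", model$r0),
             sprintf("l = %.17g", cp$l),
             sprintf("kT = %.17g", cp$kT),
             sprintf("hardcore.sigma = %.17g", cp$sigma),
             sprintf("hardcore.epsilon = %.17g", cp$epsilon),
             sprintf("hardcore.U0 = %.17g", cp$U_hc0),
             sprintf("hardcore.range = %.17g", cp$r_hc))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction model from a flat key-value config file
#'
#' @param path file written by [write_model_config()] (or hand-edited in the
#'   same dialect). Unknown keys are rejected.
#' @return an [interaction_model()].
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(
    lines,
    regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*([^[:space:]]+)[[:space:]]*$",
            lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad) > 0L) stop("malformed config line(s): ",
                             paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- as.numeric(vapply(kv, `[`, "", 3L))
  known <- c("U_ns", "U_s", "r0", "l", "kT", "hardcore.sigma",
             "hardcore.epsilon", "hardcore.U0", "hardcore.range")
  pair_keys <- grepl("^U_s\\.[^.]+\\.[^.]+$", keys)
  if (!all(keys[!pair_keys] %in% known))
    stop("unknown config key(s): ",
         paste(setdiff(keys[!pair_keys], known), collapse = ", "))
  getv <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  if (any(pair_keys)) {
    parts <- strsplit(keys[pair_keys], ".", fixed = TRUE)
    t1 <- vapply(parts, `[`, "", 2L)
    t2 <- vapply(parts, `[`, "", 3L)
    labs <- unique(c(t1, t2))
    us <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    v <- vals[pair_keys]
    for (i in seq_along(v)) {
      us[t1[i], t2[i]] <- v[i]
      us[t2[i], t1[i]] <- v[i]
    }
  } else {
    us <- getv("U_s", 0)
  }
  l <- getv("l", 1); kT <- getv("kT", 1)
  sigma <- getv("hardcore.sigma", l)
  interaction_model(
    U_ns = getv("U_ns", 0), U_s = us, r0 = getv("r0", 1.5),
    chain = chain_params(l = l, kT = kT, sigma = sigma,
                         epsilon = getv("hardcore.epsilon", kT),
                         U_hc0 = getv("hardcore.U0", 3 * kT),
                         r_hc = getv("hardcore.range", sigma)))
}
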