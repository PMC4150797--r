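test_that("initial conditions have the stated geometry", {
  m <- interaction_model()
  s3 <- epi_sequence(c("A", "B", "A"))
  expect_equal(init_coil(s3, m),
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3) / 3)
  s <- toy_small()  # N = 20
  Dc <- init_coil(s, m)
  nn <- cbind(1:19, 2:20)
  expect_true(all(Dc[nn] == 1 / 3))
  expect_true(is_embeddable(Dc))

  # globule: coil capped at the plateau; reduces to coil as plateau -> Inf
  Dg <- init_globule(s, m, plateau = 2)
  sep <- abs(row(Dg) - col(Dg))
  expect_true(all(Dg[sep >= 6] == 2))
  expect_equal(init_globule(s, m, plateau = 1e9), Dc)
  expect_true(isSymmetric(Dg))
  expect_equal(diag(Dg), rep(0, 20))
  expect_error(init_globule(s, m, plateau = -1), "positive")

  # MPS: same-type pairs closer than cross-type pairs, valid embedding
  Dm <- init_mps(s, m, intra = 1, inter = 8)
  same <- same_state_indicator(s) == 1
  far <- sep >= 5
  expect_lt(mean(Dm[far & same]), mean(Dm[far & !same]))
  expect_true(is_embeddable(Dm, tol = 1e-6))
  expect_error(init_mps(s, m, intra = 3, inter = 2), "intra < inter")

  # single-type sequence: the MPS construction degenerates to a globule
  mono <- epi_sequence(rep("A", 12))
  Dm1 <- init_mps(mono, m, intra = 1, inter = 4)
  expect_true(max(Dm1) <= max(init_globule(mono, m, plateau = 1) + 1e-9))
})

test_that("embedding projection repairs invalid distance matrices", {
  D <- ideal_chain_profile(12)
  D_bad <- D
  D_bad[1, 12] <- D_bad[12, 1] <- 40  # inconsistent with the chain
  expect_false(is_embeddable(D_bad))
  D_fix <- project_embeddable(D_bad)
  expect_true(is_embeddable(D_fix, tol = 1e-6))
  expect_true(isSymmetric(D_fix))
  expect_equal(diag(D_fix), rep(0, 12))
  # projection is the identity on already-valid matrices
  expect_equal(project_embeddable(D), D, tolerance = 1e-10)
})

test_that("the compiled right-hand side matches the reference implementation", {
  s <- toy_small()
  m <- interaction_model(U_ns = -0.3, U_s = -0.5)
  p <- sca_params()
  D <- init_globule(s, m, plateau = 3)
  r_R <- sca_rhs(D, s, m, p)
  a <- epifold:::sca_core_args(s, m, p)
  r_C <- epifold:::sca_rhs_cpp(D, a$E, a$kappa, a$kT, a$xi, a$r0, a$Uhc0,
                               a$rhc, a$noise)
  expect_equal(r_R, r_C, tolerance = 1e-12)
  expect_equal(diag(r_R), rep(0, 20))
  expect_true(isSymmetric(r_R))
})

test_that("the Rouse profile is a fixed point of the noise-balanced dynamics", {
  # the 4kT noise term balances the harmonic-chain drift exactly at
  # D_mn = |m-n| l^2/3, for end and interior monomers alike
  for (N in c(2, 10, 37)) {
    s <- epi_sequence(rep("A", N))
    m <- ideal_model()
    r <- sca_rhs(ideal_chain_profile(N), s, m)
    expect_lt(max(abs(r)), 1e-10)
  }
  # and it is an attractor: a perturbed chain relaxes back
  s <- epi_sequence(rep("A", 20))
  fit <- evolve(init_globule(s, ideal_model(), plateau = 2), s, ideal_model(),
                sca_params(steady_tol = 1e-8, rtol = 1e-9, atol = 1e-11))
  expect_true(fit$report$converged)
  expect_equal(fit$D, ideal_chain_profile(20), tolerance = 1e-4)
})

test_that("the rhs is equivariant under chain reversal for the toy copolymer", {
  s <- toy_ab()
  m <- interaction_model(U_ns = -0.2, U_s = -0.6)
  D <- init_globule(s, m)
  set.seed(9)
  pert <- matrix(rnorm(120^2, sd = 0.01), 120, 120)
  pert <- abs(pert + t(pert)); diag(pert) <- 0
  D <- D + pert
  rev_idx <- 120:1
  r1 <- sca_rhs(D[rev_idx, rev_idx], s, m)
  r2 <- sca_rhs(D, s, m)[rev_idx, rev_idx]
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("evolve honours zero horizons, snapshots and non-convergence flags", {
  s <- toy_small()
  m <- interaction_model(U_ns = -0.2, U_s = -0.2)
  D0 <- init_coil(s, m)
  # zero integration time returns the input unchanged
  r0 <- evolve(D0, s, m, sca_params(t_max = 0))
  expect_equal(r0$D, D0)

  # snapshots stay symmetric with a zero diagonal to machine precision
  r <- evolve(D0, s, m, sca_params(steady_tol = 1e-7),
              snapshot_times = c(0.5, 2, 10))
  expect_length(r$snapshots, 3)
  for (S in r$snapshots) {
    expect_identical(S, t(S))
    expect_identical(diag(S), rep(0, 20))
  }

  # a too-short horizon is reported, with partial results returned
  rshort <- evolve(D0, s, m, sca_params(t_max = 0.05, steady_tol = 1e-12))
  expect_false(rshort$report$converged)
  expect_false(rshort$report$diverged)
  expect_equal(rshort$report$t_end, 0.05)

  # exceeding the divergence bound flags the run
  mrep <- interaction_model(U_ns = 2, U_s = 0)  # purely repulsive pairs
  rdiv <- evolve(D0, s, mrep, sca_params(max_D = 20, t_max = 1e4))
  expect_true(rdiv$report$diverged)
})

test_that("a non-interacting chain has a unique fixed point from any start", {
  s <- epi_sequence(rep(c("A", "B"), each = 8))
  m <- ideal_model()
  p <- sca_params(steady_tol = 1e-7)
  fp <- find_fixed_points(s, m, p,
                          inits = list(coil = init_coil(s, m),
                                       globule = init_globule(s, m, 2),
                                       mps = init_mps(s, m, 1, 6)))
  expect_equal(fp$multiplicity, 1)
  expect_equal(fp$n_unconverged, 0)
  expect_equal(fp$fixed_points[[1]], ideal_chain_profile(16),
               tolerance = 1e-3)

  # identical inits collapse to a single cluster regardless of count
  fp2 <- find_fixed_points(s, m, p,
                           inits = list(a = init_coil(s, m),
                                        b = init_coil(s, m)))
  expect_equal(fp2$multiplicity, 1)
  expect_equal(unname(fp2$assignment), c(1L, 1L))
})

test_that("short-time integration matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  s <- epi_sequence(rep(c("A", "B"), each = 5))
  m <- interaction_model(U_ns = -0.4, U_s = -0.4)
  p <- sca_params(rtol = 1e-9, atol = 1e-11)
  D0 <- init_coil(s, m)
  t_end <- 3
  mine <- evolve(D0, s, m, sca_params(rtol = 1e-9, atol = 1e-11,
                                      steady_tol = 1e-14, t_max = t_end))
  ode_rhs <- function(t, y, parms) {
    # trial steps of the reference solver may dip infinitesimally negative
    D <- matrix(pmax(y, 0), 10, 10)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    list(as.vector(sca_rhs(D, s, m, p)))
  }
  ref <- deSolve::ode(y = as.vector(D0), times = c(0, t_end), func = ode_rhs,
                      parms = NULL, method = "ode45", rtol = 1e-9,
                      atol = 1e-11)
  D_ref <- matrix(ref[2, -1], 10, 10)
  expect_equal(mine$D, D_ref, tolerance = 1e-6)
})

test_that("weak-interaction SCA distances rank-correlate with MD equilibrium", {
  s <- make_block_sequence(c(A = 5, B = 5), repeats = 2)  # N = 20
  m <- interaction_model(U_ns = -0.2, U_s = -0.3)
  fit <- evolve(init_coil(s, m), s, m, sca_params(steady_tol = 1e-6))
  expect_true(fit$report$converged)
  tr <- simulate_md(s, m, n_steps = 1e6, dt = 0.005, thermostat_nu = 1,
                    seed = 41, sample_every = 200)
  D_md <- mean_sq_distances(tr, burn_in = 200) / 3
  ut <- upper.tri(D_md)
  expect_gt(cor(fit$D[ut], D_md[ut], method = "spearman"), 0.9)
})

test_that("strengthening non-specific attraction never expands the chain", {
  s <- toy_small()  # N = 20
  lr <- vapply(c(0, -0.3, -0.6, -0.9), function(uns) {
    m <- interaction_model(U_ns = uns, U_s = -0.2)
    fit <- evolve(init_coil(s, m), s, m, sca_params(steady_tol = 1e-5))
    mean_long_range(fit$D)
  }, numeric(1))
  expect_true(all(diff(lr) < 1e-6))
})
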