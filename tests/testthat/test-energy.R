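test_that("interaction matrix adds specific strength on same-state pairs", {
  s <- epi_sequence(c("A", "A", "B"))
  E <- interaction_matrix(s, interaction_model(U_ns = -1, U_s = -0.5))
  expect_equal(E[1, 2], -1.5)
  expect_equal(E[1, 3], -1.0)
  expect_equal(E[2, 3], -1.0)
  expect_equal(diag(E), rep(0, 3))
  expect_true(isSymmetric(E))

  # homopolymer limit: zero specificity makes all pairs equal
  E0 <- interaction_matrix(toy_ab(), interaction_model(U_ns = -0.7, U_s = 0))
  off <- row(E0) != col(E0)
  expect_true(all(E0[off] == -0.7))
})

test_that("per-type-pair strengths allow heterogeneous specific interactions", {
  s <- epi_sequence(c("Polycomb", "Polycomb", "black", "black"),
                    alphabet = default_alphabet())
  us <- matrix(0, 4, 4, dimnames = list(default_alphabet(),
                                        default_alphabet()))
  diag(us) <- c(-0.1, -0.1, -0.9, -0.3)  # Polycomb-Polycomb strongest
  m <- interaction_model(U_ns = -0.2, U_s = us)
  E <- interaction_matrix(s, m)
  expect_equal(E[1, 2], -0.2 - 0.9)  # Polycomb pair
  expect_equal(E[3, 4], -0.2 - 0.3)  # black pair
  expect_lt(E[1, 2], E[3, 4])
  expect_equal(E[1, 3], -0.2)        # cross pair: non-specific only

  bad <- epi_sequence(c("X", "Y"))
  expect_error(interaction_matrix(bad, m), "absent")
})

test_that("total energy reproduces the printed Hamiltonian term by term", {
  s2 <- epi_sequence(c("A", "B"))
  # bonded pair at separation l, pair terms off: spring energy 3kT/2
  m <- ideal_model()
  X <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(total_energy(X, s2, m), 1.5)

  # two monomers at r = 0 with E_12 = U, hard core off: Gaussian term = U
  mU <- interaction_model(U_ns = -2, U_s = 0,
                          chain = chain_params(epsilon = 0, U_hc0 = 0))
  X0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(total_energy(X0, s2, mU), -2)

  # translation invariance
  mfull <- interaction_model(U_ns = -1, U_s = -0.5)
  s4 <- epi_sequence(c("A", "B", "A", "B"))
  set.seed(2)
  Xr <- matrix(rnorm(12), 4, 3)
  shift <- matrix(c(3, -2, 5), 4, 3, byrow = TRUE)
  expect_equal(total_energy(Xr, s4, mfull),
               total_energy(Xr + shift, s4, mfull))

  expect_error(total_energy(rbind(c(0, 0, 0), c(NA, 0, 0)), s2, m),
               "non-finite")
})

test_that("Gaussian pair averages match the Monte-Carlo oracle", {
  # degenerate Gaussian at r = 0 returns the well depth
  g0 <- gaussian_pair_averages(-1.3, 1.2, 0)
  expect_equal(g0$potential, -1.3)
  # finite range: both averages vanish as D grows
  ginf <- gaussian_pair_averages(-1.3, 1.2, 1e8)
  expect_lt(abs(ginf$potential), 1e-10)
  expect_lt(abs(ginf$hessian), 1e-10)
  expect_error(gaussian_pair_averages(-1, 1, -0.1), "non-negative")

  # MC oracle: sample separations from an isotropic Gaussian and average
  # the potential and the isotropic Hessian reduction numerically
  set.seed(11)
  n <- 1e6
  for (case in list(c(E = -1, a = 1, D = 1), c(E = 0.5, a = 2, D = 3))) {
    r <- matrix(rnorm(3 * n, sd = sqrt(case["D"])), n, 3)
    r2 <- rowSums(r^2)
    w <- exp(-r2 / (2 * case["a"]^2))
    u_mc <- mean(case["E"] * w)
    h_mc <- mean(case["E"] * w * (r2 / (3 * case["a"]^4) - 1 / case["a"]^2))
    g <- gaussian_pair_averages(case["E"], case["a"], case["D"])
    expect_lt(abs(u_mc - g$potential) / abs(g$potential), 0.01)
    expect_lt(abs(h_mc - g$hessian) / abs(g$hessian), 0.01)
  }
})

test_that("mean Hessian reduces to the chain Laplacian without pair terms", {
  s <- epi_sequence(rep("A", 6))
  m <- ideal_model()
  D <- random_dist_matrix(6, seed = 4)
  J <- mean_hessian(D, s, m)
  # finite-difference oracle: numeric Hessian of the spring energy,
  # reduced to isotropic pair scalars, at an arbitrary configuration
  set.seed(5)
  X <- matrix(rnorm(18), 6, 3)
  h <- 1e-5
  J_fd <- matrix(0, 6, 6)
  for (nn in 1:6) for (mm in 1:6) {
    tr <- 0
    for (d in 1:3) {
      Xpp <- X; Xpp[nn, d] <- Xpp[nn, d] + h; Xpp[mm, d] <- Xpp[mm, d] + h
      Xpm <- X; Xpm[nn, d] <- Xpm[nn, d] + h; Xpm[mm, d] <- Xpm[mm, d] - h
      Xmp <- X; Xmp[nn, d] <- Xmp[nn, d] - h; Xmp[mm, d] <- Xmp[mm, d] + h
      Xmm <- X; Xmm[nn, d] <- Xmm[nn, d] - h; Xmm[mm, d] <- Xmm[mm, d] - h
      tr <- tr + (total_energy(Xpp, s, m) - total_energy(Xpm, s, m) -
                    total_energy(Xmp, s, m) + total_energy(Xmm, s, m)) /
        (4 * h^2)
    }
    J_fd[nn, mm] <- -tr / 3
  }
  expect_equal(J, J_fd, tolerance = 1e-5)
  expect_equal(J, -3 * epifold:::chain_laplacian(6), tolerance = 1e-12)
})

test_that("mean Hessian assembly agrees with per-pair Monte-Carlo averages", {
  s <- epi_sequence(c("A", "B", "A", "B", "A"))
  m <- interaction_model(U_ns = -0.4, U_s = -0.6)
  D <- random_dist_matrix(5, seed = 8)
  J <- mean_hessian(D, s, m)
  expect_true(isSymmetric(J))
  expect_equal(rowSums(J), rep(0, 5), tolerance = 1e-12)

  E <- interaction_matrix(s, m)
  cp <- m$chain
  set.seed(12)
  n <- 4e5
  z2 <- rowSums(matrix(rnorm(3 * n), n, 3)^2)  # chi^2_3 draws, reused
  mc_pair <- function(Epair, a, Dmn) {
    r2 <- z2 * Dmn
    w <- exp(-r2 / (2 * a^2))
    mean(Epair * w * (r2 / (3 * a^4) - 1 / a^2))
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 5))) {
    i <- pair[1]; j <- pair[2]
    expected <- mc_pair(E[i, j], m$r0, D[i, j]) +
      mc_pair(cp$U_hc0, cp$r_hc, D[i, j]) +
      if (abs(i - j) == 1) 3 * cp$kT / cp$l^2 else 0
    expect_equal(J[i, j], expected, tolerance = 0.01 * max(abs(J[i, j]), 0.1))
  }
})

test_that("mean Hessian is reversal-symmetric and continuous in the hard core", {
  s <- toy_small()
  m <- interaction_model(U_ns = -0.3, U_s = -0.3)
  N <- length(s)
  D <- ideal_chain_profile(N)
  J <- mean_hessian(D, s, m)
  rev_idx <- N:1
  expect_equal(J, J[rev_idx, rev_idx], tolerance = 1e-12)

  # J depends continuously on the hard-core amplitude and reduces to the
  # no-hard-core Hessian as U_hc0 -> 0
  J0 <- mean_hessian(D, s, interaction_model(U_ns = -0.3, U_s = -0.3,
                                             chain = chain_params(U_hc0 = 0)))
  eps_seq <- c(1e-1, 1e-3, 1e-6)
  devs <- vapply(eps_seq, function(e) {
    Je <- mean_hessian(D, s, interaction_model(U_ns = -0.3, U_s = -0.3,
                                               chain = chain_params(U_hc0 = e)))
    max(abs(Je - J0))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-5)
})

test_that("interaction models round-trip through key-value config files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  m <- interaction_model(U_ns = -0.25, U_s = -1.5, r0 = 2,
                         chain = chain_params(l = 1.1, kT = 0.9,
                                              epsilon = 0.8, U_hc0 = 2.5))
  write_model_config(m, path)
  m2 <- read_model_config(path)
  expect_equal(m2$U_ns, m$U_ns)
  expect_equal(m2$U_s, m$U_s)
  expect_equal(m2$r0, m$r0)
  expect_equal(m2$chain$l, m$chain$l)
  expect_equal(m2$chain$U_hc0, m$chain$U_hc0)

  us <- matrix(c(-0.5, -0.1, -0.1, -0.9), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  mh <- interaction_model(U_ns = -0.2, U_s = us)
  write_model_config(mh, path)
  mh2 <- read_model_config(path)
  expect_equal(mh2$U_s[c("A", "B"), c("A", "B")], us)

  writeLines("bogus_key = 1", path)
  expect_error(read_model_config(path), "unknown config key")
})
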