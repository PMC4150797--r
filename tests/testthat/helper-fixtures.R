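# Fixture builders shared across test files. Everything is generated in code;
# genomic fixtures are synthetic stand-ins shaped like the fly regions the
# model is applied to (large black domains separated by short active /
# Polycomb domains).

toy_ab <- function() make_block_sequence(c(A = 10, B = 10), repeats = 6)

toy_small <- function(block = 5, repeats = 2)
  make_block_sequence(c(A = block, B = block), repeats = repeats)

# Synthetic chromatin-state segmentation covering [start, end) of a
# chromosome: black background with interspersed short active and Polycomb
# domains, interval boundaries NOT aligned to the 10-kb grid.
synthetic_segmentation <- function(chrom = "chr3R", start = 23050000,
                                   end = 24360000, seed = 42) {
  set.seed(seed)
  breaks <- sort(c(start, end,
                   sample(seq(start + 1000, end - 1000, by = 1000),
                          25, replace = FALSE)))
  breaks <- unique(breaks)
  n <- length(breaks) - 1
  states <- character(n)
  states[seq(1, n, by = 1)] <- "black"
  others <- sample(seq_len(n), size = max(2, n %/% 3))
  states[others] <- sample(c("active", "Polycomb", "HP1"),
                           length(others), replace = TRUE)
  data.frame(chrom = chrom, start = head(breaks, -1), end = breaks[-1],
             state = states, stringsAsFactors = FALSE)
}

# Random valid distance matrix: Gram matrix of random points -> D.
random_dist_matrix <- function(N, seed = 1, scale = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * 3, sd = scale), N, 3)
  D <- as.matrix(dist(X))^2 / 3
  dimnames(D) <- NULL
  D
}

# Model with all pair interactions (attraction + excluded volume) disabled:
# a pure discrete Gaussian chain.
ideal_model <- function(l = 1, kT = 1)
  interaction_model(U_ns = 0, U_s = 0,
                    chain = chain_params(l = l, kT = kT, epsilon = 0,
                                         U_hc0 = 0))

fast_params <- function(...) sca_params(steady_tol = 1e-5, t_max = 2000, ...)
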