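#' Solver parameters tuned for phase scans
#'
#' Phase labels depend on coarse diagnostics (mean long-range distance,
#' checkerboard contrast, fixed-point multiplicity), which are insensitive
#' to residuals well above the solver's tight default stationarity
#' threshold. Scans therefore run at `steady_tol = 2e-3` with a horizon
#' long enough for excluded-volume swelling, and use a fixed-point
#' clustering radius of 0.15: at this stationarity level two runs converging
#' to the *same* fixed point from opposite sides still sit a few percent
#' apart, so the radius must be well above that, while distinct phases
#' differ by factors of several. Acceptance checks verify that labels are
#' unchanged when the integrator tolerances are halved.
#'
#' @param ... overrides passed to [sca_params()].
#' @return an [sca_params()].
#' @export
phase_scan_params <- function(...) {
  defaults <- list(steady_tol = 2e-3, t_max = 6000, fp_tol = 0.15)
  args <- utils::modifyList(defaults, list(...))
  do.call(sca_params, args)
}

#' Checkerboard index of a distance matrix
#'
#' Contrast between cross-state and same-state long-range distances:
#' \deqn{\mathrm{CI} = \frac{\overline{D}_\mathrm{cross} -
#'   \overline{D}_\mathrm{same}}{\overline{D}_\mathrm{all}}}
#' over pairs separated by at least `min_separation` monomers. Positive
#' values indicate same-state compaction, the hallmark of microphase
#' separation; 0 for a type-blind distance profile on a balanced sequence.
#'
#' @param D distance matrix (or `sca_result`).
#' @param seq an [epi_sequence()] with at least 2 states present.
#' @param min_separation minimal |m - n| included (>= 1).
#' @return a scalar score.
#' @export
checkerboard_index <- function(D, seq, min_separation = 10) {
  if (inherits(D, "sca_result")) D <- D$D
  D <- as.matrix(D)
  if (length(unique(seq$states)) < 2)
    stop("checkerboard index needs at least 2 chromatin states")
  if (min_separation < 1) stop("min_separation must be >= 1")
  sep <- abs(row(D) - col(D))
  use <- sep >= min_separation
  if (!any(use)) stop("no pairs at the requested separation")
  same <- same_state_indicator(seq) == 1
  m_same <- mean(D[use & same])
  m_cross <- mean(D[use & !same])
  (m_cross - m_same) / mean(D[use])
}

#' Mean long-range distance
#'
#' Mean of `D` over pairs with `|m - n| >= min_sep` (default `N/4`,
#' excluding intra-block pairs for the toy chain).
#'
#' @param D distance matrix.
#' @param min_sep minimal separation; default `ceiling(N/4)`.
#' @return scalar.
#' @export
mean_long_range <- function(D, min_sep = NULL) {
  D <- as.matrix(D)
  N <- nrow(D)
  if (is.null(min_sep)) min_sep <- ceiling(N / 4)
  sep <- abs(row(D) - col(D))
  mean(D[sep >= min_sep])
}

#' Classification thresholds of the phase mapper
#'
#' @param coil_fraction a point is a coil when its mean long-range distance
#'   exceeds this fraction of the ideal-chain value.
#' @param checker_threshold minimal checkerboard index for the MPS label.
#' @param min_separation separation used by the checkerboard index.
#' @param long_range_min separation defining "long range"; `NULL` = `N/4`.
#' @return an object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(coil_fraction = 0.5, checker_threshold = 0.1,
                             min_separation = 10, long_range_min = NULL) {
  structure(list(coil_fraction = coil_fraction,
                 checker_threshold = checker_threshold,
                 min_separation = min_separation,
                 long_range_min = long_range_min),
            class = "phase_thresholds")
}

#' Classify one point of the (U_ns, U_s) plane
#'
#' Runs [find_fixed_points()] from the canonical initial conditions
#' (coil, globule, microphase-separated). Labels:
#' * `multistable` - two or more distinct fixed points;
#' * `coil` - a single fixed point whose mean long-range distance exceeds
#'   `coil_fraction` of the ideal-chain value;
#' * `MPS` - checkerboard index above `checker_threshold`;
#' * `globule` - otherwise (collapsed, type-blind);
#' * `unresolved` - some run failed to converge.
#'
#' @param seq an [epi_sequence()].
#' @param model an [interaction_model()].
#' @param params an [sca_params()].
#' @param thresholds a [phase_thresholds()].
#' @param inits optional named list of initial conditions.
#' @return an object of class `phase_point`: `list(U_ns, U_s, label,
#'   diagnostics)`.
#' @export
classify_point <- function(seq, model, params = sca_params(),
                           thresholds = phase_thresholds(), inits = NULL) {
  fp <- find_fixed_points(seq, model, params, inits = inits)
  N <- length(seq)
  lr_ideal <- mean_long_range(init_coil(seq, model),
                              thresholds$long_range_min)
  two_types <- length(unique(seq$states)) >= 2
  diag_of <- function(D) {
    list(mean_long_range_D = mean_long_range(D, thresholds$long_range_min),
         checkerboard = if (two_types)
           checkerboard_index(D, seq, thresholds$min_separation)
         else NA_real_)
  }
  diagnostics <- list(multiplicity = fp$multiplicity,
                      n_unconverged = fp$n_unconverged,
                      ideal_long_range_D = lr_ideal)
  if (fp$n_unconverged > 0 || fp$multiplicity == 0) {
    label <- "unresolved"
    if (fp$multiplicity >= 1)
      diagnostics <- c(diagnostics, diag_of(fp$fixed_points[[1]]))
  } else if (fp$multiplicity >= 2) {
    label <- "multistable"
    diagnostics <- c(diagnostics, diag_of(fp$fixed_points[[1]]))
  } else {
    d <- diag_of(fp$fixed_points[[1]])
    diagnostics <- c(diagnostics, d)
    label <- if (d$mean_long_range_D > thresholds$coil_fraction * lr_ideal)
      "coil"
    else if (two_types && !is.na(d$checkerboard) &&
             d$checkerboard > thresholds$checker_threshold)
      "MPS"
    else "globule"
  }
  structure(list(U_ns = model$U_ns,
                 U_s = if (is.matrix(model$U_s)) NA_real_ else model$U_s,
                 label = label, diagnostics = diagnostics,
                 fixed_points = fp$fixed_points),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("phase_point: (U_ns = %g, U_s = %g) -> %s (multiplicity %d)\n",
              x$U_ns, x$U_s, x$label, x$diagnostics$multiplicity))
  invisible(x)
}

#' Scan a grid of interaction strengths into a phase diagram
#'
#' Classifies every node of the rectangular `(U_ns, U_s)` grid with
#' [classify_point()]. Nodes are independent (no warm-starting between
#' neighbours, avoiding hysteresis artifacts); per-node failures surface as
#' `unresolved` labels without aborting the scan.
#'
#' @param seq an [epi_sequence()].
#' @param U_ns_values,U_s_values grid axes (non-empty, in kT).
#' @param params an [sca_params()].
#' @param thresholds a [phase_thresholds()].
#' @param r0,chain passed to [interaction_model()] for every node.
#' @param shared_coil when `TRUE` (default) the coil member of the init set
#'   is the self-avoiding coil state of the non-interacting model
#'   ([coil_state()]), computed once and shared across grid nodes.
#' @param coil_D optional precomputed shared coil state (skips the
#'   computation when supplied).
#' @return an object of class `phase_diagram` with a tidy `points`
#'   data.frame (one row per node) and the scan settings.
#' @export
scan_grid <- function(seq, U_ns_values, U_s_values, params = sca_params(),
                      thresholds = phase_thresholds(), r0 = 1.5,
                      chain = chain_params(), shared_coil = TRUE,
                      coil_D = NULL) {
  if (length(U_ns_values) == 0L || length(U_s_values) == 0L)
    stop("grid axes must be non-empty")
  grid <- expand.grid(U_ns = U_ns_values, U_s = U_s_values,
                      KEEP.OUT.ATTRS = FALSE)
  if (is.null(coil_D) && shared_coil)
    coil_D <- coil_state(seq, interaction_model(r0 = r0, chain = chain),
                         params)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    model <- interaction_model(U_ns = grid$U_ns[i], U_s = grid$U_s[i],
                               r0 = r0, chain = chain)
    inits <- canonical_inits(seq, model)
    if (!is.null(coil_D)) inits$coil <- coil_D
    pt <- tryCatch(classify_point(seq, model, params, thresholds,
                                  inits = inits),
                   error = function(e)
                     list(U_ns = grid$U_ns[i], U_s = grid$U_s[i],
                          label = "unresolved",
                          diagnostics = list(multiplicity = NA_integer_,
                                             n_unconverged = NA_integer_,
                                             ideal_long_range_D = NA_real_,
                                             mean_long_range_D = NA_real_,
                                             checkerboard = NA_real_)))
    d <- pt$diagnostics
    data.frame(U_ns = grid$U_ns[i], U_s = grid$U_s[i], label = pt$label,
               multiplicity = if (is.null(d$multiplicity)) NA_integer_
               else d$multiplicity,
               n_unconverged = if (is.null(d$n_unconverged)) NA_integer_
               else d$n_unconverged,
               mean_long_range_D = if (is.null(d$mean_long_range_D))
                 NA_real_ else d$mean_long_range_D,
               checkerboard = if (is.null(d$checkerboard)) NA_real_
               else d$checkerboard,
               stringsAsFactors = FALSE)
  })
  structure(list(points = do.call(rbind, rows),
                 n_beads = length(seq),
                 U_ns_values = U_ns_values, U_s_values = U_s_values,
                 params = params, thresholds = thresholds),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase_diagram: %d x %d grid on %d beads\n",
              length(x$U_ns_values), length(x$U_s_values), x$n_beads))
  print(table(x$points$label))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.phase_diagram <- function(x, ...) x$points

#' Write a phase diagram as a tidy table
#'
#' One row per grid node: `U_ns`, `U_s`, label and diagnostics,
#' tab-separated with a header.
#'
#' @param pd a `phase_diagram`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phase_diagram <- function(pd, path) {
  stopifnot(inherits(pd, "phase_diagram"))
  write.table(pd$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
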