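---
title: "Modelling epigenome folding with epifold: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epigenome folding with epifold: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epifold` treats a chromatin fibre as a bead-spring block copolymer. Each
monomer represents a fixed genomic span (10 kb by default) and carries a
chromatin-state label; the default alphabet distinguishes active chromatin,
HP1-like constitutive heterochromatin, Polycomb-like facultative
heterochromatin and the gene-poor repressive "black" chromatin. The
configurational energy has two parts. The chain part combines harmonic
springs between successive beads, with stiffness \(3 k_B T / l^2\) so that
the free chain has bond variance \(l^2\), and excluded volume between all
bead pairs. The interaction part is a short-range Gaussian attraction
between all pairs,

\[
H_\mathrm{inter} = \sum_{n<m} E_{nm}
  \exp\!\left[-\frac{r_{nm}^2}{2 r_0^2}\right],
\qquad
E_{nm} = U_\mathrm{ns} + \delta_{nm}\, U_\mathrm{s},
\]

where \(\delta_{nm} = 1\) when monomers \(n\) and \(m\) carry the same
chromatin state. \(U_\mathrm{ns}\) is a non-specific attraction acting on
every pair — an effective description of global compaction, e.g. by nuclear
confinement — and \(U_\mathrm{s}\) acts only between same-state pairs,
standing for bridging by readers of that state (HP1, Polycomb-group
proteins, shared transcription machinery). `U_s` may also be a per-type-pair
matrix so that, for instance, Polycomb–Polycomb contacts can be made
stronger than black–black ones.

All quantities are in reduced units: \(l\) (bond length) is the length
unit, \(k_B T\) the energy unit, and bead mass 1, so the MD time unit is
\(\tau = l\sqrt{m/k_BT}\).

## Two solvers, one Hamiltonian

### Gaussian self-consistent dynamics

The chain's stochastic (overdamped Langevin) dynamics is closed at the level
of second moments by approximating the configuration distribution at each
instant with a multivariate Gaussian. The state variable is the matrix of
per-component mean squared distances \(D_{mn} = \langle (X_m - X_n)^2
\rangle / 3\), which evolves as

\[
\xi\,\frac{dD_{mn}}{dt} = 4 k_B T
 - \sum_k \left(\langle J_{mk}\rangle - \langle J_{nk}\rangle\right)
   \left(D_{mk} - D_{nk}\right), \qquad m \neq n,
\]

with \(\langle J \rangle\) the Gaussian-ensemble average of minus the
Hessian of the Hamiltonian, reduced to isotropic pair scalars. For the
Gaussian pair potential the averages are analytic: with
\(\alpha = a^2/(a^2 + D)\),

\[
\langle u \rangle = E\,\alpha^{3/2}, \qquad
\tfrac13 \langle \operatorname{tr} \nabla^2 u \rangle
 = -\frac{E}{a^2}\,\alpha^{5/2} .
\]

Both closed forms are validated against Monte-Carlo averages in the test
suite. The harmonic-chain part of \(\langle J\rangle\) is exact,
\(-(3k_BT/l^2) L\) with \(L\) the path-graph Laplacian.

**Noise prefactor.** Because every term of \(\langle J\rangle\) has zero row
sums (translation invariance), the moment equation above is exact given the
Gaussian closure, and one can verify algebraically that the discrete Rouse
profile \(D_{mn} = |m-n| l^2/3\) is an exact fixed point of the
non-interacting equation — for end monomers as well as interior ones. The
package therefore uses the \(4k_BT\) noise term with a calibration constant
of exactly 1 (`sca_params(noise_scale = 1)`); a unit test asserts that the
right-hand side vanishes at the Rouse profile to machine precision, and the
MD engine independently reproduces the same profile to a few percent.

### Molecular dynamics

`simulate_md()` integrates the same Hamiltonian with velocity Verlet plus an
Andersen thermostat (per-bead Maxwell–Boltzmann velocity redraws at rate
\(\nu\)). Excluded volume in MD is the Weeks–Chandler–Andersen potential
(purely repulsive Lennard–Jones, truncated and shifted at
\(2^{1/6}\sigma\)), with \(\sigma = l\) and \(\epsilon = k_BT\) by default.
The default timestep is \(0.005\,\tau\); energy conservation with the
thermostat off and equipartition with it on are both asserted in the tests.
Forces are evaluated over all pairs in compiled code: at the chain lengths
this package targets (\(N \le\) a few hundred) a fused all-pairs loop is
faster in practice than neighbour-list bookkeeping, and it is trivially
identical to the reference force definition.

### Excluded volume in the Gaussian solver

A hard repulsive core has no finite Gaussian average, so the SCA represents
excluded volume by a repulsive Gaussian surrogate
\(+U_{hc0}\exp(-r^2/(2 r_{hc}^2))\) with defaults \(U_{hc0} = 3k_BT\) and
\(r_{hc} = \sigma\). Together with the attraction range \(r_0 = 1.5\,l\)
this makes the net pair potential at moderate attraction a repulsive core
with a shallow outer well — the classic shape that produces first-order-like
collapse, which is what gives the model its multistability region (below).
The surrogate is deliberately *stronger* than a virial match to the WCA core
would be; the Gaussian solver is therefore an approximation whose excluded
volume is treated roughly, and the MD engine exists precisely to check that
its qualitative conclusions (phase structure, checkerboard patterns,
distance rankings) are not artifacts. Quantitatively, SCA and MD distances
are compared in the tests only through rank correlation at weak coupling.

## Numerical integration and stationarity

The distance dynamics is integrated with an embedded Dormand–Prince 5(4)
pair (adaptive step, error per step controlled by `rtol = 1e-7`,
`atol = 1e-9`), implemented in compiled code with three guards:

* steps whose candidate state has a negative off-diagonal entry are
  rejected (distances must stay positive);
* any entry exceeding `max_D` flags divergence and returns partial results;
* the state is re-symmetrised after every accepted step, so snapshots are
  symmetric with a zero diagonal to machine precision.

Stationarity is declared on the dimensionless residual
\(\max_{mn} |\xi \dot D_{mn}|/(4k_BT) <\) `steady_tol` (default `1e-6`).
The residual cannot drop below roughly \(2.5\times\)`rtol`: every accepted
step perturbs \(D\) by its local error, which the contraction toward the
fixed point maps to a residual of that size. The step tolerances therefore
default one decade below the stationarity threshold.
An independent cross-check in the test suite integrates the same right-hand
side with `deSolve::ode(method = "ode45")` over a short horizon and matches
the compiled integrator.

Two further mechanisms keep phase scans affordable:

* **Shared coil state.** The equilibrated coil of this model is not the
  ideal-chain profile but the excluded-volume-swollen fixed point of the
  non-interacting chain, whose final approach is slow (the slowest
  relaxation time of the 120-bead swollen chain is of order \(10^3\) time
  units). `scan_grid()` therefore computes that state once per scan
  (`coil_state()`) and uses it as the coil member of the canonical init set
  at every node. `init_coil()` itself remains the exact Rouse profile.
* **Absorption.** When several starts are evolved at one parameter point,
  a run that enters the fixed-point clustering ball (relative Frobenius
  distance `fp_tol/2`) of an already-found stationary state is stopped and
  assigned to it: it is by then converging to a known fixed point, and
  integrating the slow tail again adds no information.

For phase scans the package uses `steady_tol = 2e-3` rather than the solver
default: label-level diagnostics (mean long-range distance, checkerboard
index) are insensitive to residuals at that level — the remaining drift in
\(D\) is below one percent — and the stationarity budget instead limits the
swelling runs that dominate scan time. The acceptance checks verify that
grid labels are unchanged when the integrator tolerances are halved.

## Initial conditions

Four canonical starting states cover the basins observed in practice:

* `init_coil()`: the Rouse profile \(D_{mn} = |m-n| l^2/3\);
* `init_globule(plateau)`: the coil profile capped at a plateau variance,
  default \(N^{2/3} l^2/3\), the geometric scale of a dense globule;
* `init_mps(intra, inter)`: same-state pairs at a small variance,
  cross-state pairs at a large one, short-range structure preserved by an
  elementwise minimum with the coil profile;
* `init_from_contact_map()`: inversion of the contact formula (below) to
  build "experimental-like" states from Hi-C-style maps.

Constructed matrices are projected to the nearest valid Gaussian embedding
(eigenvalues of the double-centred Gram matrix clipped at zero) because the
moment dynamics presumes that \(D\) derives from a covariance.

## Contact maps

Under the Gaussian ansatz the contact probability follows
\(P_{mn} \approx A\,D_{mn}^{-3/2}\). The constant \(A\) is not determined
by the model; by default it is set so that the mean nearest-neighbour
contact probability equals 1 (then clipped at 1), and all comparisons
between maps are performed on log-transformed entries with Spearman and
Pearson correlations, stratified by genomic separation, so the choice of
\(A\) cancels. Diagonals are excluded (`min_separation >= 1`); zeros are
handled by a pseudocount equal to the smallest positive entry. MD contact
maps count the fraction of post-burn-in frames within a cutoff (default
\(1.5\,l\), exposed as configuration); the default burn-in is the time for
the end-to-end autocorrelation to fall below \(1/e\).

## Phase classification

A parameter point is classified from the stationary states reached from the
canonical init set:

* **multistable** — two or more distinct fixed points (relative Frobenius
  distance above `fp_tol = 1e-2`);
* **coil** — one fixed point whose mean long-range distance (pairs
  \(|m-n| \ge N/4\)) exceeds half the ideal-chain value;
* **MPS** — checkerboard index above 0.1, where the index is the contrast
  (cross-state mean − same-state mean)/overall mean over pairs at
  \(|m-n| \ge 10\);
* **globule** — otherwise;
* **unresolved** — some run failed to converge or diverged.

The thresholds are configurable; the defaults were fixed once so that the
four archetypes of the toy chain \((A_{10}B_{10})_6\) are recovered, and are
not tuned per dataset. On that toy chain the coil profile's checkerboard
index is not exactly zero (about \(-0.014\)): chain ends break the
same/cross separation balance slightly. This is far below the MPS threshold.

On the toy chain the interesting structure sits at weak non-specific and
strong specific attraction: with \(U_\mathrm{ns} = 0\), the chain stays a
swollen coil up to \(U_\mathrm{s} \approx -1.5\,k_BT\), is bistable
(coil vs microphase-separated, selected by the start) in a wedge around
\(U_\mathrm{s} \approx -1.6\) to \(-1.9\,k_BT\), and collapses outright
beyond it; along \(U_\mathrm{s} = 0\) the usual \(\theta\)-collapse from
coil to a type-blind globule occurs between \(-1\) and
\(-1.25\,k_BT\). These locations are specific to the
default \(r_0 = 1.5\,l\) and surrogate-core parameters; the published
experimental systems put the same four regions at different absolute
strengths because the interaction range and hard-core treatment differ.

## Genomic sequences

`load_segmentation()` coarse-grains a BED4 chromatin-state segmentation
(0-based, half-open) onto fixed bins. Each bin takes the label with the
largest overlap; ties go to the label appearing first within the bin, then
to alphabet order, which makes the result independent of record order. A
label-merge map is applied first (for segmentations that distinguish two
active sub-states, say), and uncovered bins default to black chromatin, the
prevalent repressive background state. Region boundaries given in Mb
convert exactly (23.05 Mb → 23,050,000 bp); a region of 1.31 Mb at 10 kb
per monomer yields 131 beads.

## What the synthetic generators do and do not emulate

`make_block_sequence()` and `random_block_sequence()` produce block patterns
(regular or randomised, with distinct adjacent labels) that exercise every
code path: binning, interaction assembly, phase scans, multistability
detection. They reproduce the *block* structure of real epigenomes but not
their long-tailed domain-length distributions, state-specific length biases
or centromere/telomere effects; the synthetic segmentation fixtures used in
tests likewise have uniformly random breakpoints. Passing tests therefore
demonstrate the solvers' correctness and the classifier's behaviour on
block copolymers, not biological fidelity of any particular region; applying
the model to real data requires a real segmentation and, for quantitative
contact-map agreement, an inference step for the interaction strengths that
is out of scope here.

## Problem sizes and budgets

Defaults were chosen so every routine check completes on a single CPU:
phase scans use the 120-bead toy chain with a shared coil state and
absorption as above (a 5x5 grid in a few minutes); MD validation runs use
\(N = 20\)–200 with \(10^5\)–\(10^7\) steps (seconds each in compiled
code); Monte-Carlo validation of the Gaussian averages uses \(10^6\)
samples. The acceptance script scales the same computations; all sizes are
recorded in its resolved output.

## Known limitations

* The Gaussian closure has no notion of topology: chains can cross, and
  entanglement effects are absent (negligible below a few Mb, but real at
  larger scales).
* Excluded volume in the SCA is a soft surrogate; absolute densities in
  collapsed phases are not quantitative. Use the MD engine when absolute
  distances matter.
* The contact constant \(A\) is undetermined; all map comparisons are
  rank-based or log-affine by design.
* `U_ns`/`U_s` are effective, coarse-grained parameters; mapping them to
  molecular binding energies requires inference against data, which this
  package deliberately does not attempt.
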