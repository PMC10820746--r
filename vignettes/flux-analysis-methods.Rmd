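---
title: "Bayesian 13C flux analysis of upper glucose metabolism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian 13C flux analysis of upper glucose metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pppmfa)
```

# The estimation problem

`pppmfa` estimates intracellular reaction rates (fluxes) of upper glucose
metabolism — glycolysis plus the oxidative and non-oxidative pentose
phosphate pathway (PPP) — from the 13C labeling patterns that parallel
glucose tracer experiments imprint on intracellular metabolites.  Cells are
incubated with `[1,2-13C]`, `[4,5,6-13C]` or `[U-13C]`glucose (each mixed
1:1 with unlabeled glucose), and GC–EI–MS measures, for a panel of
metabolite fragments, the fraction of molecules carrying 0, 1, 2, ...
labeled carbons — the carbon mass distribution (CMD).  Because every
reaction moves specific carbon atoms, the steady-state CMDs are an
(indirect, nonlinear) fingerprint of the flux distribution.

The package is organized as the classic R modelling idiom: `mfa_fit()` is
the fitting function and returns an `mfa_fit` object with `print()`,
`summary()`, `coef()`, `predict()`, `plot()` and companion methods;
everything else (network construction, EMU simulation, natural-isotope
correction, synthetic data, precision scores, PCA) is an exported function
behind that interface.

# Network model and the permissible flux space

The default network (`ppp_network()`) has eight metabolite pools — G6P,
F6P, a lumped Ru5P+X5P pool `XuP`, R5P, S7P, E4P, DHAP and GAP — linked by
glucose uptake `Z1` (fixed at 100, the normalization of all fluxes), the
oxidative PPP `Z3` (G6P loses C1 as CO2), the reversible isomerase `dGPI`,
aldolase+phosphofructo steps lumped as `dQ2` (backward direction `QR`),
triose isomerase `dTPI`, the pentose sub-pool exchange `dP_ex`, the
non-oxidative PPP (`dTKT1`, `dTAL`, `dTKT2`), the drains `Q4` (R5P) and
`Q11` (GAP), and optional unlabeled inputs into the S7P, pentose, triose
and F6P pools.  `d`-prefixed fluxes are net fluxes of reversible reactions;
each also carries a nonnegative exchange magnitude, with unidirectional
fluxes `forward = max(net, 0) + exchange` and
`backward = max(-net, 0) + exchange`.

Steady state imposes one linear balance per pool, `S v = 0`
(`stoichiometric_matrix()`).  Splitting the fluxes into an independent set
(`Z1`, `dQ2`, `dTAL` plus the active inputs) and a dependent set solved
from the square dependent block (`split_dependency()`) reduces the model to
2 free dimensions in the closed system, plus one per active input
(`permissible_space()`).  Only three dependent fluxes are sign-constrained
(`Z3`, `Q4`, `Q11` >= 0); their rows define the permissible polytope, from
which `sample_feasible()` draws uniformly by rejection from a bounding box
(net fluxes in [-300, 300], inputs in [0, 100] — a deliberately generous
superset of the biologically plausible range).  Choosing `Z3` as an
additional independent flux makes the dependent block singular (the G6P,
F6P and E4P balance rows become linearly dependent), which
`split_dependency()` reports as a non-invertible choice; this is why the
oxidative PPP, although the scientifically interesting control, cannot
serve as an independent coordinate.

Two structural choices were genuinely open and are resolved as follows.
The pentose pool is split into `XuP` (Ru5P+X5P lumped, the transketolase
donor) and `R5P`, joined by the exchange `dP_ex`; the co-eluting P5P
measurement is modeled as a mixture of the two sub-pool distributions,
weighted by sub-pool turnover by default (`p5p_weights = "flux"`), because
the composition of the chromatographically unresolved pool is not
observable.  The pentose input `P_Input` splits `pX = 2/3` into `XuP` and
`pR = 1/3` into `R5P`, the stoichiometric demand ratio of the two
transketolase steps; both are configurable.

# Carbon atom transitions

The atom maps (`carbon_transition_table()`) follow the classic
transketolase/transaldolase chemistry: all PPP carbon rearrangements touch
only the upper three carbons of the hexose frame, transketolase moves
two-carbon units (XuP C1–C2), transaldolase moves three-carbon units (S7P
C1–C3), and the oxidative step removes G6P C1.  For the trioses we number
DHAP in the orientation that aligns it with GAP (aldolase writes F6P
C1–C3 onto DHAP in reverse order), so that the triose isomerase map is the
identity.  This keeps the composite route chemically correct: glucose C1
and C6 both end on the phosphorylated triose carbon, and a label entering
via the trioses reaches the lower half (C4–C6) of resynthesized hexose.
The anchor property — with a pure `[4,5,6-13C]` tracer and no backward
condensation (`QR = 0`), the G6P C3–C6 fragment shows no M+1 and no M+4 —
holds under these maps and is asserted in the tests; it is the signature
used to exclude gluconeogenic transfer of lower-half to upper-half carbons.

# Simulating fragment CMDs

`simulate_cmds()` implements the elementary metabolite unit (EMU)
decomposition: starting from each fragment's carbon range it walks the atom
maps backward, collecting the minimal set of pool carbon subsets whose mass
distributions determine the targets.  EMUs of size k satisfy a linear
balance system whose inhomogeneous terms are either tracer distributions or
convolutions of strictly smaller EMUs, so the blocks are solved in
ascending size.  Condensation reactions (transketolase, transaldolase,
aldolase) are the convolution terms.  A fragment's CMD then is the EMU
distribution of its pool and carbon range (P5P: the sub-pool mixture).

As an independent check, `isotopomer_oracle()` tracks the full positional
isotopomer distribution of every pool (2^n states, 352 in total) and
iterates the steady-state balance to a fixed point.  Each pool distribution
is renormalized after every sweep: the balance map conserves mass only
exactly on the simplex, and the condensation terms amplify rounding drift
away from it, so the projection is required for numerical stability.  The
two simulators agree to 1e-8 over random feasible flux states, all three
tracers and the full fragment panel; this equivalence is the central
correctness test of the labeling code.  Flux states that leave a pool with
no outgoing flux (e.g. pure glycolysis with all PPP fluxes and exchanges at
zero) are rejected by both simulators with an explicit singularity/closed
loop error.  Exchange fluxes are bounded at 50 times `Z1` to keep the EMU
systems well-conditioned.

Tracer mixtures (`default_tracer_panel()`) model each labeled species with
independent per-position 13C probabilities: the isotopic purity (0.99, or
0.995 for `[4,5,6-13C]`) at labeled positions and the natural abundance
0.0107 elsewhere; the unlabeled half of each mixture and the unlabeled
network inputs carry natural abundance at every carbon.  Heteroatom
isotopes never enter the EMU layer: they are handled by the measurement
module.

# Measurement model

`nominal_mass()` and `fragment_panel()` reproduce the EtOx-TMS fragment
bookkeeping (metabolite, carbon range, formula, m/z).  Raw peak areas are
normalized (`normalize_areas()`) to mass isotopomer distributions (MIDs),
which still contain natural-isotope contributions of H, N, O, Si, P and the
derivatization carbons.  `correction_matrix()` builds the forward
convolution matrix from embedded IUPAC isotope abundances, and
`correct_to_cmd()` inverts it by nonnegative least squares — plain matrix
inversion produces negative fractions on noisy compositions.  Natural 13C
on the skeleton carbons is removed only for model-free evaluation
(`correct_carbon = TRUE`); flux-fit inputs keep it, because the simulator
includes natural 13C in its label definition.  Positional arithmetic
(`total_enrichment()`, `fractional_enrichment()`,
`complement_enrichment()`) implements the fragment-difference trick: when a
parent fragment and one cleavage product are measurable, the unmeasured
complement's enrichment is the difference of total enrichments — exactly
additive on simulated data, clipped at zero with a warning on noisy data.
`accuracy_check()` classifies fragments by the maximum absolute MID error:
optimal up to 0.8 mol%, acceptable up to 1.5 mol%, rejected beyond.

# Likelihood, priors and posterior sampling

Measured CMDs are compositions estimated from a finite number of ion
counts; drawing `NC` counts and normalizing induces negative correlation
between abundances.  The Dirichlet distribution with concentration
`NC * predicted` captures exactly this structure, with element variance
`Mi (1 - Mi) / (NC + 1)` (`dirichlet_variance()`).  `mfa_loglik()` floors
zero categories at 1e-6 (the density is undefined at exact zeros) and
renormalizes.  `NC` is per fragment — weak fragments such as the
full-skeleton G6P ion get their own precision — either user-supplied or
calibrated by `calibrate_precision()`, which iterates fits until the
theoretical variances match the observed residuals (the iteration diverges
to a cap on exact data, which is reported).

Priors are flat over the feasible region: uniform over the permissible
polytope for independent net fluxes and log-uniform on [1e-2, 5000] for
exchanges.  Sampling works in a reparameterized space — logit transforms
of the bounding box for net fluxes (with rejection of points violating the
`Z3, Q4, Q11 >= 0` constraints) and log transforms for exchanges.  Every
retained draw therefore satisfies the balance equations and nonnegativity
exactly by construction.

Two gradient-free backends are provided, both initialized at a posterior
mode found by screening feasible draws and polishing with BFGS:

* `sampler = "ensemble"` (default): an affine-invariant stretch-move
  ensemble.  Each "chain" is an independent ensemble of `2 npar + 4`
  walkers started around the mode; 10% of walker updates are
  prior-refresh moves on the exchange block so that directions the data
  leave flat are traversed instantly.  This backend is robust on the
  diffuse, curved posteriors produced by sparse fragment panels, where
  plain random-walk chains can stall and understate uncertainty.
* `sampler = "am"`: adaptive random-walk Metropolis (Haario-style
  covariance adaptation with block moves and the same prior-refresh
  kernel), cheaper per draw and adequate for well-identified fits.

Convergence is monitored by split-Rhat and an autocorrelation-based
effective sample size for every reported flux; `mfa_fit()` warns when any
split-Rhat exceeds 1.1.  Summaries (posterior mean, median, sd, central
68% and 95% intervals) are computed on the draws of each derived flux, not
by transforming summaries.  `pairwise_region()` returns the level-scaled
covariance ellipse of two fluxes and flags structurally degenerate pairs —
in the closed system the G6P balance forces `dGPI = Z1 - Z3`, so that pair
collapses to a segment with correlation -1.

# Synthetic data and design comparison

`generate_measurements()` draws one noisy CMD per tracer and fragment from
`Dirichlet(NC * CMD)` at a known truth.  The shipped default truth
(`default_truth()`) is a package convention, not a literature value: the
closed system plus an S7P input with `dQ2 = 85`, `dTAL = 5`,
`S_Input = 3` and moderate exchanges (GPI 50, TPI 50, P_ex 20, TKT 10,
TAL 10, condensation 10), chosen once as a realistic mixed
glycolysis/PPP state.  Default precisions are `NC = 5000`, reduced to 500
for the weak G6P full-skeleton ion.  `scenario_suite()` packages the
measurement-design comparisons: eight fragment scenarios (triose-only up
to the full 7-fragment panel, plus the variant in which the weak G6P ion
is assigned full precision) and seven tracer scenarios (singles, pairs,
complete panel).  `precision_report()` compares two designs by the squared
ratio of 95%-interval widths per flux, averaged over twelve configured
fluxes; the reference design scores exactly 1 against itself.

What the generator deliberately does not emulate: chromatographic
artifacts, co-elution beyond the P5P pool, detector saturation, drift
between replicate injections, and any deviation from isotopic steady
state.  Passing tests therefore demonstrate correctness of the model and
inference chain under the stated noise model, not robustness to real-data
pathologies outside it.

# Flux-table PCA

`pca_fluxes()` standardizes each flux column, computes SVD-based principal
components, varimax-rotates the retained loadings (variance shares are
reported from the unrotated solution, which is what "explained variance"
refers to), and also rescales the rotated loadings back to flux units.
All three loading variants are exposed because published tables do not
always state which one they print.  `jackknife_loadings()` recomputes the
solution leaving out one sample at a time, aligns replicates to the full
solution by maximal absolute congruence (with the sign convention that
each component's largest loading is positive), and flags a loading as
significant when its jackknife standard error is below half its absolute
value.

# Numerical choices and problem sizes

Tolerances: balance residuals 1e-9; EMU-vs-isotopomer agreement 1e-8
(oracle fixed-point tolerance 1e-13); natural-isotope round-trips 1e-8.
Ties and degenerate inputs: all-zero peak vectors, unknown elements,
negative exchanges, infeasible flux points and singular dependency choices
raise named errors rather than propagating NaNs.  The test-suite fits run
at reduced sampler sizes (tens of ensemble sweeps for the calibration-style
checks, ~50 replicate datasets at a 2-fragment design for the coverage
property); these sizes are the package's own choice of demonstration scale
and are deliberately small — production analyses should use the defaults
(2 chains, 1000 warmup, 1000 retained sweeps) and check the reported
split-Rhat and ESS.

# Known limitations

* Steady-state only; no isotopically nonstationary mode.
* The network family is fixed in shape (the eight upper-glucose pools);
  arbitrary genome-scale models and cofactor balancing are out of scope.
* The Dirichlet error model captures normalization-induced correlation
  only; correlations present before normalization (e.g. drifting source
  conditions) are not modeled.
* The 6PG and FBP proxy patterns are pass-through copies of the G6P and
  F6P skeletons by default (`derived_patterns()`); the triose-convolution
  alternative for FBP is provided but both are approximations for
  LC-MS-compatibility configurations.
* The ensemble sampler reports an optimistic ESS (walkers within an
  ensemble are not independent); split-Rhat across independent ensembles
  is the reliable diagnostic.
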