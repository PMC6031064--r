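---
title: "Methods: elastic-network dynamics and consensus stability prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-network dynamics and consensus stability prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(vibstab)
```

This vignette documents the models implemented in `vibstab`, the
assumptions behind them, the default parameter choices, and the numerical
and design decisions a user should understand before trusting the output.

## The harmonic model

All dynamics in this package derive from normal mode analysis (NMA) of a
coarse-grained elastic network: each residue is reduced to a site at its
C-alpha position, and the potential energy is a sum of harmonic terms whose
rest values are the input geometry. The central assumption is that the
crystallographic (or modelled) structure sits at a minimum of the energy
surface, so the Hessian of the potential fully determines small-amplitude
motion. This buys enormous speed — one dense eigendecomposition per
structure — at the cost of ignoring anharmonicity, solvent friction and
large conformational change. Empirically, low-frequency elastic-network
modes track crystallographic B-factors and collective motions well, which
is the regime this package targets.

Two network types are provided:

* **Uniform network (`build_anm_hessian`)** — springs of a single force
  constant `gamma` (default 1) connect every site pair within `cutoff`
  (default 15 Å). The 15 Å default is the conventional choice for C-alpha
  networks: large enough that the network is connected for globular folds,
  small enough that the contact topology still matters. The pair (i, j)
  contributes the 3×3 super-element `-gamma * r̂ r̂ᵀ`, and diagonal blocks
  are filled so each block row sums to zero, which enforces translational
  invariance exactly.

* **Sequence-dependent network (`build_encom_hessian`)** — a four-term
  potential along the C-alpha trace (stretch k = 100, three-site angle
  k = 20, four-site dihedral k = 1) plus long-range pairs for residues at
  least three apart in sequence. The long-range force constant is
  `epsilon` times the atom-type-weighted count of heavy-atom contacts
  within 4.5 Å between the two residues, with an 8×8 pharmacophore-class
  weight matrix that up-weights apolar packing, aromatic stacking,
  donor–acceptor pairs and salt bridges. Because contacts are counted over
  *all* heavy atoms, side-chain identity enters the model: truncating a
  leucine to alanine removes contacts and measurably softens the network,
  which is what makes mutation analysis possible at all. The bonded
  constants follow the usual stiff-to-soft ordering of covalent
  deformations (bond ≫ angle ≫ dihedral); their absolute scale only shifts
  entropies by a constant shared between wild type and mutant.

Every term is assembled as `k · ∇q ∇qᵀ` for an internal coordinate `q`
(distance, angle or dihedral). At the input geometry this is the exact
Hessian of `V = Σ k/2 (q − q₀)²`, so translational and rotational
invariance hold by construction rather than by numerical accident — the
test suite checks block-row sums and the rigid-motion null space to
round-off precision.

## Solving the modes

`solve_modes()` diagonalizes the mass-weighted Hessian
`M^{-1/2} H M^{-1/2}` with `eigen(symmetric = TRUE)`. Three numerical
choices matter:

* **Trivial-mode identification.** Rigid-body modes are those with
  eigenvalue below `1e-8 × λ_max`, with a geometric floor of 6 (5 when the
  sites are collinear, detected by a rank test on the centered
  coordinates). Disconnected networks legitimately have more than six
  near-zero modes; the builder warns and the count adapts.
* **Sign convention.** Eigenvector signs are arbitrary; we fix the
  largest-magnitude component positive so porcupine plots and trajectories
  are reproducible across platforms.
* **Symmetry guard.** The Hessian is verified symmetric to 1e-6 relative
  tolerance and symmetrized before the solve; asymmetric input is an
  error, not a silent fix.

## Vibrational entropy and the stability estimate

In the classical harmonic limit, each mode contributes
`-k_B ln(ν)` (plus a constant) to the entropy, with `ν = sqrt(λ)`.
`vibrational_entropy()` reports `S = -k_B Σ ln sqrt(λ)` over non-trivial
modes, dropping the additive constant — only *differences* between systems
with equal mode counts are meaningful, which `mutation_dynamics()`
enforces. The stability estimate is `ΔΔG_vib = -α · T · ΔΔS` at
T = 298.15 K, with the sign convention that positive ΔΔG is stabilizing.

Two deliberate design decisions:

* **Unit masses for mutation comparisons.** `mutation_dynamics()` defaults
  to `mass_scheme = "unit"` even though `extract_coarse_grain()` defaults
  to per-residue masses. With residue masses, a large-to-small
  substitution changes the mass matrix as well as the stiffness, and the
  mass term (which has nothing to do with the folded-state contact
  network) can dominate the entropy difference with the opposite sign.
  Unit masses isolate the contact-softening effect the estimate is meant
  to capture. Residue masses remain the default for plain fluctuation
  analysis, where they belong.
* **The calibration α is an open question.** The raw `-TΔΔS` is on the
  arbitrary energy scale set by the force constants; mapping it to
  kcal/mol of folding free energy requires a regression against measured
  values. We default to α = 1 and treat the scale as one feature among
  many for the consensus model, rather than pretending the elastic
  network alone is calibrated.

Mutant structures are modelled minimally (`build_mutant`): backbone and,
where shared, C-beta atoms are kept fixed and remaining side-chain atoms
are placed from idealized internal-coordinate templates. No repacking or
minimization is attempted — a known limitation that keeps the pipeline
deterministic and fast, and matches the harmonic assumption (the input is
taken as the minimum).

## Structural signatures and environment features

`cutoff_scan_signature()` counts heavy-atom pairs around a residue,
stratified by unordered pharmacophore-class pair (8 classes, 36 pairs) and
cumulative distance bins at 2, 4, 6, 8, 10 Å — a coarse histogram of the
local packing chemistry. Atoms carrying several classes contribute to
every combination; formal charges are counted once per charged group so
that, e.g., Asp→Lys changes the negative count by −1 and the positive
count by +1. Solvent accessibility uses an in-package Shrake–Rupley
implementation with deterministic golden-spiral sphere points (240 per
atom by default; accuracy improves smoothly with more points), normalized
by a Gly-X-Gly extended reference computed by the same algorithm so
systematic errors cancel. Residue depth is the mean distance of the
residue's heavy atoms beyond their own solvent-accessible radius from the
accessible surface. Secondary structure is a three-class φ/ψ-window
assignment — deterministic and adequate as a feature, not a replacement
for hydrogen-bond-based assignment.

## The consensus learner and evaluation protocol

`train_consensus()` fits a Random Forest (500 trees, `mtry = √p`,
`nodesize = 5`) to whatever numeric feature columns the table carries.
The protocol choices are the load-bearing part:

* **Reverse augmentation** (`augment_reverse`): ΔΔG is a state function,
  so each measured forward mutation implies the reverse mutation with
  negated value. Training on both halves counteracts the destabilizing
  skew of curated datasets.
* **Grouped splits** (`make_splits`): folds and train/blind splits operate
  on `group_key` (protein + chain + position), so a forward record, its
  reverse partner and any same-site records never straddle a fold —
  otherwise cross-validation leaks near-duplicates and flatters the
  metrics.
* **Trimmed metrics** (`evaluate_predictions`): alongside Pearson r and
  RMSE, the 10 % of records with the largest absolute error are dropped
  (stable tie-breaking) and the metrics recomputed, separating "bad on
  average" from "wrecked by outliers". `compare_methods()` applies the
  Fisher z-test, clamping |r| at 1 − 1e-12.

## Synthetic data: what it does and does not show

The package ships generators rather than fixtures. Their defaults are the
study conditions and were not tuned to outcomes:

* `make_synthetic_mutation_table()` (2648 records, 602 stabilizing, 131
  proteins) reproduces the *composition* of the standard curated benchmark
  — skewed, destabilization-heavy ΔΔG draws and realistic protein/site
  multiplicity — so the augmentation and split arithmetic can be exercised
  exactly. It does **not** provide real structures, so it cannot validate
  predictive accuracy on real mutations.
* `make_synthetic_feature_table()` (2000 rows, planted linear signal with
  coefficients 0.8/−0.5, noise σ = 0.2, 4 noise features) verifies that
  the learner recovers a recoverable signal (CV r ≥ 0.9) and, with
  permuted targets, reports none (|r| < 0.1). The planted signal is far
  cleaner than real ΔΔG data; headline literature correlations are not
  reproducible without the real dataset and structures, and the test suite
  says so rather than pretending otherwise.
* `make_toy_structure()` builds ideal helices, extended chains and packed
  clusters from internal-coordinate templates. Problem sizes in the tests
  (12–30 residues) are the package's own choice: large enough for
  non-trivial spectra, contacts and buried cores, small enough that the
  whole suite runs in minutes on one CPU.

## A worked example

```{r example}
helix <- make_toy_structure("ideal_helix", 12)
md <- mutation_dynamics(helix, parse_mutation("F5A", "A"))
md
```

Truncating a buried phenylalanine softens the local network, increases the
vibrational entropy of the mutant and is therefore flagged destabilizing —
the canonical behavior for a large-to-small core substitution.

```{r signature}
sig <- cutoff_scan_signature(helix, "A", 5)
length(sig)
sum(sig)
relative_solvent_accessibility(helix, "A", 5)
secondary_structure(helix, "A", 5)
```
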