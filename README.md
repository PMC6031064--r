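# vibstab

Coarse-grained normal-mode analysis of protein structures, vibrational
entropy differences between wild type and point mutants, graph-based
structural signatures, and a Random-Forest consensus predictor of the
change in folding free energy (ΔΔG) upon mutation.

## The science in one page

A folded protein near its native structure behaves, to first order, like a
network of harmonic springs. Replace each residue by a site at its C-alpha
atom, connect nearby sites by springs, and the 3N×3N Hessian of that
network decomposes motion into normal modes: eigenvectors (directions of
collective motion) with eigenvalues λ (stiffness). From the modes follow
the classic per-residue analyses — mean-square fluctuations
(`msf_i = Σ_k |a_{k,i}|²/λ_k`), motion cross-correlations, deformation
energies that separate rigidly moving regions from flexible hinges, and
porcupine vectors / PDB trajectories for visualizing individual modes.

Mutations enter through two channels:

1. **Vibrational entropy.** In the classical harmonic limit each mode
   contributes `-k_B ln sqrt(λ)` to the entropy. With a *sequence-dependent*
   network — long-range spring constants proportional to atom-type-weighted
   heavy-atom contact counts — replacing a large side chain by a small one
   removes contacts, softens the network, and changes the mode spectrum.
   The entropy difference ΔΔS_vib = S_mut − S_wt yields the stability
   estimate `ΔΔG_vib = −α·T·ΔΔS_vib` (T = 298.15 K; ΔΔG ≥ 0 means
   stabilizing throughout the package).
2. **Structural environment.** The mutated residue's surroundings are
   summarized by a cutoff-scanning signature (heavy-atom pair counts
   stratified by pharmacophore-class pair and cumulative distance bin),
   pharmacophore count changes of the substitution, relative solvent
   accessibility, residue depth and secondary structure.

A Random Forest consumes both channels. The training protocol implements
the standard safeguards for curated ΔΔG data: hypothetical reverse
mutations (swapped residues, negated ΔΔG — ΔΔG is a state function) to
counteract destabilization bias, grouped cross-validation so same-site
records never straddle folds, and outlier-trimmed Pearson/RMSE metrics
with Fisher z-tests for method comparison.

## Worked example

Build an ideal 12-residue helix, truncate the buried phenylalanine at
position 5 to alanine, and ask what the elastic network thinks:

```r
library(vibstab)

helix <- make_toy_structure("ideal_helix", 12)
md <- mutation_dynamics(helix, parse_mutation("F5A", "A"))
md
#> <mutation_dynamics> F5A (encom field)
#>   ddS_vib      = +0.001559 kcal/mol/K
#>   ENM ddG      = -0.4647 kcal/mol (destabilizing)
#>   MSF ratio    = 1.0940 at mutated site
```

Removing the phenyl ring deletes contacts, the network softens
(entropy up, fluctuations at the site up 9 %), and the substitution is
flagged destabilizing — the canonical result for a large-to-small core
mutation. Plain dynamics analysis of the wild type:

```r
cm <- extract_coarse_grain(helix)
nm <- solve_modes(build_anm_hessian(cm))
nm
#> <normal_modes> 36 modes (6 trivial), forcefield anm

head(mean_square_fluctuations(nm), 3)
#> # A tibble: 3 × 5
#>   chain resno icode resname   msf
#>   <chr> <int> <chr> <chr>   <dbl>
#> 1 A         1 ""    ALA      2.66
#> 2 A         2 ""    CYS      1.60
#> 3 A         3 ""    ASP      1.28
```

Chain termini fluctuate most, as they should. Environment features for
the mutated site:

```r
relative_solvent_accessibility(helix, "A", 5)
#> [1] 0.547347
secondary_structure(helix, "A", 5)
#> [1] "helix"
```

Train the consensus learner on a synthetic feature table with a planted
signal (the stand-in for real featurized mutation data):

```r
tbl <- make_synthetic_feature_table(n = 800, seed = 2)
model <- train_consensus(tbl, consensus_hyperparams(n_trees = 150), seed = 10)
model
#> <consensus_model> 6 features, 150 trees, trained on 800 rows
#>   10-fold CV: r = 0.966, RMSE = 0.285 kcal/mol

glance(model)
#> # A tibble: 1 × 7
#>   n_train n_features n_trees cv_pearson_r cv_rmse cv_pearson_r_trimmed
#>     <int>      <int>   <dbl>        <dbl>   <dbl>                <dbl>
#> 1     800          6     150        0.966   0.285                0.974
```

`tidy(model)` ranks feature importance, `autoplot(model, tbl)` draws the
out-of-fold scatter, and `predict_ddg(model, features)` serves new rows.
The same machinery is exposed as shell commands through
`inst/cli/vibstab.R` (`analyze`, `predict`, `batch`, `train`, `evaluate`),
and `cmd_train()` can featurize a real mutation table directly given a
directory of local PDB files.

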