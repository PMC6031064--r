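# Per-site normal-mode analyses and vibrational entropy.

kB_KCAL <- 0.0019872  # Boltzmann constant, kcal mol^-1 K^-1
T_REF <- 298.15       # reference temperature, K

nontrivial_indices <- function(modes, n_modes = NULL) {
  idx <- (modes$n_trivial + 1L):length(modes$values)
  if (!is.null(n_modes)) {
    if (n_modes > length(idx)) {
      warning(sprintf("requested %d modes but only %d non-trivial available; clipped",
                      n_modes, length(idx)))
      n_modes <- length(idx)
    }
    idx <- idx[seq_len(n_modes)]
  }
  idx
}

site_keys <- function(modes) {
  modes$model$sites[, c("chain", "resno", "icode", "resname")]
}

#' Per-site mean-square fluctuations
#'
#' `msf_i = sum_k (1 / lambda_k) * |a_k,i|^2` over the selected non-trivial
#' modes, where `a_k` is the Cartesian (un-mass-weighted) displacement field
#' of mode k. Units are Angstrom^2 on the arbitrary energy scale set by the
#' force constants (kB*T factors are omitted as a shared constant).
#'
#' @param modes A `normal_modes`.
#' @param n_modes Number of lowest non-trivial modes to include (default all).
#' @return Tibble: `chain`, `resno`, `icode`, `resname`, `msf`.
#' @export
mean_square_fluctuations <- function(modes, n_modes = NULL) {
  idx <- nontrivial_indices(modes, n_modes)
  n <- nrow(modes$model$sites)
  msf <- numeric(n)
  for (k in idx) {
    a <- mode_displacement(modes, k)
    msf <- msf + rowSums(a^2) / modes$values[k]
  }
  dplyr::bind_cols(site_keys(modes), tibble::tibble(msf = msf))
}

#' Residue motion cross-correlation matrix
#'
#' `C_ij = cov_ij / sqrt(cov_ii * cov_jj)` with
#' `cov_ij = sum_k (1 / lambda_k) * (a_k,i . a_k,j)` over the selected
#' non-trivial modes. Sites with zero variance yield NA rows/columns.
#'
#' @inheritParams mean_square_fluctuations
#' @return N x N numeric matrix, symmetric with unit diagonal.
#' @export
cross_correlation <- function(modes, n_modes = NULL) {
  idx <- nontrivial_indices(modes, n_modes)
  n <- nrow(modes$model$sites)
  cov <- matrix(0, n, n)
  for (k in idx) {
    a <- mode_displacement(modes, k)
    cov <- cov + (a %*% t(a)) / modes$values[k]
  }
  v <- diag(cov)
  zero <- v <= 0
  if (any(zero)) warning(sprintf("%d site(s) with zero variance", sum(zero)))
  denom <- sqrt(pmax(v, .Machine$double.eps))
  C <- cov / (denom %o% denom)
  C[zero, ] <- NA_real_
  C[, zero] <- NA_real_
  diag(C)[!zero] <- 1
  C
}

#' Per-site deformation energy of a displacement field
#'
#' Raw (un-normalized) elastic energy stored in the springs when sites move
#' along `displacement`: each spring contributes
#' `1/2 * k * (length change along the displacement)^2`, split half to each
#' endpoint.
#'
#' @param hessian An `enm_hessian` (its spring list is used).
#' @param displacement n x 3 matrix of site displacements.
#' @return Numeric vector of per-site energies.
#' @export
deformation_energy_vector <- function(hessian, displacement) {
  sites <- hessian$model$sites
  displacement <- as.matrix(displacement)
  if (nrow(displacement) != nrow(sites) || ncol(displacement) != 3) {
    stop("displacement dimension mismatch")
  }
  xyz <- coarse_xyz(hessian$model)
  e <- numeric(nrow(sites))
  sp <- hessian$springs
  for (p in seq_len(nrow(sp))) {
    i <- sp$i[p]; j <- sp$j[p]
    rhat <- unit(xyz[j, ] - xyz[i, ])
    dl <- sum((displacement[j, ] - displacement[i, ]) * rhat)
    w <- 0.5 * sp$force_constant[p] * dl^2
    e[i] <- e[i] + w / 2
    e[j] <- e[j] + w / 2
  }
  e
}

#' Per-site deformation energy of one normal mode
#'
#' Spring-by-spring elastic energy of the chosen non-trivial mode, normalized
#' to sum to 1 (a relative profile: low values mark rigidly moving regions).
#'
#' @param modes A `normal_modes`.
#' @param hessian The `enm_hessian` the modes were solved from.
#' @param mode_index Absolute mode index; must address a non-trivial mode.
#' @param normalize Normalize to sum 1 (default `TRUE`).
#' @return Tibble: site keys plus `deformation`.
#' @export
deformation_energy <- function(modes, hessian, mode_index,
                               normalize = TRUE) {
  if (mode_index <= modes$n_trivial) {
    stop(sprintf("mode %d is trivial (rigid-body); first non-trivial is %d",
                 mode_index, modes$n_trivial + 1L))
  }
  if (mode_index > length(modes$values)) stop("mode index out of range")
  disp <- mode_displacement(modes, mode_index)
  e <- deformation_energy_vector(hessian, disp)
  if (normalize) {
    tot <- sum(e)
    if (tot > 0) e <- e / tot
  }
  dplyr::bind_cols(site_keys(modes), tibble::tibble(deformation = e))
}

#' Porcupine vectors for one mode
#'
#' Un-mass-weighted displacement of the chosen mode, scaled so the maximum
#' vector norm equals `scale`. Direction follows the package eigenvector sign
#' convention (largest-magnitude mass-weighted component positive).
#'
#' @param modes A `normal_modes`.
#' @param mode_index Absolute mode index; default the first non-trivial mode.
#' @param scale Maximum arrow length in Angstrom, default 1.
#' @return Tibble: site keys plus `dx`, `dy`, `dz`.
#' @export
porcupine_vectors <- function(modes, mode_index = first_nontrivial_mode(modes),
                              scale = 1.0) {
  if (mode_index < 1 || mode_index > length(modes$values)) {
    stop("mode index out of range")
  }
  disp <- mode_displacement(modes, mode_index)
  norms <- sqrt(rowSums(disp^2))
  if (max(norms) > 0) disp <- disp * (scale / max(norms))
  dplyr::bind_cols(site_keys(modes),
                   tibble::tibble(dx = disp[, 1], dy = disp[, 2], dz = disp[, 3]))
}

#' Vibrational entropy of a normal-mode set
#'
#' Classical harmonic-oscillator limit `S = -kB * sum_k ln(nu_k)` over
#' non-trivial modes, `nu_k = sqrt(lambda_k)`,
#' `kB = 0.0019872 kcal mol^-1 K^-1`. The additive constant shared between
#' systems with equal mode counts is dropped, so only differences between
#' such systems are meaningful.
#'
#' @param modes A `normal_modes`.
#' @return List with `s_vib` (kcal mol^-1 K^-1, up to a shared constant) and
#'   `n_modes_used`.
#' @export
vibrational_entropy <- function(modes) {
  idx <- nontrivial_indices(modes)
  lam <- modes$values[idx]
  if (any(lam <= 0)) {
    stop("non-positive eigenvalue among non-trivial modes; check trivial-mode classification")
  }
  s <- -kB_KCAL * sum(log(sqrt(lam)))
  list(s_vib = s, n_modes_used = length(idx))
}

build_field_hessian <- function(structure, model, forcefield, anm_cutoff,
                                anm_gamma, encom_parameters) {
  if (forcefield == "anm") build_anm_hessian(model, anm_cutoff, anm_gamma)
  else build_encom_hessian(structure, model, encom_parameters)
}

#' Effect of a point mutation on vibrational entropy and stability
#'
#' Builds (or accepts) the mutant structure, constructs wild-type and mutant
#' Hessians with identical parameters, solves both eigenproblems and returns
#' the vibrational entropy difference
#' `dds_vib = S_vib(mutant) - S_vib(wild-type)` in kcal mol^-1 K^-1, the
#' elastic-network stability estimate `enm_ddg = -alpha * T * dds_vib`
#' (kcal/mol; positive = stabilizing, T = 298.15 K, calibration `alpha`
#' default 1), and the mutant/wild-type fluctuation ratio at the mutated
#' site.
#'
#' @param wt Wild-type `protein_structure`.
#' @param mutation A `mutation_spec`.
#' @param forcefield `"encom"` (default; sequence-dependent, the field that
#'   senses side-chain identity) or `"anm"`.
#' @param mut Optional user-supplied mutant structure; built by
#'   [build_mutant()] when `NULL`.
#' @param alpha Calibration factor between -T*ddS and the ddG contribution.
#' @param mass_scheme Passed to [extract_coarse_grain()]; default `"unit"`
#'   so the entropy difference reflects only the stiffness (contact) change
#'   of the substitution, not the residue mass change.
#' @param anm_cutoff,anm_gamma ANM parameters.
#' @param encom_parameters Parameters from [encom_params()].
#' @return A `mutation_dynamics` list: `dds_vib`, `enm_ddg`,
#'   `msf_ratio_site`, `s_wt`, `s_mut`, `n_modes_used`, `mutation`.
#' @export
mutation_dynamics <- function(wt, mutation, forcefield = c("encom", "anm"),
                              mut = NULL, alpha = 1,
                              mass_scheme = "unit",
                              anm_cutoff = 15.0, anm_gamma = 1.0,
                              encom_parameters = encom_params()) {
  forcefield <- match.arg(forcefield)
  if (is.null(mut)) mut <- build_mutant(wt, mutation)
  cm_wt <- extract_coarse_grain(wt, mass_scheme = mass_scheme)
  cm_mut <- extract_coarse_grain(mut, mass_scheme = mass_scheme)
  if (nrow(cm_wt$sites) != nrow(cm_mut$sites)) {
    stop("wild-type and mutant site counts differ; mutation must not add or remove residues")
  }
  h_wt <- build_field_hessian(wt, cm_wt, forcefield, anm_cutoff, anm_gamma,
                              encom_parameters)
  h_mut <- build_field_hessian(mut, cm_mut, forcefield, anm_cutoff, anm_gamma,
                               encom_parameters)
  m_wt <- solve_modes(h_wt)
  m_mut <- solve_modes(h_mut)
  s_wt <- vibrational_entropy(m_wt)
  s_mut <- vibrational_entropy(m_mut)
  if (s_wt$n_modes_used != s_mut$n_modes_used) {
    stop("wild-type and mutant non-trivial mode counts differ; entropies not comparable")
  }
  dds <- s_mut$s_vib - s_wt$s_vib
  site_idx <- which(cm_wt$sites$chain == mutation$chain &
                      cm_wt$sites$resno == mutation$resno &
                      cm_wt$sites$icode == mutation$icode)
  if (length(site_idx) != 1) stop("mutated site not present in coarse model")
  msf_wt <- mean_square_fluctuations(m_wt)$msf[site_idx]
  msf_mut <- mean_square_fluctuations(m_mut)$msf[site_idx]
  structure(list(dds_vib = dds, enm_ddg = -alpha * T_REF * dds,
                 msf_ratio_site = msf_mut / msf_wt,
                 s_wt = s_wt$s_vib, s_mut = s_mut$s_vib,
                 n_modes_used = s_wt$n_modes_used,
                 mutation = mutation, forcefield = forcefield),
            class = "mutation_dynamics")
}

#' @export
print.mutation_dynamics <- function(x, ...) {
  cat(sprintf("<mutation_dynamics> %s (%s field)\n", format(x$mutation),
              x$forcefield))
  cat(sprintf("  ddS_vib      = %+.6f kcal/mol/K\n", x$dds_vib))
  cat(sprintf("  ENM ddG      = %+.4f kcal/mol (%s)\n", x$enm_ddg,
              classify_stability(x$enm_ddg)))
  cat(sprintf("  MSF ratio    = %.4f at mutated site\n", x$msf_ratio_site))
  invisible(x)
}
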