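# Elastic-network Hessians and the normal-mode eigenproblem.
#
# Both builders assemble the 3N x 3N stiffness matrix as a sum over potential
# terms of k * grad(q) %*% t(grad(q)), where q is an internal coordinate
# (distance, angle or dihedral) whose rest value is the input geometry. At
# equilibrium this is the exact Hessian of V = sum k/2 (q - q0)^2, and it
# guarantees translational/rotational invariance by construction.

new_hessian <- function(matrix, springs, model, forcefield, notes = character()) {
  structure(list(matrix = matrix, springs = springs, model = model,
                 forcefield = forcefield, notes = notes),
            class = "enm_hessian")
}

#' @export
print.enm_hessian <- function(x, ...) {
  cat(sprintf("<enm_hessian> %s, %d sites, %d springs\n", x$forcefield,
              nrow(x$model$sites), nrow(x$springs)))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# rank-1 accumulation of one pair term k * g g^T restricted to sites i, j
add_pair_term <- function(H, i, j, rhat, k) {
  blk <- k * (rhat %o% rhat)
  ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
  H[ii, jj] <- H[ii, jj] - blk
  H[jj, ii] <- H[jj, ii] - blk
  H[ii, ii] <- H[ii, ii] + blk
  H[jj, jj] <- H[jj, jj] + blk
  H
}

# general multi-site term: grads is a list site_index -> 3-vector dq/dr_site
add_generic_term <- function(H, grads, k) {
  idx <- as.integer(names(grads))
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      ia <- (3 * idx[a] - 2):(3 * idx[a])
      ib <- (3 * idx[b] - 2):(3 * idx[b])
      H[ia, ib] <- H[ia, ib] + k * (grads[[a]] %o% grads[[b]])
    }
  }
  H
}

network_connected <- function(n, springs) {
  if (n <= 1) return(TRUE)
  if (nrow(springs) == 0) return(FALSE)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- c(springs$j[springs$i == v], springs$i[springs$j == v])
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Build a cutoff-based anisotropic-network Hessian
#'
#' Springs of uniform force constant `gamma` connect every site pair within
#' `cutoff`; the off-diagonal 3x3 block of pair (i, j) is
#' `-gamma * rhat %*% t(rhat)` and diagonal blocks make each block row sum to
#' zero.
#'
#' @param model A `coarse_model`.
#' @param cutoff Spring cutoff distance in Angstrom, default 15.
#' @param gamma Uniform spring force constant, default 1 (sets the energy
#'   scale; kcal mol^-1 A^-2 nominally).
#' @return An `enm_hessian`.
#' @export
build_anm_hessian <- function(model, cutoff = 15.0, gamma = 1.0) {
  stopifnot(cutoff > 0, gamma > 0)
  xyz <- coarse_xyz(model)
  n <- nrow(xyz)
  if (n < 2) stop("need >= 2 sites")
  H <- matrix(0, 3 * n, 3 * n)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                            rest_length = d[pairs],
                            force_constant = gamma)
  for (p in seq_len(nrow(springs))) {
    i <- springs$i[p]; j <- springs$j[p]
    rhat <- unit(xyz[j, ] - xyz[i, ])
    H <- add_pair_term(H, i, j, rhat, gamma)
  }
  notes <- character()
  if (!network_connected(n, springs)) {
    notes <- sprintf("network disconnected at cutoff %.1f A", cutoff)
    warning(notes)
  }
  new_hessian(H, springs, model, "anm", notes)
}

#' Default parameters for the sequence-dependent Hessian
#'
#' Bonded force constants follow the generalized-spring-tensor convention
#' (stretch 100, angle 20, dihedral 1 on the overall energy scale set by
#' `epsilon`); the long-range constant of a residue pair is `epsilon` times
#' the atom-type-weighted count of heavy-atom contacts within `contact_dist`.
#' The 8x8 interaction weight matrix is indexed by pharmacophore class and
#' favors apolar-apolar, aromatic stacking, donor-acceptor and opposite
#' charge pairings.
#'
#' @param k_bond,k_angle,k_dihedral Bonded-term force constants.
#' @param epsilon Long-range energy scale.
#' @param contact_dist Heavy-atom contact distance in Angstrom, default 4.5.
#' @param weights Optional 8x8 symmetric matrix with dimnames
#'   `pharmacophore_classes`.
#' @return A list of parameters for [build_encom_hessian()].
#' @export
encom_params <- function(k_bond = 100, k_angle = 20, k_dihedral = 1,
                         epsilon = 1, contact_dist = 4.5, weights = NULL) {
  if (is.null(weights)) {
    k <- length(pharmacophore_classes)
    weights <- matrix(1, k, k,
                      dimnames = list(pharmacophore_classes, pharmacophore_classes))
    weights["hydrophobic", "hydrophobic"] <- 2
    weights["aromatic", "aromatic"] <- 2
    weights["sulfur", "sulfur"] <- 2
    weights["donor", "acceptor"] <- weights["acceptor", "donor"] <- 3
    weights["positive", "negative"] <- weights["negative", "positive"] <- 3
  }
  stopifnot(isTRUE(all.equal(weights, t(weights))))
  list(k_bond = k_bond, k_angle = k_angle, k_dihedral = k_dihedral,
       epsilon = epsilon, contact_dist = contact_dist, weights = weights)
}

# primary pharmacophore class of every heavy atom (first class in the lookup)
atom_primary_class <- function(atoms) {
  vapply(seq_len(nrow(atoms)),
         function(i) pharma_lookup(atoms$resname[i], atoms$name[i])[1],
         character(1))
}

#' Atom-type-weighted heavy-atom contact strengths between residue pairs
#' @keywords internal
residue_contact_weights <- function(structure, model, params) {
  sites <- model$sites
  atoms <- structure$atoms[structure$atoms$element != "H", ]
  site_key <- paste(sites$chain, sites$resno, sites$icode)
  atom_site <- match(paste(atoms$chain, atoms$resno, atoms$icode), site_key)
  keep <- !is.na(atom_site)
  atoms <- atoms[keep, ]; atom_site <- atom_site[keep]
  cls <- atom_primary_class(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(sites)
  W <- matrix(0, n, n)
  d <- as.matrix(stats::dist(xyz))
  contact <- which(upper.tri(d) & d <= params$contact_dist, arr.ind = TRUE)
  for (p in seq_len(nrow(contact))) {
    a <- contact[p, 1]; b <- contact[p, 2]
    si <- atom_site[a]; sj <- atom_site[b]
    if (si == sj) next
    w <- params$weights[cls[a], cls[b]]
    W[si, sj] <- W[si, sj] + w
    W[sj, si] <- W[sj, si] + w
  }
  W
}

#' Build a sequence-dependent elastic-network Hessian
#'
#' Four-term coarse-grained potential: harmonic stretch between consecutive
#' C-alpha sites, harmonic angle over site triples, harmonic dihedral over
#' site quadruples (all along the chain trace, rest values at the input
#' geometry), plus a long-range harmonic pair term for residues at least
#' three apart in sequence whose force constant is `epsilon` times the
#' atom-type-weighted count of heavy-atom contacts between the two residues.
#' Side-chain identity therefore enters through the contact term: mutations
#' that remove heavy atoms soften the network.
#'
#' @param structure All-atom `protein_structure` consistent with `model`.
#' @param model A `coarse_model` extracted from `structure`.
#' @param params Parameter list from [encom_params()].
#' @return An `enm_hessian`.
#' @export
build_encom_hessian <- function(structure, model, params = encom_params()) {
  sites <- model$sites
  xyz <- coarse_xyz(model)
  n <- nrow(xyz)
  if (n < 2) stop("need >= 2 sites")
  H <- matrix(0, 3 * n, 3 * n)
  springs <- list()
  chain_of <- sites$chain

  # stretch i,i+1
  if (params$k_bond > 0) {
    for (i in seq_len(n - 1)) {
      if (chain_of[i] != chain_of[i + 1]) next
      r <- xyz[i + 1, ] - xyz[i, ]
      H <- add_pair_term(H, i, i + 1, unit(r), params$k_bond)
      springs[[length(springs) + 1]] <- tibble::tibble(
        i = i, j = i + 1, rest_length = vnorm(r),
        force_constant = params$k_bond)
    }
  }
  # angle i,i+1,i+2
  if (params$k_angle > 0 && n >= 3) {
    for (i in seq_len(n - 2)) {
      if (length(unique(chain_of[i:(i + 2)])) > 1) next
      A <- xyz[i, ]; B <- xyz[i + 1, ]; C <- xyz[i + 2, ]
      u <- A - B; v <- C - B
      a <- vnorm(u); b <- vnorm(v)
      ct <- sum(u * v) / (a * b)
      st <- sqrt(max(1e-12, 1 - ct^2))
      gA <- (ct * u / a - v / b) / (a * st)
      gC <- (ct * v / b - u / a) / (b * st)
      grads <- list(gA, -(gA + gC), gC)
      names(grads) <- c(i, i + 1, i + 2)
      H <- add_generic_term(H, grads, params$k_angle)
    }
  }
  # dihedral i..i+3
  if (params$k_dihedral > 0 && n >= 4) {
    for (i in seq_len(n - 3)) {
      if (length(unique(chain_of[i:(i + 3)])) > 1) next
      p <- xyz[i:(i + 3), ]
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
      n1sq <- sum(n1^2); n2sq <- sum(n2^2); b2n <- vnorm(b2)
      if (n1sq < 1e-10 || n2sq < 1e-10) next
      gi <- -b2n * n1 / n1sq
      gl <- b2n * n2 / n2sq
      gj <- (sum(b1 * b2) / b2n^2 - 1) * gi - (sum(b3 * b2) / b2n^2) * gl
      gk <- (sum(b3 * b2) / b2n^2 - 1) * gl - (sum(b1 * b2) / b2n^2) * gi
      grads <- list(gi, gj, gk, gl)
      names(grads) <- i:(i + 3)
      H <- add_generic_term(H, grads, params$k_dihedral)
    }
  }
  # long-range contact-weighted pairs, |i - j| >= 3
  W <- residue_contact_weights(structure, model, params)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (chain_of[i] == chain_of[j] && abs(i - j) < 3) next
      if (W[i, j] <= 0) next
      k <- params$epsilon * W[i, j]
      r <- xyz[j, ] - xyz[i, ]
      H <- add_pair_term(H, i, j, unit(r), k)
      springs[[length(springs) + 1]] <- tibble::tibble(
        i = i, j = j, rest_length = vnorm(r), force_constant = k)
    }
  }
  springs <- if (length(springs)) dplyr::bind_rows(springs) else
    tibble::tibble(i = integer(), j = integer(),
                   rest_length = numeric(), force_constant = numeric())
  new_hessian(H, springs, model, "encom")
}

#' Build a Hessian with a named forcefield
#'
#' Convenience dispatcher over the forcefield registry `{anm, encom}`.
#'
#' @param structure A `protein_structure`.
#' @param model Optional pre-built `coarse_model` (extracted if `NULL`).
#' @param forcefield `"anm"` or `"encom"`.
#' @param ... Passed to the underlying builder.
#' @return An `enm_hessian`.
#' @export
build_hessian <- function(structure, model = NULL,
                          forcefield = c("anm", "encom"), ...) {
  forcefield <- match.arg(forcefield)
  if (is.null(model)) model <- extract_coarse_grain(structure)
  if (forcefield == "anm") build_anm_hessian(model, ...)
  else build_encom_hessian(structure, model, ...)
}

#' Solve the normal-mode eigenproblem of an elastic-network Hessian
#'
#' With mass weighting on (default) the symmetric eigenproblem of
#' `M^-1/2 H M^-1/2` is solved; eigenvalues are returned ascending and
#' eigenvectors are orthonormal in mass-weighted coordinates. Trivial
#' (rigid-body) modes are identified by a relative eigenvalue threshold
#' combined with the geometric floor of 6 (5 for collinear site sets).
#' Eigenvector signs are fixed so the largest-magnitude component is
#' positive, making downstream mode outputs reproducible.
#'
#' @param hessian An `enm_hessian`.
#' @param mass_weighting Use per-site masses (default `TRUE`).
#' @param trivial_tol Relative eigenvalue threshold for rigid-body modes,
#'   default 1e-8.
#' @return A `normal_modes`: eigenvalues, eigenvector matrix (columns, in
#'   mass-weighted coordinates), `n_trivial`, per-site masses, frequencies of
#'   non-trivial modes (`sqrt(lambda)`), and the coarse model.
#' @export
solve_modes <- function(hessian, mass_weighting = TRUE, trivial_tol = 1e-8) {
  H <- hessian$matrix
  scale_ref <- max(abs(H))
  if (scale_ref == 0) scale_ref <- 1
  if (max(abs(H - t(H))) > 1e-6 * scale_ref) {
    stop("Hessian is not symmetric within tolerance")
  }
  H <- (H + t(H)) / 2
  sites <- hessian$model$sites
  masses <- if (mass_weighting) sites$mass else rep(1, nrow(sites))
  inv_sqrt_m <- rep(1 / sqrt(masses), each = 3)
  Hm <- H * (inv_sqrt_m %o% inv_sqrt_m)
  eig <- eigen(Hm, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  vmax <- max(values)
  if (vmax <= 0) stop("Hessian has no positive eigenvalues")
  if (min(values) < -1e-6 * vmax) {
    stop("Hessian has significantly negative eigenvalues")
  }
  values[values < 0] <- 0
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    comp <- vectors[, k]
    if (comp[which.max(abs(comp))] < 0) vectors[, k] <- -comp
  }
  xyz <- coarse_xyz(hessian$model)
  centered <- sweep(xyz, 2, colMeans(xyz))
  collinear <- qr(centered, tol = 1e-7)$rank <= 1
  floor_n <- if (collinear) 5L else 6L
  n_below <- sum(values <= trivial_tol * vmax)
  n_trivial <- max(floor_n, n_below)
  n_trivial <- min(n_trivial, length(values) - 1L)
  freqs <- sqrt(values[(n_trivial + 1):length(values)])
  structure(list(values = values, vectors = vectors,
                 n_trivial = as.integer(n_trivial), masses = masses,
                 frequencies = freqs, mass_weighting = mass_weighting,
                 model = hessian$model, forcefield = hessian$forcefield),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes> %d modes (%d trivial), forcefield %s\n",
              length(x$values), x$n_trivial, x$forcefield))
  invisible(x)
}

#' Number of trivial (rigid-body) modes
#' @param modes A `normal_modes`.
#' @return Integer count (6 for connected non-collinear networks, 5 for
#'   collinear ones, more for disconnected networks).
#' @export
count_trivial_modes <- function(modes) modes$n_trivial

#' Cartesian displacement field of one mode
#'
#' Un-mass-weights eigenvector `mode_index` (absolute index into the
#' ascending eigenvalue order) and reshapes it to an n x 3 matrix.
#' @param modes A `normal_modes`.
#' @param mode_index Absolute mode index (1-based over all modes).
#' @return n x 3 numeric matrix.
#' @export
mode_displacement <- function(modes, mode_index) {
  v <- modes$vectors[, mode_index] * rep(1 / sqrt(modes$masses), each = 3)
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Index of the first non-trivial mode
#' @param modes A `normal_modes`.
#' @export
first_nontrivial_mode <- function(modes) modes$n_trivial + 1L
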