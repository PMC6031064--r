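# Elastic-network Hessians and the eigensolver, checked against analytic
# cases and naive brute-force oracles.

two_site_model <- function(d = 5, mass_scheme = "unit") {
  txt <- paste(
    sprintf("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N"),
    sprintf("ATOM      2  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"),
    sprintf("ATOM      3  N   GLY A   2      %7.3f   0.000   0.000  1.00  0.00           N", d),
    sprintf("ATOM      4  CA  GLY A   2      %7.3f   0.000   0.000  1.00  0.00           C", d),
    "END", sep = "\n")
  extract_coarse_grain(read_structure(txt), mass_scheme = mass_scheme)
}

test_that("ANM super-element matches the analytic two-site block", {
  cm <- two_site_model(5)
  hess <- build_anm_hessian(cm, cutoff = 15, gamma = 1)
  off <- hess$matrix[1:3, 4:6]
  expect_equal(off, -diag(c(1, 0, 0)), tolerance = 1e-12)
  expect_equal(hess$matrix[1:3, 1:3], diag(c(1, 0, 0)), tolerance = 1e-12)
  expect_equal(nrow(hess$springs), 1)
})

test_that("sites beyond the cutoff get no springs", {
  cm <- two_site_model(20)
  expect_warning(hess <- build_anm_hessian(cm, cutoff = 15), "disconnected")
  expect_equal(nrow(hess$springs), 0)
  expect_true(all(hess$matrix == 0))
})

test_that("production ANM Hessian equals the naive double-loop oracle", {
  cl <- make_toy_structure("cluster", 30, seed = 4)
  cm <- extract_coarse_grain(cl)
  hess <- build_anm_hessian(cm, cutoff = 12, gamma = 0.7)
  H_oracle <- oracle_anm_hessian(vibstab:::coarse_xyz(cm), 12, 0.7)
  expect_lt(max(abs(hess$matrix - H_oracle)), 1e-10)
})

test_that("Hessian invariants hold: symmetry, zero block-row sums, PSD diagonal blocks", {
  cl <- make_toy_structure("cluster", 25, seed = 9)
  cm <- extract_coarse_grain(cl)
  for (hess in list(build_anm_hessian(cm, 12),
                    build_encom_hessian(cl, cm))) {
    H <- hess$matrix
    expect_lt(max(abs(H - t(H))), 1e-8 * max(abs(H)))
    n <- n_sites(cm)
    for (i in seq_len(n)) {
      ii <- (3 * i - 2):(3 * i)
      block_sum <- matrix(0, 3, 3)
      for (j in seq_len(n)) block_sum <- block_sum + H[ii, (3 * j - 2):(3 * j)]
      expect_lt(max(abs(block_sum)), 1e-8 * max(abs(H)))
      expect_gt(min(eigen(H[ii, ii], symmetric = TRUE,
                          only.values = TRUE)$values), -1e-8 * max(abs(H)))
    }
  }
})

test_that("a diatomic has one non-trivial mode with lambda = 2 gamma / m", {
  cm <- two_site_model(5, mass_scheme = "unit")
  nm <- solve_modes(build_anm_hessian(cm, cutoff = 15, gamma = 1))
  expect_equal(count_trivial_modes(nm), 5L)
  expect_equal(nm$values[6], 2, tolerance = 1e-12)
  # scaling gamma and mass: lambda = 2 gamma / m
  nm2 <- solve_modes(build_anm_hessian(cm, cutoff = 15, gamma = 3))
  expect_equal(nm2$values[6], 6, tolerance = 1e-12)
})

test_that("a connected non-collinear network has exactly six trivial modes", {
  cl <- make_toy_structure("cluster", 12, seed = 2)
  nm <- solve_modes(build_anm_hessian(extract_coarse_grain(cl), cutoff = 15))
  expect_equal(count_trivial_modes(nm), 6L)
  expect_equal(length(nm$frequencies), 3 * 12 - 6)
})

test_that("a disconnected two-component network has more than six trivial modes", {
  h <- make_toy_structure("ideal_helix", 16)
  at <- h$atoms
  at$x[at$resno > 8] <- at$x[at$resno > 8] + 300
  far <- vibstab:::new_structure(at)
  cm <- extract_coarse_grain(far)
  expect_warning(hess <- build_anm_hessian(cm, cutoff = 15), "disconnected")
  nm <- solve_modes(hess)
  expect_equal(count_trivial_modes(nm), 12L)
})

test_that("eigensolver matches dense brute-force diagonalization on small networks", {
  cl <- make_toy_structure("cluster", 25, seed = 6)
  cm <- extract_coarse_grain(cl)
  hess <- build_anm_hessian(cm, cutoff = 12)
  nm <- solve_modes(hess)
  oe <- oracle_eigen(hess$matrix, cm$sites$mass)
  expect_lt(max(abs(nm$values - oe$values)), 1e-8 * max(nm$values))
  # subspace overlap per non-degenerate non-trivial mode
  vals <- nm$values
  for (k in (nm$n_trivial + 1):length(vals)) {
    gap_ok <- (k == 1 || vals[k] - vals[k - 1] > 1e-6 * max(vals)) &&
      (k == length(vals) || vals[k + 1] - vals[k] > 1e-6 * max(vals))
    if (!gap_ok) next
    overlap <- abs(sum(nm$vectors[, k] * oe$vectors[, k]))
    expect_gt(overlap, 1 - 1e-6)
  }
  # eigenvector orthonormality
  G <- t(nm$vectors) %*% nm$vectors
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-6)
})

test_that("the spectrum is invariant under rigid rotation and translation", {
  cl <- make_toy_structure("cluster", 20, seed = 8)
  cm <- extract_coarse_grain(cl)
  nm <- solve_modes(build_anm_hessian(cm, cutoff = 12))
  moved <- rigid_copy(cl, seed = 21)
  cm2 <- extract_coarse_grain(moved)
  nm2 <- solve_modes(build_anm_hessian(cm2, cutoff = 12))
  expect_lt(max(abs(nm$values - nm2$values)), 1e-8 * max(nm$values))
})

test_that("eigenvalues scale exactly linearly with the force constant", {
  cl <- make_toy_structure("cluster", 15, seed = 5)
  cm <- extract_coarse_grain(cl)
  nm1 <- solve_modes(build_anm_hessian(cm, cutoff = 12, gamma = 1))
  nm4 <- solve_modes(build_anm_hessian(cm, cutoff = 12, gamma = 4))
  nt <- nm1$n_trivial
  idx <- (nt + 1):length(nm1$values)
  expect_lt(max(abs(nm4$values[idx] - 4 * nm1$values[idx]) / nm4$values[idx]),
            1e-10)
})

test_that("non-symmetric input is rejected", {
  cm <- two_site_model(5)
  hess <- build_anm_hessian(cm, cutoff = 15)
  hess$matrix[1, 4] <- hess$matrix[1, 4] + 1
  expect_error(solve_modes(hess), "symmetric")
})

test_that("sequence-dependent field softens when a large side chain is truncated", {
  cl <- make_toy_structure("cluster", 27, seed = 3,
                           sequence = paste(rep("L", 27), collapse = ""))
  cm <- extract_coarse_grain(cl)
  h_wt <- build_encom_hessian(cl, cm)
  mut <- build_mutant(cl, parse_mutation("L1A", "A"))
  h_mut <- build_encom_hessian(mut, extract_coarse_grain(mut))
  k_to_site <- function(h, site) {
    sp <- h$springs[h$springs$force_constant != 100 &
                      (h$springs$i == site | h$springs$j == site), ]
    stats::setNames(sp$force_constant,
                    paste(pmin(sp$i, sp$j), pmax(sp$i, sp$j)))
  }
  kw <- k_to_site(h_wt, 1); km <- k_to_site(h_mut, 1)
  shared <- intersect(names(kw), names(km))
  expect_true(all(km[shared] <= kw[shared]))
  expect_lt(sum(km), sum(kw))
})

test_that("with equal weights and zeroed bonded terms the field reduces to a contact-count ANM", {
  cl <- make_toy_structure("cluster", 12, seed = 13)
  cm <- extract_coarse_grain(cl)
  k <- length(vibstab:::pharmacophore_classes)
  eq_w <- matrix(1, k, k, dimnames = list(vibstab:::pharmacophore_classes,
                                          vibstab:::pharmacophore_classes))
  params <- encom_params(k_bond = 0, k_angle = 0, k_dihedral = 0,
                         epsilon = 2, weights = eq_w, contact_dist = 4.5)
  hess <- build_encom_hessian(cl, cm, params)
  # brute-force contact-count-weighted ANM over |i-j| >= 3 pairs
  atoms <- cl$atoms[cl$atoms$element != "H", ]
  xyz_at <- as.matrix(atoms[, c("x", "y", "z")])
  site_of <- match(atoms$resno, cm$sites$resno)
  n <- n_sites(cm)
  counts <- matrix(0, n, n)
  for (a in seq_len(nrow(atoms))) {
    for (b in seq_len(nrow(atoms))) {
      if (b <= a || site_of[a] == site_of[b]) next
      if (sqrt(sum((xyz_at[a, ] - xyz_at[b, ])^2)) <= 4.5) {
        counts[site_of[a], site_of[b]] <- counts[site_of[a], site_of[b]] + 1
        counts[site_of[b], site_of[a]] <- counts[site_of[b], site_of[a]] + 1
      }
    }
  }
  xyz <- vibstab:::coarse_xyz(cm)
  H_oracle <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || abs(i - j) < 3 || counts[i, j] == 0) next
      rij <- xyz[j, ] - xyz[i, ]
      rhat <- rij / sqrt(sum(rij^2))
      blk <- 2 * counts[i, j] * outer(rhat, rhat)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H_oracle[ii, jj] <- H_oracle[ii, jj] - blk
      H_oracle[ii, ii] <- H_oracle[ii, ii] + blk
    }
  }
  expect_lt(max(abs(hess$matrix - H_oracle)), 1e-9 * max(1, max(abs(H_oracle))))
})

test_that("ANM fluctuations agree with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  h <- make_toy_structure("ideal_helix", 20)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, path)
  pdb <- bio3d::read.pdb(path)
  ref <- bio3d::nma(pdb, ff = "anm", cutoff = 15, mass = FALSE, temp = NULL)
  cm <- extract_coarse_grain(h, mass_scheme = "unit")
  nm <- solve_modes(build_anm_hessian(cm, cutoff = 15), mass_weighting = FALSE)
  msf <- mean_square_fluctuations(nm)$msf
  expect_gt(stats::cor(msf, ref$fluctuations), 0.999)
})
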