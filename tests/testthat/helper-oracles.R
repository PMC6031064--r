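# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's production code paths: Hessians are assembled by naive
# double loops, eigenproblems solved with a non-symmetric eigen() call, and
# per-site quantities recomputed term by term.

# naive cutoff-ANM Hessian: explicit double loop over site pairs
oracle_anm_hessian <- function(xyz, cutoff, gamma) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rij <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(rij^2))
      if (d > cutoff) next
      rhat <- rij / d
      blk <- gamma * outer(rhat, rhat)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] - blk
      H[ii, ii] <- H[ii, ii] + blk
    }
  }
  H
}

# dense eigen-decomposition through the generic (non-symmetric) routine
oracle_eigen <- function(H, masses) {
  inv <- rep(1 / sqrt(masses), each = 3)
  Hm <- diag(inv) %*% H %*% diag(inv)
  e <- eigen(Hm, symmetric = FALSE)
  ord <- order(Re(e$values))
  list(values = Re(e$values)[ord],
       vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# mean-square fluctuations straight from an oracle eigen-decomposition
oracle_msf <- function(oe, masses, n_trivial) {
  n <- length(masses)
  idx <- (n_trivial + 1):length(oe$values)
  msf <- numeric(n)
  for (k in idx) {
    a <- matrix(oe$vectors[, k] * rep(1 / sqrt(masses), each = 3),
                ncol = 3, byrow = TRUE)
    msf <- msf + rowSums(a^2) / oe$values[k]
  }
  msf
}

oracle_cross_correlation <- function(oe, masses, n_trivial) {
  n <- length(masses)
  idx <- (n_trivial + 1):length(oe$values)
  cov <- matrix(0, n, n)
  for (k in idx) {
    a <- matrix(oe$vectors[, k] * rep(1 / sqrt(masses), each = 3),
                ncol = 3, byrow = TRUE)
    cov <- cov + (a %*% t(a)) / oe$values[k]
  }
  d <- sqrt(diag(cov))
  cov / outer(d, d)
}

# spring-by-spring deformation accounting for a displacement field
oracle_deformation <- function(xyz, springs, disp) {
  n <- nrow(xyz)
  e <- numeric(n)
  for (p in seq_len(nrow(springs))) {
    i <- springs$i[p]; j <- springs$j[p]
    rhat <- (xyz[j, ] - xyz[i, ]) / sqrt(sum((xyz[j, ] - xyz[i, ])^2))
    dl <- sum((disp[j, ] - disp[i, ]) * rhat)
    w <- 0.5 * springs$force_constant[p] * dl^2
    e[i] <- e[i] + w / 2
    e[j] <- e[j] + w / 2
  }
  e
}

# exhaustive class-pair / distance-bin pair count around a residue
oracle_signature <- function(labels, center_sel, radius, bin_edges) {
  xyz <- as.matrix(labels[, c("x", "y", "z")])
  cx <- xyz[center_sel, , drop = FALSE]
  in_hood <- vapply(seq_len(nrow(xyz)), function(i) {
    min(sqrt(colSums((t(cx) - xyz[i, ])^2))) <= radius
  }, logical(1))
  hood <- which(in_hood)
  counts <- new.env()
  bump <- function(key) {
    counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
  }
  for (ai in seq_along(hood)) {
    for (bi in seq_along(hood)) {
      if (bi <= ai) next
      a <- hood[ai]; b <- hood[bi]
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d > radius) next
      combos <- unique(apply(expand.grid(labels$classes[[a]],
                                         labels$classes[[b]],
                                         stringsAsFactors = FALSE), 1,
                             function(x) paste(sort(x), collapse = ":")))
      for (edge in bin_edges) {
        if (d <= edge) for (cp in combos) bump(sprintf("%s@%g", cp, edge))
      }
    }
  }
  out <- stats::setNames(rep(0L, 0), character(0))
  for (key in ls(counts)) out[key] <- counts[[key]]
  out
}

# hand formula Pearson r and RMSE
oracle_metrics <- function(pred, obs) {
  mx <- mean(pred); my <- mean(obs)
  r <- sum((pred - mx) * (obs - my)) /
    sqrt(sum((pred - mx)^2) * sum((obs - my)^2))
  list(r = r, rmse = sqrt(mean((pred - obs)^2)))
}

rigid_copy <- function(structure, seed = 1) {
  set.seed(seed)
  rot <- vibstab:::random_rotation()
  shift <- stats::rnorm(3, sd = 20)
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rot)
  at$x <- xyz[, 1] + shift[1]
  at$y <- xyz[, 2] + shift[2]
  at$z <- xyz[, 3] + shift[3]
  vibstab:::new_structure(at, structure$het, structure$model_id)
}
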