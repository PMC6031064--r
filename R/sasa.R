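# Numeric solvent-accessible surface area (rolling-probe approximation) and
# residue depth. A fixed golden-spiral point set makes every result
# deterministic; the same machinery computes both the per-residue SASA used
# for relative accessibility and the accessible surface points used for
# depth.

heavy_atoms <- function(structure) {
  structure$atoms[structure$atoms$element != "H", ]
}

atom_radii <- function(atoms) {
  r <- element_vdw_radius[atoms$element]
  r[is.na(r)] <- default_vdw_radius
  unname(r)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley style numeric integration: `n_points` test points on each
#' expanded (van der Waals + probe) atom sphere; a point is accessible when
#' it lies outside every other expanded sphere.
#'
#' @param structure A `protein_structure` (hydrogens are ignored).
#' @param probe Probe radius in Angstrom, default 1.4.
#' @param n_points Sphere sample points per atom, default 240.
#' @param keep_points Also return the accessible surface points (matrix).
#' @return Tibble of heavy atoms with columns `sasa` (A^2) and `radius`;
#'   when `keep_points` is `TRUE`, the matrix of accessible points is
#'   attached as attribute `"surface_points"`.
#' @export
atom_sasa <- function(structure, probe = 1.4, n_points = 240,
                      keep_points = FALSE) {
  atoms <- heavy_atoms(structure)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- atom_radii(atoms) + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  surface <- if (keep_points) vector("list", n) else NULL
  max_r <- max(radii)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= (radii[i] + max_r)^2)
    nb <- nb[nb != i]
    p <- sweep(pts * radii[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > radii[j]^2
      if (!any(acc)) break
    }
    frac <- sum(acc) / n_points
    sasa[i] <- 4 * pi * radii[i]^2 * frac
    if (keep_points && any(acc)) surface[[i]] <- p[acc, , drop = FALSE]
  }
  out <- atoms
  out$radius <- radii - probe
  out$sasa <- sasa
  if (keep_points) {
    attr(out, "surface_points") <- do.call(rbind, surface[!vapply(surface, is.null, TRUE)])
  }
  out
}

# cache of reference (Gly-X-Gly extended tripeptide) per-residue SASA
.rsa_ref_cache <- new.env(parent = emptyenv())

reference_sasa <- function(aa1, probe, n_points) {
  key <- paste(aa1, probe, n_points, sep = "_")
  if (!is.null(.rsa_ref_cache[[key]])) return(.rsa_ref_cache[[key]])
  tri <- make_toy_structure("extended_chain", 3,
                            sequence = paste0("G", aa1, "G"))
  sa <- atom_sasa(tri, probe = probe, n_points = n_points)
  ref <- sum(sa$sasa[sa$resno == 2])
  .rsa_ref_cache[[key]] <- ref
  ref
}

#' Relative solvent accessibility of one residue
#'
#' SASA of the residue in context divided by the SASA of the same residue
#' type in an extended Gly-X-Gly reference computed by the identical
#' algorithm, so values stay in approximately \[0, 1\] by construction.
#'
#' @param structure A `protein_structure`.
#' @param chain,resno,icode Residue reference.
#' @param probe Probe radius, default 1.4 A.
#' @param n_points Sphere sample points per atom.
#' @return Fraction (may slightly exceed 1 for distorted geometries).
#' @export
relative_solvent_accessibility <- function(structure, chain, resno,
                                           icode = "", probe = 1.4,
                                           n_points = 240) {
  sa <- atom_sasa(structure, probe = probe, n_points = n_points)
  sel <- sa$chain == chain & sa$resno == resno & sa$icode == icode
  if (!any(sel)) stop("residue not found")
  aa1 <- aa_three_to_one(sa$resname[sel][1])
  if (is.na(aa1)) stop("residue type not mappable to a standard amino acid")
  ref <- reference_sasa(aa1, probe, n_points)
  sum(sa$sasa[sel]) / ref
}

#' Residue depth below the solvent-accessible surface
#'
#' Mean over the residue's heavy atoms of the distance from the atom's
#' expanded-sphere surface to the nearest accessible surface point:
#' `max(0, min_p |x - p| - (r_vdw + probe))`. Fully exposed atoms contribute
#' ~0; buried atoms contribute their distance below the surface.
#'
#' @inheritParams relative_solvent_accessibility
#' @return Depth in Angstrom (0 with a warning for degenerate structures
#'   with no accessible surface).
#' @export
residue_depth <- function(structure, chain, resno, icode = "", probe = 1.4,
                          n_points = 240) {
  sa <- atom_sasa(structure, probe = probe, n_points = n_points,
                  keep_points = TRUE)
  pts <- attr(sa, "surface_points")
  sel <- sa$chain == chain & sa$resno == resno & sa$icode == icode
  if (!any(sel)) stop("residue not found")
  if (is.null(pts) || nrow(pts) == 0) {
    warning("no accessible surface; depth set to 0")
    return(0)
  }
  xyz <- as.matrix(sa[sel, c("x", "y", "z")])
  radii <- sa$radius[sel] + probe
  depths <- vapply(seq_len(nrow(xyz)), function(i) {
    d <- sqrt((pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
                (pts[, 3] - xyz[i, 3])^2)
    max(0, min(d) - radii[i])
  }, numeric(1))
  mean(depths)
}
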