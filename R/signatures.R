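# Graph-based structural signatures and residue-environment features.

#' Pharmacophore labels for every heavy atom
#'
#' Assigns each protein heavy atom one or more of the eight pharmacophore
#' classes (hydrophobic, positive, negative, hydrogen-bond acceptor,
#' hydrogen-bond donor, aromatic, sulfur, neutral) from the fixed
#' residue/atom lookup table shipped with the package. Atoms absent from the
#' table are labelled neutral.
#'
#' @param structure A `protein_structure`.
#' @return Tibble of heavy atoms with a list-column `classes`.
#' @export
assign_pharmacophores <- function(structure) {
  atoms <- heavy_atoms(structure)
  atoms$classes <- lapply(seq_len(nrow(atoms)), function(i)
    pharma_lookup(atoms$resname[i], atoms$name[i]))
  atoms
}

signature_names <- function(bin_edges) {
  # alphabetical class order, matching the sorted unordered-pair keys below
  cls <- sort(pharmacophore_classes)
  pairs <- character(0)
  for (a in seq_along(cls)) {
    for (b in a:length(cls)) {
      pairs <- c(pairs, paste(cls[a], cls[b], sep = ":"))
    }
  }
  as.vector(outer(pairs, bin_edges, function(p, e) sprintf("%s@%g", p, e)))
}

#' Cutoff-scanning graph-based signature around one residue
#'
#' Counts heavy-atom pairs in the neighborhood of a residue, stratified by
#' unordered pharmacophore class pair and cumulative distance bin. The
#' neighborhood is every heavy atom within `radius` of any atom of the
#' center residue; an atom carrying several classes contributes to every
#' class-pair combination.
#'
#' @param structure A `protein_structure`.
#' @param chain,resno,icode Center residue reference.
#' @param labels Optional pre-computed [assign_pharmacophores()] table.
#' @param radius Neighborhood radius in Angstrom, default 10.
#' @param bin_edges Cumulative distance-bin upper edges, default
#'   `c(2, 4, 6, 8, 10)`.
#' @return Named integer vector of length 36 * length(bin_edges); cumulative
#'   counts are non-decreasing across bins within each class pair.
#' @export
cutoff_scan_signature <- function(structure, chain, resno, icode = "",
                                  labels = NULL, radius = 10,
                                  bin_edges = c(2, 4, 6, 8, 10)) {
  if (is.null(labels)) labels <- assign_pharmacophores(structure)
  nm <- signature_names(bin_edges)
  counts <- stats::setNames(rep(0L, length(nm)), nm)
  center <- labels$chain == chain & labels$resno == resno &
    labels$icode == icode
  if (!any(center)) stop("center residue not found")
  if (radius <= 0) return(counts)
  xyz <- as.matrix(labels[, c("x", "y", "z")])
  cx <- xyz[center, , drop = FALSE]
  min_d2 <- apply(xyz, 1, function(p)
    min(colSums((t(cx) - p)^2)))
  hood <- which(min_d2 <= radius^2)
  if (length(hood) < 2) return(counts)
  hx <- xyz[hood, , drop = FALSE]
  hcls <- labels$classes[hood]
  d <- as.matrix(stats::dist(hx))
  idx_pairs <- which(upper.tri(d) & d <= min(radius, max(bin_edges)),
                     arr.ind = TRUE)
  for (p in seq_len(nrow(idx_pairs))) {
    a <- idx_pairs[p, 1]; b <- idx_pairs[p, 2]
    dist_ab <- d[idx_pairs[p, 1], idx_pairs[p, 2]]
    bins <- bin_edges[bin_edges >= dist_ab]
    if (length(bins) == 0) next
    combos <- unique(apply(expand.grid(hcls[[a]], hcls[[b]],
                                       stringsAsFactors = FALSE), 1,
                           function(x) paste(sort(x), collapse = ":")))
    for (cp in combos) {
      keys <- sprintf("%s@%g", cp, bins)
      counts[keys] <- counts[keys] + 1L
    }
  }
  counts
}

#' Pharmacophore class-count change of a mutation
#'
#' Side-chain per-class atom counts of the mutant minus those of the
#' wild type, from the fixed lookup table. Antisymmetric by construction:
#' `delta(X -> Y) = -delta(Y -> X)`.
#'
#' @param wild_aa,mutant_aa 1-letter amino-acid codes.
#' @return Named numeric vector over the eight pharmacophore classes.
#' @export
mutation_pharmacophore_delta <- function(wild_aa, mutant_aa) {
  codes <- standard_aa_codes()
  wild_aa <- toupper(wild_aa); mutant_aa <- toupper(mutant_aa)
  if (!wild_aa %in% codes || !mutant_aa %in% codes) {
    stop("non-standard amino-acid code")
  }
  delta <- as.numeric(sidechain_class_counts(mutant_aa)) -
    as.numeric(sidechain_class_counts(wild_aa))
  stats::setNames(delta, pharmacophore_classes)
}

residue_backbone <- function(atoms, chain, resno, icode) {
  sel <- atoms$chain == chain & atoms$resno == resno & atoms$icode == icode
  res <- atoms[sel, ]
  get1 <- function(nm) {
    r <- res[res$name == nm, ]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  list(N = get1("N"), CA = get1("CA"), C = get1("C"))
}

#' Backbone dihedral angles of one residue
#'
#' @param structure A `protein_structure`.
#' @param chain,resno,icode Residue reference.
#' @return List with `phi` and `psi` in degrees (NA at chain termini or with
#'   missing backbone atoms).
#' @export
backbone_dihedrals <- function(structure, chain, resno, icode = "") {
  res <- structure_residues(structure)
  res <- res[res$chain == chain, ]
  pos <- which(res$resno == resno & res$icode == icode)
  if (length(pos) != 1) stop("residue not found")
  this_bb <- residue_backbone(structure$atoms, chain, resno, icode)
  phi <- psi <- NA_real_
  if (!any(vapply(this_bb, is.null, TRUE))) {
    if (pos > 1) {
      prev_bb <- residue_backbone(structure$atoms, chain,
                                  res$resno[pos - 1], res$icode[pos - 1])
      if (!is.null(prev_bb$C)) {
        phi <- dihedral_angle(prev_bb$C, this_bb$N, this_bb$CA, this_bb$C)
      }
    }
    if (pos < nrow(res)) {
      next_bb <- residue_backbone(structure$atoms, chain,
                                  res$resno[pos + 1], res$icode[pos + 1])
      if (!is.null(next_bb$N)) {
        psi <- dihedral_angle(this_bb$N, this_bb$CA, this_bb$C, next_bb$N)
      }
    }
  }
  list(phi = phi, psi = psi)
}

#' Three-class secondary structure of one residue
#'
#' Dihedral-window assignment: helix for phi in (-100, -30) and psi in
#' (-80, -5); strand for phi in (-180, -90) and psi in (90, 180); otherwise
#' coil. Chain-terminal residues and residues with missing backbone atoms
#' are coil. A deterministic approximation to hydrogen-bond-based
#' assignment, sufficient as a 3-class feature.
#'
#' @param structure A `protein_structure`.
#' @param chain,resno,icode Residue reference.
#' @return One of `"helix"`, `"strand"`, `"coil"`.
#' @export
secondary_structure <- function(structure, chain, resno, icode = "") {
  ang <- tryCatch(backbone_dihedrals(structure, chain, resno, icode),
                  error = function(e) stop(e))
  phi <- ang$phi; psi <- ang$psi
  if (is.na(phi) || is.na(psi)) return("coil")
  if (phi > -100 && phi < -30 && psi > -80 && psi < -5) return("helix")
  if (phi > -180 && phi < -90 && psi > 90 && psi <= 180) return("strand")
  "coil"
}
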