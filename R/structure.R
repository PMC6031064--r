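# Protein structure container and PDB input/output.
#
# A `protein_structure` holds one model of a structure as a tibble of protein
# heavy/hydrogen atoms plus a separate tibble of HETATM records. Author chain
# identifiers, residue numbers and insertion codes are preserved verbatim.

new_structure <- function(atoms, het = NULL, model_id = 1L) {
  if (is.null(het)) het <- atoms[0, ]
  structure(list(atoms = tibble::as_tibble(atoms),
                 het = tibble::as_tibble(het),
                 model_id = as.integer(model_id)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("<protein_structure> %d atoms, %d residues, chains: %s (model %d)\n",
              nrow(x$atoms), nrow(res),
              paste(unique(x$atoms$chain), collapse = ","), x$model_id))
  invisible(x)
}

#' Atom table of a structure
#'
#' @param structure A `protein_structure`.
#' @return Tibble with one row per protein atom: `serial`, `name`, `element`,
#'   `resname`, `resno`, `icode`, `chain`, `altloc`, `x`, `y`, `z`,
#'   `occupancy`, `bfactor`.
#' @export
structure_atoms <- function(structure) structure$atoms

#' Residue table of a structure
#'
#' @param structure A `protein_structure`.
#' @return Tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resname`, `aa` (1-letter code, NA if unmappable).
#' @export
structure_residues <- function(structure) {
  structure$atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$resname) |>
    dplyr::mutate(aa = aa_three_to_one(.data$resname))
}

#' One-letter sequence of a chain
#'
#' @param structure A `protein_structure`.
#' @param chain Chain identifier; default first chain.
#' @return Single string of 1-letter codes (`X` for unmappable residues).
#' @export
structure_sequence <- function(structure, chain = NULL) {
  res <- structure_residues(structure)
  if (is.null(chain)) chain <- res$chain[1]
  aa <- res$aa[res$chain == chain]
  paste(ifelse(is.na(aa), "X", aa), collapse = "")
}

#' Coordinate matrix of a structure
#' @keywords internal
structure_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

resolve_altlocs <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)
}

#' Read a protein structure from a PDB file or PDB-format text
#'
#' Parsing is delegated to [bio3d::read.pdb()]; on top of it this applies the
#' package's altloc policy (keep the highest-occupancy conformer, ties broken
#' alphabetically), separates HETATM records from the protein, and selects a
#' single model.
#'
#' @param source Path to a PDB file, or a character string of PDB-format text
#'   (recognized by embedded newlines).
#' @param model Model number to keep (1-based), default 1.
#' @param altloc_policy `"occupancy"` (default, highest occupancy wins, tie
#'   goes to the alphabetically first altloc) or `"all"` (keep everything).
#' @return A `protein_structure`.
#' @export
read_structure <- function(source, model = 1L, altloc_policy = c("occupancy", "all")) {
  altloc_policy <- match.arg(altloc_policy)
  path <- source
  if (length(source) == 1 && grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(source, "\n")[[1]], path)
  } else if (!file.exists(source)) {
    stop("PDB source not found: ", source)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) > 0) {
    stop(sprintf("PDB format error at line %d: record too short: '%s'",
                 bad[1], lines[bad[1]]))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("PDB format error: ", conditionMessage(e)))
  n_models <- max(1L, nrow(pdb$xyz))
  if (model < 1 || model > n_models) {
    stop(sprintf("requested model %d but file has %d model(s)", model, n_models))
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    record = at$type
  )
  atoms$element <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    el <- toupper(trimws(at$elesy))
    ifelse(nzchar(el), substr(el, 1, 1), element_from_atom_name(atoms$name))
  } else {
    element_from_atom_name(atoms$name)
  }
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("PDB format error: non-finite coordinates")
  }
  is_het <- atoms$record == "HETATM" & !(atoms$resname %in% names(nonstandard_aa_map))
  het <- atoms[is_het, ]
  prot <- atoms[!is_het, ]
  prot <- prot[!is.na(aa_three_to_one(prot$resname)) |
                 prot$resname %in% names(nonstandard_aa_map), ]
  if (altloc_policy == "occupancy") prot <- resolve_altlocs(prot)
  prot$record <- NULL
  het$record <- NULL
  if (nrow(prot) == 0) stop("empty structure: no protein atoms found")
  new_structure(prot, het, model_id = model)
}

format_pdb_atom_line <- function(serial, name, resname, chain, resno, icode,
                                 x, y, z, occupancy, bfactor, element) {
  # short atom names start in column 14 (1-char element convention)
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_fmt, resname, chain, resno,
          ifelse(nzchar(icode), icode, " "), x, y, z, occupancy, bfactor,
          element)
}

structure_pdb_lines <- function(structure) {
  a <- structure$atoms
  mapply(format_pdb_atom_line, a$serial, a$name, a$resname, a$chain, a$resno,
         a$icode, a$x, a$y, a$z, a$occupancy, a$bfactor, a$element,
         USE.NAMES = FALSE)
}

#' Write a structure to a PDB file
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  writeLines(c(structure_pdb_lines(structure), "END"), path)
  invisible(path)
}

# -- toy structure generator ---------------------------------------------

.ideal_backbone <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                        ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                        ang_c_n_ca = 121.7, ang_ca_c_o = 120.8)

build_backbone_chain <- function(n_residues, phi, psi, omega = 180) {
  g <- .ideal_backbone
  ncoord <- vector("list", n_residues)
  for (i in seq_len(n_residues)) ncoord[[i]] <- list()
  ncoord[[1]]$N <- c(0, 0, 0)
  ncoord[[1]]$CA <- c(g$n_ca, 0, 0)
  ncoord[[1]]$C <- place_atom(c(0, 1, 0), ncoord[[1]]$N, ncoord[[1]]$CA,
                              g$ca_c, g$ang_n_ca_c, 57)
  for (i in seq_len(n_residues - 1)) {
    r <- ncoord[[i]]
    n_next <- place_atom(r$N, r$CA, r$C, g$c_n, g$ang_ca_c_n, psi)
    ca_next <- place_atom(r$CA, r$C, n_next, g$n_ca, g$ang_c_n_ca, omega)
    c_next <- place_atom(r$C, n_next, ca_next, g$ca_c, g$ang_n_ca_c, phi)
    ncoord[[i + 1]] <- list(N = n_next, CA = ca_next, C = c_next)
  }
  for (i in seq_len(n_residues)) {
    r <- ncoord[[i]]
    ncoord[[i]]$O <- place_atom(r$N, r$CA, r$C, g$c_o, g$ang_ca_c_o, psi + 180)
  }
  ncoord
}

place_sidechain <- function(res_atoms, resname) {
  zmat <- sidechain_zmat[[resname]]
  if (is.null(zmat)) zmat <- list()
  for (row in zmat) {
    res_atoms[[row$atom]] <- place_atom(res_atoms[[row$a1]],
                                        res_atoms[[row$a2]],
                                        res_atoms[[row$a3]],
                                        row$bond, row$angle, row$dihedral)
  }
  res_atoms
}

residues_to_structure <- function(res_list, resnames, chain = "A",
                                  resno = seq_along(res_list)) {
  rows <- list()
  serial <- 0L
  for (i in seq_along(res_list)) {
    atoms <- res_list[[i]]
    for (nm in names(atoms)) {
      serial <- serial + 1L
      p <- atoms[[nm]]
      rows[[serial]] <- tibble::tibble(
        serial = serial, name = nm, element = element_from_atom_name(nm),
        resname = resnames[i], resno = as.integer(resno[i]), icode = "",
        chain = chain, altloc = "", x = p[1], y = p[2], z = p[3],
        occupancy = 1, bfactor = 0)
    }
  }
  new_structure(dplyr::bind_rows(rows))
}

default_toy_sequence <- function(n) {
  base <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(rep(base, length.out = n), collapse = "")
}

#' Generate a synthetic protein structure
#'
#' Deterministic fixture generator used for tests and examples. Three kinds
#' are available: `ideal_helix` (canonical alpha-helix backbone, phi = -57,
#' psi = -47, ~1.5 A rise and ~100 degrees twist per residue),
#' `extended_chain` (beta-strand-like extended backbone, ~3.8 A consecutive
#' C-alpha spacing), and `cluster` (full residues placed with random
#' orientations on a compact cubic lattice perturbed by seeded Gaussian
#' noise — a globular-protein stand-in with realistic local geometry but no
#' chain continuity). All kinds carry full heavy-atom side chains from the
#' idealized rotamer templates.
#'
#' @param kind One of `"ideal_helix"`, `"extended_chain"`, `"cluster"`.
#' @param n_residues Number of residues (>= 2).
#' @param sequence Optional 1-letter sequence of length `n_residues`; default
#'   cycles through the 20 standard amino acids.
#' @param seed Integer seed controlling the (only) random elements: cluster
#'   perturbation and orientations.
#' @return A `protein_structure`.
#' @export
make_toy_structure <- function(kind = c("ideal_helix", "extended_chain", "cluster"),
                               n_residues, sequence = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 2)
  if (is.null(sequence)) sequence <- default_toy_sequence(n_residues)
  aa1 <- strsplit(sequence, "")[[1]]
  if (length(aa1) != n_residues) stop("sequence length must equal n_residues")
  resnames <- aa_one_to_three(aa1)
  if (anyNA(resnames)) stop("sequence contains non-standard codes")

  if (kind %in% c("ideal_helix", "extended_chain")) {
    angles <- if (kind == "ideal_helix") c(-57, -47) else c(-140, 135)
    bb <- build_backbone_chain(n_residues, phi = angles[1], psi = angles[2])
    res_list <- lapply(seq_len(n_residues), function(i)
      place_sidechain(bb[[i]], resnames[i]))
    return(residues_to_structure(res_list, resnames))
  }

  # cluster: compact cubic lattice + Gaussian jitter, random local frames
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  side <- ceiling(n_residues^(1 / 3))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  grid <- grid[order(rowSums((as.matrix(grid) - (side + 1) / 2)^2)), ]
  centers <- as.matrix(grid[seq_len(n_residues), ]) * 5.0 +
    matrix(stats::rnorm(3 * n_residues, sd = 0.3), ncol = 3)
  res_list <- lapply(seq_len(n_residues), function(i) {
    g <- .ideal_backbone
    atoms <- list(N = c(g$n_ca, 0, 0), CA = c(0, 0, 0))
    atoms$C <- place_atom(c(g$n_ca, 1, 0), atoms$N, atoms$CA,
                          g$ca_c, g$ang_n_ca_c, 57)
    atoms$O <- place_atom(atoms$N, atoms$CA, atoms$C, g$c_o, g$ang_ca_c_o, 135)
    atoms <- place_sidechain(atoms, resnames[i])
    rot <- random_rotation()
    lapply(atoms, function(p) as.numeric(rot %*% p + centers[i, ]))
  })
  residues_to_structure(res_list, resnames)
}
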