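# Coarse-grained (C-alpha) model extraction.

#' Build a C-alpha coarse-grained model
#'
#' One site per standard amino-acid residue possessing a C-alpha atom, in
#' chain order then residue order. Residues without a C-alpha (or with an
#' unmappable residue name) are skipped and reported via the `skipped`
#' attribute and a warning.
#'
#' @param structure A `protein_structure`.
#' @param chains Optional character vector of chain identifiers to keep.
#' @param mass_scheme `"residue"` (default, total residue mass by type, Da)
#'   or `"unit"` (all masses 1, the convention of much of the C-alpha ANM
#'   literature).
#' @return A `coarse_model`: list with `sites` (tibble: `chain`, `resno`,
#'   `icode`, `resname`, `aa`, `x`, `y`, `z`, `mass`), `mass_scheme` and the
#'   source `structure`.
#' @export
extract_coarse_grain <- function(structure, chains = NULL,
                                 mass_scheme = c("residue", "unit")) {
  mass_scheme <- match.arg(mass_scheme)
  atoms <- structure$atoms
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, ]
  res <- atoms |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$resname)
  ca <- atoms[atoms$name == "CA", ]
  sites <- res |>
    dplyr::inner_join(ca, by = c("chain", "resno", "icode", "resname")) |>
    dplyr::mutate(aa = aa_three_to_one(.data$resname)) |>
    dplyr::filter(!is.na(.data$aa)) |>
    dplyr::select("chain", "resno", "icode", "resname", "aa", "x", "y", "z")
  skipped <- dplyr::anti_join(res, sites,
                              by = c("chain", "resno", "icode", "resname"))
  if (nrow(skipped) > 0) {
    warning(sprintf("%d residue(s) without usable C-alpha skipped", nrow(skipped)))
  }
  if (nrow(sites) < 2) stop("too few sites: need >= 2 residues with C-alpha")
  sites$mass <- if (mass_scheme == "unit") 1 else
    unname(aa_residue_mass[sites$aa])
  structure(list(sites = sites, mass_scheme = mass_scheme,
                 structure = structure, skipped = skipped),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("<coarse_model> %d sites, mass scheme: %s\n",
              nrow(x$sites), x$mass_scheme))
  invisible(x)
}

#' @keywords internal
coarse_xyz <- function(model) as.matrix(model$sites[, c("x", "y", "z")])

#' Number of sites in a coarse model
#' @param model A `coarse_model`.
#' @export
n_sites <- function(model) nrow(model$sites)
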