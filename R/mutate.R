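# Point-mutation specification and idealized mutant-structure modelling.

#' Create a mutation specification
#'
#' @param chain Chain identifier (single character).
#' @param wild_aa Wild-type 1-letter code.
#' @param resno Author residue number.
#' @param mutant_aa Mutant 1-letter code.
#' @param icode Insertion code, default `""`.
#' @param allow_identity Permit `wild_aa == mutant_aa` (used only in
#'   featurization self-checks), default `FALSE`.
#' @return A `mutation_spec`.
#' @export
mutation_spec <- function(chain, wild_aa, resno, mutant_aa, icode = "",
                          allow_identity = FALSE) {
  wild_aa <- toupper(wild_aa); mutant_aa <- toupper(mutant_aa)
  codes <- standard_aa_codes()
  if (!wild_aa %in% codes) stop("unknown wild-type code: ", wild_aa)
  if (!mutant_aa %in% codes) stop("unknown mutant code: ", mutant_aa)
  if (!allow_identity && wild_aa == mutant_aa) {
    stop("wild-type and mutant residue are identical: ", wild_aa)
  }
  structure(list(chain = chain, wild_aa = wild_aa, resno = as.integer(resno),
                 icode = icode, mutant_aa = mutant_aa),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s%d%s%s (chain %s)\n", x$wild_aa, x$resno,
              x$icode, x$mutant_aa, x$chain))
  invisible(x)
}

#' @export
format.mutation_spec <- function(x, ...) {
  sprintf("%s%d%s%s", x$wild_aa, x$resno, x$icode, x$mutant_aa)
}

#' Parse a mutation string
#'
#' Accepts the common compact form wild-type code + residue number +
#' optional insertion code + mutant code, e.g. `"A17G"` or `"A17BG"`.
#'
#' @param string Mutation string.
#' @param chain Chain identifier the residue lives in.
#' @param allow_identity Permit identity "mutations".
#' @return A `mutation_spec`.
#' @export
parse_mutation <- function(string, chain, allow_identity = FALSE) {
  m <- regmatches(string, regexec("^([A-Za-z])([0-9]+)([A-Za-z]?)([A-Za-z])$",
                                  toupper(trimws(string))))[[1]]
  if (length(m) == 0) stop("cannot parse mutation string: '", string, "'")
  mutation_spec(chain = chain, wild_aa = m[2], resno = as.integer(m[3]),
                mutant_aa = m[5], icode = m[4], allow_identity = allow_identity)
}

#' Reverse a mutation specification
#' @param mutation A `mutation_spec`.
#' @return The mutant-to-wild-type counterpart.
#' @export
reverse_mutation <- function(mutation) {
  mutation_spec(mutation$chain, mutation$mutant_aa, mutation$resno,
                mutation$wild_aa, mutation$icode, allow_identity = TRUE)
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Build a mutant structure by idealized side-chain replacement
#'
#' Backbone atoms (N, CA, C, O) are preserved exactly; an existing C-beta is
#' kept when the mutant has one; remaining mutant side-chain atoms are placed
#' from idealized internal coordinates of the single most common rotamer. No
#' minimization is performed. All other residues are untouched.
#'
#' @param structure Wild-type `protein_structure`.
#' @param mutation A `mutation_spec` valid on `structure`.
#' @return Mutant `protein_structure`.
#' @export
build_mutant <- function(structure, mutation) {
  atoms <- structure$atoms
  sel <- atoms$chain == mutation$chain & atoms$resno == mutation$resno &
    atoms$icode == mutation$icode
  if (!any(sel)) {
    stop(sprintf("residue %d%s in chain %s not found", mutation$resno,
                 mutation$icode, mutation$chain))
  }
  found_res <- atoms$resname[sel][1]
  found_aa <- aa_three_to_one(found_res)
  if (is.na(found_aa) || found_aa != mutation$wild_aa) {
    stop(sprintf("wild-type mismatch at %s%d%s: expected %s, found %s",
                 mutation$chain, mutation$resno, mutation$icode,
                 mutation$wild_aa, found_res))
  }
  res_atoms <- atoms[sel, ]
  mut3 <- aa_one_to_three(mutation$mutant_aa)
  keep_names <- .backbone_names
  if (mutation$mutant_aa != "G" && "CB" %in% res_atoms$name) {
    keep_names <- c(keep_names, "CB")
  }
  kept <- res_atoms[res_atoms$name %in% keep_names, ]
  if (!all(c("N", "CA", "C") %in% kept$name)) {
    stop("mutation site lacks complete backbone (N, CA, C) — cannot model side chain")
  }
  kept$resname <- mut3
  pos <- stats::setNames(
    lapply(seq_len(nrow(kept)), function(i) c(kept$x[i], kept$y[i], kept$z[i])),
    kept$name)
  new_rows <- list()
  for (row in sidechain_zmat[[mut3]]) {
    if (row$atom %in% names(pos)) next
    p <- place_atom(pos[[row$a1]], pos[[row$a2]], pos[[row$a3]],
                    row$bond, row$angle, row$dihedral)
    pos[[row$atom]] <- p
    new_rows[[length(new_rows) + 1]] <- tibble::tibble(
      serial = 0L, name = row$atom, element = element_from_atom_name(row$atom),
      resname = mut3, resno = mutation$resno, icode = mutation$icode,
      chain = mutation$chain, altloc = "", x = p[1], y = p[2], z = p[3],
      occupancy = 1, bfactor = 0)
  }
  res_new <- dplyr::bind_rows(c(list(kept), new_rows))
  out <- dplyr::bind_rows(atoms[!sel & seq_len(nrow(atoms)) < which(sel)[1], ],
                          res_new,
                          atoms[!sel & seq_len(nrow(atoms)) > which(sel)[1], ])
  out$serial <- seq_len(nrow(out))
  new_structure(out, structure$het, structure$model_id)
}
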