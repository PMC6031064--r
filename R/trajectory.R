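# Multi-model PDB trajectory along a normal mode.

#' Write a mode animation as a multi-model PDB
#'
#' Frame k (k = 1..n_frames) places each site at
#' `coord + amplitude * sin(2 * pi * k / n_frames) * mode`, giving one full
#' oscillation through the equilibrium structure.
#'
#' @param model A `coarse_model`.
#' @param mode Numeric n x 3 matrix of per-site displacement vectors.
#' @param amplitude Peak displacement scale in Angstrom.
#' @param n_frames Number of frames (>= 2).
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_mode_trajectory <- function(model, mode, amplitude, n_frames, path) {
  sites <- model$sites
  mode <- as.matrix(mode)
  if (nrow(mode) != nrow(sites) || ncol(mode) != 3) {
    stop(sprintf("mode dimension mismatch: need %d x 3, got %d x %d",
                 nrow(sites), nrow(mode), ncol(mode)))
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  xyz <- coarse_xyz(model)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames)) {
    frame <- xyz + amplitude * sin(2 * pi * k / n_frames) * mode
    writeLines(sprintf("MODEL     %4d", k), con)
    lines <- mapply(format_pdb_atom_line,
                    seq_len(nrow(sites)), "CA", sites$resname, sites$chain,
                    sites$resno, sites$icode,
                    frame[, 1], frame[, 2], frame[, 3], 1, 0, "C",
                    USE.NAMES = FALSE)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
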