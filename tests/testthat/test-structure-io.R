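# Structure parsing, coarse-graining, mutant modelling, trajectories and
# the toy-structure generator.

minimal_pdb_text <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      12.560   6.351  -6.510  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      13.253   5.292  -5.650  1.00  0.00           C",
  "ATOM      4  O   ALA A   1      12.661   4.755  -4.710  1.00  0.00           O",
  "ATOM      5  N   GLY A   2      14.522   5.013  -5.943  1.00  0.00           N",
  "ATOM      6  CA  GLY A   2      15.285   3.998  -5.211  1.00  0.00           C",
  "ATOM      7  C   GLY A   2      16.084   4.636  -4.077  1.00  0.00           C",
  "ATOM      8  O   GLY A   2      16.130   5.861  -3.963  1.00  0.00           O",
  "END", sep = "\n")

test_that("hand-written PDB text parses to the printed fields", {
  s <- read_structure(minimal_pdb_text)
  at <- structure_atoms(s)
  expect_equal(nrow(structure_residues(s)), 2)
  expect_equal(at$x[at$name == "N" & at$resno == 1], 11.104)
  expect_equal(at$z[at$name == "CA" & at$resno == 2], -5.211)
  expect_equal(structure_sequence(s), "AG")
})

test_that("altloc policy keeps the highest-occupancy conformer", {
  txt <- paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   1.000   0.000  0.60  0.00           C",
    "ATOM      4  CB BALA A   1       2.000   1.000   0.000  0.40  0.00           C",
    "ATOM      5  N   GLY A   2       3.800   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       5.258   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  s <- read_structure(txt)
  cb <- structure_atoms(s) |> dplyr::filter(name == "CB")
  expect_equal(nrow(cb), 1)
  expect_equal(cb$occupancy, 0.6)
  expect_equal(cb$x, 1.0)
})

test_that("malformed and empty inputs raise informative errors", {
  expect_error(read_structure("ATOM short line\nEND"), "line 1")
  expect_error(read_structure(minimal_pdb_text, model = 3), "model")
})

test_that("write/read round-trips coordinates to PDB precision", {
  h <- make_toy_structure("ideal_helix", 20)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, path)
  back <- read_structure(path)
  expect_equal(nrow(structure_atoms(back)), nrow(structure_atoms(h)))
  expect_lt(max(abs(vibstab:::structure_xyz(back) - vibstab:::structure_xyz(h))),
            1e-3 + 1e-9)
  expect_identical(structure_atoms(back)$name, structure_atoms(h)$name)
  expect_identical(structure_atoms(back)$resno, structure_atoms(h)$resno)
})

test_that("coarse-graining yields one site per residue with a C-alpha", {
  h <- make_toy_structure("ideal_helix", 20)
  cm <- extract_coarse_grain(h)
  expect_equal(n_sites(cm), 20)
  expect_identical(cm$sites$resno, 1:20)
  expect_true(all(cm$sites$mass > 0))
  # unit scheme
  cm1 <- extract_coarse_grain(h, mass_scheme = "unit")
  expect_true(all(cm1$sites$mass == 1))
  # residue masses differ by type
  expect_equal(cm$sites$mass,
               unname(vibstab:::aa_residue_mass[cm$sites$aa]))
  # drop a C-alpha: site skipped with a warning
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 7 &
                                   broken$atoms$name == "CA"), ]
  expect_warning(cm2 <- extract_coarse_grain(broken), "skipped")
  expect_equal(n_sites(cm2), 19)
  expect_error(extract_coarse_grain(read_structure(minimal_pdb_text),
                                    chains = "Z"))
})

test_that("mutation strings parse and validate", {
  m <- parse_mutation("A17G", "B")
  expect_equal(m$wild_aa, "A"); expect_equal(m$resno, 17L)
  expect_equal(m$mutant_aa, "G"); expect_equal(m$chain, "B")
  m2 <- parse_mutation("K10AR", "A")
  expect_equal(m2$icode, "A")
  expect_error(parse_mutation("A17X", "A"), "mutant")
  expect_error(parse_mutation("A17A", "A"), "identical")
  expect_equal(format(reverse_mutation(m)), "G17A")
})

test_that("X->Ala truncation keeps only CB beyond the backbone, backbone fixed", {
  h <- make_toy_structure("ideal_helix", 12)
  mut <- build_mutant(h, parse_mutation("F5A", "A"))
  wt_at <- structure_atoms(h); mu_at <- structure_atoms(mut)
  res5 <- mu_at[mu_at$resno == 5, ]
  expect_setequal(res5$name, c("N", "CA", "C", "O", "CB"))
  expect_true(all(res5$resname == "ALA"))
  # backbone atoms of every residue unchanged, displacement exactly 0
  for (nm in c("N", "CA", "C", "O")) {
    a <- wt_at[wt_at$name == nm, c("x", "y", "z")]
    b <- mu_at[mu_at$name == nm, c("x", "y", "z")]
    expect_identical(as.matrix(a), as.matrix(b))
  }
  # all other residues untouched atom-for-atom
  expect_identical(wt_at[wt_at$resno != 5, c("name", "x", "y", "z")],
                   mu_at[mu_at$resno != 5, c("name", "x", "y", "z")])
})

test_that("Gly->Ala builds an ideal-geometry C-beta", {
  g <- make_toy_structure("ideal_helix", 5, sequence = "GGGGG")
  mut <- build_mutant(g, parse_mutation("G3A", "A"))
  at <- structure_atoms(mut)
  cb <- unlist(at[at$resno == 3 & at$name == "CB", c("x", "y", "z")])
  ca <- unlist(at[at$resno == 3 & at$name == "CA", c("x", "y", "z")])
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 0.02 / 1.53)
})

test_that("mutant building rejects mismatches and missing residues", {
  h <- make_toy_structure("ideal_helix", 10)  # residue 17 absent, 3 is D
  expect_error(build_mutant(h, parse_mutation("A17G", "A")), "not found")
  expect_error(build_mutant(h, parse_mutation("A3G", "A")), "ASP")
})

read_traj_frames <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  lapply(seq_along(starts), function(k) {
    at <- lines[(starts[k] + 1):(ends[k] - 1)]
    cbind(as.numeric(substr(at, 31, 38)),
          as.numeric(substr(at, 39, 46)),
          as.numeric(substr(at, 47, 54)))
  })
}

test_that("mode trajectories sample a sine through the input coordinates", {
  h <- make_toy_structure("ideal_helix", 6)
  cm <- extract_coarse_grain(h)
  xyz <- vibstab:::coarse_xyz(cm)
  path <- withr::local_tempfile(fileext = ".pdb")

  # zero mode: every frame identical to the input
  write_mode_trajectory(cm, matrix(0, 6, 3), amplitude = 2, n_frames = 3, path)
  frames <- read_traj_frames(path)
  expect_length(frames, 3)
  for (f in frames) expect_lt(max(abs(f - xyz)), 1e-3 + 1e-9)

  # sin(pi) = 0: frame at half period equals the input
  mode <- matrix(stats::rnorm(18), 6, 3)
  write_mode_trajectory(cm, mode, amplitude = 1.5, n_frames = 4, path)
  frames <- read_traj_frames(path)
  expect_lt(max(abs(frames[[2]] - xyz)), 1e-3 + 1e-9)

  # unit x-displacement on one site, amplitude 2: max x-excursion is 2.0
  mode <- matrix(0, 6, 3); mode[4, 1] <- 1
  write_mode_trajectory(cm, mode, amplitude = 2, n_frames = 8, path)
  frames <- read_traj_frames(path)
  exc <- vapply(frames, function(f) f[4, 1] - xyz[4, 1], numeric(1))
  expect_equal(max(exc), 2.0, tolerance = 1e-3)
  expect_error(write_mode_trajectory(cm, matrix(0, 5, 3), 1, 4, path),
               "mismatch")
})

test_that("toy structures have the advertised geometry and are deterministic", {
  h <- make_toy_structure("ideal_helix", 10)
  ca <- vibstab:::coarse_xyz(extract_coarse_grain(h))
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))

  e <- make_toy_structure("extended_chain", 8)
  cae <- vibstab:::coarse_xyz(extract_coarse_grain(e))
  de <- sqrt(rowSums(diff(cae)^2))
  expect_true(all(abs(de - 3.8) < 0.2))

  c1 <- make_toy_structure("cluster", 30, seed = 11)
  c2 <- make_toy_structure("cluster", 30, seed = 11)
  expect_identical(vibstab:::structure_xyz(c1), vibstab:::structure_xyz(c2))
  c3 <- make_toy_structure("cluster", 30, seed = 12)
  expect_false(identical(vibstab:::structure_xyz(c1),
                         vibstab:::structure_xyz(c3)))
  xyz <- vibstab:::structure_xyz(c1)
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  expect_gt(rg, 0)
  expect_true(is.finite(rg))
  expect_error(make_toy_structure("spiral", 5))
})
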