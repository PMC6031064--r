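# Mutation tables, reverse augmentation, grouped splits and metrics.

write_table_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("mutation tables parse, sniff delimiters and honor sign conventions", {
  path <- write_table_fixture(c(
    "pdb_id,chain,mutation,ddg",
    "1abc,A,V10A,-1.25",
    "1abc,A,D27K,0.40",
    "2xyz,B,G5W,-3.10"))
  tbl <- read_mutation_table(path)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$ddg_exp, c(-1.25, 0.40, -3.10))
  expect_equal(tbl$wild_aa, c("V", "D", "G"))
  expect_equal(tbl$resno, c(10L, 27L, 5L))
  expect_equal(tbl$group_key, c("1abc_A_10", "1abc_A_27", "2xyz_B_5"))
  expect_true(all(tbl$direction == "forward"))
  # destabilizing-positive sources are negated on input
  tbl2 <- read_mutation_table(path, sign_convention = "destabilizing_positive")
  expect_equal(tbl2$ddg_exp, -tbl$ddg_exp)
  # tab-separated variant parses identically
  tsv <- write_table_fixture(c(
    "pdb_id\tchain\tmutation\tddg",
    "1abc\tA\tV10A\t-1.25"))
  expect_equal(read_mutation_table(tsv)$ddg_exp, -1.25)
})

test_that("malformed rows are rejected with their line numbers", {
  path <- write_table_fixture(c(
    "pdb_id,chain,mutation,ddg",
    "1abc,A,V10A,-1.0",
    "1abc,A,A17X,0.5",       # X is not a standard mutant code
    "1abc,A,L3L,1.0",        # silent substitution
    "1abc,A,K8R,not_a_number"))
  expect_warning(tbl <- read_mutation_table(path), "line\\(s\\): 3, 4, 5")
  expect_equal(nrow(tbl), 1)
  bad_header <- write_table_fixture(c("a,b,c", "1,2,3"))
  expect_error(read_mutation_table(bad_header), "column layout")
})

test_that("reverse augmentation doubles the table with swapped codes and negated ddg", {
  path <- write_table_fixture(c(
    "pdb_id,chain,mutation,ddg",
    "1abc,A,V10A,-1.25",
    "1abc,A,D27K,0.40",
    "2xyz,B,G5W,0"))
  tbl <- read_mutation_table(path)
  aug <- augment_reverse(tbl)
  expect_equal(nrow(aug), 6)
  rev <- aug[aug$direction == "reverse", ]
  expect_equal(rev$mutation, c("A10V", "K27D", "W5G"))
  expect_equal(rev$ddg_exp, c(1.25, -0.40, 0))     # -0 is normalized to 0
  expect_false(any(sign(1 / rev$ddg_exp) == -1 & rev$ddg_exp == 0))
  expect_equal(rev$group_key, tbl$group_key)        # partners share groups
  # augmenting an already-augmented table is refused
  expect_error(augment_reverse(aug), "forward")
  # duplicates are collapsed before augmentation
  expect_warning(aug2 <- augment_reverse(rbind(tbl, tbl[1, ])), "de-dup")
  expect_equal(nrow(aug2), 6)
})

test_that("grouped splits keep shared sites together and are deterministic", {
  set.seed(1)
  n <- 200
  tbl <- tibble::tibble(
    pdb_id = sprintf("p%02d", sample(20, n, replace = TRUE)),
    chain = "A",
    resno = sample(50, n, replace = TRUE),
    ddg_exp = stats::rnorm(n),
    direction = "forward")
  tbl$group_key <- paste(tbl$pdb_id, tbl$chain, tbl$resno, sep = "_")
  folds <- make_splits(tbl, "kfold", k = 10, seed = 7)
  expect_length(folds, n)
  expect_setequal(unique(folds), 1:10)
  # every group lives in exactly one fold
  expect_true(all(tapply(folds, tbl$group_key,
                         function(f) length(unique(f))) == 1))
  expect_identical(folds, make_splits(tbl, "kfold", k = 10, seed = 7))
  expect_false(identical(folds, make_splits(tbl, "kfold", k = 10, seed = 8)))
  expect_error(make_splits(tbl[1:3, ], "kfold", k = 10), "exceeds")
  # train/blind honors the group boundary and the requested fraction
  lab <- make_splits(tbl, "train_blind", blind_fraction = 0.2, seed = 3)
  expect_setequal(unique(lab), c("train", "blind"))
  expect_true(all(tapply(lab, tbl$group_key,
                         function(l) length(unique(l))) == 1))
  n_groups <- length(unique(tbl$group_key))
  blind_groups <- length(unique(tbl$group_key[lab == "blind"]))
  expect_equal(blind_groups, round(0.2 * n_groups))
})

test_that("stability classification puts the boundary on the stabilizing side", {
  expect_equal(classify_stability(c(-0.5, 0, 2)),
               c("destabilizing", "stabilizing", "stabilizing"))
  expect_error(classify_stability(c(1, NA)), "NA")
})

test_that("metrics match hand-computed values on a fixed vector", {
  obs <- c(1.0, -0.5, 2.0, 0.0, -1.5)
  pred <- c(0.8, -0.2, 2.5, 0.1, -1.0)
  rec <- tibble::tibble(ddg_exp = obs,
                        direction = c("forward", "forward", "forward",
                                      "reverse", "reverse"))
  rep <- evaluate_predictions(pred, rec, outlier_fraction = 0.2)
  o <- oracle_metrics(pred, obs)
  expect_equal(rep$pearson_r, o$r, tolerance = 1e-12)
  expect_equal(rep$rmse, o$rmse, tolerance = 1e-12)
  # trimming drops one of the two |err| = 0.5 ties; the stable order keeps
  # the earlier record (index 3) and drops index 5
  expect_equal(rep$n_trimmed, 4)
  keep <- c(1, 2, 3, 4)
  ot <- oracle_metrics(pred[keep], obs[keep])
  expect_equal(rep$pearson_r_trimmed, ot$r, tolerance = 1e-12)
  expect_equal(rep$rmse_trimmed, ot$rmse, tolerance = 1e-12)
  # subsets present only when they hold >= 3 records (reverse and
  # destabilizing have 2 each here)
  expect_named(rep$subsets, c("forward", "stabilizing"), ignore.order = TRUE)
  expect_equal(rep$subsets$forward$n, 3)
  td <- tidy(rep)
  expect_true(all(c("subset", "n", "pearson_r", "rmse") %in% names(td)))
  expect_true(all(c("overall", "trimmed") %in% td$subset))
  expect_error(evaluate_predictions(pred[1:4], rec), "misaligned")
})

test_that("trimmed RMSE never exceeds the untrimmed RMSE (property)", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 50
    obs <- stats::rnorm(n)
    pred <- obs + stats::rnorm(n, sd = 0.5)
    rep <- evaluate_predictions(pred, tibble::tibble(ddg_exp = obs))
    expect_lte(rep$rmse_trimmed, rep$rmse)
    expect_equal(rep$n_trimmed, round(0.9 * n))
  }
})

test_that("Fisher z comparison behaves at the boundaries", {
  same <- compare_methods(list(a = 0.7, b = 0.7), n = 100)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # a strong correlation is distinguishable from none at n = 100
  strong <- compare_methods(list(good = 0.9, none = 0.0), n = 100)
  expect_lt(strong$p_value, 0.001)
  # order of the pair flips the sign of z but not the p-value
  flipped <- compare_methods(list(none = 0.0, good = 0.9), n = 100)
  expect_equal(flipped$z, -strong$z)
  expect_equal(flipped$p_value, strong$p_value)
  # perfect correlations are clamped, not infinite
  clamped <- compare_methods(list(perfect = 1.0, good = 0.9), n = 50)
  expect_true(is.finite(clamped$z))
  # metrics_report inputs carry their own n
  obs <- c(1, 2, 3, 4, 5, 6); pred <- c(1.1, 1.9, 3.2, 3.8, 5.1, 6.0)
  r1 <- evaluate_predictions(pred, tibble::tibble(ddg_exp = obs))
  cmp <- compare_methods(list(m1 = r1, m2 = r1))
  expect_equal(cmp$p_value, 1)
})

test_that("the synthetic benchmark generator honors its composition contract", {
  tbl <- make_synthetic_mutation_table(n = 400, n_stabilizing = 90,
                                       n_proteins = 25, seed = 5)
  expect_equal(nrow(tbl), 400)
  expect_equal(sum(classify_stability(tbl$ddg_exp) == "stabilizing"), 90)
  expect_equal(length(unique(tbl$pdb_id)), 25)
  expect_false(any(duplicated(paste(tbl$pdb_id, tbl$chain, tbl$mutation))))
  # deterministic per seed
  expect_identical(tbl, make_synthetic_mutation_table(400, 90, 25, seed = 5))
  aug <- augment_reverse(tbl)
  expect_equal(nrow(aug), 800)
})
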