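# Synthetic dataset generators: an S2648-like mutation table (for protocol
# arithmetic and split machinery) and a feature table with a planted linear
# signal (for consensus-recovery checks). Both are deterministic per seed.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Synthetic S2648-like mutation table
#'
#' Emulates the composition of the standard ProTherm-derived benchmark:
#' `n` point mutations across `n_proteins` globular proteins with
#' `n_stabilizing` stabilizing records (ddG >= 0). Destabilizing ddG values
#' are drawn from -|N(1.3, 1)| and stabilizing ones from |N(0.7, 0.6)|,
#' matching the skewed, destabilization-heavy spread of the real benchmark.
#' What it does not emulate: real structures (pdb_ids are synthetic
#' 4-character codes), sequence context, or site redundancy patterns.
#'
#' @param n Total records, default 2648.
#' @param n_stabilizing Records with ddG >= 0, default 602.
#' @param n_proteins Distinct synthetic protein codes, default 131.
#' @param seed Integer seed.
#' @return Forward mutation-record tibble (see [read_mutation_table()]).
#' @export
make_synthetic_mutation_table <- function(n = 2648, n_stabilizing = 602,
                                          n_proteins = 131, seed = 1L) {
  with_seed(seed, {
    codes <- standard_aa_codes()
    pdb_ids <- sprintf("%d%s%s%s", sample(1:9, n_proteins, TRUE),
                       sample(LETTERS, n_proteins, TRUE),
                       sample(LETTERS, n_proteins, TRUE),
                       sample(LETTERS, n_proteins, TRUE))
    pdb_ids <- make.unique(pdb_ids, sep = "")
    pdb <- sample(pdb_ids, n, replace = TRUE)
    resno <- sample(1:250, n, replace = TRUE)
    wild <- sample(codes, n, replace = TRUE)
    mut <- vapply(wild, function(w) sample(setdiff(codes, w), 1), character(1))
    stab <- abs(stats::rnorm(n_stabilizing, 0.7, 0.6))
    destab <- -abs(stats::rnorm(n - n_stabilizing, 1.3, 1.0))
    ddg <- sample(c(stab, destab))
    rec <- tibble::tibble(
      pdb_id = pdb, chain = "A",
      mutation = paste0(wild, resno, mut),
      wild_aa = wild, resno = as.integer(resno), icode = "",
      mutant_aa = mut, ddg_exp = ddg, direction = "forward",
      group_key = paste(pdb, "A", resno, sep = "_"))
    key <- paste(rec$pdb_id, rec$chain, rec$mutation)
    while (anyDuplicated(key)) {
      dup <- which(duplicated(key))
      rec$resno[dup] <- rec$resno[dup] + sample(1:50, length(dup), TRUE)
      rec$mutation[dup] <- paste0(rec$wild_aa[dup], rec$resno[dup],
                                  rec$mutant_aa[dup])
      rec$group_key[dup] <- paste(rec$pdb_id[dup], "A", rec$resno[dup],
                                  sep = "_")
      key <- paste(rec$pdb_id, rec$chain, rec$mutation)
    }
    rec
  })
}

#' Synthetic feature table with a planted linear signal
#'
#' `ddg_exp = coefs[1] * f1 + coefs[2] * f2 + N(0, sigma)` with all features
#' standard normal; `n_noise_features` pure-noise columns are appended. Used
#' to verify that the consensus learner recovers a recoverable signal and
#' returns a null result on permuted targets.
#'
#' @param n Rows, default 2000.
#' @param coefs Signal coefficients, default `c(0.8, -0.5)`.
#' @param sigma Noise standard deviation, default 0.2.
#' @param n_noise_features Extra uninformative features, default 4.
#' @param seed Integer seed.
#' @return Tibble with `f1`, `f2`, noise features, `ddg_exp`, `direction`,
#'   `group_key`.
#' @export
make_synthetic_feature_table <- function(n = 2000, coefs = c(0.8, -0.5),
                                         sigma = 0.2, n_noise_features = 4,
                                         seed = 1L) {
  with_seed(seed, {
    f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
    noise <- matrix(stats::rnorm(n * n_noise_features), n)
    colnames(noise) <- paste0("noise", seq_len(n_noise_features))
    ddg <- coefs[1] * f1 + coefs[2] * f2 + stats::rnorm(n, sd = sigma)
    dplyr::bind_cols(tibble::tibble(f1 = f1, f2 = f2),
                     tibble::as_tibble(noise),
                     tibble::tibble(ddg_exp = ddg, direction = "forward",
                                    group_key = sprintf("row%06d", seq_len(n))))
  })
}
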