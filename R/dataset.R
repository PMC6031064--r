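# Mutation tables, reverse-mutation augmentation, grouped splits and the
# evaluation metrics (Pearson r, RMSE, outlier-trimmed variants, Fisher z
# method comparison).
#
# Package sign convention throughout: ddG >= 0 is stabilizing.

#' Read a mutation table (S2648-style)
#'
#' Expects a CSV/TSV with columns `pdb_id`, `chain`, `mutation`, `ddg`
#' (extra columns are preserved). Mutation strings are parsed as
#' wild-type code + residue number + mutant code. Rows that fail to parse
#' are dropped with a warning listing their line numbers.
#'
#' @param path File path (delimiter sniffed from the header line).
#' @param sign_convention `"stabilizing_positive"` (default; values enter
#'   unchanged) or `"destabilizing_positive"` (values are negated on input).
#' @return Tibble of mutation records: `pdb_id`, `chain`, `mutation`
#'   (string), `wild_aa`, `resno`, `icode`, `mutant_aa`, `ddg_exp`
#'   (kcal/mol, stabilizing positive), `direction` (`"forward"`),
#'   `group_key`.
#' @export
read_mutation_table <- function(path,
                                sign_convention = c("stabilizing_positive",
                                                    "destabilizing_positive")) {
  sign_convention <- match.arg(sign_convention)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  names(raw) <- tolower(names(raw))
  if ("ddg" %in% names(raw)) {
    raw$ddg <- suppressWarnings(as.numeric(raw$ddg))
  }
  needed <- c("pdb_id", "chain", "mutation", "ddg")
  if (!all(needed %in% names(raw))) {
    stop("unknown column layout; found headers: ",
         paste(names(raw), collapse = ", "),
         " (need pdb_id, chain, mutation, ddg)")
  }
  parsed <- lapply(seq_len(nrow(raw)), function(i) {
    tryCatch(parse_mutation(raw$mutation[i], chain = raw$chain[i]),
             error = function(e) NULL)
  })
  bad <- vapply(parsed, is.null, TRUE) | !is.finite(raw$ddg)
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  keep <- which(!bad)
  sgn <- if (sign_convention == "stabilizing_positive") 1 else -1
  tibble::tibble(
    pdb_id = raw$pdb_id[keep],
    chain = raw$chain[keep],
    mutation = toupper(raw$mutation[keep]),
    wild_aa = vapply(parsed[keep], function(m) m$wild_aa, character(1)),
    resno = vapply(parsed[keep], function(m) m$resno, integer(1)),
    icode = vapply(parsed[keep], function(m) m$icode, character(1)),
    mutant_aa = vapply(parsed[keep], function(m) m$mutant_aa, character(1)),
    ddg_exp = sgn * raw$ddg[keep],
    direction = "forward",
    group_key = paste(raw$pdb_id[keep], raw$chain[keep],
                      vapply(parsed[keep], function(m) m$resno, integer(1)),
                      sep = "_")
  )
}

#' Add hypothetical reverse mutations
#'
#' The change in folding free energy is a thermodynamic state function, so
#' each measured forward mutation implies a reverse mutation with swapped
#' amino acids and negated ddG. Output holds each forward record plus its
#' reverse partner (sharing `group_key`), doubling the table.
#'
#' @param records Forward mutation records (as from
#'   [read_mutation_table()]).
#' @return Tibble of 2x the (de-duplicated) input rows.
#' @export
augment_reverse <- function(records) {
  if (any(records$direction != "forward")) {
    stop("augment_reverse expects forward records only")
  }
  key <- paste(records$pdb_id, records$chain, records$mutation, records$icode)
  if (anyDuplicated(key)) {
    warning(sprintf("de-duplicated %d duplicate forward record(s)",
                    sum(duplicated(key))))
    records <- records[!duplicated(key), ]
  }
  rev <- records
  rev$wild_aa <- records$mutant_aa
  rev$mutant_aa <- records$wild_aa
  rev$mutation <- paste0(rev$wild_aa, rev$resno, rev$icode, rev$mutant_aa)
  rev$ddg_exp <- ifelse(records$ddg_exp == 0, 0, -records$ddg_exp)
  rev$direction <- "reverse"
  dplyr::bind_rows(records, rev)
}

#' Group-aware data splits
#'
#' Splits operate on `group_key`, so a forward record and its hypothetical
#' reverse (and any records sharing a site) never straddle a fold or the
#' train/blind boundary. Deterministic per seed.
#'
#' @param records Mutation records.
#' @param mode `"kfold"` (default) or `"train_blind"`.
#' @param k Number of folds (kfold mode), default 10.
#' @param blind_fraction Fraction of groups held out (train_blind mode),
#'   default 0.132 (the 351-of-2648 convention).
#' @param seed Integer seed.
#' @return `kfold`: integer vector of fold assignments (1..k per record).
#'   `train_blind`: character vector of `"train"` / `"blind"`.
#' @export
make_splits <- function(records, mode = c("kfold", "train_blind"), k = 10,
                        blind_fraction = 351 / 2648, seed = 1L) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) stop("no records to split")
  groups <- unique(records$group_key)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  shuffled <- sample(groups)
  if (mode == "kfold") {
    if (k > length(groups)) {
      stop(sprintf("k = %d exceeds the %d available groups", k, length(groups)))
    }
    fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                                     shuffled)
    return(unname(fold_of_group[records$group_key]))
  }
  n_blind <- round(length(groups) * blind_fraction)
  blind_groups <- shuffled[seq_len(n_blind)]
  ifelse(records$group_key %in% blind_groups, "blind", "train")
}

#' Classify a ddG value
#'
#' `ddG >= 0` is stabilizing, `ddG < 0` destabilizing (the boundary is
#' included on the stabilizing side).
#'
#' @param ddg Numeric vector, kcal/mol.
#' @return Character vector of `"stabilizing"` / `"destabilizing"`.
#' @export
classify_stability <- function(ddg) {
  if (any(is.na(ddg))) stop("ddg contains NA/NaN")
  ifelse(ddg >= 0, "stabilizing", "destabilizing")
}

pearson_or_na <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

metrics_pair <- function(pred, obs) {
  list(n = length(obs),
       pearson_r = pearson_or_na(pred, obs),
       rmse = sqrt(mean((pred - obs)^2)))
}

#' Evaluate ddG predictions against experimental values
#'
#' Computes Pearson r and RMSE over all records, outlier-trimmed variants
#' after dropping the `outlier_fraction` of records with the largest
#' absolute error (ties broken by stable record order), and sub-reports for
#' forward-only, reverse-only, stabilizing-only and destabilizing-only
#' subsets.
#'
#' @param predictions Numeric vector of predicted ddG, aligned with
#'   `records`.
#' @param records Mutation records with `ddg_exp` (and optionally
#'   `direction`).
#' @param outlier_fraction Fraction trimmed, default 0.10.
#' @return A `metrics_report` list; see [tidy.metrics_report()].
#' @export
evaluate_predictions <- function(predictions, records, outlier_fraction = 0.10) {
  obs <- records$ddg_exp
  n <- length(obs)
  if (length(predictions) != n) stop("predictions and records misaligned")
  if (n < 3) stop("need at least 3 records")
  overall <- metrics_pair(predictions, obs)
  n_keep <- round(n * (1 - outlier_fraction))
  err <- abs(predictions - obs)
  keep <- order(err, seq_len(n))[seq_len(n_keep)]  # stable tie-break
  trimmed <- metrics_pair(predictions[keep], obs[keep])
  sub <- list()
  subsets <- list(
    forward = if ("direction" %in% names(records)) records$direction == "forward",
    reverse = if ("direction" %in% names(records)) records$direction == "reverse",
    stabilizing = classify_stability(obs) == "stabilizing",
    destabilizing = classify_stability(obs) == "destabilizing")
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    if (!is.null(s) && sum(s) >= 3) sub[[nm]] <- metrics_pair(predictions[s], obs[s])
  }
  structure(list(n = overall$n, pearson_r = overall$pearson_r,
                 rmse = overall$rmse,
                 n_trimmed = trimmed$n, pearson_r_trimmed = trimmed$pearson_r,
                 rmse_trimmed = trimmed$rmse,
                 outlier_fraction = outlier_fraction,
                 subsets = sub),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d: r = %.3f, RMSE = %.3f kcal/mol\n",
              x$n, x$pearson_r, x$rmse))
  cat(sprintf("  trimmed (top %.0f%% |error| removed, n = %d): r = %.3f, RMSE = %.3f\n",
              100 * x$outlier_fraction, x$n_trimmed, x$pearson_r_trimmed,
              x$rmse_trimmed))
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    cat(sprintf("  %-13s n = %4d: r = %.3f, RMSE = %.3f\n", nm, s$n,
                ifelse(is.na(s$pearson_r), NA, s$pearson_r), s$rmse))
  }
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with one row per subset (`overall`, `trimmed`, and any
#'   direction/class subsets) and columns `subset`, `n`, `pearson_r`,
#'   `rmse`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(subset = "overall", n = x$n, pearson_r = x$pearson_r,
                   rmse = x$rmse),
    tibble::tibble(subset = "trimmed", n = x$n_trimmed,
                   pearson_r = x$pearson_r_trimmed, rmse = x$rmse_trimmed))
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    rows[[length(rows) + 1]] <- tibble::tibble(subset = nm, n = s$n,
                                               pearson_r = s$pearson_r,
                                               rmse = s$rmse)
  }
  dplyr::bind_rows(rows)
}

#' Compare correlation coefficients between methods (Fisher z-test)
#'
#' Two-sided z-test on Fisher-transformed Pearson correlations, applied to
#' every pair of named reports. Correlations with |r| = 1 are clamped to
#' 1 - 1e-12 before the transform.
#'
#' @param reports Named list of `metrics_report` objects (or named numeric
#'   correlations).
#' @param n Sample size(s): single value or named vector; defaults to each
#'   report's `n`.
#' @return Tibble: `method_a`, `method_b`, `r_a`, `r_b`, `z`, `p_value`.
#' @export
compare_methods <- function(reports, n = NULL) {
  rs <- vapply(reports, function(x)
    if (inherits(x, "metrics_report")) x$pearson_r else as.numeric(x),
    numeric(1))
  ns <- if (!is.null(n)) {
    if (length(n) == 1) stats::setNames(rep(n, length(reports)), names(reports))
    else n
  } else {
    vapply(reports, function(x) {
      if (inherits(x, "metrics_report")) x$n else stop("n required")
    }, numeric(1))
  }
  fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  out <- list()
  nm <- names(reports)
  for (a in seq_along(nm)) {
    for (b in seq_along(nm)) {
      if (b <= a) next
      se <- sqrt(1 / (ns[[a]] - 3) + 1 / (ns[[b]] - 3))
      z <- (fisher_z(rs[[a]]) - fisher_z(rs[[b]])) / se
      out[[length(out) + 1]] <- tibble::tibble(
        method_a = nm[a], method_b = nm[b], r_a = rs[[a]], r_b = rs[[b]],
        z = z, p_value = 2 * stats::pnorm(-abs(z)))
    }
  }
  dplyr::bind_rows(out)
}
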