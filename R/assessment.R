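#' SCOP-style homology labels
#'
#' @param ids Profile identifiers.
#' @param class,fold,superfamily,family Parallel identifier vectors.
#' @return A tibble with one row per profile.
#' @export
homology_labels <- function(ids, class, fold, superfamily, family) {
  tibble::tibble(profile_id = as.character(ids), class = as.character(class),
                 fold = as.character(fold),
                 superfamily = as.character(superfamily),
                 family = as.character(family))
}

#' Read / write a two-column label TSV
#'
#' Format: `profile_id <TAB> class.fold.superfamily.family` (SCOP-ccs
#' style dot-separated identifier).
#'
#' @param path File path.
#' @param labels A label tibble from [homology_labels()].
#' @return `read_labels()`: a label tibble.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  parts <- strsplit(tab[[2]], ".", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    abort("label identifiers must have 4 dot-separated fields",
          class = "alignhush_format_error")
  }
  homology_labels(tab[[1]],
                  vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2),
                  vapply(parts, `[[`, "", 3), vapply(parts, `[[`, "", 4))
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  writeLines(sprintf("%s\t%s.%s.%s.%s", labels$profile_id, labels$class,
                     labels$fold, labels$superfamily, labels$family), path)
  invisible(path)
}

#' Classify the benchmark relation between two labelled profiles
#'
#' True positives are pairs of distinct families in the same
#' superfamily; false positives are pairs from different classes.
#' Intermediate relations are ignored: same fold but different
#' superfamily, different folds in the same class, and same-family pairs
#' (a family is not its own remote homolog).
#'
#' @param a,b Single-row label tibbles (or named lists) with fields
#'   `class`, `fold`, `superfamily`, `family`.
#' @return One of `"TRUE_POSITIVE_ELIGIBLE"`, `"FALSE_POSITIVE_ELIGIBLE"`,
#'   `"IGNORED"`.
#' @export
classify_relation <- function(a, b) {
  need <- c("class", "fold", "superfamily", "family")
  if (!all(need %in% names(a)) || !all(need %in% names(b)) ||
      anyNA(c(a[need], b[need], recursive = TRUE))) {
    abort("missing homology label", class = "alignhush_label_error")
  }
  if (a$family == b$family && a$superfamily == b$superfamily) return("IGNORED")
  if (a$superfamily == b$superfamily && a$fold == b$fold) return("TRUE_POSITIVE_ELIGIBLE")
  if (a$class != b$class) return("FALSE_POSITIVE_ELIGIBLE")
  "IGNORED"  # same fold/different superfamily, or same class/different fold
}

#' Attach relation classes to a hit table
#'
#' Deduplicates to the best-scoring hit per unordered profile pair
#' (matching the unordered-pair sensitivity denominator of
#' [count_true_relations()], so a relationship found in both search
#' directions is counted once), drops self hits, and classifies every
#' remaining pair against the label set.
#'
#' @param hits Tibble with at least `query`, `target`, `score`.
#' @param labels Label tibble from [homology_labels()].
#' @return `hits` with an added `relation` column.
#' @export
classify_hits <- function(hits, labels) {
  lab <- split(labels, labels$profile_id)
  hits <- hits |>
    dplyr::filter(.data$query != .data$target) |>
    dplyr::mutate(.pair = paste(pmin(.data$query, .data$target),
                                pmax(.data$query, .data$target))) |>
    dplyr::group_by(.data$.pair) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".pair")
  hits$relation <- vapply(seq_len(nrow(hits)), function(k) {
    la <- lab[[hits$query[k]]]; lb <- lab[[hits$target[k]]]
    if (is.null(la) || is.null(lb)) {
      abort(sprintf("no homology label for '%s' or '%s'",
                    hits$query[k], hits$target[k]),
            class = "alignhush_label_error")
    }
    classify_relation(la, lb)
  }, character(1))
  hits
}

#' Count the true relations in a label set
#'
#' The sensitivity denominator TP + FN: the number of unordered pairs of
#' distinct families classified `TRUE_POSITIVE_ELIGIBLE`.
#'
#' @param labels Label tibble (one row per profile).
#' @return Integer count.
#' @export
count_true_relations <- function(labels) {
  n <- nrow(labels)
  total <- 0L
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (classify_relation(labels[a, ], labels[b, ]) == "TRUE_POSITIVE_ELIGIBLE") {
      total <- total + 1L
    }
  }
  if (total == 0L) {
    abort("label set contains no true relations", class = "alignhush_benchmark_error")
  }
  total
}

#' Sensitivity / error-rate curve over a ranked hit list
#'
#' Sweeps a score threshold from the best hit downwards, accumulating
#' true and false positives over eligible hits only (`IGNORED` hits are
#' skipped and do not affect the curve), and emits `sensitivity =
#' TP / (TP + FN)` and `error = FP / (FP + TP)` at each eligible hit.
#'
#' @param classified_hits Output of [classify_hits()] (needs `score` and
#'   `relation`).
#' @param n_true Total number of true relations (TP + FN), from
#'   [count_true_relations()].
#' @param by Ranking column, `"score"` (descending) or `"evalue"`
#'   (ascending).
#' @return A tibble of class `hush_curve` with columns `threshold`,
#'   `tp`, `fp`, `sensitivity`, `error`.
#' @export
sensitivity_error_curve <- function(classified_hits, n_true, by = "score") {
  if (n_true < 1) abort("n_true must be positive", class = "alignhush_benchmark_error")
  el <- classified_hits[classified_hits$relation != "IGNORED", , drop = FALSE]
  if (nrow(el) == 0L) {
    return(structure(tibble::tibble(threshold = numeric(0), tp = integer(0),
                                    fp = integer(0), sensitivity = numeric(0),
                                    error = numeric(0)),
                     class = c("hush_curve", "tbl_df", "tbl", "data.frame")))
  }
  ord <- if (by == "evalue") order(el$evalue) else order(-el$score)
  el <- el[ord, ]
  tp <- cumsum(el$relation == "TRUE_POSITIVE_ELIGIBLE")
  fp <- cumsum(el$relation == "FALSE_POSITIVE_ELIGIBLE")
  structure(tibble::tibble(threshold = if (by == "evalue") el$evalue else el$score,
                           tp = tp, fp = fp,
                           sensitivity = tp / n_true,
                           error = fp / (fp + tp)),
            class = c("hush_curve", "tbl_df", "tbl", "data.frame"))
}

#' Sensitivity at a fixed error rate
#'
#' The highest sensitivity attained at any point of the curve whose
#' error rate does not exceed `error_rate`.
#'
#' @param curve A `hush_curve`.
#' @param error_rate Error-rate budget (default 0.10).
#' @return Scalar sensitivity (0 when the curve never dips below the
#'   budget).
#' @export
sensitivity_at_error <- function(curve, error_rate = 0.10) {
  ok <- curve$error <= error_rate
  if (!any(ok)) return(0)
  max(curve$sensitivity[ok])
}

#' Rank-based ROC AUC of two score samples
#'
#' Probability that a randomly chosen positive outranks a randomly
#' chosen negative (ties count 1/2); the Mann-Whitney statistic divided
#' by `n_pos * n_neg`.
#'
#' @param pos,neg Numeric score vectors for positive and negative pairs.
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) abort("need scores in both classes")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Compose sequence-profile and profile-profile alignments
#'
#' Transitively combines `seq -> profile P`, `P -> Q` (MM pairs of a
#' profile-profile alignment) and `Q -> seq` maps into a residue-residue
#' alignment: the pair `(r1, r2)` is emitted iff `r1` maps to P column
#' `i`, `(i, j)` is an aligned MM pair, and column `j` maps to `r2`.
#'
#' @param seq_to_p Two-column matrix/data frame `(residue, column)`
#'   mapping residues of sequence 1 to match columns of P; strictly
#'   increasing in both columns.
#' @param p_to_q A `hush_alignment` (or a two-column matrix of `(i, j)`
#'   pairs).
#' @param q_to_seq Two-column matrix/data frame `(column, residue)`
#'   mapping match columns of Q to residues of sequence 2.
#' @return A tibble `(r1, r2)`, strictly increasing in both columns.
#' @export
compose_alignments <- function(seq_to_p, p_to_q, q_to_seq) {
  pairs <- if (inherits(p_to_q, "hush_alignment")) p_to_q$pairs else as.matrix(p_to_q)
  sp <- as.matrix(seq_to_p); qs <- as.matrix(q_to_seq)
  check_monotone <- function(m, what) {
    if (nrow(m) >= 2 && (any(diff(m[, 1]) <= 0) || any(diff(m[, 2]) <= 0))) {
      abort(sprintf("%s mapping is not strictly increasing", what),
            class = "alignhush_contract_error")
    }
  }
  check_monotone(sp, "sequence-to-profile")
  check_monotone(pairs, "profile-profile")
  check_monotone(qs, "profile-to-sequence")
  if (nrow(pairs) == 0L || nrow(sp) == 0L || nrow(qs) == 0L) {
    return(tibble::tibble(r1 = integer(0), r2 = integer(0)))
  }
  r1_of_i <- setNames(sp[, 1], sp[, 2])
  r2_of_j <- setNames(qs[, 2], qs[, 1])
  r1 <- r1_of_i[as.character(pairs[, 1])]
  r2 <- r2_of_j[as.character(pairs[, 2])]
  keep <- !is.na(r1) & !is.na(r2)
  tibble::tibble(r1 = as.integer(r1[keep]), r2 = as.integer(r2[keep]))
}

#' Developer and modeller alignment accuracy
#'
#' Against a gold-standard reference alignment: `correct` is the number
#' of residue pairs shared by test and reference; the developer score
#' divides by the number of test pairs falling inside the reference's
#' covered region (on both sequences), the modeller score by the
#' reference length. An empty test alignment scores (0, 0) by
#' convention.
#'
#' @param test Tibble/matrix of test residue pairs `(r1, r2)`.
#' @param reference Tibble/matrix of reference residue pairs.
#' @return A tibble with columns `developer`, `modeller`, `correct`,
#'   `test_in_region`, `reference_length`.
#' @export
alignment_accuracy <- function(test, reference) {
  ref <- as.matrix(reference)
  if (nrow(ref) == 0L) {
    abort("empty reference alignment", class = "alignhush_accuracy_error")
  }
  tst <- as.matrix(test)
  ref_keys <- paste(ref[, 1], ref[, 2])
  if (nrow(tst) == 0L) {
    return(tibble::tibble(developer = 0, modeller = 0, correct = 0L,
                          test_in_region = 0L, reference_length = nrow(ref)))
  }
  correct <- sum(paste(tst[, 1], tst[, 2]) %in% ref_keys)
  in_region <- tst[, 1] >= min(ref[, 1]) & tst[, 1] <= max(ref[, 1]) &
    tst[, 2] >= min(ref[, 2]) & tst[, 2] <= max(ref[, 2])
  denom <- sum(in_region)
  tibble::tibble(developer = if (denom > 0) correct / denom else 0,
                 modeller = correct / nrow(ref),
                 correct = as.integer(correct),
                 test_in_region = as.integer(denom),
                 reference_length = nrow(ref))
}

#' Grid-search scoring parameters on a labelled benchmark
#'
#' Evaluates every grid point by aligning all unordered profile pairs,
#' building the sensitivity/error curve and reading off the sensitivity
#' at a fixed error-rate budget; returns the best point, with ties
#' broken toward smaller windows and then smaller weights.
#'
#' @param profiles Named list of [hush_profile()]s.
#' @param labels Label tibble covering every profile.
#' @param grid A data frame whose columns are [hush_params()] arguments
#'   (e.g. `Wh`, `Ws`, `win_c`); unspecified parameters keep their
#'   defaults.
#' @param error_rate Error-rate budget for the criterion (default 0.10).
#' @param base_params Defaults for parameters absent from the grid.
#' @return List with `params` (the winning [hush_params()]), `best`
#'   (winning grid row with its sensitivity) and `grid` (the full grid
#'   with a `sensitivity` column).
#' @export
tune_parameters <- function(profiles, labels, grid, error_rate = 0.10,
                            base_params = hush_params()) {
  grid <- unique(as.data.frame(grid))
  if (nrow(grid) == 0L) abort("empty tuning grid", class = "alignhush_config_error")
  n_true <- count_true_relations(labels)
  grid$sensitivity <- NA_real_
  for (g in seq_len(nrow(grid))) {
    pars <- utils::modifyList(unclass(base_params), as.list(grid[g, , drop = FALSE]))
    pars$sensitivity <- NULL
    params <- do.call(hush_params, pars[names(pars) %in% names(formals(hush_params))])
    hits <- pairwise_hits(profiles, params)
    curve <- sensitivity_error_curve(classify_hits(hits, labels), n_true)
    grid$sensitivity[g] <- sensitivity_at_error(curve, error_rate)
  }
  tie_cols <- intersect(c("win_c", "win_h", "win_s", "Wc", "Wh", "Ws", "Wg"),
                        names(grid))
  ord <- do.call(order, c(list(-grid$sensitivity), grid[tie_cols]))
  best <- grid[ord[1], , drop = FALSE]
  pars <- utils::modifyList(unclass(base_params),
                            as.list(best[setdiff(names(best), "sensitivity")]))
  list(params = do.call(hush_params,
                        pars[names(pars) %in% names(formals(hush_params))]),
       best = tibble::as_tibble(best), grid = tibble::as_tibble(grid))
}

#' All unordered pairwise alignments of a profile set
#'
#' @param profiles Named list of [hush_profile()]s.
#' @param params A [hush_params()].
#' @return Hit tibble (`query`, `target`, `score`, `n_pairs`).
#' @export
pairwise_hits <- function(profiles, params = hush_params()) {
  nm <- names(profiles)
  out <- list()
  np <- length(profiles)
  if (np >= 2) for (a in 1:(np - 1)) for (b in (a + 1):np) {
    aln <- viterbi_align(profiles[[a]], profiles[[b]], params)
    out[[length(out) + 1L]] <- tibble::tibble(query = nm[a], target = nm[b],
                                              score = aln$score,
                                              n_pairs = nrow(aln$pairs))
  }
  dplyr::bind_rows(out)
}
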