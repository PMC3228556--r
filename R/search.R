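#' Search a profile database with one query profile
#'
#' Aligns the query against every target with [viterbi_align()] and
#' returns a ranked hit table. When an [EvalueFit][calibrate()] is
#' supplied, hits carry E-values (with `db_size` defaulting to the
#' number of targets searched) and are ranked by E-value; otherwise by
#' score. Ties are broken by target name so the ranking is independent
#' of database order. Per-target failures are logged as warnings and
#' skipped.
#'
#' @param query A [hush_profile()].
#' @param database A (named or not) list of [hush_profile()] targets.
#' @param params A [hush_params()].
#' @param fit Optional `hush_evalue_fit` from [calibrate()].
#' @return A tibble with columns `query`, `target`, `score`, `evalue`
#'   (`NA` without a fit), `n_pairs`, `i_from`, `i_to`, `j_from`,
#'   `j_to`; the alignments themselves are attached as the
#'   `"alignments"` attribute (a list parallel to the rows).
#' @export
align_all <- function(query, database, params = hush_params(), fit = NULL) {
  if (length(database) == 0L) abort("empty database")
  alns <- vector("list", length(database))
  failures <- 0L
  for (k in seq_along(database)) {
    alns[[k]] <- tryCatch(viterbi_align(query, database[[k]], params),
                          error = function(e) {
                            warn(sprintf("target %d failed: %s", k, conditionMessage(e)))
                            NULL
                          })
    if (is.null(alns[[k]])) failures <- failures + 1L
  }
  keep <- !vapply(alns, is.null, logical(1))
  alns <- alns[keep]
  hits <- purrr::map_dfr(alns, function(a) {
    tibble::tibble(
      query = a$query, target = a$target, score = a$score,
      n_pairs = nrow(a$pairs),
      i_from = if (nrow(a$pairs)) min(a$pairs[, 1]) else NA_integer_,
      i_to = if (nrow(a$pairs)) max(a$pairs[, 1]) else NA_integer_,
      j_from = if (nrow(a$pairs)) min(a$pairs[, 2]) else NA_integer_,
      j_to = if (nrow(a$pairs)) max(a$pairs[, 2]) else NA_integer_)
  })
  hits$evalue <- if (!is.null(fit)) {
    db_size <- if (is.na(fit$db_size)) nrow(hits) else fit$db_size
    evalue(hits$score, fit, db_size = db_size)
  } else {
    NA_real_
  }
  ord <- if (!is.null(fit)) order(hits$evalue, hits$target)
         else order(-hits$score, hits$target)
  hits <- hits[ord, c("query", "target", "score", "evalue", "n_pairs",
                      "i_from", "i_to", "j_from", "j_to")]
  attr(hits, "alignments") <- alns[ord]
  attr(hits, "failures") <- failures
  hits
}

#' Write a per-hit alignment report
#'
#' Plain-text report (query/target names, score, E-value when present,
#' aligned index ranges) followed by a TSV block of aligned pairs
#' `(i, j, state)`.
#'
#' @param aln A `hush_alignment`.
#' @param evalue Optional E-value to print.
#' @param path Output path, or `NULL` to return the lines.
#' @return The report lines, invisibly when written to `path`.
#' @export
report_alignment <- function(aln, evalue = NULL, path = NULL) {
  hdr <- c(
    sprintf("# query  %s", aln$query),
    sprintf("# target %s", aln$target),
    sprintf("# score  %.4f", aln$score),
    if (!is.null(evalue)) sprintf("# evalue %.4g", evalue),
    if (nrow(aln$pairs)) sprintf("# range  query %d-%d target %d-%d",
                                 min(aln$pairs[, 1]), max(aln$pairs[, 1]),
                                 min(aln$pairs[, 2]), max(aln$pairs[, 2]))
    else "# empty alignment",
    "i\tj\tstate")
  body <- sprintf("%d\t%d\t%s", aln$path$i, aln$path$j, aln$path$state)
  lines <- c(hdr, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(lines)
  } else {
    lines
  }
}
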