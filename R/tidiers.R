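#' Tidy an alignment into a tibble of aligned pairs
#'
#' @param x A `hush_alignment`.
#' @param ... Unused.
#' @return Tibble with columns `query`, `target`, `state`, `i`, `j`.
#' @method tidy hush_alignment
#' @export
tidy.hush_alignment <- function(x, ...) {
  dplyr::mutate(x$path, query = x$query, target = x$target,
                .before = 1)
}

#' One-row summary of an alignment
#'
#' @param x A `hush_alignment`.
#' @param ... Unused.
#' @return One-row tibble: `query`, `target`, `score`, `n_pairs`,
#'   `n_gap_steps`, coverage fractions of both profiles.
#' @method glance hush_alignment
#' @export
glance.hush_alignment <- function(x, ...) {
  tibble::tibble(query = x$query, target = x$target, score = x$score,
                 n_pairs = nrow(x$pairs),
                 n_gap_steps = nrow(x$path) - nrow(x$pairs))
}

#' Tidy an E-value calibration fit
#'
#' @param x A `hush_evalue_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates (`term`, `estimate`).
#' @method tidy hush_evalue_fit
#' @export
tidy.hush_evalue_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "mu"), estimate = c(x$lambda, x$mu))
}

#' One-row summary of an E-value calibration
#'
#' @param x A `hush_evalue_fit`.
#' @param ... Unused.
#' @return One-row tibble: `lambda`, `mu`, `n_calibration`, `db_size`,
#'   `reliable`.
#' @method glance hush_evalue_fit
#' @export
glance.hush_evalue_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, mu = x$mu,
                 n_calibration = x$n_calibration, db_size = x$db_size,
                 reliable = x$reliable)
}

#' Plot a sensitivity/error-rate curve
#'
#' @param object A `hush_curve` from [sensitivity_error_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hush_curve
#' @export
autoplot.hush_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$error, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "error rate  FP / (FP + TP)",
                  y = "sensitivity  TP / (TP + FN)") +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit against its score sample
#'
#' Histogram of the calibration scores with the fitted Gumbel density.
#'
#' @param object A `hush_evalue_fit` carrying its raw scores.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hush_evalue_fit
#' @export
autoplot.hush_evalue_fit <- function(object, ...) {
  if (is.null(object$scores)) abort("fit carries no raw scores to plot")
  df <- tibble::tibble(score = object$scores)
  dens <- function(x) {
    z <- object$lambda * (x - object$mu)
    object$lambda * exp(-z - exp(-z))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey50") +
    ggplot2::stat_function(fun = dens, colour = "firebrick") +
    ggplot2::labs(x = "Viterbi score (bits)", y = "density") +
    ggplot2::theme_minimal()
}
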