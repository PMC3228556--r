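#' Fit a Gumbel (extreme-value) distribution by maximum likelihood
#'
#' Local alignment scores of a query against random (unrelated) profiles
#' follow an extreme-value distribution; this fits the Gumbel location
#' `mu` and inverse-scale `lambda` by maximum likelihood with
#' moment-based initialisation. Optionally the top `censor_frac` of the
#' sample is treated as right-censored (type-2 censoring), which guards
#' the fit against contamination by true homologs hiding in a randomly
#' selected calibration database.
#'
#' @param x Numeric score sample.
#' @param censor_frac Fraction of the largest scores to censor
#'   (default 0: plain MLE).
#' @return List with `lambda`, `mu`, `n`.
#' @export
fit_gumbel <- function(x, censor_frac = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0) {
    abort("degenerate score sample: cannot fit an extreme-value distribution",
          class = "alignhush_calibration_error")
  }
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0

  r <- floor(censor_frac * n)
  xs <- sort(x)
  obs <- if (r > 0) xs[seq_len(n - r)] else xs
  cens_at <- if (r > 0) xs[n - r] else NULL

  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (obs - mu) / beta
    ll <- sum(-z - exp(-z) - log(beta))
    if (r > 0) {
      zc <- (cens_at - mu) / beta
      surv <- 1 - exp(-exp(-zc))
      ll <- ll + r * log(max(surv, 1e-300))
    }
    -ll
  }
  opt <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  list(lambda = 1 / exp(opt$par[2]), mu = opt$par[1], n = n)
}

#' Calibrate a query profile's E-value parameters
#'
#' Aligns the query against every profile of a random database and fits
#' a Gumbel distribution to the resulting Viterbi scores. The fit is per
#' query (per family), avoiding database-wide parameters that are biased
#' by profile length and composition.
#'
#' @param query A [hush_profile()].
#' @param random_db List of random/unrelated [hush_profile()]s (at least
#'   50 for the fit to be marked reliable).
#' @param params A [hush_params()].
#' @param censor_frac Top fraction of calibration scores treated as
#'   censored (default 0.01).
#' @param db_size Effective database size used when converting scores to
#'   E-values; `NA` (default) defers to the size of the database
#'   actually searched later.
#' @return An object of class `hush_evalue_fit`: list with `lambda`,
#'   `mu`, `n_calibration`, `db_size`, `reliable`, `scores`.
#' @export
calibrate <- function(query, random_db, params = hush_params(),
                      censor_frac = 0.01, db_size = NA_real_) {
  scores <- vapply(random_db, function(t) viterbi_align(query, t, params)$score,
                   numeric(1))
  fit <- fit_gumbel(scores, censor_frac = censor_frac)
  structure(list(lambda = fit$lambda, mu = fit$mu,
                 n_calibration = length(scores), db_size = db_size,
                 reliable = length(scores) >= 50, scores = scores),
            class = "hush_evalue_fit")
}

#' @export
print.hush_evalue_fit <- function(x, ...) {
  cat(sprintf("<hush_evalue_fit> lambda=%.4f mu=%.3f (n=%d%s)\n",
              x$lambda, x$mu, x$n_calibration,
              if (x$reliable) "" else ", unreliable"))
  invisible(x)
}

#' Convert alignment scores to E-values
#'
#' `E = N * p` with `p = 1 - exp(-exp(-lambda (s - mu)))`, the Gumbel
#' exceedance probability; clamped to `[0, N]`.
#'
#' @param score Numeric vector of scores (bits).
#' @param fit A `hush_evalue_fit`.
#' @param db_size Effective database size `N`; defaults to the fit's.
#' @return Numeric vector of E-values.
#' @export
evalue <- function(score, fit, db_size = fit$db_size) {
  if (is.na(db_size)) abort("no effective database size available")
  p <- 1 - exp(-exp(-fit$lambda * (score - fit$mu)))
  pmin(pmax(db_size * p, 0), db_size)
}

#' Build a random calibration database
#'
#' Seeded sampling without replacement from a profile pool; optionally
#' each sampled profile's match-state order is shuffled
#' (`shuffle = TRUE`) to destroy any residual homology while preserving
#' the multiset of columns.
#'
#' @param profile_pool List of [hush_profile()]s.
#' @param size Number of profiles to draw.
#' @param seed Integer seed (recorded for reproducibility).
#' @param shuffle Also permute match-state order within each profile.
#' @return List of [hush_profile()]s with attribute `seed`.
#' @export
make_random_db <- function(profile_pool, size = 200, seed = 1, shuffle = FALSE) {
  if (length(profile_pool) == 0L) abort("empty profile pool")
  if (size > length(profile_pool) && !shuffle) {
    abort(sprintf("requested %d profiles from a pool of %d without shuffling",
                  size, length(profile_pool)),
          class = "alignhush_sampling_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- if (size <= length(profile_pool)) {
    sample(length(profile_pool), size)
  } else {
    sample(length(profile_pool), size, replace = TRUE)
  }
  db <- lapply(seq_along(idx), function(k) {
    p <- profile_pool[[idx[k]]]
    if (shuffle) p <- shuffle_profile(p, suffix = k)
    p
  })
  attr(db, "seed") <- seed
  db
}

# Permute match-state order (emissions, annotations and transitions move
# together); the per-column content is preserved, positional structure is not.
shuffle_profile <- function(p, suffix = NULL) {
  perm <- sample(p$length)
  hush_profile(
    name = paste0(p$name, "_shuf", if (!is.null(suffix)) suffix),
    odds = p$odds[perm, , drop = FALSE],
    hydro = p$hydro[perm],
    ss = p$ss[perm, , drop = FALSE],
    ss_annotated = p$ss_annotated[perm],
    trans = p$trans[perm, , drop = FALSE],
    background = p$background,
    provenance = paste(p$provenance, "(column-shuffled)"))
}

#' Write / read an E-value calibration sidecar file
#'
#' Small text sidecar (`key value` lines) storing `lambda`, `mu`,
#' `n_calibration` and `db_size` for a calibrated profile.
#'
#' @param fit A `hush_evalue_fit`.
#' @param path File path.
#' @return `write_evalue_fit()`: `path` invisibly; `read_evalue_fit()`:
#'   a `hush_evalue_fit` (without the raw calibration scores).
#' @export
write_evalue_fit <- function(fit, path) {
  writeLines(c("ALIGNHUSH-CALIBRATION 1",
               sprintf("lambda %.10g", fit$lambda),
               sprintf("mu %.10g", fit$mu),
               sprintf("n_calibration %d", fit$n_calibration),
               sprintf("db_size %.10g", fit$db_size)), path)
  invisible(path)
}

#' @rdname write_evalue_fit
#' @export
read_evalue_fit <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "ALIGNHUSH-CALIBRATION")) {
    abort("not a calibration sidecar", class = "alignhush_format_error")
  }
  kv <- strsplit(lines[-1], "\\s+")
  vals <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(kv, `[[`, "", 1))
  structure(list(lambda = vals[["lambda"]], mu = vals[["mu"]],
                 n_calibration = as.integer(vals[["n_calibration"]]),
                 db_size = vals[["db_size"]],
                 reliable = vals[["n_calibration"]] >= 50, scores = NULL),
            class = "hush_evalue_fit")
}
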