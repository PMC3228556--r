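#' Scoring parameters for profile-profile alignment
#'
#' Bundles the term weights, window widths, hydrophobic-score offset and
#' SS substitution table that define the column match score
#' \deqn{M(i,j) = W_c \sum_w S_{cons} + W_h \sum_w S_{hyd} + W_s \sum_w S_{ss}}
#' plus the gap-penalty weight `Wg` applied to every log-transition term
#' of the pair-HMM recurrences.
#'
#' Defaults: `Wc = 1`, `Wh = 0.3`, `Ws = 0.3`, `Wg = 1`, all three
#' windows 5 columns wide, `hydro_offset = 1.5` Kyte-Doolittle units.
#' Setting `Wh = 0` / `Ws = 0` / all windows to 1 reproduces the
#' `no_hyd` / `no_sec` / `no_neigh` scoring variants.
#'
#' @param Wc,Wh,Ws Non-negative weights of the conservation,
#'   hydrophobicity and secondary-structure terms.
#' @param Wg Non-negative weight on the log transition (gap-penalty)
#'   terms of the alignment recurrences.
#' @param win_c,win_h,win_s Odd positive window widths (columns) for the
#'   three terms.
#' @param hydro_offset Offset `c0` (Kyte-Doolittle units) of the
#'   hydrophobic similarity `c0 - |Hx - Hy|`.
#' @param ss_table A `hush_ss_table`; defaults to [default_ss_table()].
#' @return An object of class `hush_params` (a list).
#' @export
hush_params <- function(Wc = 1, Wh = 0.3, Ws = 0.3, Wg = 1,
                        win_c = 5, win_h = 5, win_s = 5,
                        hydro_offset = 1.5, ss_table = default_ss_table()) {
  for (w in c(win_c, win_h, win_s)) {
    if (w < 1 || w %% 2 != 1) abort("window widths must be odd and >= 1")
  }
  if (any(c(Wc, Wh, Ws, Wg) < 0)) abort("weights must be non-negative")
  structure(list(Wc = Wc, Wh = Wh, Ws = Ws, Wg = Wg,
                 win_c = win_c, win_h = win_h, win_s = win_s,
                 hydro_offset = hydro_offset, ss_table = ss_table),
            class = "hush_params")
}

#' @export
print.hush_params <- function(x, ...) {
  cat(sprintf(
    "<hush_params> Wc=%g Wh=%g Ws=%g Wg=%g | windows c/h/s = %d/%d/%d | hydro_offset=%g\n",
    x$Wc, x$Wh, x$Ws, x$Wg, x$win_c, x$win_h, x$win_s, x$hydro_offset))
  invisible(x)
}

#' Conservation score of two profile columns
#'
#' The log-sum-of-odds co-emission score
#' \deqn{S_{cons} = \log_2 \sum_a \frac{P(i,a) Q(j,a)}{b_a}}
#' which, with emissions stored as square-root background odds, is just
#' the log2 of the dot product of the two stored odds vectors. A zero
#' dot product is floored at -50 rather than \eqn{-\infty}.
#'
#' @param x,y Length-20 sqrt-background-odds vectors (rows of
#'   `hush_profile$odds`).
#' @return Scalar score in bits.
#' @export
conservation_score <- function(x, y) {
  log2_floor(sum(x * y))
}

#' Hydrophobic similarity of two profile columns
#'
#' `hydro_offset - |Hx - Hy|`: maximal when the two column
#' hydrophobicities agree, zero when they differ by exactly the offset,
#' negative beyond.
#'
#' @param Hx,Hy Column hydrophobicities (Kyte-Doolittle units).
#' @param hydro_offset Offset `c0` in the same units.
#' @return Scalar score.
#' @export
hydrophobic_score <- function(Hx, Hy, hydro_offset = 1.5) {
  hydro_offset - abs(Hx - Hy)
}

#' Secondary-structure similarity of two profile columns
#'
#' The bilinear form \eqn{\sum_s \sum_{s'} f_x(s) f_y(s') L(s, s')} over
#' the 3x3 substitution table `L`.
#'
#' @param fx,fy Length-3 SS frequency vectors (H, E, C).
#' @param L A `hush_ss_table`.
#' @return Scalar score in bits.
#' @export
ss_score <- function(fx, fy, L) {
  as.numeric(fx %*% unclass(L) %*% fy)
}

#' Windowed diagonal sum of a column-pair term
#'
#' Sums `term_fn(P_state(i+k), Q_state(j+k))` over offsets `k = -w..w`
#' (`w = (width-1)/2`), truncating offsets that run off either profile
#' end (no padding: out-of-range offsets contribute 0).
#'
#' @param term_fn Function of two match-state indices `(ii, jj)`
#'   returning the raw term at that column pair.
#' @param n,m Profile lengths.
#' @param i,j Centre column pair (1-based).
#' @param width Odd window width.
#' @return Scalar windowed sum.
#' @export
windowed_term <- function(term_fn, n, m, i, j, width) {
  if (i < 1 || i > n || j < 1 || j > m) abort("window centre out of range")
  w <- (width - 1) / 2
  total <- 0
  for (k in -w:w) {
    ii <- i + k; jj <- j + k
    if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
      total <- total + term_fn(ii, jj)
    }
  }
  total
}

#' Combined column match score
#'
#' `M(i,j)`: the weighted sum of the three windowed terms. The SS term
#' contributes nothing at column pairs where either profile is
#' unannotated at the involved column.
#'
#' @param P,Q [hush_profile()] objects.
#' @param i,j Column indices.
#' @param params A [hush_params()].
#' @return Scalar score.
#' @seealso [column_score_matrix()] for the vectorised all-pairs version.
#' @export
column_match_score <- function(P, Q, i, j, params = hush_params()) {
  cons <- function(ii, jj) conservation_score(P$odds[ii, ], Q$odds[jj, ])
  hyd <- function(ii, jj) hydrophobic_score(P$hydro[ii], Q$hydro[jj],
                                            params$hydro_offset)
  ss <- function(ii, jj) {
    if (!P$ss_annotated[ii] || !Q$ss_annotated[jj]) return(0)
    ss_score(P$ss[ii, ], Q$ss[jj, ], params$ss_table)
  }
  params$Wc * windowed_term(cons, P$length, Q$length, i, j, params$win_c) +
    params$Wh * windowed_term(hyd, P$length, Q$length, i, j, params$win_h) +
    params$Ws * windowed_term(ss, P$length, Q$length, i, j, params$win_s)
}

# Diagonal window sum of a full n x m term matrix: out-of-range diagonal
# offsets are truncated, matching windowed_term().
diag_window_sum <- function(B, width) {
  w <- (width - 1) / 2
  if (w == 0) return(B)
  n <- nrow(B); m <- ncol(B)
  out <- matrix(0, n, m)
  for (k in -w:w) {
    if (max(1, 1 - k) > min(n, n - k) || max(1, 1 - k) > min(m, m - k)) next
    si <- max(1, 1 - k):min(n, n - k)   # rows i with i+k in range
    sj <- max(1, 1 - k):min(m, m - k)
    out[si, sj] <- out[si, sj] + B[si + k, sj + k, drop = FALSE]
  }
  out
}

#' All-pairs column match score matrix
#'
#' Vectorised computation of `M(i,j)` for every column pair of two
#' profiles; identical (within floating point) to calling
#' [column_match_score()] cell by cell.
#'
#' @inheritParams column_match_score
#' @return An `n x m` numeric matrix.
#' @export
column_score_matrix <- function(P, Q, params = hush_params()) {
  C <- log2_floor(P$odds %*% t(Q$odds))
  dim(C) <- c(P$length, Q$length)
  M <- params$Wc * diag_window_sum(C, params$win_c)
  if (params$Wh > 0) {
    H <- params$hydro_offset - abs(outer(P$hydro, Q$hydro, `-`))
    M <- M + params$Wh * diag_window_sum(H, params$win_h)
  }
  if (params$Ws > 0) {
    S <- P$ss %*% unclass(params$ss_table) %*% t(Q$ss)
    S[!P$ss_annotated, ] <- 0
    S[, !Q$ss_annotated] <- 0
    M <- M + params$Ws * diag_window_sum(S, params$win_s)
  }
  M
}
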