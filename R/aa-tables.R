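#' Amino-acid alphabet and residue-level tables
#'
#' All emission vectors in the package are ordered by the 20 one-letter
#' amino-acid codes in alphabetical order: A, C, D, E, F, G, H, I, K, L,
#' M, N, P, Q, R, S, T, V, W, Y.
#'
#' @format `aa_alphabet()` returns a character vector of length 20.
#' @return `aa_alphabet()`: the 20-letter alphabet, in the canonical order.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (dimensionless; positive = hydrophobic).
#' Column hydrophobicity of a profile match state is the emission-weighted
#' average of these values.
#'
#' @return A named numeric vector of length 20 over [aa_alphabet()].
#' @export
#' @examples
#' kyte_doolittle()[["I"]]  # isoleucine, most hydrophobic: 4.5
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Uniform amino-acid background
#'
#' Fallback background distribution (1/20 per residue) used when an HMM
#' file carries no usable null-emission line.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), aa_alphabet())
}

# Log floor replacing -Inf in all base-2 log terms of the scoring system.
SCORE_FLOOR <- -50

# plan7 integer score scale (HMMER2 INTSCALE).
INTSCALE <- 1000

# Secondary-structure state order used everywhere: helix, sheet, loop.
SS_STATES <- c("H", "E", "C")

log2_floor <- function(x, floor = SCORE_FLOOR) {
  out <- rep(floor, length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- pmax(log2(x[pos]), floor)
  out
}
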