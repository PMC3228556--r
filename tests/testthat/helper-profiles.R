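# Small random profile fixtures built in code. Uses the current RNG
# stream; wrap calls in withr::with_seed for reproducibility.

random_emissions <- function(n, conc = 0.5) {
  e <- matrix(stats::rgamma(n * 20, conc), n, 20)
  e / rowSums(e)
}

random_trans <- function(n) {
  tr <- cbind(
    matrix(stats::rgamma(n * 3, c(20, 1, 1)), n, 3, byrow = TRUE),  # M ->
    matrix(stats::rgamma(n * 2, c(3, 1)), n, 2, byrow = TRUE),      # I ->
    matrix(stats::rgamma(n * 2, c(3, 1)), n, 2, byrow = TRUE)       # D ->
  )
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  for (cols in list(1:3, 4:5, 6:7)) {
    tr[, cols] <- tr[, cols, drop = FALSE] / rowSums(tr[, cols, drop = FALSE])
  }
  tr
}

random_ss <- function(n) {
  s <- matrix(stats::rgamma(n * 3, 1), n, 3)
  s / rowSums(s)
}

random_profile <- function(n, name = "p", with_ss = TRUE,
                           background = uniform_background()) {
  encode_alignhush(random_emissions(n), random_trans(n), background,
                   ss = if (with_ss) random_ss(n), name = name)
}

# A pair of profiles guaranteed to share a strong diagonal signal:
# the second is a noisy copy of the first.
related_profile_pair <- function(n, noise = 0.1) {
  e1 <- random_emissions(n, conc = 0.2)
  e2 <- (1 - noise) * e1 + noise * random_emissions(n)
  bg <- uniform_background()
  list(P = encode_alignhush(e1, random_trans(n), bg, name = "P"),
       Q = encode_alignhush(e2, random_trans(n), bg, name = "Q"))
}

test_ss_table <- function() {
  L <- matrix(c(1, -1.5, -1.2,
                -1.5, 1.4, -1.3,
                -1.2, -1.3, 0.9), 3, 3, byrow = TRUE,
              dimnames = list(SS_STATES, SS_STATES))
  structure(L, class = c("hush_ss_table", "matrix", "array"))
}

small_params <- function(...) {
  hush_params(ss_table = test_ss_table(), ...)
}
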