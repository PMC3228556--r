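# Hand-written minimal plan7 fixture: 2 nodes, uniform background,
# node 1 doubles the odds of A, node 2 is flat with a sentinel at C.
toy_plan7 <- function(sentinel = FALSE) {
  zeros20 <- paste(rep("0", 20), collapse = " ")
  node2 <- if (sentinel) {
    paste("      2 0 *", paste(rep("0", 18), collapse = " "))
  } else {
    paste("      2", zeros20)
  }
  c("HMMER2.0  [fixture]",
    "NAME  toy",
    "LENG  2",
    "ALPH  Amino",
    paste("NULE ", zeros20),
    paste("HMM  ", paste(aa_alphabet(), collapse = " ")),
    "        m->m   m->i   m->d   i->m   i->i   d->m   d->d",
    paste("      1 1000", paste(rep("0", 19), collapse = " ")),
    paste("      -", zeros20),
    "      - -100 -2000 -3000 -500 -1500 -400 -1800",
    node2,
    paste("      -", zeros20),
    "      - 0 * * 0 * 0 *",
    "//")
}
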