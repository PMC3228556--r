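#' Construct an AlignHUSH profile
#'
#' The working representation of a profile for HMM-HMM alignment: per
#' match state a 20-vector of square-root background odds `e(a) = p(a) /
#' sqrt(b_a)`, a Kyte-Doolittle column hydrophobicity, a 3-vector of
#' secondary-structure frequencies (helix, sheet, loop) and the seven
#' plan7 transition probabilities. Storing odds against the square root
#' of the background makes the conservation score of a column pair a
#' plain dot product (see [conservation_score()]).
#'
#' @param name Profile identifier.
#' @param odds n x 20 matrix of sqrt-background odds, columns in
#'   [aa_alphabet()] order.
#' @param hydro Length-n numeric vector of column hydrophobicities
#'   (Kyte-Doolittle units).
#' @param ss n x 3 matrix of secondary-structure frequencies (H, E, C),
#'   rows summing to 1.
#' @param ss_annotated Length-n logical; `FALSE` marks states whose SS
#'   vector is the uninformative uniform placeholder.
#' @param trans n x 7 matrix of transition probabilities (MM, MI, MD,
#'   IM, II, DM, DD).
#' @param background Length-20 background distribution.
#' @param provenance Free-text metadata carried through file round trips.
#' @return An object of class `hush_profile`.
#' @export
hush_profile <- function(name, odds, hydro, ss, ss_annotated, trans,
                         background, provenance = "") {
  odds <- as.matrix(odds)
  n <- nrow(odds)
  stopifnot(n >= 1L, ncol(odds) == 20L, length(hydro) == n,
            nrow(ss) == n, ncol(ss) == 3L, length(ss_annotated) == n,
            nrow(trans) == n, ncol(trans) == 7L, length(background) == 20L)
  if (any(odds < 0)) abort("odds must be non-negative")
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    abort("background must be positive and sum to 1")
  }
  p <- sweep(odds, 2, sqrt(background), `*`)
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    abort("odds do not recover a probability vector: sum(odds * sqrt(b)) != 1")
  }
  if (any(abs(rowSums(ss) - 1) > 1e-6)) {
    abort("ss frequencies must sum to 1 per state")
  }
  colnames(odds) <- aa_alphabet()
  ss <- matrix(as.numeric(ss), n, 3)  # drop any carried-over attributes
  colnames(ss) <- SS_STATES
  colnames(trans) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  structure(
    list(name = name, length = n, odds = odds, hydro = as.numeric(hydro),
         ss = as.matrix(ss), ss_annotated = as.logical(ss_annotated),
         trans = as.matrix(trans),
         background = setNames(as.numeric(background), aa_alphabet()),
         provenance = provenance),
    class = "hush_profile"
  )
}

#' @export
print.hush_profile <- function(x, ...) {
  cat(sprintf("<hush_profile> %s: %d match states, %s SS annotation\n",
              x$name, x$length,
              if (all(x$ss_annotated)) "full" else
                if (any(x$ss_annotated)) "partial" else "no"))
  invisible(x)
}

#' @export
length.hush_profile <- function(x) x$length

#' Re-encode a plan7 model as an AlignHUSH profile
#'
#' Takes renormalised match emission probabilities (insert emissions
#' already discarded), converts them to square-root background odds, and
#' attaches per-state hydrophobicity and secondary-structure frequency
#' annotations. When `hydro` is not supplied it is computed from the
#' emissions as the Kyte-Doolittle expectation; when `ss` is not
#' supplied, uniform (1/3, 1/3, 1/3) placeholders are stored and flagged
#' as unannotated so the SS score term can be switched off.
#'
#' @inheritParams hush_profile
#' @param emissions n x 20 match emission probability matrix.
#' @param transitions n x 7 transition probability matrix.
#' @param hydro Optional length-n hydrophobicity vector.
#' @param ss Optional n x 3 SS frequency matrix (H, E, C).
#' @return A [hush_profile()].
#' @export
encode_alignhush <- function(emissions, transitions, background,
                             hydro = NULL, ss = NULL, name = "profile",
                             provenance = "") {
  emissions <- as.matrix(emissions)
  n <- nrow(emissions)
  emissions <- emissions / rowSums(emissions)
  if (is.null(hydro)) {
    hydro <- as.numeric(emissions %*% kyte_doolittle()[aa_alphabet()])
  }
  if (length(hydro) != n) {
    abort(sprintf("hydrophobicity annotation has length %d, profile has %d states",
                  length(hydro), n),
          class = "alignhush_annotation_error")
  }
  if (is.null(ss)) {
    ss <- matrix(1 / 3, n, 3)
    ss_annotated <- rep(FALSE, n)
  } else {
    ss <- as.matrix(ss)
    if (nrow(ss) != n) {
      abort(sprintf("SS annotation has %d rows, profile has %d states",
                    nrow(ss), n),
            class = "alignhush_annotation_error")
    }
    ss_annotated <- rep(TRUE, n)
  }
  odds <- sweep(emissions, 2, sqrt(background), `/`)
  hush_profile(name, odds, hydro, ss, ss_annotated, transitions,
               background, provenance)
}

#' Read a plan7 HMM straight into an AlignHUSH profile
#'
#' Convenience wrapper chaining [parse_hmmer2()], [scores_to_probs()] and
#' [encode_alignhush()].
#'
#' @inheritParams parse_hmmer2
#' @inheritParams encode_alignhush
#' @return A [hush_profile()].
#' @export
read_hmmer2_profile <- function(input, hydro = NULL, ss = NULL) {
  raw <- parse_hmmer2(input)
  pr <- scores_to_probs(raw)
  encode_alignhush(pr$emissions, pr$transitions, pr$background,
                   hydro = hydro, ss = ss, name = raw$name,
                   provenance = "re-encoded from plan7")
}

PROFILE_FORMAT_VERSION <- 1L

#' Write and read the AlignHUSH profile interchange format
#'
#' A versioned plain-text dialect: one header block (name, length,
#' provenance, background) followed by one block per match state carrying
#' the 20 odds values, the hydrophobicity, the 3 SS frequencies, the
#' SS-annotation flag and the 7 transition probabilities. Numbers are
#' written with 10 significant digits so that a write/read round trip
#' reproduces every field within 1e-9.
#'
#' @param profile A [hush_profile()].
#' @param path Output (or input) file path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a [hush_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "hush_profile"))
  num <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  lines <- c(
    sprintf("ALIGNHUSH-PROFILE %d", PROFILE_FORMAT_VERSION),
    paste("name", profile$name),
    paste("length", profile$length),
    paste("provenance", profile$provenance),
    paste("background", num(profile$background))
  )
  for (i in seq_len(profile$length)) {
    lines <- c(lines,
               sprintf("state %d %d", i, as.integer(profile$ss_annotated[i])),
               paste("odds", num(profile$odds[i, ])),
               paste("hydro", num(profile$hydro[i])),
               paste("ssfreq", num(profile$ss[i, ])),
               paste("trans", num(profile$trans[i, ])))
  }
  writeLines(c(lines, "end"), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (hdr[1] != "ALIGNHUSH-PROFILE") {
    abort("not an AlignHUSH profile file", class = "alignhush_format_error")
  }
  if (as.integer(hdr[2]) != PROFILE_FORMAT_VERSION) {
    abort(sprintf("unsupported profile format version %s", hdr[2]),
          class = "alignhush_version_error")
  }
  field <- function(key, i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] != key) {
      abort(sprintf("line %d: expected '%s', found '%s'", i, key, tok[1]),
            class = "alignhush_format_error")
    }
    tok[-1]
  }
  nums <- function(key, i, k) {
    v <- suppressWarnings(as.numeric(field(key, i)))
    if (length(v) != k || anyNA(v)) {
      abort(sprintf("line %d: '%s' must carry %d numbers", i, key, k),
            class = "alignhush_format_error")
    }
    v
  }
  name <- paste(field("name", 2), collapse = " ")
  n <- as.integer(field("length", 3)[1])
  if (!startsWith(trimws(lines[4]), "provenance")) {
    abort("line 4: expected 'provenance'", class = "alignhush_format_error")
  }
  provenance <- trimws(sub("^\\s*provenance\\s?", "", lines[4]))
  background <- nums("background", 5, 20)
  odds <- matrix(0, n, 20); hydro <- numeric(n)
  ss <- matrix(0, n, 3); annot <- logical(n); trans <- matrix(0, n, 7)
  at <- 6L
  for (i in seq_len(n)) {
    st <- field("state", at)
    if (as.integer(st[1]) != i) {
      abort(sprintf("state blocks out of order at line %d", at),
            class = "alignhush_format_error")
    }
    annot[i] <- as.integer(st[2]) == 1L
    odds[i, ] <- nums("odds", at + 1L, 20)
    hydro[i] <- nums("hydro", at + 2L, 1)
    ss[i, ] <- nums("ssfreq", at + 3L, 3)
    trans[i, ] <- nums("trans", at + 4L, 7)
    at <- at + 5L
  }
  hush_profile(name, odds, hydro, ss, annot, trans, background, provenance)
}
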