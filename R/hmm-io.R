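#' Parse a plan7 (HMMER2) ASCII profile HMM
#'
#' Reads the HMMER2.0 text format: header, `NAME`/`LENG`/`NULE` lines and
#' one three-line block per node (match emission scores, insert emission
#' scores, seven transition scores for M->M, M->I, M->D, I->M, I->I,
#' D->M, D->D). Integer scores are kept verbatim; the sentinel `*`
#' ("impossible") is represented as `NA` and maps to probability zero on
#' conversion. Insert emission scores are parsed but discarded by the
#' downstream re-encoding, because only the probability of an insertion
#' (not its composition) matters for profile-profile alignment.
#'
#' @param input Path to a plan7 file, or a character vector of lines.
#' @return An object of class `plan7_hmm`: a list with `name`, `length`,
#'   `match_scores` (n x 20 matrix), `insert_scores` (n x 20),
#'   `trans_scores` (n x 7), `null_scores` (length 20) and `specials`
#'   (unparsed header lines, retained opaquely).
#' @seealso [scores_to_probs()], [encode_alignhush()]
#' @export
parse_hmmer2 <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    readLines(input)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  if (length(lines) == 0L || !startsWith(trimws(lines[1]), "HMMER2.0")) {
    abort(sprintf("not a HMMER2.0 file: first line is '%s'",
                  if (length(lines)) lines[1] else "<empty>"),
          class = "alignhush_format_error")
  }

  take_field <- function(key) {
    hit <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^", key, "\\s+"), "", hit[1]))
  }

  name <- take_field("NAME")
  if (is.null(name)) name <- "unnamed"
  leng <- take_field("LENG")
  if (is.null(leng) || is.na(suppressWarnings(as.integer(leng)))) {
    abort("missing or malformed LENG line", class = "alignhush_format_error")
  }
  leng <- as.integer(leng)
  if (leng < 1L) abort("declared length must be >= 1", class = "alignhush_format_error")

  parse_scores <- function(tokens, where) {
    vals <- suppressWarnings(as.numeric(tokens))
    vals[tokens == "*"] <- NA_real_
    if (anyNA(vals[tokens != "*"])) {
      abort(sprintf("unparseable score token in %s", where),
            class = "alignhush_format_error")
    }
    vals
  }

  nule <- take_field("NULE")
  null_scores <- if (is.null(nule)) {
    rep(0, 20)  # uniform background fallback
  } else {
    v <- parse_scores(strsplit(nule, "\\s+")[[1]], "NULE line")
    if (length(v) != 20L) {
      abort("NULE line must carry 20 scores", class = "alignhush_format_error")
    }
    v
  }

  hmm_at <- grep("^HMM\\s", lines)
  if (length(hmm_at) == 0L) {
    abort("no 'HMM' alphabet line found", class = "alignhush_format_error")
  }
  body <- lines[(hmm_at[1] + 2L):length(lines)]  # skip transition-header line
  body <- body[trimws(body) != ""]
  end_at <- which(trimws(body) == "//")
  if (length(end_at)) body <- body[seq_len(end_at[1] - 1L)]

  if (length(body) < 3L * leng) {
    abort(sprintf("truncated file: declared length %d but only %d node lines",
                  leng, length(body)),
          class = "alignhush_truncation_error")
  }

  match_scores <- matrix(NA_real_, leng, 20, dimnames = list(NULL, aa_alphabet()))
  insert_scores <- match_scores
  trans_scores <- matrix(NA_real_, leng, 7,
                         dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (i in seq_len(leng)) {
    blk <- body[(3L * (i - 1L) + 1L):(3L * i)]
    mtok <- strsplit(trimws(blk[1]), "\\s+")[[1]]
    if (suppressWarnings(as.integer(mtok[1])) != i) {
      abort(sprintf("node %d: match line starts with '%s', expected node index",
                    i, mtok[1]),
            class = "alignhush_format_error")
    }
    mv <- parse_scores(mtok[-1], sprintf("node %d match line", i))
    if (length(mv) < 20L) {
      abort(sprintf("node %d: match line has %d scores, expected 20", i, length(mv)),
            class = "alignhush_format_error")
    }
    match_scores[i, ] <- mv[1:20]
    itok <- strsplit(trimws(blk[2]), "\\s+")[[1]]
    if (itok[1] == "-") itok <- itok[-1]
    iv <- parse_scores(itok, sprintf("node %d insert line", i))
    insert_scores[i, ] <- iv[1:20]
    ttok <- strsplit(trimws(blk[3]), "\\s+")[[1]]
    if (ttok[1] == "-") ttok <- ttok[-1]
    tv <- parse_scores(ttok, sprintf("node %d transition line", i))
    if (length(tv) < 7L) {
      abort(sprintf("node %d: transition line has %d scores, expected >= 7",
                    i, length(tv)),
            class = "alignhush_format_error")
    }
    trans_scores[i, ] <- tv[1:7]
  }

  structure(
    list(name = name, length = leng,
         match_scores = match_scores, insert_scores = insert_scores,
         trans_scores = trans_scores, null_scores = null_scores,
         specials = lines[seq_len(hmm_at[1] - 1L)]),
    class = "plan7_hmm"
  )
}

#' Convert plan7 integer scores to probabilities
#'
#' plan7 integer scores are scaled bit scores: `score = 1000 * log2(p /
#' p_null)`. Emissions convert as `p(a) = b_a * 2^(score/1000)` with the
#' background `b_a` recovered from the NULE line (`b_a = (1/20) *
#' 2^(null_score/1000)`, renormalised), and transitions as `t =
#' 2^(score/1000)` clamped to `[0, 1]` with each outgoing triplet
#' (M->., I->., D->.) renormalised. Sentinel scores map to probability 0.
#'
#' @param raw A `plan7_hmm` from [parse_hmmer2()].
#' @return A list with `emissions` (n x 20 match emission probabilities,
#'   rows summing to 1), `transitions` (n x 7 probabilities) and
#'   `background` (length-20 probability vector).
#' @export
scores_to_probs <- function(raw) {
  stopifnot(inherits(raw, "plan7_hmm"))
  background <- (1 / 20) * score_to_ratio(raw$null_scores)
  if (any(background <= 0)) {
    abort("null line yields a non-positive background probability",
          class = "alignhush_null_error")
  }
  background <- background / sum(background)
  names(background) <- aa_alphabet()

  # raw probabilities p(a) = b_a * 2^(s/1000); renormalisation (after the
  # insert line is dropped) happens in encode_alignhush()
  emissions <- sweep(score_to_ratio(raw$match_scores), 2, background, `*`)
  if (any(rowSums(emissions) <= 0)) {
    abort("a match state has all-zero emissions", class = "alignhush_null_error")
  }

  transitions <- pmin(score_to_ratio(raw$trans_scores), 1)
  transitions <- normalize_trans_triplets(transitions)
  list(emissions = emissions, transitions = transitions, background = background)
}

# 2^(score/INTSCALE); sentinel NA -> 0
score_to_ratio <- function(s) {
  out <- 2^(s / INTSCALE)
  out[is.na(s)] <- 0
  out
}

normalize_trans_triplets <- function(tr) {
  for (cols in list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))) {
    sums <- rowSums(tr[, cols, drop = FALSE])
    ok <- sums > 0
    tr[ok, cols] <- tr[ok, cols, drop = FALSE] / sums[ok]
  }
  tr
}

#' Write a plan7 (HMMER2) ASCII profile HMM
#'
#' Serialises match emission probabilities, transition probabilities and a
#' background distribution back to the HMMER2.0 text format with integer
#' scores (`round(1000 * log2(p / p_null))`; probability 0 becomes the
#' sentinel `*`). Insert emissions are written as background (score 0).
#'
#' @param emissions n x 20 matrix of match emission probabilities.
#' @param transitions n x 7 matrix of transition probabilities.
#' @param background length-20 background distribution.
#' @param name Model name.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the file lines.
#' @export
write_hmmer2 <- function(emissions, transitions, background, name = "model",
                         path = NULL) {
  n <- nrow(emissions)
  fmt <- function(p, ref) {
    s <- round(INTSCALE * log2(p / ref))
    ifelse(p <= 0 | !is.finite(s), "*", sprintf("%d", as.integer(s)))
  }
  nule <- fmt(background, 1 / 20)
  lines <- c(
    "HMMER2.0  [alignhush]",
    paste("NAME ", name),
    paste("LENG ", n),
    "ALPH  Amino",
    paste("NULE ", paste(nule, collapse = " ")),
    paste("HMM  ", paste(aa_alphabet(), collapse = "      ")),
    "        m->m   m->i   m->d   i->m   i->i   d->m   d->d"
  )
  for (i in seq_len(n)) {
    lines <- c(
      lines,
      paste(sprintf("%7d", i),
            paste(fmt(emissions[i, ], background), collapse = " ")),
      paste("      -", paste(rep("0", 20), collapse = " ")),
      paste("      -", paste(fmt(transitions[i, ], 1), collapse = " "))
    )
  }
  lines <- c(lines, "//")
  if (!is.null(path)) {
    writeLines(lines, path)
    invisible(lines)
  } else {
    lines
  }
}
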