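#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Path to an aligned FASTA file (all records equal length;
#'   `-` or `.` as gap).
#' @return A named character vector of aligned sequences (gaps as `-`).
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  msa <- toupper(chartr(".", "-", as.character(set)))
  if (length(unique(nchar(msa))) != 1L) {
    abort("alignment records differ in length", class = "alignhush_format_error")
  }
  msa
}

#' Write an aligned FASTA multiple sequence alignment
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(msa), path)
  invisible(path)
}

#' Read 3-state secondary-structure predictions
#'
#' `read_ss2()` parses PSIPRED vertical (.ss2) output (columns: position,
#' residue, state, three confidences) for a single sequence; confidences
#' are ignored and only the argmax state column is used. `read_horiz()`
#' parses PSIPRED horizontal output (`Pred:` lines). `read_ss_tsv()`
#' reads the neutral two-column format `id <TAB> ss_string` covering many
#' sequences. All return strings over the alphabet H (helix), E (sheet),
#' C (loop); any other predicted letter is mapped to C.
#'
#' @param path Input file path.
#' @return `read_ss2()`/`read_horiz()`: a single SS string.
#'   `read_ss_tsv()`: a named character vector of SS strings.
#' @export
read_ss2 <- function(path) {
  lines <- grep("^\\s*\\d+\\s+\\S\\s+\\S", readLines(path), value = TRUE)
  states <- vapply(strsplit(trimws(lines), "\\s+"), `[[`, "", 3L)
  normalize_ss(paste(states, collapse = ""))
}

#' @rdname read_ss2
#' @export
read_horiz <- function(path) {
  lines <- grep("^Pred:", readLines(path), value = TRUE)
  normalize_ss(paste(sub("^Pred:\\s*", "", lines), collapse = ""))
}

#' @rdname read_ss2
#' @export
read_ss_tsv <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  setNames(normalize_ss(tab[[2]]), tab[[1]])
}

normalize_ss <- function(x) {
  x <- toupper(x)
  x <- gsub("[^HE]", "C", x)  # PSIPRED mapping: H -> helix, E -> sheet, rest -> loop
  x
}

#' Label MSA columns as match or insert states
#'
#' A column becomes a match state when its gap fraction does not exceed
#' `gap_fraction_threshold`; otherwise it is an insert column. This is
#' the classical profile-construction heuristic relating alignment
#' columns to HMM nodes.
#'
#' @param msa Named character vector of aligned sequences.
#' @param gap_fraction_threshold Maximum tolerated gap fraction for a
#'   match column (default 0.5).
#' @return Character vector (length = alignment width) of `"match"` /
#'   `"insert"` labels.
#' @export
assign_match_columns <- function(msa, gap_fraction_threshold = 0.5) {
  if (length(msa) == 0L) abort("empty MSA")
  mat <- msa_matrix(msa)
  gap_frac <- colMeans(mat == "-")
  assignment <- ifelse(gap_frac <= gap_fraction_threshold, "match", "insert")
  if (!any(assignment == "match")) {
    abort("no column satisfies the match-column threshold: empty profile",
          class = "alignhush_empty_profile_error")
  }
  assignment
}

msa_matrix <- function(msa) {
  t(vapply(strsplit(msa, ""), identity, character(nchar(msa[[1]]))))
}

#' Column hydrophobicity under a residue distribution
#'
#' The emission-weighted Kyte-Doolittle hydropathy of a profile column:
#' `H = sum_a p(a) * kd(a)`.
#'
#' @param p Length-20 probability vector over [aa_alphabet()].
#' @param kd Hydropathy table (named numeric vector), by default
#'   [kyte_doolittle()].
#' @return Scalar hydrophobicity, Kyte-Doolittle units.
#' @export
column_hydrophobicity <- function(p, kd = kyte_doolittle()) {
  stopifnot(length(p) == 20L, abs(sum(p) - 1) < 1e-6)
  sum(p * kd[aa_alphabet()])
}

#' Secondary-structure frequencies of MSA match columns
#'
#' For every match column, counts the predicted secondary-structure
#' states of the residues present in that column (gap cells and
#' sequences lacking an SS string contribute nothing) and normalises to
#' frequencies over (H, E, C).
#'
#' @param msa Named character vector of aligned sequences.
#' @param ss_strings Named character vector of unaligned 3-state SS
#'   strings; each must match its sequence's ungapped length. Sequences
#'   absent from this vector are excluded from SS counts.
#' @param column_assignment Output of [assign_match_columns()].
#' @return A matrix (match columns x 3, columns H/E/C) of frequencies;
#'   rows of columns where no annotated residue is present are uniform
#'   and flagged via the `"annotated"` attribute (logical vector).
#' @export
ss_column_frequencies <- function(msa, ss_strings, column_assignment) {
  mat <- msa_matrix(msa)
  match_cols <- which(column_assignment == "match")
  counts <- matrix(0, length(match_cols), 3,
                   dimnames = list(NULL, SS_STATES))
  for (id in names(msa)) {
    if (!id %in% names(ss_strings)) next
    row <- mat[id, ]
    resid <- which(row != "-")
    ss <- strsplit(normalize_ss(ss_strings[[id]]), "")[[1]]
    if (length(ss) != length(resid)) {
      abort(sprintf("sequence '%s': SS string length %d != ungapped length %d",
                    id, length(ss), length(resid)),
            class = "alignhush_annotation_error")
    }
    ss_by_col <- setNames(ss, resid)
    for (k in seq_along(match_cols)) {
      s <- ss_by_col[as.character(match_cols[k])]
      if (!is.na(s)) counts[k, s] <- counts[k, s] + 1
    }
  }
  tot <- rowSums(counts)
  freq <- counts
  annotated <- tot > 0
  freq[annotated, ] <- counts[annotated, , drop = FALSE] / tot[annotated]
  freq[!annotated, ] <- 1 / 3
  attr(freq, "annotated") <- annotated
  freq
}
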