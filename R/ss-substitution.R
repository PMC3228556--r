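#' Estimate a secondary-structure substitution table
#'
#' From pairs of aligned 3-state secondary-structure strings, accumulates
#' joint substitution counts N(s, s') over aligned positions, symmetrises
#' them (`N(s,s') <- N(s,s') + N(s',s)`), adds a pseudocount to every
#' cell, and converts to log-odds: `L(s,s') = log2( P(s,s') / (P(s) P(s')) )`
#' with the marginals taken from the symmetrised joint. The resulting
#' 3x3 table (rows/columns ordered helix, sheet, loop) is what the SS
#' score term [ss_score()] consumes.
#'
#' @param pairs A list of length-2 character vectors (or 2-column
#'   matrices/data frames) of equal-length aligned SS strings over
#'   H/E/C. Positions where either string carries a gap (`-`) are
#'   skipped.
#' @param pseudocount Added to every joint count cell (default 1).
#' @return A `hush_ss_table`: a symmetric 3x3 numeric matrix of base-2
#'   log-odds with attribute `pseudocount`.
#' @export
estimate_ss_table <- function(pairs, pseudocount = 1) {
  if (length(pairs) == 0L) {
    abort("no aligned SS string pairs supplied", class = "alignhush_estimation_error")
  }
  counts <- matrix(0, 3, 3, dimnames = list(SS_STATES, SS_STATES))
  for (pr in pairs) {
    a <- strsplit(toupper(pr[[1]]), "")[[1]]
    b <- strsplit(toupper(pr[[2]]), "")[[1]]
    if (length(a) != length(b)) {
      abort("aligned SS strings differ in length",
            class = "alignhush_estimation_error")
    }
    keep <- a %in% SS_STATES & b %in% SS_STATES
    if (!any(keep)) next
    tab <- table(factor(a[keep], SS_STATES), factor(b[keep], SS_STATES))
    counts <- counts + unclass(tab)
  }
  counts <- counts + t(counts)           # symmetrise
  counts <- counts + pseudocount
  p_joint <- counts / sum(counts)
  p_marg <- rowSums(p_joint)             # == colSums by symmetry
  L <- log2(p_joint / outer(p_marg, p_marg))
  L <- (L + t(L)) / 2                    # kill floating-point asymmetry
  structure(L, class = c("hush_ss_table", "matrix", "array"),
            pseudocount = pseudocount)
}

#' Default secondary-structure substitution table
#'
#' A synthetic stand-in for a table fitted to structural alignments of
#' real protein families: it is estimated, at build time of the shipped
#' data file, from SS-conserving alignments produced by the package's own
#' synthetic world generator (see the methods vignette). Favor
#' supplying a table estimated from your own aligned data via
#' [estimate_ss_table()] when one is available.
#'
#' @return A `hush_ss_table` (3x3 base-2 log-odds matrix).
#' @export
default_ss_table <- function() {
  path <- system.file("extdata", "ss_substitution_synthetic.tsv",
                      package = "alignhush")
  if (nzchar(path)) return(read_ss_table(path))
  # development fallback before installation
  read_ss_table(file.path("inst", "extdata", "ss_substitution_synthetic.tsv"))
}

#' Read / write a 3x3 SS substitution table
#'
#' Whitespace-delimited matrix with header row and column naming the
#' states H, E and C; comment lines start with `#`.
#'
#' @param path File path.
#' @param table A `hush_ss_table` (or plain 3x3 matrix) for writing.
#' @return `read_ss_table()`: a `hush_ss_table`; `write_ss_table()`:
#'   `path`, invisibly.
#' @export
read_ss_table <- function(path) {
  tab <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     comment.char = "#"))
  if (!all(dim(tab) == c(3, 3))) {
    abort("SS table must be 3x3", class = "alignhush_format_error")
  }
  tab <- tab[SS_STATES, SS_STATES]
  structure(tab, class = c("hush_ss_table", "matrix", "array"))
}

#' @rdname read_ss_table
#' @export
write_ss_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# alignhush 3x3 secondary-structure substitution table (log2 odds)", con)
  writeLines(paste(c("", SS_STATES), collapse = "\t"), con)
  for (s in SS_STATES) {
    writeLines(paste(c(s, sprintf("%.6f", table[s, ])), collapse = "\t"), con)
  }
  invisible(path)
}
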