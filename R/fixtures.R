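# Residue pools preferred by each secondary-structure state. Substituted
# residues are drawn from the pool of the column's SS state, so the
# secondary-structure and hydrophobicity signals survive sequence
# divergence -- the property the scoring scheme exploits.
SS_POOLS <- list(
  H = c("A", "E", "L", "M", "Q", "K", "R", "H"),
  E = c("V", "I", "F", "Y", "W", "T", "C"),
  C = c("G", "P", "S", "N", "D")
)

#' Specification of a synthetic benchmark world
#'
#' Describes a desk-scale stand-in for a curated HMM benchmark: a set of
#' superfamilies (each in its own fold and class, so cross-superfamily
#' pairs are clean false-positive material), each containing several
#' families diverged from a common ancestor, each family an MSA of
#' diverged sequences with matching 3-state secondary-structure strings.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_superfamilies,families_per_superfamily,sequences_per_family
#'   World dimensions.
#' @param length_range Ancestor length range (residues).
#' @param within_rate Per-site substitution probability within a family.
#' @param between_rate Per-site substitution probability between a
#'   family and its superfamily ancestor.
#' @param indel_rate Per-site insertion/deletion probability.
#' @param ss_mean_run Named vector of mean secondary-structure segment
#'   lengths (geometric), states H/E/C.
#' @param ss_conservation Probability that an ancestral SS segment keeps
#'   its state in a derived family.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42, n_superfamilies = 5,
                         families_per_superfamily = 2,
                         sequences_per_family = 8,
                         length_range = c(60, 90),
                         within_rate = 0.08, between_rate = 0.35,
                         indel_rate = 0.02,
                         ss_mean_run = c(H = 8, E = 5, C = 4),
                         ss_conservation = 0.9) {
  stopifnot(all(c(within_rate, between_rate, indel_rate, ss_conservation) >= 0),
            all(c(within_rate, between_rate, indel_rate, ss_conservation) <= 1),
            length_range[1] >= 10)
  structure(list(seed = seed, n_superfamilies = n_superfamilies,
                 families_per_superfamily = families_per_superfamily,
                 sequences_per_family = sequences_per_family,
                 length_range = length_range, within_rate = within_rate,
                 between_rate = between_rate, indel_rate = indel_rate,
                 ss_mean_run = ss_mean_run,
                 ss_conservation = ss_conservation),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

draw_ss_string <- function(len, mean_run) {
  states <- character(0)
  cur <- sample(SS_STATES, 1, prob = c(0.2, 0.1, 0.7))  # proteins tend to start in loops
  while (length(states) < len) {
    run <- 1 + stats::rgeom(1, 1 / mean_run[[cur]])
    states <- c(states, rep(cur, run))
    cur <- sample(setdiff(SS_STATES, cur), 1)
  }
  states[seq_len(len)]
}

mutate_seq <- function(seq, ss, rate) {
  hit <- runif(length(seq)) < rate
  if (any(hit)) {
    seq[hit] <- vapply(ss[hit], function(s) sample(SS_POOLS[[s]], 1), "")
  }
  seq
}

perturb_ss <- function(ss, conservation) {
  runs <- rle(ss)
  flip <- runif(length(runs$values)) >= conservation
  runs$values[flip] <- vapply(runs$values[flip],
                              function(s) sample(setdiff(SS_STATES, s), 1), "")
  inverse.rle(runs)
}

#' Generate a synthetic benchmark world
#'
#' Draws, per superfamily, an ancestral sequence and secondary-structure
#' string; derives families by SS-pool-conditioned substitution at the
#' between-family rate (SS segments flipped with probability
#' `1 - ss_conservation`); derives each family's sequences at the
#' within-family rate with indels; and emits SCOP-style labels where
#' every superfamily sits in its own fold and class (so cross-superfamily
#' pairs are eligible false positives).
#'
#' @param spec A [fixture_spec()].
#' @return A list with `msas` (named list of aligned named character
#'   vectors, one per family), `ss` (named list of per-sequence
#'   unaligned SS strings), `labels` (tibble) and `spec`.
#' @export
generate_world <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    msas <- list(); ss_all <- list(); lab_rows <- list()
    for (k in seq_len(spec$n_superfamilies)) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      anc_ss <- draw_ss_string(L, spec$ss_mean_run)
      anc_seq <- vapply(anc_ss, function(s) sample(SS_POOLS[[s]], 1), "")
      for (f in seq_len(spec$families_per_superfamily)) {
        fam_id <- sprintf("sf%02d_fam%d", k, f)
        fam_ss <- perturb_ss(anc_ss, spec$ss_conservation)
        fam_seq <- mutate_seq(anc_seq, fam_ss, spec$between_rate)
        fam <- build_family_msa(fam_seq, fam_ss, spec)
        msas[[fam_id]] <- fam$msa
        ss_all[[fam_id]] <- fam$ss
        lab_rows[[fam_id]] <- homology_labels(
          fam_id, class = sprintf("c%02d", k), fold = sprintf("f%02d", k),
          superfamily = sprintf("sf%02d", k), family = fam_id)
      }
    }
    list(msas = msas, ss = ss_all, labels = dplyr::bind_rows(lab_rows),
         spec = spec)
  })
}

# One family: per-sequence substitution, per-site deletions, and shared
# insertion columns occupied by a random subset of sequences.
build_family_msa <- function(fam_seq, fam_ss, spec) {
  nseq <- spec$sequences_per_family
  L <- length(fam_seq)
  seqs <- lapply(seq_len(nseq), function(s) mutate_seq(fam_seq, fam_ss, spec$within_rate))
  deleted <- lapply(seq_len(nseq), function(s) runif(L) < spec$indel_rate)
  ins_after <- which(runif(L) < spec$indel_rate)

  ids <- sprintf("s%02d", seq_len(nseq))
  aligned <- setNames(vector("list", nseq), ids)
  ss_out <- setNames(vector("list", nseq), ids)
  for (s in seq_len(nseq)) {
    cols <- character(0); ss_cols <- character(0)
    for (p in seq_len(L)) {
      if (deleted[[s]][p]) {
        cols <- c(cols, "-")
      } else {
        cols <- c(cols, seqs[[s]][p])
        ss_cols <- c(ss_cols, fam_ss[p])
      }
      if (p %in% ins_after) {
        if (runif(1) < 0.3) {
          cols <- c(cols, sample(SS_POOLS$C, 1))
          ss_cols <- c(ss_cols, "C")
        } else {
          cols <- c(cols, "-")
        }
      }
    }
    aligned[[s]] <- paste(cols, collapse = "")
    ss_out[[s]] <- paste(ss_cols, collapse = "")
  }
  list(msa = unlist(aligned), ss = unlist(ss_out))
}

#' Build an AlignHUSH profile (and optionally a plan7 file) from an MSA
#'
#' Count-based profile construction: match columns are assigned by gap
#' fraction, emissions are background-pseudocounted column counts
#' (`p(a) = (count_a + pc * b_a) / (N + pc)`), transitions are Laplace-
#' smoothed counts of the observed match/insert/delete paths, column
#' hydrophobicity is the Kyte-Doolittle expectation of the emissions and
#' SS frequencies come from [ss_column_frequencies()]. The same model
#' can be serialised as a HMMER2 plan7 file to exercise the plan7
#' reader end to end.
#'
#' @param msa Named character vector of aligned sequences.
#' @param ss_strings Named character vector of unaligned SS strings
#'   (optional; omit for an SS-unannotated profile).
#' @param pseudocount Emission pseudocount (default 1).
#' @param background Background distribution (default uniform).
#' @param name Profile name.
#' @param gap_fraction_threshold Match-column rule (default 0.5).
#' @param plan7_path When non-`NULL`, also write the model as a plan7
#'   file at this path.
#' @return A [hush_profile()].
#' @export
build_profile_from_msa <- function(msa, ss_strings = NULL, pseudocount = 1,
                                   background = uniform_background(),
                                   name = "profile",
                                   gap_fraction_threshold = 0.5,
                                   plan7_path = NULL) {
  assignment <- assign_match_columns(msa, gap_fraction_threshold)
  mat <- msa_matrix(msa)
  match_cols <- which(assignment == "match")
  n <- length(match_cols)

  emissions <- matrix(0, n, 20, dimnames = list(NULL, aa_alphabet()))
  for (k in seq_len(n)) {
    col <- mat[, match_cols[k]]
    col <- col[col != "-"]
    counts <- table(factor(col, aa_alphabet()))
    emissions[k, ] <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
  }
  emissions <- emissions / rowSums(emissions)

  transitions <- count_transitions(mat, assignment, smoothing = 1)

  ss <- NULL
  if (!is.null(ss_strings)) {
    fr <- ss_column_frequencies(msa, ss_strings, assignment)
    ss <- fr
  }
  prof <- encode_alignhush(emissions, transitions, background,
                           ss = ss, name = name,
                           provenance = "count-based synthetic profile")
  if (!is.null(ss)) prof$ss_annotated <- attr(fr, "annotated")
  if (!is.null(plan7_path)) {
    write_hmmer2(emissions, transitions, background, name = name,
                 path = plan7_path)
  }
  prof
}

# Laplace-smoothed plan7 transition counts from observed paths through
# the column assignment. plan7 has no I->D move: inserts preceding a
# deleted match column are folded into the direct X->D transition.
count_transitions <- function(mat, assignment, smoothing = 1) {
  match_cols <- which(assignment == "match")
  n <- length(match_cols)
  counts <- matrix(0, n, 7,
                   dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  nseq <- nrow(mat)
  if (n >= 2) for (s in seq_len(nseq)) {
    row <- mat[s, ]
    for (k in 1:(n - 1)) {
      from <- if (row[match_cols[k]] != "-") "M" else "D"
      to <- if (row[match_cols[k + 1]] != "-") "M" else "D"
      between <- setdiff(seq(match_cols[k] + 1, length.out = match_cols[k + 1] - match_cols[k] - 1),
                         match_cols)
      n_ins <- if (length(between)) sum(row[between] != "-") else 0L
      if (n_ins > 0 && to == "M" && from == "M") {
        counts[k, "MI"] <- counts[k, "MI"] + 1
        if (n_ins > 1) counts[k, "II"] <- counts[k, "II"] + (n_ins - 1)
        counts[k, "IM"] <- counts[k, "IM"] + 1
      } else {
        # plan7 has no D->I / I->D moves: inserts around a deletion fold
        # into the direct transition
        counts[k, paste0(from, to)] <- counts[k, paste0(from, to)] + 1
      }
    }
  }
  counts <- counts + smoothing
  normalize_trans_triplets(counts)
}

#' Build every profile of a generated world
#'
#' @param world Output of [generate_world()].
#' @param pseudocount Emission pseudocount passed to
#'   [build_profile_from_msa()].
#' @param with_ss Attach SS annotations (default `TRUE`).
#' @return Named list of [hush_profile()]s, one per family.
#' @export
world_profiles <- function(world, pseudocount = 1, with_ss = TRUE) {
  profs <- lapply(names(world$msas), function(id) {
    build_profile_from_msa(world$msas[[id]],
                           ss_strings = if (with_ss) world$ss[[id]],
                           pseudocount = pseudocount, name = id)
  })
  setNames(profs, names(world$msas))
}

#' Write a generated world to files
#'
#' Per family: aligned FASTA, a two-column SS TSV, a plan7 HMM and an
#' AlignHUSH profile; plus one labels TSV for the whole world. Every
#' file format written here is read back by the package's own parsers.
#'
#' @param world Output of [generate_world()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(world$msas)) {
    write_msa(world$msas[[id]], file.path(dir, paste0(id, ".afa")))
    writeLines(sprintf("%s\t%s", names(world$ss[[id]]), world$ss[[id]]),
               file.path(dir, paste0(id, ".ss.tsv")))
    prof <- build_profile_from_msa(world$msas[[id]], world$ss[[id]], name = id,
                                   plan7_path = file.path(dir, paste0(id, ".hmm")))
    write_profile(prof, file.path(dir, paste0(id, ".ah")))
  }
  write_labels(world$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}
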