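# Floored base-2 log transition terms for one profile, one vector per
# transition type, indexed by node.
trans_logs <- function(profile) {
  tr <- profile$trans
  lapply(setNames(colnames(tr), colnames(tr)),
         function(cn) log2_floor(tr[, cn]))
}

#' Local Viterbi alignment of two AlignHUSH profiles
#'
#' Five-state pair-HMM dynamic programming over states MM, MI, IM, DG,
#' GD. `MM` consumes a column of both profiles and adds the column match
#' score `M(i,j)`; `MI`/`DG` advance only the first profile (through the
#' second profile's insert transitions / the first profile's delete
#' transitions respectively) and `IM`/`GD` mirror them. Every log
#' transition term is weighted by `Wg`. Alignment is local: the `MM`
#' recurrence takes a max with 0 (fresh start) and traceback begins at
#' the global maximum of the MM matrix, which is also the reported
#' score. Gap states can only be entered from and left into `MM`, so
#' alignments begin and end in `MM`.
#'
#' @param P,Q [hush_profile()] objects (the query and the target).
#' @param params A [hush_params()].
#' @return An object of class `hush_alignment`: list with `query`,
#'   `target`, `score` (bits, >= 0), `pairs` (k x 2 matrix of aligned
#'   match-state indices), `path` (tibble with columns `state`, `i`,
#'   `j`) and `params`. An empty alignment (score 0) is returned when no
#'   cell of the MM matrix is positive.
#' @export
viterbi_align <- function(P, Q, params = hush_params()) {
  stopifnot(inherits(P, "hush_profile"), inherits(Q, "hush_profile"))
  if (!isTRUE(all.equal(P$background, Q$background, tolerance = 1e-6))) {
    warn("profiles carry different backgrounds; using the query's for scoring")
  }
  n <- P$length; m <- Q$length
  M <- column_score_matrix(P, Q, params)
  lp <- trans_logs(P); lq <- trans_logs(Q)
  Wg <- params$Wg

  NEG <- -Inf
  MMs <- matrix(NEG, n + 1, m + 1); MIs <- MMs; IMs <- MMs; DGs <- MMs; GDs <- MMs
  # pointer codes: 0 start, 1 MM, 2 MI, 3 IM, 4 DG, 5 GD
  pMM <- matrix(0L, n + 1, m + 1); pMI <- pMM; pIM <- pMM; pDG <- pMM; pGD <- pMM

  for (i in 1:n) {
    ii <- i + 1L
    for (j in 1:m) {
      jj <- j + 1L
      # MM: predecessors at (i-1, j-1)
      best <- 0; ptr <- 0L
      if (i > 1 && j > 1) {
        cand <- c(
          MMs[ii - 1L, jj - 1L] + Wg * (lp$MM[i - 1L] + lq$MM[j - 1L]),
          MIs[ii - 1L, jj - 1L] + Wg * (lp$MM[i - 1L] + lq$IM[j - 1L]),
          IMs[ii - 1L, jj - 1L] + Wg * (lp$IM[i - 1L] + lq$MM[j - 1L]),
          DGs[ii - 1L, jj - 1L] + Wg * (lp$DM[i - 1L] + lq$MM[j - 1L]),
          GDs[ii - 1L, jj - 1L] + Wg * (lp$MM[i - 1L] + lq$DM[j - 1L]))
        for (s in 1:5) {
          if (cand[s] > best) { best <- cand[s]; ptr <- s }
        }
      }
      MMs[ii, jj] <- M[i, j] + best
      pMM[ii, jj] <- ptr

      if (i > 1) {
        # MI: P advances, Q inserts at column j
        a <- MMs[ii - 1L, jj] + Wg * (lp$MM[i - 1L] + lq$MI[j])
        b <- MIs[ii - 1L, jj] + Wg * (lp$MM[i - 1L] + lq$II[j])
        if (a >= b) { MIs[ii, jj] <- a; pMI[ii, jj] <- 1L }
        else { MIs[ii, jj] <- b; pMI[ii, jj] <- 2L }
        # DG: P advances through its delete states
        a <- MMs[ii - 1L, jj] + Wg * lp$MD[i - 1L]
        b <- DGs[ii - 1L, jj] + Wg * lp$DD[i - 1L]
        if (a >= b) { DGs[ii, jj] <- a; pDG[ii, jj] <- 1L }
        else { DGs[ii, jj] <- b; pDG[ii, jj] <- 4L }
      }
      # IM: Q advances, P inserts at column i
      if (j > 1) {
        a <- MMs[ii, jj - 1L] + Wg * (lq$MM[j - 1L] + lp$MI[i])
        b <- IMs[ii, jj - 1L] + Wg * (lq$MM[j - 1L] + lp$II[i])
        if (a >= b) { IMs[ii, jj] <- a; pIM[ii, jj] <- 1L }
        else { IMs[ii, jj] <- b; pIM[ii, jj] <- 3L }
      }
      # GD: Q advances through its delete states
      if (j > 1) {
        a <- MMs[ii, jj - 1L] + Wg * lq$MD[j - 1L]
        b <- GDs[ii, jj - 1L] + Wg * lq$DD[j - 1L]
        if (a >= b) { GDs[ii, jj] <- a; pGD[ii, jj] <- 1L }
        else { GDs[ii, jj] <- b; pGD[ii, jj] <- 5L }
      }
    }
  }

  core <- MMs[-1, -1, drop = FALSE]
  score <- max(core)
  if (score <= 0) {
    return(new_hush_alignment(P$name, Q$name, 0,
                              matrix(integer(0), 0, 2),
                              tibble::tibble(state = character(0),
                                             i = integer(0), j = integer(0)),
                              params))
  }
  hit <- which(core == score, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]  # deterministic ties
  i <- hit[[1]]; j <- hit[[2]]

  states <- character(0); is <- integer(0); js <- integer(0)
  state <- 1L
  repeat {
    states <- c("MM", "MI", "IM", "DG", "GD")[state] |> c(states)
    is <- c(i, is); js <- c(j, js)
    prev <- switch(state, pMM, pMI, pIM, pDG, pGD)[i + 1L, j + 1L]
    if (state == 1L && prev == 0L) break
    # coordinate step back depends on the state we are LEAVING
    di <- if (state %in% c(1L, 2L, 4L)) 1L else 0L
    dj <- if (state %in% c(1L, 3L, 5L)) 1L else 0L
    i <- i - di; j <- j - dj
    state <- prev
  }
  pairs <- cbind(i = is[states == "MM"], j = js[states == "MM"])
  new_hush_alignment(P$name, Q$name, score, pairs,
                     tibble::tibble(state = states, i = is, j = js), params)
}

new_hush_alignment <- function(query, target, score, pairs, path, params) {
  structure(list(query = query, target = target, score = score,
                 pairs = pairs, path = path, params = params),
            class = "hush_alignment")
}

#' @export
print.hush_alignment <- function(x, ...) {
  if (nrow(x$pairs) == 0) {
    cat(sprintf("<hush_alignment> %s vs %s: empty (score 0)\n", x$query, x$target))
  } else {
    cat(sprintf("<hush_alignment> %s[%d-%d] vs %s[%d-%d]: %d aligned pairs, score %.3f bits\n",
                x$query, min(x$pairs[, 1]), max(x$pairs[, 1]),
                x$target, min(x$pairs[, 2]), max(x$pairs[, 2]),
                nrow(x$pairs), x$score))
  }
  invisible(x)
}

#' Recompute an alignment's score term by term
#'
#' Walks the stored state path, validating every transition against the
#' pair-HMM state machine (gap runs are homogeneous; `MM` steps move
#' diagonally by exactly (1,1); gap steps advance exactly one profile)
#' and summing column match scores plus `Wg`-weighted log transition
#' terms. For any output of [viterbi_align()] this reproduces `score`
#' within 1e-9; structurally invalid paths raise a contract violation
#' naming the offending step.
#'
#' @param P,Q The aligned profiles.
#' @param aln A `hush_alignment`.
#' @param params Scoring parameters (defaults to those stored in `aln`).
#' @return Scalar score in bits.
#' @export
rescore_alignment <- function(P, Q, aln, params = aln$params) {
  path <- aln$path
  if (nrow(path) == 0) return(0)
  if (path$state[1] != "MM" || path$state[nrow(path)] != "MM") {
    abort("path must begin and end in MM", class = "alignhush_contract_error")
  }
  M <- column_score_matrix(P, Q, params)
  lp <- trans_logs(P); lq <- trans_logs(Q)
  Wg <- params$Wg

  total <- M[path$i[1], path$j[1]]
  if (nrow(path) >= 2) for (k in 2:nrow(path)) {
    s1 <- path$state[k - 1]; s2 <- path$state[k]
    i1 <- path$i[k - 1]; j1 <- path$j[k - 1]
    i2 <- path$i[k]; j2 <- path$j[k]
    bad <- function() {
      abort(sprintf("invalid path step %d: %s(%d,%d) -> %s(%d,%d)",
                    k, s1, i1, j1, s2, i2, j2),
            class = "alignhush_contract_error")
    }
    term <- switch(
      s2,
      MM = {
        if (i2 != i1 + 1 || j2 != j1 + 1) bad()
        switch(s1,
               MM = lp$MM[i1] + lq$MM[j1],
               MI = lp$MM[i1] + lq$IM[j1],
               IM = lp$IM[i1] + lq$MM[j1],
               DG = lp$DM[i1] + lq$MM[j1],
               GD = lp$MM[i1] + lq$DM[j1])
      },
      MI = {
        if (i2 != i1 + 1 || j2 != j1 || !s1 %in% c("MM", "MI")) bad()
        lp$MM[i1] + if (s1 == "MM") lq$MI[j2] else lq$II[j2]
      },
      IM = {
        if (i2 != i1 || j2 != j1 + 1 || !s1 %in% c("MM", "IM")) bad()
        lq$MM[j1] + if (s1 == "MM") lp$MI[i2] else lp$II[i2]
      },
      DG = {
        if (i2 != i1 + 1 || j2 != j1 || !s1 %in% c("MM", "DG")) bad()
        if (s1 == "MM") lp$MD[i1] else lp$DD[i1]
      },
      GD = {
        if (i2 != i1 || j2 != j1 + 1 || !s1 %in% c("MM", "GD")) bad()
        if (s1 == "MM") lq$MD[j1] else lq$DD[j1]
      }
    )
    total <- total + Wg * term
    if (s2 == "MM") total <- total + M[i2, j2]
  }
  total
}
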