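test_that("a single positive cell aligns locally; a negative one does not", {
  withr::with_seed(31, {
    P <- random_profile(1, "P"); Q <- random_profile(1, "Q")
    params <- small_params(win_c = 1, win_h = 1, win_s = 1)
    m11 <- column_match_score(P, Q, 1, 1, params)
    aln <- viterbi_align(P, Q, params)
    if (m11 > 0) {
      expect_equal(aln$score, m11)
      expect_equal(unname(aln$pairs), matrix(c(1L, 1L), 1))
    }
    # force a negative sole cell: all weights 0 except a hydrophobic
    # mismatch pushed below zero
    P$hydro <- 10; Q$hydro <- -10
    neg <- small_params(Wc = 0, Wh = 1, Ws = 0, win_h = 1)
    aln2 <- viterbi_align(P, Q, neg)
    expect_equal(aln2$score, 0)
    expect_equal(nrow(aln2$pairs), 0L)
  })
})

test_that("the DP score equals exhaustive path enumeration on small profiles", {
  withr::with_seed(32, {
    for (k in 1:60) {
      n <- sample(1:6, 1); m <- sample(1:6, 1)
      P <- random_profile(n, "P"); Q <- random_profile(m, "Q")
      params <- small_params(win_c = sample(c(1, 3, 5), 1),
                             Wg = runif(1, 0.5, 1.5))
      expect_equal(viterbi_align(P, Q, params)$score,
                   oracle_best_score(P, Q, params), tolerance = 1e-12)
    }
  })
})

test_that("rescoring the traceback path reproduces the Viterbi score", {
  withr::with_seed(33, {
    for (k in 1:20) {
      n <- sample(2:12, 1); m <- sample(2:12, 1)
      pair <- related_profile_pair(max(n, m))
      P <- pair$P; Q <- pair$Q
      params <- small_params()
      aln <- viterbi_align(P, Q, params)
      if (nrow(aln$path) > 0) {
        expect_equal(rescore_alignment(P, Q, aln), aln$score, tolerance = 1e-9)
      }
    }
  })
})

test_that("structurally invalid paths are rejected with the offending step", {
  withr::with_seed(34, {
    pair <- related_profile_pair(6)
    aln <- viterbi_align(pair$P, pair$Q, small_params())
    expect_gt(nrow(aln$path), 1)
    broken <- aln
    broken$path$i[2] <- broken$path$i[2] + 1L  # MM jump of offset (2,1)
    expect_error(rescore_alignment(pair$P, pair$Q, broken),
                 "invalid path step", class = "alignhush_contract_error")
  })
})

test_that("a hand-built two-pair diagonal path scores M11 + M22 + one transition", {
  withr::with_seed(35, {
    pair <- related_profile_pair(2)
    P <- pair$P; Q <- pair$Q
    params <- small_params(win_c = 1, win_h = 1, win_s = 1)
    path <- tibble::tibble(state = c("MM", "MM"), i = 1:2, j = 1:2)
    aln <- structure(list(query = "P", target = "Q", score = NA,
                          pairs = cbind(1:2, 1:2), path = path,
                          params = params),
                     class = "hush_alignment")
    expected <- column_match_score(P, Q, 1, 1, params) +
      column_match_score(P, Q, 2, 2, params) +
      params$Wg * (log2(P$trans[[1, "MM"]]) + log2(Q$trans[[1, "MM"]]))
    expect_equal(rescore_alignment(P, Q, aln), expected, tolerance = 1e-12)
  })
})

test_that("alignment score is symmetric under profile exchange", {
  withr::with_seed(36, {
    for (k in 1:10) {
      P <- random_profile(sample(3:8, 1), "P")
      Q <- random_profile(sample(3:8, 1), "Q")
      params <- small_params()
      expect_equal(viterbi_align(P, Q, params)$score,
                   viterbi_align(Q, P, params)$score, tolerance = 1e-9)
    }
  })
})

test_that("the local score dominates every single column pair and zero", {
  withr::with_seed(37, {
    P <- random_profile(7, "P"); Q <- random_profile(8, "Q")
    params <- small_params()
    aln <- viterbi_align(P, Q, params)
    M <- column_score_matrix(P, Q, params)
    expect_gte(aln$score, 0)
    expect_gte(aln$score, max(M) - 1e-12)
  })
})

test_that("appending identical conserved columns never lowers the score", {
  withr::with_seed(38, {
    bg <- uniform_background()
    base <- related_profile_pair(5)
    params <- small_params(win_c = 1, win_h = 1, win_s = 1)
    s0 <- viterbi_align(base$P, base$Q, params)$score
    extend <- function(prof, extra) {
      e <- sweep(prof$odds, 2, sqrt(bg), `*`)
      e2 <- rbind(e, extra)
      encode_alignhush(e2, rbind(prof$trans, random_trans(nrow(extra))), bg,
                       name = prof$name)
    }
    sharp <- matrix(0.001 / 19, 3, 20, dimnames = list(NULL, aa_alphabet()))
    sharp[, "W"] <- 0.999
    P2 <- extend(base$P, sharp); Q2 <- extend(base$Q, sharp)
    s1 <- viterbi_align(P2, Q2, params)$score
    expect_gte(s1, s0 - 1e-9)
  })
})

test_that("self-alignment of a sharply conserved profile is the full diagonal", {
  withr::with_seed(39, {
    e <- matrix(0.02 / 19, 6, 20, dimnames = list(NULL, aa_alphabet()))
    for (i in 1:6) e[i, sample(20, 1)] <- 0.98
    P <- encode_alignhush(e, random_trans(6), uniform_background(), name = "self")
    aln <- viterbi_align(P, P, small_params(win_c = 1, Wh = 0, Ws = 0))
    expect_equal(unname(aln$pairs), cbind(1:6, 1:6))
  })
})

test_that("database search ranks the query's self-hit first, order-independently", {
  withr::with_seed(40, {
    profs <- lapply(1:5, function(k) random_profile(8, sprintf("t%d", k)))
    query <- profs[[3]]
    params <- small_params()
    hits <- align_all(query, profs, params)
    expect_equal(hits$target[1], "t3")
    expect_equal(nrow(hits), 5L)
    # reordering the database leaves the ranked table unchanged
    hits2 <- align_all(query, profs[c(4, 1, 5, 3, 2)], params)
    cols <- c("query", "target", "score", "n_pairs")
    expect_equal(hits2[cols], hits[cols], ignore_attr = TRUE)
    # degenerate database of one
    expect_equal(nrow(align_all(query, profs[2], params)), 1L)
  })
})
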