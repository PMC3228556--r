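bg <- uniform_background()

test_that("conservation score has its closed-form values", {
  # both columns at the background distribution: sum_a b_a = 1 -> 0 bits
  flat <- sqrt(bg)
  expect_equal(conservation_score(flat, flat), 0)
  # point masses on the same residue, uniform background: log2(20)
  pm <- setNames(rep(0, 20), aa_alphabet()); pm["A"] <- 1 / sqrt(bg[["A"]])
  expect_equal(conservation_score(pm, pm), log2(20))
  # disjoint support: floored at -50, not -Inf
  pm2 <- setNames(rep(0, 20), aa_alphabet()); pm2["C"] <- 1 / sqrt(bg[["C"]])
  expect_equal(conservation_score(pm, pm2), -50)
})

test_that("hydrophobic score is a symmetric offset-minus-difference", {
  expect_equal(hydrophobic_score(2.1, 2.1, hydro_offset = 1.5), 1.5)
  expect_equal(hydrophobic_score(0, 1.5, hydro_offset = 1.5), 0)
  expect_equal(hydrophobic_score(-3, 4, 1.5), hydrophobic_score(4, -3, 1.5))
})

test_that("SS score is the bilinear form over the substitution table", {
  L <- test_ss_table()
  helix <- c(1, 0, 0)
  expect_equal(ss_score(helix, helix, L), L["H", "H"])
  u <- rep(1 / 3, 3)
  expect_equal(ss_score(u, u, L), mean(unclass(L)))
  withr::with_seed(2, {
    fx <- random_ss(1)[1, ]; fy <- random_ss(1)[1, ]
    expect_equal(ss_score(fx, fy, L), ss_score(fy, fx, L))
  })
})

test_that("windowed terms sum over a truncated diagonal window", {
  const <- function(ii, jj) 2.5
  expect_equal(windowed_term(const, 10, 10, 4, 7, width = 1), 2.5)
  expect_equal(windowed_term(const, 10, 10, 5, 5, width = 5), 5 * 2.5)
  # corner: offsets -2 and -1 truncated
  expect_equal(windowed_term(const, 10, 10, 1, 1, width = 5), 3 * 2.5)
  # off-centre truncation driven by the shorter profile
  expect_equal(windowed_term(const, 3, 10, 2, 5, width = 5), 3 * 2.5)
  expect_error(windowed_term(const, 3, 3, 4, 1, width = 1))
})

test_that("the combined column score matches its term-by-term recomputation", {
  withr::with_seed(21, {
    P <- random_profile(7, "P"); Q <- random_profile(9, "Q")
    params <- small_params(Wc = 1, Wh = 0.4, Ws = 0.6,
                           win_c = 5, win_h = 3, win_s = 5)
    cons <- function(ii, jj) conservation_score(P$odds[ii, ], Q$odds[jj, ])
    hyd <- function(ii, jj) hydrophobic_score(P$hydro[ii], Q$hydro[jj],
                                              params$hydro_offset)
    ssf <- function(ii, jj) ss_score(P$ss[ii, ], Q$ss[jj, ], params$ss_table)
    for (cell in list(c(1, 1), c(4, 5), c(7, 9), c(3, 8))) {
      i <- cell[1]; j <- cell[2]
      manual <-
        params$Wc * windowed_term(cons, 7, 9, i, j, params$win_c) +
        params$Wh * windowed_term(hyd, 7, 9, i, j, params$win_h) +
        params$Ws * windowed_term(ssf, 7, 9, i, j, params$win_s)
      expect_equal(column_match_score(P, Q, i, j, params), manual,
                   tolerance = 1e-12)
    }
  })
})

test_that("the vectorised score matrix equals the per-cell operation", {
  withr::with_seed(22, {
    P <- random_profile(6, "P"); Q <- random_profile(5, "Q")
    P$ss_annotated[2] <- FALSE  # unannotated column switches the SS term off
    params <- small_params(win_c = 3, win_h = 5, win_s = 3)
    M <- column_score_matrix(P, Q, params)
    for (i in 1:6) for (j in 1:5) {
      expect_equal(M[i, j], column_match_score(P, Q, i, j, params),
                   tolerance = 1e-10)
    }
  })
})

test_that("column scores are symmetric under profile exchange", {
  withr::with_seed(23, {
    P <- random_profile(6, "P"); Q <- random_profile(8, "Q")
    params <- small_params()
    M_pq <- column_score_matrix(P, Q, params)
    M_qp <- column_score_matrix(Q, P, params)
    expect_equal(M_pq, t(M_qp), tolerance = 1e-10)
  })
})

test_that("zeroed weights and unit windows reproduce the ablated variants", {
  withr::with_seed(24, {
    P <- random_profile(6, "P"); Q <- random_profile(6, "Q")
    # no_hyd / no_sec: dropping a term equals zeroing its weight
    full <- small_params(Wc = 1, Wh = 0.3, Ws = 0.3)
    no_hyd <- small_params(Wc = 1, Wh = 0, Ws = 0.3)
    H <- full$hydro_offset - abs(outer(P$hydro, Q$hydro, `-`))
    M_full <- column_score_matrix(P, Q, full)
    expect_equal(M_full - 0.3 * alignhush:::diag_window_sum(H, 5),
                 column_score_matrix(P, Q, no_hyd), tolerance = 1e-10)
    # all weights zero annihilate the score
    none <- small_params(Wc = 0, Wh = 0, Ws = 0)
    expect_equal(column_score_matrix(P, Q, none), matrix(0, 6, 6))
    # no_neigh: unit windows equal the raw single-column terms
    raw <- small_params(win_c = 1, win_h = 1, win_s = 1)
    M_raw <- column_score_matrix(P, Q, raw)
    expect_equal(M_raw[3, 4],
                 raw$Wc * conservation_score(P$odds[3, ], Q$odds[4, ]) +
                   raw$Wh * hydrophobic_score(P$hydro[3], Q$hydro[4],
                                              raw$hydro_offset) +
                   raw$Ws * ss_score(P$ss[3, ], Q$ss[4, ], raw$ss_table),
                 tolerance = 1e-12)
  })
})
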