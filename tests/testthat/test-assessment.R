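lab <- function(f, sf, fo, cl) {
  list(family = f, superfamily = sf, fold = fo, class = cl)
}

test_that("relation classes follow the SCOP-style rules", {
  # same superfamily, different family: true relation
  expect_equal(classify_relation(lab("f1", "sf1", "fo1", "c1"),
                                 lab("f2", "sf1", "fo1", "c1")),
               "TRUE_POSITIVE_ELIGIBLE")
  # different class: false-positive material
  expect_equal(classify_relation(lab("f1", "sf1", "fo1", "c1"),
                                 lab("f2", "sf2", "fo2", "c2")),
               "FALSE_POSITIVE_ELIGIBLE")
  # same fold, different superfamily: ignored
  expect_equal(classify_relation(lab("f1", "sf1", "fo1", "c1"),
                                 lab("f2", "sf2", "fo1", "c1")),
               "IGNORED")
  # same class, different fold: ignored
  expect_equal(classify_relation(lab("f1", "sf1", "fo1", "c1"),
                                 lab("f2", "sf2", "fo2", "c1")),
               "IGNORED")
  # self-family pairs are not scored
  expect_equal(classify_relation(lab("f1", "sf1", "fo1", "c1"),
                                 lab("f1", "sf1", "fo1", "c1")),
               "IGNORED")
  expect_error(classify_relation(lab("f1", "sf1", "fo1", NA),
                                 lab("f2", "sf2", "fo2", "c2")),
               class = "alignhush_label_error")
})

test_that("sensitivity/error arithmetic matches the definitions", {
  hits <- tibble::tibble(
    score = seq(100, 91),
    relation = c(rep("TRUE_POSITIVE_ELIGIBLE", 9), "FALSE_POSITIVE_ELIGIBLE"))
  curve <- sensitivity_error_curve(hits, n_true = 20)
  last <- curve[nrow(curve), ]
  expect_equal(last$error, 0.10)
  expect_equal(last$sensitivity, 0.45)
  # error rate rises exactly at false hits, never at ignored ones
  hits2 <- tibble::tibble(
    score = seq(100, 96),
    relation = c("TRUE_POSITIVE_ELIGIBLE", "IGNORED", "FALSE_POSITIVE_ELIGIBLE",
                 "IGNORED", "TRUE_POSITIVE_ELIGIBLE"))
  c2 <- sensitivity_error_curve(hits2, n_true = 4)
  expect_equal(c2$error, c(0, 1 / 2, 1 / 3))
  expect_equal(c2$sensitivity, c(0.25, 0.25, 0.5))
  # dropping the ignored rows changes nothing
  c3 <- sensitivity_error_curve(hits2[hits2$relation != "IGNORED", ], n_true = 4)
  expect_equal(c3, c2)
  # all hits ignored: empty curve
  expect_equal(nrow(sensitivity_error_curve(
    tibble::tibble(score = 1, relation = "IGNORED"), n_true = 4)), 0L)
  expect_equal(sensitivity_at_error(c2, 0.10), 0.25)
})

test_that("hit classification deduplicates to the best hit per pair", {
  labels <- homology_labels(c("a1", "a2", "b1"),
                            class = c("c1", "c1", "c2"),
                            fold = c("fo1", "fo1", "fo2"),
                            superfamily = c("sf1", "sf1", "sf2"),
                            family = c("a1", "a2", "b1"))
  hits <- tibble::tibble(query = c("a1", "a1", "a1", "a1"),
                         target = c("a2", "a2", "b1", "a1"),
                         score = c(5, 9, 3, 99))
  out <- classify_hits(hits, labels)
  expect_equal(nrow(out), 2L)  # deduplicated, self hit dropped
  expect_equal(out$score[out$target == "a2"], 9)
  expect_equal(sort(unique(out$relation)),
               c("FALSE_POSITIVE_ELIGIBLE", "TRUE_POSITIVE_ELIGIBLE"))
  expect_equal(count_true_relations(labels), 1L)
})

test_that("transitive composition maps residues through profile columns", {
  ident <- cbind(1:5, 1:5)
  out <- compose_alignments(ident, ident, ident)
  expect_equal(out, tibble::tibble(r1 = 1:5, r2 = 1:5))
  # a column missing from the profile-profile alignment drops its residues
  out2 <- compose_alignments(ident, ident[-3, ], ident)
  expect_equal(out2$r1, c(1, 2, 4, 5))
  # empty middle alignment annihilates
  empty <- matrix(integer(0), 0, 2)
  expect_equal(nrow(compose_alignments(ident, empty, ident)), 0L)
  # offset maps compose correctly
  seq_to_p <- cbind(11:14, 2:5)       # residues 11..14 sit in columns 2..5
  p_to_q <- cbind(c(2, 3, 5), c(1, 2, 4))
  q_to_seq <- cbind(1:4, 21:24)
  out3 <- compose_alignments(seq_to_p, p_to_q, q_to_seq)
  expect_equal(out3, tibble::tibble(r1 = c(11L, 12L, 14L),
                                    r2 = c(21L, 22L, 24L)))
  expect_error(compose_alignments(cbind(c(1, 3, 2), 1:3), ident, ident),
               class = "alignhush_contract_error")
})

test_that("developer and modeller scores follow their definitions", {
  ref <- cbind(1:10, 11:20)
  # 8 pairs inside the reference region, 4 of them exact matches
  test8 <- cbind(1:8, c(11, 12, 13, 14, 16, 15, 18, 17))
  acc <- alignment_accuracy(test8, ref)
  expect_equal(acc$developer, 0.5)
  expect_equal(acc$modeller, 0.4)
  # identity: perfect on both
  acc2 <- alignment_accuracy(ref, ref)
  expect_equal(c(acc2$developer, acc2$modeller), c(1, 1))
  # empty test alignment scores zero by convention
  acc3 <- alignment_accuracy(matrix(integer(0), 0, 2), ref)
  expect_equal(c(acc3$developer, acc3$modeller), c(0, 0))
  expect_error(alignment_accuracy(ref, matrix(integer(0), 0, 2)),
               class = "alignhush_accuracy_error")
  # test pairs outside the reference's covered region are excluded from
  # the developer denominator
  acc4 <- alignment_accuracy(rbind(test8, c(40, 50)), ref)
  expect_equal(acc4$developer, 0.5)
})

test_that("grid search picks the sensitivity-maximising parameters", {
  withr::with_seed(61, {
    # two superfamilies, two families each; conservation carries the
    # signal while SS and hydrophobicity are pure noise
    mk_family_pair <- function(tag, cl) {
      pair <- related_profile_pair(12, noise = 0.15)
      noisy <- function(p, nm) {
        p$ss <- random_ss(p$length); p$ss_annotated <- rep(TRUE, p$length)
        p$hydro <- runif(p$length, -4, 4)
        p$name <- nm
        p
      }
      list(noisy(pair$P, paste0(tag, "_fam1")),
           noisy(pair$Q, paste0(tag, "_fam2")))
    }
    profs <- c(mk_family_pair("sfA", "c1"), mk_family_pair("sfB", "c2"))
    names(profs) <- vapply(profs, function(p) p$name, "")
    labels <- homology_labels(
      names(profs),
      class = c("c1", "c1", "c2", "c2"),
      fold = c("foA", "foA", "foB", "foB"),
      superfamily = c("sfA", "sfA", "sfB", "sfB"),
      family = names(profs))

    grid <- expand.grid(Wh = c(0, 5), Ws = c(0, 5))
    tuned <- tune_parameters(profs, labels, grid,
                             base_params = small_params(win_c = 3))
    expect_equal(tuned$params$Wh, 0)
    expect_equal(tuned$params$Ws, 0)
    expect_equal(nrow(tuned$grid), 4L)

    # degenerate grids: a single point, or duplicated points
    one <- tune_parameters(profs, labels, data.frame(Wh = 0.3),
                           base_params = small_params())
    expect_equal(one$params$Wh, 0.3)
    dup <- tune_parameters(profs, labels, data.frame(Wh = c(0.3, 0.3)),
                           base_params = small_params())
    expect_equal(dup$best, one$best)
    expect_error(tune_parameters(profs, labels, data.frame()),
                 class = "alignhush_config_error")
  })
})

test_that("rank AUC behaves as a Mann-Whitney statistic", {
  expect_equal(roc_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2), c(3, 4)), 0)
  expect_equal(roc_auc(c(1, 2), c(1, 2)), 0.5)
})
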