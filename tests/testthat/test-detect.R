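make_clutch_matrix <- function(rows) {
  x <- do.call(rbind, rows)
  colnames(x) <- trait_names()
  rownames(x) <- paste0("e", seq_len(nrow(x)))
  x
}

test_that("MED matches hand computation and the threshold rule", {
  same <- make_clutch_matrix(rep(list(rep(0.3, 9)), 5))
  m0 <- med_statistic(same)
  expect_equal(m0$med, 0)
  expect_false(m0$classified_parasitized)

  # 4 identical eggs + 1 outlier at distance d: outlier mean = d, others d/4
  d <- 12
  out <- make_clutch_matrix(c(rep(list(rep(0, 9)), 4), list(rep(d / 3, 9))))
  m1 <- med_statistic(out)
  expect_equal(m1$med, d)
  expect_equal(m1$most_different_egg, "e5")
  expect_equal(unname(m1$per_egg_mean_distance[1:4]), rep(d / 4, 4))

  big <- make_clutch_matrix(c(rep(list(rep(0, 9)), 4), list(rep(120, 9))))
  expect_true(med_statistic(big)$classified_parasitized)       # MED = 360 > 350
  expect_false(med_statistic(out, threshold = 350)$classified_parasitized)

  expect_error(med_statistic(same[1:2, ]), "at least 3")
  expect_warning(med_statistic(same, weights_provenance = "fitted"), "reference")
})

test_that("MED scales linearly with the trait scale", {
  set.seed(8)
  x <- matrix(rnorm(45), 5, 9, dimnames = list(paste0("e", 1:5), trait_names()))
  expect_equal(med_statistic(3 * x)$med, 3 * med_statistic(x)$med, tolerance = 1e-12)
})

test_that("unsupervised identification calls obvious parasites and ties are ambiguous", {
  tr <- fix_traits()
  sets <- sample_assessment_sets(tr, 1, seed = 2)
  lay <- build_layouts(sets[1:5, ], tr, game = 1, seed = 3)
  w <- weight_traits(scale_traits(tr), reference_weights())

  # clearly displaced parasite
  far <- w
  far[far$egg_id == lay[[1]]$parasite_id, trait_names()] <-
    as.list(rep(500, 9))
  expect_equal(unsupervised_identify(lay[[1]], far)$called_egg,
               lay[[1]]$parasite_id)

  # all identical -> ambiguous
  flat <- w
  flat[trait_names()] <- 0
  u0 <- unsupervised_identify(lay[[1]], flat)
  expect_true(u0$ambiguous)
  expect_true(is.na(u0$called_egg))

  # oracle equality over random layouts, both games
  for (game in 1:2) {
    lays <- build_layouts(sets[6:25, ], tr, game = game, seed = game)
    for (pc in lays) {
      u <- unsupervised_identify(pc, w)
      expect_identical(u$called_egg, brute_force_identify(pc, w))
    }
  }
})

test_that("pair training is balanced, forced pairs are included, and sampling is seeded", {
  tr <- scale_traits(fix_traits())
  pool <- tr[tr$clutch_id != "F01", ]        # 53 clutches x 5 eggs
  tt <- build_pair_training(pool, n_same = 265, n_diff = 265, seed = 5)
  expect_equal(as.vector(table(tt$label)), c(265, 265))
  # available same pairs: 53 * choose(5,2) = 530; no duplicates when sampling
  key <- paste(pmin(tt$egg_a, tt$egg_b), pmax(tt$egg_a, tt$egg_b))
  expect_false(any(duplicated(key[tt$label == "same"])))
  expect_true(all(as.matrix(tt[, grep("^d_", names(tt))]) >= 0))

  tt2 <- build_pair_training(pool, n_same = 265, n_diff = 265, seed = 5)
  expect_identical(tt, tt2)

  hosts <- tr$egg_id[tr$clutch_id == "F02"][1:4]
  tt3 <- build_pair_training(pool, n_same = 265, n_diff = 265, seed = 1,
                             forced_host_eggs = hosts)
  forced_keys <- apply(combn(sort(hosts), 2), 2, paste, collapse = " ")
  key3 <- paste(pmin(tt3$egg_a, tt3$egg_b), pmax(tt3$egg_a, tt3$egg_b))
  expect_length(forced_keys, 6)               # choose(4, 2)
  expect_true(all(forced_keys %in% key3[tt3$label == "same"]))

  expect_warning(build_pair_training(pool[1:10, ], n_same = 100, n_diff = 5,
                                     seed = 1), "with replacement")
})

test_that("pair features are symmetric under egg swap", {
  tr <- scale_traits(fix_traits())
  X <- as.matrix(tr[, trait_names()]); rownames(X) <- tr$egg_id
  f1 <- cbpdetect:::.pair_features(X, 1, 7)
  f2 <- cbpdetect:::.pair_features(X, 7, 1)
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
})

test_that("supervised voting identifies parasites under strong signal, reproducibly", {
  cfg <- synth_config(n_females = 10, eggs_per_clutch = 5, sigma_between = 3,
                      sigma_within = 0.05, seed = 17)
  tr <- scale_traits(synth_clutches(cfg))
  sets <- sample_assessment_sets(tr, 1, seed = 4)
  lays <- build_layouts(sets[1:6, ], tr, game = 1, seed = 5)
  tallies <- evaluate_layouts(lays, tr, mode = "loco", n_repeats = 2,
                              n_same = 60, n_diff = 60, ntree = 100, seed = 9)
  for (i in seq_along(lays)) {
    expect_false(tallies[[i]]$ambiguous)
    expect_equal(tallies[[i]]$called_egg, lays[[i]]$parasite_id)
    # bookkeeping: each egg accrues at most 2 x 5 votes per repeat, in steps of 2
    v <- tallies[[i]]$per_egg_votes
    expect_true(all(v <= 10 * tallies[[i]]$n_repeats))
    expect_true(all(v %% 2 == 0))
  }
  # single-layout wrapper agrees with the batch path
  t1 <- supervised_identify(lays[[1]], tr, mode = "loco", n_repeats = 2,
                            n_same = 60, n_diff = 60, ntree = 100, seed = 9)
  expect_identical(t1$per_egg_votes, tallies[[1]]$per_egg_votes)
  # reproducible under the same seed, regardless of ambient RNG state
  set.seed(31415); invisible(runif(100))
  t2 <- supervised_identify(lays[[1]], tr, mode = "loco", n_repeats = 2,
                            n_same = 60, n_diff = 60, ntree = 100, seed = 9)
  expect_identical(t1, t2)
})

test_that("leave-one-egg-out is restricted to game 2 and uses the known hosts", {
  cfg <- synth_config(n_females = 8, eggs_per_clutch = 5, sigma_between = 3,
                      sigma_within = 0.05, seed = 3)
  tr <- scale_traits(synth_clutches(cfg))
  sets <- sample_assessment_sets(tr, 1, seed = 1)
  g1 <- build_layouts(sets[1, , drop = FALSE], tr, game = 1, seed = 2)
  expect_error(evaluate_layouts(g1, tr, mode = "leo"), "game 2")
  g2 <- build_layouts(sets[1:3, ], tr, game = 2, seed = 2)
  tl <- evaluate_layouts(g2, tr, mode = "leo", n_repeats = 2, n_same = 40,
                         n_diff = 40, ntree = 100, seed = 11)
  for (i in seq_along(g2)) {
    expect_equal(tl[[i]]$called_egg, g2[[i]]$parasite_id)
    # game-2 candidates accrue at most 2 x 4 votes per repeat
    expect_true(all(tl[[i]]$per_egg_votes[g2[[i]]$candidates] <=
                      8 * tl[[i]]$n_repeats))
  }
})

test_that("degenerate training pools raise errors", {
  cfg <- synth_config(n_females = 2, eggs_per_clutch = 5, sigma_between = 1,
                      sigma_within = 0.1, seed = 1)
  tr <- scale_traits(synth_clutches(cfg))
  pc <- make_parasitized_clutch(tr, "F01", tr$egg_id[tr$clutch_id == "F02"][1],
                                game = 1, seed = 1)
  # leave-one-clutch-out leaves a single female: no 'different' pairs exist
  expect_error(supervised_identify(pc, tr, mode = "loco", n_repeats = 1,
                                   n_same = 10, n_diff = 10, ntree = 50, seed = 1),
               "pairs available")
})

test_that("accuracy summaries reproduce the ambiguity-excluding arithmetic", {
  expect_equal(accuracy_summary(1890, 17, 1417)$accuracy_pct, 100 * 1417 / 1873)
  expect_equal(round(accuracy_summary(1890, 13, 1720)$accuracy_pct, 1), 91.6)
  expect_equal(accuracy_summary(10, 0, 0)$accuracy_pct, 0)
  expect_error(accuracy_summary(10, 2, 9))

  # brute-force recount over constructed tallies
  tallies <- list(
    structure(list(called_egg = "a", ambiguous = FALSE, truth = "a"), class = "vote_tally"),
    structure(list(called_egg = "b", ambiguous = FALSE, truth = "x"), class = "vote_tally"),
    structure(list(called_egg = NA_character_, ambiguous = TRUE, truth = "c"), class = "vote_tally"))
  s <- summarize_accuracy(tallies)
  expect_equal(s$n_total, 3); expect_equal(s$n_ambiguous, 1)
  expect_equal(s$n_correct, 1); expect_equal(s$accuracy_pct, 50)
})
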