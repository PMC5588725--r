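test_that("LOOCV holds out each patient exactly once", {
  f <- encode_cohort(tiny_cohort(3, 3, n_cdr3 = 5), k = 6)
  cv <- loocv(f, tiny_config())
  expect_equal(nrow(cv$per_fold), 6)
  expect_setequal(cv$per_fold$held_out, f$patient_ids)
  expect_equal(cv$accuracy, cv$n_correct / 6)
  expect_equal(glance(cv)$n_correct, cv$n_correct)
})

test_that("LOOCV training folds exclude the held-out patient", {
  f <- encode_cohort(tiny_cohort(2, 2, n_cdr3 = 4), k = 6)
  sub <- maxsnippet:::subset_features(f, c(2, 3, 4))
  expect_false(f$patient_ids[1] %in% sub$patient_ids)
  expect_equal(nrow(sub$X),
               sum(f$patient_index %in% 2:4))
  expect_identical(sub$X, f$X[f$patient_index %in% 2:4, ])
})

test_that("a fold that would lose a label class is refused", {
  cohort <- tiny_cohort(1, 3, n_cdr3 = 5)
  f <- encode_cohort(cohort, k = 6)
  expect_error(loocv(f, tiny_config()), "single-label")
})

test_that("candidate ranking breaks accuracy ties toward fewer features", {
  tab <- tibble::tibble(
    k = c(6L, 6L, 5L, 18L),
    unit = c("amino_acid", "amino_acid", "amino_acid", "nucleotide"),
    scheme = c("aa_onehot", "atchley", "atchley", "nt_onehot"),
    n_features = c(120L, 30L, 25L, 72L),
    n_correct = c(20L, 20L, 15L, NA),
    n_total = c(23L, 23L, 23L, NA),
    cv_accuracy = c(20 / 23, 20 / 23, 15 / 23, NA),
    feasible = c(TRUE, TRUE, TRUE, FALSE))
  sel <- rank_candidates(tab)
  # tie at 20/23: the 30-feature Atchley candidate beats 120-feature one-hot
  expect_equal(sel$winner$scheme, "atchley")
  expect_equal(sel$winner$k, 6L)
  expect_true(sel$tie_broken)
  # row order never matters
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 4, 1, 2))) {
    expect_equal(rank_candidates(tab[perm, ])$winner, sel$winner)
  }
  # infeasible rows stay in the table but can never win
  expect_equal(nrow(sel$table), 4)
  expect_error(rank_candidates(tab[tab$feasible == FALSE, ]), "feasible")
})

test_that("model selection favors the snippet length carrying the signal", {
  # 2-mers occur everywhere in background, so k = 2 carries no signal,
  # while the planted 6-mer is recovered at k = 6
  sim <- cohort_preset("separable", seed = 5)
  grid <- tibble::tibble(k = c(2L, 6L), unit = "amino_acid",
                         scheme = "atchley")
  cfg <- fit_config(n_restarts = 100, n_iterations = 2500, seed = 5)
  sel <- select_model(sim$cohort, grid, cfg)
  expect_equal(sel$winner$k, 6L)
  acc <- sel$table$cv_accuracy
  expect_gt(acc[sel$table$k == 6], acc[sel$table$k == 2])
  expect_gte(acc[sel$table$k == 6], 0.75)
})

test_that("infeasible grid rows are flagged rather than dropped", {
  cohort <- tiny_cohort(2, 2, n_cdr3 = 4, len = 8)
  grid <- tibble::tibble(k = c(6L, 30L), unit = "amino_acid",
                         scheme = "atchley")
  sel <- select_model(cohort, grid, tiny_config())
  expect_equal(nrow(sel$table), 2)
  expect_false(sel$table$feasible[sel$table$k == 30])
  expect_equal(sel$winner$k, 6L)
  expect_error(select_model(cohort, grid[0, ], tiny_config()), "empty")
})

test_that("refitting the winner equals a direct fit under the same seed", {
  cohort <- tiny_cohort(2, 2, n_cdr3 = 4)
  winner <- tibble::tibble(k = 6L, unit = "amino_acid", scheme = "atchley")
  direct <- fit_detector(encode_cohort(cohort, k = 6), tiny_config())
  refit <- refit_full(cohort, winner, tiny_config())
  expect_identical(refit$params, direct$params)
  expect_equal(refit$k, 6L)
  expect_equal(refit$scheme, "atchley")
})

test_that("the add-one permutation p-value reproduces 1/21 when unbeaten", {
  expect_equal(permutation_pvalue(20, rep(0:15, length.out = 20)), 1 / 21)
  expect_lt(permutation_pvalue(20, 0:19), 0.05)
  expect_equal(permutation_pvalue(5, c(5, 7, 2)), 3 / 4)  # ties count
  expect_error(permutation_pvalue(5, integer(0)), "one permutation")
})

test_that("the permutation test reruns LOOCV under shuffled labels", {
  f <- encode_cohort(tiny_cohort(2, 2, n_cdr3 = 4, seed = 2), k = 6)
  cfg <- fit_config(n_restarts = 2, n_iterations = 100, seed = 6)
  pt <- permutation_test(f, cfg, n_permutations = 3)
  expect_length(pt$permuted_n_correct, 3)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
  expect_equal(pt$p_value,
               permutation_pvalue(pt$observed_n_correct,
                                  pt$permuted_n_correct))
  expect_equal(pt$mean_permuted_accuracy,
               mean(pt$permuted_n_correct / 4))
  expect_error(permutation_test(f, cfg, n_permutations = 0), ">= 1")
})

test_that("ROC handles separation, reversal symmetry, and ties", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  rev <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  expect_equal(rev$auc, 0)
  set.seed(13)
  p <- runif(30); y <- rbinom(30, 1, 0.5)
  expect_equal(roc_curve(p, y)$auc, 1 - roc_curve(p, 1 - y)$auc)
  # tied probabilities step diagonally, giving the 0.5 credit
  tied <- roc_curve(c(0.5, 0.5), c(1, 0))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)), "both")
})

test_that("ROC AUC equals the normalized Mann-Whitney statistic", {
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    p <- c(runif(n1, 0.2, 1), runif(n0, 0, 0.8))
    p <- round(p, 1)  # force ties
    y <- c(rep(1, n1), rep(0, n0))
    u <- suppressWarnings(
      stats::wilcox.test(p[y == 1], p[y == 0])$statistic)
    expect_equal(roc_curve(p, y)$auc, unname(u) / (n1 * n0),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  p <- runif(40); y <- rbinom(40, 1, 0.5)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, p, levels = c(0, 1), direction = "<",
                        quiet = TRUE))))
  expect_equal(roc_curve(p, y)$auc, ref, tolerance = 1e-12)
})
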