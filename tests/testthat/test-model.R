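test_that("snippet logits are the biased weighted feature sum", {
  p0 <- detector_params(0, rep(0, 4))
  expect_equal(snippet_logit(c(1, 2, 3, 4), p0), 0)
  p1 <- detector_params(2, c(1, 0, 0, 0))
  expect_equal(snippet_logit(c(3, 9, 9, 9), p1), 5)
  # random pair matches elementwise summation
  set.seed(2)
  x <- rnorm(30); p <- detector_params(rnorm(1), rnorm(30))
  manual <- p$b0
  for (i in 1:30) manual <- manual + p$W[i] * x[i]
  expect_equal(snippet_logit(x, p), manual)
  expect_error(snippet_logit(c(1, 2), p), "match")
})

test_that("the sigmoid score saturates without overflow and is symmetric", {
  expect_equal(snippet_score(0), 0.5)
  expect_equal(snippet_score(1000), 1)
  expect_equal(snippet_score(-1000), 0)
  set.seed(3)
  x <- rnorm(50, 0, 5)
  expect_equal(snippet_score(x) + snippet_score(-x), rep(1, 50))
})

test_that("repertoire probability is the max score with first-index argmax", {
  r <- repertoire_probability(c(0.2, 0.7, 0.4))
  expect_equal(r$probability, 0.7)
  expect_equal(r$argmax_index, 2)
  expect_equal(repertoire_probability(0.3),
               list(probability = 0.3, argmax_index = 1))
  r2 <- repertoire_probability(c(0.2, 0.7, 0.4, 0.7))
  expect_equal(r2$argmax_index, 2)   # tie: first wins
  expect_error(repertoire_probability(numeric(0)), "no snippets")
})

test_that("the null detector gives score 0.5 everywhere and NLL = 2 ln 2", {
  f <- features_from_matrices(
    list(matrix(rnorm(30), 1), matrix(rnorm(90), 3)), c(1, 0))
  p0 <- detector_params(0, rep(0, 30))
  expect_equal(snippet_score(snippet_logit(f$X, p0)), rep(0.5, 4))
  expect_equal(negative_log_likelihood(p0, f), 2 * log(2))
})

test_that("NLL approaches 0 as a positive patient's score saturates", {
  f <- features_from_matrices(list(matrix(1, 1, 1)), 1)
  expect_lt(negative_log_likelihood(detector_params(50, 0), f), 1e-20)
})

test_that("likelihood and gradient match brute force and finite differences", {
  for (s in 1:10) {
    inst <- random_instance(s)
    expect_equal(negative_log_likelihood(inst$params, inst$features),
                 oracle_nll(inst$params, inst$features), tolerance = 1e-10)
    g <- nll_gradient(inst$params, inst$features)
    fd <- fd_gradient(inst$params, inst$features)
    expect_equal(g$d_W, fd$d_W, tolerance = 1e-5)
    expect_equal(g$d_b0, fd$d_b0, tolerance = 1e-5)
  }
})

test_that("one patient, one snippet reduces to the logistic gradient", {
  set.seed(7)
  x <- rnorm(30)
  p <- detector_params(0.2, rnorm(30))
  f <- features_from_matrices(list(matrix(x, 1)), 1)
  g <- nll_gradient(p, f)
  resid <- plogis(snippet_logit(x, p)) - 1
  expect_equal(g$d_W, resid * x)
  expect_equal(g$d_b0, resid)
})

test_that("tied snippets route the gradient through the first index", {
  x <- rnorm(30)
  f <- features_from_matrices(list(rbind(x, x)), 1)
  p <- detector_params(0, rnorm(30))
  g <- nll_gradient(p, f)
  single <- nll_gradient(p, features_from_matrices(list(matrix(x, 1)), 1))
  expect_equal(g, single)
})

test_that("penalty terms enter the objective and its gradient", {
  inst <- random_instance(11)
  base <- negative_log_likelihood(inst$params, inst$features)
  pen <- negative_log_likelihood(inst$params, inst$features,
                                 l1 = 0.3, l2 = 0.7)
  expect_equal(pen, base + 0.3 * sum(abs(inst$params$W)) +
                 0.7 * sum(inst$params$W^2))
  g <- nll_gradient(inst$params, inst$features, l1 = 0.3, l2 = 0.7)
  g0 <- nll_gradient(inst$params, inst$features)
  expect_equal(g$d_W, g0$d_W + 0.3 * sign(inst$params$W) +
                 1.4 * inst$params$W)
})

test_that("the first Adam step matches the hand-computed update", {
  cfg <- fit_config(step_size = 0.01, n_restarts = 1)
  p <- detector_params(0.5, c(1, -2))
  g <- list(d_b0 = 0.3, d_W = c(-0.4, 0))
  st <- adam_step(adam_init(p), g, cfg)
  # t = 1: mhat = g, vhat = g^2, update = -step * g / (|g| + eps)
  expect_equal(st$params$b0, 0.5 - 0.01 * 0.3 / (0.3 + 1e-8))
  expect_equal(st$params$W[1], 1 - 0.01 * (-0.4) / (0.4 + 1e-8))
  expect_equal(st$params$W[2], -2)   # zero gradient leaves it unchanged
  expect_equal(st$t, 1L)
})

test_that("fitting a separable fixture recovers the labels", {
  f <- encode_cohort(tiny_cohort(3, 3, n_cdr3 = 6), k = 6)
  fit <- fit_detector(f, fit_config(n_restarts = 6, n_iterations = 500,
                                    seed = 5))
  # well below the null objective of 6 * ln 2
  expect_lt(fit$train_nll, 2)
  pred <- predict(fit, f)
  expect_equal(as.integer(pred$probability > 0.5), unname(f$labels))
  # optimizer sanity: every restart improved on its initialization
  expect_true(all(fit$per_restart$final_nll <=
                    fit$per_restart$init_nll + 1e-8))
})

test_that("fits are deterministic and monotone in the restart budget", {
  f <- encode_cohort(tiny_cohort(2, 2, n_cdr3 = 4), k = 6)
  f1 <- fit_detector(f, tiny_config())
  f2 <- fit_detector(f, tiny_config())
  expect_identical(f1$params, f2$params)
  expect_identical(f1$per_restart, f2$per_restart)

  one <- fit_detector(f, fit_config(n_restarts = 1, n_iterations = 150,
                                    seed = 1))
  ten <- fit_detector(f, fit_config(n_restarts = 10, n_iterations = 150,
                                    seed = 1))
  # restart 1 is shared, so the 10-restart minimum can only be lower
  expect_lte(ten$train_nll, one$train_nll)
  expect_equal(ten$per_restart$final_nll[1], one$per_restart$final_nll[1])
})

test_that("fits are invariant to cohort row order", {
  cohort <- tiny_cohort(2, 2, n_cdr3 = 4)
  set.seed(8)
  blocks <- split(seq_len(nrow(cohort)), cohort$patient_id)
  shuffled <- cohort[unlist(blocks[sample(names(blocks))]), ]
  fit1 <- fit_detector(encode_cohort(cohort, k = 6), tiny_config())
  fit2 <- fit_detector(encode_cohort(shuffled, k = 6), tiny_config())
  expect_identical(fit1$params, fit2$params)
})

test_that("the compiled fitter agrees with the reference likelihood", {
  f <- encode_cohort(tiny_cohort(2, 2, n_cdr3 = 4), k = 6)
  for (prec in c("double", "single")) {
    fit <- fit_detector(f, tiny_config(precision = prec))
    expect_equal(fit$train_nll,
                 negative_log_likelihood(fit$params, f),
                 tolerance = 1e-10)
  }
  # codebook fast path and generic GEMM path optimize identically (double)
  f2 <- f; f2$codes <- NULL; f2$codebook <- NULL
  fit_a <- fit_detector(f, tiny_config(precision = "double"))
  fit_b <- fit_detector(f2, tiny_config(precision = "double"))
  expect_equal(fit_a$params$W, fit_b$params$W, tolerance = 1e-8)
})

test_that("weight initialization respects the variance convention", {
  cfg_var <- fit_config(n_restarts = 300, seed = 2)
  W0 <- maxsnippet:::initial_weights(30, cfg_var)
  expect_equal(stats::sd(W0), sqrt(1 / 30), tolerance = 0.02)
  cfg_sd <- fit_config(n_restarts = 300, seed = 2, init_scale = "sd")
  W0s <- maxsnippet:::initial_weights(30, cfg_sd)
  expect_equal(stats::sd(W0s), 1 / 30, tolerance = 0.02)
})

test_that("prediction enforces encoding compatibility and 0.5 boundary", {
  f <- encode_cohort(tiny_cohort(1, 1, n_cdr3 = 3), k = 6)
  fit <- fit_detector(f, tiny_config())
  f5 <- encode_cohort(tiny_cohort(1, 1, n_cdr3 = 3), k = 5)
  expect_error(predict(fit, f5), "mismatch")

  null_fit <- fit
  null_fit$params <- detector_params(0, rep(0, 30))
  pred <- predict(null_fit, f)
  expect_true(all(pred$probability == 0.5))
  expect_true(all(pred$diagnosis == "negative"))
  expect_true(all(pred$boundary))

  low <- fit
  low$params <- detector_params(-10, rep(0, 30))
  expect_equal(predict(low, f)$probability, rep(plogis(-10), 2))
  expect_true(all(predict(low, f)$diagnosis == "negative"))
})

test_that("tidy and glance summarize fits in broom style", {
  f <- encode_cohort(tiny_cohort(1, 1, n_cdr3 = 3), k = 6)
  fit <- fit_detector(f, tiny_config())
  td <- tidy(fit)
  expect_equal(nrow(td), 31)
  expect_equal(td$term[1], "b0")
  expect_equal(td$estimate[-1], unname(fit$params$W))
  gl <- glance(fit)
  expect_equal(gl$n_restarts, 4)
  expect_equal(gl$train_nll, fit$train_nll)
})

test_that("serialized models round-trip and refuse table mismatches", {
  f <- encode_cohort(tiny_cohort(2, 2, n_cdr3 = 4), k = 6)
  fit <- fit_detector(f, tiny_config())
  path <- tempfile(fileext = ".json")
  write_detector(fit, path)
  back <- read_detector(path)
  expect_equal(back$params$b0, fit$params$b0)
  expect_equal(back$params$W, fit$params$W)
  expect_equal(predict(back, f), predict(fit, f))

  tampered <- jsonlite::read_json(path, simplifyVector = TRUE)
  tampered$atchley_table_checksum <- "0000000000"
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(tampered, path2, auto_unbox = TRUE, digits = NA)
  expect_error(read_detector(path2), "checksum")
})

test_that("early stopping returns the best held-out-iteration parameters", {
  f <- encode_cohort(tiny_cohort(3, 3, n_cdr3 = 4), k = 6)
  cfg <- fit_config(n_restarts = 2, n_iterations = 80, seed = 3,
                    early_stopping = list(fraction = 0.34, patience = 10))
  fit <- fit_detector(f, cfg)
  expect_s3_class(fit, "snippet_fit")
  expect_true(is.finite(fit$train_nll))
})

test_that("bagging averages member probabilities within their range", {
  f <- encode_cohort(tiny_cohort(3, 3, n_cdr3 = 4), k = 6)
  bag <- bagged_fit(f, fit_config(n_restarts = 2, n_iterations = 100,
                                  seed = 4, bagging = 3))
  expect_length(bag$fits, 3)
  pb <- predict(bag, f)
  member <- vapply(bag$fits, function(m) predict(m, f)$probability,
                   numeric(length(f$patient_ids)))
  expect_true(all(pb$probability >= apply(member, 1, min) - 1e-12))
  expect_true(all(pb$probability <= apply(member, 1, max) + 1e-12))

  solo <- bagged_fit(f, fit_config(n_restarts = 2, n_iterations = 100,
                                   seed = 4, bagging = 1))
  plain <- fit_detector(f, fit_config(n_restarts = 2, n_iterations = 100,
                                      seed = 4))
  expect_equal(predict(solo, f)$probability, predict(plain, f)$probability)
})
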