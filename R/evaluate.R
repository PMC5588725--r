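# Exhaustive leave-one-out cross-validation, model selection over
# representation grids, label-permutation significance, and ROC/AUC.

#' Exhaustive leave-one-out cross-validation
#'
#' For each patient, fits the detector on all other patients (fresh random
#' restarts, fold-specific derived seeds) and predicts the held-out
#' patient. The held-out patient never influences fitting.
#'
#' @param features A labeled `snippet_features` with at least two patients
#'   per label (so every training fold retains both classes).
#' @param config A [fit_config()].
#' @return A `snippet_cv` object with a `per_fold` tibble
#'   (`held_out`, `probability`, `predicted`, `true`, `correct`),
#'   `n_correct`, and `accuracy`.
#' @export
loocv <- function(features, config = fit_config()) {
  stopifnot(inherits(features, "snippet_features"))
  y <- unname(features$labels)
  if (is.null(y)) abort("`features` must carry labels.")
  P <- length(features$patient_ids)
  folds <- vector("list", P)
  for (i in seq_len(P)) {
    train_idx <- setdiff(seq_len(P), i)
    if (length(unique(y[train_idx])) < 2) {
      abort(paste0("Fold holding out '", features$patient_ids[i],
                   "' would leave a single-label training set."))
    }
    fit <- fit_detector(subset_features(features, train_idx), config,
                        fold = i)
    pred <- predict(fit, subset_features(features, i))
    folds[[i]] <- tibble(
      held_out = features$patient_ids[i],
      probability = pred$probability,
      predicted = as.integer(pred$probability > 0.5),
      true = y[i]
    )
  }
  per_fold <- dplyr::bind_rows(folds) |>
    dplyr::mutate(correct = .data$predicted == .data$true)
  structure(list(
    per_fold = per_fold,
    n_correct = sum(per_fold$correct),
    n_total = P,
    accuracy = sum(per_fold$correct) / P,
    config = config
  ), class = "snippet_cv")
}

#' @export
print.snippet_cv <- function(x, ...) {
  cat("<snippet_cv> leave-one-out cross-validation: ",
      x$n_correct, "/", x$n_total, " correct (",
      sprintf("%.1f%%", 100 * x$accuracy), ")\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy snippet_cv
tidy.snippet_cv <- function(x, ...) x$per_fold

#' @export
#' @method glance snippet_cv
glance.snippet_cv <- function(x, ...) {
  tibble(n_correct = x$n_correct, n_total = x$n_total,
         accuracy = x$accuracy)
}

#' Default model-selection grid
#'
#' The seven candidate representations compared in the original analysis:
#' snippet lengths 4-7 in amino acids under the Atchley encoding, 2 and 6
#' DNA triplets (6 and 18 nt) one-hot, and 6 amino acids one-hot.
#'
#' @return A tibble with columns `k`, `unit`, `scheme`.
#' @export
default_grid <- function() {
  tibble(
    k = c(4L, 5L, 6L, 7L, 6L, 18L, 6L),
    unit = c(rep("amino_acid", 4), "nucleotide", "nucleotide", "amino_acid"),
    scheme = c(rep("atchley", 4), "nt_onehot", "nt_onehot", "aa_onehot")
  )
}

#' Model selection by cross-validated accuracy over a representation grid
#'
#' Runs [loocv()] for every candidate (k, unit, scheme) and declares the
#' winner by maximum accuracy; ties break toward fewer features (then
#' smaller k, then scheme name) so the winner is invariant to grid row
#' order. Candidates infeasible for the data (e.g. every CDR3 shorter than
#' k, or no nucleotide sequences) are kept in the table flagged
#' `feasible = FALSE`, never silently dropped. Each candidate is evaluated
#' on its own feasible snippet set: patients are never dropped, CDR3s
#' shorter than k are simply skipped.
#'
#' @param cohort A labeled cohort tibble.
#' @param grid Candidate tibble as from [default_grid()].
#' @param config A [fit_config()].
#' @return A `model_selection` object: `table` (one row per candidate with
#'   `cv_accuracy`, `n_correct`, `n_total`) and `winner` (a one-row tibble).
#' @export
select_model <- function(cohort, grid = default_grid(),
                         config = fit_config()) {
  assert_cohort(cohort, need_label = TRUE)
  if (nrow(grid) == 0) abort("Candidate grid is empty.")
  rows <- purrr::pmap(grid, function(k, unit, scheme) {
    res <- tryCatch({
      feats <- encode_cohort(cohort, k = k, scheme = scheme)
      cv <- loocv(feats, config)
      tibble(k = as.integer(k), unit = unit, scheme = scheme,
             n_features = feats$n_features,
             n_correct = cv$n_correct, n_total = cv$n_total,
             cv_accuracy = cv$accuracy, feasible = TRUE)
    }, error = function(e) {
      tibble(k = as.integer(k), unit = unit, scheme = scheme,
             n_features = as.integer(k) * features_per_position(scheme),
             n_correct = NA_integer_, n_total = NA_integer_,
             cv_accuracy = NA_real_, feasible = FALSE)
    })
    res
  })
  rank_candidates(dplyr::bind_rows(rows), config)
}

#' Rank evaluated candidates and declare a winner
#'
#' The deterministic selection rule behind [select_model()], exposed so the
#' ranking is testable and reusable on precomputed tables: sort by
#' descending cross-validated accuracy, break ties toward fewer features,
#' then smaller k, then scheme name. Row order of the input never affects
#' the winner.
#'
#' @param table A tibble with columns `k`, `unit`, `scheme`, `n_features`,
#'   `n_correct`, `n_total`, `cv_accuracy`, `feasible`.
#' @param config The [fit_config()] used (stored for provenance; optional).
#' @return A `model_selection` object.
#' @export
rank_candidates <- function(table, config = NULL) {
  table <- dplyr::arrange(table,
                          dplyr::desc(.data$cv_accuracy), .data$n_features,
                          .data$k, .data$scheme)
  feas <- dplyr::filter(table, .data$feasible)
  if (nrow(feas) == 0) abort("No feasible candidate in the grid.")
  winner <- feas[1, ]
  tied <- sum(feas$cv_accuracy == winner$cv_accuracy, na.rm = TRUE)
  structure(list(table = table, winner = winner, tie_broken = tied > 1,
                 config = config),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> winner: k = ", x$winner$k, ", ", x$winner$scheme,
      " (", x$winner$n_correct, "/", x$winner$n_total, " = ",
      sprintf("%.1f%%", 100 * x$winner$cv_accuracy), ")",
      if (x$tie_broken) " [tie broken toward fewer features]", "\n",
      sep = "")
  print(x$table)
  invisible(x)
}

#' @export
#' @method tidy model_selection
tidy.model_selection <- function(x, ...) x$table

#' Refit the winning representation on the full cohort
#'
#' The deployable model: a plain [fit_detector()] on every patient under
#' the selected (k, scheme).
#'
#' @param cohort A labeled cohort tibble.
#' @param winner A one-row tibble (or list) with `k` and `scheme`, e.g.
#'   `select_model(...)$winner`.
#' @param config A [fit_config()].
#' @return A `snippet_fit`.
#' @export
refit_full <- function(cohort, winner, config = fit_config()) {
  feats <- encode_cohort(cohort, k = winner$k, scheme = winner$scheme)
  fit_detector(feats, config, fold = 0L)
}

#' Add-one permutation p-value
#'
#' `(1 + #permutations with n_correct >= observed) / (1 + n_permutations)`.
#' When the observed accuracy beats all of 20 permutations this gives
#' 1/21 (about 0.048), i.e. p < 0.05.
#'
#' @param observed_n_correct Observed fold-correct count.
#' @param permuted_n_correct Integer vector of permuted counts.
#' @return The p-value, in (0, 1].
#' @export
permutation_pvalue <- function(observed_n_correct, permuted_n_correct) {
  if (length(permuted_n_correct) < 1) {
    abort("At least one permutation is required.")
  }
  (1 + sum(permuted_n_correct >= observed_n_correct)) /
    (1 + length(permuted_n_correct))
}

#' Label-permutation significance of cross-validated accuracy
#'
#' Estimates how often the observed LOOCV accuracy would arise by chance:
#' each permutation shuffles the patient labels uniformly (label counts
#' preserved) and repeats the *entire* LOOCV procedure under the permuted
#' labels. The p-value uses the add-one rule ([permutation_pvalue()]).
#'
#' @param features A labeled `snippet_features`.
#' @param config A [fit_config()].
#' @param n_permutations Number of label permutations (default 20).
#' @param perm_seed Seed for the permutation stream (defaults to
#'   `config$seed`).
#' @param observed Optionally, a precomputed `snippet_cv` for the observed
#'   labels (to avoid recomputation).
#' @return A `snippet_permutation` object with `observed_n_correct`,
#'   `permuted_n_correct`, `p_value`, and `mean_permuted_accuracy`.
#' @export
permutation_test <- function(features, config = fit_config(),
                             n_permutations = 20L,
                             perm_seed = config$seed,
                             observed = NULL) {
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  y <- unname(features$labels)
  if (is.null(observed)) observed <- loocv(features, config)
  P <- length(features$patient_ids)
  permuted <- integer(n_permutations)
  for (j in seq_len(n_permutations)) {
    set.seed(derive_seed(perm_seed, 5000L, j))
    yp <- y[sample.int(P)]
    fp <- features
    fp$labels <- setNames(yp, features$patient_ids)
    cfg <- config
    cfg$seed <- derive_seed(perm_seed, 6000L, j)
    permuted[j] <- loocv(fp, cfg)$n_correct
  }
  structure(list(
    observed_n_correct = observed$n_correct,
    n_total = observed$n_total,
    permuted_n_correct = permuted,
    p_value = permutation_pvalue(observed$n_correct, permuted),
    mean_permuted_accuracy = mean(permuted / observed$n_total)
  ), class = "snippet_permutation")
}

#' @export
print.snippet_permutation <- function(x, ...) {
  cat("<snippet_permutation> observed ", x$observed_n_correct, "/",
      x$n_total, "; mean permuted accuracy ",
      sprintf("%.1f%%", 100 * x$mean_permuted_accuracy),
      "; p = ", format(x$p_value, digits = 4), " (add-one, ",
      length(x$permuted_n_correct), " permutations)\n", sep = "")
  invisible(x)
}

#' @export
#' @method glance snippet_permutation
glance.snippet_permutation <- function(x, ...) {
  tibble(observed_n_correct = x$observed_n_correct,
         n_total = x$n_total,
         mean_permuted_accuracy = x$mean_permuted_accuracy,
         p_value = x$p_value,
         n_permutations = length(x$permuted_n_correct))
}

#' ROC curve and AUC for repertoire probabilities
#'
#' Sweeps thresholds over the unique predicted probabilities (ties step
#' simultaneously) and integrates the (FPR, TPR) staircase by the
#' trapezoid rule. Equivalent to the normalized Mann-Whitney U statistic.
#'
#' @param probabilities Predicted probabilities, one per patient.
#' @param labels 0/1 truth, one per patient (both classes required).
#' @return A `snippet_roc` object: `points` tibble (`threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("ROC requires both positive and negative labels.")
  }
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]
  y <- labels[ord]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(p, fromLast = TRUE)  # collapse probability ties
  points <- tibble(
    threshold = c(Inf, p[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) +
                                   points$tpr[-1]) / 2)
  structure(list(points = points, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "snippet_roc")
}

#' @export
print.snippet_roc <- function(x, ...) {
  cat("<snippet_roc> ", x$n_pos, " positives / ", x$n_neg,
      " negatives; AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy snippet_roc
tidy.snippet_roc <- function(x, ...) x$points

#' @export
#' @method glance snippet_roc
glance.snippet_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
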