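# Maximum-likelihood fitting with random restarts, prediction, and model
# serialization.

#' Fit the max-snippet detector by maximum likelihood
#'
#' Runs `n_restarts` independent Adam optimizations (batched in compiled
#' code), each from bias 0 and weights drawn N(0, 1/n_features), and keeps
#' the restart with the lowest final *unpenalized* training negative
#' log-likelihood — likelihood is the selection criterion even when L1/L2
#' penalties shape the search. Restart r of fold `fold` draws its
#' initialization from a seed derived only from `(config$seed, fold, r)`,
#' so results do not depend on execution order or parallelism.
#'
#' @param features A `snippet_features` object with 0/1 labels for every
#'   patient (both classes present).
#' @param config A [fit_config()].
#' @param fold Internal stream label used by [loocv()] so each fold has
#'   independent restarts; leave at 0 for a plain fit.
#' @return A `snippet_fit` object: `params` ([detector_params()]),
#'   `train_nll`, a `per_restart` tibble (restart, seed, initial and final
#'   NLL, convergence flag), and the encoding metadata needed to apply the
#'   model.
#' @export
fit_detector <- function(features, config = fit_config(), fold = 0L) {
  stopifnot(inherits(features, "snippet_features"))
  y <- unname(features$labels)
  if (is.null(y)) abort("`features` must carry labels to fit.")
  if (length(unique(y)) < 2) {
    abort("Fitting requires both labels (cases and controls) present.")
  }
  if (!is.null(config$early_stopping)) {
    return(fit_early_stopping(features, config, fold))
  }
  nf <- features$n_features
  W0 <- initial_weights(nf, config, fold)
  codes <- features$codes
  res <- .fit_restarts_cpp(features$X, features$patient_index, y, W0,
                           config$n_iterations, config$step_size,
                           config$beta1, config$beta2, config$epsilon,
                           config$l1, config$l2,
                           identical(config$precision, "single"),
                           if (is.null(codes)) matrix(0L, 0, 0)
                           else codes - 1L,
                           features$codebook %||% matrix(0, 0, 0))
  res$nll_final <- as.numeric(res$nll_final)
  res$nll_init <- as.numeric(res$nll_init)
  finite <- is.finite(res$nll_final)
  if (!any(finite)) {
    abort(paste0("All ", config$n_restarts, " restarts diverged to a ",
                 "non-finite likelihood; inspect the feature scale."))
  }
  best <- which(res$nll_final == min(res$nll_final[finite]) & finite)[1]
  per_restart <- tibble(
    restart = seq_len(config$n_restarts),
    seed = vapply(seq_len(config$n_restarts),
                  function(r) derive_seed(config$seed, fold, r), integer(1)),
    init_nll = res$nll_init,
    final_nll = res$nll_final,
    converged = finite
  )
  new_snippet_fit(
    params = detector_params(res$b0[best], res$W[, best]),
    train_nll = res$nll_final[best],
    per_restart = per_restart, best_restart = best,
    config = config, features = features, fold = fold
  )
}

# Early-stopping path: per restart, a plain R Adam loop that tracks the
# held-out patients' NLL and returns the best-held-out-iteration
# parameters, halting after `patience` non-improving iterations.
fit_early_stopping <- function(features, config, fold = 0L) {
  es <- config$early_stopping
  y <- unname(features$labels)
  P <- length(features$patient_ids)
  n_val <- max(1L, floor(es$fraction * P))
  set.seed(derive_seed(config$seed, fold, 777L))
  repeat {
    val <- sort(sample.int(P, n_val))
    if (length(unique(y[-val])) == 2) break
  }
  train_f <- subset_features(features, setdiff(seq_len(P), val))
  val_f <- subset_features(features, val)
  nf <- features$n_features
  W0 <- initial_weights(nf, config, fold)
  rows <- vector("list", config$n_restarts)
  best_nll <- Inf
  best_params <- NULL
  best_restart <- NA_integer_
  for (r in seq_len(config$n_restarts)) {
    st <- adam_init(detector_params(0, W0[, r]))
    best_val <- Inf
    best_p <- st$params
    stall <- 0L
    init_nll <- negative_log_likelihood(st$params, train_f)
    for (it in seq_len(config$n_iterations)) {
      g <- nll_gradient(st$params, train_f, l1 = config$l1, l2 = config$l2)
      st <- adam_step(st, g, config)
      vnll <- negative_log_likelihood(st$params, val_f)
      if (vnll < best_val - 1e-12) {
        best_val <- vnll
        best_p <- st$params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= es$patience) break
      }
    }
    fnll <- negative_log_likelihood(best_p, train_f)
    rows[[r]] <- tibble(restart = r,
                        seed = derive_seed(config$seed, fold, r),
                        init_nll = init_nll, final_nll = fnll,
                        converged = is.finite(fnll))
    if (is.finite(fnll) && fnll < best_nll) {
      best_nll <- fnll
      best_params <- best_p
      best_restart <- r
    }
  }
  if (is.null(best_params)) abort("All restarts diverged.")
  new_snippet_fit(params = best_params, train_nll = best_nll,
                  per_restart = dplyr::bind_rows(rows),
                  best_restart = best_restart,
                  config = config, features = features, fold = fold)
}

new_snippet_fit <- function(params, train_nll, per_restart, best_restart,
                            config, features, fold = 0L) {
  structure(list(
    params = params,
    train_nll = as.numeric(train_nll),
    per_restart = per_restart,
    best_restart = best_restart,
    config = config,
    k = features$k, unit = features$unit, scheme = features$scheme,
    n_features = features$n_features,
    feature_names = colnames(features$X),
    n_patients = length(features$patient_ids),
    atchley_checksum = if (features$scheme == "atchley") atchley_checksum()
                       else NA_character_,
    fold = fold
  ), class = "snippet_fit")
}

#' @export
print.snippet_fit <- function(x, ...) {
  cat("<snippet_fit> max-snippet logistic detector\n",
      "  encoding: ", x$scheme, ", k = ", x$k, " (", x$n_features,
      " features)\n",
      "  restarts: ", nrow(x$per_restart), "; best train NLL = ",
      format(x$train_nll, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Predict repertoire diagnoses with a fitted detector
#'
#' Scores every snippet of every patient and takes the per-patient maximum
#' as the diagnosis probability. A probability strictly above 0.5 is a
#' positive diagnosis; exactly 0.5 maps to negative and is flagged in the
#' `boundary` column. The argmax snippet (first index on ties) is reported
#' with its source CDR3 index and offset when bookkeeping is available.
#'
#' @param object A `snippet_fit`.
#' @param features A `snippet_features` object encoded under the same
#'   scheme and k as the fit.
#' @param ... Unused.
#' @return A tibble with one row per patient: `patient_id`, `probability`,
#'   `diagnosis` (`"positive"`/`"negative"`), `boundary`, `argmax_row`, and
#'   snippet provenance columns when available.
#' @export
predict.snippet_fit <- function(object, features, ...) {
  stopifnot(inherits(features, "snippet_features"))
  if (features$n_features != object$n_features ||
      !identical(features$scheme, object$scheme) ||
      !identical(features$k, object$k)) {
    abort(sprintf(
      "Encoding mismatch: model is %s/k=%d (%d features), data is %s/k=%d (%d features).",
      object$scheme, object$k, object$n_features,
      features$scheme, features$k, features$n_features))
  }
  if (nrow(features$X) == 0) abort("No snippets to score.")
  ml <- max_logits(features, object$params)
  prob <- plogis(ml$m)
  out <- tibble(
    patient_id = features$patient_ids,
    probability = unname(prob),
    diagnosis = ifelse(prob > 0.5, "positive", "negative"),
    boundary = prob == 0.5,
    argmax_row = unname(ml$row)
  )
  if (!is.null(features$snippets)) {
    sn <- features$snippets[ml$row, c("snippet", "cdr3_index", "offset")]
    out <- dplyr::bind_cols(out, sn)
  }
  out
}

#' @export
#' @method tidy snippet_fit
tidy.snippet_fit <- function(x, ...) {
  terms <- x$feature_names %||% paste0("w", seq_along(x$params$W))
  tibble(term = c("b0", terms),
         estimate = c(x$params$b0, x$params$W))
}

#' @export
#' @method glance snippet_fit
glance.snippet_fit <- function(x, ...) {
  tibble(
    train_nll = x$train_nll,
    n_restarts = nrow(x$per_restart),
    n_converged = sum(x$per_restart$converged),
    best_restart = x$best_restart,
    n_iterations = x$config$n_iterations,
    n_features = x$n_features,
    k = x$k,
    scheme = x$scheme,
    n_patients = x$n_patients
  )
}

# subset a snippet_features by patient positions (repeats allowed, as in
# bootstrap resampling); repeated patients get disambiguated ids
subset_features <- function(features, idx) {
  stopifnot(inherits(features, "snippet_features"))
  ids <- features$patient_ids[idx]
  new_ids <- make.unique(ids, sep = "#")
  row_list <- split(seq_len(nrow(features$X)),
                    factor(features$patient_index,
                           levels = seq_along(features$patient_ids)))
  rows <- unlist(row_list[idx], use.names = FALSE)
  pidx <- rep(seq_along(idx), vapply(row_list[idx], length, integer(1)))
  snippets <- NULL
  if (!is.null(features$snippets) && !anyDuplicated(ids)) {
    snippets <- features$snippets[rows, , drop = FALSE]
    snippets$patient_id <- new_ids[pidx]
  }
  new_snippet_features(
    X = features$X[rows, , drop = FALSE],
    patient_index = pidx,
    patient_ids = new_ids,
    labels = if (!is.null(features$labels))
      setNames(unname(features$labels)[idx], new_ids),
    snippets = snippets,
    k = features$k, unit = features$unit, scheme = features$scheme,
    codes = if (!is.null(features$codes))
      features$codes[rows, , drop = FALSE],
    codebook = features$codebook
  )
}

#' Serialize a fitted detector to JSON
#'
#' The file records the encoding (scheme, k, unit), the ordered weights and
#' bias, the fit configuration, the training NLL, and a checksum of the
#' embedded Atchley table; [read_detector()] refuses to load a model whose
#' checksum does not match the running package's table.
#'
#' @param fit A `snippet_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detector <- function(fit, path) {
  stopifnot(inherits(fit, "snippet_fit"))
  cfg <- fit$config
  cfg$early_stopping <- cfg$early_stopping %||% NA
  cfg$bagging <- cfg$bagging %||% NA
  obj <- list(
    model = "max_snippet_logistic",
    scheme = fit$scheme, k = fit$k, unit = fit$unit,
    b0 = fit$params$b0,
    W = setNames(as.list(fit$params$W),
                 fit$feature_names %||% paste0("w", seq_along(fit$params$W))),
    atchley_table_checksum = fit$atchley_checksum,
    fit_config = unclass(cfg),
    train_nll = fit$train_nll
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized detector
#'
#' @param path JSON path written by [write_detector()].
#' @return A `snippet_fit` (without per-restart diagnostics).
#' @export
read_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$scheme, "atchley") &&
      !identical(obj$atchley_table_checksum, atchley_checksum())) {
    abort(paste0("Atchley table checksum mismatch: model was fit under a ",
                 "different encoding table; refusing to load."))
  }
  cfg_in <- obj$fit_config
  cfg <- fit_config(
    n_restarts = cfg_in$n_restarts, n_iterations = cfg_in$n_iterations,
    step_size = cfg_in$step_size, beta1 = cfg_in$beta1, beta2 = cfg_in$beta2,
    epsilon = cfg_in$epsilon, seed = cfg_in$seed,
    l1 = cfg_in$l1, l2 = cfg_in$l2, init_scale = cfg_in$init_scale,
    precision = cfg_in$precision %||% "single"
  )
  structure(list(
    params = detector_params(obj$b0, as.numeric(unlist(obj$W))),
    train_nll = obj$train_nll,
    per_restart = NULL, best_restart = NA_integer_,
    config = cfg,
    k = as.integer(obj$k), unit = obj$unit, scheme = obj$scheme,
    n_features = length(obj$W),
    feature_names = names(obj$W),
    n_patients = NA_integer_,
    atchley_checksum = obj$atchley_table_checksum,
    fold = 0L
  ), class = "snippet_fit")
}

#' Fit a bagged ensemble of detectors
#'
#' Each member is fit on a bootstrap resample of patients (with
#' replacement, same cohort size); a resample missing one label is redrawn
#' (bounded retries). The ensemble predicts the mean of member
#' probabilities.
#'
#' @param features A labeled `snippet_features`.
#' @param config A [fit_config()] with `bagging >= 2` (set `bagging = 1`
#'   to recover a plain fit on the original cohort).
#' @return A `snippet_bag` with elements `fits` (list of `snippet_fit`)
#'   and `config`.
#' @export
bagged_fit <- function(features, config = fit_config(bagging = 10)) {
  n_bags <- config$bagging %||% abort("`config$bagging` must be set.")
  stopifnot(n_bags >= 1)
  y <- unname(features$labels)
  P <- length(features$patient_ids)
  fits <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    if (n_bags == 1) {
      fits[[b]] <- fit_detector(features, strip_bagging(config), fold = 0L)
      break
    }
    set.seed(derive_seed(config$seed, 31L, b))
    ok <- FALSE
    for (try in 1:100) {
      idx <- sample.int(P, P, replace = TRUE)
      if (length(unique(y[idx])) == 2) { ok <- TRUE; break }
    }
    if (!ok) abort("Could not draw a bootstrap sample with both labels.")
    fits[[b]] <- fit_detector(subset_features(features, idx),
                              strip_bagging(config), fold = 1000L + b)
  }
  structure(list(fits = fits, config = config), class = "snippet_bag")
}

strip_bagging <- function(config) { config$bagging <- NULL; config }

#' @export
#' @rdname bagged_fit
#' @param object A `snippet_bag`.
#' @param ... Unused.
predict.snippet_bag <- function(object, features, ...) {
  member <- lapply(object$fits, predict, features = features)
  prob <- rowMeans(vapply(member, function(m) m$probability,
                          numeric(length(features$patient_ids))))
  tibble(
    patient_id = features$patient_ids,
    probability = prob,
    diagnosis = ifelse(prob > 0.5, "positive", "negative"),
    boundary = prob == 0.5
  )
}
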