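# Post-fit interpretation: weight maps over (position, factor), top
# snippets per patient, score histograms, and codon encoding-degeneracy
# analysis of diagnostic vs non-diagnostic snippets.

#' Re-index detector weights as a (position, factor) map
#'
#' Under the position-major Atchley encoding, weight `(j - 1) * 5 + i`
#' belongs to factor i at snippet position j. The re-indexing is a
#' bijection: `weight_map()` and flattening back are lossless.
#'
#' @param fit A `snippet_fit` with `scheme == "atchley"` (or a
#'   [detector_params()] plus `k`).
#' @param k Snippet length (taken from the fit when omitted).
#' @return A tibble with columns `position` (1..k), `factor`
#'   (`"I"`..`"V"`), and `weight`; the bias is in attribute `"b0"`.
#' @export
weight_map <- function(fit, k = NULL) {
  if (inherits(fit, "snippet_fit")) {
    if (!identical(fit$scheme, "atchley")) {
      abort("`weight_map()` is defined for the Atchley encoding only.")
    }
    k <- fit$k
    params <- fit$params
  } else {
    stopifnot(inherits(fit, "detector_params"), !is.null(k))
    params <- fit
  }
  stopifnot(length(params$W) == 5 * k)
  out <- tibble(
    position = rep(seq_len(k), each = 5L),
    factor = factor(rep(c("I", "II", "III", "IV", "V"), k),
                    levels = c("I", "II", "III", "IV", "V")),
    weight = params$W
  )
  attr(out, "b0") <- params$b0
  class(out) <- c("weight_map", class(out))
  out
}

#' Flatten a weight map back to the ordered weight vector
#' @param wm A tibble from [weight_map()].
#' @return Numeric weight vector in position-major order.
#' @export
flatten_weight_map <- function(wm) {
  wm <- dplyr::arrange(wm, .data$position, .data$factor)
  wm$weight
}

#' Highest-scoring snippet per patient
#'
#' Reports, for every patient, the argmax snippet (first index on ties),
#' its offset within its source CDR3, its score — by construction equal to
#' the patient's diagnosis probability — and, for Atchley-encoded models,
#' its per-position factor values in long format.
#'
#' @param fit A `snippet_fit`.
#' @param features A `snippet_features` with snippet bookkeeping.
#' @param cohort Optional cohort tibble; when given, the full source CDR3
#'   string is included.
#' @return A tibble, one row per patient, with an `atchley` list-column of
#'   per-residue factor values for Atchley models.
#' @export
top_snippets <- function(fit, features, cohort = NULL) {
  pred <- predict(fit, features)
  if (!"snippet" %in% names(pred)) {
    abort("`features` has no snippet bookkeeping; use encode_cohort().")
  }
  out <- pred |>
    dplyr::rename(score = "probability") |>
    dplyr::select("patient_id", "cdr3_index", "offset", "snippet", "score",
                  "diagnosis")
  if (identical(fit$scheme, "atchley")) {
    tab <- atchley_table(as_matrix = TRUE)
    out$atchley <- lapply(out$snippet, function(s) {
      aa <- strsplit(s, "")[[1]]
      tibble::as_tibble(tab[aa, , drop = FALSE]) |>
        dplyr::mutate(position = dplyr::row_number(), residue = aa,
                      .before = 1)
    })
  }
  if (!is.null(cohort)) {
    src <- cohort |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(cdr3_index = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "cdr3_index", "cdr3_aa")
    out <- dplyr::left_join(out, src, by = c("patient_id", "cdr3_index"))
  }
  out
}

#' Snippet score histograms by diagnosis group
#'
#' Scores every snippet in the cohort under the fitted detector and bins
#' the scores separately for case and control patients; also counts, per
#' patient, the snippets above the diagnostic threshold. Bin totals
#' conserve snippet totals exactly.
#'
#' @param fit A `snippet_fit`.
#' @param features A labeled `snippet_features`.
#' @param threshold Diagnostic score threshold (default 0.5).
#' @param breaks Histogram bin edges covering the unit interval.
#' @return A `score_histogram` object: `bins` tibble (`group`, `bin_low`,
#'   `bin_high`, `n`), `above_threshold` per-patient tibble, `threshold`.
#' @export
score_histogram <- function(fit, features, threshold = 0.5,
                            breaks = seq(0, 1, by = 0.05)) {
  y <- unname(features$labels)
  if (is.null(y)) abort("`features` must carry labels.")
  scores <- snippet_score(snippet_logit(features$X, fit$params))
  group <- ifelse(y[features$patient_index] == 1, "case", "control")
  cut_idx <- cut(scores, breaks = breaks, include.lowest = TRUE)
  bins <- tibble(group = group, bin = cut_idx) |>
    dplyr::count(.data$group, .data$bin, .drop = FALSE) |>
    dplyr::mutate(bin_low = breaks[as.integer(.data$bin)],
                  bin_high = breaks[as.integer(.data$bin) + 1L]) |>
    dplyr::select("group", "bin_low", "bin_high", "n")
  above <- tibble(
    patient_id = features$patient_ids[features$patient_index],
    above = scores > threshold
  ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_above = sum(.data$above), .groups = "drop")
  structure(list(bins = bins, above_threshold = above,
                 threshold = threshold,
                 n_snippets = length(scores)),
            class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  n_above <- sum(x$above_threshold$n_above)
  cat("<score_histogram> ", x$n_snippets, " snippets; ", n_above,
      " above threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Number of distinct DNA encodings of an amino-acid string
#'
#' The product over residues of the standard genetic code's codon
#' multiplicity (Met and Trp have 1 codon; Leu, Ser and Arg have 6), i.e.
#' the number of distinct DNA spellings of the peptide.
#'
#' @param snippet_aa Character vector of amino-acid strings (standard
#'   residues only).
#' @return Numeric vector of encoding counts (>= 1; at most `6^nchar`).
#' @examples
#' encoding_count(c("MW", "LLLLLL"))  # 1 and 6^6 = 46656
#' @export
encoding_count <- function(snippet_aa) {
  codons <- table(Biostrings::GENETIC_CODE)  # residue -> codon multiplicity
  vapply(toupper(snippet_aa), function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- !aa %in% names(codons) | aa == "*"
    if (any(bad)) {
      abort(paste0("Nonstandard residue '", aa[bad][1], "' in '", s, "'."))
    }
    prod(as.numeric(codons[aa]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Encoding degeneracy of diagnostic vs non-diagnostic snippets
#'
#' Scores every snippet under the fitted detector, labels those above the
#' threshold "diagnostic", and computes each snippet's encoding count. By
#' default each distinct snippet string is counted once per group.
#'
#' @param fit A `snippet_fit` on amino-acid snippets.
#' @param features A `snippet_features` with snippet bookkeeping.
#' @param threshold Diagnostic score threshold (default 0.5).
#' @param unique_snippets Count each distinct snippet once per group
#'   (default `TRUE`); `FALSE` weights by occurrence.
#' @return A tibble with columns `snippet`, `score`, `group`, `encodings`.
#' @export
snippet_degeneracy <- function(fit, features, threshold = 0.5,
                               unique_snippets = TRUE) {
  if (features$unit != "amino_acid") {
    abort("Degeneracy analysis needs amino-acid snippets.")
  }
  scores <- snippet_score(snippet_logit(features$X, fit$params))
  out <- tibble(
    snippet = features$snippets$snippet,
    score = scores,
    group = ifelse(scores > threshold, "diagnostic", "non_diagnostic")
  )
  if (unique_snippets) {
    out <- out |>
      dplyr::group_by(.data$snippet, .data$group) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  out$encodings <- encoding_count(out$snippet)
  out
}

#' Compare encoding degeneracy between snippet groups
#'
#' Two-sided rank-based comparison (Mann-Whitney U via
#' [stats::wilcox.test()], normal approximation with tie correction) of
#' encoding counts between diagnostic and non-diagnostic snippets;
#' encoding counts are discrete and heavily skewed, so a rank test is the
#' default. A Welch t-test alternative is available.
#'
#' @param diagnostic,non_diagnostic Numeric vectors of encoding counts, or
#'   pass a tibble from [snippet_degeneracy()] as the first argument.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return A tibble with the statistic, `p_value`, group medians, and the
#'   direction of the shift.
#' @export
degeneracy_comparison <- function(diagnostic, non_diagnostic = NULL,
                                  test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  if (is.data.frame(diagnostic)) {
    df <- diagnostic
    diagnostic <- df$encodings[df$group == "diagnostic"]
    non_diagnostic <- df$encodings[df$group == "non_diagnostic"]
  }
  if (length(diagnostic) == 0 || length(non_diagnostic) == 0) {
    abort("Both snippet groups must be nonempty.")
  }
  if (test == "wilcoxon") {
    ht <- suppressWarnings(
      wilcox.test(diagnostic, non_diagnostic, exact = FALSE, correct = TRUE))
    stat <- unname(ht$statistic)
  } else {
    ht <- t.test(diagnostic, non_diagnostic)
    stat <- unname(ht$statistic)
  }
  tibble(
    test = test,
    statistic = stat,
    p_value = ht$p.value,
    median_diagnostic = stats::median(diagnostic),
    median_non_diagnostic = stats::median(non_diagnostic),
    direction = dplyr::case_when(
      stats::median(diagnostic) < stats::median(non_diagnostic) ~
        "diagnostic_fewer",
      stats::median(diagnostic) > stats::median(non_diagnostic) ~
        "diagnostic_more",
      TRUE ~ "none"
    ),
    n_diagnostic = length(diagnostic),
    n_non_diagnostic = length(non_diagnostic)
  )
}
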