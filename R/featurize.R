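# Cutting CDR3s into overlapping k-mer snippets and encoding snippets as
# numeric feature vectors. Three representations are supported: the five
# Atchley factors per residue (the biochemical encoding), amino-acid
# one-hot, and nucleotide one-hot.

#' Extract overlapping k-mer snippets from a cohort
#'
#' Each CDR3 of length L >= k contributes exactly L - k + 1 snippets, one at
#' every offset (step 1). Shorter CDR3s contribute none and are recorded in
#' the `"skipped"` attribute. Snippets never span CDR3 boundaries.
#'
#' @param cohort A cohort tibble (`patient_id`, `cdr3_aa`, optionally
#'   `cdr3_nt`, ...).
#' @param k Snippet length, in residues or nucleotides. For
#'   `unit = "nucleotide"` it must be a positive multiple of 3 (whole
#'   codons).
#' @param unit `"amino_acid"` (cuts `cdr3_aa`) or `"nucleotide"` (cuts
#'   `cdr3_nt`, which must be present).
#' @return A tibble with columns `patient_id`, `cdr3_index` (1-based, within
#'   patient), `offset` (0-based start), and `snippet`; attributes `k`,
#'   `unit`, and `skipped` (tibble of too-short CDR3s).
#' @examples
#' cohort <- tibble::tibble(patient_id = "P1", label = 1L,
#'                          cdr3_aa = "CARDYWGQGT")
#' extract_snippets(cohort, k = 6)
#' @export
extract_snippets <- function(cohort, k, unit = c("amino_acid", "nucleotide")) {
  unit <- match.arg(unit)
  assert_cohort(cohort)
  if (length(k) != 1 || is.na(k) || k != as.integer(k) || k < 1) {
    abort("`k` must be a single positive integer.")
  }
  k <- as.integer(k)
  if (unit == "nucleotide") {
    if (!"cdr3_nt" %in% names(cohort)) {
      abort("`unit = \"nucleotide\"` requires a `cdr3_nt` column.")
    }
    if (k %% 3L != 0L) {
      abort("Nucleotide snippet length `k` must be a multiple of 3.")
    }
    seqs <- toupper(cohort$cdr3_nt)
  } else {
    seqs <- toupper(cohort$cdr3_aa)
  }
  by_patient <- split(seq_along(seqs), cohort$patient_id)
  pieces <- lapply(names(by_patient), function(pid) {
    idx <- by_patient[[pid]]
    s <- seqs[idx]
    L <- nchar(s)
    n_snip <- pmax(0L, L - k + 1L)
    cdr3_index <- rep(seq_along(s), n_snip)
    offset <- unlist(lapply(n_snip, function(n) seq_len(n) - 1L),
                     use.names = FALSE)
    if (length(offset) == 0) offset <- integer(0)
    tibble(
      patient_id = pid,
      cdr3_index = as.integer(cdr3_index),
      offset = as.integer(offset),
      snippet = substring(rep(s, n_snip), offset + 1L, offset + k)
    )
  })
  out <- dplyr::bind_rows(pieces)
  skipped <- tibble(
    patient_id = cohort$patient_id[nchar(seqs) < k],
    length = nchar(seqs)[nchar(seqs) < k]
  )
  attr(out, "k") <- k
  attr(out, "unit") <- unit
  attr(out, "skipped") <- skipped
  out
}

#' Encode snippets as numeric feature vectors
#'
#' Encodes each snippet string into a fixed-length numeric vector. Ordering
#' is position-major: all features of position 1, then position 2, and so
#' on. Under `"atchley"` each residue contributes its five Atchley factors
#' (k residues -> 5k features; a 6-mer gives 30); `"aa_onehot"` gives k
#' blocks of 20 indicator features; `"nt_onehot"` k blocks of 4 (alphabet
#' order A, C, G, T).
#'
#' @param snippets Character vector of equal-length snippet strings.
#' @param scheme `"atchley"`, `"aa_onehot"`, or `"nt_onehot"`.
#' @return A numeric matrix, one row per snippet.
#' @examples
#' encode_snippets("CARDYW", "atchley")   # 1 x 30
#' @export
encode_snippets <- function(snippets,
                            scheme = c("atchley", "aa_onehot", "nt_onehot")) {
  scheme <- match.arg(scheme)
  if (length(snippets) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  snippets <- toupper(snippets)
  k <- unique(nchar(snippets))
  if (length(k) != 1) abort("All snippets must have the same length.")
  cm <- matrix(unlist(strsplit(snippets, "", fixed = TRUE), use.names = FALSE),
               nrow = length(snippets), ncol = k, byrow = TRUE)
  alphabet <- if (scheme == "nt_onehot") NT_ALPHABET else AA_ALPHABET
  bad <- !(cm %in% alphabet)
  if (any(bad)) {
    ij <- which(matrix(bad, nrow = nrow(cm)), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Cannot encode symbol '%s' at position %d of snippet '%s' under scheme '%s'.",
      cm[ij[1], ij[2]], ij[2], snippets[ij[1]], scheme))
  }
  codes <- matrix(match(cm, alphabet), nrow = nrow(cm), ncol = k)
  if (scheme == "atchley") {
    width <- 5L
    codebook <- unname(.atchley_values)
    out <- matrix(0, nrow = length(snippets), ncol = 5L * k)
    for (j in seq_len(k)) {
      out[, (j - 1L) * 5L + (1:5)] <- .atchley_values[cm[, j], , drop = FALSE]
    }
  } else {
    width <- length(alphabet)
    codebook <- diag(width)
    out <- matrix(0, nrow = length(snippets), ncol = width * k)
    for (j in seq_len(k)) {
      col <- (j - 1L) * width + codes[, j]
      out[cbind(seq_along(snippets), col)] <- 1
    }
  }
  colnames(out) <- paste0("p", rep(seq_len(k), each = width), "_",
                          if (scheme == "atchley") paste0("f", 1:5)
                          else alphabet)
  attr(out, "codes") <- codes
  attr(out, "codebook") <- codebook
  out
}

#' Number of features per snippet position under a scheme
#' @param scheme Encoding scheme name.
#' @return Integer: 5 (atchley), 20 (aa_onehot), or 4 (nt_onehot).
#' @export
features_per_position <- function(scheme = c("atchley", "aa_onehot",
                                             "nt_onehot")) {
  scheme <- match.arg(scheme)
  c(atchley = 5L, aa_onehot = 20L, nt_onehot = 4L)[[scheme]]
}

#' Encode a whole cohort into per-patient snippet feature matrices
#'
#' Extracts snippets from every patient's CDR3s and encodes them, producing
#' the container consumed by [fit_detector()], [loocv()] and the
#' interpretation tools. Patients are ordered by `patient_id` internally, so
#' the result (and everything downstream, including fits) is invariant to
#' the row order of the input cohort.
#'
#' @param cohort A cohort tibble; a `label` column (0/1) is carried along
#'   when present (it is required for fitting).
#' @param k Snippet length.
#' @param scheme Encoding scheme; `"nt_onehot"` implies nucleotide snippets
#'   (requires `cdr3_nt`), the others amino-acid snippets.
#' @return A `snippet_features` object: the stacked feature matrix `X`, the
#'   per-row patient index, per-patient labels, and the snippet bookkeeping
#'   tibble mapping every row back to its source CDR3 and offset.
#' @export
encode_cohort <- function(cohort, k,
                          scheme = c("atchley", "aa_onehot", "nt_onehot")) {
  scheme <- match.arg(scheme)
  assert_cohort(cohort)
  unit <- if (scheme == "nt_onehot") "nucleotide" else "amino_acid"
  if (nrow(cohort) == 0) {
    nf <- as.integer(k) * features_per_position(scheme)
    return(new_snippet_features(
      X = matrix(numeric(0), 0, nf), patient_index = integer(0),
      patient_ids = character(0), snippets = extract_snippets(cohort, k, unit),
      k = as.integer(k), unit = unit, scheme = scheme))
  }
  snippets <- extract_snippets(cohort, k = k, unit = unit)
  patient_ids <- sort(unique(cohort$patient_id))
  counts <- table(factor(snippets$patient_id, levels = patient_ids))
  if (any(counts == 0)) {
    abort(paste0("No snippets of length ", k, " for patient(s): ",
                 paste(names(counts)[counts == 0], collapse = ", "),
                 ". A diagnosis cannot be computed for them."))
  }
  snippets <- dplyr::arrange(snippets,
                             factor(.data$patient_id, levels = patient_ids),
                             .data$cdr3_index, .data$offset)
  X <- encode_snippets(snippets$snippet, scheme)
  codes <- attr(X, "codes")
  codebook <- attr(X, "codebook")
  attr(X, "codes") <- NULL
  attr(X, "codebook") <- NULL
  labels <- NULL
  if ("label" %in% names(cohort)) {
    lab <- cohort |>
      dplyr::distinct(.data$patient_id, .data$label) |>
      dplyr::arrange(.data$patient_id)
    if (nrow(lab) != length(patient_ids)) {
      abort("Each patient must have a single label.")
    }
    labels <- setNames(as.integer(lab$label), lab$patient_id)
  }
  new_snippet_features(
    X = X,
    patient_index = match(snippets$patient_id, patient_ids),
    patient_ids = patient_ids,
    labels = labels,
    snippets = snippets,
    k = as.integer(k), unit = unit, scheme = scheme,
    codes = codes, codebook = codebook
  )
}

#' Construct a snippet-features container directly
#'
#' Low-level constructor used by [encode_cohort()] and handy for building
#' small feature sets programmatically (e.g. in simulations or tests).
#'
#' @param X Numeric matrix, one row per snippet.
#' @param patient_index Integer vector (one per row of `X`) mapping rows to
#'   patients `1..n_patients`.
#' @param patient_ids Character vector of patient ids.
#' @param labels Optional named integer vector of 0/1 labels per patient.
#' @param snippets Optional snippet bookkeeping tibble.
#' @param k,unit,scheme Encoding metadata.
#' @param codes,codebook Optional position-wise lookup structure (an
#'   integer matrix of 1-based symbol codes per snippet position and the
#'   per-position codebook matrix whose rows the feature blocks equal);
#'   produced by [encode_cohort()] and used by the fitter's fast path.
#' @return A `snippet_features` object.
#' @export
new_snippet_features <- function(X, patient_index, patient_ids,
                                 labels = NULL, snippets = NULL,
                                 k = NA_integer_, unit = "amino_acid",
                                 scheme = "atchley",
                                 codes = NULL, codebook = NULL) {
  stopifnot(is.matrix(X), length(patient_index) == nrow(X))
  patient_index <- as.integer(patient_index)
  if (any(is.na(patient_index)) ||
      (nrow(X) > 0 && (min(patient_index) < 1 ||
                       max(patient_index) > length(patient_ids)))) {
    abort("`patient_index` must map rows to 1..n_patients.")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(patient_ids),
              all(labels %in% c(0L, 1L)))
  }
  if (!is.null(codes)) {
    stopifnot(nrow(codes) == nrow(X), !is.null(codebook),
              ncol(codes) * ncol(codebook) == ncol(X))
  }
  structure(
    list(X = X, patient_index = patient_index,
         patient_ids = as.character(patient_ids),
         labels = labels, snippets = snippets,
         k = as.integer(k), unit = unit, scheme = scheme,
         n_features = ncol(X), codes = codes, codebook = codebook),
    class = "snippet_features"
  )
}

#' @export
print.snippet_features <- function(x, ...) {
  cat("<snippet_features> ", length(x$patient_ids), " patients, ",
      nrow(x$X), " snippets, ", x$n_features, " features (k = ", x$k,
      ", ", x$scheme, ")\n", sep = "")
  if (!is.null(x$labels)) {
    cat("  labels: ", sum(x$labels == 1L), " case / ",
        sum(x$labels == 0L), " control\n", sep = "")
  }
  invisible(x)
}

#' Export a feature matrix with snippet provenance for audit
#'
#' Writes one TSV row per snippet: `patient_id`, `cdr3_index`, `offset`,
#' `snippet`, then the feature values.
#'
#' @param features A `snippet_features` object from [encode_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "snippet_features"))
  if (is.null(features$snippets)) {
    abort("This feature set has no snippet bookkeeping to export.")
  }
  out <- dplyr::bind_cols(features$snippets,
                          tibble::as_tibble(features$X))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
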