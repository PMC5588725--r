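# Reading repertoire files and applying the sequence hygiene filters:
# read length / quality thresholds on raw reads, duplicate collapsing,
# removal of ambiguous calls, and removal of CDR3s shared across patients
# (putative carry-over contamination).

#' Read a cohort of labeled CDR3 repertoires
#'
#' Reads a tabular rearrangement file into the package's cohort format: one
#' row per CDR3 with columns `patient_id`, `label` (1 = case, 0 = control,
#' may be absent for prediction-only AIRR input), `cdr3_aa`, and optionally
#' `cdr3_nt` and `count`. Two dialects are supported: a plain CSV with those
#' column names, and an AIRR Rearrangement TSV whose `repertoire_id`,
#' `junction_aa`, `junction` and `duplicate_count` columns are mapped onto
#' them. Rows with an empty CDR3 are dropped (and counted in the
#' `"dropped_empty"` attribute).
#'
#' @param path Path to a CSV or AIRR TSV file.
#' @param dialect `"auto"` (by extension: `.tsv` means AIRR), `"csv"`, or
#'   `"airr"`.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "airr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "airr" else "csv"
  }
  x <- tryCatch(
    if (dialect == "airr") {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    } else {
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    },
    error = function(e) abort(paste0("Could not parse ", path, ": ",
                                     conditionMessage(e)))
  )
  if (nrow(x) == 0 || ncol(x) <= 1 && dialect == "csv" && ncol(x) == 0) {
    abort(paste0("Empty rearrangement file: ", path))
  }
  if (dialect == "airr") {
    map <- c(repertoire_id = "patient_id", junction_aa = "cdr3_aa",
             junction = "cdr3_nt", duplicate_count = "count")
    for (old in names(map)) {
      if (old %in% names(x) && !map[[old]] %in% names(x)) {
        names(x)[names(x) == old] <- map[[old]]
      }
    }
  }
  for (col in c("patient_id", "cdr3_aa")) {
    if (!col %in% names(x)) {
      abort(paste0("Missing required column `", col, "` in ", path,
                   if (dialect == "airr") " (or its AIRR equivalent)" else ""))
    }
  }
  if ("label" %in% names(x)) {
    if (!all(x$label %in% c(0, 1))) {
      abort("`label` must be binary 0/1.")
    }
    x$label <- as.integer(x$label)
  }
  x$patient_id <- as.character(x$patient_id)
  n0 <- nrow(x)
  x <- dplyr::filter(x, !is.na(.data$cdr3_aa), .data$cdr3_aa != "")
  keep <- intersect(c("patient_id", "label", "cdr3_aa", "cdr3_nt", "count"),
                    names(x))
  out <- tibble::as_tibble(x[keep])
  if (!"count" %in% names(out)) out$count <- 1L
  attr(out, "dropped_empty") <- n0 - nrow(out)
  attr(out, "source_file") <- path
  out
}

#' Write a cohort to the plain CSV dialect
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Read raw reads from a FASTQ file
#'
#' Parses a Sanger (Phred+33) FASTQ file into a tibble of reads with their
#' per-base Phred scores, ready for [filter_reads()].
#'
#' @param path FASTQ path.
#' @return A tibble with columns `read_id`, `sequence`, `quality` (a
#'   list-column of integer Phred vectors), and `mean_quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as(Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities),
          "IntegerList")
  q <- as.list(q)
  tibble(
    read_id = names(x) %||% paste0("read", seq_along(x)),
    sequence = as.character(x),
    quality = q,
    mean_quality = vapply(q, function(v) mean(as.numeric(v)), numeric(1))
  )
}

#' Filter raw reads on length and average base quality
#'
#' Retains exactly the reads with length >= `min_length` and mean Phred
#' score >= `min_avg_quality`, preserving order. The thresholds are
#' inclusive: the removal rule is strictly "shorter than" / "lower than",
#' so a 300-bp read of mean quality exactly 35 is kept.
#'
#' @param reads A tibble as returned by [read_fastq()] (columns `sequence`
#'   and `quality`).
#' @param min_length Minimum read length in bases (default 300).
#' @param min_avg_quality Minimum mean Phred score (default 35).
#' @return The filtered tibble, attribute `"n_removed"` recording the count.
#' @export
filter_reads <- function(reads, min_length = 300, min_avg_quality = 35) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads),
            "quality" %in% names(reads))
  len <- nchar(reads$sequence)
  avg <- vapply(reads$quality, function(v) mean(as.numeric(v)), numeric(1))
  bad_len <- vapply(reads$quality, length, integer(1)) != len
  if (any(bad_len)) {
    abort(paste0("Quality length differs from sequence length for read(s): ",
                 paste(which(bad_len), collapse = ", ")))
  }
  keep <- len >= min_length & avg >= min_avg_quality
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Collapse duplicate CDR3 sequences within each patient
#'
#' Identical sequences within one patient are merged into a single row with
#' summed `count`. The collapse keys on the nucleotide sequence when a
#' `cdr3_nt` column is present (duplicates are counted before translation),
#' otherwise on the amino-acid sequence. Total count is conserved.
#'
#' @param cohort A cohort tibble.
#' @return The collapsed cohort tibble.
#' @export
collapse_duplicates <- function(cohort) {
  assert_cohort(cohort)
  if (!"count" %in% names(cohort)) cohort$count <- 1L
  key <- if ("cdr3_nt" %in% names(cohort)) "cdr3_nt" else "cdr3_aa"
  cohort |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id, .key = .data[[key]]) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("label", "cdr3_aa", "cdr3_nt")),
                    dplyr::first),
      count = sum(.data$count),
      .row = min(.data$.row),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row", -".key")
}

#' Drop CDR3s with ambiguous or non-standard symbols
#'
#' Removes rows whose amino-acid sequence contains a symbol outside the 20
#' standard residues (e.g. `X`, `*`) or, when `cdr3_nt` is present, whose
#' nucleotide sequence contains a non-ACGT base (e.g. `N`).
#'
#' @param cohort A cohort tibble.
#' @return The filtered cohort tibble, attribute `"n_removed"` recording
#'   the count.
#' @export
drop_ambiguous <- function(cohort) {
  assert_cohort(cohort)
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
              toupper(cohort$cdr3_aa))
  if ("cdr3_nt" %in% names(cohort)) {
    nt <- toupper(cohort$cdr3_nt)
    ok <- ok & (is.na(nt) | grepl("^[ACGT]+$", nt))
  }
  out <- cohort[ok, , drop = FALSE]
  attr(out, "n_removed") <- sum(!ok)
  out
}

#' Remove CDR3 sequences shared across patients
#'
#' Any amino-acid CDR3 string (compared case-insensitively) observed in two
#' or more distinct patients is removed from every patient, on the grounds
#' that cross-sample sharing indicates carry-over contamination. If the
#' removal empties a patient's repertoire a warning names the patient and
#' the id is recorded in the `"emptied_patients"` attribute; the patient is
#' not silently dropped from downstream bookkeeping.
#'
#' @param cohort A cohort tibble with at least two patients.
#' @return The filtered cohort tibble, with attributes `"removed_log"`
#'   (per-patient removal counts) and `"emptied_patients"`.
#' @export
remove_shared_sequences <- function(cohort) {
  assert_cohort(cohort)
  ids <- unique(cohort$patient_id)
  if (length(ids) < 2) {
    abort("`remove_shared_sequences()` needs a cohort of at least 2 patients.")
  }
  seq_up <- toupper(cohort$cdr3_aa)
  shared <- cohort |>
    dplyr::mutate(.seq = seq_up) |>
    dplyr::distinct(.data$patient_id, .data$.seq) |>
    dplyr::count(.data$.seq) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(".seq")
  drop <- seq_up %in% shared
  out <- cohort[!drop, , drop = FALSE]
  log <- cohort |>
    dplyr::mutate(.drop = drop) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_removed = sum(.data$.drop), .groups = "drop")
  emptied <- setdiff(ids, unique(out$patient_id))
  if (length(emptied) > 0) {
    warn(paste0("Shared-sequence removal emptied the repertoire of: ",
                paste(emptied, collapse = ", ")))
  }
  attr(out, "removed_log") <- log
  attr(out, "emptied_patients") <- emptied
  out
}

#' Run the full preprocessing chain on a cohort
#'
#' Convenience wrapper applying, in order, [collapse_duplicates()],
#' [drop_ambiguous()], and (optionally) [remove_shared_sequences()], and
#' attaching a per-patient filter report.
#'
#' @param cohort A cohort tibble.
#' @param shared_sequence_removal Apply the cross-patient filter (default
#'   `TRUE`; requires >= 2 patients).
#' @return The cleaned cohort; `filter_report()` retrieves the report.
#' @export
preprocess_cohort <- function(cohort, shared_sequence_removal = TRUE) {
  assert_cohort(cohort)
  per_patient <- function(x) {
    dplyr::count(x, .data$patient_id, name = "n")
  }
  report <- per_patient(cohort) |> dplyr::rename(n_input = "n")
  out <- collapse_duplicates(cohort)
  report <- dplyr::left_join(report,
    per_patient(out) |> dplyr::rename(n_collapsed = "n"), by = "patient_id")
  out <- drop_ambiguous(out)
  report <- dplyr::left_join(report,
    per_patient(out) |> dplyr::rename(n_unambiguous = "n"), by = "patient_id")
  if (shared_sequence_removal && length(unique(out$patient_id)) >= 2) {
    out <- remove_shared_sequences(out)
  }
  report <- dplyr::left_join(report,
    per_patient(out) |> dplyr::rename(n_final = "n"), by = "patient_id")
  report <- dplyr::mutate(report, dplyr::across(dplyr::where(is.numeric),
                                                ~ tidyr::replace_na(.x, 0L)))
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the per-patient filter report from a preprocessed cohort
#'
#' @param cohort A cohort returned by [preprocess_cohort()].
#' @return A tibble of per-patient sequence counts after each filter.
#' @export
filter_report <- function(cohort) {
  rep <- attr(cohort, "filter_report")
  if (is.null(rep)) abort("No filter report: run `preprocess_cohort()` first.")
  rep
}
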