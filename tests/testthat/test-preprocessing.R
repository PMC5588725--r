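write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("CSV cohorts group rows by patient and validate labels", {
  path <- write_tmp(c("patient_id,label,cdr3_aa",
                      "P1,1,CARDYW", "P1,1,CSSGYW", "P2,0,CTRDFW"), ".csv")
  cohort <- read_cohort(path)
  expect_equal(sort(unique(cohort$patient_id)), c("P1", "P2"))
  expect_equal(nrow(cohort), 3)
  expect_true(all(cohort$count == 1L))

  bad <- write_tmp(c("patient_id,label,cdr3_aa", "P1,2,CARDYW"), ".csv")
  expect_error(read_cohort(bad), "binary")
  missing <- write_tmp(c("patient_id,label", "P1,1"), ".csv")
  expect_error(read_cohort(missing), "cdr3_aa")
  empty <- write_tmp(character(0), ".csv")
  expect_error(read_cohort(empty))
})

test_that("AIRR TSV columns map onto the cohort schema", {
  path <- write_tmp(c("repertoire_id\tjunction_aa\tjunction\tduplicate_count",
                      "P9\tCARDYW\tTGTGCAAGAGATTACTGG\t3"), ".tsv")
  cohort <- read_cohort(path)
  expect_equal(cohort$patient_id, "P9")
  expect_equal(cohort$cdr3_aa, "CARDYW")
  expect_equal(cohort$cdr3_nt, "TGTGCAAGAGATTACTGG")
  expect_equal(cohort$count, 3)
})

test_that("empty CDR3 rows are dropped and counted", {
  path <- write_tmp(c("patient_id,label,cdr3_aa",
                      "P1,1,CARDYW", "P1,1,", "P2,0,CTRDFW"), ".csv")
  cohort <- read_cohort(path)
  expect_equal(nrow(cohort), 2)
  expect_equal(attr(cohort, "dropped_empty"), 1)
})

test_that("cohorts round-trip through the CSV dialect", {
  cohort <- tiny_cohort(2, 2, n_cdr3 = 3)
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  back$count <- as.integer(back$count)
  expect_equal(as.data.frame(back), as.data.frame(cohort),
               ignore_attr = TRUE)
})

test_that("read filters apply inclusive length/quality thresholds", {
  mk_read <- function(len, quals) {
    tibble::tibble(read_id = "r", sequence = rand_dna(len),
                   quality = list(as.integer(quals)))
  }
  rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                collapse = "")
  reads <- dplyr::bind_rows(
    mk_read(299, rep(40, 299)),                      # too short
    mk_read(300, rep(35, 300)),                      # boundary: retained
    mk_read(400, c(rep(35, 360), rep(34, 40))),      # mean 34.9: removed
    mk_read(400, rep(36, 400))                       # retained
  )
  out <- filter_reads(reads)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 2)
  expect_equal(nchar(out$sequence), c(300, 400))
  # idempotence
  again <- filter_reads(out)
  expect_equal(again$sequence, out$sequence)
  expect_equal(attr(again, "n_removed"), 0)
})

test_that("FASTQ reads parse with Phred+33 qualities", {
  path <- write_tmp(c("@r1", "ACGTN", "+", "IIII#",
                      "@r2", "ACGTACGT", "+", "IIIIIIII"), ".fastq")
  reads <- read_fastq(path)
  expect_equal(reads$read_id, c("r1", "r2"))
  expect_equal(reads$quality[[1]], c(40, 40, 40, 40, 2))
  expect_equal(reads$mean_quality[2], 40)
})

test_that("duplicate collapsing sums counts and conserves the total", {
  cohort <- tibble::tibble(
    patient_id = "P1", label = 1L,
    cdr3_aa = c("AAA", "AAA", "CCC"), count = c(1L, 1L, 1L))
  out <- collapse_duplicates(cohort)
  expect_equal(out$cdr3_aa, c("AAA", "CCC"))
  expect_equal(out$count, c(2L, 1L))

  # all-distinct input is unchanged; x repeated 5 times collapses to count 5
  distinct <- tibble::tibble(patient_id = "P1", label = 1L,
                             cdr3_aa = c("AB", "CD"), count = c(2L, 3L))
  expect_equal(collapse_duplicates(distinct)$count, c(2L, 3L))
  five <- tibble::tibble(patient_id = "P1", label = 1L,
                         cdr3_aa = rep("CARDYW", 5), count = rep(1L, 5))
  expect_equal(collapse_duplicates(five)$count, 5L)

  # property: total count conserved on random cohorts
  for (s in 1:5) {
    set.seed(s)
    rnd <- tibble::tibble(
      patient_id = sample(c("A", "B"), 30, TRUE), label = 1L,
      cdr3_aa = sample(c("AAA", "CCC", "GGG"), 30, TRUE),
      count = sample(1:4, 30, TRUE))
    expect_equal(sum(collapse_duplicates(rnd)$count), sum(rnd$count))
  }
})

test_that("duplicate collapsing keys on nucleotide sequence when present", {
  cohort <- tibble::tibble(
    patient_id = "P1", label = 1L, cdr3_aa = c("M", "M"),
    cdr3_nt = c("ATG", "ATG"), count = 1L)
  expect_equal(nrow(collapse_duplicates(cohort)), 1)
  # same amino acid, different codons: kept distinct
  syn <- tibble::tibble(
    patient_id = "P1", label = 1L, cdr3_aa = c("L", "L"),
    cdr3_nt = c("TTA", "TTG"), count = 1L)
  expect_equal(nrow(collapse_duplicates(syn)), 2)
})

test_that("ambiguous sequences are removed", {
  cohort <- tibble::tibble(
    patient_id = "P1", label = 1L,
    cdr3_aa = c("CARDYW", "CARDX", "CARD*W", "MKV"),
    cdr3_nt = c("ATGNCC", NA, NA, NA), count = 1L)
  out <- drop_ambiguous(cohort)
  expect_equal(out$cdr3_aa, "MKV")
  expect_equal(attr(out, "n_removed"), 3)
  clean <- tibble::tibble(patient_id = "P1", label = 1L,
                          cdr3_aa = c("MKV", "CARDYW"), count = 1L)
  expect_equal(drop_ambiguous(clean)$cdr3_aa, clean$cdr3_aa)
})

test_that("cross-patient shared sequences are removed from every patient", {
  cohort <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    label = c(1L, 1L, 0L, 0L, 0L),
    cdr3_aa = c("CARDYW", "AAAQQQ", "cardyw", "CSSGYW", "CARDYW"),
    count = 1L)
  expect_warning(out <- remove_shared_sequences(cohort), "P3")
  expect_false(any(toupper(out$cdr3_aa) == "CARDYW"))
  expect_setequal(out$cdr3_aa, c("AAAQQQ", "CSSGYW"))
  log <- attr(out, "removed_log")
  expect_equal(sum(log$n_removed), 3)

  no_overlap <- tibble::tibble(patient_id = c("P1", "P2"), label = c(1L, 0L),
                               cdr3_aa = c("AAA", "CCC"), count = 1L)
  expect_equal(remove_shared_sequences(no_overlap)$cdr3_aa,
               no_overlap$cdr3_aa)
  expect_error(remove_shared_sequences(no_overlap[1, ]), "2 patients")
})

test_that("emptied repertoires are flagged, not silently dropped", {
  cohort <- tibble::tibble(
    patient_id = c("P1", "P2", "P2"), label = c(1L, 0L, 0L),
    cdr3_aa = c("CARDYW", "CARDYW", "CSSGYW"), count = 1L)
  expect_warning(out <- remove_shared_sequences(cohort), "P1")
  expect_equal(attr(out, "emptied_patients"), "P1")
})

test_that("shared-removal output has pairwise-disjoint repertoires", {
  sim <- simulate_cohort(n_cases = 3, n_controls = 3, n_cdr3 = 30,
                         contamination_rate = 0.1, seed = 5)
  out <- remove_shared_sequences(sim$cohort)
  sets <- split(toupper(out$cdr3_aa), out$patient_id)
  for (i in seq_along(sets)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
  }
})

test_that("the preprocessing chain reports per-patient counts", {
  cohort <- tiny_cohort(2, 2, n_cdr3 = 6)
  cohort$cdr3_aa[1] <- "CARDXW"  # ambiguous
  out <- preprocess_cohort(cohort)
  rep <- filter_report(out)
  expect_setequal(rep$patient_id, unique(cohort$patient_id))
  expect_true(all(rep$n_final <= rep$n_input))
  expect_equal(rep$n_input[rep$patient_id == "T01"], 6)
  expect_error(filter_report(cohort), "preprocess_cohort")
})
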