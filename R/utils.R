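# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a master seed plus stream labels
# (fold index, restart index, ...). FNV-1a-style integer mixing; every
# consumer of randomness in the package draws its seed through this, so
# results depend only on (seed, labels), never on execution order.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 2166136261
  for (p in parts) {
    # mix each byte of the (possibly negative) integer
    x <- as.numeric(p) %% 4294967296
    for (i in 1:4) {
      b <- x %% 256
      x <- (x - b) / 256
      h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
      h <- (h * 16777619) %% 4294967296
    }
  }
  as.integer(h %% 2147483647) + 1L
}

# Small stable checksum over a numeric table, used to stamp the Atchley
# constants into serialized models so a model is never applied under a
# different encoding table than it was fit with.
numeric_checksum <- function(x) {
  s <- paste(format(round(as.numeric(x), 6), trim = TRUE, scientific = FALSE),
             collapse = ",")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%010d", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
NT_ALPHABET <- c("A", "C", "G", "T")

assert_cohort <- function(cohort, need_label = FALSE) {
  if (!is.data.frame(cohort)) {
    abort("`cohort` must be a data frame with columns patient_id and cdr3_aa.")
  }
  missing <- setdiff(c("patient_id", "cdr3_aa"), names(cohort))
  if (length(missing) > 0) {
    abort(paste0("`cohort` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (need_label) {
    if (!"label" %in% names(cohort)) {
      abort("`cohort` must have a `label` column (1 = case, 0 = control).")
    }
    bad <- !cohort$label %in% c(0L, 1L)
    if (any(bad)) {
      abort(paste0("`label` must be binary 0/1; found: ",
                   paste(unique(cohort$label[bad]), collapse = ", ")))
    }
  }
  invisible(cohort)
}
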