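# Shared fixtures and independent oracles for the test suite. Oracles are
# written as plain enumeration/brute force, deliberately independent of the
# package's vectorized implementations.

# random amino-acid string
rand_aa <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               n, replace = TRUE), collapse = "")
}

# tiny labeled cohort tibble with a planted motif in the cases
tiny_cohort <- function(n_cases = 3, n_controls = 3, n_cdr3 = 8,
                        len = 10, motif = "QKRAAD", seed = 42) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_cases + n_controls)) {
    lab <- as.integer(i <= n_cases)
    seqs <- replicate(n_cdr3, rand_aa(len))
    if (lab == 1) {
      for (t in 1:2) {   # two planted CDR3s per case
        off <- sample.int(len - nchar(motif) + 1, 1) - 1
        seqs[t] <- paste0(substr(seqs[t], 1, off), motif,
                          substr(seqs[t], off + nchar(motif) + 1, len))
      }
    }
    rows[[i]] <- tibble::tibble(patient_id = sprintf("T%02d", i),
                                label = lab, cdr3_aa = seqs, count = 1L)
  }
  dplyr::bind_rows(rows)
}

# hand-built snippet_features: list of per-patient feature matrices
features_from_matrices <- function(mats, labels) {
  X <- do.call(rbind, mats)
  pidx <- rep(seq_along(mats), vapply(mats, nrow, integer(1)))
  ids <- sprintf("M%02d", seq_along(mats))
  new_snippet_features(X, pidx, ids,
                       labels = stats::setNames(as.integer(labels), ids),
                       k = ncol(X) %/% 5L)
}

# random small instance for likelihood/gradient oracle checks
random_instance <- function(seed, n_features = 30) {
  set.seed(seed)
  P <- sample(2:5, 1)
  labels <- c(0, 1, sample(0:1, P - 2, replace = TRUE))
  mats <- lapply(seq_len(P), function(i) {
    matrix(rnorm(sample(1:10, 1) * n_features), ncol = n_features)
  })
  list(features = features_from_matrices(mats, labels),
       params = detector_params(rnorm(1, 0, 0.3),
                                rnorm(n_features, 0, 0.3)))
}

# brute-force NLL: enumerate every snippet's sigmoid explicitly
oracle_nll <- function(params, features) {
  total <- 0
  for (p in seq_along(features$patient_ids)) {
    rows <- which(features$patient_index == p)
    scores <- numeric(length(rows))
    for (j in seq_along(rows)) {
      z <- params$b0
      for (f in seq_len(ncol(features$X))) {
        z <- z + params$W[f] * features$X[rows[j], f]
      }
      scores[j] <- 1 / (1 + exp(-z))
    }
    pr <- max(scores)
    y <- unname(features$labels)[p]
    total <- total - (y * log(pr) + (1 - y) * log(1 - pr))
  }
  total
}

# central finite-difference gradient of negative_log_likelihood
fd_gradient <- function(params, features, h = 1e-6) {
  nf <- length(params$W)
  d_W <- numeric(nf)
  for (f in seq_len(nf)) {
    up <- params; up$W[f] <- up$W[f] + h
    dn <- params; dn$W[f] <- dn$W[f] - h
    d_W[f] <- (negative_log_likelihood(up, features) -
                 negative_log_likelihood(dn, features)) / (2 * h)
  }
  up <- params; up$b0 <- up$b0 + h
  dn <- params; dn$b0 <- dn$b0 - h
  list(d_b0 = (negative_log_likelihood(up, features) -
                 negative_log_likelihood(dn, features)) / (2 * h),
       d_W = d_W)
}

# exhaustive codon-spelling enumeration for a peptide
oracle_encoding_count <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  chars <- strsplit(aa, "")[[1]]
  spellings <- Reduce(function(acc, a) {
    unlist(lapply(acc, function(s) paste0(s, by_aa[[a]])))
  }, chars, accumulate = FALSE, init = "")
  length(unique(spellings))
}

# small fitting configuration for unit tests
tiny_config <- function(seed = 1, ...) {
  fit_config(n_restarts = 4, n_iterations = 150, seed = seed, ...)
}
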