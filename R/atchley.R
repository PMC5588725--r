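# The five Atchley factors: standardized numeric summaries of ~50
# physicochemical amino-acid properties (Atchley et al. 2005, PNAS 102:6395).
# Factor I tracks polarity/hydrophilicity, II secondary-structure propensity,
# III molecular volume, IV codon diversity / compositional rarity, and
# V electrostatic charge. Constants are embedded verbatim as published;
# they are a fixed data resource, never recomputed.
.atchley_values <- matrix(c(
  # f1       f2       f3       f4       f5
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, ncol = 5, byrow = TRUE,
  dimnames = list(c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y"),
                  paste0("f", 1:5)))

#' Atchley-factor table for the 20 standard amino acids
#'
#' Returns the five published Atchley factors per residue. The factors are
#' standardized (mean ~0, SD ~1 across the 20 residues) projections of a
#' large panel of physicochemical properties: factor I relates to polarity,
#' II to secondary-structure propensity, III to molecular volume, IV to
#' codon diversity, and V to electrostatic charge.
#'
#' @param as_matrix Return a 20 x 5 numeric matrix (row names are residues)
#'   instead of a tibble.
#' @return A tibble with columns `amino_acid` and `f1`..`f5`, or a matrix.
#' @examples
#' atchley_table()
#' @export
atchley_table <- function(as_matrix = FALSE) {
  if (as_matrix) return(.atchley_values)
  tibble::as_tibble(.atchley_values, rownames = "amino_acid")
}

#' Checksum of the embedded Atchley constants
#'
#' A stable checksum stamped into serialized models so that a model fit
#' under one encoding table is never scored under another.
#'
#' @return A character scalar.
#' @export
atchley_checksum <- function() {
  numeric_checksum(.atchley_values)
}
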