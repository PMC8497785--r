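#' Random-coil backbone chemical shift reference table
#'
#' Residue-specific random-coil chemical shifts (ppm) for the backbone atoms
#' used in secondary-shift analysis, taken from the standard published
#' random-coil tables for unstructured peptides. Glycine has no CB and
#' proline no amide H; those cells are `NA`.
#'
#' @return A tibble with columns `residue_type` (one-letter code) and the
#'   atoms `CA`, `CB`, `C`, `HA`, `H`, `N` in ppm.
#' @seealso [secondary_shifts()], [helix_propensity()]
#' @export
coil_shifts <- function() {
  tibble::tribble(
    ~residue_type,  ~CA,  ~CB,    ~C,  ~HA,   ~H,    ~N,
    "A", 52.5, 19.1, 177.8, 4.32, 8.24, 123.8,
    "R", 56.0, 30.9, 176.3, 4.34, 8.23, 120.5,
    "N", 52.8, 38.9, 175.2, 4.74, 8.40, 118.7,
    "D", 54.2, 41.1, 176.3, 4.64, 8.34, 120.4,
    "C", 58.2, 28.0, 174.6, 4.55, 8.32, 118.8,
    "Q", 56.6, 29.4, 176.0, 4.34, 8.32, 119.8,
    "E", 56.6, 29.9, 176.6, 4.35, 8.42, 120.2,
    "G", 45.1,   NA, 174.9, 3.96, 8.33, 108.8,
    "H", 55.0, 29.0, 174.1, 4.73, 8.42, 118.2,
    "I", 61.1, 38.8, 176.4, 4.17, 8.00, 119.9,
    "L", 55.1, 42.4, 177.6, 4.34, 8.16, 121.8,
    "K", 56.2, 33.1, 176.6, 4.32, 8.29, 120.4,
    "M", 55.4, 32.9, 176.3, 4.48, 8.28, 119.6,
    "F", 57.7, 39.6, 175.8, 4.62, 8.30, 120.3,
    "P", 63.3, 32.1, 177.3, 4.42,   NA, 128.1,
    "S", 58.3, 63.8, 174.6, 4.47, 8.31, 115.7,
    "T", 61.8, 69.8, 174.7, 4.35, 8.15, 113.6,
    "W", 57.5, 29.6, 176.1, 4.66, 8.25, 121.3,
    "Y", 57.9, 38.8, 175.9, 4.55, 8.12, 120.3,
    "V", 62.2, 32.9, 176.3, 4.12, 8.03, 119.2
  )
}

# canonical full-helix secondary shift offsets (ppm); the size of the
# deviation from random coil expected for a 100% populated alpha-helix
helix_reference_shifts <- function() {
  c(CA = 2.8, CB = -0.5, C = 1.8, HA = -0.3)
}
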