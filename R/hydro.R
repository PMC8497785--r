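#' Hydrodynamic radius of a disordered chain from polymer scaling
#'
#' Predicts the hydrodynamic radius of an intrinsically disordered protein
#' from chain length with the empirical IDP power law
#' `Rh = 2.49 * N^0.509` (Angstroms), where N is the number of residues.
#' `rh_idp_nm()` reports the same value in nanometres rounded to one
#' decimal, the convention used when comparing against measured radii.
#'
#' @param n_residues Number of residues in the chain (integer >= 1).
#' @return `rh_idp()`: radius in Angstroms; `rh_idp_nm()`: nm to 1 decimal.
#' @examples
#' rh_idp(212)    # 38.05 A
#' rh_idp_nm(212) # 3.8 nm
#' @export
rh_idp <- function(n_residues) {
  if (any(!is.finite(n_residues)) || any(n_residues < 1) ||
      any(abs(n_residues - round(n_residues)) > 1e-8)) {
    stop_idpnmr("`n_residues` must be integer(s) >= 1")
  }
  2.49 * n_residues^0.509
}

#' @rdname rh_idp
#' @export
rh_idp_nm <- function(n_residues) {
  round(rh_idp(n_residues) / 10, 1)
}

#' Compare a measured hydrodynamic radius with the IDP prediction
#'
#' @param n_residues Chain length.
#' @param rh_measured Optional measured radius in Angstroms (e.g. from DLS).
#' @return A one-row tibble: `n_residues`, `rh_predicted` (A),
#'   `rh_predicted_nm`, `rh_measured`, `compaction_ratio`
#'   (measured / predicted; < 1 indicates compaction relative to the
#'   disordered-chain expectation).
#' @export
hydro_summary <- function(n_residues, rh_measured = NULL) {
  pred <- rh_idp(n_residues)
  tibble(
    n_residues = as.integer(n_residues),
    rh_predicted = pred,
    rh_predicted_nm = rh_idp_nm(n_residues),
    rh_measured = rh_measured %||% NA_real_,
    compaction_ratio = if (is.null(rh_measured)) NA_real_ else rh_measured / pred
  )
}

# average residue masses (Da); residue = amino acid - water
residue_masses <- function() {
  c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
  )
}

water_mass <- 18.0153

#' Average molecular weight of a protein sequence
#'
#' Sums average residue masses over a one-letter sequence and adds one water
#' for the chain termini.
#'
#' @param sequence One-letter amino-acid string (non-empty).
#' @return Molecular weight in Da.
#' @examples
#' mw_from_sequence("G")  # 75.07
#' @export
mw_from_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0) {
    stop_idpnmr("`sequence` must be a non-empty one-letter string")
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  m <- residue_masses()[letters1]
  if (anyNA(m)) {
    stop_idpnmr(
      "unknown amino-acid letter(s): ",
      paste(unique(letters1[is.na(m)]), collapse = ", ")
    )
  }
  sum(m) + water_mass
}

#' Log-linear size-exclusion column calibration
#'
#' Fits the standard SEC calibration line `log10(MW) = a + b * V` to
#' (elution volume, molecular weight) standards; `sec_predict()` converts an
#' elution volume back to an apparent molecular weight. With exactly two
#' standards the line passes through both points.
#'
#' @param points A data frame or tibble with columns `ml` (elution volume)
#'   and `mw` (Da), at least 2 rows with distinct volumes.
#' @return `sec_calibrate()`: an object of class `"sec_calibration"`.
#'   `sec_predict()`: apparent MW in Da (vectorized over `ml`).
#' @examples
#' cal <- sec_calibrate(data.frame(ml = c(14.7, 13.3), mw = c(51.6e3, 95.9e3)))
#' sec_predict(cal, 14.7) # 51600
#' @export
sec_calibrate <- function(points) {
  if (!all(c("ml", "mw") %in% names(points))) {
    stop_idpnmr("`points` needs columns `ml` and `mw`")
  }
  if (nrow(points) < 2L) {
    stop_idpnmr("at least 2 calibration points required")
  }
  if (length(unique(points$ml)) < 2L) {
    stop_idpnmr("calibration volumes must be distinct")
  }
  if (any(points$mw <= 0)) {
    stop_idpnmr("molecular weights must be positive")
  }
  fit <- lm(log10(mw) ~ ml, data = as.data.frame(points))
  structure(
    list(fit = fit, points = as_tibble(points)),
    class = "sec_calibration"
  )
}

#' @rdname sec_calibrate
#' @param calibration A `"sec_calibration"`.
#' @param ml Elution volume(s) to convert.
#' @export
sec_predict <- function(calibration, ml) {
  stopifnot(inherits(calibration, "sec_calibration"))
  10^unname(stats::predict(calibration$fit, newdata = data.frame(ml = ml)))
}

#' @export
print.sec_calibration <- function(x, ...) {
  b <- coef(x$fit)
  cat(
    "<sec_calibration> log10(MW) = ", format(b[1], digits = 6), " ",
    ifelse(b[2] < 0, "-", "+"), " ", format(abs(b[2]), digits = 6),
    " * V(ml); ", nrow(x$points), " standards\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname sec_calibrate
#' @param x A `"sec_calibration"`.
#' @param ... Unused.
#' @export
tidy.sec_calibration <- function(x, ...) {
  # a 2-point calibration is an exact line; summary.lm warns about that
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2])
  )
}

#' @rdname sec_calibrate
#' @export
glance.sec_calibration <- function(x, ...) {
  tibble(
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    n = nrow(x$points)
  )
}

#' Mean residue ellipticity from raw CD signal
#'
#' Converts an observed circular-dichroism signal to mean residue
#' ellipticity using the peptide-bond convention:
#' `MRE = theta / (10 * l * c * (N - 1))` with `theta` in millidegrees,
#' pathlength `l` in cm, molar concentration `c`, and `N - 1` peptide bonds
#' for an N-residue chain.
#'
#' @param theta_mdeg Observed ellipticity (mdeg); may be a vector (spectrum).
#' @param pathlength_cm Cuvette pathlength (cm, > 0).
#' @param conc_molar Protein concentration (M, > 0).
#' @param n_residues Number of residues (>= 2).
#' @return Mean residue ellipticity in deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(theta_mdeg, pathlength_cm, conc_molar,
                                     n_residues) {
  check_number(pathlength_cm, "pathlength_cm", positive = TRUE)
  check_number(conc_molar, "conc_molar", positive = TRUE)
  check_number(n_residues, "n_residues", integerish = TRUE)
  if (n_residues < 2) {
    stop_idpnmr("`n_residues` must be >= 2 (at least one peptide bond)")
  }
  theta_mdeg / (10 * pathlength_cm * conc_molar * (n_residues - 1))
}

#' Per-column conservation mask from a multiple sequence alignment
#'
#' Marks an alignment column as conserved when the reference row's amino
#' acid at that column occurs (identity only; gaps never count) in at least
#' `min_species` of the aligned sequences, the reference included. Columns
#' where the reference has a gap are skipped. Each conserved column is
#' mapped back to the reference sequence's residue numbering.
#'
#' @param msa An [read_msa()] object.
#' @param min_species Minimum number of sequences sharing the reference's
#'   amino acid (default 7).
#' @param reference Reference row: an index or a sequence label.
#' @param ref_start Residue number of the reference row's first non-gap
#'   position (default 1).
#' @return A tibble over reference (non-gap) positions: `column`,
#'   `residue_number`, `residue_type`, `n_matching`, `conserved`.
#' @export
conservation_mask <- function(msa, min_species = 7, reference = 1,
                              ref_start = 1) {
  stopifnot(inherits(msa, "msa"))
  check_number(min_species, "min_species", positive = TRUE, integerish = TRUE)
  n_rows <- nrow(msa$seqs)
  if (min_species > n_rows) {
    stop_idpnmr(
      "`min_species` (", min_species, ") exceeds the number of sequences (",
      n_rows, ")"
    )
  }
  ref_idx <- if (is.character(reference)) {
    hit <- which(msa$labels == reference)
    if (length(hit) == 0) stop_idpnmr("reference label '", reference, "' not found")
    hit[1]
  } else {
    as.integer(reference)
  }
  if (ref_idx < 1 || ref_idx > n_rows) {
    stop_idpnmr("reference index out of range")
  }
  ref_row <- msa$seqs[ref_idx, ]
  nongap <- which(ref_row != "-")
  if (length(nongap) == 0) {
    stop_idpnmr("reference row contains only gaps")
  }
  counts <- vapply(
    nongap,
    function(j) sum(msa$seqs[, j] == ref_row[j]),
    integer(1)
  )
  tibble(
    column = nongap,
    residue_number = ref_start + seq_along(nongap) - 1L,
    residue_type = ref_row[nongap],
    n_matching = counts,
    conserved = counts >= min_species
  )
}
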