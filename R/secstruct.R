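#' Secondary chemical shifts against a random-coil reference
#'
#' Subtracts residue-type-specific random-coil values from observed backbone
#' shifts: `delta_sec = observed - coil(residue_type)`. Atoms absent from a
#' residue (unassigned, or structurally absent like glycine CB) propagate as
#' not computed.
#'
#' @param shifts Wide shift tibble (`residue_number`, `residue_type`, atom
#'   columns), e.g. from [read_shift_table()] or [simulate_shift_table()].
#' @param coil_table Random-coil reference, as from [coil_shifts()].
#' @return A long tibble: `residue_number`, `residue_type`, `atom`,
#'   `delta_sec` (ppm; `NA` when not computed).
#' @export
secondary_shifts <- function(shifts, coil_table = coil_shifts()) {
  atoms <- intersect(shift_atoms, names(shifts))
  if (length(atoms) == 0) {
    stop_idpnmr("`shifts` contains no atom columns")
  }
  missing_types <- setdiff(
    unique(shifts$residue_type), coil_table$residue_type
  )
  if (length(missing_types) > 0) {
    stop_idpnmr(
      "residue type(s) missing from the coil table: ",
      paste(missing_types, collapse = ", ")
    )
  }
  obs <- shifts |>
    select("residue_number", "residue_type", dplyr::all_of(atoms)) |>
    tidyr::pivot_longer(
      dplyr::all_of(atoms), names_to = "atom", values_to = "observed"
    )
  ref <- coil_table |>
    tidyr::pivot_longer(
      -"residue_type", names_to = "atom", values_to = "coil"
    )
  obs |>
    left_join(ref, by = c("residue_type", "atom")) |>
    mutate(delta_sec = .data$observed - .data$coil) |>
    select("residue_number", "residue_type", "atom", "delta_sec")
}

#' Windowed helical propensity from secondary shifts
#'
#' Estimates a per-residue secondary-structure propensity in \[-1, 1\]
#' (positive helical, negative extended) by scaling each atom's secondary
#' shift by its canonical full-helix value (CA +2.8, CB -0.5, C +1.8,
#' HA -0.3 ppm), averaging the available atoms with weights proportional to
#' the magnitude of those reference shifts, then smoothing with a centred
#' running mean of odd width `window` (shrinking at the chain ends) and
#' clipping to \[-1, 1\]. A residue with no usable atom is not computed and
#' does not enter its neighbours' windows.
#'
#' @inheritParams secondary_shifts
#' @param window Odd window width >= 1 (residues).
#' @param atoms Atoms to use; default the four with canonical helix offsets.
#' @return A tibble (`residue_number`, `propensity`) with attributes
#'   `"window"` and `"atoms_used"`.
#' @export
helix_propensity <- function(shifts, coil_table = coil_shifts(), window = 5,
                             atoms = c("CA", "CB", "C", "HA")) {
  check_number(window, "window", integerish = TRUE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop_idpnmr("`window` must be an odd integer >= 1")
  }
  atoms <- intersect(atoms, names(helix_reference_shifts()))
  if (length(atoms) == 0) {
    stop_idpnmr("no usable atoms requested")
  }
  if (nrow(shifts) < window) {
    stop_idpnmr("need at least `window` residues")
  }
  ref <- helix_reference_shifts()[atoms]
  sec <- secondary_shifts(shifts, coil_table) |>
    filter(.data$atom %in% atoms) |>
    mutate(
      w = abs(ref[.data$atom]),
      score = .data$delta_sec / ref[.data$atom]
    )
  per_res <- sec |>
    group_by(.data$residue_number) |>
    summarise(
      raw = {
        ok <- is.finite(.data$score)
        if (!any(ok)) NA_real_ else sum(.data$w[ok] * .data$score[ok]) /
          sum(.data$w[ok])
      },
      .groups = "drop"
    ) |>
    arrange(.data$residue_number)

  half <- (window - 1L) %/% 2L
  n <- nrow(per_res)
  smoothed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    v <- per_res$raw[lo:hi]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  out <- tibble(
    residue_number = per_res$residue_number,
    propensity = pmin(pmax(smoothed, -1), 1)
  )
  attr(out, "window") <- window
  attr(out, "atoms_used") <- atoms
  out
}

#' Call contiguous helical segments from a propensity profile
#'
#' Returns the maximal runs of residues whose propensity meets `threshold`,
#' of length at least `min_len`. A single sub-threshold residue flanked on
#' both sides by passing residues is bridged into its run, so one noisy
#' residue cannot split a helix.
#'
#' @param profile Tibble (`residue_number`, `propensity`), e.g. from
#'   [helix_propensity()].
#' @param threshold Minimum propensity (default 0.5).
#' @param min_len Minimum segment length in residues (default 4).
#' @return A tibble of intervals: `first_residue`, `last_residue`, `length`,
#'   `mean_propensity`, in ascending order. Zero rows when nothing passes.
#' @export
detect_segments <- function(profile, threshold = 0.5, min_len = 4) {
  check_number(threshold, "threshold")
  check_number(min_len, "min_len", positive = TRUE, integerish = TRUE)
  prof <- profile |> arrange(.data$residue_number)
  pass <- !is.na(prof$propensity) & prof$propensity >= threshold
  n <- length(pass)
  if (n >= 3) {
    bridged <- pass
    # one-gap bridging: FALSE flanked by TRUE on both sides becomes TRUE
    mid <- which(!pass[2:(n - 1)]) + 1L
    mid <- mid[pass[mid - 1L] & pass[mid + 1L]]
    # contiguity in residue numbers, not just row order
    mid <- mid[prof$residue_number[mid + 1L] - prof$residue_number[mid - 1L] == 2L]
    bridged[mid] <- TRUE
    pass <- bridged
  }
  if (!any(pass)) {
    return(tibble(
      first_residue = integer(), last_residue = integer(),
      length = integer(), mean_propensity = numeric()
    ))
  }
  # split runs at numbering gaps
  grp <- cumsum(c(TRUE, diff(prof$residue_number) != 1L | diff(pass) != 0))
  segs <- tibble(
    residue_number = prof$residue_number,
    propensity = prof$propensity,
    pass = pass,
    grp = grp
  ) |>
    filter(.data$pass) |>
    group_by(.data$grp) |>
    summarise(
      first_residue = min(.data$residue_number),
      last_residue = max(.data$residue_number),
      length = dplyr::n(),
      mean_propensity = mean(.data$propensity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    filter(.data$length >= min_len) |>
    arrange(.data$first_residue) |>
    select(-"grp")
  segs
}
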