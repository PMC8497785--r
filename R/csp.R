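#' Exact two-state bound fraction
#'
#' Fraction of protein bound to ligand for a single-site interaction
#' `P + L <-> PL`, from total concentrations and the dissociation constant:
#' the physical root of the mass-balance quadratic,
#' `fb = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`.
#' `kd = 0` gives the stoichiometric limit `min(L / P, 1)`.
#'
#' @param protein_conc Total protein concentration (molar, > 0).
#' @param ligand_conc Total ligand concentration (molar, >= 0).
#' @param kd Dissociation constant (molar, >= 0).
#' @return Bound fraction in \[0, 1\] (vectorized over `ligand_conc`).
#' @export
bound_fraction <- function(protein_conc, ligand_conc, kd) {
  check_number(protein_conc, "protein_conc", positive = TRUE)
  if (any(ligand_conc < 0)) stop_idpnmr("`ligand_conc` must be >= 0")
  if (kd < 0) stop_idpnmr("`kd` must be >= 0")
  b <- protein_conc + ligand_conc + kd
  disc <- pmax(b^2 - 4 * protein_conc * ligand_conc, 0)
  pl <- (b - sqrt(disc)) / 2
  pmin(pmax(pl / protein_conc, 0), 1)
}

#' Gyromagnetically weighted chemical shift perturbation
#'
#' Combines amide 1H and 15N shift changes into a single perturbation,
#' down-weighting nitrogen for its smaller gyromagnetic ratio:
#' `sqrt(dh^2 + 0.1 * dn^2)`.
#'
#' @param dh 1H shift change (ppm).
#' @param dn 15N shift change (ppm).
#' @return Combined perturbation in ppm (vectorized).
#' @examples
#' csp(0.03, 0.2)
#' @export
csp <- function(dh, dn) {
  sqrt(dh^2 + 0.1 * dn^2)
}

#' Maximum chemical shift perturbation profile with significance
#'
#' For each residue, computes the weighted CSP of every non-apo titration
#' point relative to the apo peak position and keeps the maximum over the
#' series. A residue's perturbation is called significant when it exceeds
#' the standard deviation of the maximal CSPs over all computed residues
#' (population sd, zeros included).
#'
#' @param series Titration series tibble (`residue_number`,
#'   `condition_label`, `h_ppm`, `n_ppm`), apo condition required (ratio 0 /
#'   lowest `ratio` value, or condition label `"r0.0"`; see Details).
#' @param apo_label Condition label of the apo point; by default the
#'   condition with `ratio == 0` when a `ratio` column exists, otherwise the
#'   first condition in the tibble.
#' @param exclude Optional residue numbers to drop before computing the sd
#'   threshold (e.g. overlapped peaks); they still receive a `delta_max`.
#' @return A tibble (`residue_number`, `delta_max`, `significant`) with the
#'   scalar threshold attached both as column `threshold` and as attribute
#'   `"threshold"`. Residues missing their apo point are not computed.
#' @export
delta_max_profile <- function(series, apo_label = NULL, exclude = NULL) {
  conds <- unique(series$condition_label)
  if (length(conds) < 2) {
    stop_idpnmr("at least 2 conditions (apo + one titration point) required")
  }
  if (is.null(apo_label)) {
    apo_label <- if ("ratio" %in% names(series)) {
      lab <- series$condition_label[series$ratio == 0]
      if (length(lab) == 0) stop_idpnmr("no apo (ratio 0) condition present")
      lab[1]
    } else {
      conds[1]
    }
  }
  apo <- series |>
    filter(.data$condition_label == apo_label) |>
    select("residue_number", h0 = "h_ppm", n0 = "n_ppm")
  prof <- series |>
    filter(.data$condition_label != apo_label) |>
    left_join(apo, by = "residue_number") |>
    group_by(.data$residue_number) |>
    summarise(
      delta_max = {
        d <- csp(.data$h_ppm - .data$h0, .data$n_ppm - .data$n0)
        if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
      },
      .groups = "drop"
    )
  pool <- prof$delta_max[is.finite(prof$delta_max) &
                           !(prof$residue_number %in% exclude)]
  if (length(pool) == 0) {
    stop_idpnmr("no residue has a computed delta_max")
  }
  # population sd (ddof 0) over all computed residues, zeros included
  thr <- sqrt(mean((pool - mean(pool))^2))
  out <- prof |>
    mutate(
      significant = is.finite(.data$delta_max) & .data$delta_max > thr,
      threshold = thr
    )
  attr(out, "threshold") <- thr
  out
}

#' Normalized peak intensity profile at one titration point
#'
#' Divides each residue's intensity at the requested condition by the
#' average apo intensity over all residues (one scalar), so that the apo
#' profile has mean exactly 1 and the reference line is flat. The ratio of
#' each peak to its own apo intensity is reported as a secondary track.
#'
#' @inheritParams delta_max_profile
#' @param condition Condition label to profile.
#' @return A tibble: `residue_number`, `value` (intensity / apo average),
#'   `self_ratio` (intensity / own apo intensity).
#' @export
intensity_profile <- function(series, condition, apo_label = NULL) {
  if (!condition %in% series$condition_label) {
    stop_idpnmr("condition '", condition, "' not present in the series")
  }
  if (is.null(apo_label)) {
    apo_label <- if ("ratio" %in% names(series)) {
      lab <- series$condition_label[series$ratio == 0]
      if (length(lab) == 0) stop_idpnmr("no apo (ratio 0) condition present")
      lab[1]
    } else {
      unique(series$condition_label)[1]
    }
  }
  apo <- series |>
    filter(.data$condition_label == apo_label) |>
    select("residue_number", apo_intensity = "intensity")
  apo_avg <- mean(apo$apo_intensity, na.rm = TRUE)
  if (!is.finite(apo_avg) || apo_avg <= 0) {
    stop_idpnmr("average apo intensity must be positive")
  }
  series |>
    filter(.data$condition_label == condition) |>
    left_join(apo, by = "residue_number") |>
    mutate(
      value = .data$intensity / apo_avg,
      self_ratio = ifelse(
        is.finite(.data$apo_intensity) & .data$apo_intensity > 0,
        .data$intensity / .data$apo_intensity,
        NA_real_
      )
    ) |>
    select("residue_number", "value", "self_ratio")
}

#' Global fast-exchange Kd fit from a titration series
#'
#' Fits a shared dissociation constant and per-residue bound-state CSP
#' amplitudes to a titration under two-state fast exchange. The observed
#' perturbation of residue r at ligand:protein ratio x is modelled as
#' `csp_r(x) = fb(x; Kd) * B_r`, with `fb` the exact quadratic bound
#' fraction. For a trial Kd, the amplitudes `B_r` are profiled out by linear
#' least squares, leaving a one-dimensional optimization over log10(Kd).
#'
#' A titration whose shifts grow linearly with ligand (far from saturation)
#' carries no lower information on Kd: the fit is then flagged
#' non-identifiable and the Kd reported is a lower bound.
#'
#' @param series Titration series tibble with a numeric `ratio` column (as
#'   from [simulate_titration()]).
#' @param protein_conc Total protein concentration (molar).
#' @param candidate_residues Residues to fit; default: residues significant
#'   under [delta_max_profile()].
#' @param kd_range Search interval for Kd (molar).
#' @return An object of class `"kd_fit"` with components `kd`, `kd_sd`
#'   (profile-curvature estimate), `non_identifiable`, `bound_csp`
#'   (per-residue amplitudes), `residuals`, `rss`, `n_obs`. Methods:
#'   [tidy()], [glance()], `print()`, [ggplot2::autoplot()].
#' @export
fit_kd <- function(series, protein_conc, candidate_residues = NULL,
                   kd_range = c(1e-12, 1e-2)) {
  check_number(protein_conc, "protein_conc", positive = TRUE)
  if (!"ratio" %in% names(series)) {
    stop_idpnmr("`series` needs a numeric `ratio` column")
  }
  if (is.null(candidate_residues)) {
    prof <- delta_max_profile(series)
    candidate_residues <- prof$residue_number[prof$significant]
    if (length(candidate_residues) == 0) {
      stop_idpnmr("no significant residues to fit; supply `candidate_residues`")
    }
  }
  apo <- series |>
    filter(.data$ratio == 0) |>
    select("residue_number", h0 = "h_ppm", n0 = "n_ppm")
  obs <- series |>
    filter(.data$ratio > 0, .data$residue_number %in% candidate_residues) |>
    left_join(apo, by = "residue_number") |>
    mutate(y = csp(.data$h_ppm - .data$h0, .data$n_ppm - .data$n0)) |>
    filter(is.finite(.data$y))
  n_ratio <- length(unique(obs$ratio))
  n_res <- length(unique(obs$residue_number))
  if (n_ratio < 3 && n_res < 3) {
    stop_idpnmr(
      "need >= 3 non-apo conditions or a shared fit over >= 3 residues"
    )
  }
  ratios <- sort(unique(obs$ratio))

  rss_at <- function(log10kd) {
    fb <- bound_fraction(protein_conc, ratios * protein_conc, 10^log10kd)
    fbmap <- setNames(fb, as.character(ratios))
    o <- obs |> mutate(fb = fbmap[as.character(.data$ratio)])
    per <- o |>
      group_by(.data$residue_number) |>
      summarise(
        b = sum(.data$fb * .data$y) / sum(.data$fb^2),
        rss = sum((.data$y - .data$b * .data$fb)^2),
        .groups = "drop"
      )
    list(rss = sum(per$rss), b = per)
  }

  lo <- log10(kd_range[1]); hi <- log10(kd_range[2])
  opt <- optimize(function(l) rss_at(l)$rss, c(lo, hi), tol = 1e-10)
  l_hat <- opt$minimum
  kd_hat <- 10^l_hat
  best <- rss_at(l_hat)

  # curvature of the profile RSS in log10(Kd) -> approximate sd
  h <- 0.05
  curv <- (rss_at(l_hat + h)$rss - 2 * best$rss + rss_at(l_hat - h)$rss) / h^2
  dof <- max(nrow(obs) - n_res - 1L, 1L)
  sigma2 <- best$rss / dof
  kd_sd <- if (curv > 0 && sigma2 > 0) {
    kd_hat * log(10) * sqrt(2 * sigma2 / curv)
  } else {
    NA_real_
  }
  non_id <- l_hat <= lo + 0.05 || l_hat >= hi - 0.05 ||
    (is.finite(kd_sd) && kd_sd > 10 * kd_hat)

  fb_hat <- bound_fraction(protein_conc, ratios * protein_conc, kd_hat)
  fbmap <- setNames(fb_hat, as.character(ratios))
  resid_tbl <- obs |>
    left_join(best$b |> select("residue_number", "b"), by = "residue_number") |>
    mutate(
      fb = fbmap[as.character(.data$ratio)],
      fitted = .data$b * .data$fb,
      residual = .data$y - .data$fitted
    ) |>
    select("residue_number", "ratio", observed = "y", "fitted", "residual")

  structure(
    list(
      kd = kd_hat,
      kd_sd = kd_sd,
      non_identifiable = non_id,
      protein_conc = protein_conc,
      bound_csp = best$b |> rename(bound_csp = "b") |> select(-"rss"),
      residuals = resid_tbl,
      rss = best$rss,
      n_obs = nrow(obs),
      n_residues = n_res
    ),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(
    "<kd_fit> Kd = ", format(x$kd * 1e6, digits = 4), " uM",
    if (x$non_identifiable) " (lower bound; fit non-identifiable)" else "",
    "; ", x$n_residues, " residues, ", x$n_obs, " observations, RSS ",
    format(x$rss, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_kd
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @export
tidy.kd_fit <- function(x, ...) {
  x$bound_csp |> rename(estimate = "bound_csp") |>
    mutate(term = paste0("bound_csp_", .data$residue_number)) |>
    select("term", "estimate", "residue_number")
}

#' @rdname fit_kd
#' @export
glance.kd_fit <- function(x, ...) {
  tibble(
    kd = x$kd,
    kd_sd = x$kd_sd,
    non_identifiable = x$non_identifiable,
    rss = x$rss,
    n_obs = x$n_obs,
    n_residues = x$n_residues
  )
}
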