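#' Fit a monoexponential intensity decay
#'
#' Fits `I(t) = I0 * exp(-R * t)` to one residue's intensity series by
#' unweighted nonlinear least squares. Starting values come from a log-linear
#' regression on the positive intensities; negative noisy intensities are
#' kept in the nonlinear fit itself. The rate uncertainty is taken from the
#' fit covariance; a jackknife over delays is available as an alternative.
#'
#' @param delays Delay times in seconds, strictly increasing.
#' @param intensities Peak intensities, same length as `delays`; `NA` points
#'   are dropped before fitting.
#' @param uncertainty `"covariance"` (default) or `"jackknife"` (leave one
#'   delay out, scaled pseudo-sd).
#' @return A one-row tibble: `rate` (s^-1), `rate_sd`, `i0`, `converged`.
#'   A degenerate series (all intensities equal, or an optimizer failure)
#'   returns `converged = FALSE` rather than throwing.
#' @examples
#' d <- t1_delay_schedule()
#' fit_monoexponential(d, 1e6 * exp(-1.5 * d))
#' @export
fit_monoexponential <- function(delays, intensities,
                                uncertainty = c("covariance", "jackknife")) {
  uncertainty <- match.arg(uncertainty)
  if (length(delays) != length(intensities)) {
    stop_idpnmr("`delays` and `intensities` must have equal length")
  }
  if (is.unsorted(delays, strictly = TRUE)) {
    stop_idpnmr("`delays` must be strictly increasing")
  }
  ok <- is.finite(delays) & is.finite(intensities)
  t <- delays[ok]
  y <- intensities[ok]
  failed <- tibble(
    rate = NA_real_, rate_sd = NA_real_, i0 = NA_real_, converged = FALSE
  )
  if (length(t) < 3L) {
    stop_idpnmr("at least 3 finite points are required, found ", length(t))
  }
  if (diff(range(y)) == 0) {
    return(failed)
  }

  start <- loglinear_start(t, y)
  if (is.null(start)) {
    return(failed)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * exp(-rate * t),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(failed)
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 2))
  rate_sd <- unname(se["rate"])
  if (uncertainty == "jackknife" && length(t) >= 4L) {
    rates <- vapply(seq_along(t), function(k) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          y[-k] ~ i0 * exp(-rate * t[-k]),
          start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(f)) NA_real_ else unname(coef(f)["rate"])
    }, numeric(1))
    rates <- rates[is.finite(rates)]
    m <- length(rates)
    if (m >= 2L) {
      rate_sd <- sqrt((m - 1) / m * sum((rates - mean(rates))^2))
    }
  }
  tibble(
    rate = unname(est["rate"]),
    rate_sd = rate_sd,
    i0 = unname(est["i0"]),
    converged = is.finite(est["rate"]) && est["rate"] > 0
  )
}

loglinear_start <- function(t, y) {
  pos <- y > 0
  if (sum(pos) < 2L) {
    return(NULL)
  }
  sl <- lm(log(y[pos]) ~ t[pos])
  r0 <- -unname(coef(sl)[2])
  i00 <- exp(unname(coef(sl)[1]))
  if (!is.finite(r0) || !is.finite(i00)) {
    return(NULL)
  }
  list(i0 = i00, rate = max(r0, 1e-6))
}

#' Fit per-residue relaxation rates from a series tibble
#'
#' Applies [fit_monoexponential()] to every residue of a long-format
#' relaxation series (as produced by [simulate_relaxation()] or
#' [read_series()] plus a `delay_s` column). Residues with valid
#' measurements at fewer than half the delays are reported as not computed
#' (`converged = NA` row with `NA` rate) rather than fitted.
#'
#' @param series Series tibble with columns `residue_number`, `delay_s`,
#'   `intensity`.
#' @param uncertainty Passed to [fit_monoexponential()].
#' @return A tibble with one row per residue: `residue_number`, `rate`,
#'   `rate_sd`, `i0`, `converged`.
#' @export
fit_rates <- function(series, uncertainty = c("covariance", "jackknife")) {
  uncertainty <- match.arg(uncertainty)
  if (!all(c("residue_number", "delay_s", "intensity") %in% names(series))) {
    stop_idpnmr("`series` needs columns residue_number, delay_s, intensity")
  }
  n_delays <- length(unique(series$delay_s))
  series |>
    group_by(.data$residue_number) |>
    arrange(.data$delay_s, .by_group = TRUE) |>
    summarise(
      fit = list({
        keep <- is.finite(.data$intensity)
        if (sum(keep) < max(3L, ceiling(n_delays / 2))) {
          tibble(
            rate = NA_real_, rate_sd = NA_real_, i0 = NA_real_,
            converged = NA
          )
        } else {
          fit_monoexponential(
            .data$delay_s[keep], .data$intensity[keep],
            uncertainty = uncertainty
          )
        }
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest("fit")
}

#' Convert a rotating-frame rate to R2 with the tilt-angle correction
#'
#' The rotating-frame relaxation rate mixes longitudinal and transverse
#' relaxation according to the tilt of the effective field,
#' `R1rho = R1*cos(theta)^2 + R2*sin(theta)^2` with
#' `theta = arctan(omega1 / Omega)`. This inverts that relation:
#' `R2 = (R1rho - R1*cos(theta)^2) / sin(theta)^2`. On resonance
#' (`offset = 0`) theta is 90 degrees and R1rho is returned unchanged. The
#' sign of the offset is irrelevant. All frequency arguments are in Hz; the
#' units cancel inside the arctangent.
#'
#' @param r1rho Rotating-frame rate(s), s^-1.
#' @param r1 Longitudinal rate(s), s^-1.
#' @param omega1 Spin-lock field strength, Hz (> 0).
#' @param offset Offset(s) of the resonance from the spin-lock carrier, Hz.
#' @return R2 in s^-1 (vectorized over residues).
#' @examples
#' r2_from_r1rho(12, 1.5, 1400, 1400) # theta = 45 degrees -> 22.5
#' @export
r2_from_r1rho <- function(r1rho, r1, omega1, offset) {
  check_number(omega1, "omega1", positive = TRUE)
  theta <- atan2(omega1, abs(offset))
  s2 <- sin(theta)^2
  if (any(s2 < 1e-12, na.rm = TRUE)) {
    stop_idpnmr("offset too far off resonance: sin(theta)^2 below 1e-12")
  }
  (r1rho - r1 * cos(theta)^2) / s2
}

#' Heteronuclear NOE from a saturated/unsaturated intensity pair
#'
#' Computes the per-residue intensity ratio of the proton-saturated to the
#' unsaturated experiment. When intensity noise estimates are supplied, the
#' ratio's uncertainty follows from first-order error propagation:
#' `sd = |ratio| * sqrt((sd_sat/I_sat)^2 + (sd_unsat/I_unsat)^2)`.
#'
#' @param saturated,unsaturated Tibbles with columns `residue_number`,
#'   `intensity`, optionally `intensity_sd`.
#' @return A residue profile tibble: `residue_number`, `value` (the NOE),
#'   `sd`. Residues whose unsaturated intensity is not positive are marked
#'   not computed (`NA`).
#' @export
hetnoe_ratio <- function(saturated, unsaturated) {
  s <- saturated |>
    select("residue_number", sat = "intensity",
           dplyr::any_of(c(sat_sd = "intensity_sd")))
  u <- unsaturated |>
    select("residue_number", unsat = "intensity",
           dplyr::any_of(c(unsat_sd = "intensity_sd")))
  j <- dplyr::inner_join(s, u, by = "residue_number")
  if (nrow(j) == 0) {
    stop_idpnmr("no matched residues between the two experiments")
  }
  if (!"sat_sd" %in% names(j)) j$sat_sd <- NA_real_
  if (!"unsat_sd" %in% names(j)) j$unsat_sd <- NA_real_
  j |>
    mutate(
      computed = is.finite(.data$unsat) & .data$unsat > 0 & is.finite(.data$sat),
      value = ifelse(.data$computed, .data$sat / .data$unsat, NA_real_),
      sd = ifelse(
        .data$computed & is.finite(.data$sat_sd) & is.finite(.data$unsat_sd),
        abs(.data$value) * sqrt((.data$sat_sd / .data$sat)^2 +
                                  (.data$unsat_sd / .data$unsat)^2),
        NA_real_
      )
    ) |>
    select("residue_number", "value", "sd")
}

#' Summarise a residue profile over a region
#'
#' Arithmetic mean, standard deviation and count of a per-residue track over
#' a residue interval, ignoring residues whose value was not computed.
#'
#' @param profile A tibble with `residue_number` and a value column.
#' @param region `"all"` or `c(first, last)` in full-length numbering.
#' @param col Name of the value column; by default `"value"` if present,
#'   otherwise the first numeric column after `residue_number`.
#' @return A one-row tibble: `mean`, `sd`, `n`.
#' @examples
#' prof <- tibble::tibble(residue_number = 1:5, value = c(1, 2, 3, NA, 5))
#' profile_summary(prof, region = c(1, 3))
#' @export
profile_summary <- function(profile, region = "all", col = NULL) {
  if (is.null(col)) {
    col <- if ("value" %in% names(profile)) {
      "value"
    } else {
      cand <- setdiff(
        names(profile)[vapply(profile, is.numeric, logical(1))],
        "residue_number"
      )
      if (length(cand) == 0) stop_idpnmr("no numeric value column found")
      cand[1]
    }
  }
  keep <- region_filter(profile$residue_number, region)
  v <- profile[[col]][keep]
  v <- v[is.finite(v)]
  if (length(v) == 0) {
    stop_idpnmr("no computed residues in the requested region")
  }
  tibble(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v))
}
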