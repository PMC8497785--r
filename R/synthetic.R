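#' Relaxation delay schedules
#'
#' The interleaved delay schedules used for the 15N longitudinal (T1) and
#' rotating-frame (T1rho) relaxation experiments, in seconds.
#'
#' @return Numeric vector of delays (s), strictly increasing.
#' @export
t1_delay_schedule <- function() {
  c(40, 80, 200, 280, 300, 400, 600, 800) / 1000
}

#' @rdname t1_delay_schedule
#' @export
t1rho_delay_schedule <- function() {
  c(1, 21, 31, 41, 61, 81, 121, 161) / 1000
}

#' Ground truth for synthetic IDP NMR datasets
#'
#' Builds a residue-resolved ground-truth parameter set for a disordered
#' protein construct carrying one stable helix, one exchange-broadened
#' RGG-like segment, and one C-terminal RNA-binding segment. Defaults
#' reproduce the study conditions for the 189-400 construct: coil residues
#' relax with R1 = 1.5 s^-1, R2 = 9.6 s^-1, hetNOE = 0.4 while the helix
#' (289-299) has R1 = 1.2 s^-1, R2 = 22.5 s^-1, hetNOE = 0.75 and 85%
#' helical population; ligand-induced bound-state shift offsets are confined
#' to residues 383-398 and exchange broadening to the RGG box 366-386.
#'
#' Residue-specific quantities with no stated value (free peak positions,
#' spin-lock offsets, bound-shift magnitudes, the construct sequence when
#' none is supplied) are drawn reproducibly from `seed`. Drawing noise later
#' uses a separate seed, so two datasets simulated from the same truth with
#' different noise seeds share an identical noiseless component.
#'
#' @param first_residue,last_residue Construct bounds, full-length numbering.
#' @param sequence Optional one-letter sequence for the construct; when
#'   `NULL` a reproducible random sequence (no prolines) is drawn.
#' @param helix_segment,broadened_segment,binding_segment Residue intervals
#'   `c(first, last)` for the helix, the exchange-broadened segment and the
#'   segment carrying bound-state shift offsets.
#' @param r1_coil,r2_coil,noe_coil Relaxation parameters outside the helix
#'   (s^-1, s^-1, dimensionless).
#' @param r1_helix,r2_helix,noe_helix Relaxation parameters inside the helix.
#' @param helicity Helical population of the helix segment in \[0, 1\].
#' @param kd Ligand dissociation constant (molar).
#' @param extra_decay Exchange-broadening strength: peak intensities inside
#'   `broadened_segment` are multiplied by `exp(-extra_decay * fb)` where
#'   `fb` is the bound fraction.
#' @param noise_sd Intensity noise, as a fraction of the reference peak
#'   intensity.
#' @param max_offset_hz Half-width of the uniform spread of per-residue 15N
#'   offsets from the spin-lock carrier (Hz).
#' @param seed Integer seed for all residue-specific draws.
#'
#' @return An object of class `"synthetic_truth"`: scalar parameters plus a
#'   `residues` tibble (`residue_number`, `residue_type`, `r1`, `r2`,
#'   `hetnoe`, `h_free`, `n_free`, `offset_hz`, `dh_bound`, `dn_bound`,
#'   `extra_decay`).
#' @examples
#' truth <- synthetic_truth(seed = 7)
#' truth$residues
#' @export
synthetic_truth <- function(first_residue = 189,
                            last_residue = 400,
                            sequence = NULL,
                            helix_segment = c(289, 299),
                            broadened_segment = c(366, 386),
                            binding_segment = c(383, 398),
                            r1_coil = 1.5, r2_coil = 9.6, noe_coil = 0.4,
                            r1_helix = 1.2, r2_helix = 22.5, noe_helix = 0.75,
                            helicity = 0.85,
                            kd = 5e-7,
                            extra_decay = 2,
                            noise_sd = 0.01,
                            max_offset_hz = 700,
                            seed = 1L) {
  cons <- construct("synthetic", first_residue, last_residue, sequence)
  if (min(r1_coil, r1_helix) <= 0) stop_idpnmr("R1 must be > 0")
  if (r2_coil < r1_coil || r2_helix < r1_helix) {
    stop_idpnmr("R2 must be >= R1 for 15N backbone relaxation")
  }
  if (max(noe_coil, noe_helix) > 1) stop_idpnmr("hetNOE must be <= 1")
  if (kd < 0) stop_idpnmr("`kd` must be >= 0")
  if (noise_sd < 0) stop_idpnmr("`noise_sd` must be >= 0")
  if (helicity < 0 || helicity > 1) stop_idpnmr("`helicity` must be in [0, 1]")

  resnum <- seq.int(cons$first_residue, cons$last_residue)
  in_helix <- region_filter(resnum, helix_segment)
  in_broad <- region_filter(resnum, broadened_segment)
  in_bind <- region_filter(resnum, binding_segment)

  res <- with_local_seed(seed, {
    type <- if (is.null(cons$sequence)) {
      # prolines carry no amide and would only punch holes in every track
      sample(setdiff(coil_shifts()$residue_type, "P"), cons$n_residues,
             replace = TRUE)
    } else {
      strsplit(cons$sequence, "")[[1]]
    }
    tibble(
      residue_number = resnum,
      residue_type = type,
      r1 = ifelse(in_helix, r1_helix, r1_coil),
      r2 = ifelse(in_helix, r2_helix, r2_coil),
      hetnoe = ifelse(in_helix, noe_helix, noe_coil),
      h_free = runif(cons$n_residues, 7.8, 8.6),
      n_free = runif(cons$n_residues, 110, 125),
      offset_hz = runif(cons$n_residues, -max_offset_hz, max_offset_hz),
      dh_bound = ifelse(
        in_bind,
        sample(c(-1, 1), cons$n_residues, replace = TRUE) *
          runif(cons$n_residues, 0.03, 0.12),
        0
      ),
      dn_bound = ifelse(
        in_bind,
        sample(c(-1, 1), cons$n_residues, replace = TRUE) *
          runif(cons$n_residues, 0.15, 0.6),
        0
      ),
      extra_decay = ifelse(in_broad, extra_decay, 0)
    )
  })

  structure(
    list(
      construct = cons,
      residues = res,
      helix_segment = helix_segment,
      broadened_segment = broadened_segment,
      binding_segment = binding_segment,
      helicity = helicity,
      kd = kd,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(
    "<synthetic_truth> residues ", x$construct$first_residue, "-",
    x$construct$last_residue,
    "; helix ", x$helix_segment[1], "-", x$helix_segment[2],
    " (helicity ", x$helicity, ")",
    "; Kd ", format(x$kd), " M; noise_sd ", x$noise_sd,
    "; seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

delay_label <- function(delay_s) {
  sprintf("t%03dms", as.integer(round(1000 * delay_s)))
}

#' Simulate a relaxation intensity series
#'
#' Generates per-residue peak intensities decaying monoexponentially across a
#' delay schedule. For a T1 experiment the effective rate is R1; for a T1rho
#' experiment it is the tilted-frame mixture
#' `R1*cos(theta)^2 + R2*sin(theta)^2` with `theta = arctan(omega1 / Omega)`,
#' where `omega1` is the spin-lock field strength and `Omega` the residue's
#' offset from the spin-lock carrier. Gaussian noise with standard deviation
#' `truth$noise_sd * i0` is added to every intensity.
#'
#' @param truth A [synthetic_truth()].
#' @param delays Delay schedule in seconds, strictly positive; defaults to
#'   the experiment's standard schedule.
#' @param experiment `"T1"` or `"T1rho"`.
#' @param omega1 Spin-lock field strength in Hz (T1rho only; default 1400).
#' @param offsets Per-residue offsets from the carrier in Hz (T1rho only);
#'   defaults to the truth's reproducible offsets.
#' @param i0 Reference (zero-delay) intensity.
#' @param seed Seed for the noise draw; defaults to the truth's seed.
#'
#' @return A series tibble (`residue_number`, `condition_label`, `h_ppm`,
#'   `n_ppm`, `intensity`) with extra columns `delay_s` and, for T1rho,
#'   `offset_hz`; attribute `"experiment"` records the experiment type.
#'   Writable as-is with [write_series()].
#' @export
simulate_relaxation <- function(truth,
                                delays = NULL,
                                experiment = c("T1", "T1rho"),
                                omega1 = 1400,
                                offsets = NULL,
                                i0 = 1e6,
                                seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  experiment <- match.arg(experiment)
  if (is.null(delays)) {
    delays <- if (experiment == "T1") t1_delay_schedule() else t1rho_delay_schedule()
  }
  if (any(delays <= 0)) {
    stop_idpnmr("all delays must be strictly positive")
  }
  res <- truth$residues
  if (experiment == "T1rho") {
    check_number(omega1, "omega1", positive = TRUE)
    offsets <- offsets %||% res$offset_hz
    if (length(offsets) != nrow(res)) {
      stop_idpnmr("`offsets` must supply one value per residue")
    }
    theta <- atan2(omega1, abs(offsets))
    r_eff <- res$r1 * cos(theta)^2 + res$r2 * sin(theta)^2
  } else {
    offsets <- rep(NA_real_, nrow(res))
    r_eff <- res$r1
  }

  grid <- tidyr::expand_grid(
    residue_number = res$residue_number,
    delay_s = delays
  )
  grid <- grid |>
    left_join(
      tibble(
        residue_number = res$residue_number,
        r_eff = r_eff,
        h_ppm = res$h_free,
        n_ppm = res$n_free,
        offset_hz = offsets
      ),
      by = "residue_number"
    ) |>
    mutate(clean = i0 * exp(-.data$r_eff * .data$delay_s))
  noise <- with_local_seed(seed, rnorm(nrow(grid), 0, truth$noise_sd * i0))
  out <- grid |>
    mutate(
      condition_label = delay_label(.data$delay_s),
      intensity = .data$clean + noise
    ) |>
    select(
      "residue_number", "condition_label", "h_ppm", "n_ppm", "intensity",
      "delay_s", "offset_hz"
    )
  if (experiment == "T1") {
    out$offset_hz <- NULL
  }
  attr(out, "experiment") <- experiment
  if (experiment == "T1rho") attr(out, "omega1") <- omega1
  out
}

#' Simulate a heteronuclear NOE experiment pair
#'
#' Produces the two interleaved intensity tables of a 1H-15N heteronuclear
#' NOE measurement: with and without proton saturation. Before noise, the
#' saturated intensity is `hetNOE * unsaturated`.
#'
#' @inheritParams simulate_relaxation
#' @param noise_sd Fractional intensity noise; defaults to the truth's.
#' @return A list with series tibbles `saturated` and `unsaturated`.
#' @export
simulate_hetnoe <- function(truth, noise_sd = truth$noise_sd, i0 = 1e6,
                            seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (noise_sd < 0) stop_idpnmr("`noise_sd` must be >= 0")
  res <- truth$residues
  n <- nrow(res)
  noise <- with_local_seed(seed, rnorm(2L * n, 0, noise_sd * i0))
  mk <- function(label, clean, eps) {
    tibble(
      residue_number = res$residue_number,
      condition_label = label,
      h_ppm = res$h_free,
      n_ppm = res$n_free,
      intensity = clean + eps
    )
  }
  list(
    unsaturated = mk("unsat", rep(i0, n), noise[seq_len(n)]),
    saturated = mk("sat", res$hetnoe * i0, noise[n + seq_len(n)])
  )
}

#' Simulate a fast-exchange ligand titration
#'
#' Generates an HSQC titration series under two-state fast exchange: at each
#' ligand:protein ratio the observed peak position is the population-weighted
#' average `free + fb * bound_offset`, with the bound fraction `fb` given by
#' the exact quadratic solution of the binding mass balance (see
#' [bound_fraction()]). Inside the truth's broadened segment, intensities
#' additionally lose `exp(-extra_decay * fb)`, a phenomenological model of
#' intermediate-exchange broadening.
#'
#' @inheritParams simulate_relaxation
#' @param protein_conc Total protein concentration (molar).
#' @param ratios Ligand:protein ratios, non-negative and ascending; must
#'   include 0 (the apo point).
#' @param shift_noise_sd Gaussian noise added to both 1H and 15N peak
#'   positions (ppm); 0 disables it.
#' @param intensity_noise_sd Fractional intensity noise; defaults to the
#'   truth's `noise_sd`.
#' @return A series tibble with one condition per ratio (labels `"r0.0"`,
#'   `"r0.4"`, ...), plus a numeric `ratio` column.
#' @export
simulate_titration <- function(truth,
                               protein_conc = 50e-6,
                               ratios = c(0, 2, 4, 6, 8) / 5,
                               shift_noise_sd = 0,
                               intensity_noise_sd = truth$noise_sd,
                               i0 = 1e6,
                               seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_number(protein_conc, "protein_conc", positive = TRUE)
  if (any(ratios < 0)) stop_idpnmr("ratios must be non-negative")
  if (is.unsorted(ratios, strictly = TRUE)) {
    stop_idpnmr("ratios must be strictly ascending")
  }
  if (!any(ratios == 0)) {
    stop_idpnmr("the apo point (ratio 0) must be included")
  }
  res <- truth$residues
  fb <- vapply(
    ratios,
    function(r) bound_fraction(protein_conc, r * protein_conc, truth$kd),
    numeric(1)
  )
  grid <- tidyr::expand_grid(
    residue_number = res$residue_number,
    ratio = ratios
  ) |>
    left_join(
      res |>
        select(
          "residue_number", "h_free", "n_free", "dh_bound", "dn_bound",
          "extra_decay"
        ),
      by = "residue_number"
    ) |>
    left_join(tibble(ratio = ratios, fb = fb), by = "ratio")
  nr <- nrow(grid)
  noise <- with_local_seed(seed, {
    list(
      h = rnorm(nr, 0, shift_noise_sd),
      n = rnorm(nr, 0, shift_noise_sd),
      i = rnorm(nr, 0, intensity_noise_sd * i0)
    )
  })
  grid |>
    mutate(
      condition_label = sprintf("r%.1f", .data$ratio),
      h_ppm = .data$h_free + .data$fb * .data$dh_bound + noise$h,
      n_ppm = .data$n_free + .data$fb * .data$dn_bound + noise$n,
      intensity = i0 * exp(-.data$extra_decay * .data$fb) + noise$i
    ) |>
    select(
      "residue_number", "condition_label", "h_ppm", "n_ppm", "intensity",
      "ratio"
    )
}

#' Simulate an assigned chemical shift table
#'
#' Builds per-residue backbone shifts from a random-coil reference: coil
#' residues take the reference values, helix residues additionally receive
#' the canonical full-helix secondary-shift offsets (CA +2.8, CB -0.5,
#' C +1.8, HA -0.3 ppm) scaled by the truth's helical population.
#'
#' @inheritParams simulate_relaxation
#' @param coil_table Random-coil reference, as from [coil_shifts()].
#' @param jitter_ppm Gaussian jitter applied to the heavy-atom shifts
#'   (one tenth of it to 1H shifts); 0 gives the exact noiseless table.
#' @return A wide shift tibble (`residue_number`, `residue_type`, `CA`,
#'   `CB`, `C`, `HA`, `H`, `N`).
#' @export
simulate_shift_table <- function(truth,
                                 coil_table = coil_shifts(),
                                 jitter_ppm = 0,
                                 seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (jitter_ppm < 0) stop_idpnmr("`jitter_ppm` must be >= 0")
  res <- truth$residues
  out <- res |>
    select("residue_number", "residue_type") |>
    left_join(coil_table, by = "residue_type")
  if (anyNA(match(res$residue_type, coil_table$residue_type))) {
    stop_idpnmr("coil table does not cover all residue types present")
  }
  in_helix <- region_filter(out$residue_number, truth$helix_segment)
  ref <- helix_reference_shifts()
  for (atom in names(ref)) {
    out[[atom]] <- out[[atom]] + ifelse(in_helix, truth$helicity * ref[[atom]], 0)
  }
  if (jitter_ppm > 0) {
    heavy <- c("CA", "CB", "C", "N")
    light <- c("HA", "H")
    jit <- with_local_seed(seed, {
      rnorm(nrow(out) * 6L)
    })
    jm <- matrix(jit, nrow = nrow(out))
    for (k in seq_along(heavy)) {
      out[[heavy[k]]] <- out[[heavy[k]]] + jitter_ppm * jm[, k]
    }
    for (k in seq_along(light)) {
      out[[light[k]]] <- out[[light[k]]] + jitter_ppm / 10 * jm[, 4L + k]
    }
  }
  out |> select("residue_number", "residue_type", "CA", "CB", "C", "HA", "H", "N")
}
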