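test_that("noiseless monoexponential decays are fitted to high precision", {
  d <- t1_delay_schedule()
  fit <- fit_monoexponential(d, 1e6 * exp(-1.5 * d))
  expect_true(fit$converged)
  expect_equal(fit$rate, 1.5, tolerance = 1e-7)
  expect_equal(fit$i0, 1e6, tolerance = 1e-6)
})

test_that("degenerate and invalid decay inputs are handled as specified", {
  d <- t1_delay_schedule()
  flat <- fit_monoexponential(d, rep(5e5, length(d)))
  expect_false(flat$converged)

  expect_error(fit_monoexponential(c(0.1, 0.2), c(2, 1)), "3 finite points")
  expect_error(fit_monoexponential(c(0.2, 0.1, 0.3), c(3, 2, 1)), "increasing")
})

test_that("fitted rates are invariant to uniform intensity rescaling", {
  d <- t1rho_delay_schedule()
  y <- 3e5 * exp(-9.6 * d) * (1 + 0.01 * sin(seq_along(d)))
  f1 <- fit_monoexponential(d, y)
  f2 <- fit_monoexponential(d, 1e3 * y)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-9)
})

test_that("on noiseless data the fitted rate is independent of the delay subset", {
  d <- t1_delay_schedule()
  y <- 1e6 * exp(-2.2 * d)
  withr::with_seed(2, {
    for (i in 1:10) {
      keep <- sort(sample(seq_along(d), sample(3:8, 1)))
      fit <- fit_monoexponential(d[keep], y[keep])
      expect_equal(fit$rate, 2.2, tolerance = 1e-6)
    }
  })
})

test_that("the tilt-angle inversion recovers R2 from the forward model", {
  # on-resonance limit: R1rho is R2 already
  expect_equal(r2_from_r1rho(12, 1.5, 1400, 0), 12)
  # 45-degree tilt: R2 = 2*R1rho - R1
  expect_equal(r2_from_r1rho(12, 1.5, 1400, 1400), 22.5)
  expect_error(r2_from_r1rho(12, 1.5, -5, 0), "positive")

  withr::with_seed(3, {
    for (i in 1:50) {
      r1 <- runif(1, 0.5, 3)
      r2 <- runif(1, r1, 30)
      om <- runif(1, -700, 700)
      theta <- atan2(1400, abs(om))
      fwd <- r1 * cos(theta)^2 + r2 * sin(theta)^2
      expect_equal(r2_from_r1rho(fwd, r1, 1400, om), r2, tolerance = 1e-12)
    }
  })
})

test_that("per-residue rate fitting recovers synthetic truth within noise", {
  tr <- synthetic_truth(
    first_residue = 1, last_residue = 80,
    helix_segment = c(61, 80),
    noise_sd = 0.01, seed = 21
  )
  t1 <- simulate_relaxation(tr, experiment = "T1", seed = 77)
  r1 <- fit_rates(t1)
  expect_true(all(r1$converged))
  err <- abs(r1$rate - tr$residues$r1) / tr$residues$r1
  expect_lt(median(err), 0.02)

  t1r <- simulate_relaxation(tr, experiment = "T1rho", seed = 78)
  r1rho <- fit_rates(t1r)
  offsets <- dplyr::distinct(t1r, residue_number, offset_hz)
  r2 <- r2_from_r1rho(
    r1rho$rate, r1$rate, 1400,
    offsets$offset_hz[match(r1rho$residue_number, offsets$residue_number)]
  )
  expect_lt(median(abs(r2 - tr$residues$r2) / tr$residues$r2), 0.02)
})

test_that("residues with too many missing delays are reported not computed", {
  d <- t1_delay_schedule()
  ser <- tidyr::expand_grid(residue_number = 1:2, delay_s = d) |>
    dplyr::mutate(intensity = 1e6 * exp(-1.5 * delay_s))
  ser$intensity[ser$residue_number == 2][1:6] <- NA
  out <- fit_rates(ser)
  expect_true(out$converged[out$residue_number == 1])
  expect_true(is.na(out$rate[out$residue_number == 2]))
})

test_that("hetNOE ratios and propagated uncertainties behave as expected", {
  sat <- tibble::tibble(residue_number = 1:5, intensity = rep(1e6, 5))
  expect_equal(hetnoe_ratio(sat, sat)$value, rep(1, 5))

  sat04 <- dplyr::mutate(sat, intensity = 0.4 * intensity)
  expect_equal(hetnoe_ratio(sat04, sat)$value, rep(0.4, 5))

  # first-order propagation: sd = |r| sqrt((s_s/I_s)^2 + (s_u/I_u)^2)
  sat_sd <- dplyr::mutate(sat04, intensity_sd = 1e4)
  unsat_sd <- dplyr::mutate(sat, intensity_sd = 2e4)
  out <- hetnoe_ratio(sat_sd, unsat_sd)
  expect_equal(
    out$sd,
    rep(0.4 * sqrt((1e4 / 4e5)^2 + (2e4 / 1e6)^2), 5)
  )

  # non-positive unsaturated intensity marks the residue not computed
  bad_unsat <- sat
  bad_unsat$intensity[3] <- 0
  out2 <- hetnoe_ratio(sat04, bad_unsat)
  expect_true(is.na(out2$value[3]))
  expect_equal(sum(is.na(out2$value)), 1)
})

test_that("noisy synthetic hetNOE recovers the helix step within its spread", {
  tr <- synthetic_truth(
    first_residue = 1, last_residue = 100, helix_segment = c(41, 60),
    noe_coil = 0.4, noe_helix = 0.75, noise_sd = 0.01, seed = 31
  )
  pair <- simulate_hetnoe(tr, seed = 32)
  prof <- hetnoe_ratio(pair$saturated, pair$unsaturated)
  helix_mean <- profile_summary(prof, region = c(41, 60))$mean
  coil_mean <- profile_summary(prof, region = c(1, 40))$mean
  expect_equal(helix_mean, 0.75, tolerance = 0.02)
  expect_equal(coil_mean, 0.4, tolerance = 0.02)
})

test_that("profile summaries aggregate computed residues over regions", {
  prof <- tibble::tibble(residue_number = 1:10, value = rep(1.5, 10))
  s <- profile_summary(prof)
  expect_equal(s$mean, 1.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 10)

  expect_error(profile_summary(prof, region = c(50, 60)), "no computed residues")
  expect_error(profile_summary(prof, region = c(6, 2)), "region")
})
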