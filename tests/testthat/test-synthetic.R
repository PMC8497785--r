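test_that("noiseless T1 decays are exactly monoexponential at the standard schedule", {
  tr <- tiny_truth(r1_coil = 1.5, r1_helix = 1.5, r2_coil = 9.6, r2_helix = 9.6)
  s <- simulate_relaxation(tr, experiment = "T1", i0 = 1e6)
  one <- s[s$residue_number == 5, ]
  expect_equal(one$intensity, 1e6 * exp(-1.5 * t1_delay_schedule()), tolerance = 1e-12)
})

test_that("the T1rho effective rate follows the tilt-angle mixture", {
  tr <- tiny_truth()
  r1 <- tr$residues$r1[1]
  r2 <- tr$residues$r2[1]
  delays <- t1rho_delay_schedule()

  # on resonance: theta = 90 degrees, pure R2
  s0 <- simulate_relaxation(
    tr, experiment = "T1rho", omega1 = 1400,
    offsets = rep(0, nrow(tr$residues))
  )
  one <- s0[s0$residue_number == tr$residues$residue_number[1], ]
  expect_equal(one$intensity, 1e6 * exp(-r2 * delays), tolerance = 1e-12)

  # offset equal to the field: theta = 45 degrees, rate (R1 + R2) / 2
  s45 <- simulate_relaxation(
    tr, experiment = "T1rho", omega1 = 1400,
    offsets = rep(1400, nrow(tr$residues))
  )
  one45 <- s45[s45$residue_number == tr$residues$residue_number[1], ]
  expect_equal(
    one45$intensity, 1e6 * exp(-(r1 + r2) / 2 * delays),
    tolerance = 1e-12
  )

  expect_error(simulate_relaxation(tr, delays = c(-0.1, 0.2)), "positive")
})

test_that("hetNOE simulation scales the saturated experiment by the NOE", {
  tr_flat <- tiny_truth(noe_coil = 1, noe_helix = 1)
  pair <- simulate_hetnoe(tr_flat, noise_sd = 0)
  expect_equal(pair$saturated$intensity, pair$unsaturated$intensity)

  tr04 <- tiny_truth(noe_coil = 0.4, noe_helix = 0.4)
  pair04 <- simulate_hetnoe(tr04, noise_sd = 0)
  expect_equal(
    pair04$saturated$intensity / pair04$unsaturated$intensity,
    rep(0.4, nrow(tr04$residues))
  )

  # NOE raised only inside the helix: the ratio profile steps at its bounds
  tr_step <- tiny_truth(noe_coil = 0.4, noe_helix = 0.75)
  ratio <- with(simulate_hetnoe(tr_step, noise_sd = 0), {
    saturated$intensity / unsaturated$intensity
  })
  resnum <- tr_step$residues$residue_number
  in_helix <- resnum >= 21 & resnum <= 31
  expect_equal(unique(ratio[in_helix]), 0.75)
  expect_equal(unique(ratio[!in_helix]), 0.4)
})

test_that("titration shifts follow the exact two-state bound fraction", {
  tr <- tiny_truth(kd = 0)
  s <- simulate_titration(tr, protein_conc = 50e-6, intensity_noise_sd = 0)
  top <- s[s$ratio == 1.6, ]
  res <- tr$residues
  # stoichiometric limit: fb = 1, observed = free + full bound offset
  expect_equal(top$h_ppm, res$h_free + res$dh_bound, tolerance = 1e-12)
  expect_equal(top$n_ppm, res$n_free + res$dn_bound, tolerance = 1e-12)
  apo <- s[s$ratio == 0, ]
  expect_equal(apo$h_ppm, res$h_free)
  expect_equal(apo$n_ppm, res$n_free)

  expect_error(simulate_titration(tr, protein_conc = -1), "positive")
  expect_error(
    simulate_titration(tr, ratios = c(0.4, 0.8)), "apo"
  )
})

test_that("the quadratic bound fraction matches a bisection mass-balance oracle", {
  expect_equal(
    bound_fraction(50e-6, 80e-6, 1e-6),
    oracle_bound_fraction(50e-6, 80e-6, 1e-6),
    tolerance = 1e-8
  )
  withr::with_seed(5, {
    for (i in 1:25) {
      p <- runif(1, 1e-6, 2e-4)
      l <- runif(1, 0, 4e-4)
      kd <- 10^runif(1, -8, -4)
      expect_equal(
        bound_fraction(p, l, kd),
        oracle_bound_fraction(p, l, kd),
        tolerance = 1e-7
      )
    }
  })
})

test_that("synthetic shift tables carry the canonical helix offsets", {
  tr0 <- tiny_truth(helicity = 0)
  tab0 <- simulate_shift_table(tr0)
  coil <- coil_shifts()
  expected_ca <- coil$CA[match(tab0$residue_type, coil$residue_type)]
  expect_equal(tab0$CA, expected_ca)

  tr1 <- tiny_truth(helicity = 1)
  tab1 <- simulate_shift_table(tr1)
  in_helix <- tab1$residue_number >= 21 & tab1$residue_number <= 31
  expect_equal(unique(tab1$CA[in_helix] - expected_ca[in_helix]), 2.8)
  expect_equal(tab1$CA[!in_helix], expected_ca[!in_helix])
})

test_that("generation is seed-deterministic with a seed-independent noiseless part", {
  tr <- synthetic_truth(
    first_residue = 1, last_residue = 40, noise_sd = 0.02, seed = 9
  )
  a <- simulate_relaxation(tr, experiment = "T1", seed = 100)
  b <- simulate_relaxation(tr, experiment = "T1", seed = 100)
  expect_identical(a, b)

  c2 <- simulate_relaxation(tr, experiment = "T1", seed = 101)
  expect_false(identical(a$intensity, c2$intensity))

  # different noise seeds share the identical noiseless component
  tr0 <- synthetic_truth(
    first_residue = 1, last_residue = 40, noise_sd = 0, seed = 9
  )
  clean <- simulate_relaxation(tr0, experiment = "T1", seed = 100)
  clean2 <- simulate_relaxation(tr0, experiment = "T1", seed = 101)
  expect_equal(clean$intensity, clean2$intensity)
})

test_that("simulated series are readable by the io layer without modification", {
  tr <- tiny_truth()
  s <- simulate_titration(tr, intensity_noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(s, path)
  back <- read_series(path)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$h_ppm, round(s$h_ppm, 6))
})
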