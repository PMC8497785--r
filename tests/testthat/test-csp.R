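test_that("the weighted CSP matches hand arithmetic and its invariances", {
  expect_identical(csp(0, 0), 0)
  expect_equal(csp(0.1, 0), 0.1, tolerance = 1e-12)
  # sqrt(0.03^2 + 0.1 * 0.2^2) = sqrt(0.0049) = 0.07
  expect_equal(csp(0.03, 0.2), 0.07, tolerance = 1e-12)

  withr::with_seed(8, {
    dh <- rnorm(20, 0, 0.1)
    dn <- rnorm(20, 0, 0.5)
    a <- runif(20, -3, 3)
    expect_equal(csp(-dh, dn), csp(dh, dn))
    expect_equal(csp(dh, -dn), csp(dh, dn))
    expect_equal(csp(a * dh, a * dn), abs(a) * csp(dh, dn))
  })
})

make_static_series <- function(n_res = 10, shift_res = NULL, dh = 0.12) {
  tidyr::expand_grid(
    residue_number = seq_len(n_res),
    ratio = c(0, 0.4, 0.8, 1.2, 1.6)
  ) |>
    dplyr::mutate(
      condition_label = sprintf("r%.1f", ratio),
      h_ppm = 8.2 + ifelse(
        residue_number %in% shift_res & ratio > 0, dh * ratio / 1.6, 0
      ),
      n_ppm = 118,
      intensity = 1e6
    )
}

test_that("a static titration yields zero delta_max and no significant residues", {
  prof <- delta_max_profile(make_static_series())
  expect_equal(prof$delta_max, rep(0, 10))
  expect_false(any(prof$significant))
})

test_that("one moving residue among many static ones is called significant", {
  ser <- make_static_series(n_res = 100, shift_res = 42, dh = 0.12)
  prof <- delta_max_profile(ser)
  # direct sd computation: population sd of 99 zeros and one 0.12
  vals <- c(rep(0, 99), 0.12)
  expect_equal(
    attr(prof, "threshold"),
    sqrt(mean((vals - mean(vals))^2)),
    tolerance = 1e-12
  )
  expect_identical(which(prof$significant), 42L)
})

test_that("delta_max is invariant to condition ordering and peaks at saturation", {
  tr <- tiny_truth()
  ser <- simulate_titration(tr, intensity_noise_sd = 0)
  prof <- delta_max_profile(ser)
  shuffled <- ser[sample(nrow(ser)), ]
  prof2 <- delta_max_profile(shuffled)
  expect_equal(
    prof2[order(prof2$residue_number), ]$delta_max,
    prof[order(prof$residue_number), ]$delta_max
  )

  # for a saturating noiseless titration the maximum sits at the top ratio
  apo <- dplyr::filter(ser, ratio == 0)
  top <- dplyr::filter(ser, ratio == 1.6) |>
    dplyr::left_join(
      dplyr::select(apo, residue_number, h0 = h_ppm, n0 = n_ppm),
      by = "residue_number"
    ) |>
    dplyr::mutate(d = csp(h_ppm - h0, n_ppm - n0))
  expect_equal(prof$delta_max, top$d[match(prof$residue_number, top$residue_number)])
})

test_that("significant residues on noiseless data stay inside the binding segment", {
  tr <- tiny_truth()
  ser <- simulate_titration(tr, intensity_noise_sd = 0)
  prof <- delta_max_profile(ser)
  sig <- prof$residue_number[prof$significant]
  expect_gt(length(sig), 0)
  expect_true(all(sig >= 45 & sig <= 55))
})

test_that("intensity profiles are normalized to the apo average", {
  tr <- tiny_truth()
  ser <- simulate_titration(tr, intensity_noise_sd = 0)
  apo_prof <- intensity_profile(ser, "r0.0")
  expect_equal(mean(apo_prof$value), 1, tolerance = 1e-12)

  half <- dplyr::mutate(
    make_static_series(),
    intensity = ifelse(ratio > 0, 5e5, 1e6)
  )
  prof <- intensity_profile(half, "r1.6")
  expect_equal(prof$value, rep(0.5, 10))
  expect_equal(prof$self_ratio, rep(0.5, 10))

  # exchange broadening depresses the RGG-like segment below the rest
  top <- intensity_profile(ser, "r1.6")
  in_seg <- top$residue_number >= 41 & top$residue_number <= 50
  expect_true(all(top$value[in_seg] < median(top$value[!in_seg])))
  wt <- stats::wilcox.test(top$value[in_seg], top$value[!in_seg],
                           alternative = "less")
  expect_lt(wt$p.value, 1e-4)
})

test_that("the global fast-exchange fit recovers Kd", {
  tr <- tiny_truth(kd = 5e-6)
  ser <- simulate_titration(tr, protein_conc = 50e-6, intensity_noise_sd = 0)
  fit <- fit_kd(ser, protein_conc = 50e-6)
  expect_s3_class(fit, "kd_fit")
  expect_equal(fit$kd, 5e-6, tolerance = 0.01)
  expect_false(fit$non_identifiable)

  g <- glance(fit)
  expect_equal(g$kd, fit$kd)
  td <- tidy(fit)
  expect_true(all(td$residue_number %in% 45:55))

  # stoichiometric limit: the estimate collapses to (numerically) zero Kd
  tr0 <- tiny_truth(kd = 0)
  ser0 <- simulate_titration(tr0, protein_conc = 50e-6, intensity_noise_sd = 0)
  fit0 <- fit_kd(ser0, protein_conc = 50e-6)
  expect_lt(fit0$kd, 1e-7)
})

test_that("shuffling condition labels degrades the Kd fit residuals", {
  tr <- tiny_truth(kd = 5e-6)
  ser <- simulate_titration(tr, protein_conc = 50e-6, intensity_noise_sd = 0)
  fit <- fit_kd(ser, protein_conc = 50e-6)

  shuffled <- ser |>
    dplyr::group_by(residue_number) |>
    dplyr::mutate(
      h_ppm = h_ppm[c(3, 5, 1, 4, 2)],
      n_ppm = n_ppm[c(3, 5, 1, 4, 2)]
    ) |>
    dplyr::ungroup()
  fit_bad <- fit_kd(
    shuffled, protein_conc = 50e-6,
    candidate_residues = fit$bound_csp$residue_number
  )
  expect_gt(fit_bad$rss, 100 * fit$rss)
})
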