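test_that("the IDP polymer scaling law matches its closed form", {
  expect_equal(rh_idp(1), 2.49)
  expect_equal(rh_idp_nm(212), 3.8)
  # direct high-precision evaluation for the 252-residue construct
  expect_equal(rh_idp(252), 2.49 * exp(0.509 * log(252)), tolerance = 1e-12)
  expect_error(rh_idp(0), ">= 1")
  expect_error(rh_idp(2.5), ">= 1")

  n <- 1:500
  expect_true(all(diff(rh_idp(n)) > 0))

  hs <- hydro_summary(212, rh_measured = 34)
  expect_equal(hs$compaction_ratio, 34 / rh_idp(212))
})

test_that("sequence molecular weights follow the average-mass table", {
  expect_equal(mw_from_sequence("G"), 75.07, tolerance = 1e-3)
  expect_equal(mw_from_sequence("GG"), 132.12, tolerance = 1e-3)
  expect_error(mw_from_sequence(""), "non-empty")
  expect_error(mw_from_sequence("GXZ"), "unknown amino-acid")
})

test_that("SEC calibration reproduces its standards and recovers a line", {
  cal <- sec_calibrate(data.frame(ml = c(14.7, 13.3), mw = c(51.6e3, 95.9e3)))
  expect_equal(sec_predict(cal, 14.7), 51.6e3, tolerance = 1e-9)
  expect_equal(sec_predict(cal, 13.3), 95.9e3, tolerance = 1e-9)

  # three exactly collinear points: slope and intercept recovered
  slope <- -0.19
  intercept <- 7.5
  ml <- c(10, 12, 15)
  cal3 <- sec_calibrate(data.frame(ml = ml, mw = 10^(intercept + slope * ml)))
  td <- tidy(cal3)
  expect_equal(td$estimate[td$term == "slope"], slope, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "intercept"], intercept, tolerance = 1e-10)
  expect_equal(glance(cal3)$r.squared, 1)

  expect_error(sec_calibrate(data.frame(ml = 14.7, mw = 51.6e3)), "at least 2")
  expect_error(
    sec_calibrate(data.frame(ml = c(14.7, 14.7), mw = c(1e3, 2e3))),
    "distinct"
  )
})

test_that("mean residue ellipticity follows the peptide-bond convention", {
  expect_equal(mean_residue_ellipticity(0, 0.2, 1e-5, 213), 0)
  # hand arithmetic: -20 / (10 * 0.2 * 1e-5 * 212)
  expect_equal(
    mean_residue_ellipticity(-20, 0.2, 1e-5, 213),
    -4716.981,
    tolerance = 1e-6
  )
  expect_equal(
    mean_residue_ellipticity(-20, 0.2, 2e-5, 213),
    mean_residue_ellipticity(-20, 0.2, 1e-5, 213) / 2
  )
  expect_error(mean_residue_ellipticity(-20, 0.2, 1e-5, 1), ">= 2")
})

test_that("conservation masking applies the identity threshold exactly", {
  # 11 identical sequences: everything conserved
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(unlist(lapply(1:11, function(i) {
    c(paste0(">sp", i), "MKRVGA")
  })), path)
  msa <- read_msa(path)
  mask <- conservation_mask(msa, min_species = 7)
  expect_true(all(mask$conserved))
  expect_equal(mask$residue_number, 1:6)

  # threshold boundary: 6 of 11 fails, 7 of 11 passes
  mk <- function(n_match) {
    rows <- c(
      rep("RA", n_match - 1),          # share the reference R
      rep("KA", 11 - n_match)          # do not
    )
    p <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
    writeLines(unlist(lapply(seq_along(c("RA", rows)), function(i) {
      c(paste0(">s", i), c("RA", rows)[i])
    })), p)
    conservation_mask(read_msa(p), min_species = 7)
  }
  expect_false(mk(6)$conserved[1])
  expect_true(mk(7)$conserved[1])
})

test_that("conservation masking equals brute-force counting on random alignments", {
  withr::with_seed(13, {
    for (i in 1:30) {
      fx <- random_msa_fixture(sample(8:12, 1), sample(10:30, 1))
      msa <- read_msa(fx$path)
      min_sp <- sample(5:8, 1)
      got <- conservation_mask(msa, min_species = min_sp)
      expect_equal(got$conserved, oracle_conservation(fx$mat, 1, min_sp))
    }
  })
})

test_that("FRAP fits recover amplitude, rate and the 95% plateau time", {
  t <- seq(0, 80, by = 2)
  y <- 0.8 * (1 - exp(-0.1 * t)) + 0.1
  fit <- fit_frap_recovery(t, y)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(fit$rate, 0.1, tolerance = 1e-6)
  expect_equal(fit$mobile_fraction, 0.9, tolerance = 1e-6)
  # closed form: t95 = ln(20) / k
  expect_equal(fit$plateau_time, log(20) / 0.1, tolerance = 1e-5)

  g <- glance(fit)
  expect_equal(g$mobile_fraction, fit$mobile_fraction)

  # pre-bleach normalization
  fit2 <- fit_frap_recovery(t, 200 * y, prebleach = rep(200, 5))
  expect_equal(fit2$mobile_fraction, fit$mobile_fraction, tolerance = 1e-6)

  expect_error(fit_frap_recovery(c(0, 1, 2), c(1, 1, 1)), "at least 4")
})

test_that("a flat FRAP trace is flagged rate-unidentifiable", {
  t <- seq(0, 40, by = 2)
  fit <- fit_frap_recovery(t, rep(0.35, length(t)))
  expect_false(fit$converged)
  expect_equal(fit$mobile_fraction, 0.35, tolerance = 1e-9)
  expect_true(is.na(fit$rate))
})

test_that("faster recovery plateaus earlier (rate ordering preserved)", {
  t <- seq(0, 120, by = 3)
  slow <- fit_frap_recovery(t, 0.8 * (1 - exp(-0.043 * t)) + 0.1)
  fast <- fit_frap_recovery(t, 0.8 * (1 - exp(-0.075 * t)) + 0.1)
  expect_lt(fast$plateau_time, slow$plateau_time)
  expect_equal(slow$plateau_time, log(20) / 0.043, tolerance = 1e-4)
})
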