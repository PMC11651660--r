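test_that("dilution schemes reproduce the plate chemistry", {
  g8 <- gen_dose_grid("twofold-8", stock = 0.01)
  expect_length(g8, 9)
  expect_equal(g8[1], 400e-6, tolerance = 1e-12) # 10 mM /12.5 /2
  expect_equal(g8[1] / g8[2], 2, tolerance = 1e-12)
  expect_identical(g8[9], 0)
  g12 <- gen_dose_grid("onehalf-12")
  expect_length(g12, 13)
  expect_equal(unique(round(g12[1:11] / g12[2:12], 9)), 1.5)
  for (g in list(g8, g12)) {
    pos <- g[g > 0]
    expect_true(all(pos > 0) && all(diff(pos) < 0))
  }
})

test_that("identical generator configs give identical outputs", {
  cfg <- gen_config(seed = 99)
  a <- gen_ftsa_plate(1e-9, cfg = cfg)
  b <- gen_ftsa_plate(1e-9, cfg = cfg)
  expect_identical(a, b)
  c1 <- gen_competition_plate(1e-9, cfg = cfg)
  c2 <- gen_competition_plate(1e-9, cfg = cfg)
  expect_identical(c1, c2)
  m1 <- gen_ms_peaklist(29574.69, 319.25, c(0.5, 0.1), cfg)
  m2 <- gen_ms_peaklist(29574.69, 319.25, c(0.5, 0.1), cfg)
  expect_identical(m1, m2)
  k1 <- gen_kinetics_timecourse(kinetics_preset("ester-fast"), 1e-6,
                                1e-6, cfg = cfg)
  k2 <- gen_kinetics_timecourse(kinetics_preset("ester-fast"), 1e-6,
                                1e-6, cfg = cfg)
  expect_identical(k1, k2)
  # a different seed changes the noise
  expect_false(identical(a$tm_table$Tm_C,
                         gen_ftsa_plate(1e-9,
                                        cfg = gen_config(seed = 100)
                                        )$tm_table$Tm_C))
})

test_that("noise-free thermal-shift plates round-trip through the fitter", {
  cfg <- gen_config(seed = 1, tm_sigma = 0, fluor_sigma = 0)
  plate <- gen_ftsa_plate(7.8e-12, cfg = cfg)
  fit <- fit_kd_app(plate$tm_table$Lt_M,
                    celsius_to_kelvin(plate$tm_table$Tm_C),
                    s = plate$truth$stability)
  expect_equal(fit$Kd_app, 7.8e-12, tolerance = 0.05)
  # picomolar affinity at micromolar protein: top-dose shift over 10 K
  shift <- max(plate$truth$tm_true_K) - plate$truth$stability$Tm_ref
  expect_gt(shift, 10)
})

test_that("melt curves in generated plates refit to the per-well Tm truth", {
  cfg <- gen_config(seed = 8)
  plate <- gen_ftsa_plate(1e-9, cfg = cfg)
  w <- plate$tm_table$well_id[5]
  mc <- plate$melt[plate$melt$well_id == w, ]
  f <- fit_melt(celsius_to_kelvin(mc$temperature_C), mc$fluorescence)
  expect_true(f$ok)
  expect_equal(f$params$Tm_ref, plate$truth$tm_true_K[5],
               tolerance = 0.1)
})

test_that("noise-free competition plates round-trip through the fitter", {
  cfg <- gen_config(seed = 1, signal_cv = 0)
  g <- gen_competition_plate(0.30e-9, cfg = cfg)
  fit <- fit_competitor_kd(g$data$competitor_total_M, g$data$signal,
                           g$truth$setup)
  expect_equal(fit$KdA, 0.30e-9, tolerance = 0.05)
  # an effectively non-binding competitor leaves the curve flat
  flat <- gen_competition_plate(1, cfg = gen_config(seed = 2))
  fitf <- fit_competitor_kd(flat$data$competitor_total_M,
                            flat$data$signal, flat$truth$setup)
  expect_true(fitf$flagged)
})

test_that("generated peak lists recover the generating compound", {
  cpd12 <- compound_record("12", "C10H9F4NO6S2", leaving_group = "C2H4O2",
                           warhead_class = "ester")
  sh <- adduct_shift(cpd12)[["average"]]
  g <- gen_ms_peaklist(29574.69, sh, c(0.45, 0.05),
                       gen_config(seed = 4, mass_ppm = 0))
  expect_equal(g$peaks$mass_da, 29574.69 + (0:2) * sh, tolerance = 1e-9)
  m <- match_shift(g$peaks, base = 29574.69, candidates = list(cpd12))
  expect_identical(m$candidate_id[-1], c("12", "12"))
  expect_identical(m$n_sites[-1], c(1L, 2L))
  # with 20 ppm jitter the match still lands inside the 1 Da tolerance
  g2 <- gen_ms_peaklist(29574.69, sh, c(0.45, 0.05),
                        gen_config(seed = 4, mass_ppm = 20))
  m2 <- match_shift(g2$peaks, 29574.69, list(cpd12))
  expect_identical(m2$candidate_id[2], "12")
})

test_that("kinetics time courses carry an exact noise-free truth", {
  r <- kinetics_preset("ester-fast")
  g0 <- gen_kinetics_timecourse(r, 1e-6, 1e-6,
                                cfg = gen_config(seed = 3,
                                                 fluor_sigma = 0))
  expect_equal(g0$data$fraction_modified, g0$truth$fraction_modified,
               tolerance = 1e-12)
  expect_true(all(g0$data$fraction_modified >= 0 &
                    g0$data$fraction_modified <= 1))
})

test_that("ester and carbamate presets differ 100-fold in half-time", {
  half_time <- function(preset) {
    g <- gen_kinetics_timecourse(kinetics_preset(preset), 1e-6, 1e-6,
                                 t_grid = c(0, 10^seq(0, 6, by = 0.05)),
                                 cfg = gen_config(fluor_sigma = 0))
    g$data$time_s[min(which(g$data$fraction_modified >= 0.5))]
  }
  t_ester <- half_time("ester-fast")
  t_carb <- half_time("carbamate-slow")
  expect_gte(t_carb / t_ester, 100 / 1.3) # grid-resolution slack
  expect_equal(t_ester, 180, tolerance = 0.3)
})
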