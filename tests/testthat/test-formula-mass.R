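test_that("formula parsing handles counts, implicit ones and repeats", {
  comp <- parse_formula("C10H9F4NO6S2")
  expect_setequal(names(comp), c("C", "H", "F", "N", "O", "S"))
  expect_identical(comp[c("C", "H", "F", "N", "O", "S")],
                   c(C = 10L, H = 9L, F = 4L, N = 1L, O = 6L, S = 2L))
  expect_identical(comp[["C"]], 10L)
  expect_identical(comp[["N"]], 1L)
  expect_identical(parse_formula("C")[["C"]], 1L)
  expect_identical(parse_formula("C2H4O2"),
                   parse_formula("CH2O2CH2")) # repeated symbols sum
})

test_that("parsing round-trips through the canonical Hill string", {
  for (f in c("C10H9F4NO6S2", "C23H28F3N3O6S2", "C2H4O2", "H2O",
              "NaCl", "C", "C7H7NO2")) {
    expect_identical(parse_formula(format_formula(parse_formula(f))),
                     parse_formula(f))
  }
  expect_identical(format_formula(parse_formula("C2H4O2")), "C2H4O2")
  expect_identical(format_formula(parse_formula("H2O")), "H2O")
})

test_that("parse errors name the offending symbol or count", {
  expect_error(parse_formula("C10Xx2"), "Xx")
  expect_error(parse_formula("C0H4"), "positive")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C10 H9"), "unexpected characters")
})

test_that("monoisotopic masses reproduce printed values", {
  expect_equal(monoisotopic_mass("C23H28F3N3O6S2"), 563.1372,
               tolerance = 5e-5)
  expect_equal(monoisotopic_mass("H"), 1.007825, tolerance = 1e-6)
  # neutral mass of the vinylsulfone warhead compound: printed [M-H]-
  # 317.9523 plus the proton mass
  expect_equal(monoisotopic_mass("C8H5F4NO4S2"), 317.9523 + 1.00728,
               tolerance = 5e-4)
})

test_that("average masses use standard atomic weights", {
  expect_equal(average_mass("C10H9F4NO6S2"), 379.30, tolerance = 0.01)
  expect_equal(average_mass("C"), 12.011, tolerance = 1e-6)
})

test_that("mass additivity holds elementwise on both scales", {
  set.seed(42)
  els <- c("C", "H", "N", "O", "F", "S", "Na", "Cl")
  for (i in 1:25) {
    a <- sample(1:30, 4); names(a) <- sample(els, 4)
    b <- sample(1:30, 4); names(b) <- sample(els, 4)
    ab <- tapply(c(a, b), names(c(a, b)), sum)
    ab <- stats::setNames(as.integer(ab), names(ab))
    expect_equal(monoisotopic_mass(ab),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
    expect_equal(average_mass(ab), average_mass(a) + average_mass(b),
                 tolerance = 1e-9)
    # monoisotopic below average whenever carbon or sulfur is present
    if (any(names(ab) %in% c("C", "S"))) {
      expect_lt(monoisotopic_mass(ab), average_mass(ab))
    }
  }
})

test_that("ion m/z matches printed HRMS anchor values", {
  expect_equal(ion_mz("C23H28F3N3O6S2", "M+H"), 564.1444,
               tolerance = 5e-4)
  expect_equal(ion_mz("C10H9F4NO6S2", "M-H"), 377.9735,
               tolerance = 5e-4)
  expect_equal(ion_mz("C8H5F4NO4S2", "M-H"), 317.9523,
               tolerance = 5e-4)
  expect_error(ion_mz("C8H5F4NO4S2", "M+K"))
})

test_that("protonated and deprotonated m/z differ by two proton masses", {
  for (f in c("C23H28F3N3O6S2", "H2O", "C6H6")) {
    expect_equal(ion_mz(f, "M+H") - ion_mz(f, "M-H"), 2 * 1.00728,
                 tolerance = 1e-12)
  }
})

test_that("the full packaged HRMS reference suite reproduces to 5e-4 Da", {
  ref <- load_hrms_reference()
  expect_gte(nrow(ref), 24)
  for (i in seq_len(nrow(ref))) {
    expect_equal(ion_mz(ref$formula[i], ref$species[i]), ref$calc_mz[i],
                 tolerance = 5e-4,
                 label = paste(ref$formula[i], ref$species[i]))
  }
})

test_that("adduct shifts subtract the leaving group on both mass scales", {
  cpd22 <- compound_record("22", "C23H28F3N3O6S2",
                           leaving_group = "C7H7NO2",
                           warhead_class = "carbamate")
  sh22 <- adduct_shift(cpd22)
  expect_equal(sh22[["monoisotopic"]], 426.0895, tolerance = 5e-4)

  cpd12 <- compound_record("12", "C10H9F4NO6S2", leaving_group = "C2H4O2",
                           warhead_class = "ester")
  sh12 <- adduct_shift(cpd12)
  expect_equal(round(sh12[["average"]]), 319)

  # vinylsulfone: the whole molecule adds
  cpd15 <- compound_record("15", "C8H5F4NO4S2",
                           warhead_class = "vinylsulfone")
  expect_equal(adduct_shift(cpd15)[["average"]],
               average_mass("C8H5F4NO4S2"), tolerance = 1e-12)

  # shift + leaving group mass == compound mass, both scales
  for (cpd in list(cpd22, cpd12)) {
    sh <- adduct_shift(cpd)
    expect_equal(sh[["monoisotopic"]] +
                   monoisotopic_mass(cpd$leaving_group),
                 monoisotopic_mass(cpd$formula), tolerance = 1e-9)
    expect_equal(sh[["average"]] + average_mass(cpd$leaving_group),
                 average_mass(cpd$formula), tolerance = 1e-9)
  }
})

test_that("compound records reject impossible leaving groups", {
  expect_error(compound_record("x", "C2H4O2", leaving_group = "C3H6O2",
                               warhead_class = "ester"),
               "sub-composition")
  expect_error(compound_record("x", "C2H4O2", warhead_class = "ester"),
               "leaving group")
  expect_error(adduct_shift(compound_record("nc", "C2H4O2",
                                            warhead_class = "none")),
               "non-covalent")
})

test_that("predicted modified-protein mass ladders are arithmetic", {
  expect_equal(predict_modified_masses(29574.69, 319.25, 2),
               c(29574.69, 29893.94, 30213.19))
  expect_equal(predict_modified_masses(28060.32, 426.4, 1),
               c(28060.32, 28486.72))
  expect_equal(predict_modified_masses(1000, 50, 3)[1], 1000)
})

test_that("shift matching reproduces intact-mass bookkeeping", {
  cpd12 <- compound_record("12", "C10H9F4NO6S2", leaving_group = "C2H4O2",
                           warhead_class = "ester")
  peaks <- data.frame(mass_da = c(29574.69, 29893.97),
                      intensity = c(100, 90))
  # observed difference 319.28 vs predicted average shift 319.24:
  # matches at the 1.0 Da default tolerance
  m <- match_shift(peaks, base = 29574.69, candidates = list(cpd12))
  expect_true(is.na(m$candidate_id[1])) # base peak never matched
  expect_identical(m$candidate_id[2], "12")
  expect_equal(m$observed_shift[2], 319.28, tolerance = 1e-9)
  expect_equal(m$error_da[2], 319.28 - adduct_shift(cpd12)[["average"]],
               tolerance = 1e-9)
  # but not at a 0.02 Da tolerance
  m2 <- match_shift(peaks, 29574.69, list(cpd12), tol = 0.02)
  expect_true(all(is.na(m2$candidate_id)))
  # a peak at exactly base + shift has zero error
  sh <- adduct_shift(cpd12)[["average"]]
  m3 <- match_shift(data.frame(mass_da = 29574.69 + sh, intensity = 1),
                    29574.69, list(cpd12))
  expect_equal(m3$error_da, 0, tolerance = 1e-9)
  # doubly modified peaks match at n_sites = 2
  m4 <- match_shift(data.frame(mass_da = 29574.69 + 2 * sh, intensity = 1),
                    29574.69, list(cpd12))
  expect_identical(m4$n_sites, 2L)
  expect_error(match_shift(peaks, 29574.69, list()), "empty")
})
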