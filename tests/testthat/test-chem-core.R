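test_that("monoisotopic masses match hand-summed atomic masses", {
  expect_identical(monoisotopic_mass(composition()), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  # phosphoethanolamine head-group loss, the classic delta m/z 141.02
  expect_equal(monoisotopic_mass("C2H8NO4P"),
               2 * ORACLE_MASS[["C"]] + 8 * ORACLE_MASS[["H"]] +
                 ORACLE_MASS[["N"]] + 4 * ORACLE_MASS[["O"]] + ORACLE_MASS[["P"]],
               tolerance = 1e-9)
  expect_equal(round(monoisotopic_mass("C2H8NO4P"), 2), 141.02)
  expect_error(monoisotopic_mass("Xx2"), "element")
})

test_that("mass arithmetic is additive over composition addition", {
  set.seed(42)
  for (i in 1:20) {
    a <- composition(C = sample(0:30, 1), H = sample(0:60, 1), O = sample(0:10, 1))
    b <- composition(C = sample(0:30, 1), H = sample(0:60, 1),
                     N = sample(0:3, 1), P = sample(0:2, 1))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-9)
  }
  expect_error(composition(C = 1) - composition(C = 2), "negative")
})

test_that("ion m/z accounts for the electron and reproduces printed anchors", {
  expect_equal(round(ion_mz("C16H31O2", -1), 1), 255.2) # 16:0 acyl anion
  expect_equal(round(ion_mz("C17H31O2", -1), 1), 267.2) # 17:1 acyl anion
  expect_equal(round(ion_mz("C38H73NO8P", -1), 1), 702.5) # PE 33:1 [M-H]-
  expect_equal(ion_mz("H", +1), 1.00728, tolerance = 1e-5) # bare proton
  expect_error(ion_mz("H2O", 0), "nonzero")
  # charge sign shifts m/z by exactly two electron masses
  for (f in c("C16H31O2", "C38H73NO8P", "H2O")) {
    expect_equal(ion_mz(f, -1) - ion_mz(f, +1), 2 * ELECTRON_MASS,
                 tolerance = 1e-9)
  }
})

test_that("double-bond equivalents follow the trivalent N/P convention", {
  expect_equal(double_bond_equivalents("CH4"), 0)
  expect_equal(double_bond_equivalents("C16H31O2"), 1.5) # saturated acyl anion
  expect_equal(double_bond_equivalents("C17H31O2"), 2.5)
  expect_equal(double_bond_equivalents("C38H73NO8P"), 3.5)
})

test_that("composition parsing accepts compact and spaced formulas", {
  expect_true(as_composition("C5 H11 O4 N1 P1") == as_composition("C5H11NO4P"))
  expect_identical(format(as_composition("C5H11NO4P")), "C5 H11 N1 O4 P1")
  expect_error(as_composition("C5 H-1"), "parse|negative")
})

test_that("constraint parsing round-trips the shared bracket syntax", {
  k <- parse_constraint("C[30..50] H[40..100] N[1..1] O[8..8] P[1..1]",
                        dbr = c(1.5, 7.5), charge = -1)
  expect_equal(k$elements$C, c(30L, 50L))
  expect_equal(k$elements$O, c(8L, 8L))
  expect_equal(k$dbr, c(1.5, 7.5))
  # an exact formula is a degenerate box
  k2 <- parse_constraint("C5 H11 O4 N1 P1", charge = 0)
  expect_equal(k2$elements$H, c(11L, 11L))
  expect_error(sum_constraint(C = c(5, 2)), "min > max")
})

test_that("composition enumeration recovers the worked precursor and fragments", {
  k <- sum_constraint(C = c(10, 20), H = c(20, 40), O = 2,
                      dbr = c(1.5, 7.5), charge = -1)
  hit <- enumerate_compositions(255.233, k, mass_tolerance(5, "ppm"))
  expect_identical(hit$formula, "C16 H31 O2")
  empty <- enumerate_compositions(255.233,
    sum_constraint(C = c(2, 4), H = c(2, 4), O = 2, charge = -1),
    mass_tolerance(5, "ppm"))
  expect_identical(nrow(empty), 0L)
  kp <- sum_constraint(C = c(30, 50), H = c(40, 100), N = 1, O = 8, P = 1,
                       dbr = c(-100, 100), charge = -1)
  expect_identical(enumerate_compositions(702.508, kp, mass_tolerance(5, "ppm"))$formula,
                   "C38 H73 N1 O8 P1")
})

test_that("enumeration equals a naive brute-force loop on random boxes", {
  set.seed(7)
  for (i in 1:15) {
    c_lo <- sample(5:25, 1); c_hi <- c_lo + sample(5:15, 1)
    h_lo <- sample(5:40, 1); h_hi <- h_lo + sample(10:30, 1)
    o <- sample(0:4, 1)
    dbr <- sort(stats::runif(2, -5, 15))
    mz <- stats::runif(1, 150, 600)
    tol_da <- mz * 50e-6 # wide enough to catch several candidates
    got <- enumerate_compositions(mz,
      sum_constraint(C = c(c_lo, c_hi), H = c(h_lo, h_hi), O = c(o, o),
                     dbr = dbr, charge = -1),
      mass_tolerance(50, "ppm"))
    want <- brute_force_enumerate(mz,
      list(C = c(c_lo, c_hi), H = c(h_lo, h_hi), O = c(o, o)),
      dbr, -1, tol_da)
    expect_setequal(got$formula, want)
    # sorted by absolute mass error
    expect_false(is.unsorted(abs(got$error_ppm)))
  }
})

test_that("enumeration refuses unbounded or oversized boxes", {
  expect_error(enumerate_compositions(500,
    sum_constraint(C = c(0, 2000), H = c(0, 5000), charge = -1),
    mass_tolerance(5, "ppm")), "too large")
})

test_that("isotope patterns match element abundances and first-order sums", {
  expect_equal(isotope_pattern("C", 2)$abundance, c(0.9893, 0.0107),
               tolerance = 1e-12)
  expect_identical(isotope_pattern("H2O", 1)$abundance, 1)
  ip <- isotope_pattern("C38H73NO8P", 3)
  expect_equal(ip$abundance[2] / ip$abundance[1], 0.427, tolerance = 0.005)
  expect_equal(sum(ip$abundance), 1, tolerance = 1e-12)
})

test_that("isotope pattern M+0 falls off monotonically with carbon count", {
  m0 <- vapply(seq(5, 60, by = 5), function(n) {
    isotope_pattern(composition(C = n, H = 2 * n), 4)$abundance[1]
  }, numeric(1))
  expect_true(all(diff(m0) < 0))
})
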