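# build a minimal record tibble by hand for correction tests
make_records <- function(formulas, intensities, class = "PE", samples = "S1") {
  tibble::tibble(
    query = class, class = class,
    annotation = paste(class, seq_along(formulas)),
    molecular_species = NA_character_,
    formula = formulas,
    precursor_id = seq_along(formulas),
    precursor_mz = vapply(formulas, ion_mz, numeric(1), charge = -1),
    error_ppm = 0,
    composition = lapply(formulas, as_composition),
    intensity = lapply(intensities, function(x) stats::setNames(x, samples)),
    fragments = rep(list(tibble::tibble()), length(formulas)),
    report = rep(list(list()), length(formulas)))
}

toy_ms <- function() build_masterscan(toy_dda_scans(), masterscan_settings())

test_that("a lone species passes isotopic correction unchanged", {
  r <- make_records("C38H73NO8P", list(1e6))
  out <- isotopic_correction(r, toy_ms())
  expect_equal(out$intensity[[1]], c(S1 = 1e6))
  expect_false(out$isotope_clipped)
})

test_that("the M+2 overlap of one double bond less is subtracted", {
  # PE 33:1 below PE 33:0: precursors 2.0157 apart, matching M+2 within the
  # (deliberately loose) tolerance used here
  r <- make_records(c("C38H73NO8P", "C38H75NO8P"), list(1e5, 5e4))
  ms <- toy_ms()
  ms$settings$tol <- mass_tolerance(20, "ppm")
  out <- isotopic_correction(r, ms)
  pat <- isotope_pattern("C38H73NO8P", 4)$abundance
  f <- pat[3] / pat[1] # oracle: full convolution M+2 fraction (~0.105)
  expect_equal(out$intensity[[2]], c(S1 = 5e4 - f * 1e5), tolerance = 1e-9)
  expect_equal(out$intensity[[1]], c(S1 = 1e5)) # lighter species untouched
  expect_false(any(out$isotope_clipped))
})

test_that("correction clips at zero and flags the record", {
  r <- make_records(c("C38H73NO8P", "C38H75NO8P"), list(1e6, 1e3))
  ms <- toy_ms()
  ms$settings$tol <- mass_tolerance(20, "ppm")
  out <- isotopic_correction(r, ms)
  expect_equal(out$intensity[[2]], c(S1 = 0))
  expect_true(out$isotope_clipped[2])
})

test_that("correction never increases intensities (conservation property)", {
  set.seed(13)
  formulas <- sprintf("C38H%dNO8P", c(61, 63, 65, 67, 69, 71, 73, 75))
  r <- make_records(formulas, as.list(10^stats::runif(8, 3, 6)))
  ms <- toy_ms()
  ms$settings$tol <- mass_tolerance(20, "ppm")
  out <- isotopic_correction(r, ms)
  before <- vapply(r$intensity, sum, numeric(1))
  after <- vapply(out$intensity, sum, numeric(1))
  expect_true(all(after <= before + 1e-12))
  expect_true(all(after >= 0))
})

test_that("records of different classes never correct each other", {
  r <- dplyr::bind_rows(make_records("C38H73NO8P", list(1e6), class = "PE"),
                        make_records("C38H75NO8P", list(5e4), class = "PG"))
  ms <- toy_ms()
  ms$settings$tol <- mass_tolerance(20, "ppm")
  out <- isotopic_correction(r, ms)
  expect_equal(out$intensity[[2]], c(S1 = 5e4))
})

test_that("class normalization divides by the class total per sample", {
  r <- make_records(c("C38H73NO8P", "C38H71NO8P"), list(300, 100))
  p <- class_normalize(r)
  expect_s3_class(p, "lipid_profiles")
  expect_equal(sort(p$abundance), c(0.25, 0.75))
  p1 <- class_normalize(make_records("C38H73NO8P", list(42)))
  expect_equal(p1$abundance, 1)
})

test_that("colliding annotations (isobaric / molecular species) are combined", {
  r <- make_records(c("C38H73NO8P", "C38H73NO8P"), list(300, 100))
  r$annotation <- c("PE 33:1", "PE 33:1") # e.g. 16:0/17:1 and 15:0/18:1
  p <- class_normalize(r)
  expect_identical(nrow(p), 1L)
  expect_equal(p$intensity, 400)
  expect_equal(p$abundance, 1)
})

test_that("normalized abundances sum to one per class and sample", {
  lip <- generate_lipidome(c("PE", "PG"), 14, seed = 51)
  scans <- simulate_dda(lip, instrument_model(), n_replicates = 3, seed = 52)
  ms <- build_masterscan(scans, masterscan_settings())
  recs <- run_queries(list(mfql_example("pe_dda"), mfql_example("pg_dda")), ms)
  p <- class_normalize(isotopic_correction(recs, ms))
  sums <- p |>
    dplyr::group_by(class, sample_id) |>
    dplyr::summarise(s = sum(abundance), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("a zero class total is flagged and yields NA abundances", {
  r <- make_records("C38H73NO8P", list(0))
  expect_warning(p <- class_normalize(r), "zero")
  expect_true(is.na(p$abundance))
})

test_that("profile concordance matches a hand-computed regression", {
  prof <- function(ab) {
    structure(tibble::tibble(class = "PE",
                             species = paste("PE", seq_along(ab)),
                             sample_id = "S1", intensity = ab,
                             abundance = ab / sum(ab)),
              class = c("lipid_profiles", class(tibble::tibble())))
  }
  a <- prof(c(1, 2, 3))
  expect_equal(profile_concordance(a, a)$r_squared, 1)
  expect_equal(profile_concordance(a, a)$slope, 1)
  # same proportions scaled then renormalized: still identity
  b <- prof(c(0.5, 1, 1.5))
  cc <- profile_concordance(a, b)
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$slope, 1, tolerance = 1e-12)
  # analytic least squares for a chosen 3-point configuration
  x <- c(0.2, 0.3, 0.5); y <- c(0.25, 0.25, 0.5)
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2_hat <- stats::cor(x, y)^2
  cc2 <- profile_concordance(prof(x), prof(y))
  expect_equal(cc2$slope, slope_hat, tolerance = 1e-12)
  expect_equal(cc2$r_squared, r2_hat, tolerance = 1e-12)
  expect_error(profile_concordance(prof(c(1, 2)), prof(1)[1, ]), "2 shared")
})

test_that("profile and MasterScan plots build without error", {
  r <- make_records(c("C38H73NO8P", "C38H71NO8P"), list(300, 100))
  p <- class_normalize(r)
  expect_s3_class(ggplot2::autoplot(p), "ggplot")
  ms <- toy_ms()
  expect_s3_class(ggplot2::autoplot(ms), "ggplot")
  expect_s3_class(tidy(ms), "tbl_df")
  expect_identical(glance(ms)$n_precursor_clusters, 1L)
})
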