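test_that("grouping tolerance follows the linear resolution model", {
  m <- resolution_model(7500)
  expect_equal(tolerance_at(m, 750), 0.1)
  expect_equal(tolerance_at(resolution_model(15000), 750), 0.05)
  bad <- resolution_model(7500, slope = -5, m_ref = 0)
  expect_error(tolerance_at(bad, 3000), "non-positive")
})

test_that("scan merging reproduces the weighted-mean worked example", {
  # two scans, each with peaks (100.000, 2) and (100.010, 6); tolerance ~0.05
  scans <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = c(100.000, 100.010),
                                            intensity = c(2, 6))),
    scan_tbl("A", 1, -1, scan_index = 2,
             peaks = data.frame(mz = c(100.000, 100.010), intensity = c(2, 6))))
  rep <- merge_scans(scans, resolution_model(2000))
  pk <- rep$peaks[[1]]
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$mz, 100.0075, tolerance = 1e-9)     # (2*100+6*100.01)*2/16
  expect_equal(pk$intensity, 8)                       # 16 total over 2 scans
  expect_identical(pk$n_scans, 2L)
})

test_that("scan merging is idempotent and keeps resolved peaks apart", {
  s <- scan_tbl("A", 1, -1,
                peaks = data.frame(mz = c(400, 401), intensity = c(5, 7)))
  m <- resolution_model(4000) # tolerance 0.1 at m/z 400
  rep1 <- merge_scans(s, m)
  rep2 <- merge_scans(rep1, m)
  expect_identical(nrow(rep1$peaks[[1]]), 2L)
  expect_equal(rep2$peaks[[1]]$mz, rep1$peaks[[1]]$mz, tolerance = 1e-9)
  expect_equal(rep2$peaks[[1]]$intensity, rep1$peaks[[1]]$intensity)
  expect_error(merge_scans(dplyr::bind_rows(s, scan_tbl("B", 1, -1)), m),
               "identical metadata")
})

test_that("cross-sample alignment gives the intensity-weighted average mass", {
  reps <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = 702.505, intensity = 1e4)),
    scan_tbl("B", 1, -1, peaks = data.frame(mz = 702.511, intensity = 3e4)))
  cl <- align_across_samples(reps, resolution_model(7025))
  expect_identical(nrow(cl), 1L)
  expect_equal(cl$mz, 702.5095, tolerance = 1e-6)
  expect_equal(cl$intensity[[1]], c(A = 1e4, B = 3e4))
  expect_equal(cl$occupancy, 1)

  # peaks 0.5 Th apart at tolerance ~0.1 stay separate, occupancy 0.5 each
  reps2 <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = 700.0, intensity = 10)),
    scan_tbl("B", 1, -1, peaks = data.frame(mz = 700.5, intensity = 20)))
  cl2 <- align_across_samples(reps2, resolution_model(7000))
  expect_identical(nrow(cl2), 2L)
  expect_equal(cl2$occupancy, c(0.5, 0.5))
})

test_that("alignment conserves total intensity and bounds the cluster mass", {
  set.seed(11)
  for (i in 1:8) {
    reps <- dplyr::bind_rows(lapply(1:4, function(s) {
      n <- sample(5:25, 1)
      scan_tbl(sprintf("S%d", s), 1, -1,
               peaks = data.frame(mz = sort(stats::runif(n, 500, 520)),
                                  intensity = stats::rexp(n, 1e-4)))
    }))
    cl <- align_across_samples(reps, resolution_model(7500))
    expect_equal(sum(unlist(cl$intensity)),
                 sum(unlist(lapply(reps$peaks, `[[`, "intensity"))),
                 tolerance = 1e-9)
    pk_all <- peaks_long(reps)
    expect_true(all(cl$mz >= min(pk_all$mz) & cl$mz <= max(pk_all$mz)))
    # a sample contributes at most one peak per cluster
    expect_true(all(vapply(cl$intensity,
                           function(x) !anyDuplicated(names(x)), logical(1))))
  }
})

test_that("occupancy is invariant under sample relabeling", {
  reps <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = c(500, 501), intensity = c(1, 2))),
    scan_tbl("B", 1, -1, peaks = data.frame(mz = 500, intensity = 3)))
  relabeled <- reps
  relabeled$sample_id <- c("B", "A")
  o1 <- sort(align_across_samples(reps, resolution_model(7500))$occupancy)
  o2 <- sort(align_across_samples(relabeled, resolution_model(7500))$occupancy)
  expect_identical(o1, o2)
})

test_that("intensity and occupancy thresholds drop the right clusters", {
  cl <- tibble::tibble(
    mz = c(500, 600, 700),
    occupancy = c(0.25, 1, 1),
    n_members = c(1L, 2L, 2L),
    intensity = list(c(A = 1e5), c(A = 50, B = 200), c(A = 20, B = 30)),
    deltas = list(NULL, NULL, NULL))
  # occupancy 0.25 under a 100% threshold is dropped
  expect_identical(apply_thresholds(cl, 0, 1)$mz, c(600, 700))
  # the maximal per-sample intensity decides the intensity constraint
  expect_identical(apply_thresholds(cl, 100, 0)$mz, c(500, 600))
  expect_identical(nrow(apply_thresholds(cl, 0, 0)), 3L)
})

test_that("MasterScan construction attaches fragments to survey clusters", {
  ms <- build_masterscan(toy_dda_scans(), masterscan_settings())
  expect_identical(nrow(ms$ms1), 1L)
  expect_false(ms$ms1$virtual[1])
  expect_identical(nrow(ms$ms2), 2L)
  expect_identical(unique(ms$ms2$precursor_id), ms$ms1$cluster_id[1])
  expect_equal(ms$ms1$mz[1], 702.5095, tolerance = 1e-6)
})

test_that("MS/MS groups without a survey peak get flagged virtual precursors", {
  scans <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = 650.0, intensity = 1e4)),
    scan_tbl("A", 2, -1, precursor_mz = 702.5, scan_index = 2,
             peaks = data.frame(mz = 255.233, intensity = 500)))
  ms <- build_masterscan(scans, masterscan_settings())
  virt <- ms$ms1[ms$ms1$virtual, ]
  expect_identical(nrow(virt), 1L)
  expect_equal(virt$mz, 702.5, tolerance = 1e-6)
  expect_equal(virt$intensity[[1]], c(A = 500))
  expect_identical(ms$ms2$precursor_id, virt$cluster_id)
})

test_that("a transposed dataset yields a MasterScan of virtual precursors only", {
  lip <- generate_lipidome("PE", 5, seed = 2)
  pis <- simulate_pis(lip, inst = perfect_instrument(), n_replicates = 2, seed = 3)
  ms <- build_masterscan(transpose_pis(pis, resolution_model(7500)),
                         masterscan_settings())
  expect_gt(nrow(ms$ms1), 0)
  expect_true(all(ms$ms1$virtual))
})

test_that("the MasterScan container round-trips losslessly and checks versions", {
  ms <- build_masterscan(toy_dda_scans(), masterscan_settings())
  f <- withr::local_tempfile(fileext = ".json")
  save_masterscan(ms, f)
  back <- load_masterscan(f)
  expect_equal(back$ms1$mz, ms$ms1$mz, tolerance = 1e-9)
  expect_equal(back$ms2$mz, ms$ms2$mz, tolerance = 1e-9)
  expect_identical(back$samples, ms$samples)
  for (i in seq_len(nrow(ms$ms1))) {
    expect_equal(back$ms1$intensity[[i]], ms$ms1$intensity[[i]], tolerance = 1e-9)
  }
  expect_equal(back$settings$tol$value, ms$settings$tol$value)

  # truncated file refuses to load
  txt <- readLines(f)
  writeLines(substr(paste(txt, collapse = ""), 1, 50), f)
  expect_error(load_masterscan(f), "cannot read")

  # future format versions are refused with a clear message
  save_masterscan(ms, f)
  j <- jsonlite::read_json(f)
  j$version <- "99.0"
  jsonlite::write_json(j, f, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_masterscan(f), "version 99.0")
})

test_that("building from an empty or mixed-polarity dataset errors", {
  expect_error(build_masterscan(toy_dda_scans()[0, ]), "no scans")
  mixed <- dplyr::bind_rows(scan_tbl("A", 1, -1), scan_tbl("A", 1, 1))
  expect_error(build_masterscan(mixed), "polarit")
})
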