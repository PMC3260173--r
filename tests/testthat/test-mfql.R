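test_that("the PE query parses into the expected AST", {
  q <- parse_mfql(fig_pe_query())
  expect_s3_class(q, "mfql_query")
  expect_identical(q$name, "PE")
  expect_identical(names(q$defines), c("prPE", "FA1", "FA2"))
  expect_identical(q$defines$prPE$charge, -1L)
  expect_equal(q$defines$FA1$dbr, c(1.5, 7.5))
  expect_identical(length(q$identify), 3L)
  expect_identical(q$ms1_variable, "prPE")
  expect_identical(q$polarity, -1L)
  # SUCHTHAT is an additive equality over compositions
  expect_identical(q$suchthat$type, "bin")
  expect_identical(q$suchthat$op, "==")
  expect_identical(names(q$report), c("MASS", "CHEMSC", "INTENS"))
})

test_that("undefined variables and syntax errors are reported with context", {
  bad <- sub("FA2 IN MS2-", "FA3 IN MS2-", fig_pe_query())
  expect_error(parse_mfql(bad), "FA3")
  expect_error(parse_mfql("QUERYNAME = X"), "syntax error")
  expect_error(parse_mfql(sub("DBR = \\(1.5, 7.5\\)", "DBR = (", fig_pe_query())),
               "syntax error")
  # a query must anchor exactly one variable in MS1
  noms1 <- sub("prPE IN MS1-", "prPE IN MS2-", fig_pe_query())
  expect_error(parse_mfql(noms1), "MS1")
})

test_that("a minimal query (one define, no suchthat) is accepted", {
  q <- parse_mfql(paste(
    "QUERYNAME = X;",
    "DEFINE pr = 'C[10..20] H[10..40] O[2..2]' WITH DBR = (0.5, 9.5), CHG = -1;",
    "IDENTIFY pr IN MS1-;",
    "SUCHTHAT ;",
    "REPORT MASS = pr.mass;", sep = "\n"))
  expect_null(q$suchthat)
  expect_identical(length(q$defines), 1L)
})

test_that("the bundled queries parse and carry per-class constants", {
  for (f in mfql_example()) {
    q <- read_mfql(f)
    expect_s3_class(q, "mfql_query")
    expect_true(q$name %in% c("PE", "PG"))
  }
})

test_that("evaluation identifies PE 33:1 from its precursor and acyl anions", {
  ms <- build_masterscan(toy_dda_scans(), masterscan_settings())
  recs <- evaluate_query(parse_mfql(fig_pe_query()), ms)
  expect_identical(nrow(recs), 1L)
  expect_identical(recs$annotation, "PE 33:1")
  expect_identical(recs$molecular_species, "PE 16:0/17:1")
  expect_identical(recs$formula, "C38 H73 N1 O8 P1")
  expect_equal(recs$intensity[[1]], c(A = 1e4, B = 3e4))
  expect_identical(nrow(recs$fragments[[1]]), 2L)
  # the report section evaluated: MASS is the measured cluster m/z
  expect_equal(recs$report[[1]]$MASS, recs$precursor_mz)
})

test_that("the additivity constraint rejects fragment pairs that miss the precursor", {
  # 17:0 instead of 17:1: sums to PE 33:0, ~2 Da above the observed precursor
  scans <- dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = 702.508, intensity = 1e4)),
    scan_tbl("A", 2, -1, precursor_mz = 702.508, scan_index = 2,
             peaks = data.frame(mz = c(255.233, 269.249), intensity = c(5e3, 4e3))))
  ms <- build_masterscan(scans, masterscan_settings())
  recs <- evaluate_query(parse_mfql(fig_pe_query()), ms)
  expect_identical(nrow(recs), 0L)
})

test_that("every emitted record satisfies its SUCHTHAT constraint exactly", {
  lip <- generate_lipidome(c("PE", "PG"), 15, seed = 21)
  scans <- simulate_dda(lip, instrument_model(), n_replicates = 2, seed = 22)
  ms <- build_masterscan(scans, masterscan_settings())
  recs <- run_queries(list(mfql_example("pe_dda"), mfql_example("pg_dda")), ms)
  expect_gt(nrow(recs), 0)
  head_const <- list(PE = as_composition("C5H11NO4P"),
                     PG = as_composition("C6H12O6P"))
  for (i in seq_len(nrow(recs))) {
    fr <- recs$fragments[[i]]
    total <- Reduce(`+`, fr$composition) + head_const[[recs$class[i]]]
    expect_true(total == recs$composition[[i]])
  }
})

test_that("evaluation matches brute force over candidate tuples on small instances", {
  # independent oracle: enumerate all (precursor comp x FA1 comp x FA2 comp)
  # tuples over the raw clusters and keep those satisfying the additivity rule
  lip <- generate_lipidome(c("PE"), 6, seed = 31)
  scans <- simulate_dda(lip, instrument_model(noise_density = 0),
                        n_replicates = 2, seed = 32)
  ms <- build_masterscan(scans, masterscan_settings())
  q <- read_mfql(mfql_example("pe_dda"))
  recs <- evaluate_query(q, ms)

  tol <- ms$settings$tol
  head_const <- as_composition("C5H11NO4P")
  expected <- character(0)
  for (i in seq_len(nrow(ms$ms1))) {
    pc <- enumerate_compositions(ms$ms1$mz[i], q$defines$prPE, tol)
    frags <- ms$ms2[ms$ms2$precursor_id == ms$ms1$cluster_id[i], ]
    if (nrow(frags) == 0) next
    fc <- lapply(frags$mz, enumerate_compositions, k = q$defines$FA1, tol = tol)
    for (a in seq_len(nrow(pc))) for (b1 in seq_along(fc)) for (b2 in seq_along(fc)) {
      f1 <- fc[[b1]]; f2 <- fc[[b2]]
      if (nrow(f1) == 0 || nrow(f2) == 0) next
      for (c1 in seq_len(nrow(f1))) for (c2 in seq_len(nrow(f2))) {
        ok <- (f1$composition[[c1]] + f2$composition[[c2]] + head_const) ==
          pc$composition[[a]]
        if (ok) {
          key <- paste(i, pc$formula[a],
                       paste(sort(c(paste(b1, f1$formula[c1]),
                                    paste(b2, f2$formula[c2]))), collapse = "&"))
          expected <- union(expected, key)
        }
      }
    }
  }
  expect_identical(nrow(recs), length(expected))
})

test_that("query results are deterministic and concatenate per query", {
  lip <- generate_lipidome(c("PE", "PG"), 10, seed = 41)
  scans <- simulate_dda(lip, instrument_model(), n_replicates = 2, seed = 42)
  ms <- build_masterscan(scans, masterscan_settings())
  qs <- list(mfql_example("pe_dda"), mfql_example("pg_dda"))
  r1 <- run_queries(qs, ms)
  r2 <- run_queries(qs, ms)
  expect_identical(r1, r2)
  # the same query twice reports twice; zero queries report nothing
  twice <- run_queries(list(mfql_example("pe_dda"), mfql_example("pe_dda")), ms)
  once <- run_queries(list(mfql_example("pe_dda")), ms)
  expect_identical(nrow(twice), 2L * nrow(once))
  expect_identical(nrow(run_queries(list(), ms)), 0L)
})

test_that("a fragment query against an MS1-only MasterScan warns and returns empty", {
  scans <- scan_tbl("A", 1, -1,
                    peaks = data.frame(mz = 702.508, intensity = 1e4))
  ms <- build_masterscan(scans, masterscan_settings())
  expect_warning(recs <- evaluate_query(parse_mfql(fig_pe_query()), ms),
                 "no MS/MS")
  expect_identical(nrow(recs), 0L)
})

test_that("polarity mismatches between query and MasterScan are errors", {
  ms <- build_masterscan(toy_dda_scans(), masterscan_settings())
  expect_error(evaluate_query(read_mfql(mfql_example("pe_nls")), ms), "polarity")
})

test_that("per-query tolerance overrides and membership sets parse and evaluate", {
  q <- parse_mfql(paste(
    "QUERYNAME = X;",
    "TOLERANCE = 0.5 DA;",
    "DEFINE pr = 'C[10..20] H[10..40] O[2..2]' WITH DBR = (0.5, 9.5), CHG = -1;",
    "IDENTIFY pr IN MS1-;",
    "SUCHTHAT pr.chemsc IN (C16H31O2, C18H33O2);",
    "REPORT MASS = pr.mass;", sep = "\n"))
  expect_equal(q$tolerance$value, 0.5)
  expect_identical(q$tolerance$unit, "mz")
  scans <- scan_tbl("A", 1, -1, peaks = data.frame(
    mz = c(255.233, 283.264), intensity = c(10, 20)))
  ms <- build_masterscan(scans, masterscan_settings())
  recs <- evaluate_query(q, ms)
  # 283.264 is 18:0 (C18H35O2), not in the membership set; 255.233 is
  expect_identical(recs$formula, "C16 H31 O2")
})
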