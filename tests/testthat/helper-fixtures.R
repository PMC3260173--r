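# shared fixtures and independent oracles

# atomic masses typed in independently of the package's element table
ORACLE_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, P = 30.97376163, S = 31.97207100)
ORACLE_ELECTRON <- 0.00054858

# brute-force composition enumeration: plain triple loop, no vectorization
brute_force_enumerate <- function(mz, ranges, dbr, charge, tol_da) {
  hits <- character(0)
  cs <- seq(ranges$C[1], ranges$C[2])
  hs <- seq(ranges$H[1], ranges$H[2])
  os <- seq(ranges$O[1], ranges$O[2])
  for (c in cs) for (h in hs) for (o in os) {
    m <- c * ORACLE_MASS[["C"]] + h * ORACLE_MASS[["H"]] + o * ORACLE_MASS[["O"]]
    cand_mz <- (m - charge * ORACLE_ELECTRON) / abs(charge)
    dbe <- c + 1 - h / 2
    if (abs(cand_mz - mz) <= tol_da && dbe >= dbr[1] && dbe <= dbr[2]) {
      hits <- c(hits, sprintf("C%d H%d O%d", c, h, o))
    }
  }
  hits
}

# two-sample toy scan set: one species seen in both samples
toy_dda_scans <- function() {
  dplyr::bind_rows(
    scan_tbl("A", 1, -1, peaks = data.frame(mz = 702.505, intensity = 1e4)),
    scan_tbl("B", 1, -1, peaks = data.frame(mz = 702.511, intensity = 3e4)),
    scan_tbl("A", 2, -1, precursor_mz = 702.508, scan_index = 2,
             peaks = data.frame(mz = c(255.233, 267.233), intensity = c(5e3, 4e3))),
    scan_tbl("B", 2, -1, precursor_mz = 702.508, scan_index = 2,
             peaks = data.frame(mz = c(255.233, 267.233), intensity = c(1.5e4, 1.2e4)))
  )
}

# MFQL text of a minimal PE query used across parser/evaluator tests
fig_pe_query <- function() {
  paste(
    "QUERYNAME = PE;",
    "DEFINE prPE = 'C[30..50] H[40..100] N[1..1] O[8..8] P[1..1]' WITH DBR = (1.5, 14.5), CHG = -1;",
    "DEFINE FA1 = 'C[10..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;",
    "DEFINE FA2 = 'C[10..22] H[11..43] O[2..2]' WITH DBR = (1.5, 7.5), CHG = -1;",
    "IDENTIFY prPE IN MS1-, FA1 IN MS2-, FA2 IN MS2-;",
    "SUCHTHAT FA1.chemsc + FA2.chemsc + C5H11O4N1P1 == PR.chemsc;",
    "REPORT MASS = PR.mass; CHEMSC = PR.chemsc; INTENS = PR.intensity;",
    sep = "\n")
}

hires_settings <- function(...) {
  masterscan_settings(ms1_model = resolution_model(5e5, 0, 700),
                      ms2_model = resolution_model(5e5, 0, 700),
                      tol = mass_tolerance(5, "ppm"), ...)
}

sum_intensity <- function(records) vapply(records$intensity, sum, numeric(1))
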