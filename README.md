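# lipidquery

Cross-platform interpretation of shotgun lipidomics spectra in R.

Shotgun lipidomics identifies and quantifies lipid molecular species by
direct infusion of a total lipid extract into a tandem mass spectrometer.
The catch is that different instruments produce differently structured
datasets — survey + full MS/MS spectra from data-dependent acquisition
(DDA) on high-resolution machines, but precursor-ion scans (PIS) and
neutral-loss scans (NLS) on triple quadrupoles — and most interpretation
software is wedded to one of them. `lipidquery` makes the three modes
interchangeable:

* **MasterScan** — scans are merged into representative spectra and peaks
  are aligned across samples into clusters carrying one intensity-weighted
  average mass plus the per-sample intensities, filtered by minimal
  intensity and an occupancy threshold, and stored in a versioned
  flat-file container.
* **MFQL queries** — lipid classes are described by *sum-composition
  constraints* instead of mass lists. The phosphatidylethanolamine (PE)
  query DEFINEs the intact precursor `prPE` and two acyl-anion fragments
  `FA1`, `FA2` (singly charged, `CHG = -1`, double-bond equivalents `DBR`
  within 1.5–7.5), IDENTIFYs them in MS1−/MS2−, and accepts an assignment
  SUCHTHAT

  ```
  FA1.chemsc + FA2.chemsc + C5H11O4N1P1 == PR.chemsc
  ```

  i.e. the two fatty-acid compositions plus the head-group/backbone
  constant add up to the precursor composition. A PE 33:1 molecular anion
  at *m/z* 702.5 with acyl anions at 255.2 (16:0) and 267.2 (17:1) is
  thereby resolved as the molecular species PE 16:0/17:1.
* **Transposition** — PIS/NLS spectra are aligned by precursor mass and
  rearranged into virtual MS/MS spectra
  (`[precursor mass]: [frag1, abundance], ...`), after which the *same*
  queries apply.
* **Quantification** — isotope-corrected precursor intensities, normalized
  per class to relative abundances; `profile_concordance()` compares
  profiles between modes or instruments (r², slope).

A synthetic-data module (`generate_lipidome()`, `simulate_dda()`,
`simulate_pis()`, `simulate_nls()`) generates PE/PG lipidomes and all
three dataset shapes with configurable instrument imperfections; it is the
test bed for every other module.

## Worked example

```r
library(lipidquery)

lip <- generate_lipidome(classes = c("PE", "PG"), n_species = 6, seed = 42)
scans <- simulate_dda(lip, instrument_model(), n_replicates = 4, seed = 43)
settings <- masterscan_settings(ms1_model = resolution_model(2.5e4, 0, 700),
                                ms2_model = resolution_model(2.5e4, 0, 700))
ms <- build_masterscan(scans, settings)
ms
#> <master_scan> v1.0, polarity -1, 4 sample(s)
#>   precursor clusters: 51 (0 virtual)
#>   fragment clusters:  305

records <- run_queries(list(mfql_example("pe_dda"), mfql_example("pg_dda")), ms)
records[, c("query", "annotation", "molecular_species", "formula",
            "precursor_mz", "error_ppm")]
#> # A tibble: 6 × 6
#>   query annotation molecular_species formula          precursor_mz error_ppm
#>   <chr> <chr>      <chr>             <chr>                   <dbl>     <dbl>
#> 1 PE    PE 29:4    PE 12:4/17:0      C34 H59 N1 O8 P1         640.     0.575
#> 2 PE    PE 31:6    PE 14:5/17:1      C36 H59 N1 O8 P1         664.    -2.78
#> 3 PE    PE 36:4    PE 15:3/21:1      C41 H73 N1 O8 P1         739.     0.686
#> 4 PE    PE 37:2    PE 15:2/22:0      C42 H79 N1 O8 P1         757.    -2.90
#> 5 PG    PG 29:7    PG 12:2/17:5      C35 H54 O10 P1           665.    -2.35
#> 6 PG    PG 32:9    PG 14:3/18:6      C38 H56 O10 P1           703.    -4.12
```

All six simulated species are recovered as molecular species (class plus
both fatty acids), each with its assigned precursor composition and mass
error in ppm; the 45 chemical-noise precursor clusters match no query.
Class-normalized relative abundances (mean over the four replicates):

```r
profiles <- class_normalize(isotopic_correction(records, ms))
dplyr::group_by(profiles, class, species) |>
  dplyr::summarise(abundance = mean(abundance), .groups = "drop")
#> # A tibble: 6 × 3
#>   class species abundance
#>   <chr> <chr>       <dbl>
#> 1 PE    PE 29:4    0.492
#> 2 PE    PE 31:6    0.148
#> 3 PE    PE 36:4    0.308
#> 4 PE    PE 37:2    0.0518
#> 5 PG    PG 29:7    0.776
#> 6 PG    PG 32:9    0.224
```

Each class sums to 1 per sample; these are the quantities compared across
acquisition modes. `autoplot(profiles)` draws the per-class bar profiles,
and `tidy(ms)` / `glance(ms)` expose the MasterScan content as tibbles.

A command-line front end wraps the same pipeline:

```sh
lipidquery simulate --seed 5 --classes PE,PG --n-species 6 --mode dda --out data/
lipidquery run --config exp.yaml --queries pe.mfql,pg.mfql
```

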