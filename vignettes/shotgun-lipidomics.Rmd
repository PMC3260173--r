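---
title: "Interpreting shotgun lipidomics spectra across acquisition modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting shotgun lipidomics spectra across acquisition modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidquery)
```

## The problem

Shotgun lipidomics infuses a total lipid extract directly into a tandem mass
spectrometer and identifies molecular species from accurate intact masses and
structure-specific fragments, without chromatographic separation. Different
instruments acquire differently structured datasets: rapid-scanning
high-resolution machines run data-dependent acquisition (DDA: a survey MS1
scan, then one full MS/MS spectrum per selected precursor), while triple
quadrupoles profile lipids by precursor-ion scanning (PIS: the intensity of
one fixed fragment recorded along the precursor axis) or neutral-loss
scanning (NLS: precursors losing a fixed mass difference). `lipidquery`
interprets all three through one machinery:

1. **MasterScan** — repeated scans are merged into representative spectra;
   peaks are aligned across samples into clusters carrying a single
   intensity-weighted average mass and the per-sample intensities.
2. **MFQL** — a small query language (DEFINE / IDENTIFY / SUCHTHAT / REPORT)
   describes a lipid class as *sum-composition constraints* rather than
   lists of expected masses, and states the arithmetic that ties fragments
   to their precursor.
3. **Transposition** — PIS and NLS spectra are rearranged into virtual
   MS/MS spectra (`[precursor mass]: [fragment, abundance], ...`) so the
   same MasterScan and the same queries apply.
4. **Quantification** — isotope-corrected intensities, normalized per lipid
   class to relative abundances.

## Composition algebra

All mass arithmetic runs over integer elemental compositions
(`composition()`, `as_composition()`). Monoisotopic masses use IUPAC
atomic masses; ion m/z subtracts `charge` electron masses
(`ion_mz()`); at ppm-level accuracy the electron is not negligible.
Double-bond equivalents use

$$\mathrm{DBE} = C + 1 - \tfrac{H}{2} + \tfrac{N + P}{2},$$

treating N and P as trivalent. This convention makes a saturated acyl
anion C~n~H~2n-1~O~2~ come out at DBE 1.5, which is why the acyl-anion
queries use the DBR window (1.5, 7.5) for 0–6 double bonds. The DBE
convention for phosphorus is a package choice: it is fixed here because it
reproduces that anchor, not asserted as the only possible convention.

`enumerate_compositions()` exhaustively scans a constraint box (per-element
count ranges) and keeps candidates whose ion m/z matches the measured mass
within tolerance and whose DBE lies in the window. Exhaustiveness over the
box is part of the contract: the unit tests compare it against a naive
triple loop. Tolerances (`mass_tolerance()`) can be relative (ppm) or
absolute (Th) because the workflow mixes high-resolution and
unit-resolution instruments.

## MasterScan construction

Peak grouping is a deterministic greedy procedure: clusters are seeded from
the most intense remaining peak and collect peaks within the tolerance
`m/R(m)` given by the linear resolution model `R(m) = r0 + slope (m -
m_ref)`. In cross-sample alignment a sample contributes at most one peak
per cluster (nearest in m/z wins; a displaced peak re-enters the pool), so
the total intensity is conserved — a property test. Merged intensity across
repeated scans is the summed member intensity divided by the number of
contributing scans, making intensities independent of how many scans were
acquired. Two data-reduction constraints apply: a minimal intensity
(against the maximal per-sample intensity, so a species present in a subset
of samples survives) and the occupancy threshold — the fraction of
acquisitions in which a peak must appear; at 1.0 only peaks observed in
every spectrum are kept. Occupancy counts samples by default; a `"scans"`
basis is available because the replicate-level reading is equally
defensible.

MS/MS scans are grouped by precursor m/z within the selection window
(±0.5 Th by default, matching unit-resolution precursor selection) and
attached to the nearest survey cluster. Groups with no survey peak in
reach get a flagged *virtual* precursor whose per-sample intensity is the
summed fragment signal; a transposed PIS/NLS dataset consists entirely of
such virtual precursors. Virtual (transposed) scans group by near-exact
precursor equality instead of the selection window, because their
precursor values are already aligned cluster masses; attaching them to
windows would let unrelated chemical-noise clusters capture species
fragments.

The MasterScan persists as versioned JSON (`save_masterscan()` /
`load_masterscan()`); loading refuses unknown format versions rather than
guessing.

## The MFQL dialect

The grammar is a defined dialect: `QUERYNAME`, one `DEFINE` per variable
(constraint string, DBR interval, charge), `IDENTIFY <var> IN MS1−/MS2−/…`,
an optional `SUCHTHAT` boolean/arithmetic expression over variable
attributes (`chemsc`, `mass`, `intensity`, `errppm`), and `REPORT`
columns. Design choices worth stating:

* Composition equality in SUCHTHAT is exact element-wise equality, not mass
  equality — the constraint is that sum compositions *add up*.
* `PR` aliases the query's MS1 variable, so the canonical phrasing
  `FA1.chemsc + FA2.chemsc + C5H11O4N1P1 == PR.chemsc` works regardless of
  the precursor variable's name. Exactly one MS1-anchored variable is
  allowed per query; fragment variables are unlimited.
* When several precursor compositions fit within tolerance, all are
  emitted, ranked by absolute ppm error; the package deliberately applies
  no disambiguation rule, since none is scientifically established for
  shotgun data.
* Records identical up to permutation of fragment variables with identical
  constraints are reported once: without this, every diacyl species would
  appear twice with FA1/FA2 swapped.
* sn-positions are never asserted structurally; the acyl-anion intensity
  ratio can be REPORTed (`FA1.intensity / FA2.intensity`) and interpreted
  by the user.
* A per-query `TOLERANCE` override is supported as a dialect extension.
* Scripts written for other MFQL implementations are not guaranteed to
  parse.

Identification of fragments in virtual spectra uses an absolute tolerance
(±0.5 Th by default) instead of ppm, because the fragment axis of a
transposed spectrum holds the *nominal* monitored values (a triple quad
parks Q3 on the target mass); fragment mass errors are not meaningful
there and are recorded as NA.

Species are annotated `Class C:D` (total fatty-acid carbons and double
bonds) from the bound acyl anions when at least two are resolved, else
from the precursor composition via the PE/PG head-group registry; with
both acyls resolved the molecular species (`PE 16:0/17:1`) is reported as
well.

## Quantification

Isotopic correction works within one lipid class in order of ascending
precursor m/z: each species' predicted isotopologue envelope (full
binomial/multinomial convolution of natural abundances, truncated and
renormalized) is scaled by its intensity and subtracted from any heavier
record sitting at an isotopologue spacing (1.00336 Da per neutron) within
the MS1 tolerance — the classic M+2 overlap with the species one double
bond down. Corrected intensities are clipped at zero and flagged; the
correction can only decrease intensities, which is asserted as a property
test. Fragment intensities are corrected with the fragment's own
composition pattern (whether the original tool used the fragment's or the
precursor's pattern is not derivable from the published description; the
fragment's own pattern is the physically direct choice). Cross-class
overlaps are not corrected — no published rule exists.

`class_normalize()` divides species intensities by the class total per
sample; records colliding on one sum annotation (isobars of one class, or
one species reported as several molecular species) are combined by
summation first. `profile_concordance()` compares two profiles the way
cross-platform validations are reported: mean abundance per species,
ordinary least squares of one profile on the other with a free intercept,
returning r² and slope. OLS with intercept is a choice — the quantities
compared are compositional and a through-origin fit would be equally
defensible; the choice is recorded here and used consistently.

## The synthetic testbed

`generate_lipidome()` draws distinct diacyl PE/PG species (fatty acids
from a pool of chain lengths 12–22 with 0–6 double bonds, abundances
log-uniform over 1e4–1e6) and the simulators produce the three dataset
shapes: DDA (4 replicates by default), PIS over the acyl-anion masses, NLS
over Δ 141.02 ([M+H]⁺ of PE) and Δ 189.04 ([M+NH₄]⁺ of PG), 3 replicates
each, mirroring the replication of the validation experiments this package
models. The default instrument imperfections are 5 ppm Gaussian mass
error, 10% relative intensity noise, chemical noise at 0.02 peaks/Th with
exponential intensities (mean 1e3), and no detection limit. Each replicate
is treated as one sample.

What the simulator deliberately does **not** emulate: isotopologue
envelopes (peaks are monoisotopic sticks; the isotopic correction is
therefore exercised by constructed unit-test records, and runs as a
near-no-op in the simulated pipelines), peak shapes and centroiding
artifacts, Q1/Q3 transmission efficiency, scan-speed artifacts, in-source
fragmentation, ether lipids and cardiolipins. Passing tests on this
testbed therefore demonstrate the correctness of the interpretation
machinery, not instrument realism.

## Numerical and processing choices

* Grouping tolerance versus data quality: `m/R(m)` with R = 7500 (FWHM,
  the resolution the modeled instruments share) is the default and is the
  right scale for profile-derived peak lists. The simulator, however,
  emits centroided sticks whose scatter is set by mass accuracy, not peak
  width; the validation workflows therefore group with an
  accuracy-matched tolerance (about 4x the cross-scan error spread,
  r0 = 2.5e4, i.e. ~28 ppm). Too tight a tolerance splits clusters across
  replicates; too loose a tolerance merges distinct species that the data
  could resolve. Both failure modes exist physically, and species closer
  than the grouping tolerance genuinely merge — with 20 random species
  over two classes this occasionally assigns one cluster's intensity to
  two compositions, visible as occasional outliers in the cross-mode
  comparison.
* Zero-noise closure tests use an essentially exact grouping tolerance
  (r0 = 5e5) because noise-free sticks are infinitely sharp.
* Identification tolerance defaults to 10 ppm; enumeration boxes are
  guarded against combinatorial blow-up (error beyond ~2e6 candidates).
* Ties in greedy grouping break by m/z, then owner, then input order, so
  every pipeline stage is deterministic; rerunning a configuration
  reproduces results byte for byte.
* Problem sizes in the test-suite validation runs: 20-species lipidomes,
  2–4 replicates, and a 50-seed cross-mode comparison assessed on the mean
  r² and slope per mode pair and class; these sizes give stable statistics
  while keeping the suite quick to run.

## Known limitations

* Only PE and PG are wired into the simulator and the annotation registry;
  the query engine itself is class-agnostic (any class expressible as
  constraints plus fragment arithmetic works, but annotation falls back to
  `NA` off-registry).
* Charge states beyond |1| are untested and cardiolipins are out of scope.
* No false-discovery control: every assignment satisfying a query is
  reported, because no statistical framework for shotgun lipid
  identification exists to implement.
* Quantification is relative (class-normalized); absolute quantification
  against internal standards is not provided.
* mzXML reading requires centroided spectra and the `mzR` package; mzML
  and vendor formats are not read.
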