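#' Default fatty acid pool for the simulator
#'
#' All chain lengths 12–22 with 0–6 double bonds.
#' @export
fatty_acid_pool <- function(chains = 12:22, dbs = 0:6) {
  tidyr::expand_grid(chain = chains, db = dbs)
}

#' Instrument imperfection model for the simulator
#'
#' @param resolution a [resolution_model()]; default 7500 FWHM, flat.
#' @param mass_error_ppm Gaussian standard deviation of m/z errors (ppm).
#' @param intensity_cv relative standard deviation of intensity noise.
#' @param noise_density chemical-noise peaks per Th of scanned range.
#' @param noise_intensity mean of the exponential chemical-noise intensity.
#' @param detection_limit peaks below this intensity are not recorded.
#' @param mz_range scanned precursor m/z range.
#' @export
instrument_model <- function(resolution = resolution_model(7500, 0, 700),
                             mass_error_ppm = 5, intensity_cv = 0.1,
                             noise_density = 0.02, noise_intensity = 1e3,
                             detection_limit = 0, mz_range = c(400, 1000)) {
  stopifnot(mass_error_ppm >= 0, intensity_cv >= 0, noise_density >= 0,
            detection_limit >= 0)
  structure(list(resolution = resolution, mass_error_ppm = mass_error_ppm,
                 intensity_cv = intensity_cv, noise_density = noise_density,
                 noise_intensity = noise_intensity,
                 detection_limit = detection_limit, mz_range = mz_range),
            class = "instrument_model")
}

#' A noise-free instrument (for closure tests)
#' @export
perfect_instrument <- function() {
  instrument_model(mass_error_ppm = 0, intensity_cv = 0, noise_density = 0)
}

#' One explicitly chosen molecular species
#'
#' @param class lipid class (`"PE"` or `"PG"`).
#' @param fa1,fa2 fatty acids as `c(chain, double_bonds)`.
#' @param abundance relative molar abundance.
#' @return A one-row lipidome tibble (row-bind several to build a lipidome).
#' @export
lipid_species <- function(class, fa1, fa2, abundance = 1e5) {
  info <- class_info(class)
  fas <- list(fa1, fa2)
  fas <- fas[order(purrr::map_dbl(fas, 1), purrr::map_dbl(fas, 2))]
  a1 <- acyl_anion(fas[[1]][1], fas[[1]][2])
  a2 <- acyl_anion(fas[[2]][1], fas[[2]][2])
  anion <- a1 + a2 + as_composition(info$anion_constant)
  neutral <- anion + composition(H = 1)
  n <- fas[[1]][1] + fas[[2]][1]
  d <- fas[[1]][2] + fas[[2]][2]
  tibble::tibble(
    class = class,
    fa1_chain = as.integer(fas[[1]][1]), fa1_db = as.integer(fas[[1]][2]),
    fa2_chain = as.integer(fas[[2]][1]), fa2_db = as.integer(fas[[2]][2]),
    species = sprintf("%s %d:%d", class, n, d),
    molecular_species = sprintf("%s %d:%d/%d:%d", class,
                                fas[[1]][1], fas[[1]][2], fas[[2]][1], fas[[2]][2]),
    formula = format(neutral),
    anion_formula = format(anion),
    abundance = abundance)
}

#' Generate a reproducible synthetic lipidome
#'
#' Draws distinct diacyl species of the requested classes with fatty acids
#' from the pool and log-uniform abundances; the stand-in for a real total
#' lipid extract in all validation experiments.
#'
#' @param classes classes to draw from (must be in [lipid_classes]).
#' @param n_species total number of distinct molecular species.
#' @param seed RNG seed; the result is a pure function of the arguments.
#' @param fa_pool fatty acid pool tibble (`chain`, `db`).
#' @param abundance_range log-uniform abundance range.
#' @return A lipidome tibble (one row per species).
#' @export
generate_lipidome <- function(classes = c("PE", "PG"), n_species = 20, seed = 1,
                              fa_pool = fatty_acid_pool(),
                              abundance_range = c(1e4, 1e6)) {
  purrr::walk(classes, class_info) # validate early
  if (n_species == 0) return(lipid_species("PE", c(16, 0), c(16, 0))[0, ])
  withr_seed(seed, {
    out <- list()
    seen <- character(0)
    tries <- 0
    while (length(out) < n_species) {
      tries <- tries + 1
      if (tries > 100 * n_species) {
        stop("cannot draw ", n_species, " distinct species from this pool",
             call. = FALSE)
      }
      cl <- sample(classes, 1)
      i1 <- sample.int(nrow(fa_pool), 1)
      i2 <- sample.int(nrow(fa_pool), 1)
      ab <- 10^stats::runif(1, log10(abundance_range[1]), log10(abundance_range[2]))
      sp <- lipid_species(cl, c(fa_pool$chain[i1], fa_pool$db[i1]),
                          c(fa_pool$chain[i2], fa_pool$db[i2]), ab)
      if (sp$molecular_species %in% seen) next
      seen <- c(seen, sp$molecular_species)
      out[[length(out) + 1]] <- sp
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$class, .data$species,
                   .data$molecular_species)
  })
}

# evaluate expr under a locally seeded RNG, restoring the global state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

noisy_mz <- function(mz, inst) mz * (1 + stats::rnorm(length(mz), 0, inst$mass_error_ppm * 1e-6))
noisy_int <- function(x, inst) pmax(x * (1 + stats::rnorm(length(x), 0, inst$intensity_cv)), 0)

chem_noise <- function(inst, lo = inst$mz_range[1], hi = inst$mz_range[2]) {
  n <- stats::rpois(1, inst$noise_density * max(hi - lo, 0))
  if (n == 0) return(tibble::tibble(mz = numeric(), intensity = numeric()))
  tibble::tibble(mz = stats::runif(n, lo, hi),
                 intensity = stats::rexp(n, 1 / inst$noise_intensity))
}

finish_peaks <- function(pk, inst) {
  pk <- pk[pk$intensity >= inst$detection_limit & pk$intensity > 0, ]
  dplyr::arrange(pk, .data$mz)
}

species_anion_mz <- function(lip) {
  purrr::map_dbl(lip$anion_formula, ion_mz, charge = -1)
}

species_pos_mz <- function(lip) {
  purrr::map2_dbl(lip$formula, lip$class, function(f, cl) {
    info <- class_info(cl)
    ion_mz(as_composition(f) + as_composition(info$pos_adduct), +1)
  })
}

#' Simulate a data-dependent acquisition (DDA) shotgun experiment
#'
#' Per replicate (treated as one sample, `S1`, `S2`, ...): one negative-mode
#' survey scan with the [M-H]- peak of every species, then one full MS/MS
#' scan per species containing its two acyl-anion fragments, intensities
#' proportional to abundance with an optional sn-position bias. Mass error,
#' intensity noise and chemical noise follow the instrument model.
#'
#' @param lip lipidome tibble from [generate_lipidome()].
#' @param inst an [instrument_model()].
#' @param n_replicates number of replicate acquisitions.
#' @param seed RNG seed.
#' @param sn_bias intensity ratio of the first (lighter) to the second acyl
#'   anion; 1 means equal.
#' @return A scan tibble.
#' @export
simulate_dda <- function(lip, inst = instrument_model(), n_replicates = 4,
                         seed = 1, sn_bias = 1) {
  withr_seed(seed, {
    anion_mz <- species_anion_mz(lip)
    share1 <- sn_bias / (1 + sn_bias)
    out <- list()
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("S%d", r)
      idx <- 1L
      ms1 <- tibble::tibble(mz = noisy_mz(anion_mz, inst),
                            intensity = noisy_int(lip$abundance, inst))
      ms1 <- finish_peaks(dplyr::bind_rows(ms1, chem_noise(inst)), inst)
      out[[length(out) + 1]] <- scan_tbl(sid, 1, -1, peaks = ms1,
                                         scan_index = idx, replicate = r)
      for (i in seq_len(nrow(lip))) {
        idx <- idx + 1L
        f1 <- acyl_anion(lip$fa1_chain[i], lip$fa1_db[i])
        f2 <- acyl_anion(lip$fa2_chain[i], lip$fa2_db[i])
        fmz <- c(ion_mz(f1, -1), ion_mz(f2, -1))
        fint <- lip$abundance[i] * c(share1, 1 - share1)
        if (isTRUE(all.equal(fmz[1], fmz[2]))) {
          fmz <- fmz[1]; fint <- sum(fint)
        }
        pk <- tibble::tibble(mz = noisy_mz(fmz, inst),
                             intensity = noisy_int(fint, inst))
        pk <- finish_peaks(dplyr::bind_rows(
          pk, chem_noise(inst, lo = 100, hi = anion_mz[i])), inst)
        out[[length(out) + 1]] <- scan_tbl(
          sid, 2, -1, peaks = pk, precursor_mz = anion_mz[i],
          scan_index = idx, replicate = r)
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate precursor-ion scanning (PIS) experiments
#'
#' One negative-mode scan per monitored acyl-anion m/z per replicate; a
#' species contributes a precursor-axis peak to the scan of a monitored
#' value if (and only if) one of its fatty acids yields that acyl anion,
#' with intensity proportional to abundance times the acyl share.
#'
#' @inheritParams simulate_dda
#' @param fragment_mz_list monitored fragment m/z values; defaults to the
#'   nominal (one-decimal) acyl anion masses present in the lipidome.
#' @param match_window how close (Th) the true acyl m/z must be to the
#'   monitored value to produce signal.
#' @export
simulate_pis <- function(lip, fragment_mz_list = NULL, inst = instrument_model(),
                         n_replicates = 3, seed = 1, sn_bias = 1,
                         match_window = 0.3) {
  acyl_mz <- function(chain, db) ion_mz(acyl_anion(chain, db), -1)
  if (is.null(fragment_mz_list)) {
    fragment_mz_list <- sort(unique(round(c(
      purrr::map2_dbl(lip$fa1_chain, lip$fa1_db, acyl_mz),
      purrr::map2_dbl(lip$fa2_chain, lip$fa2_db, acyl_mz)), 1)))
  }
  if (length(fragment_mz_list) == 0) stop("empty monitored fragment list", call. = FALSE)
  withr_seed(seed, {
    anion_mz <- species_anion_mz(lip)
    share1 <- sn_bias / (1 + sn_bias)
    mz1 <- purrr::map2_dbl(lip$fa1_chain, lip$fa1_db, acyl_mz)
    mz2 <- purrr::map2_dbl(lip$fa2_chain, lip$fa2_db, acyl_mz)
    out <- list()
    idx <- 0L
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("S%d", r)
      for (f in fragment_mz_list) {
        idx <- idx + 1L
        hit1 <- abs(mz1 - f) <= match_window
        hit2 <- abs(mz2 - f) <= match_window
        sig <- lip$abundance * (share1 * hit1 + (1 - share1) * hit2)
        keep <- sig > 0
        pk <- tibble::tibble(mz = noisy_mz(anion_mz[keep], inst),
                             intensity = noisy_int(sig[keep], inst))
        pk <- finish_peaks(dplyr::bind_rows(pk, chem_noise(inst)), inst)
        out[[length(out) + 1]] <- scan_tbl(
          sid, 2, -1, mode = "pis", peaks = pk,
          monitored_fragment_mz = f, scan_index = idx, replicate = r)
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate neutral-loss scanning (NLS) experiments
#'
#' Positive-mode analogue of [simulate_pis()]: one scan per monitored mass
#' difference per replicate. A species appears on the precursor axis of the
#' scan whose delta matches its class-specific head-group loss ([M+H]+ of
#' PE loses 141.02 Da; [M+NH4]+ of PG loses 189.04 Da).
#'
#' @inheritParams simulate_pis
#' @param delta_list monitored neutral-loss mass differences (Th).
#' @export
simulate_nls <- function(lip, delta_list = c(141.02, 189.04),
                         inst = instrument_model(), n_replicates = 3, seed = 1,
                         match_window = 0.3) {
  if (length(delta_list) == 0) stop("empty neutral-loss list", call. = FALSE)
  withr_seed(seed, {
    pos_mz <- species_pos_mz(lip)
    true_delta <- purrr::map_dbl(lip$class,
                                 ~ monoisotopic_mass(class_info(.x)$nls_loss))
    out <- list()
    idx <- 0L
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("S%d", r)
      for (d in delta_list) {
        idx <- idx + 1L
        keep <- abs(true_delta - d) <= match_window
        pk <- tibble::tibble(mz = noisy_mz(pos_mz[keep], inst),
                             intensity = noisy_int(lip$abundance[keep], inst))
        pk <- finish_peaks(dplyr::bind_rows(pk, chem_noise(inst)), inst)
        out[[length(out) + 1]] <- scan_tbl(
          sid, 2, 1, mode = "nls", peaks = pk,
          neutral_loss_delta = d, scan_index = idx, replicate = r)
      }
    }
    dplyr::bind_rows(out)
  })
}
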