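#' Configuration for the stepped-collision-energy spectrum simulator
#'
#' The simulator emulates the composite MS2 spectra produced by stepping
#' the normalized collision energy: the low-energy regime contributes the
#' glycosidic Y-ion ladder (intact peptide plus a shrinking glycan), the
#' high-energy regime contributes peptide-backbone y ions, and oxonium
#' b1-b3 ions appear throughout. Intensities are class-based constants
#' (oxonium high, glycosidic ladder mid, backbone low), not a physical
#' fragmentation model.
#'
#' @param seed Integer seed; `NULL` uses the current RNG state (so a
#'   caller can seed once for a whole batch).
#' @param include_glycosidic_ladder Low-energy regime on/off.
#' @param include_peptide_backbone High-energy regime on/off.
#' @param include_oxonium Oxonium b1-b3 on/off.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (default 0.005).
#' @param n_noise_peaks Number of uniform-random noise peaks (default 30).
#' @param noise_mz_range Noise m/z window (default 200-2000 Da).
#' @param intensity_profile Named numeric: relative intensity per ion
#'   class (`oxonium`, `ladder`, `backbone`, `noise_max`).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = NULL,
                              include_glycosidic_ladder = TRUE,
                              include_peptide_backbone = TRUE,
                              include_oxonium = TRUE,
                              mz_jitter_sd = 0.005,
                              n_noise_peaks = 30L,
                              noise_mz_range = c(200, 2000),
                              intensity_profile = c(oxonium = 100,
                                                    ladder = 60,
                                                    backbone = 20,
                                                    noise_max = 10)) {
  stopifnot(mz_jitter_sd >= 0, n_noise_peaks >= 0L,
            noise_mz_range[1] < noise_mz_range[2])
  structure(list(seed = seed,
                 include_glycosidic_ladder = include_glycosidic_ladder,
                 include_peptide_backbone = include_peptide_backbone,
                 include_oxonium = include_oxonium,
                 mz_jitter_sd = mz_jitter_sd,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range,
                 intensity_profile = intensity_profile),
            class = "simulation_config")
}

#' Simulate one glycopeptide MS2 spectrum with ground truth
#'
#' Peak set by regime: (i) the glycosidic ladder -- y ions retaining the
#' full peptide plus k glycan residues for k = 1..len(glycan), the top
#' rung emitted as the intact `[M+H]+`; (ii) peptide-backbone y ions
#' (ordinals 1..len(peptide), no glycan residues); (iii) oxonium b1-b3 of
#' the glycan prefix. Every true peak is jittered by Gaussian noise of SD
#' `mz_jitter_sd`, and `n_noise_peaks` uniform-random noise peaks are
#' added, kept at least 0.1 Da away from any true peak so ground truth
#' stays unambiguous. The simulated precursor charge is 2+ for neutral
#' mass up to 3000 Da and 3+ above. Deterministic under a fixed seed.
#'
#' @param form A [glycopeptide_form()].
#' @param cfg A [simulation_config()].
#' @param alphabet A [glycan_alphabet()].
#' @param spectrum_id Title for the spectrum.
#' @return List with `spectrum` (a `spectrum` object) and `truth` (a
#'   one-row data frame: spectrum/entry identifiers, sequences, fucose and
#'   oxidation positions, charge, precursor m/z).
#' @export
simulate_spectrum <- function(form, cfg = simulation_config(),
                              alphabet = default_alphabet(),
                              spectrum_id = "simulated_1") {
  stopifnot(inherits(form, "glycopeptide_form"),
            inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  proton <- mass_constants$proton
  nm <- neutral_mass(form, alphabet)
  p_len <- nchar(form$peptide)
  g <- form$glycan_len
  ions <- fragment_ions(form, alphabet, charges = 1L)
  y1 <- ions[ions$series == "y" & ions$charge == 1L, , drop = FALSE]
  prof <- cfg$intensity_profile
  mz <- numeric(); int <- numeric()
  if (cfg$include_glycosidic_ladder && g > 0L) {
    ord <- p_len + seq_len(g - 1L)          # peptide + 1..g-1 glycan residues
    mz <- c(mz, y1$mz[match(ord, y1$ordinal)], nm + proton)
    int <- c(int, rep(prof[["ladder"]], g))
  }
  if (cfg$include_peptide_backbone && p_len >= 1L) {
    ord <- seq_len(min(p_len, nrow(y1)))    # y1..y_plen (no glycan)
    mz <- c(mz, y1$mz[match(ord, y1$ordinal)])
    int <- c(int, rep(prof[["backbone"]], length(ord)))
  }
  if (cfg$include_oxonium && g > 0L) {
    b <- ions[ions$series == "b" & ions$ordinal <= min(3L, g) &
                ions$charge == 1L, , drop = FALSE]
    mz <- c(mz, b$mz)
    int <- c(int, rep(prof[["oxonium"]], nrow(b)))
  }
  true_mz <- mz
  if (cfg$mz_jitter_sd > 0)
    mz <- mz + stats::rnorm(length(mz), 0, cfg$mz_jitter_sd)
  # uniform noise peaks, rejected within 0.1 Da of any true peak
  if (cfg$n_noise_peaks > 0L) {
    noise <- numeric(0)
    guard <- 0L
    while (length(noise) < cfg$n_noise_peaks && guard < 100L) {
      draw <- stats::runif(cfg$n_noise_peaks - length(noise),
                           cfg$noise_mz_range[1], cfg$noise_mz_range[2])
      ok <- vapply(draw, function(x)
        !length(true_mz) || min(abs(true_mz - x)) > 0.1, logical(1))
      noise <- c(noise, draw[ok])
      guard <- guard + 1L
    }
    mz <- c(mz, noise)
    int <- c(int, stats::runif(length(noise), 1, prof[["noise_max"]]))
  }
  z <- if (nm > 3000) 3L else 2L
  s <- spectrum(spectrum_id, precursor_mz = (nm + z * proton) / z,
                charge = z, peaks = cbind(mz, int))
  truth <- data.frame(
    spectrum_id = spectrum_id,
    entry_id = form$entry_id,
    peptide = form$peptide, glycan_seq = form$glycan_seq,
    glycan_name = form$glycan_name,
    fucose_pos = paste(form$fucose_pos, collapse = ","),
    oxidation_pos = paste(form$oxidation_pos, collapse = ","),
    charge = z, precursor_mz = s$precursor_mz,
    stringsAsFactors = FALSE
  )
  list(spectrum = s, truth = truth)
}

#' Build an MGF fixture dataset with a ground-truth table
#'
#' Samples glycopeptide entries (with or without fucose) from a database,
#' simulates one composite spectrum per draw, and writes an MGF file plus
#' a tab-separated truth table mapping each spectrum to its generating
#' entry and modification placement.
#'
#' @param db A `glyco_db` from [build_database()].
#' @param n_spectra Number of spectra to simulate (>= 1).
#' @param cfg A [simulation_config()]; its `seed` governs both sampling
#'   and simulation.
#' @param mgf_path,truth_path Output paths.
#' @param alphabet A [glycan_alphabet()].
#' @param fucose_prob Probabilities of attaching 0, 1, 2 fucoses to a
#'   sampled entry (renormalized when the glycan has too few O residues).
#' @return Invisible list with `spectra`, `truth`, `mgf_path`,
#'   `truth_path`.
#' @export
make_fixture_dataset <- function(db, n_spectra, cfg = simulation_config(),
                                 mgf_path, truth_path,
                                 alphabet = default_alphabet(),
                                 fucose_prob = c(0.6, 0.3, 0.1)) {
  stopifnot(inherits(db, "glyco_db"), n_spectra >= 1L)
  e <- db$entries
  if (!nrow(e)) stop("database is empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL                     # one RNG stream for the batch
  picks <- sample.int(nrow(e), n_spectra, replace = TRUE)
  spectra <- vector("list", n_spectra)
  truths <- vector("list", n_spectra)
  for (k in seq_len(n_spectra)) {
    row <- e[picks[k], ]
    chars <- strsplit(row$glycan_seq, "", fixed = TRUE)[[1]]
    o_pos <- which(chars == "O")
    nf_max <- min(length(o_pos), length(fucose_prob) - 1L)
    pr <- fucose_prob[seq_len(nf_max + 1L)]
    nf <- sample(0:nf_max, 1L, prob = pr / sum(pr))
    fuc <- if (nf > 0L) sort(sample(o_pos, nf)) else integer(0)
    form <- glycopeptide_form(row$peptide, row$glycan_seq,
                              fucose_pos = fuc,
                              entry_id = row$entry_id,
                              accession = row$accession,
                              glycan_name = row$glycan_name)
    sim <- simulate_spectrum(form, cfg_inner, alphabet,
                             spectrum_id = sprintf("sim_%04d|%s", k,
                                                   row$entry_id))
    spectra[[k]] <- sim$spectrum
    truths[[k]] <- sim$truth
  }
  truth <- do.call(rbind, truths)
  write_mgf(spectra, mgf_path)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(spectra = spectra, truth = truth, mgf_path = mgf_path,
                 truth_path = truth_path))
}
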