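ab <- default_alphabet()

test_that("candidate selection by precursor ppm matches a linear scan", {
  db <- toy_db(60, seed = 201)
  forms <- db_to_forms(db, ab, max_fucose = 1)
  f <- .33; i <- max(1L, as.integer(nrow(forms) * f))
  target <- forms[i, ]
  z <- 3L
  mz_exact <- (target$neutral_mass + z * 1.007276) / z
  s_exact <- spectrum("exact", mz_exact, z, cbind(500, 1))
  cand <- select_candidates(s_exact, forms, ppm = 10)
  expect_true(target$form_id %in% cand$form_id)
  # +25 ppm offset: rejected at 10 ppm, retained at 30 ppm
  s_off <- spectrum("off", mz_exact * (1 + 25e-6), z, cbind(500, 1))
  expect_false(target$form_id %in%
                 select_candidates(s_off, forms, ppm = 10)$form_id)
  expect_true(target$form_id %in%
                select_candidates(s_off, forms, ppm = 30)$form_id)
  # oracle: exhaustive scan over every form
  oracle <- forms$form_id[vapply(seq_len(nrow(forms)), function(j) {
    theo <- (forms$neutral_mass[j] + z * 1.007276) / z
    abs((mz_exact - theo) / theo * 1e6) <= 10
  }, logical(1))]
  expect_setequal(cand$form_id, oracle)
  expect_error(select_candidates(spectrum("x", 500, NA, cbind(1, 1)),
                                 forms), "unknown")
})

test_that("peak matching is one-to-one within tolerance", {
  f <- glycopeptide_form("ENGTISR", "OJUUJOJJJOO")
  ions <- scored_ions(fragment_ions(f, ab), f$glycan_len)
  # noise-free simulated peaks at exactly the 1+ ion positions
  i1 <- ions[ions$charge == 1, ]
  s <- spectrum("t", 1000, 2, cbind(i1$mz, rep(50, nrow(i1))))
  m <- match_peaks(s, i1, tol_da = 0.05)
  expect_equal(nrow(m), nrow(i1))
  expect_true(all(abs(m$error_da) < 1e-9))
  # a peak 0.06 Da away is not matched at 0.05 Da
  s2 <- spectrum("t2", 1000, 2, cbind(i1$mz[1] + 0.06, 50))
  expect_equal(nrow(match_peaks(s2, i1, tol_da = 0.05)), 0)
  expect_equal(nrow(match_peaks(s2, i1, tol_da = 0.07)), 1)
  # each peak consumed at most once even when two ions are close
  ions_close <- data.frame(series = "y", ordinal = 1:2, charge = 1L,
                           mz = c(500.00, 500.04), spans_glycan = FALSE)
  s3 <- spectrum("t3", 1000, 2, cbind(500.02, 50))
  expect_equal(nrow(match_peaks(s3, ions_close, tol_da = 0.05)), 1)
})

test_that("greedy matching equals exhaustive assignment on small instances", {
  set.seed(41)
  for (i in 1:25) {
    n_ion <- sample(3:8, 1)
    # ions separated by > 2 * tol, as real fragment series are
    ion_mz <- sort(200 + cumsum(runif(n_ion, 0.3, 50)))
    n_peak <- sample(3:20, 1)
    peak_mz <- sort(runif(n_peak, 195, max(ion_mz) + 5))
    # drop some peaks onto ions to create matches
    hit <- sample(n_ion, min(n_ion, 3))
    peak_mz <- sort(c(peak_mz, ion_mz[hit] + runif(length(hit), -0.04, 0.04)))
    ions <- data.frame(series = "y", ordinal = seq_along(ion_mz),
                       charge = 1L, mz = ion_mz, spans_glycan = FALSE)
    s <- spectrum("r", 1000, 2,
                  cbind(peak_mz, runif(length(peak_mz), 1, 100)))
    m <- match_peaks(s, ions, tol_da = 0.05)
    expect_equal(nrow(m),
                 oracle_max_matching(ion_mz, s$peaks[, 1], 0.05))
  }
})

test_that("binomial score equals the direct tail sum and is monotone", {
  # construct a spectrum giving exactly q = 0.01:
  # 10 ions spanning 100 Da, 10 peaks in range, tol 0.05
  ion_mz <- seq(500, 600, length.out = 10)
  ions <- data.frame(series = "y", ordinal = 1:10, charge = 1L,
                     mz = ion_mz, spans_glycan = FALSE)
  peaks <- cbind(seq(505, 595, length.out = 10), rep(10, 10))
  s <- spectrum("q", 1000, 2, peaks)
  sc5 <- score_psm(ions[1:5, ], s, ions, tol_da = 0.05)
  expect_equal(sc5$q, 0.01, tolerance = 1e-12)
  oracle <- -10 * log10(sum(dbinom(5:10, 10, 0.01)))
  expect_equal(sc5$score, oracle, tolerance = 1e-9)
  # k = 0 scores 0; score strictly increases with k at fixed n, q
  expect_equal(score_psm(ions[0, ], s, ions)$score, 0)
  scores <- vapply(1:10, function(k)
    score_psm(ions[seq_len(k), ], s, ions)$score, numeric(1))
  expect_true(all(diff(scores) > 0))
  # no scored ions -> score 0
  expect_equal(score_psm(ions[0, ], s, ions[0, ])$score, 0)
})

test_that("acceptance rules equal a brute-force re-check on 50 PSMs", {
  set.seed(42)
  psms <- data.frame(
    spectrum_id = rep(sprintf("s%02d", 1:10), each = 5),
    score = runif(50, 0, 60),
    precursor_error_ppm = runif(50, -9, 9),
    full_sequence = replicate(50, random_protein(8)),
    stringsAsFactors = FALSE
  )
  psms$p_value <- 10^(-psms$score / 10)
  # rank within spectrum exactly as the search does
  psms <- do.call(rbind, lapply(split(psms, psms$spectrum_id), function(g) {
    g <- g[order(-g$score, abs(g$precursor_error_ppm), g$full_sequence), ]
    g$rank <- seq_len(nrow(g))
    g
  }))
  acc <- rank_and_filter(psms, min_score = 25, max_p = 0.001)
  oracle_keep <- vapply(seq_len(nrow(psms)), function(i) {
    grp <- psms[psms$spectrum_id == psms$spectrum_id[i], ]
    top <- grp[order(-grp$score, abs(grp$precursor_error_ppm),
                     grp$full_sequence)[1], ]
    identical(top$full_sequence, psms$full_sequence[i]) &&
      psms$score[i] >= 25 && psms$p_value[i] < 0.001
  }, logical(1))
  expect_setequal(acc$full_sequence, psms$full_sequence[oracle_keep])
  # two candidates 30 vs 20: only the 30 survives; a lone 24 is rejected
  two <- data.frame(spectrum_id = "a", score = c(30, 20),
                    precursor_error_ppm = 0, full_sequence = c("A", "B"),
                    p_value = c(1e-4, 1e-4), rank = 1:2)
  expect_equal(rank_and_filter(two)$full_sequence, "A")
  one <- data.frame(spectrum_id = "b", score = 24, precursor_error_ppm = 0,
                    full_sequence = "C", p_value = 1e-4, rank = 1L)
  expect_equal(nrow(rank_and_filter(one)), 0)
})

test_that("decoys reverse the peptide, keep C-terminal K/R and the mass", {
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MKPEPTIDERENGTISR", stringsAsFactors = FALSE)
  lib <- as_glycan_library(data.frame(name = "g", sequence = "OJU"))
  # O-mode (PEPTIDER qualifies via its T); Keil rule off since the
  # peptide of interest starts with proline
  db <- build_database(prot, lib, mode = "O", keil = FALSE)
  dec <- build_decoys(db)
  expect_equal(nrow(dec$entries), nrow(db$entries))
  i <- which(db$entries$peptide == "PEPTIDER")
  expect_equal(dec$entries$peptide[i], "EDITPEPR")
  expect_equal(dec$entries$full_sequence[i], "OJUEDITPEPR")
  expect_true(all(startsWith(dec$entries$entry_id, "DECOY_")))
  # mass conserved under permutation
  for (j in seq_len(nrow(db$entries))) {
    ft <- glycopeptide_form(db$entries$peptide[j], db$entries$glycan_seq[j])
    fd <- glycopeptide_form(dec$entries$peptide[j], dec$entries$glycan_seq[j])
    expect_equal(neutral_mass(fd, ab), neutral_mass(ft, ab))
  }
})

test_that("fucose localization reads the Y1 +146 diagnostic", {
  pep <- "QDQCIYNTTYLNVQR"
  gly <- "OJUUJOJJJOO"  # O positions 1, 6, 10, 11; core O = 11
  cfg <- simulation_config(seed = 51, mz_jitter_sd = 0, n_noise_peaks = 0)
  core <- glycopeptide_form(pep, gly, fucose_pos = 11L)
  s_core <- simulate_spectrum(core, cfg, ab)$spectrum
  expect_equal(classify_fucose_site(core, s_core, ab), "core")
  antenna <- glycopeptide_form(pep, gly, fucose_pos = 6L)
  s_ant <- simulate_spectrum(antenna, cfg, ab)$spectrum
  expect_equal(classify_fucose_site(antenna, s_ant, ab), "antenna")
  # spectrum missing Y1 entirely -> undetermined
  s_bare <- spectrum("bare", 1000, 3, cbind(c(204.087, 366.14), c(9, 9)))
  expect_equal(classify_fucose_site(antenna, s_bare, ab), "undetermined")
  # no fucose -> not applicable
  plain <- glycopeptide_form(pep, gly)
  expect_equal(classify_fucose_site(plain, s_core, ab), "not_applicable")
})

test_that("composition summary equals a brute-force tally", {
  acc <- data.frame(
    glycan_seq = c(rep("OJUUJOJJJOO", 4), "UJO"),
    n_fucose = c(0, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
  tab <- summarize_by_composition(acc, ab)
  expect_equal(tab$n_psms[tab$composition == "O4 J5 U2" & tab$n_fucose == 0],
               3)
  expect_equal(tab$n_psms[tab$composition == "O4 J5 U2" & tab$n_fucose == 1],
               1)
  expect_equal(tab$n_psms[tab$composition == "O1 J1 U1"], 1)
  expect_equal(sum(tab$n_psms), nrow(acc))
  expect_equal(nrow(summarize_by_composition(acc[0, ], ab)), 0)
  # attached ratios are summarized per group by their median
  acc$ratio <- c(1.0, 1.2, 1.4, 2.0, 0.5)
  tab2 <- summarize_by_composition(acc, ab)
  expect_equal(tab2$median_ratio[tab2$composition == "O4 J5 U2" &
                                   tab2$n_fucose == 0], 1.2)
})

test_that("the report TSV round-trips accepted PSMs", {
  db <- toy_db(30, seed = 202)
  cfg <- simulation_config(seed = 53)
  paths <- withr::local_tempfile(fileext = c(".mgf", ".tsv", ".rep"))
  make_fixture_dataset(db, 5, cfg, paths[1], paths[2])
  forms <- db_to_forms(db, ab)
  psms <- glyco_search(read_mgf(paths[1]), forms, ab)
  acc <- rank_and_filter(psms)
  write_report(acc, paths[3])
  back <- read.delim(paths[3], stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(acc))
  expect_equal(back$score, acc$score, tolerance = 1e-9)
  expect_equal(back$spectrum_id, acc$spectrum_id)
  expect_identical(back$is_decoy, acc$is_decoy)
})

test_that("target and decoy hit rates agree on noise-only spectra", {
  # mass-matched target/decoy pair; noise-only spectra at their precursor
  prot <- data.frame(accession = "T1", description = "",
                     sequence = "LANVTEGISK", stringsAsFactors = FALSE)
  lib <- as_glycan_library(data.frame(name = "g", sequence = "OJUUJOJJJOO"))
  db <- build_database(prot, lib)
  forms <- db_to_forms(db, ab, max_fucose = 0, decoys = TRUE)
  expect_equal(sum(forms$is_decoy), sum(!forms$is_decoy))
  z <- 2L
  mz <- (forms$neutral_mass[1] + z * 1.007276) / z
  set.seed(57)
  n_trials <- 300L
  loose <- matrix(0L, n_trials, 2)
  for (i in seq_len(n_trials)) {
    peaks <- cbind(runif(60, 200, 2100), runif(60, 1, 100))
    s <- spectrum("noise", mz, z, peaks)
    psms <- suppressWarnings(glyco_search(s, forms, ab,
                                          fucose_class = FALSE))
    loose[i, ] <- c(sum(psms$p_value < 0.05 & !psms$is_decoy),
                    sum(psms$p_value < 0.05 & psms$is_decoy))
  }
  t_rate <- mean(loose[, 1]); d_rate <- mean(loose[, 2])
  se <- sqrt((t_rate * (1 - t_rate) + d_rate * (1 - d_rate)) / n_trials)
  expect_lt(abs(t_rate - d_rate), max(4 * se, 0.05))
})
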