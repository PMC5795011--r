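ab <- default_alphabet()

test_that("neutral mass matches hand sums and the independent oracle", {
  # single HexNAc "peptide": residue + water
  f1 <- glycopeptide_form("O", "")
  expect_equal(neutral_mass(f1, ab), 203.0794 + 18.010565,
               tolerance = 1e-3)
  # worked example: di-sialylated biantennary glycan + sequon peptide,
  # carbamidomethyl on C applied implicitly
  f2 <- glycopeptide_form("QDQCIYNTTYLNVQR", "OJUUJOJJJOO")
  expect_equal(neutral_mass(f2, ab), 4119.662, tolerance = 5e-3)
  # one fucose adds exactly its delta
  f3 <- glycopeptide_form("QDQCIYNTTYLNVQR", "OJUUJOJJJOO",
                          fucose_pos = 11L)
  expect_equal(neutral_mass(f3, ab) - neutral_mass(f2, ab), 146.0579)
  expect_error(neutral_mass(glycopeptide_form("XAA", ""), ab),
               "no defined mass")
})

test_that("precursor m/z follows (M + zH)/z and is monotone in z", {
  f <- glycopeptide_form("QDQCIYNTTYLNVQR", "OJUUJOJJJOO")
  expect_equal(precursor_mz(f, 3, ab), 1374.228, tolerance = 2e-3)
  expect_equal(precursor_mz(f, 1, ab),
               neutral_mass(f, ab) + 1.007276)
  expect_gt(precursor_mz(f, 2, ab), precursor_mz(f, 3, ab))
  expect_error(precursor_mz(f, 0, ab), ">= 1")
})

test_that("glycan-prefix b ions reproduce the oxonium ions", {
  f <- glycopeptide_form("ENGTISR", "OJUUJOJJJOO")
  ions <- fragment_ions(f, ab)
  b1 <- ions[ions$series == "b" & ions$charge == 1, ]
  expect_equal(b1$mz[b1$ordinal == 1], 204.087, tolerance = 2e-3)
  expect_equal(b1$mz[b1$ordinal == 2], 366.140, tolerance = 2e-3)
  expect_equal(b1$mz[b1$ordinal == 3], 657.235, tolerance = 2e-3)
  # O-glycan prefix: Neu5Ac oxonium and Neu5Ac-Hex
  fo <- glycopeptide_form("HTFSGVASVESSSGEAFHVGK", "UJO")
  bo <- fragment_ions(fo, ab)
  bo1 <- bo[bo$series == "b" & bo$charge == 1, ]
  expect_equal(bo1$mz[bo1$ordinal == 1], 292.103, tolerance = 2e-3)
  expect_equal(bo1$mz[bo1$ordinal == 2], 454.156, tolerance = 2e-3)
  # every b ion of a glycosylated form spans the glycan; y ions only
  # once they reach past the peptide
  expect_true(all(ions$spans_glycan[ions$series == "b"]))
  y <- ions[ions$series == "y" & ions$charge == 1, ]
  expect_identical(y$spans_glycan, y$ordinal > nchar("ENGTISR"))
})

test_that("b/y complementarity holds on random glycopeptide forms", {
  set.seed(31)
  lib <- generate_sialylated_library()
  checked <- 0L
  for (i in 1:110) {
    pep <- random_protein(sample(5:25, 1))
    gseq <- lib$sequence[sample.int(nrow(lib), 1)]
    chars <- strsplit(paste0(gseq, pep), "", fixed = TRUE)[[1]]
    o_pos <- which(chars[seq_len(nchar(gseq))] == "O")
    nf <- sample(0:2, 1)
    fuc <- if (nf > 0) sort(sample(o_pos, nf)) else integer(0)
    m_pos <- which(chars == "M")
    m_pos <- m_pos[m_pos > nchar(gseq)]
    oxp <- if (length(m_pos)) m_pos[sample.int(length(m_pos), 1)] else
      integer(0)
    f <- glycopeptide_form(pep, gseq, fucose_pos = fuc,
                           oxidation_pos = oxp)
    nm <- neutral_mass(f, ab)
    # oracle: independent residue-sum loop
    expect_equal(nm, oracle_neutral_mass(f$full_sequence, fuc, oxp),
                 tolerance = 1e-9)
    ions <- fragment_ions(f, ab, charges = 1)
    b <- ions[ions$series == "b", ]
    y <- ions[ions$series == "y", ]
    n <- nchar(f$full_sequence)
    for (k in seq_len(n - 1)) {
      expect_equal(b$mz[b$ordinal == k] + y$mz[y$ordinal == n - k],
                   nm + 2 * 1.007276, tolerance = 1e-6)
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})

test_that("doubly charged fragments appear only above the mass threshold", {
  f <- glycopeptide_form("QDQCIYNTTYLNVQR", "OJUUJOJJJOO")
  ions <- fragment_ions(f, ab)
  two <- ions[ions$charge == 2, ]
  one <- ions[ions$charge == 1, ]
  expect_true(all((two$mz * 2 - 2 * 1.007276) > 900))
  # every 2+ ion has its 1+ partner, at (m + 2H)/2
  for (i in seq_len(nrow(two))) {
    partner <- one[one$series == two$series[i] &
                     one$ordinal == two$ordinal[i], ]
    expect_equal(two$mz[i], (partner$mz - 1.007276 + 2 * 1.007276) / 2)
  }
})

test_that("scored ions are all y plus the glycan b1-b3 only", {
  f <- glycopeptide_form("ENGTISR", "OJUUJOJJJOO")
  ions <- fragment_ions(f, ab)
  sc <- scored_ions(ions, f$glycan_len)
  expect_true(all(sc$ordinal[sc$series == "b"] <= 3))
  expect_true(all(sc$charge[sc$series == "b"] == 1))
  expect_equal(sum(sc$series == "y"), sum(ions$series == "y"))
  # a bare peptide has no b ions scored
  fp <- glycopeptide_form("ENGTISR", "")
  scp <- scored_ions(fragment_ions(fp, ab), 0)
  expect_equal(sum(scp$series == "b"), 0)
})

test_that("fucoform enumeration counts follow binomial sums", {
  e <- list(peptide = "ENGTISR", glycan_seq = "OJUUJOJJJOO")  # 4 O residues
  expect_length(enumerate_fucoforms(e, max_fucose = 1, max_oxidation = 0), 5)
  expect_length(enumerate_fucoforms(e, max_fucose = 0, max_oxidation = 0), 1)
  expect_length(enumerate_fucoforms(e, max_fucose = 2, max_oxidation = 0),
                1 + 4 + choose(4, 2))
  # oxidation crosses with fucose placements
  em <- list(peptide = "ENGMTISR", glycan_seq = "OJUUJOJJJOO")
  expect_length(enumerate_fucoforms(em, max_fucose = 1, max_oxidation = 1),
                5 * 2)
  # di-fucosylated forms need at least two O residues
  e1 <- list(peptide = "ENGTISR", glycan_seq = "UJO")
  forms <- enumerate_fucoforms(e1, max_fucose = 2, max_oxidation = 0)
  expect_length(forms, 2)  # 0 or 1 fucose on the single O
  expect_error(glycopeptide_form("ENGTISR", "UJO", fucose_pos = c(2L)),
               "must hold an O")
})
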