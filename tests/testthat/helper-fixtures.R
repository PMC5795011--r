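# shared fixtures and independent oracles -----------------------------------

AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
          "E", "M", "H", "F", "R", "Y", "W")

# residue masses re-declared independently of the package's tables, so the
# oracle does not share a code path with what it checks
ORACLE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931,
  O = 203.0794, J = 162.0528, U = 291.0954
)
ORACLE_PROTON <- 1.007276
ORACLE_WATER <- 18.010565

# brute-force neutral mass: plain loop over characters + mod deltas
oracle_neutral_mass <- function(full_seq, fucose_pos = integer(),
                                oxidation_pos = integer()) {
  chars <- strsplit(full_seq, "", fixed = TRUE)[[1]]
  total <- ORACLE_WATER
  for (i in seq_along(chars)) {
    total <- total + ORACLE_MASS[[chars[i]]]
    if (chars[i] == "C") total <- total + 57.02146
    if (i %in% fucose_pos) total <- total + 146.0579
    if (i %in% oxidation_pos) total <- total + 15.99491
  }
  total
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

toy_proteome <- function(n_prot = 10L, len = 200L) {
  data.frame(
    accession = sprintf("TOY%03d", seq_len(n_prot)),
    description = "random toy protein",
    sequence = vapply(seq_len(n_prot), function(i) random_protein(len),
                      character(1)),
    stringsAsFactors = FALSE
  )
}

# database with exactly n_entries, grown from a seeded random proteome
toy_db <- function(n_entries = 200L, seed = 101L,
                   library = generate_sialylated_library()) {
  set.seed(seed)
  proteins <- toy_proteome(1L)
  repeat {
    db <- suppressWarnings(build_database(proteins, library))
    if (db$stats$n_glycopeptide_entries >= n_entries) break
    proteins <- rbind(proteins, toy_proteome(1L))
    proteins$accession <- sprintf("TOY%03d", seq_len(nrow(proteins)))
  }
  db$entries <- db$entries[seq_len(n_entries), , drop = FALSE]
  db$stats$n_glycopeptide_entries <- n_entries
  db$stats$n_residues_total <- sum(nchar(db$entries$full_sequence))
  db$stats$n_proteins_with_candidates <- length(unique(db$entries$accession))
  db
}

# exhaustive maximum one-to-one assignment between ions and peaks
oracle_max_matching <- function(ion_mz, peak_mz, tol) {
  n_ion <- length(ion_mz)
  best <- 0L
  recurse <- function(i, used_peaks, count) {
    if (count + (n_ion - i + 1L) <= best) return(invisible(NULL))
    if (i > n_ion) {
      if (count > best) best <<- count
      return(invisible(NULL))
    }
    cand <- which(abs(peak_mz - ion_mz[i]) <= tol & !used_peaks)
    for (p in cand) {
      used_peaks[p] <- TRUE
      recurse(i + 1L, used_peaks, count + 1L)
      used_peaks[p] <- FALSE
    }
    recurse(i + 1L, used_peaks, count)  # leave ion i unmatched
    invisible(NULL)
  }
  recurse(1L, logical(length(peak_mz)), 0L)
  best
}

# independent sequon scan: explicit substring test at every position
oracle_n_sites <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "N" && i + 2L <= length(chars) &&
        chars[i + 2L] %in% c("T", "S", "C"))
      out <- c(out, i)
  }
  out
}
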