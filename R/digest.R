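#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path (multi-record, uncompressed or gzipped).
#' @return Data frame with columns `accession` (first whitespace-delimited
#'   header token), `description` (remainder of the header) and `sequence`
#'   (uppercase amino-acid string).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(accession = acc, description = desc,
             sequence = toupper(as.character(aa)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# cleavage positions (residue index after which the backbone is cut)
.trypsin_sites <- function(chars, keil = TRUE) {
  n <- length(chars)
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n]
  if (keil) sites <- sites[chars[sites + 1L] != "P"]
  sites
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R; by default the Keil rule suppresses cleavage when
#' the next residue is proline (the trypsin definition used by most search
#' engines). With `missed_cleavages = 0` the peptides tile the protein
#' exactly.
#'
#' @param proteins Data frame as from [read_protein_fasta()], or a single
#'   sequence string.
#' @param missed_cleavages Maximum number of missed cleavage sites per
#'   peptide (0 = fully cleaved peptides only).
#' @param keil Apply the no-cleavage-before-proline rule (default TRUE).
#' @return Data frame with columns `accession`, `start`, `end` (1-based,
#'   inclusive) and `sequence`.
#' @examples
#' tryptic_digest("AAAKLLLRCCC")$sequence  # "AAAK" "LLLR" "CCC"
#' @export
tryptic_digest <- function(proteins, missed_cleavages = 0L, keil = TRUE) {
  if (is.character(proteins))
    proteins <- data.frame(accession = "protein1", description = "",
                           sequence = proteins, stringsAsFactors = FALSE)
  stopifnot(missed_cleavages >= 0L)
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    seqstr <- proteins$sequence[i]
    if (!nzchar(seqstr)) stop("empty protein sequence: ",
                              proteins$accession[i])
    chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    bounds <- c(0L, .trypsin_sites(chars, keil = keil), length(chars))
    npep <- length(bounds) - 1L
    rows <- list()
    for (j in seq_len(npep)) {
      kmax <- min(missed_cleavages, npep - j)
      for (k in 0:kmax) {
        s <- bounds[j] + 1L
        e <- bounds[j + 1L + k]
        rows[[length(rows) + 1L]] <-
          c(start = s, end = e)
      }
    }
    m <- do.call(rbind, rows)
    out[[i]] <- data.frame(
      accession = proteins$accession[i],
      start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
      sequence = substring(seqstr, m[, "start"], m[, "end"]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Find N-glycosylation sequons in a peptide
#'
#' Scans for the N-x-T/S/C consensus: asparagine at position i with T, S or
#' C at position i+2. The x residue is unrestricted by default; strict mode
#' excludes proline at x (N-[^P]-[TSC]).
#'
#' @param sequence Peptide sequence string.
#' @param exclude_proline_x If TRUE, require x != P.
#' @return Integer positions (1-based within the peptide) of the sequon N.
#' @examples
#' find_n_glycosites("QDQCIYNTTYLNVQR")  # 7 (the N of NTT)
#' @export
find_n_glycosites <- function(sequence, exclude_proline_x = FALSE) {
  pat <- if (exclude_proline_x) "N(?=[^P][TSC])" else "N(?=.[TSC])"
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find candidate O-glycosylation sites in a peptide
#'
#' O-glycosylation has no consensus motif; every serine and threonine is a
#' candidate site.
#'
#' @param sequence Peptide sequence string.
#' @return Integer positions (1-based) of all S and T residues.
#' @export
find_o_glycosites <- function(sequence) {
  m <- gregexpr("[ST]", sequence)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Filter peptides by length and glycosylation-site content
#'
#' Retains peptides whose length lies in `[min_len, max_len]` and that
#' carry at least one glycosylation site of the requested kind. Peptides
#' containing non-standard letters (anything outside the 20 amino-acid
#' codes: B, X, Z, U, O, J, ...) are excluded with a warning, since those
#' letters collide with glycan codes or lack residue masses.
#'
#' @param peptides Data frame as from [tryptic_digest()].
#' @param min_len,max_len Inclusive length bounds (defaults 5 and 30).
#' @param require_site `"N"` for N-linked sequons, `"O"` for S/T sites.
#' @param exclude_proline_x Passed to [find_n_glycosites()].
#' @return The retained rows with added list-columns `sites` (integer
#'   positions) and `n_sites` (their count).
#' @export
filter_peptides <- function(peptides, min_len = 5L, max_len = 30L,
                            require_site = c("N", "O"),
                            exclude_proline_x = FALSE) {
  require_site <- match.arg(require_site)
  if (min_len > max_len) stop("min_len exceeds max_len")
  nonstd <- grepl(sprintf("[^%s]",
                          paste(names(mass_constants$aa_residues),
                                collapse = "")),
                  peptides$sequence)
  if (any(nonstd))
    warning(sum(nonstd), " peptide(s) with non-standard letters excluded ",
            "from glycopeptide candidacy")
  peptides <- peptides[!nonstd, , drop = FALSE]
  len <- nchar(peptides$sequence)
  peptides <- peptides[len >= min_len & len <= max_len, , drop = FALSE]
  sites <- lapply(peptides$sequence, function(s)
    if (require_site == "N") find_n_glycosites(s, exclude_proline_x)
    else find_o_glycosites(s))
  keep <- lengths(sites) > 0L
  out <- peptides[keep, , drop = FALSE]
  out$sites <- I(sites[keep])
  out$n_sites <- lengths(sites[keep])
  row.names(out) <- NULL
  out
}
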