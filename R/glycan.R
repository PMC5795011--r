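#' Parse a linear glycan sequence
#'
#' A glycan structure is written as a linear string over the alphabet's
#' one-letter codes, N-terminal-prefix first: the rightmost character is the
#' residue attached to the peptide N-terminus (the core HexNAc for
#' N-glycans). For the default N-glycan encoding the first three characters
#' are one antenna written core-to-terminal, so that b1/b2/b3 over the
#' prefix reproduce the classic oxonium ions (204.087, 366.140, 657.235).
#'
#' @param text Glycan sequence string (non-empty).
#' @param alphabet A [glycan_alphabet()].
#' @param name Optional label; defaults to the sequence itself.
#' @return A `linear_glycan` object with fields `name`, `sequence`,
#'   `composition` (named counts) and `mass` (Da, no water term).
#' @examples
#' g <- parse_linear_glycan("OJUUJOJJJOO", default_alphabet())
#' g$composition  # O:4 J:5 U:2 -- di-sialylated biantennary
#' @export
parse_linear_glycan <- function(text, alphabet, name = text) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("glycan sequence must be a non-empty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet$codes)
  if (length(bad))
    stop(sprintf("invalid glycan: character '%s' at position %d is not a glycan code",
                 chars[bad[1]], bad[1]))
  comp <- glycan_composition(text, alphabet)
  structure(
    list(name = name, sequence = text, composition = comp,
         mass = sum(comp * glycan_residue_masses(alphabet)[names(comp)])),
    class = "linear_glycan"
  )
}

#' Monosaccharide composition of a linear glycan
#'
#' @param g A `linear_glycan` or a plain sequence string.
#' @param alphabet A [glycan_alphabet()].
#' @return Named integer vector, code -> count, over the alphabet codes
#'   present in the sequence. Counts sum to the sequence length.
#' @export
glycan_composition <- function(g, alphabet) {
  seqstr <- if (inherits(g, "linear_glycan")) g$sequence else g
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet$codes)
  if (length(bad))
    stop(sprintf("invalid glycan: character '%s' at position %d is not a glycan code",
                 chars[bad[1]], bad[1]))
  counts <- table(factor(chars, levels = alphabet$codes))
  out <- as.integer(counts)
  names(out) <- alphabet$codes
  out[out > 0L]
}

#' Monoisotopic mass of a linear glycan
#'
#' Residue masses are condensation residues, so the glycan mass is a plain
#' sum with no water term; fucoses (variable monosaccharides on O) add
#' their delta per copy. The empty string has mass 0 (internal convenience
#' for unglycosylated fragments).
#'
#' @param g A `linear_glycan` or sequence string (may be `""`).
#' @param alphabet A [glycan_alphabet()].
#' @param n_fucose Number of fucose residues attached (each on one O);
#'   must not exceed the O count.
#' @return Mass in Da.
#' @examples
#' glycan_mass("O", default_alphabet())            # 203.0794
#' glycan_mass("OJUUJOJJJOO", default_alphabet())  # 2204.772
#' @export
glycan_mass <- function(g, alphabet, n_fucose = 0L) {
  seqstr <- if (inherits(g, "linear_glycan")) g$sequence else g
  stopifnot(n_fucose >= 0L)
  if (!nzchar(seqstr)) {
    if (n_fucose > 0L) stop("cannot place fucose on an empty glycan")
    return(0)
  }
  comp <- glycan_composition(seqstr, alphabet)
  fuc <- alphabet$variable[alphabet$variable$name == "fucose", , drop = FALSE]
  if (n_fucose > 0L) {
    if (nrow(fuc) == 0L)
      stop("alphabet has no fucose variable monosaccharide")
    n_target <- sum(comp[names(comp) == fuc$target])
    if (n_fucose > n_target)
      stop(sprintf("n_fucose (%d) exceeds the number of %s residues (%d)",
                   n_fucose, fuc$target, n_target))
  }
  sum(comp * glycan_residue_masses(alphabet)[names(comp)]) +
    if (n_fucose > 0L) n_fucose * fuc$delta_mass else 0
}

# canonical linear encoding of one sialylated complex N-glycan:
# first antenna core->terminal ("OJU"), remaining antennae terminal->core
# (sialylated ones "UJO" first, asialo "JO"), then trimannosyl core "JJJ",
# then chitobiose core "OO" (peptide-adjacent end last).
.nglycan_sequence <- function(antennae, sialylation) {
  stopifnot(antennae >= 2L, antennae <= 4L,
            sialylation >= 1L, sialylation <= antennae)
  rest <- c(rep("UJO", sialylation - 1L), rep("JO", antennae - sialylation))
  paste0("OJU", paste(rest, collapse = ""), "JJJ", "OO")
}

#' Generate the canonical sialylated N-glycan library
#'
#' Enumerates complex N-glycans with 2-4 antennae and 1..antennae terminal
#' sialic acids under a canonical linearization: one antenna written
#' core-to-terminal so the b1/b2/b3 prefix ions are the HexNAc /
#' HexNAc-Hex / HexNAc-Hex-Neu5Ac oxonium ions; the remaining antennae
#' written terminal-to-core (sialylated antennae first); then the
#' trimannosyl core `JJJ` and the chitobiose core `OO`, peptide-adjacent
#' end last. Successive y ions then strip terminal residues in
#' glycosidic-loss order. The (2,2) entry is the di-sialylated biantennary
#' glycan `"OJUUJOJJJOO"`.
#'
#' @param antennae Integer vector of antenna counts (subset of 2:4).
#' @param sialylation Optional integer vector of sialylation levels; by
#'   default all levels `1..antennae` per antenna count.
#' @param alphabet A [glycan_alphabet()].
#' @return A `glycan_library`: data frame with columns `name`, `sequence`.
#' @examples
#' lib <- generate_sialylated_library()
#' nrow(lib)  # 9
#' @export
generate_sialylated_library <- function(antennae = 2:4, sialylation = NULL,
                                        alphabet = default_alphabet()) {
  antennae <- as.integer(antennae)
  if (any(antennae < 2L | antennae > 4L))
    stop("antennae must lie in 2..4")
  rows <- list()
  sia_names <- c("mono", "di", "tri", "tetra")
  ant_names <- c(`2` = "biantennary", `3` = "triantennary",
                 `4` = "tetraantennary")
  for (a in antennae) {
    slevels <- if (is.null(sialylation)) seq_len(a) else
      sialylation[sialylation <= a]
    for (s in as.integer(slevels)) {
      if (s < 1L) stop("sialylation must be >= 1")
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(sia_names[s], "-sialylated_",
                      ant_names[[as.character(a)]]),
        sequence = .nglycan_sequence(a, s),
        stringsAsFactors = FALSE
      )
    }
  }
  lib <- do.call(rbind, rows)
  as_glycan_library(lib, alphabet)
}

#' Validate a glycan library
#'
#' @param lib Data frame with columns `name`, `sequence`.
#' @param alphabet A [glycan_alphabet()] used to validate each sequence.
#' @return The library with class `glycan_library`.
#' @export
as_glycan_library <- function(lib, alphabet = default_alphabet()) {
  stopifnot(is.data.frame(lib), all(c("name", "sequence") %in% names(lib)))
  if (anyDuplicated(lib$name))
    stop("glycan library names must be unique")
  if (any(grepl("[|[:space:]]", lib$name)))
    stop("glycan names must not contain whitespace or '|' ",
         "(they become FASTA header tokens)")
  if (anyDuplicated(lib$sequence))
    stop("glycan library sequences must be unique")
  for (s in lib$sequence) parse_linear_glycan(s, alphabet)
  class(lib) <- c("glycan_library", "data.frame")
  lib
}

#' Read a glycan library from a TSV file
#'
#' Plain text, UTF-8, one `name<TAB>sequence` per line; lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @param alphabet A [glycan_alphabet()].
#' @return A `glycan_library`.
#' @export
read_glycan_library <- function(path, alphabet = default_alphabet()) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("glycan library file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed glycan library line ", bad[1], ": expected name<TAB>sequence")
  lib <- data.frame(
    name = vapply(parts, `[[`, character(1), 1L),
    sequence = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  as_glycan_library(lib, alphabet)
}

#' Write a glycan library to a TSV file
#'
#' @param lib A `glycan_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_glycan_library <- function(lib, path) {
  stopifnot(inherits(lib, "glycan_library"))
  writeLines(c("# glycan library: name<TAB>sequence",
               paste(lib$name, lib$sequence, sep = "\t")), path)
  invisible(path)
}

#' @export
print.linear_glycan <- function(x, ...) {
  comp <- paste(sprintf("%s:%d", names(x$composition), x$composition),
                collapse = " ")
  cat(sprintf("linear glycan %s: %s (%s; %.4f Da)\n",
              x$name, x$sequence, comp, x$mass))
  invisible(x)
}
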