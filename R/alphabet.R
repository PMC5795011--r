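#' Define a monosaccharide residue code
#'
#' A monosaccharide is encoded as a single one-letter residue code, mirroring
#' how search engines treat amino acids. Codes must not collide with the 20
#' standard amino-acid letters, nor with B, X, Z (reserved ambiguity codes).
#'
#' @param code Single uppercase letter.
#' @param name Human-readable name (e.g. `"N-acetylhexosamine"`).
#' @param residue_mass Monoisotopic residue (condensation) mass in Da.
#' @param formula Optional elemental formula used to cross-check
#'   `residue_mass` (must agree within 1e-3 Da).
#' @return A `monosaccharide_def` object.
#' @examples
#' monosaccharide_def("O", "N-acetylhexosamine", 203.0794, "C8H13NO5")
#' @export
monosaccharide_def <- function(code, name, residue_mass, formula = NA_character_) {
  stopifnot(is.character(code), length(code) == 1L)
  if (nchar(code) != 1L || code != toupper(code))
    stop("code must be exactly one uppercase letter, got '", code, "'")
  reserved <- c(names(mass_constants$aa_residues), "B", "X", "Z")
  if (code %in% reserved)
    stop("code '", code, "' collides with a reserved amino-acid letter")
  if (!is.numeric(residue_mass) || residue_mass <= 0)
    stop("residue_mass must be a positive number")
  if (!is.na(formula)) {
    fm <- formula_mass(formula)
    if (abs(fm - residue_mass) > 1e-3)
      stop(sprintf(
        "residue_mass %.4f disagrees with formula %s (%.4f) by more than 1e-3 Da",
        residue_mass, formula, fm))
  }
  structure(
    list(code = code, name = name, residue_mass = residue_mass,
         formula = formula),
    class = "monosaccharide_def"
  )
}

#' Assemble a glycan alphabet
#'
#' Bundles monosaccharide residue definitions with variable-monosaccharide
#' modifications (mass deltas targeting one residue code, e.g. fucose
#' +146.0579 on O).
#'
#' @param defs List of [monosaccharide_def()] objects.
#' @param variable Data frame with columns `name`, `delta_mass`, `target`
#'   describing variable monosaccharides; may be empty.
#' @return A `glycan_alphabet` object.
#' @seealso [default_alphabet()]
#' @export
glycan_alphabet <- function(defs, variable = NULL) {
  stopifnot(is.list(defs), length(defs) > 0L)
  codes <- vapply(defs, function(d) d$code, character(1))
  if (anyDuplicated(codes))
    stop("duplicate monosaccharide codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  if (is.null(variable)) {
    variable <- data.frame(name = character(), delta_mass = numeric(),
                           target = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "delta_mass", "target") %in% names(variable)))
  bad <- setdiff(variable$target, codes)
  if (length(bad))
    stop("variable monosaccharide targets unknown code(s): ",
         paste(bad, collapse = ", "))
  structure(list(defs = defs, codes = codes, variable = variable),
            class = "glycan_alphabet")
}

#' The default O/J/U glycan alphabet
#'
#' The three free Latin letters left over once 20 amino acids and the
#' reserved B/X/Z are excluded: O for N-acetylhexosamine (GlcNAc, GalNAc,
#' 203.0794 Da), J for hexose (Gal, Man, 162.0528 Da) and U for sialic acid
#' (Neu5Ac, 291.0954 Da). Fucose (deoxyhexose, +146.0579 Da) is registered
#' as a variable monosaccharide on O.
#'
#' @return A [glycan_alphabet()].
#' @examples
#' ab <- default_alphabet()
#' glycan_codes(ab)
#' @export
default_alphabet <- function() {
  glycan_alphabet(
    defs = list(
      monosaccharide_def("O", "N-acetylhexosamine", 203.0794, "C8H13NO5"),
      monosaccharide_def("J", "hexose", 162.0528, "C6H10O5"),
      monosaccharide_def("U", "Neu5Ac", 291.0954, "C11H17NO8")
    ),
    variable = data.frame(
      name = "fucose", delta_mass = 146.0579, target = "O",
      stringsAsFactors = FALSE
    )
  )
}

#' Residue codes of a glycan alphabet
#' @param alphabet A [glycan_alphabet()].
#' @return Character vector of one-letter codes.
#' @export
glycan_codes <- function(alphabet) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  alphabet$codes
}

#' Residue masses of a glycan alphabet
#' @param alphabet A [glycan_alphabet()].
#' @return Named numeric vector, code -> monoisotopic residue mass (Da).
#' @export
glycan_residue_masses <- function(alphabet) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  m <- vapply(alphabet$defs, function(d) d$residue_mass, numeric(1))
  names(m) <- alphabet$codes
  m
}

#' Combined residue-mass table (amino acids + glycan codes)
#'
#' @param alphabet A [glycan_alphabet()].
#' @return Named numeric vector covering the 20 amino acids and every
#'   glycan code.
#' @export
residue_mass_table <- function(alphabet) {
  c(mass_constants$aa_residues, glycan_residue_masses(alphabet))
}

#' @export
print.glycan_alphabet <- function(x, ...) {
  cat("glycan alphabet:", length(x$codes), "residue code(s)\n")
  for (d in x$defs)
    cat(sprintf("  %s  %-22s %9.4f Da\n", d$code, d$name, d$residue_mass))
  if (nrow(x$variable))
    for (i in seq_len(nrow(x$variable)))
      cat(sprintf("  variable: %s %+.4f Da on %s\n",
                  x$variable$name[i], x$variable$delta_mass[i],
                  x$variable$target[i]))
  invisible(x)
}

#' @export
print.monosaccharide_def <- function(x, ...) {
  cat(sprintf("monosaccharide %s (%s): %.4f Da\n", x$code, x$name,
              x$residue_mass))
  invisible(x)
}
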