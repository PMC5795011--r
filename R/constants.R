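#' Monoisotopic mass constants
#'
#' Community-standard monoisotopic constants used throughout the package:
#' the proton and water masses, the residue (condensation) masses of the 20
#' standard amino acids, and the default fixed/variable modification deltas
#' (carbamidomethyl on C, oxidation on M, fucose on O).
#'
#' @format A named list with elements `proton`, `water`, `aa_residues`
#'   (named numeric vector), and `modifications` (data frame with columns
#'   `name`, `delta_mass`, `target`, `kind`).
#' @export
mass_constants <- local({
  aa <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  mods <- data.frame(
    name = c("carbamidomethyl", "oxidation", "fucose"),
    delta_mass = c(57.02146, 15.99491, 146.0579),
    target = c("C", "M", "O"),
    kind = c("fixed", "variable", "variable"),
    stringsAsFactors = FALSE
  )
  list(proton = 1.007276, water = 18.010565, aa_residues = aa,
       modifications = mods)
})

# monoisotopic atomic masses for formula cross-checks
.element_masses <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069, P = 30.97376151
)

#' Monoisotopic mass of an elemental formula
#'
#' Computes the monoisotopic mass of a simple elemental formula such as
#' `"C6H10O5"` (hexose residue) or `"C8H13NO5"` (HexNAc residue). Used to
#' cross-check tabulated residue masses against their compositions.
#'
#' @param formula Formula string: element symbols (C, H, N, O, S, P)
#'   followed by optional counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C6H10O5") # hexose residue, 162.0528
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.element_masses))
      stop("unknown element '", el, "' in formula ", formula)
    total <- total + .element_masses[[el]] * n
  }
  total
}
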