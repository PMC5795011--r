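#' Construct a concrete glycopeptide form
#'
#' A form is one glycopeptide entry (glycan sequence prepended to the
#' peptide) plus a concrete placement of variable modifications: fucoses on
#' specific O residues and oxidations on specific M residues. Positions are
#' 1-based indices into the full glycan+peptide sequence. Carbamidomethyl
#' on every C is applied implicitly as a fixed modification.
#'
#' @param peptide Peptide amino-acid sequence.
#' @param glycan_seq Linear glycan sequence (may be `""` for a bare
#'   peptide).
#' @param fucose_pos Integer positions (within the full sequence) of O
#'   residues carrying fucose.
#' @param oxidation_pos Integer positions of oxidized M residues.
#' @param entry_id,accession,glycan_name Optional provenance labels.
#' @return A `glycopeptide_form`.
#' @examples
#' f <- glycopeptide_form("QDQCIYNTTYLNVQR", "OJUUJOJJJOO")
#' neutral_mass(f, default_alphabet())
#' @export
glycopeptide_form <- function(peptide, glycan_seq = "",
                              fucose_pos = integer(),
                              oxidation_pos = integer(),
                              entry_id = NA_character_,
                              accession = NA_character_,
                              glycan_name = NA_character_) {
  full <- paste0(glycan_seq, peptide)
  chars <- strsplit(full, "", fixed = TRUE)[[1]]
  fucose_pos <- as.integer(fucose_pos)
  oxidation_pos <- as.integer(oxidation_pos)
  if (anyDuplicated(c(fucose_pos, oxidation_pos)))
    stop("modification positions must be unique")
  if (length(fucose_pos) && any(chars[fucose_pos] != "O"))
    stop("every fucose position must hold an O residue")
  if (length(oxidation_pos) && any(chars[oxidation_pos] != "M"))
    stop("every oxidation position must hold an M residue")
  structure(
    list(peptide = peptide, glycan_seq = glycan_seq,
         full_sequence = full, glycan_len = nchar(glycan_seq),
         fucose_pos = fucose_pos, oxidation_pos = oxidation_pos,
         entry_id = entry_id, accession = accession,
         glycan_name = glycan_name),
    class = "glycopeptide_form"
  )
}

#' @export
print.glycopeptide_form <- function(x, ...) {
  cat(sprintf("glycopeptide form %s + %s (%d fucose, %d oxidation)\n",
              if (nzchar(x$glycan_seq)) x$glycan_seq else "<no glycan>",
              x$peptide, length(x$fucose_pos), length(x$oxidation_pos)))
  invisible(x)
}

# per-residue mass vector of a form, fixed + variable mods applied in place
.residue_vector <- function(form, alphabet) {
  chars <- strsplit(form$full_sequence, "", fixed = TRUE)[[1]]
  tab <- residue_mass_table(alphabet)
  res <- tab[chars]
  if (anyNA(res)) {
    bad <- chars[which(is.na(res))[1]]
    stop("residue '", bad, "' has no defined mass")
  }
  res <- unname(res)
  mods <- mass_constants$modifications
  cam <- mods$delta_mass[mods$name == "carbamidomethyl"]
  ox <- mods$delta_mass[mods$name == "oxidation"]
  res[chars == "C"] <- res[chars == "C"] + cam
  if (length(form$oxidation_pos))
    res[form$oxidation_pos] <- res[form$oxidation_pos] + ox
  if (length(form$fucose_pos)) {
    vm <- alphabet$variable
    fuc <- vm$delta_mass[vm$name == "fucose"]
    if (!length(fuc)) stop("alphabet has no fucose variable monosaccharide")
    res[form$fucose_pos] <- res[form$fucose_pos] + fuc
  }
  res
}

#' Neutral monoisotopic mass of a glycopeptide form
#'
#' Sum of all residue masses (amino acids and glycan letters) plus one
#' water, plus all modification deltas (implicit carbamidomethyl on C,
#' fucose and oxidation at the form's positions).
#'
#' @param form A [glycopeptide_form()].
#' @param alphabet A [glycan_alphabet()].
#' @return Mass in Da.
#' @export
neutral_mass <- function(form, alphabet = default_alphabet()) {
  stopifnot(inherits(form, "glycopeptide_form"))
  sum(.residue_vector(form, alphabet)) + mass_constants$water
}

#' Precursor m/z of a glycopeptide form
#'
#' @param form A [glycopeptide_form()].
#' @param z Charge state (>= 1).
#' @param alphabet A [glycan_alphabet()].
#' @return `(neutral_mass + z * proton) / z` in Da/charge.
#' @export
precursor_mz <- function(form, z, alphabet = default_alphabet()) {
  if (z < 1L) stop("charge must be >= 1")
  (neutral_mass(form, alphabet) + z * mass_constants$proton) / z
}

#' Theoretical b/y fragment ions of a glycopeptide form
#'
#' Standard peptide fragment arithmetic over the extended glycan+peptide
#' alphabet: `b_i = prefix_i + proton`, `y_i = suffix_i + water + proton`,
#' with doubly charged variants `(m + 2 proton)/2` generated for fragments
#' whose neutral mass exceeds `two_plus_min_mass` (large glycan-retaining y
#' ions are commonly 2+). `spans_glycan` marks fragments containing at
#' least one glycan residue: every b ion of a glycosylated form (the glycan
#' sits at the N-terminus), and y ions long enough to reach into the
#' glycan.
#'
#' @param form A [glycopeptide_form()].
#' @param alphabet A [glycan_alphabet()].
#' @param charges Fragment charge states to consider (subset of 1:2).
#' @param two_plus_min_mass Minimum fragment neutral mass (Da) for 2+ ions.
#' @return Data frame with columns `series` ("b"/"y"), `ordinal`, `charge`,
#'   `mz`, `spans_glycan`.
#' @examples
#' f <- glycopeptide_form("ENGTISR", "OJUUJOJJJOO")
#' ions <- fragment_ions(f)
#' ions[ions$series == "b" & ions$ordinal <= 3 & ions$charge == 1, "mz"]
#' @export
fragment_ions <- function(form, alphabet = default_alphabet(),
                          charges = c(1L, 2L), two_plus_min_mass = 900) {
  stopifnot(inherits(form, "glycopeptide_form"))
  res <- .residue_vector(form, alphabet)
  n <- length(res)
  if (n < 2L) stop("sequence must have at least 2 residues")
  proton <- mass_constants$proton
  water <- mass_constants$water
  prefix <- cumsum(res)
  i <- seq_len(n - 1L)
  b_neutral <- prefix[i]
  y_neutral <- prefix[n] - prefix[n - i] + water
  g <- form$glycan_len
  b_spans <- rep(g > 0L, n - 1L)
  y_spans <- i > (n - g)          # y_i reaches into the glycan prefix
  rows <- list(
    data.frame(series = "b", ordinal = i, charge = 1L,
               mz = b_neutral + proton, spans_glycan = b_spans,
               neutral = b_neutral, stringsAsFactors = FALSE),
    data.frame(series = "y", ordinal = i, charge = 1L,
               mz = y_neutral + proton, spans_glycan = y_spans,
               neutral = y_neutral, stringsAsFactors = FALSE)
  )
  if (2L %in% charges) {
    bi2 <- b_neutral > two_plus_min_mass
    yi2 <- y_neutral > two_plus_min_mass
    if (any(bi2))
      rows[[length(rows) + 1L]] <- data.frame(
        series = "b", ordinal = i[bi2], charge = 2L,
        mz = (b_neutral[bi2] + 2 * proton) / 2,
        spans_glycan = b_spans[bi2], neutral = b_neutral[bi2],
        stringsAsFactors = FALSE)
    if (any(yi2))
      rows[[length(rows) + 1L]] <- data.frame(
        series = "y", ordinal = i[yi2], charge = 2L,
        mz = (y_neutral[yi2] + 2 * proton) / 2,
        spans_glycan = y_spans[yi2], neutral = y_neutral[yi2],
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$series, out$ordinal, out$charge), c("series", "ordinal",
                                                    "charge", "mz",
                                                    "spans_glycan")]
}

#' Restrict ions to the scored set
#'
#' Peptide b ions are meaningless for N-terminally glycan-prepended
#' sequences (every b ion spans the glycan), so scoring uses all y ions
#' plus only the first three b ions of the glycan prefix -- the oxonium
#' ions b1-b3.
#'
#' @param ions Data frame from [fragment_ions()].
#' @param glycan_len Glycan length of the originating form.
#' @param max_b Number of leading glycan b ions retained (default 3).
#' @return The scored subset of `ions`.
#' @export
scored_ions <- function(ions, glycan_len, max_b = 3L) {
  keep_b <- ions$series == "b" & ions$ordinal <= min(max_b, glycan_len) &
    ions$charge == 1L
  out <- ions[ions$series == "y" | keep_b, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Enumerate fucoform / oxidation variants of a glycopeptide entry
#'
#' Generates every placement of up to `max_fucose` fucoses on the glycan's
#' O residues crossed with up to `max_oxidation` oxidations on peptide M
#' residues, including the unmodified form.
#'
#' @param entry A one-row data frame (or list) with fields `peptide` and
#'   `glycan_seq` (plus optional `entry_id`, `accession`, `glycan_name`),
#'   e.g. one row of `build_database()$entries`.
#' @param max_fucose Maximum number of fucose residues (default 2).
#' @param max_oxidation Maximum number of oxidized methionines (default 1).
#' @return List of [glycopeptide_form()] objects.
#' @examples
#' e <- list(peptide = "ENGTISR", glycan_seq = "OJUUJOJJJOO")
#' length(enumerate_fucoforms(e, max_fucose = 1))  # 1 + 4 O positions = 5
#' @export
enumerate_fucoforms <- function(entry, max_fucose = 2L, max_oxidation = 1L) {
  stopifnot(max_fucose >= 0L, max_oxidation >= 0L)
  peptide <- entry$peptide
  glycan_seq <- entry$glycan_seq
  full <- paste0(glycan_seq, peptide)
  chars <- strsplit(full, "", fixed = TRUE)[[1]]
  g <- nchar(glycan_seq)
  o_pos <- which(chars[seq_len(g)] == "O")
  m_pos <- which(chars == "M")
  m_pos <- m_pos[m_pos > g]
  subsets <- function(pos, kmax) {
    out <- list(integer(0))
    for (k in seq_len(min(kmax, length(pos)))) {
      cmb <- if (length(pos) == 1L) list(pos)  # combn treats a scalar as 1:n
        else utils::combn(pos, k, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  fuc_sets <- subsets(o_pos, max_fucose)
  ox_sets <- subsets(m_pos, max_oxidation)
  forms <- vector("list", length(fuc_sets) * length(ox_sets))
  idx <- 1L
  for (fs in fuc_sets) for (os in ox_sets) {
    forms[[idx]] <- glycopeptide_form(
      peptide, glycan_seq, fucose_pos = fs, oxidation_pos = os,
      entry_id = if (!is.null(entry$entry_id)) entry$entry_id else NA_character_,
      accession = if (!is.null(entry$accession)) entry$accession else NA_character_,
      glycan_name = if (!is.null(entry$glycan_name)) entry$glycan_name else NA_character_)
    idx <- idx + 1L
  }
  forms
}
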