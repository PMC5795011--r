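#' Build a combinatorial glycopeptide database
#'
#' Digests each protein with trypsin, keeps peptides carrying at least one
#' glycosylation site of the requested kind (N-linked sequons or S/T), and
#' prepends every library glycan to every retained peptide. The glycan is
#' attached at the peptide N-terminus via its peptide-adjacent (rightmost)
#' residue, so glycosidic Y ions of the glycopeptide become ordinary
#' peptide y ions. One entry is produced per (peptide, glycan) pair; for
#' peptides with several sequons all site positions are recorded and the
#' first reported as primary (the entry sequence is identical regardless of
#' which site carries the glycan).
#'
#' @param proteins Data frame as from [read_protein_fasta()].
#' @param library A `glycan_library` (see [as_glycan_library()]).
#' @param mode `"N"` or `"O"` glycosylation.
#' @param min_len,max_len Peptide length bounds (defaults 5 and 30).
#' @param missed_cleavages Tryptic missed cleavages (default 0).
#' @param keil Apply the no-cleavage-before-proline rule.
#' @param exclude_proline_x Strict sequon mode (N-[^P]-[TSC]).
#' @param alphabet A [glycan_alphabet()] used to validate glycans.
#' @return A `glyco_db`: list with `entries` (data frame: `entry_id`,
#'   `accession`, `start`, `end`, `peptide`, `sites`, `site_primary`,
#'   `glycan_name`, `glycan_seq`, `full_sequence`) and `stats` (list:
#'   `n_proteins_in`, `n_proteins_with_candidates`,
#'   `n_glycopeptide_entries`, `n_residues_total`).
#' @examples
#' prot <- data.frame(accession = "P1", description = "",
#'                    sequence = "MKQDQCIYNTTYLNVQRENGTISR")
#' db <- build_database(prot, generate_sialylated_library())
#' db$stats$n_glycopeptide_entries
#' @export
build_database <- function(proteins, library, mode = c("N", "O"),
                           min_len = 5L, max_len = 30L,
                           missed_cleavages = 0L, keil = TRUE,
                           exclude_proline_x = FALSE,
                           alphabet = default_alphabet()) {
  mode <- match.arg(mode)
  stopifnot(nrow(proteins) > 0L)
  library <- as_glycan_library(as.data.frame(library), alphabet)
  if (!nrow(library)) stop("glycan library is empty")
  peps <- tryptic_digest(proteins, missed_cleavages = missed_cleavages,
                         keil = keil)
  peps <- filter_peptides(peps, min_len = min_len, max_len = max_len,
                          require_site = mode,
                          exclude_proline_x = exclude_proline_x)
  if (!nrow(peps)) {
    warning("no eligible peptides; database is empty")
    entries <- data.frame(
      entry_id = character(), accession = character(), start = integer(),
      end = integer(), peptide = character(), sites = character(),
      site_primary = integer(), glycan_name = character(),
      glycan_seq = character(), full_sequence = character(),
      stringsAsFactors = FALSE
    )
  } else {
    # stable ordering: accession, peptide start, then library order
    peps <- peps[order(peps$accession, peps$start, peps$end), , drop = FALSE]
    ip <- rep(seq_len(nrow(peps)), each = nrow(library))
    ig <- rep(seq_len(nrow(library)), times = nrow(peps))
    site1 <- vapply(peps$sites, `[[`, integer(1), 1L)
    entries <- data.frame(
      entry_id = sprintf("%s|%d-%d|site%d|%s",
                         peps$accession[ip], peps$start[ip], peps$end[ip],
                         site1[ip], library$name[ig]),
      accession = peps$accession[ip],
      start = peps$start[ip], end = peps$end[ip],
      peptide = peps$sequence[ip],
      sites = vapply(peps$sites[ip], paste, character(1), collapse = ","),
      site_primary = site1[ip],
      glycan_name = library$name[ig],
      glycan_seq = library$sequence[ig],
      stringsAsFactors = FALSE
    )
    entries$full_sequence <- paste0(entries$glycan_seq, entries$peptide)
    row.names(entries) <- NULL
  }
  stats <- list(
    n_proteins_in = nrow(proteins),
    n_proteins_with_candidates = length(unique(entries$accession)),
    n_glycopeptide_entries = nrow(entries),
    n_residues_total = sum(nchar(entries$full_sequence))
  )
  structure(list(entries = entries, stats = stats, mode = mode),
            class = "glyco_db")
}

#' @export
print.glyco_db <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "glycopeptide database (%s-linked): %d entries, %d residues\n",
    x$mode, s$n_glycopeptide_entries, s$n_residues_total))
  cat(sprintf("  from %d protein(s), %d with candidate peptides\n",
              s$n_proteins_in, s$n_proteins_with_candidates))
  invisible(x)
}

#' Write a glycopeptide database as FASTA
#'
#' Peptide-centric (default): one record per glycopeptide entry with header
#' `>{accession}|{start}-{end}|site{site}|{glycan_name}`, so each entry is
#' an independent search target. Protein-centric: the same records, but the
#' record identifier is the bare accession (entry coordinates move to the
#' description), so a search engine's protein grouping collapses all
#' glycopeptides of one protein. Sequence lines are wrapped at 60 columns.
#'
#' @param db A `glyco_db` from [build_database()].
#' @param path Output FASTA path.
#' @param centric `"peptide"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(db, path, centric = c("peptide", "protein")) {
  centric <- match.arg(centric)
  stopifnot(inherits(db, "glyco_db"))
  e <- db$entries
  headers <- if (centric == "peptide") e$entry_id else
    paste0(e$accession, " ", sprintf("%d-%d|site%d|%s", e$start, e$end,
                                     e$site_primary, e$glycan_name))
  x <- Biostrings::AAStringSet(e$full_sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a glycopeptide database FASTA back into an entry table
#'
#' Parses the header grammar written by [write_database_fasta()]
#' (peptide-centric form).
#'
#' @param path FASTA path.
#' @return Data frame with the same columns as `build_database()$entries`
#'   except `sites` (only the primary site survives the header).
#' @export
read_database_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("header ", bad[1], " does not follow accession|start-end|site|glycan")
  acc <- vapply(parts, `[[`, character(1), 1L)
  se <- strsplit(vapply(parts, `[[`, character(1), 2L), "-", fixed = TRUE)
  data.frame(
    entry_id = hdr,
    accession = acc,
    start = as.integer(vapply(se, `[[`, character(1), 1L)),
    end = as.integer(vapply(se, `[[`, character(1), 2L)),
    site_primary = as.integer(sub("^site", "",
                                  vapply(parts, `[[`, character(1), 3L))),
    glycan_name = vapply(parts, `[[`, character(1), 4L),
    full_sequence = as.character(aa),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Export residue and modification definitions
#'
#' Writes the glycan alphabet as (i) a unimod-style XML fragment defining
#' each monosaccharide code with its monoisotopic mass plus the
#' modification set used by the search (fucose on O, oxidation on M,
#' carbamidomethyl on C), for users who configure an external search
#' engine; and (ii) the same data as a TSV that [import_mod_definitions()]
#' reads back. Bit-exact unimod.xml patching is not attempted.
#'
#' @param alphabet A [glycan_alphabet()].
#' @param xml_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of written paths.
#' @export
export_mod_definitions <- function(alphabet, xml_path = NULL,
                                   tsv_path = NULL) {
  stopifnot(inherits(alphabet, "glycan_alphabet"))
  mods <- mass_constants$modifications
  # fucose delta comes from the alphabet, not the shipped default table
  vm <- alphabet$variable
  written <- list()
  if (!is.null(xml_path)) {
    root <- xml2::xml_new_root(
      "umod:residue_definitions",
      "xmlns:umod" = "http://www.unimod.org/xmlns/schema/unimod_2")
    res_node <- xml2::xml_add_child(root, "umod:residues")
    for (d in alphabet$defs) {
      xml2::xml_add_child(res_node, "umod:residue",
                          code = d$code, title = d$name,
                          mono_mass = sprintf("%.4f", d$residue_mass))
    }
    mod_node <- xml2::xml_add_child(root, "umod:modifications")
    add_mod <- function(name, delta, target, kind) {
      xml2::xml_add_child(mod_node, "umod:mod",
                          title = name, site = target,
                          delta_mono_mass = sprintf("%.4f", delta),
                          classification = kind)
    }
    for (i in seq_len(nrow(vm)))
      add_mod(vm$name[i], vm$delta_mass[i], vm$target[i], "variable")
    std <- mods[mods$name != "fucose", , drop = FALSE]
    for (i in seq_len(nrow(std)))
      add_mod(std$name[i], std$delta_mass[i], std$target[i], std$kind[i])
    xml2::write_xml(root, xml_path)
    written$xml <- xml_path
  }
  if (!is.null(tsv_path)) {
    res <- data.frame(
      record = "residue",
      code = vapply(alphabet$defs, function(d) d$code, character(1)),
      name = vapply(alphabet$defs, function(d) d$name, character(1)),
      mass = vapply(alphabet$defs, function(d) d$residue_mass, numeric(1)),
      formula = vapply(alphabet$defs, function(d) d$formula, character(1)),
      stringsAsFactors = FALSE
    )
    std <- mods[mods$name != "fucose", , drop = FALSE]
    modrows <- data.frame(
      record = "modification",
      code = c(vm$target, std$target),
      name = c(vm$name, std$name),
      mass = c(vm$delta_mass, std$delta_mass),
      formula = NA_character_,
      stringsAsFactors = FALSE
    )
    utils::write.table(rbind(res, modrows), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written$tsv <- tsv_path
  }
  invisible(written)
}

#' Re-import an alphabet from an exported TSV
#'
#' Inverse of the TSV half of [export_mod_definitions()]: reconstructs the
#' [glycan_alphabet()] (residue rows plus variable monosaccharides whose
#' target is a glycan code).
#'
#' @param tsv_path Path written by [export_mod_definitions()].
#' @return A [glycan_alphabet()].
#' @export
import_mod_definitions <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  res <- tab[tab$record == "residue", , drop = FALSE]
  defs <- lapply(seq_len(nrow(res)), function(i)
    monosaccharide_def(res$code[i], res$name[i], res$mass[i],
                       res$formula[i]))
  codes <- res$code
  mods <- tab[tab$record == "modification" & tab$code %in% codes, ,
              drop = FALSE]
  variable <- data.frame(name = mods$name, delta_mass = mods$mass,
                         target = mods$code, stringsAsFactors = FALSE)
  glycan_alphabet(defs, variable)
}
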