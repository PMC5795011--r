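#' Generate a decoy database by peptide reversal
#'
#' Reverses the peptide portion of every entry while keeping a C-terminal
#' K/R in place (preserving tryptic character) and leaving the glycan
#' unchanged. Decoys therefore have exactly the target's precursor mass,
#' giving a mass-matched null model for false-discovery estimation.
#'
#' @param db A `glyco_db` from [build_database()].
#' @return A `glyco_db` whose entries are decoys (`entry_id` prefixed
#'   `DECOY_`).
#' @export
build_decoys <- function(db) {
  stopifnot(inherits(db, "glyco_db"))
  e <- db$entries
  rev_pep <- vapply(e$peptide, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n > 1L && chars[n] %in% c("K", "R"))
      paste(c(rev(chars[-n]), chars[n]), collapse = "")
    else paste(rev(chars), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  e$peptide <- rev_pep
  e$full_sequence <- paste0(e$glycan_seq, e$peptide)
  e$entry_id <- paste0("DECOY_", e$entry_id)
  e$accession <- paste0("DECOY_", e$accession)
  structure(list(entries = e, stats = db$stats, mode = db$mode),
            class = "glyco_db")
}

#' Expand a database into a searchable form table
#'
#' Enumerates fucoform/oxidation variants for every entry (each variant is
#' an independent search candidate) and precomputes neutral masses so
#' precursor-based candidate selection is a vectorized filter.
#'
#' @param db A `glyco_db` (targets), or a list of `glycopeptide_form`s.
#' @param alphabet A [glycan_alphabet()].
#' @param max_fucose,max_oxidation Variable-modification limits (see
#'   [enumerate_fucoforms()]).
#' @param decoys If TRUE, append reversed-peptide decoy forms
#'   ([build_decoys()]).
#' @return Data frame with one row per form: identifiers, sequences,
#'   list-columns `fucose_pos`/`oxidation_pos`, `n_fucose`, `is_decoy`,
#'   and `neutral_mass`.
#' @export
db_to_forms <- function(db, alphabet = default_alphabet(),
                        max_fucose = 2L, max_oxidation = 1L,
                        decoys = FALSE) {
  dbs <- list(list(db = db, decoy = FALSE))
  if (decoys) dbs[[2]] <- list(db = build_decoys(db), decoy = TRUE)
  rows <- list()
  for (d in dbs) {
    e <- d$db$entries
    for (i in seq_len(nrow(e))) {
      forms <- enumerate_fucoforms(e[i, ], max_fucose = max_fucose,
                                   max_oxidation = max_oxidation)
      for (f in forms) {
        rows[[length(rows) + 1L]] <- list(
          entry_id = e$entry_id[i], accession = e$accession[i],
          peptide = f$peptide, glycan_name = e$glycan_name[i],
          glycan_seq = f$glycan_seq, full_sequence = f$full_sequence,
          fucose_pos = list(f$fucose_pos),
          oxidation_pos = list(f$oxidation_pos),
          n_fucose = length(f$fucose_pos),
          is_decoy = d$decoy,
          neutral_mass = neutral_mass(f, alphabet))
      }
    }
  }
  out <- data.frame(
    entry_id = vapply(rows, `[[`, character(1), "entry_id"),
    accession = vapply(rows, `[[`, character(1), "accession"),
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    glycan_name = vapply(rows, `[[`, character(1), "glycan_name"),
    glycan_seq = vapply(rows, `[[`, character(1), "glycan_seq"),
    full_sequence = vapply(rows, `[[`, character(1), "full_sequence"),
    n_fucose = vapply(rows, `[[`, integer(1), "n_fucose"),
    is_decoy = vapply(rows, `[[`, logical(1), "is_decoy"),
    neutral_mass = vapply(rows, `[[`, numeric(1), "neutral_mass"),
    stringsAsFactors = FALSE
  )
  out$fucose_pos <- I(lapply(rows, function(r) r$fucose_pos[[1]]))
  out$oxidation_pos <- I(lapply(rows, function(r) r$oxidation_pos[[1]]))
  out$form_id <- sprintf(
    "%s/fuc:%s/ox:%s", out$entry_id,
    vapply(out$fucose_pos, paste, character(1), collapse = "."),
    vapply(out$oxidation_pos, paste, character(1), collapse = "."))
  out
}

# rebuild a glycopeptide_form from one row of a form table
.form_from_row <- function(forms, i) {
  glycopeptide_form(
    peptide = forms$peptide[i], glycan_seq = forms$glycan_seq[i],
    fucose_pos = forms$fucose_pos[[i]],
    oxidation_pos = forms$oxidation_pos[[i]],
    entry_id = forms$entry_id[i], accession = forms$accession[i],
    glycan_name = forms$glycan_name[i])
}

#' Select candidate forms by precursor mass
#'
#' @param s A `spectrum` (charge must be known).
#' @param forms Form table from [db_to_forms()].
#' @param ppm Precursor tolerance in parts per million (default 10).
#' @return The rows of `forms` whose precursor m/z at the spectrum's charge
#'   lies within `ppm` of the observed precursor, with an added
#'   `precursor_error_ppm` column.
#' @export
select_candidates <- function(s, forms, ppm = 10) {
  if (is.na(s$charge)) stop("spectrum charge is unknown")
  z <- s$charge
  theo <- (forms$neutral_mass + z * mass_constants$proton) / z
  err <- (s$precursor_mz - theo) / theo * 1e6
  keep <- abs(err) <= ppm
  out <- forms[keep, , drop = FALSE]
  out$precursor_error_ppm <- err[keep]
  row.names(out) <- NULL
  out
}

#' Match theoretical ions to observed peaks
#'
#' Greedy one-to-one assignment in descending peak intensity: each peak is
#' assigned to the closest still-unmatched theoretical ion within
#' `tol_da`; each theoretical ion is matched at most once, so at most its
#' single most-intense peak within tolerance is used.
#'
#' @param s A `spectrum` (peaks sorted ascending).
#' @param ions Data frame of theoretical ions (from [fragment_ions()] /
#'   [scored_ions()]).
#' @param tol_da Fragment tolerance in Da (default 0.05).
#' @return Data frame of matches: ion columns plus `observed_mz`,
#'   `intensity`, `error_da`.
#' @export
match_peaks <- function(s, ions, tol_da = 0.05) {
  peaks <- s$peaks
  n_ions <- nrow(ions)
  if (n_ions == 0L || nrow(peaks) == 0L) {
    out <- cbind(ions[0, , drop = FALSE],
                 data.frame(observed_mz = numeric(), intensity = numeric(),
                            error_da = numeric()))
    return(out)
  }
  taken <- logical(n_ions)
  hit_peak <- integer(0); hit_ion <- integer(0)
  for (p in order(peaks[, 2], decreasing = TRUE)) {
    d <- abs(ions$mz - peaks[p, 1])
    cand <- which(d <= tol_da & !taken)
    if (length(cand)) {
      best <- cand[which.min(d[cand])]
      taken[best] <- TRUE
      hit_peak <- c(hit_peak, p); hit_ion <- c(hit_ion, best)
    }
  }
  out <- ions[hit_ion, , drop = FALSE]
  out$observed_mz <- peaks[hit_peak, 1]
  out$intensity <- peaks[hit_peak, 2]
  out$error_da <- out$observed_mz - out$mz
  row.names(out) <- NULL
  out[order(out$mz), , drop = FALSE]
}

#' Binomial-tail ion score of a peptide-spectrum match
#'
#' An open probabilistic score in the spirit of probability-based peptide
#' scoring: under the null, each of the `n` scored theoretical ions
#' independently hits a random peak with probability
#' `q = 2 * tol_da * peak_density`, where the peak density is estimated
#' from the observed spectrum over the scored m/z range. The match
#' probability is the binomial survival `P(X >= k)` at the observed match
#' count `k`, and the score is `-10 log10(p)`, capped at 300. This is not
#' numerically equal to any proprietary engine's score; the conventional
#' acceptance threshold of 25 is kept as the default cutoff.
#'
#' @param matches Data frame from [match_peaks()].
#' @param s The `spectrum`.
#' @param ions The scored theoretical ions used for matching.
#' @param tol_da Fragment tolerance in Da (default 0.05).
#' @return List with `score`, `p_value`, `n_scored`, `n_matched`, `q`.
#' @export
score_psm <- function(matches, s, ions, tol_da = 0.05) {
  n <- nrow(ions)
  k <- nrow(matches)
  if (n == 0L)
    return(list(score = 0, p_value = 1, n_scored = 0L, n_matched = 0L,
                q = NA_real_))
  rng <- range(ions$mz)
  width <- diff(rng)
  peaks_in <- sum(s$peaks[, 1] >= rng[1] - tol_da &
                    s$peaks[, 1] <= rng[2] + tol_da)
  q <- if (width > 0) 2 * tol_da * peaks_in / width else 1
  q <- min(max(q, 1e-12), 0.999)
  if (k == 0L)
    return(list(score = 0, p_value = 1, n_scored = n, n_matched = 0L,
                q = q))
  logp <- stats::pbinom(k - 1L, n, q, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  score <- min(-10 * logp / log(10), 300)
  list(score = score, p_value = p, n_scored = n, n_matched = k, q = q)
}

# score one candidate row against a spectrum -> one PSM row
.score_candidate <- function(s, forms, i, alphabet, tol_da, two_plus_min_mass) {
  form <- .form_from_row(forms, i)
  ions <- scored_ions(fragment_ions(form, alphabet,
                                    two_plus_min_mass = two_plus_min_mass),
                      form$glycan_len)
  matches <- match_peaks(s, ions, tol_da = tol_da)
  sc <- score_psm(matches, s, ions, tol_da = tol_da)
  data.frame(
    spectrum_id = s$spectrum_id, form_id = forms$form_id[i],
    entry_id = forms$entry_id[i], accession = forms$accession[i],
    peptide = forms$peptide[i], glycan_name = forms$glycan_name[i],
    glycan_seq = forms$glycan_seq[i],
    full_sequence = forms$full_sequence[i],
    n_fucose = forms$n_fucose[i],
    fucose_pos = paste(forms$fucose_pos[[i]], collapse = ","),
    charge = s$charge,
    precursor_error_ppm = forms$precursor_error_ppm[i],
    score = sc$score, p_value = sc$p_value,
    n_matched_y = sum(matches$series == "y"),
    n_matched_b = sum(matches$series == "b"),
    n_scored = sc$n_scored,
    is_decoy = forms$is_decoy[i],
    stringsAsFactors = FALSE
  )
}

#' Search spectra against a glycopeptide form table
#'
#' For each spectrum: select candidates within the precursor tolerance,
#' generate scored theoretical ions per candidate, match peaks, compute
#' the binomial ion score, and rank candidates (ties broken by smaller
#' absolute precursor error, then lexicographic full sequence -- search
#' results never depend on a random seed). Spectra with unknown charge are
#' skipped with a warning.
#'
#' @param spectra List of `spectrum` objects (e.g. from [read_mgf()]).
#' @param forms Form table from [db_to_forms()].
#' @param alphabet A [glycan_alphabet()].
#' @param ppm Precursor tolerance (default 10 ppm).
#' @param tol_da Fragment tolerance (default 0.05 Da).
#' @param two_plus_min_mass 2+ fragment threshold (see [fragment_ions()]).
#' @param fucose_class Annotate accepted-candidate fucose localization
#'   ([classify_fucose_site()]) on every PSM row (default TRUE).
#' @return Data frame of PSMs with a `rank` column (1 = best per
#'   spectrum).
#' @seealso [rank_and_filter()] for the acceptance rules.
#' @export
glyco_search <- function(spectra, forms, alphabet = default_alphabet(),
                         ppm = 10, tol_da = 0.05,
                         two_plus_min_mass = 900, fucose_class = TRUE) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  psm_rows <- list()
  for (s in spectra) {
    if (is.na(s$charge)) {
      warning("skipping spectrum '", s$spectrum_id, "': unknown charge")
      next
    }
    cand <- select_candidates(s, forms, ppm = ppm)
    if (!nrow(cand)) next
    rows <- lapply(seq_len(nrow(cand)), function(i)
      .score_candidate(s, cand, i, alphabet, tol_da, two_plus_min_mass))
    psms <- do.call(rbind, rows)
    # ties (e.g. fucoforms capped at the maximum score share the same
    # sequence and precursor error) are broken by total matched ions, so
    # the placement explaining the most peaks ranks first
    ord <- order(-psms$score, -(psms$n_matched_y + psms$n_matched_b),
                 abs(psms$precursor_error_ppm), psms$full_sequence,
                 psms$fucose_pos)
    psms <- psms[ord, , drop = FALSE]
    psms$rank <- seq_len(nrow(psms))
    if (fucose_class) {
      psms$fucose_class <- vapply(seq_len(nrow(psms)), function(i) {
        j <- match(psms$form_id[i], cand$form_id)
        classify_fucose_site(.form_from_row(cand, j), s, alphabet,
                             tol_da = tol_da,
                             two_plus_min_mass = two_plus_min_mass)
      }, character(1))
    }
    psm_rows[[length(psm_rows) + 1L]] <- psms
  }
  if (!length(psm_rows)) {
    warning("no spectrum produced any candidate")
    return(data.frame())
  }
  out <- do.call(rbind, psm_rows)
  row.names(out) <- NULL
  out
}

#' Apply the acceptance rules to a PSM table
#'
#' Keeps, per spectrum, the top-ranked match (ties already broken
#' deterministically by [glyco_search()]) with ion score at least
#' `min_score` and match probability below `max_p` -- the standard
#' top-match / score-threshold / significance filter.
#'
#' @param psms PSM data frame from [glyco_search()].
#' @param min_score Minimum ion score (default 25).
#' @param max_p Maximum match probability (default 0.001).
#' @param top_only Keep only rank-1 hits (default TRUE).
#' @return The accepted subset.
#' @export
rank_and_filter <- function(psms, min_score = 25, max_p = 0.001,
                            top_only = TRUE) {
  if (!nrow(psms)) return(psms)
  keep <- psms$score >= min_score & psms$p_value < max_p
  if (top_only) keep <- keep & psms$rank == 1L
  out <- psms[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

# does any observed peak fall within tol of mz?
.has_peak <- function(s, mz, tol) any(abs(s$peaks[, 1] - mz) <= tol)

#' Localize fucose as core or antenna
#'
#' The diagnostic is the Y1 ion (peptide + core HexNAc, the
#' peptide-adjacent O): a peak 146.0579 Da above Y1 shows the fucose rides
#' on the core HexNAc; Y1 present without the +146 companion, while larger
#' fucose-bearing y ions do match, places the fucose beyond the
#' trimannosyl core (antenna). Both 1+ and (above the 2+ mass threshold)
#' 2+ ions are checked.
#'
#' @param form A [glycopeptide_form()] carrying at least one fucose.
#' @param s The matched `spectrum`.
#' @param alphabet A [glycan_alphabet()].
#' @param tol_da Fragment tolerance (default 0.05 Da).
#' @param two_plus_min_mass 2+ fragment threshold.
#' @return `"core"`, `"antenna"`, `"undetermined"`, or
#'   `"not_applicable"` when the form carries no fucose.
#' @export
classify_fucose_site <- function(form, s, alphabet = default_alphabet(),
                                 tol_da = 0.05, two_plus_min_mass = 900) {
  stopifnot(inherits(form, "glycopeptide_form"))
  if (!length(form$fucose_pos)) return("not_applicable")
  if (form$glycan_len < 1L) return("not_applicable")
  proton <- mass_constants$proton
  fuc_delta <- alphabet$variable$delta_mass[
    alphabet$variable$name == "fucose"][1]
  # Y1 neutral mass computed fucose-free: peptide (+fixed/ox mods) + core O
  base <- glycopeptide_form(form$peptide, form$glycan_seq,
                            fucose_pos = integer(),
                            oxidation_pos = form$oxidation_pos)
  res <- .residue_vector(base, alphabet)
  n <- length(res)
  p_len <- nchar(form$peptide)
  y1_neutral <- sum(res[(n - p_len):n]) + mass_constants$water
  mz_of <- function(neutral) {
    out <- neutral + proton
    if (neutral > two_plus_min_mass) out <- c(out, (neutral + 2 * proton) / 2)
    out
  }
  y1_seen <- any(vapply(mz_of(y1_neutral), .has_peak, logical(1), s = s,
                        tol = tol_da))
  y1_fuc_seen <- any(vapply(mz_of(y1_neutral + fuc_delta), .has_peak,
                            logical(1), s = s, tol = tol_da))
  if (y1_fuc_seen) return("core")
  if (!y1_seen) return("undetermined")
  # antenna evidence: larger fucose-spanning y ions of the actual form
  ions <- fragment_ions(form, alphabet,
                        two_plus_min_mass = two_plus_min_mass)
  yions <- ions[ions$series == "y" & ions$ordinal > p_len + 1L, ,
                drop = FALSE]
  if (nrow(yions)) {
    spans_fuc <- vapply(yions$ordinal, function(o)
      any(form$fucose_pos > n - o), logical(1))
    yions <- yions[spans_fuc, , drop = FALSE]
    if (nrow(yions) &&
        any(vapply(yions$mz, .has_peak, logical(1), s = s, tol = tol_da)))
      return("antenna")
  }
  "undetermined"
}

#' Tabulate accepted identifications by glycan composition
#'
#' Groups accepted PSMs by monosaccharide composition plus fucose count
#' (irrespective of protein origin). When a `ratio` column is attached to
#' the PSMs (e.g. external quantification values), the per-group median
#' ratio is reported.
#'
#' @param accepted Accepted PSM data frame ([rank_and_filter()]).
#' @param alphabet A [glycan_alphabet()].
#' @return Data frame with `composition` (e.g. `"O4 J5 U2"`), `n_fucose`,
#'   `n_psms`, and `median_ratio` when ratios are present.
#' @export
summarize_by_composition <- function(accepted,
                                     alphabet = default_alphabet()) {
  if (!nrow(accepted))
    return(data.frame(composition = character(), n_fucose = integer(),
                      n_psms = integer(), stringsAsFactors = FALSE))
  comp_str <- vapply(accepted$glycan_seq, function(g) {
    comp <- glycan_composition(g, alphabet)
    paste(sprintf("%s%d", names(comp), comp), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  key <- paste(comp_str, accepted$n_fucose, sep = " / ")
  groups <- split(seq_len(nrow(accepted)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    row <- data.frame(
      composition = comp_str[idx[1]],
      n_fucose = accepted$n_fucose[idx[1]],
      n_psms = length(idx),
      stringsAsFactors = FALSE
    )
    if ("ratio" %in% names(accepted))
      row$median_ratio <- stats::median(accepted$ratio[idx], na.rm = TRUE)
    row
  }))
  out <- out[order(-out$n_psms, out$composition, out$n_fucose), ,
             drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Write an identification report as TSV
#'
#' @param accepted PSM data frame (accepted or full).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(accepted, path) {
  cols <- c("spectrum_id", "accession", "peptide", "glycan_name",
            "glycan_seq", "n_fucose", "fucose_class", "charge",
            "precursor_error_ppm", "score", "p_value", "n_matched_y",
            "n_matched_b", "rank", "is_decoy")
  cols <- cols[cols %in% names(accepted)]
  utils::write.table(accepted[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
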