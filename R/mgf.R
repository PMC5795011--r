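#' Read MS2 spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` (first
#' token = precursor m/z), `CHARGE` (e.g. `"3+"`) and optional
#' `RTINSECONDS`; peak lines are `mz intensity`. Peaks are returned sorted
#' ascending by m/z. A spectrum without a CHARGE line is kept with charge
#' `NA` and flagged with a warning.
#'
#' @param path MGF file path.
#' @return List of `spectrum` objects: each a list with `spectrum_id`,
#'   `precursor_mz`, `charge`, `rt` (seconds or NA) and `peaks` (two-column
#'   matrix `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  block_start <- NA_integer_
  title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
  rt <- NA_real_; mz <- numeric(); int <- numeric()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block)
        stop("malformed MGF at line ", ln, ": nested BEGIN IONS")
      in_block <- TRUE; block_start <- ln
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      rt <- NA_real_; mz <- numeric(); int <- numeric()
    } else if (line == "END IONS") {
      if (!in_block)
        stop("malformed MGF at line ", ln, ": END IONS without BEGIN IONS")
      if (is.na(pepmass))
        stop("malformed MGF block starting at line ", block_start,
             ": missing PEPMASS")
      if (is.na(charge))
        warning("spectrum '", title, "' has no CHARGE line; charge unset")
      ord <- order(mz)
      peaks <- cbind(mz = mz[ord], intensity = int[ord])
      spectra[[length(spectra) + 1L]] <- structure(
        list(spectrum_id = title, precursor_mz = pepmass, charge = charge,
             rt = rt, peaks = peaks),
        class = "spectrum")
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("=", line, fixed = TRUE)) {
        key <- sub("=.*$", "", line)
        val <- sub("^[^=]*=", "", line)
        if (key == "TITLE") title <- val
        else if (key == "PEPMASS")
          pepmass <- as.numeric(strsplit(trimws(val), "\\s+")[[1]][1])
        else if (key == "CHARGE") {
          ch <- suppressWarnings(as.integer(gsub("[+ ]", "", val)))
          if (is.na(ch)) stop("malformed CHARGE at line ", ln, ": ", val)
          if (grepl("-", val, fixed = TRUE)) ch <- -abs(ch)
          charge <- ch
        } else if (key == "RTINSECONDS") rt <- as.numeric(val)
        # other headers ignored
      } else {
        tok <- strsplit(line, "\\s+")[[1]]
        v <- suppressWarnings(as.numeric(tok))
        if (length(v) < 2L || anyNA(v[1:2]))
          stop("malformed MGF peak line ", ln, ": ", line)
        mz <- c(mz, v[1]); int <- c(int, v[2])
      }
    } else {
      stop("malformed MGF at line ", ln, ": content outside BEGIN/END IONS")
    }
  }
  if (in_block)
    stop("malformed MGF: block starting at line ", block_start,
         " has no END IONS")
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]; m/z values are written with 6 decimals so a
#' write/read round trip preserves peaks to 1e-6.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$charge))
      writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (!is.null(s$rt) && !is.na(s$rt))
      writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    writeLines(sprintf("%.6f %.4f", s$peaks[, 1], s$peaks[, 2]), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Construct a spectrum object
#'
#' @param spectrum_id Spectrum title.
#' @param precursor_mz Precursor m/z (Da/charge).
#' @param charge Precursor charge state (positive integer, or NA).
#' @param peaks Two-column matrix or data frame of (mz, intensity); sorted
#'   ascending by m/z on construction.
#' @param rt Retention time in seconds (optional).
#' @return A `spectrum` object.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, peaks,
                     rt = NA_real_) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  if (any(peaks[, 2] < 0)) stop("intensities must be >= 0")
  if (precursor_mz <= 0) stop("precursor_mz must be positive")
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  structure(list(spectrum_id = spectrum_id, precursor_mz = precursor_mz,
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 rt = rt, peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum %s: precursor %.4f (%s+), %d peaks\n",
              x$spectrum_id, x$precursor_mz,
              ifelse(is.na(x$charge), "?", x$charge), nrow(x$peaks)))
  invisible(x)
}
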