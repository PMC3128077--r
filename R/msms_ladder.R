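#' Theoretical b/y fragment-ion series
#'
#' Singly charged monoisotopic fragment series of a peptide:
#' `y_n` = sum of the C-terminal n residue masses + water + proton;
#' `b_n` = sum of the N-terminal n residue masses + proton;
#' n = 1..length-1.
#'
#' @param peptide Amino-acid string of length >= 2, standard residues
#'   only.
#' @param series `"y"` (default) or `"b"`.
#' @return A data.frame with columns `series`, `index`, `mz`
#'   (strictly increasing with index).
#' @examples
#' fragment_mz_series("MNEKHAAELK", "y")
#' @export
fragment_mz_series <- function(peptide, series = c("y", "b")) {
  series <- match.arg(series)
  peptide <- toupper(as.character(peptide))
  n <- nchar(peptide)
  if (n < 2L) stop("peptide must have at least 2 residues")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  rmass <- .residue_mass_table("monoisotopic")
  m <- rmass[aa]
  if (anyNA(m)) {
    stop(
      "non-standard residue(s): ",
      paste(unique(aa[!aa %in% names(rmass)]), collapse = ", ")
    )
  }
  idx <- seq_len(n - 1L)
  mz <- if (series == "y") {
    cumsum(rev(m))[idx] + .water_mass("monoisotopic") + .PROTON_MASS
  } else {
    cumsum(m)[idx] + .PROTON_MASS
  }
  data.frame(series = series, index = idx, mz = unname(mz),
    stringsAsFactors = FALSE
  )
}

# residue masses with I/L (and, at loose tolerance, K/Q) reported as
# ambiguity sets rather than a guessed single residue
.ladder_residue_label <- function(delta, tolerance_da) {
  rmass <- .residue_mass_table("monoisotopic")
  hit <- names(rmass)[abs(rmass - delta) <= tolerance_da]
  if (length(hit) == 0L) return(NA_character_)
  if (any(c("I", "L") %in% hit)) hit <- union(hit, c("I", "L"))
  if (tolerance_da >= 0.04 && any(c("K", "Q") %in% hit)) {
    hit <- union(hit, c("K", "Q"))
  }
  paste(sort(hit), collapse = "/")
}

#' Read a residue sequence out of a y-ion ladder
#'
#' Sorts the peaks by m/z, interprets successive mass differences as
#' residue masses (within `tolerance_da`), and reports every contiguous
#' run of at least two matched steps as an inferred residue string,
#' indexed from the C-terminus. The lowest peak is additionally tested
#' as a y1 ion (peak minus water+proton matched to a residue mass) so
#' that the C-terminal residue itself can be read. Residues
#' indistinguishable at the working tolerance are reported as ambiguity
#' sets: always `I/L`, and `K/Q` when `tolerance_da >= 0.04`.
#'
#' @param peaks A data.frame with an `mz` column (and optionally
#'   `intensity`), or a numeric vector of m/z values; at least 3 peaks.
#' @param tolerance_da Residue-match tolerance in Da (default 0.5, a
#'   manual low-resolution TOF/TOF read).
#'
#' @return A list: `runs` — a list of data.frames (`position`
#'   from the C-terminus where known, else within-run; `residues`
#'   ambiguity label; `delta_da` observed step), `residues` — the
#'   concatenated labels of the longest run, `rms_error` — RMS (Da) of
#'   matched steps against their nearest residue mass, `n_runs`.
#' @examples
#' lad <- fragment_mz_series("MNEKHAAELK", "y")
#' read_ladder(lad$mz)$residues
#' @export
read_ladder <- function(peaks, tolerance_da = 0.5) {
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  if (length(mz) < 3L) stop("need at least 3 peaks")
  mz <- sort(mz)
  # virtual anchor: a y1 peak differs from water+proton by one residue
  anchor <- .water_mass("monoisotopic") + .PROTON_MASS
  mzx <- c(anchor, mz)
  deltas <- diff(mzx)
  labels <- vapply(deltas, .ladder_residue_label, character(1L),
    tolerance_da = tolerance_da
  )
  anchored <- !is.na(labels[1L])
  matched <- !is.na(labels)
  rmass <- .residue_mass_table("monoisotopic")
  errs <- vapply(deltas[matched], function(d) min(abs(rmass - d)),
    numeric(1L)
  )
  rms <- if (length(errs)) sqrt(mean(errs^2)) else NA_real_

  r <- rle(matched)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  for (k in which(r$values & r$lengths >= 2L)) {
    ix <- starts[k]:ends[k]
    # step i spans mzx[i] -> mzx[i+1]; if the run is anchored at the
    # virtual y0, positions are true C-terminal indices
    pos <- if (starts[k] == 1L) ix else ix - starts[k] + 1L
    runs[[length(runs) + 1L]] <- data.frame(
      position = pos,
      residues = labels[ix],
      delta_da = deltas[ix],
      anchored = starts[k] == 1L,
      stringsAsFactors = FALSE
    )
  }
  if (length(runs) == 0L) {
    message("no contiguous run of >= 2 matched mass differences")
    return(list(
      runs = list(), residues = character(0), rms_error = rms, n_runs = 0L
    ))
  }
  longest <- runs[[which.max(vapply(runs, nrow, integer(1L)))]]
  list(
    runs = runs,
    residues = longest$residues,
    rms_error = rms,
    n_runs = length(runs)
  )
}

#' Read an MGF (Mascot generic format) peak list
#'
#' Minimal reader for MS/MS peak lists: parses `BEGIN IONS`/`END IONS`
#' blocks, `TITLE`/`PEPMASS` headers and `m/z intensity` peak lines.
#'
#' @param path Path to an MGF file.
#' @return A list of spectra; each is a list with `title`, `pepmass`,
#'   and `peaks` (data.frame `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  title <- NA_character_
  pepmass <- NA_real_
  mzs <- numeric()
  ints <- numeric()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      in_block <- TRUE
      title <- NA_character_
      pepmass <- NA_real_
      mzs <- numeric()
      ints <- numeric()
    } else if (ln == "END IONS") {
      spectra[[length(spectra) + 1L]] <- list(
        title = title, pepmass = pepmass,
        peaks = data.frame(mz = mzs, intensity = ints)
      )
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") title <- val
      if (key == "PEPMASS") {
        pepmass <- as.numeric(strsplit(val, "\\s+")[[1L]][1L])
      }
    } else if (in_block) {
      parts <- strsplit(ln, "\\s+")[[1L]]
      mzs <- c(mzs, as.numeric(parts[1L]))
      ints <- c(ints, if (length(parts) > 1L) as.numeric(parts[2L]) else 0)
    }
  }
  spectra
}

#' Write spectra to MGF
#'
#' @param spectra A list of spectra as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con)
    }
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    }
    writeLines(
      sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity), con
    )
    writeLines("END IONS", con)
  }
  invisible(path)
}
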