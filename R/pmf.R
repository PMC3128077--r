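#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine except when the next
#' residue is proline (KP/RP suppression), and emits every peptide with
#' 0 to `max_missed` missed cleavages. Each peptide carries its
#' monoisotopic mass.
#'
#' @param parent Amino-acid string.
#' @param max_missed Maximum missed cleavages (default 0).
#' @return A data.frame: `start_aa`, `end_aa` (1-based inclusive),
#'   `sequence`, `missed_cleavages`, `mono_mass`.
#' @examples
#' tryptic_digest("AKRPGK")       # "AK", "RPGK"
#' tryptic_digest("AKCK", max_missed = 1)
#' @export
tryptic_digest <- function(parent, max_missed = 0) {
  parent <- toupper(as.character(parent))
  n <- nchar(parent)
  if (n == 0L) stop("empty parent sequence")
  aa <- strsplit(parent, "", fixed = TRUE)[[1L]]
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites < n & aa[pmin(sites + 1L, n)] != "P"]
  bounds <- c(0L, sites, n) # fragment i spans (bounds[i]+1)..bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      seqs <- substr(parent, s, e)
      out[[length(out) + 1L]] <- data.frame(
        start_aa = s, end_aa = e, sequence = seqs,
        missed_cleavages = m,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$mono_mass <- vapply(res$sequence, peptide_mass, numeric(1L),
    mode = "monoisotopic"
  )
  rownames(res) <- NULL
  res
}

#' Peptide-mass-fingerprint coverage of a parent protein
#'
#' Matches observed masses (singly protonated, `[M+H]+`, by default) to
#' the in-silico tryptic digest of `parent` within a ppm tolerance, and
#' reports the fraction of parent residues covered by at least one
#' matched peptide. Optionally flags whether any matched peptide
#' overlaps a designated N-terminal interval (e.g. a newly proposed
#' N-terminal extension of the annotated protein).
#'
#' @param parent Amino-acid string.
#' @param observed_masses Numeric vector of observed `[M+H]+` m/z
#'   values.
#' @param tolerance_ppm Match tolerance (default 50 ppm, typical
#'   reflectron PMF).
#' @param max_missed Missed cleavages allowed in the digest (default 1).
#' @param n_term_interval Optional length-2 integer vector
#'   `c(first, last)` of the N-terminal extension interval.
#'
#' @return A list: `covered_fraction` (percent of residues covered),
#'   `matched` (data.frame of matched digest peptides with `obs_mz` and
#'   `delta_ppm`), `covers_extension` (logical, `NA` when no interval
#'   given).
#' @export
pmf_coverage <- function(parent, observed_masses, tolerance_ppm = 50,
                         max_missed = 1, n_term_interval = NULL) {
  stopifnot(tolerance_ppm > 0)
  digest <- tryptic_digest(parent, max_missed = max_missed)
  digest$theo_mz <- digest$mono_mass + .PROTON_MASS
  matched <- digest[0, , drop = FALSE]
  matched$obs_mz <- numeric()
  matched$delta_ppm <- numeric()
  if (length(observed_masses) > 0L) {
    hits <- list()
    for (obs in observed_masses) {
      dp <- ppm_delta(obs, digest$theo_mz)
      ok <- which(abs(dp) <= tolerance_ppm)
      if (length(ok) == 0L) next
      h <- digest[ok, , drop = FALSE]
      h$obs_mz <- obs
      h$delta_ppm <- dp[ok]
      hits[[length(hits) + 1L]] <- h
    }
    if (length(hits) > 0L) matched <- do.call(rbind, hits)
  }
  n <- nchar(parent)
  covered <- logical(n)
  for (i in seq_len(nrow(matched))) {
    covered[matched$start_aa[i]:matched$end_aa[i]] <- TRUE
  }
  covers_extension <- NA
  if (!is.null(n_term_interval)) {
    stopifnot(length(n_term_interval) == 2L)
    covers_extension <- any(
      matched$start_aa <= n_term_interval[2L] &
        matched$end_aa >= n_term_interval[1L]
    )
  }
  rownames(matched) <- NULL
  list(
    covered_fraction = 100 * sum(covered) / n,
    matched = matched,
    covers_extension = covers_extension
  )
}
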