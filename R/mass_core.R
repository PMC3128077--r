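#' Neutral mass of a peptide or protein
#'
#' Sums residue masses from the packaged elemental-composition table and
#' adds one water. `"monoisotopic"` uses principal-isotope masses
#' (reflectron-mode MALDI peaks); `"average"` uses standard atomic
#' weights (linear-mode peaks of intact proteins).
#'
#' @param peptide Amino-acid string over the 20 standard residues.
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Neutral (uncharged) mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")          # 799.36 Da monoisotopic
#' peptide_mass("PEPTIDE", "average")
#' @export
peptide_mass <- function(peptide, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  peptide <- toupper(as.character(peptide))
  if (nchar(peptide) == 0L) stop("empty peptide")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  rmass <- .residue_mass_table(mode)
  m <- rmass[aa]
  if (anyNA(m)) {
    stop(
      "non-standard residue(s) in peptide: ",
      paste(unique(aa[!aa %in% names(rmass)]), collapse = ", ")
    )
  }
  sum(m) + .water_mass(mode)
}

#' Theoretical m/z of a singly charged species hypothesis
#'
#' Computes the m/z (z = 1, MALDI context) of a neutral molecule under
#' a charge-carrier / neutral-loss / adduct hypothesis:
#' protonated (+1.007276 Da) or sodiated (+22.989218 Da), minus
#' 17.026549 Da per NH3 loss, plus 42.010565 Da per acetyl group
#' (monoisotopic deltas; average-mode deltas are computed from the same
#' element table when `mode = "average"`).
#'
#' @param neutral_mass Neutral mass in Da (> 0).
#' @param base Charge carrier: `"protonated"` or `"sodiated"`.
#' @param n_nh3_loss Number of NH3 neutral losses (default 0).
#' @param n_acetyl Number of acetyl adducts (default 0).
#' @param mode Mass mode used for the loss/adduct deltas.
#' @return Theoretical m/z in Da.
#' @examples
#' mz_of_species(5104.46, "protonated")              # 5105.47
#' mz_of_species(5104.46, "protonated", n_nh3_loss = 1)
#' @export
mz_of_species <- function(neutral_mass,
                          base = c("protonated", "sodiated"),
                          n_nh3_loss = 0, n_acetyl = 0,
                          mode = c("monoisotopic", "average")) {
  base <- match.arg(base)
  mode <- match.arg(mode)
  stopifnot(neutral_mass > 0, n_nh3_loss >= 0, n_acetyl >= 0)
  carrier <- switch(base,
    protonated = .PROTON_MASS,
    sodiated = .SODIUM_CATION_MASS
  )
  neutral_mass + carrier -
    n_nh3_loss * .mod_delta("NH3", mode) +
    n_acetyl * .mod_delta("acetyl", mode)
}

#' Signed ppm deviation between observed and theoretical mass
#'
#' @param observed,theoretical Masses in Da; `theoretical > 0`.
#' @return `(observed - theoretical) / theoretical * 1e6`, signed.
#' @examples
#' ppm_delta(16725.2, 16724.4)  # ~ +48 ppm
#' @export
ppm_delta <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

.enumerate_hypotheses <- function(max_mods = 1,
                                  carriers = c("protonated", "sodiated")) {
  # each modification type applied at most max_mods times per hypothesis
  expand.grid(
    base = carriers,
    n_nh3_loss = 0:max_mods,
    n_acetyl = 0:max_mods,
    stringsAsFactors = FALSE
  )
}

#' Explain observed MS1 peaks with species hypotheses
#'
#' For each observed peak, enumerates singly charged species hypotheses
#' over all candidates (charge carrier x NH3-loss x acetyl-adduct
#' counts, each modification at most `max_mods` times) and keeps those
#' whose theoretical m/z lies within `tolerance_ppm`. One best
#' assignment per peak (smallest |ppm|) is flagged; the full accepted
#' list is returned.
#'
#' @param peaks A data.frame with columns `mz` and (optionally)
#'   `intensity`.
#' @param candidates A data.frame with a `name` column and either a
#'   `peptide` column (masses computed via [peptide_mass()]) or a
#'   `neutral_mass` column (Da), for intact proteins whose sequence is
#'   not at hand.
#' @param tolerance_ppm Acceptance tolerance (default 150 ppm,
#'   covering typical external-calibration error of linear/reflectron
#'   MALDI).
#' @param max_mods Maximum count of each modification type per
#'   hypothesis (default 1).
#' @param mode Mass mode for candidate masses and deltas.
#'
#' @return A data.frame of accepted assignments: `peak_mz`,
#'   `intensity`, `candidate`, `carrier`, `n_nh3_loss`, `n_acetyl`,
#'   `theoretical_mz`, `delta_ppm`, `best` (logical, best hypothesis
#'   for that peak). Zero rows when nothing matches.
#' @export
assign_peaks <- function(peaks, candidates, tolerance_ppm = 150,
                         max_mods = 1,
                         mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  stopifnot(tolerance_ppm > 0)
  empty <- data.frame(
    peak_mz = numeric(), intensity = numeric(), candidate = character(),
    carrier = character(), n_nh3_loss = integer(), n_acetyl = integer(),
    theoretical_mz = numeric(), delta_ppm = numeric(), best = logical(),
    stringsAsFactors = FALSE
  )
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  if (is.null(candidates$neutral_mass)) {
    candidates$neutral_mass <- vapply(
      candidates$peptide, peptide_mass, numeric(1L), mode = mode
    )
  }
  hyp <- .enumerate_hypotheses(max_mods)
  theo <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(ci) {
    data.frame(
      candidate = candidates$name[ci],
      carrier = hyp$base,
      n_nh3_loss = hyp$n_nh3_loss,
      n_acetyl = hyp$n_acetyl,
      theoretical_mz = vapply(seq_len(nrow(hyp)), function(hi) {
        mz_of_species(
          candidates$neutral_mass[ci], hyp$base[hi],
          hyp$n_nh3_loss[hi], hyp$n_acetyl[hi], mode
        )
      }, numeric(1L)),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(peaks$intensity)) peaks$intensity <- NA_real_
  out <- list()
  for (pi in seq_len(nrow(peaks))) {
    dp <- ppm_delta(peaks$mz[pi], theo$theoretical_mz)
    ok <- which(abs(dp) <= tolerance_ppm)
    if (length(ok) == 0L) next
    acc <- theo[ok, , drop = FALSE]
    acc$peak_mz <- peaks$mz[pi]
    acc$intensity <- peaks$intensity[pi]
    acc$delta_ppm <- dp[ok]
    acc <- acc[order(abs(acc$delta_ppm)), , drop = FALSE]
    acc$best <- seq_len(nrow(acc)) == 1L
    out[[length(out) + 1L]] <- acc
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[, c(
    "peak_mz", "intensity", "candidate", "carrier", "n_nh3_loss",
    "n_acetyl", "theoretical_mz", "delta_ppm", "best"
  )]
  rownames(res) <- NULL
  res
}

#' Read an MS1 peak list from a two-column TSV
#'
#' @param path TSV file with columns `mz` and `intensity` (header
#'   optional).
#' @return A data.frame with numeric columns `mz`, `intensity`.
#' @export
read_ms1_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path,
    sep = "\t", header = has_header,
    stringsAsFactors = FALSE
  )
  names(df)[1:2] <- c("mz", "intensity")
  df$mz <- as.numeric(df$mz)
  df$intensity <- as.numeric(df$intensity)
  df
}
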