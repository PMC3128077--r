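#' Call transmembrane segments by windowed hydropathy
#'
#' Slides a window of `window` residues along the peptide, computes the
#' mean Kyte-Doolittle hydropathy of each window, and merges maximal
#' runs of windows at or above `threshold` into candidate
#' membrane-spanning segments. A segment spans the union of the
#' residues covered by its above-threshold windows; overlapping
#' segments are merged; segments shorter than `min_segment` residues
#' are dropped.
#'
#' @param peptide Amino-acid string. Non-standard residues (e.g. `X`)
#'   score 0 with a warning.
#' @param window Window length in residues (default 19, the canonical
#'   single-helix span).
#' @param threshold Mean-hydropathy call threshold (default 1.6,
#'   dimensionless Kyte-Doolittle units).
#' @param min_segment Minimum merged segment length in residues
#'   (default 15).
#'
#' @return A data.frame with columns `start_aa`, `end_aa` (1-based
#'   inclusive residue indices) and `mean_hydropathy` (mean of the
#'   segment's above-threshold window means, hence always at or above
#'   `threshold`), sorted by `start_aa`; zero rows when nothing is
#'   called.
#' @examples
#' call_tm_segments(paste0(strrep("E", 10), strrep("L", 19), strrep("E", 10)))
#' @export
call_tm_segments <- function(peptide, window = 19, threshold = 1.6,
                             min_segment = 15) {
  peptide <- toupper(as.character(peptide))
  n <- nchar(peptide)
  empty <- data.frame(
    start_aa = integer(), end_aa = integer(),
    mean_hydropathy = numeric(), stringsAsFactors = FALSE
  )
  if (n < window) {
    message("peptide shorter than the ", window, "-residue window")
    return(empty)
  }
  aa <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  h <- unname(.KD_SCALE[aa])
  if (anyNA(h)) {
    warning(
      "non-standard residue(s) scored as hydropathy 0: ",
      paste(unique(aa[is.na(h)]), collapse = ", ")
    )
    h[is.na(h)] <- 0
  }
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  above <- means >= threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(
    start_aa = starts[r$values],
    end_aa = ends[r$values] + window - 1L
  )
  # merge segments whose residue spans overlap
  merged <- seg[1L, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (i in 2L:nrow(seg)) {
      last <- nrow(merged)
      if (seg$start_aa[i] <= merged$end_aa[last]) {
        merged$end_aa[last] <- max(merged$end_aa[last], seg$end_aa[i])
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  merged <- merged[merged$end_aa - merged$start_aa + 1L >= min_segment, ,
    drop = FALSE
  ]
  if (nrow(merged) == 0L) return(empty)
  # segment hydropathy = mean over its above-threshold windows, so the
  # reported value is itself >= threshold
  win_start <- seq_len(n - window + 1L)
  merged$mean_hydropathy <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- above & win_start >= merged$start_aa[i] &
      win_start + window - 1L <= merged$end_aa[i]
    mean(means[inside])
  }, numeric(1L))
  rownames(merged) <- NULL
  merged
}

#' Apply the subunit-IIa candidacy filter
#'
#' A candidate micro-ORF qualifies as a putative subunit IIa when its
#' peptide carries exactly one predicted transmembrane segment and its
#' length lies within `[min_aa, max_aa]` residues.
#'
#' @param orf Either an amino-acid string or a one-row data.frame/list
#'   with a `peptide` field (as produced by [scan_small_orfs()]).
#' @param min_aa,max_aa Accepted peptide length range (defaults 25 and
#'   100).
#' @param ... Passed on to [call_tm_segments()].
#'
#' @return A list with `is_candidate` (logical), `reason` (character;
#'   `"ok"` when accepted) and `n_tm` (number of called segments).
#' @examples
#' pep <- paste0("MNEKH", strrep("L", 20), strrep("E", 16))
#' is_candidate_iia(pep)
#' @export
is_candidate_iia <- function(orf, min_aa = 25, max_aa = 100, ...) {
  peptide <- if (is.character(orf) && length(orf) == 1L) {
    orf
  } else {
    as.character(orf$peptide[1L])
  }
  len <- nchar(peptide)
  segs <- suppressMessages(call_tm_segments(peptide, ...))
  n_tm <- nrow(segs)
  if (len < min_aa || len > max_aa) {
    return(list(
      is_candidate = FALSE,
      reason = sprintf("length outside [%d,%d]", min_aa, max_aa),
      n_tm = n_tm
    ))
  }
  if (n_tm == 0L) {
    return(list(
      is_candidate = FALSE, reason = "no transmembrane segment", n_tm = 0L
    ))
  }
  if (n_tm > 1L) {
    return(list(
      is_candidate = FALSE, reason = "multiple transmembrane segments",
      n_tm = n_tm
    ))
  }
  list(is_candidate = TRUE, reason = "ok", n_tm = 1L)
}
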