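#' Locate the upstream search window of an anchor gene
#'
#' Returns the region of up to `window` nucleotides immediately 5' of
#' the anchor gene's start codon, on the anchor's strand. The window is
#' truncated at the genome edge and, optionally, at the nearest
#' annotated gene on the same strand.
#'
#' @param anchor A one-row data.frame (or list) with fields `start`,
#'   `end`, `strand` (and optionally `genome_id`).
#' @param genome The genome sequence the anchor lies on (character,
#'   DNAString, or 1-element DNAStringSet); only its length is used.
#' @param window Maximum window size in nt (default 750, sized to the
#'   intergenic regions where subunit-IIa genes sit).
#' @param annotations Optional annotation data.frame; when given, the
#'   window is truncated at the nearest same-strand gene upstream of the
#'   anchor.
#'
#' @return A list with `start`, `end` (1-based inclusive, forward
#'   coordinates) and `strand`.
#' @examples
#' anchor <- data.frame(start = 1001, end = 1600, strand = "+")
#' upstream_window(anchor, strrep("A", 2000), window = 500)
#' @export
upstream_window <- function(anchor, genome, window = 750, annotations = NULL) {
  stopifnot(window > 0)
  glen <- nchar(.as_dna_string(genome))
  strand <- as.character(anchor$strand)
  if (strand == "+") {
    end <- anchor$start - 1L
    start <- max(1L, anchor$start - as.integer(window))
    if (!is.null(annotations)) {
      same <- annotations[annotations$strand == strand &
        annotations$end < anchor$start, , drop = FALSE]
      same <- same[!(same$start == anchor$start & same$end == anchor$end), ,
        drop = FALSE
      ]
      if (nrow(same) > 0L) start <- max(start, max(same$end) + 1L)
    }
  } else if (strand == "-") {
    start <- anchor$end + 1L
    end <- min(glen, anchor$end + as.integer(window))
    if (!is.null(annotations)) {
      same <- annotations[annotations$strand == strand &
        annotations$start > anchor$end, , drop = FALSE]
      if (nrow(same) > 0L) end <- min(end, min(same$start) - 1L)
    }
  } else {
    stop("anchor strand must be '+' or '-'")
  }
  if (end < start || end < 1L || start > glen) {
    stop("empty upstream window: no sequence 5' of the anchor gene")
  }
  list(start = as.integer(start), end = as.integer(end), strand = strand)
}

.stop_codons <- function(table = "11") {
  code <- Biostrings::getGeneticCode(table)
  names(code)[code == "*"]
}

#' Scan a region for small open reading frames
#'
#' Finds every ORF on the given strand of `region` (all three frames)
#' that begins with an allowed start codon, ends at an in-frame stop
#' codon (or at the window edge, flagged `open_ended`), and whose
#' peptide length falls in `[min_aa, max_aa]`. Coordinates returned are
#' 1-based within `region`; `end` includes the stop codon when present.
#'
#' @param region A DNA character string, already oriented in reading
#'   direction (callers hand in the reverse complement for `-` strand
#'   searches).
#' @param min_aa,max_aa Peptide length bounds in residues (defaults 25
#'   and 100, covering the 34-78 aa range of known subunit IIa genes).
#' @param starts Allowed start codons (default `ATG`, `GTG`, `TTG`).
#' @param all_starts Keep every start for a shared stop codon instead
#'   of only the longest ORF (default `FALSE`).
#' @param include_open_ended Also return ORFs running off the window
#'   edge without a stop codon (default `FALSE`).
#' @param table NCBI genetic-code table (default `"11"`).
#'
#' @return A data.frame with columns `start`, `end`, `frame` (0,1,2),
#'   `length_aa`, `peptide`, `open_ended`, sorted by `start`.
#' @examples
#' region <- paste0(strrep("C", 10), "ATG", strrep("GCT", 30), "TAA",
#'                  strrep("C", 10))
#' scan_small_orfs(region, min_aa = 25)
#' @export
scan_small_orfs <- function(region, min_aa = 25, max_aa = 100,
                            starts = c("ATG", "GTG", "TTG"),
                            all_starts = FALSE,
                            include_open_ended = FALSE,
                            table = "11") {
  stopifnot(min_aa <= max_aa, min_aa >= 1)
  region <- toupper(as.character(region))
  n <- nchar(region)
  empty <- data.frame(
    start = integer(), end = integer(), frame = integer(),
    length_aa = integer(), peptide = character(),
    open_ended = logical(), stringsAsFactors = FALSE
  )
  if (n < 3L * min_aa) {
    message("region shorter than ", 3L * min_aa, " nt; no ORFs possible")
    return(empty)
  }
  stops <- .stop_codons(table)
  code <- Biostrings::getGeneticCode(table)
  out <- list()
  for (frame in 0:2) {
    n_codon <- (n - frame) %/% 3L
    if (n_codon < 2L) next
    pos <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
    codons <- substring(region, pos, pos + 2L)
    start_idx <- which(codons %in% starts)
    stop_idx <- which(codons %in% stops)
    if (length(start_idx) == 0L) next
    # index of the first stop codon strictly after each start
    nxt <- if (length(stop_idx)) {
      stop_idx[findInterval(start_idx, stop_idx) + 1L]
    } else {
      rep(NA_integer_, length(start_idx))
    }
    for (k in seq_along(start_idx)) {
      i <- start_idx[k]
      j <- nxt[k]
      open_ended <- is.na(j)
      len_aa <- if (open_ended) n_codon - i + 1L else j - i
      if (len_aa < min_aa || len_aa > max_aa) next
      if (open_ended && !include_open_ended) next
      end_codon <- if (open_ended) n_codon else j
      pep <- paste(unname(code[codons[i:(i + len_aa - 1L)]]), collapse = "")
      out[[length(out) + 1L]] <- data.frame(
        start = pos[i], end = pos[end_codon] + 2L, frame = frame,
        length_aa = len_aa, peptide = pep, open_ended = open_ended,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  if (!all_starts) {
    # ORFs sharing a stop (same frame, same end) keep only the longest
    grp <- paste(res$frame, res$end)
    keep <- unlist(lapply(split(seq_len(nrow(res)), grp), function(ix) {
      ix[which.min(res$start[ix])]
    }), use.names = FALSE)
    res <- res[keep, , drop = FALSE]
  }
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# closed ORFs only: open-ended stretches (no stop before the region
# edge) would make the gain score depend on where the window was cut
.all_orfs <- function(region, starts, table) {
  suppressMessages(scan_small_orfs(region,
    min_aa = 2, max_aa = .Machine$integer.max %/% 4L,
    starts = starts, all_starts = FALSE,
    include_open_ended = FALSE, table = table
  ))
}

# Length (nt) of the longest ORF in an ORF table whose span covers
# position `pos`.
.longest_covering <- function(orfs, pos) {
  if (nrow(orfs) == 0L) return(0L)
  cover <- orfs$start <= pos & orfs$end >= pos
  if (!any(cover)) return(0L)
  max(orfs$end[cover] - orfs$start[cover] + 1L)
}

.homopolymer_runs <- function(region) {
  r <- rle(strsplit(region, "", fixed = TRUE)[[1L]])
  ends <- cumsum(r$lengths)
  data.frame(
    base = r$values, start = ends - r$lengths + 1L, end = ends,
    stringsAsFactors = FALSE
  )
}

#' Detect frame-disrupting single-nucleotide indels
#'
#' Tests, for every homopolymer run in `region`, whether deleting one
#' base (and optionally inserting one) would fuse a substantially
#' longer open reading frame across the site — the signature of a
#' single-nucleotide sequencing error splitting a gene. Within a
#' homopolymer run all single-base indels are indistinguishable, so
#' each run yields at most one call.
#'
#' Calls from adjacent runs that restore an ORF of identical length
#' with identical score are likewise indistinguishable (the re-read
#' stretch between them contains no stop codon) and are merged into a
#' single call spanning those runs.
#'
#' @param region A DNA character string of at least 60 nt.
#' @param min_gain_aa Minimum ORF length gain, in residues, for a call
#'   to be reported (default 20; the gain is measured in nt as
#'   `3 * min_gain_aa`).
#' @param edits `"deletion"` (default) tests single-base deletions —
#'   the correction for an insertion error in the reported sequence;
#'   `"both"` additionally tests single-base insertions.
#' @param starts,table As in [scan_small_orfs()].
#'
#' @return A data.frame of calls ranked by `score` (nt gained)
#'   descending, ties broken leftmost: columns `position` (first base
#'   of the homopolymer run), `run_start`, `run_end`, `edit`, `score`,
#'   `fused_length_aa`, `fused_peptide`.
#' @export
detect_frameshift <- function(region, min_gain_aa = 20,
                              edits = c("deletion", "both"),
                              starts = c("ATG", "GTG", "TTG"),
                              table = "11") {
  edits <- match.arg(edits)
  region <- toupper(as.character(region))
  n <- nchar(region)
  if (n < 60L) stop("region must be at least 60 nt")
  runs <- .homopolymer_runs(region)
  min_gain_nt <- 3L * min_gain_aa
  orig_orfs <- .all_orfs(region, starts, table)

  calls <- list()
  eval_edit <- function(edited, pos_edited, run, edit_label) {
    orfs <- .all_orfs(edited, starts, table)
    cover <- orfs[orfs$start <= pos_edited & orfs$end >= pos_edited, ,
      drop = FALSE
    ]
    if (nrow(cover) == 0L) return(NULL)
    best <- cover[which.max(cover$end - cover$start), , drop = FALSE]
    after <- best$end - best$start + 1L
    # gain for the gene model that begins at the fused ORF's start
    # codon: the edit extends that reading frame across the break, so
    # the baseline is the original ORF sharing the same start (the
    # 5' partial). When the start itself is new, fall back to the
    # longest original ORF covering that position.
    same_start <- orig_orfs$start == best$start
    before <- if (any(same_start)) {
      max(orig_orfs$end[same_start] - orig_orfs$start[same_start] + 1L)
    } else {
      .longest_covering(orig_orfs, best$start)
    }
    score <- after - before
    if (score >= min_gain_nt) {
      pep <- sub("\\*$", "", best$peptide)
      data.frame(
        position = run$start, run_start = run$start, run_end = run$end,
        edit = edit_label, score = score,
        fused_length_aa = nchar(pep), fused_peptide = pep,
        stringsAsFactors = FALSE
      )
    } else {
      NULL
    }
  }

  for (ri in seq_len(nrow(runs))) {
    run <- runs[ri, ]
    # deletion of one base of this run
    edited <- paste0(
      substr(region, 1L, run$start - 1L),
      substr(region, run$start + 1L, n)
    )
    calls[[length(calls) + 1L]] <-
      eval_edit(edited, max(1L, run$start - 1L), run, "delete_1")
    if (edits == "both") {
      for (base in c("A", "C", "G", "T")) {
        # inserting `base` just before the run; inserting the run's own
        # base anywhere inside the run gives the same edited sequence
        edited_i <- paste0(
          substr(region, 1L, run$start - 1L), base,
          substr(region, run$start, n)
        )
        calls[[length(calls) + 1L]] <-
          eval_edit(edited_i, run$start, run, paste0("insert_1:", base))
      }
    }
  }
  calls <- calls[!vapply(calls, is.null, logical(1L))]
  if (length(calls) == 0L) {
    return(data.frame(
      position = integer(), run_start = integer(), run_end = integer(),
      edit = character(), score = integer(), fused_length_aa = integer(),
      fused_peptide = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, calls)
  res <- res[order(res$position), , drop = FALSE]
  # merge immediately adjacent runs whose edits are indistinguishable
  # (same edit type, same score, same restored ORF length)
  keep <- res[1L, , drop = FALSE]
  if (nrow(res) > 1L) {
    for (i in 2L:nrow(res)) {
      last <- nrow(keep)
      if (res$run_start[i] == keep$run_end[last] + 1L &&
        res$edit[i] == keep$edit[last] &&
        res$score[i] == keep$score[last] &&
        res$fused_length_aa[i] == keep$fused_length_aa[last]) {
        keep$run_end[last] <- res$run_end[i]
      } else {
        keep <- rbind(keep, res[i, ])
      }
    }
  }
  keep <- keep[order(-keep$score, keep$position), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
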