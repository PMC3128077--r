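#' Scan a peptide for the conserved subunit-IIa motif
#'
#' Finds every non-overlapping occurrence of the pattern
#' `P X(1-3) G [TA]` — a proline, one to three arbitrary residues, a
#' glycine, then threonine or alanine — with leftmost-shortest match
#' preference. Also reports whether the peptide carries the conserved
#' tryptophan seen across subunit-IIa sequences.
#'
#' @param peptide Amino-acid string.
#' @return A list with `hits` (data.frame: `position` of the motif's
#'   proline, 1-based; `matched_text`; `pattern`) and `has_trp`
#'   (logical: any `W` in the peptide).
#' @examples
#' scan_motif("MNEKHPAAGTW")
#' @export
scan_motif <- function(peptide) {
  peptide <- toupper(as.character(peptide))
  pattern <- "P.{1,3}?G[TA]"
  m <- gregexpr(pattern, peptide, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    hits <- data.frame(
      position = integer(), matched_text = character(),
      pattern = character(), stringsAsFactors = FALSE
    )
  } else {
    hits <- data.frame(
      position = as.integer(m),
      matched_text = substring(
        peptide, m, m + attr(m, "match.length") - 1L
      ),
      pattern = "PX(1,3)G[TA]",
      stringsAsFactors = FALSE
    )
  }
  list(hits = hits, has_trp = grepl("W", peptide, fixed = TRUE))
}

#' Pairwise global alignment identity and similarity
#'
#' Aligns two peptides globally (Needleman-Wunsch, BLOSUM62, affine
#' gaps) and summarizes the alignment as percent identity and percent
#' similarity. Identity counts columns with identical residues;
#' similarity additionally counts columns whose residue pair falls in
#' one of the ClustalW strong conservation groups (STA, NEQK, NHQK,
#' NDEQ, QHRK, MILV, MILF, HY, FYW). Both percentages use the full
#' alignment length (gap columns included) as denominator.
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (positive costs;
#'   defaults 10 and 0.5).
#'
#' @return A list: `identity_pct`, `similarity_pct`, `aligned_length`,
#'   `gaps` (number of gap columns), `score` (alignment score),
#'   `aligned_a`, `aligned_b` (gapped strings).
#' @examples
#' pairwise_identity_similarity("MNEKH", "MNEKH")$identity_pct
#' @export
pairwise_identity_similarity <- function(a, b, gap_open = 10,
                                         gap_extend = 0.5) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("both sequences must be non-empty")
  }
  blosum <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = blosum,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  xa <- as.character(Biostrings::alignedPattern(pa))
  xb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(xa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(xb, "", fixed = TRUE)[[1L]]
  len <- length(ca)
  gap_col <- ca == "-" | cb == "-"
  ident <- !gap_col & ca == cb
  strong <- !gap_col & !ident &
    vapply(seq_len(len), function(i) {
      any(vapply(.STRONG_GROUPS, function(g) {
        grepl(ca[i], g, fixed = TRUE) && grepl(cb[i], g, fixed = TRUE)
      }, logical(1L)))
    }, logical(1L))
  list(
    identity_pct = 100 * sum(ident) / len,
    similarity_pct = 100 * (sum(ident) + sum(strong)) / len,
    aligned_length = len,
    gaps = sum(gap_col),
    score = Biostrings::score(pa),
    aligned_a = xa,
    aligned_b = xb
  )
}

.blosum_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$BLOSUM62 <- e$BLOSUM62
  }
  .blosum_cache$BLOSUM62
}
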