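# Independent oracles, deliberately coded on different principles than
# the package implementation.

# --- brute-force ORF enumeration ------------------------------------
# Walks every position; at each allowed start codon, reads codon by
# codon to the first stop. Longest-per-stop dedup done by (frame, end).
oracle_scan_orfs <- function(region, min_aa, max_aa,
                             starts = c("ATG", "GTG", "TTG"),
                             stops = c("TAA", "TAG", "TGA")) {
  region <- toupper(region)
  n <- nchar(region)
  found <- list()
  for (p in seq_len(max(0L, n - 2L))) {
    if (!substr(region, p, p + 2L) %in% starts) next
    q <- p + 3L
    stop_at <- NA_integer_
    while (q + 2L <= n) {
      if (substr(region, q, q + 2L) %in% stops) {
        stop_at <- q
        break
      }
      q <- q + 3L
    }
    if (is.na(stop_at)) next # open-ended: excluded by default
    len_aa <- (stop_at - p) %/% 3L
    if (len_aa < min_aa || len_aa > max_aa) next
    found[[length(found) + 1L]] <- data.frame(
      start = p, end = stop_at + 2L, frame = (p - 1L) %% 3L,
      length_aa = len_aa
    )
  }
  if (length(found) == 0L) {
    return(data.frame(
      start = integer(), end = integer(), frame = integer(),
      length_aa = integer()
    ))
  }
  df <- do.call(rbind, found)
  keep <- unlist(lapply(split(seq_len(nrow(df)), paste(df$frame, df$end)),
    function(ix) ix[which.min(df$start[ix])]
  ), use.names = FALSE)
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- elemental-composition mass oracle ------------------------------
# Free-amino-acid molecular formulas; a peptide of n residues is the
# sum of its free amino acids minus (n - 1) waters.
.oracle_free_aa <- c(
  G = "C2H5N1O2", A = "C3H7N1O2", S = "C3H7N1O3", P = "C5H9N1O2",
  V = "C5H11N1O2", T = "C4H9N1O3", C = "C3H7N1O2S1", L = "C6H13N1O2",
  I = "C6H13N1O2", N = "C4H8N2O3", D = "C4H7N1O4", Q = "C5H10N2O3",
  K = "C6H14N2O2", E = "C5H9N1O4", M = "C5H11N1O2S1", H = "C6H9N3O2",
  F = "C9H11N1O2", R = "C6H14N4O2", Y = "C9H11N1O3", W = "C11H12N2O2"
)

.oracle_elem <- list(
  monoisotopic = c(C = 12, H = 1.00782503, N = 14.0030740,
                   O = 15.9949146, S = 31.9720707),
  average = c(C = 12.0107, H = 1.00794, N = 14.0067,
              O = 15.9994, S = 32.065)
)

.oracle_formula_mass <- function(formula, mode) {
  m <- gregexpr("([A-Z])([0-9]+)", formula)[[1L]]
  parts <- regmatches(formula, gregexpr("([A-Z])([0-9]+)", formula))[[1L]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1L, 1L)
    cnt <- as.numeric(substr(p, 2L, nchar(p)))
    total <- total + cnt * .oracle_elem[[mode]][[el]]
  }
  total
}

oracle_peptide_mass <- function(peptide, mode = "monoisotopic") {
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  n <- length(aa)
  water <- .oracle_formula_mass("H2O1", mode)
  sum(vapply(.oracle_free_aa[aa], .oracle_formula_mass, numeric(1L),
    mode = mode
  )) - (n - 1L) * water
}

# --- brute-force global alignment score -----------------------------
# Enumerates every global alignment of two short strings and scores it
# with BLOSUM62 + affine gaps (gap of length L costs open + L * ext).
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  blosum <- iiascout:::.blosum62()
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  score_alignment <- function(cols_a, cols_b) {
    s <- 0
    for (k in seq_along(cols_a)) {
      if (cols_a[k] != "-" && cols_b[k] != "-") {
        s <- s + blosum[cols_a[k], cols_b[k]]
      }
    }
    gap_cost <- function(cols) {
      r <- rle(cols == "-")
      sum(gap_open + gap_extend * r$lengths[r$values])
    }
    s - gap_cost(cols_a) - gap_cost(cols_b)
  }
  recurse <- function(i, j, ca, cb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_alignment(ca, cb))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1L, j + 1L, c(ca, av[i]), c(cb, bv[j]))
    }
    if (i <= length(av)) recurse(i + 1L, j, c(ca, av[i]), c(cb, "-"))
    if (j <= length(bv)) recurse(i, j + 1L, c(ca, "-"), c(cb, bv[j]))
  }
  recurse(1L, 1L, character(0), character(0))
  best
}

# --- misc helpers ---------------------------------------------------
random_peptide <- function(len) {
  paste(sample(rownames(iiascout:::.residue_formula), len, replace = TRUE),
    collapse = ""
  )
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
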