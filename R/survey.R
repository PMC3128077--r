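#' Survey one genome for a subunit-IIa gene upstream of its anchor
#'
#' Implements the per-genome decision procedure of the cross-genome
#' survey: compute transmembrane count and theoretical mass of the
#' anchor (subunit II) protein; if an annotated small gene sits in the
#' window directly upstream of the anchor and passes the subunit-IIa
#' candidacy filter, record it as `annotated`; otherwise scan the
#' upstream window for unannotated micro-ORFs and record a passing one
#' as `detected_unannotated`; otherwise `absent`.
#'
#' @param genome Genome sequence (character, DNAString or 1-element
#'   DNAStringSet).
#' @param annotations Annotation data.frame as returned by
#'   [load_annotated_genome()].
#' @param anchor_id `gene_id` of the subunit-II anchor gene.
#' @param organism Organism label for the report row.
#' @param sub2_accession Optional accession string for the anchor.
#' @param window Upstream window in nt (default 750).
#' @param min_aa,max_aa Candidate peptide length range (defaults 25,
#'   100).
#' @param starts Allowed start codons for the micro-ORF scan.
#' @param table Genetic-code table.
#' @param verbose Log one line per decision (default `FALSE`).
#'
#' @return A one-row data.frame with columns `organism`,
#'   `sub2_accession`, `sub2_tm`, `sub2_mm`, `iia_status`,
#'   `iia_accession`, `iia_tm`, `iia_mm`, `iia_start`, `iia_end`,
#'   `iia_peptide`.
#' @export
survey_genome <- function(genome, annotations, anchor_id,
                          organism = "unknown",
                          sub2_accession = NA_character_,
                          window = 750, min_aa = 25, max_aa = 100,
                          starts = c("ATG", "GTG", "TTG"),
                          table = "11", verbose = FALSE) {
  log1 <- function(...) if (verbose) message("[survey] ", sprintf(...))
  anchor <- annotations[annotations$gene_id == anchor_id, , drop = FALSE]
  if (nrow(anchor) != 1L) {
    stop("anchor gene '", anchor_id, "' not found (or not unique)")
  }
  gseq <- .as_dna_string(genome)

  anchor_pep <- .gene_peptide(gseq, anchor, table)
  sub2_tm <- nrow(suppressMessages(call_tm_segments(anchor_pep)))
  sub2_mm <- peptide_mass(anchor_pep, mode = "average")
  log1("anchor %s: %d aa, %d TM segment(s)", anchor_id,
       nchar(anchor_pep), sub2_tm)

  win <- upstream_window(anchor, gseq, window = window,
                         annotations = annotations)
  log1("upstream window %d-%d (%s)", win$start, win$end, win$strand)

  row <- data.frame(
    organism = organism, sub2_accession = sub2_accession,
    sub2_tm = sub2_tm, sub2_mm = sub2_mm,
    iia_status = "absent", iia_accession = NA_character_,
    iia_tm = NA_integer_, iia_mm = NA_real_,
    iia_start = NA_integer_, iia_end = NA_integer_,
    iia_peptide = NA_character_, stringsAsFactors = FALSE
  )

  # 1. an annotated small gene directly upstream, on the anchor strand
  upstream <- annotations[
    annotations$gene_id != anchor_id &
      annotations$strand == anchor$strand &
      annotations$genome_id == anchor$genome_id &
      annotations$start <= win$end + 1L & annotations$end >= win$start - 1L, ,
    drop = FALSE
  ]
  for (gi in order(-upstream$end)) {
    g <- upstream[gi, , drop = FALSE]
    pep <- .gene_peptide(gseq, g, table)
    verdict <- is_candidate_iia(pep, min_aa = min_aa, max_aa = max_aa)
    log1("annotated upstream gene %s: %s", g$gene_id, verdict$reason)
    if (verdict$is_candidate) {
      row$iia_status <- "annotated"
      row$iia_accession <- g$gene_id
      row$iia_tm <- 1L
      row$iia_mm <- peptide_mass(pep, mode = "average")
      row$iia_start <- g$start
      row$iia_end <- g$end
      row$iia_peptide <- pep
      return(row)
    }
  }

  # 2. scan the window for unannotated micro-ORFs
  region <- extract_subsequence(gseq, win$start, win$end, win$strand)
  orfs <- suppressMessages(scan_small_orfs(region,
    min_aa = min_aa, max_aa = max_aa, starts = starts, table = table
  ))
  log1("scan found %d ORF(s) in window", nrow(orfs))
  if (nrow(orfs) > 0L) {
    verdicts <- lapply(orfs$peptide, is_candidate_iia,
      min_aa = min_aa, max_aa = max_aa
    )
    pass <- vapply(verdicts, `[[`, logical(1L), "is_candidate")
    orfs <- orfs[pass, , drop = FALSE]
  }
  if (nrow(orfs) > 0L) {
    # nearest the anchor = largest region-coordinate end on either strand
    best <- orfs[order(-orfs$end, -orfs$length_aa), , drop = FALSE][1L, ]
    coords <- .region_to_genomic(best$start, best$end, win)
    pep <- sub("\\*$", "", best$peptide)
    row$iia_status <- "detected_unannotated"
    row$iia_tm <- 1L
    row$iia_mm <- peptide_mass(pep, mode = "average")
    row$iia_start <- coords[1L]
    row$iia_end <- coords[2L]
    row$iia_peptide <- pep
    log1("detected unannotated candidate at %d-%d", coords[1L], coords[2L])
  } else {
    log1("no candidate passed the filter; status absent")
  }
  row
}

# translate an annotated gene into its peptide (stop trimmed)
.gene_peptide <- function(gseq, gene, table = "11") {
  dna <- extract_subsequence(gseq, gene$start, gene$end, gene$strand)
  usable <- 3L * (nchar(dna) %/% 3L)
  pep <- translate_dna(substr(dna, 1L, usable), table = table)
  sub("\\*.*$", "", pep)
}

# map region-local (reading-direction) coordinates back to the genome
.region_to_genomic <- function(rstart, rend, win) {
  if (win$strand == "+") {
    c(win$start + rstart - 1L, win$start + rend - 1L)
  } else {
    c(win$end - rend + 1L, win$end - rstart + 1L)
  }
}

#' Tabulate survey rows and summarize counts
#'
#' @param rows A data.frame of survey rows ([survey_genome()] output,
#'   row-bound), or the fixture rows from [read_survey_table()].
#' @param path Optional TSV output path for the report table.
#'
#' @return A list: `table` — the rows in report column order —
#'   and `summary`, a list with `n_regions`, `n_annotated_iia`,
#'   `n_detected_iia`, `n_absent` (which partition `n_regions`).
#' @export
tabulate_survey <- function(rows, path = NULL) {
  cols <- c(
    "organism", "sub2_accession", "sub2_tm", "sub2_mm",
    "iia_status", "iia_accession", "iia_tm", "iia_mm"
  )
  if (nrow(rows) == 0L) {
    tab <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(cols)), cols)
    )
    summary <- list(
      n_regions = 0L, n_annotated_iia = 0L, n_detected_iia = 0L,
      n_absent = 0L
    )
  } else {
    missing_cols <- setdiff(cols, names(rows))
    for (mc in missing_cols) rows[[mc]] <- NA
    tab <- rows[, cols, drop = FALSE]
    summary <- list(
      n_regions = nrow(tab),
      n_annotated_iia = sum(tab$iia_status == "annotated"),
      n_detected_iia = sum(tab$iia_status == "detected_unannotated"),
      n_absent = sum(tab$iia_status == "absent")
    )
  }
  stopifnot(
    summary$n_regions ==
      summary$n_annotated_iia + summary$n_detected_iia + summary$n_absent
  )
  if (!is.null(path)) write_report(tab, path, "tsv")
  list(table = tab, summary = summary)
}

#' Read a packaged survey table
#'
#' Reads the transcription of the published cross-genome survey table
#' shipped with the package (36 B-family oxidase gene regions). The
#' `iia_accession` column encodes the subunit-IIa status: an accession
#' string (`annotated`), `Not annotated` (an ORF detected in this work,
#' `detected_unannotated`), or `Absent`.
#'
#' @param path Path to the TSV; defaults to the packaged fixture.
#' @return A data.frame in [tabulate_survey()] row format.
#' @examples
#' rows <- read_survey_table()
#' tabulate_survey(rows)$summary
#' @export
read_survey_table <- function(path = system.file("extdata",
                                                 "table1_survey.tsv",
                                                 package = "iiascout")) {
  raw <- utils::read.table(path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    quote = "", comment.char = ""
  )
  status <- ifelse(raw$iia_accession == "Absent", "absent",
    ifelse(raw$iia_accession == "Not annotated",
      "detected_unannotated", "annotated"
    )
  )
  data.frame(
    organism = raw$organism,
    sub2_accession = raw$sub2_accession,
    sub2_tm = as.integer(raw$sub2_tm),
    sub2_mm = as.numeric(raw$sub2_mm),
    iia_status = status,
    iia_accession = ifelse(status == "annotated", raw$iia_accession,
      NA_character_
    ),
    iia_tm = suppressWarnings(as.integer(raw$iia_tm)),
    iia_mm = suppressWarnings(as.numeric(raw$iia_mm)),
    stringsAsFactors = FALSE
  )
}
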