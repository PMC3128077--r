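#' Load an annotated genome from FASTA + GFF3
#'
#' Reads a (multi-record) genome FASTA and a GFF3 file, keeps `gene`
#' features, validates coordinates against the genome, and returns both.
#' All coordinates are 1-based inclusive on the forward strand (GFF3
#' convention).
#'
#' @param fasta_path Path to a FASTA file of genome sequences.
#' @param gff_path Path to a GFF3 file; only features of type `gene`
#'   (or `CDS` when no `gene` rows exist) are kept. Gene identifiers are
#'   taken from the `ID` attribute.
#' @param anchor_ids Character vector of gene IDs to flag with role
#'   `anchor_subunit_II`; all other genes get role `other`.
#'
#' @return A list with components `genomes` (a named
#'   [Biostrings::DNAStringSet]) and `annotations` (a data.frame with
#'   columns `gene_id`, `genome_id`, `start`, `end`, `strand`, `role`).
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(">g1", strrep("ACGT", 150)), fa)
#' writeLines(c("##gff-version 3",
#'   "g1\ttest\tgene\t101\t400\t.\t+\t.\tID=geneA"), gff)
#' ag <- load_annotated_genome(fa, gff)
#' ag$annotations
#' @export
load_annotated_genome <- function(fasta_path, gff_path, anchor_ids = character()) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF file not found: ", gff_path)
  genomes <- Biostrings::readDNAStringSet(fasta_path)
  names(genomes) <- sub("\\s.*$", "", names(genomes))

  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0L) {
    warning("GFF contains no features: ", gff_path)
    ann <- data.frame(
      gene_id = character(), genome_id = character(),
      start = integer(), end = integer(), strand = character(),
      role = character(), stringsAsFactors = FALSE
    )
    return(list(genomes = genomes, annotations = ann))
  }
  types <- as.character(gr$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  gr <- gr[keep]

  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("gene_", seq_len(sum(is.na(ids))))
  ann <- data.frame(
    gene_id = as.character(ids),
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$role <- ifelse(ann$gene_id %in% anchor_ids, "anchor_subunit_II", "other")

  unresolved <- setdiff(unique(ann$genome_id), names(genomes))
  if (length(unresolved) > 0L) {
    stop(
      "GFF seqids not present in FASTA: ",
      paste(unresolved, collapse = ", ")
    )
  }
  glen <- Biostrings::width(genomes)[match(ann$genome_id, names(genomes))]
  bad <- ann$start < 1L | ann$end > glen | ann$start > ann$end
  if (any(bad)) {
    stop(
      "annotation outside genome bounds: ",
      paste(ann$gene_id[bad], collapse = ", ")
    )
  }
  if (nrow(ann) == 0L) warning("no gene annotations found in ", gff_path)
  list(genomes = genomes, annotations = ann)
}

#' Translate a DNA sequence codon by codon
#'
#' Translation under a chosen NCBI genetic-code table (default 11,
#' bacterial/archaeal). Stop codons render as `*` and translation
#' continues past them (the caller decides about truncation). Any codon
#' containing `N` translates to `X`.
#'
#' @param dna A DNA string over `A,C,G,T,N`; length must be a multiple
#'   of 3.
#' @param table NCBI genetic-code table identifier (character), default
#'   `"11"`.
#'
#' @return A single amino-acid string, possibly containing `*` and `X`.
#'
#' @examples
#' translate_dna("ATGAAA")  # "MK"
#' translate_dna("ATGTAA")  # "M*"
#' @export
translate_dna <- function(dna, table = "11") {
  dna <- toupper(as.character(dna))
  n <- nchar(dna)
  if (n == 0L) return("")
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not divisible by 3")
  }
  if (grepl("[^ACGTN]", dna)) {
    stop("sequence contains symbols outside {A,C,G,T,N}")
  }
  code <- Biostrings::getGeneticCode(table)
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  paste(aa, collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param dna A DNA string over `A,C,G,T,N`.
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("ACG")  # "CGT"
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Extract a genomic subsequence
#'
#' Returns the forward-strand slice for `strand = "+"`, or its reverse
#' complement for `strand = "-"`. Coordinates are 1-based inclusive.
#'
#' @param genome A genome sequence: a character string, a
#'   [Biostrings::DNAString], or a single-element DNAStringSet.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end
#'   <= length(genome)`.
#' @param strand `"+"` or `"-"`.
#'
#' @return A DNA character string of length `end - start + 1`.
#' @examples
#' extract_subsequence("AACGT", 2, 4, "+")  # "ACG"
#' extract_subsequence("AACGT", 2, 4, "-")  # "CGT"
#' @export
extract_subsequence <- function(genome, start, end, strand = "+") {
  seqstr <- toupper(.as_dna_string(genome))
  n <- nchar(seqstr)
  if (start < 1L || end > n || start > end) {
    stop(
      "coordinates out of bounds: [", start, ", ", end,
      "] on a ", n, "-nt sequence (1-based inclusive)"
    )
  }
  out <- substr(seqstr, start, end)
  if (identical(strand, "-")) out <- reverse_complement(out)
  out
}

.as_dna_string <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(as.character(x[[1L]]))
  }
  as.character(x)
}

#' Write a candidate report
#'
#' Writes a data.frame of ORF candidates (or any tabular report) as TSV
#' or JSON.
#'
#' @param x A data.frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
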