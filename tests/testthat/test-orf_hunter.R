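test_that("upstream window arithmetic handles both strands and edges", {
  g <- strrep("A", 2000)
  win <- upstream_window(
    data.frame(start = 1001, end = 1600, strand = "+"), g, window = 500
  )
  expect_equal(win[c("start", "end")], list(start = 501L, end = 1000L))
  expect_equal(win$strand, "+")

  win <- upstream_window(
    data.frame(start = 101, end = 700, strand = "-"), g, window = 500
  )
  expect_equal(win[c("start", "end")], list(start = 701L, end = 1200L))

  expect_error(
    upstream_window(
      data.frame(start = 1, end = 300, strand = "+"), g, window = 500
    ),
    "empty upstream window"
  )
})

test_that("upstream window is truncated at same-strand neighbors", {
  g <- strrep("A", 2000)
  ann <- data.frame(
    gene_id = c("up", "anchor"), genome_id = "g",
    start = c(100, 1001), end = c(400, 1600), strand = "+",
    role = c("other", "anchor_subunit_II")
  )
  win <- upstream_window(ann[2, ], g, window = 900, annotations = ann)
  expect_equal(win$start, 401L)
  expect_equal(win$end, 1000L)
})

test_that("a planted micro-ORF is found with exact coordinates", {
  region <- paste0(
    strrep("C", 10), "ATG", strrep("GCT", 30), "TAA", strrep("C", 10)
  )
  orfs <- scan_small_orfs(region, min_aa = 25)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 11L)
  expect_equal(orfs$end, 11L + 93L - 1L + 3L)
  expect_equal(orfs$length_aa, 31L)
  expect_equal(orfs$frame, (11L - 1L) %% 3L)
  expect_equal(orfs$peptide, paste0("M", strrep("A", 30)))
})

test_that("a start-codon-free region yields no ORFs", {
  region <- strrep("CCA", 200) # no ATG/GTG/TTG in any frame
  expect_equal(nrow(scan_small_orfs(region, min_aa = 5)), 0L)
})

test_that("ORF scan equals the brute-force six-frame oracle", {
  set.seed(7)
  for (len in c(300, 800, 1200, 2000)) {
    region <- random_dna(len)
    for (strand_seq in c(region, reverse_complement(region))) {
      got <- scan_small_orfs(strand_seq, min_aa = 10, max_aa = 200)
      want <- oracle_scan_orfs(strand_seq, min_aa = 10, max_aa = 200)
      expect_equal(
        got[, c("start", "end", "frame", "length_aa")], want,
        ignore_attr = TRUE
      )
    }
  }
})

test_that("ORF scan matches the oracle across length bounds", {
  set.seed(11)
  for (i in 1:5) {
    region <- random_dna(1000)
    got <- scan_small_orfs(region, min_aa = 25, max_aa = 100)
    want <- oracle_scan_orfs(region, min_aa = 25, max_aa = 100)
    expect_equal(got[, c("start", "end", "frame", "length_aa")], want,
      ignore_attr = TRUE
    )
  }
})

# hydrophilic gene-like content: shifted reading frames are rich in
# stop codons and free of start codons, as in the generator's genes
random_hydrophilic_peptide <- function(len) {
  paste(sample(c("E", "D", "K", "N", "Q"), len, TRUE), collapse = "")
}

test_that("a planted single-base insertion is detected and top-ranked", {
  set.seed(19)
  pep <- random_hydrophilic_peptide(89)
  clean <- paste0("ATG", iiascout:::.reverse_translate(pep), "TAA")
  # 90 codons + stop; insert one A after codon 45
  at <- 3 * 45
  broken <- paste0(substr(clean, 1, at), "A", substr(clean, at + 1, nchar(clean)))
  calls <- detect_frameshift(broken, min_gain_aa = 20)
  expect_gt(nrow(calls), 0L)
  top <- calls[1, ]
  expect_equal(top$edit, "delete_1")
  expect_true(top$run_start <= at + 1 && top$run_end >= at + 1)
  expect_equal(top$fused_length_aa, 90L)
})

test_that("a clean ORF produces no frameshift calls", {
  set.seed(23)
  pep <- random_hydrophilic_peptide(80)
  clean <- paste0("ATG", iiascout:::.reverse_translate(pep), "TAA")
  calls <- detect_frameshift(clean, min_gain_aa = 20)
  expect_equal(nrow(calls), 0L)
})

test_that("two distant planted insertions yield two local calls", {
  set.seed(29)
  pep1 <- random_hydrophilic_peptide(59)
  pep2 <- random_hydrophilic_peptide(59)
  orf1 <- paste0("ATG", iiascout:::.reverse_translate(pep1), "TAA")
  orf2 <- paste0("ATG", iiascout:::.reverse_translate(pep2), "TAA")
  ins <- function(x, at, b) {
    paste0(substr(x, 1, at), b, substr(x, at + 1, nchar(x)))
  }
  region <- paste0(ins(orf1, 90, "G"), strrep("TAC", 20), ins(orf2, 90, "G"))
  off2 <- nchar(orf1) + 1 + 60 # start of the second ORF block
  calls <- detect_frameshift(region, min_gain_aa = 15)
  expect_gte(nrow(calls), 2L)
  near1 <- any(calls$run_start <= 95 & calls$run_end >= 85)
  near2 <- any(calls$run_start <= off2 + 95 & calls$run_end >= off2 + 85)
  expect_true(near1)
  expect_true(near2)
})
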