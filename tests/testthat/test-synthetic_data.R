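test_that("the same seed produces byte-identical outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_operon_genome(operon_spec(seed = 5), out_dir = d1)
  simulate_operon_genome(operon_spec(seed = 5), out_dir = d2)
  for (f in c("genome.fa", "genome.gff3", "truth.json")) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
  s1 <- simulate_spectra("MNEKHAAELK", spectrum_spec(seed = 5))
  s2 <- simulate_spectra("MNEKHAAELK", spectrum_spec(seed = 5))
  expect_identical(s1$ms1, s2$ms1)
  expect_identical(s1$msms, s2$msms)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  a <- runif(1)
  set.seed(1234)
  invisible(simulate_operon_genome(operon_spec(seed = 99)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("generated FASTA/GFF pass loader validation", {
  d <- withr::local_tempdir()
  sim <- simulate_operon_genome(operon_spec(seed = 3), out_dir = d)
  ag <- load_annotated_genome(
    file.path(d, "genome.fa"), file.path(d, "genome.gff3"),
    anchor_ids = "coxB2_anchor"
  )
  expect_equal(sort(ag$annotations$gene_id),
    sort(sim$annotations$gene_id))
  expect_equal(
    ag$annotations$role[ag$annotations$gene_id == "coxB2_anchor"],
    "anchor_subunit_II"
  )
})

test_that("the planted ORF is recovered verbatim by scan + filter", {
  for (s in c(2, 4, 6)) {
    sim <- simulate_operon_genome(operon_spec(seed = s))
    anchor <- sim$annotations[sim$annotations$gene_id == "coxB2_anchor", ]
    win <- upstream_window(anchor, sim$genome[[1]], window = 750)
    region <- extract_subsequence(
      as.character(sim$genome[[1]]), win$start, win$end, "+"
    )
    orfs <- scan_small_orfs(region)
    pass <- vapply(
      orfs$peptide, function(p) is_candidate_iia(p)$is_candidate, logical(1)
    )
    hits <- orfs[pass, ]
    expect_equal(nrow(hits), 1L)
    expect_equal(win$start + hits$start - 1L, sim$truth$iia$start)
    expect_equal(win$start + hits$end - 1L, sim$truth$iia$end)
    expect_equal(hits$peptide, sim$truth$iia$peptide)
  }
})

test_that("planted frameshifts are found in the true homopolymer run", {
  for (s in c(8, 9, 10)) {
    sim <- simulate_operon_genome(operon_spec(
      seed = s, frameshift = list(offset_nt = 135, base = "A")
    ))
    tr <- sim$truth$frameshift
    region <- extract_subsequence(
      as.character(sim$genome[[1]]),
      sim$truth$anchor$start, sim$truth$anchor$end, "+"
    )
    calls <- detect_frameshift(region, min_gain_aa = 20)
    expect_gt(nrow(calls), 0L)
    pos_local <- tr$genomic_position - sim$truth$anchor$start + 1L
    expect_true(
      calls$run_start[1] <= pos_local && calls$run_end[1] >= pos_local
    )
  }
})

test_that("planted spectra are recovered by assignment and ladder readout", {
  pep <- "MNEKHPAAGTLLIVFFLIVLEDKQW"
  sim <- simulate_spectra(pep, spectrum_spec(
    seed = 7, ppm_jitter = 80, noise_peaks = 20
  ))
  cand <- data.frame(name = "planted", peptide = pep)
  res <- assign_peaks(sim$ms1, cand, tolerance_ppm = 150)
  best <- res[res$best, ]
  # every planted species recovered with the correct hypothesis
  sp <- sim$truth$species
  for (i in seq_len(nrow(sp))) {
    j <- which(abs(best$peak_mz - sp$observed_mz[i]) < 1e-9)
    expect_length(j, 1L)
    expect_equal(best$carrier[j], sp$base[i])
    expect_equal(best$n_nh3_loss[j], sp$n_nh3_loss[i])
    expect_equal(best$n_acetyl[j], sp$n_acetyl[i])
  }
  # noise peaks (>= 500 ppm from any species) are never assigned
  noise_mz <- setdiff(sim$ms1$mz, sp$observed_mz)
  expect_false(any(res$peak_mz %in% noise_mz))

  out <- read_ladder(sim$msms$mz, tolerance_da = 0.5)
  rev_res <- rev(strsplit(pep, "")[[1]])
  run <- out$runs[[which.max(vapply(out$runs, nrow, 1L))]]
  ok <- vapply(seq_len(nrow(run)), function(k) {
    grepl(rev_res[run$position[k]], run$residues[k], fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero-jitter spectra assign at 0 ppm", {
  pep <- "MNEKHAAELK"
  sim <- simulate_spectra(pep, spectrum_spec(
    seed = 1, ppm_jitter = 0, noise_peaks = 0
  ))
  res <- assign_peaks(sim$ms1, data.frame(name = "p", peptide = pep),
    tolerance_ppm = 50
  )
  best <- res[res$best, ]
  expect_equal(nrow(best), 3L)
  expect_true(all(abs(best$delta_ppm) < 1e-9))
})

test_that("infeasible operon specs are rejected", {
  expect_error(operon_spec(iia_len_aa = 20, iia_tm_core_len = 19))
})
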