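test_that("terminal fragment masses match composition arithmetic", {
  y <- fragment_mz_series("AGK", "y")
  expect_equal(y$mz[1], 147.1128, tolerance = 1e-3) # y1 of ...K
  b <- fragment_mz_series("GK", "b")
  expect_equal(b$mz[1], 58.0293, tolerance = 1e-3) # b1 = G residue + proton
})

test_that("fragment series are strictly increasing", {
  set.seed(89)
  for (i in 1:10) {
    pep <- random_peptide(sample(5:40, 1))
    for (s in c("y", "b")) {
      lad <- fragment_mz_series(pep, s)
      expect_true(all(diff(lad$mz) > 0))
      expect_equal(lad$index, seq_len(nchar(pep) - 1L))
    }
  }
})

test_that("b_k + y_(n-k) equals the precursor mass plus two protons", {
  set.seed(97)
  for (i in 1:20) {
    pep <- random_peptide(sample(4:45, 1))
    n <- nchar(pep)
    b <- fragment_mz_series(pep, "b")$mz
    y <- fragment_mz_series(pep, "y")$mz
    m <- peptide_mass(pep)
    for (k in seq_len(n - 1L)) {
      expect_equal(b[k] + y[n - k], m + 2 * 1.007276, tolerance = 1e-3)
    }
  }
})

test_that("an exact y-ladder reads back the C-terminal residue string", {
  pep <- "MNEKHAAELK"
  lad <- fragment_mz_series(pep, "y")
  out <- read_ladder(lad$mz)
  expect_equal(out$n_runs, 1L)
  expect_lte(out$rms_error, 1e-6)
  rev_res <- rev(strsplit(pep, "")[[1]])[1:9]
  for (k in 1:9) {
    expect_match(out$residues[k], rev_res[k], fixed = TRUE)
  }
})

test_that("a 0.3 Da jittered ladder reads back at 0.5 Da tolerance", {
  set.seed(101)
  pep <- "MNEKHAAELK"
  lad <- fragment_mz_series(pep, "y")
  jit <- lad$mz + runif(length(lad$mz), -0.3, 0.3)
  out <- read_ladder(jit, tolerance_da = 0.5)
  rev_res <- rev(strsplit(pep, "")[[1]])
  run <- out$runs[[which.max(vapply(out$runs, nrow, 1L))]]
  # positions are true C-terminal indices when anchored at y1
  for (k in seq_len(nrow(run))) {
    expect_match(run$residues[k], rev_res[run$position[k]], fixed = TRUE)
  }
  expect_lte(out$rms_error, 0.5)
})

test_that("a deleted internal ion splits the readout into two runs", {
  pep <- "MNEKHAAELKW"
  lad <- fragment_mz_series(pep, "y")
  peaks <- lad$mz[-5] # drop y5
  out <- read_ladder(peaks)
  expect_gte(out$n_runs, 2L)
  # no run spans all remaining steps
  expect_lt(
    max(vapply(out$runs, nrow, 1L)), length(peaks) - 1L
  )
})

test_that("random peptides are recovered up to I/L and K/Q ambiguity", {
  set.seed(103)
  for (i in 1:200) {
    pep <- random_peptide(sample(5:45, 1))
    lad <- fragment_mz_series(pep, "y")
    out <- read_ladder(lad$mz, tolerance_da = 0.5)
    rev_res <- rev(strsplit(pep, "")[[1]])
    run <- out$runs[[1]]
    expect_true(run$anchored[1])
    expect_equal(nrow(run), nchar(pep) - 1L)
    ok <- vapply(seq_len(nrow(run)), function(k) {
      grepl(rev_res[run$position[k]], run$residues[k], fixed = TRUE)
    }, logical(1))
    expect_true(all(ok))
    expect_lte(out$rms_error, 0.5)
  }
})

test_that("MGF files round-trip through the reader and writer", {
  sp <- list(list(
    title = "test spectrum", pepmass = 1234.5678,
    peaks = data.frame(mz = c(100.1, 200.22, 300.333), intensity = c(1, 2, 3))
  ))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$title, "test spectrum")
  expect_equal(back[[1]]$pepmass, 1234.5678, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$mz, sp[[1]]$peaks$mz, tolerance = 1e-6)
})
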