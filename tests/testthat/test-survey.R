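test_that("an annotated planted IIa gene is classified as annotated", {
  sim <- simulate_operon_genome(operon_spec(seed = 11, annotate_iia = TRUE))
  row <- survey_genome(sim$genome, sim$annotations, "coxB2_anchor",
    organism = "sim"
  )
  expect_equal(row$iia_status, "annotated")
  expect_equal(row$iia_accession, "coxIIa_planted")
  expect_equal(row$iia_start, sim$truth$iia$start)
  expect_equal(row$iia_end, sim$truth$iia$end)
  expect_equal(row$sub2_tm, 1L)
  expect_equal(row$iia_tm, 1L)
})

test_that("stripping the IIa annotation flips status to detected_unannotated", {
  sim <- simulate_operon_genome(operon_spec(seed = 11, annotate_iia = TRUE))
  stripped <- sim$annotations[sim$annotations$gene_id == "coxB2_anchor", ]
  row <- survey_genome(sim$genome, stripped, "coxB2_anchor")
  expect_equal(row$iia_status, "detected_unannotated")
  # same ORF recovered at the planted coordinates
  expect_equal(row$iia_start, sim$truth$iia$start)
  expect_equal(row$iia_end, sim$truth$iia$end)
  expect_equal(row$iia_peptide, sim$truth$iia$peptide)
})

test_that("a two-helix anchor with no upstream ORF is absent", {
  sim <- simulate_operon_genome(
    operon_spec(seed = 13, anchor_n_cores = 2, annotate_iia = FALSE)
  )
  # blank out the planted IIa ORF so nothing can be found upstream
  gseq <- as.character(sim$genome[[1]])
  s <- sim$truth$iia$start
  e <- sim$truth$iia$end
  gseq <- paste0(
    substr(gseq, 1, s - 1), strrep("C", e - s + 1),
    substr(gseq, e + 1, nchar(gseq))
  )
  ann <- sim$annotations[sim$annotations$gene_id == "coxB2_anchor", ]
  row <- survey_genome(gseq, ann, "coxB2_anchor")
  expect_equal(row$sub2_tm, 2L)
  expect_equal(row$iia_status, "absent")
  expect_true(is.na(row$iia_accession))
  expect_true(is.na(row$iia_mm))
})

test_that("missing anchor raises an error", {
  sim <- simulate_operon_genome(operon_spec(seed = 17))
  expect_error(
    survey_genome(sim$genome, sim$annotations, "nope"),
    "not found"
  )
})

test_that("summary counts partition the rows", {
  rows <- do.call(rbind, lapply(c(21, 22, 23), function(s) {
    sim <- simulate_operon_genome(operon_spec(seed = s))
    survey_genome(sim$genome, sim$annotations, "coxB2_anchor",
      organism = paste0("sim", s)
    )
  }))
  rows$iia_status <- c("annotated", "detected_unannotated", "absent")
  res <- tabulate_survey(rows)
  expect_equal(res$summary$n_regions, 3L)
  expect_equal(res$summary$n_annotated_iia, 1L)
  expect_equal(res$summary$n_detected_iia, 1L)
  expect_equal(res$summary$n_absent, 1L)

  empty <- tabulate_survey(rows[0, ])
  expect_equal(
    unlist(empty$summary),
    c(n_regions = 0L, n_annotated_iia = 0L, n_detected_iia = 0L,
      n_absent = 0L)
  )
})

test_that("the packaged survey table reproduces the published counts", {
  rows <- read_survey_table()
  res <- tabulate_survey(rows)
  expect_equal(res$summary$n_regions, 36L)
  expect_equal(res$summary$n_annotated_iia, 21L)
  expect_equal(res$summary$n_detected_iia, 6L)
  expect_equal(res$summary$n_absent, 9L)
  # one-helix subunit II wherever a IIa is present; two helices otherwise
  present <- rows$iia_status != "absent"
  expect_true(all(rows$sub2_tm[present] == 1L))
  expect_true(all(rows$sub2_tm[!present] == 2L))
})

test_that("status assignment is perfect on a batch of synthetic genomes", {
  seeds <- 101:120
  correct <- 0L
  for (s in seeds) {
    annotate <- s %% 2 == 0
    sim <- simulate_operon_genome(operon_spec(seed = s,
      annotate_iia = annotate,
      iia_len_aa = 34 + (s %% 5) * 11 # 34-78 aa
    ))
    row <- survey_genome(sim$genome, sim$annotations, "coxB2_anchor")
    want <- if (annotate) "annotated" else "detected_unannotated"
    ok <- row$iia_status == want &&
      row$iia_start == sim$truth$iia$start &&
      row$iia_end == sim$truth$iia$end
    correct <- correct + ok
  }
  expect_equal(correct, length(seeds))
})
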