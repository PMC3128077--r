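# Seeded generators for operon genomes and mass spectra with truth
# files, so every pipeline stage can be validated at desk scale.

# run code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# one fixed codon per amino acid: reverse translation is deterministic
.CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  E = "GAA", Q = "CAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTA", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

.reverse_translate <- function(peptide) {
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  paste(.CODON_OF[aa], collapse = "")
}

# flanks are Glu/Lys/Gln only: Ser is hydrophilic enough to stretch
# called segments, and the Asp/Asn codons (ending AT) read as Ile/Met
# in the +1 phase, which would let frame-shifted flank readings build
# spurious transmembrane ORFs; the GAA/AAA/CAA codons read as
# Lys/Asn/Arg/Thr in every shifted phase and contain no start codon
.HYDROPHILIC_FLANK_AA <- c("E", "K", "Q")

# planted cores alternate Leu/Ile: with the CTA/ATT codons the +1
# reading frame is a wall of TAA stops and the +2 frame reads
# hydrophilic Asn/Ser, so no frame-shifted reading of a core can form
# a competing transmembrane ORF
.core_residues <- function(core_len) {
  rep(c("L", "I"), length.out = core_len)
}

.random_flank <- function(n) {
  if (n <= 0L) return(character(0))
  sample(.HYDROPHILIC_FLANK_AA, n, replace = TRUE)
}

# a peptide of length len with n_cores hydrophobic cores of core_len,
# optionally opening with the conserved P-x-G-T motif region
.build_peptide <- function(len, core_len = 19, n_cores = 1,
                           with_motif = FALSE, with_trp = FALSE) {
  stopifnot(len >= n_cores * core_len + 4L)
  aa <- .random_flank(len)
  aa[1L] <- "M"
  motif_end <- 1L
  if (with_motif && len >= core_len + 18L) {
    aa[12:16] <- c("P", "A", "A", "G", "T")
    motif_end <- 16L
  }
  avail_start <- motif_end + 3L
  # the Leu/Ile cores average 4.15 on the Kyte-Doolittle scale, so the
  # called window-union span reaches ~6 residues into each flank; 14
  # hydrophilic residues keep two called spans disjoint
  gap <- 14L
  need <- n_cores * core_len + (n_cores - 1L) * gap
  if (avail_start + need - 1L > len - 2L) {
    avail_start <- max(2L, len - 1L - need)
  }
  pos <- avail_start
  cores <- list()
  for (k in seq_len(n_cores)) {
    aa[pos:(pos + core_len - 1L)] <- .core_residues(core_len)
    cores[[k]] <- c(pos, pos + core_len - 1L)
    pos <- pos + core_len + gap
  }
  if (with_trp) {
    tail_free <- setdiff(seq.int(max(2L, len - 4L), len), unlist(
      lapply(cores, function(cc) cc[1L]:cc[2L])
    ))
    if (length(tail_free) > 0L) aa[tail_free[1L]] <- "W"
  }
  structure(paste(aa, collapse = ""), cores = cores)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intergenic/background sequence: random DNA interleaved with a short
# block carrying stop codons in all three frames ("TAAATAAATAA" has
# TAA at offsets 0, 4 and 8), so no reading frame can run stop-free
# for more than ~13 codons and read-through ORFs cannot borrow
# hydrophobic stretches from non-genic sequence
.noncoding_dna <- function(n) {
  if (n <= 0L) return("")
  chunks <- character(0)
  len <- 0L
  while (len < n) {
    chunks <- c(chunks, .random_dna(24L), "TAAATAAATAA")
    len <- len + 35L
  }
  substr(paste(chunks, collapse = ""), 1L, n)
}

#' Specification for a synthetic operon genome
#'
#' Defaults emulate the arrangement in which subunit-IIa genes are
#' found: a micro-ORF (41 aa by default, within the observed 34-78 aa
#' range) with one 19-residue hydrophobic core and the conserved
#' P-x(1-3)-G-[TA] motif, sitting in the intergenic region directly
#' upstream of the subunit-II anchor gene.
#'
#' @param anchor_len_aa Anchor (subunit II) peptide length (default
#'   150).
#' @param iia_len_aa Planted micro-ORF peptide length (default 41).
#' @param iia_tm_core_len Hydrophobic-core length in the planted
#'   peptide (default 19).
#' @param intergenic_len Intergenic spacing between the micro-ORF stop
#'   and the anchor start, nt (default 120).
#' @param frameshift `NULL`, or a list `list(offset_nt = , base = )`
#'   to insert one base inside the anchor gene at that 1-based offset.
#' @param annotate_iia Include the planted micro-ORF in the GFF
#'   (default `TRUE`).
#' @param with_motif,with_trp Plant the conserved motif / tryptophan in
#'   the micro-ORF peptide (defaults `TRUE`).
#' @param anchor_n_cores Hydrophobic cores in the anchor peptide (1 or
#'   2; default 1).
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return A list of class `operon_spec`.
#' @export
operon_spec <- function(anchor_len_aa = 150, iia_len_aa = 41,
                        iia_tm_core_len = 19, intergenic_len = 120,
                        frameshift = NULL, annotate_iia = TRUE,
                        with_motif = TRUE, with_trp = TRUE,
                        anchor_n_cores = 1, seed = 1) {
  stopifnot(
    iia_len_aa >= iia_tm_core_len + 4L,
    intergenic_len >= 10L,
    anchor_n_cores %in% c(1L, 2L)
  )
  structure(as.list(environment()), class = "operon_spec")
}

#' Simulate an operon genome with a planted subunit-IIa micro-ORF
#'
#' Generates a genome of random background containing (5' to 3' on the
#' forward strand) a planted micro-ORF with one hydrophobic core, an
#' intergenic gap, and an anchor gene whose peptide has one (or two)
#' hydrophobic core(s); optionally a single-base insertion inside the
#' anchor gene. In-frame stop codons are placed immediately before the
#' micro-ORF so upstream read-through cannot extend it. All planted
#' coordinates and peptides are recorded in the truth object.
#'
#' @param spec An [operon_spec()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genome.gff3` and `truth.json` there.
#' @return A list: `genome` (named DNAStringSet), `annotations`
#'   (data.frame), `truth` (list), and — when `out_dir` is given —
#'   `paths`.
#' @examples
#' sim <- simulate_operon_genome(operon_spec(seed = 7))
#' sim$truth$iia$peptide
#' @export
simulate_operon_genome <- function(spec = operon_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "operon_spec"))
  .with_seed(spec$seed, {
    iia_pep <- .build_peptide(spec$iia_len_aa,
      core_len = spec$iia_tm_core_len, n_cores = 1L,
      with_motif = spec$with_motif, with_trp = spec$with_trp
    )
    anchor_pep <- .build_peptide(spec$anchor_len_aa,
      core_len = 19L,
      n_cores = spec$anchor_n_cores, with_motif = FALSE
    )
    iia_dna <- paste0(.reverse_translate(iia_pep), "TAA")
    anchor_dna <- paste0(.reverse_translate(anchor_pep), "TAA")

    bg1 <- .noncoding_dna(200L)
    gap <- .noncoding_dna(spec$intergenic_len)
    bg2 <- .noncoding_dna(200L)

    # in-frame stops right before the planted ORF block read-through
    iia_start <- nchar(bg1) + 7L
    genome_seq <- paste0(
      bg1, "TAATAA", iia_dna, gap, anchor_dna, bg2
    )
    iia_end <- iia_start + nchar(iia_dna) - 1L
    anchor_start <- iia_end + nchar(gap) + 1L
    anchor_end <- anchor_start + nchar(anchor_dna) - 1L

    truth_fs <- NULL
    if (!is.null(spec$frameshift)) {
      off <- spec$frameshift$offset_nt
      base <- spec$frameshift$base
      stopifnot(off >= 1L, off <= nchar(anchor_dna))
      pos <- anchor_start + off - 1L # insertion goes after this base
      genome_seq <- paste0(
        substr(genome_seq, 1L, pos), base,
        substr(genome_seq, pos + 1L, nchar(genome_seq))
      )
      anchor_end <- anchor_end + 1L
      runs <- .homopolymer_runs(genome_seq)
      ri <- which(runs$start <= pos + 1L & runs$end >= pos + 1L)
      truth_fs <- list(
        genomic_position = pos + 1L,
        run_start = runs$start[ri], run_end = runs$end[ri],
        base = base, anchor_offset_nt = off + 1L
      )
    }

    genome_id <- sprintf("simulated_operon_seed%d", spec$seed)
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, genome_id))
    ann <- data.frame(
      gene_id = "coxB2_anchor", genome_id = genome_id,
      start = anchor_start, end = anchor_end, strand = "+",
      role = "anchor_subunit_II", stringsAsFactors = FALSE
    )
    if (spec$annotate_iia) {
      ann <- rbind(ann, data.frame(
        gene_id = "coxIIa_planted", genome_id = genome_id,
        start = iia_start, end = iia_end, strand = "+",
        role = "other", stringsAsFactors = FALSE
      ))
    }
    truth <- list(
      seed = spec$seed,
      genome_id = genome_id,
      genome_length = nchar(genome_seq),
      iia = list(
        start = iia_start, end = iia_end, strand = "+",
        length_aa = spec$iia_len_aa, peptide = as.character(iia_pep),
        annotated = spec$annotate_iia
      ),
      anchor = list(
        start = anchor_start, end = anchor_end, strand = "+",
        peptide = as.character(anchor_pep),
        n_cores = spec$anchor_n_cores
      ),
      frameshift = truth_fs
    )
    out <- list(genome = genome, annotations = ann, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(out_dir, "genome.fa")
      gff <- file.path(out_dir, "genome.gff3")
      tj <- file.path(out_dir, "truth.json")
      Biostrings::writeXStringSet(genome, fa)
      .write_gff3(ann, gff)
      jsonlite::write_json(truth, tj,
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
      out$paths <- list(fasta = fa, gff = gff, truth_json = tj)
    }
    out
  })
}

.write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann))) {
    writeLines(paste(
      ann$genome_id[i], "iiascout", "gene", ann$start[i], ann$end[i],
      ".", ann$strand[i], ".", paste0("ID=", ann$gene_id[i]),
      sep = "\t"
    ), con)
  }
  invisible(path)
}

#' Specification for synthetic MS1 / MS/MS spectra
#'
#' Defaults emulate an intact-protein MALDI spectrum with its
#' protonated base peak plus -NH3 and +acetyl satellites, ~80 ppm
#' calibration error, and random noise peaks kept >= 500 ppm away from
#' any true species. MS/MS y-ion error has two components, as on a
#' TOF/TOF instrument: a slowly varying calibration drift (shared by
#' neighboring peaks, so it largely cancels in consecutive mass
#' differences) plus a small peak-wise random term; together they give
#' peak deviations up to ~0.5 Da while successive differences stay
#' readable.
#'
#' @param species Data.frame with columns `base`, `n_nh3_loss`,
#'   `n_acetyl`, `abundance`.
#' @param ppm_jitter Multiplicative m/z jitter, ppm (default 80).
#' @param noise_peaks Number of random MS1 noise peaks (default 20).
#' @param noise_min_ppm Minimum ppm distance of noise peaks from any
#'   true species (default 500).
#' @param msms_da_jitter Half-width of the peak-wise uniform random
#'   error on y-ion m/z, Da (default 0.15).
#' @param msms_drift_da Amplitude of the linear calibration drift
#'   across the MS/MS mass range, Da (default 0.35).
#' @param drop_ions Integer y-ion indices to remove from the MS/MS
#'   spectrum (default none).
#' @param seed Integer seed.
#' @return A list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(species = data.frame(
                            base = c("protonated", "protonated",
                                     "protonated"),
                            n_nh3_loss = c(0L, 1L, 0L),
                            n_acetyl = c(0L, 0L, 1L),
                            abundance = c(100, 35, 25),
                            stringsAsFactors = FALSE
                          ),
                          ppm_jitter = 80, noise_peaks = 20,
                          noise_min_ppm = 500,
                          msms_da_jitter = 0.15,
                          msms_drift_da = 0.35,
                          drop_ions = integer(0), seed = 1) {
  stopifnot(
    ppm_jitter >= 0, msms_da_jitter >= 0, msms_drift_da >= 0,
    noise_peaks >= 0
  )
  structure(as.list(environment()), class = "spectrum_spec")
}

#' Simulate MS1 and MS/MS spectra for a peptide, with truth
#'
#' @param peptide Amino-acid string (standard residues).
#' @param spec A [spectrum_spec()].
#' @param out_dir Optional directory; when given, writes `ms1.tsv`,
#'   `msms.mgf` and `truth.json` there.
#' @return A list: `ms1` (data.frame `mz`, `intensity`), `msms`
#'   (data.frame `mz`, `intensity`), `truth` (planted species with
#'   their theoretical and observed m/z, kept y-ion indices), and
#'   `paths` when written.
#' @examples
#' sim <- simulate_spectra("MNEKHAAELK", spectrum_spec(seed = 7))
#' head(sim$ms1)
#' @export
simulate_spectra <- function(peptide, spec = spectrum_spec(),
                             out_dir = NULL) {
  stopifnot(inherits(spec, "spectrum_spec"))
  .with_seed(spec$seed, {
    neutral <- peptide_mass(peptide, "monoisotopic")
    sp <- spec$species
    sp$theoretical_mz <- vapply(seq_len(nrow(sp)), function(i) {
      mz_of_species(neutral, sp$base[i], sp$n_nh3_loss[i], sp$n_acetyl[i])
    }, numeric(1L))
    jit <- stats::runif(nrow(sp), -spec$ppm_jitter, spec$ppm_jitter)
    sp$observed_mz <- sp$theoretical_mz * (1 + jit * 1e-6)

    noise <- numeric(0)
    if (spec$noise_peaks > 0L) {
      lo <- min(sp$theoretical_mz) * 0.8
      hi <- max(sp$theoretical_mz) * 1.2
      while (length(noise) < spec$noise_peaks) {
        cand <- stats::runif(spec$noise_peaks, lo, hi)
        far <- vapply(cand, function(x) {
          all(abs(ppm_delta(x, sp$theoretical_mz)) >= spec$noise_min_ppm)
        }, logical(1L))
        noise <- c(noise, cand[far])
      }
      noise <- noise[seq_len(spec$noise_peaks)]
    }
    ms1 <- rbind(
      data.frame(mz = sp$observed_mz, intensity = 10 * sp$abundance),
      data.frame(
        mz = noise,
        intensity = stats::runif(length(noise), 1, 80)
      )
    )
    ms1 <- ms1[order(ms1$mz), , drop = FALSE]
    rownames(ms1) <- NULL

    ladder <- fragment_mz_series(peptide, "y")
    keep <- !(ladder$index %in% spec$drop_ions)
    mz_true <- ladder$mz[keep]
    # calibration drift: linear between two random endpoints
    ends <- stats::runif(2, -spec$msms_drift_da, spec$msms_drift_da)
    frac <- if (length(mz_true) > 1L) {
      (mz_true - min(mz_true)) / (max(mz_true) - min(mz_true))
    } else {
      0
    }
    drift <- ends[1L] + (ends[2L] - ends[1L]) * frac
    msms <- data.frame(
      mz = mz_true + drift +
        stats::runif(length(mz_true), -spec$msms_da_jitter,
                     spec$msms_da_jitter),
      intensity = stats::runif(length(mz_true), 50, 100)
    )
    msms <- msms[order(msms$mz), , drop = FALSE]
    rownames(msms) <- NULL

    truth <- list(
      seed = spec$seed,
      peptide = peptide,
      neutral_mass = neutral,
      species = sp,
      y_indices_kept = ladder$index[keep]
    )
    out <- list(ms1 = ms1, msms = msms, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      ms1_path <- file.path(out_dir, "ms1.tsv")
      mgf_path <- file.path(out_dir, "msms.mgf")
      tj <- file.path(out_dir, "truth.json")
      utils::write.table(ms1, ms1_path,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write_mgf(list(list(
        title = paste0("simulated_msms_seed", spec$seed),
        pepmass = mz_of_species(neutral, "protonated"),
        peaks = msms
      )), mgf_path)
      jsonlite::write_json(truth, tj,
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
      out$paths <- list(ms1 = ms1_path, mgf = mgf_path, truth_json = tj)
    }
    out
  })
}
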