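test_that("make_genome satisfies its invariants at the default configuration", {
  gm <- make_genome(synth_config())
  expect_s3_class(gm, "genome_model")
  expect_length(gm$genes, 6L)
  expect_length(gm$chromosomes, 2L)
  expect_false(any(grepl("[^ACGT]", gm$chromosomes)))

  chroms <- vapply(gm$genes, function(g) g$chromosome, character(1))
  expect_gte(length(unique(chroms)), 2L)

  for (g in gm$genes) {
    # exons sorted, non-overlapping, within the chromosome
    expect_true(all(diff(g$exons[, "start"]) > 0))
    if (nrow(g$exons) > 1L)
      expect_true(all(g$exons[-1L, "start"] > g$exons[-nrow(g$exons), "end"]))
    expect_lte(max(g$exons[, "end"]), nchar(gm$chromosomes[[g$chromosome]]))
    # CDS length multiple of 3, encoded protein stop-free and terminated
    cds_len <- sum(g$cds[, "end"] - g$cds[, "start"] + 1L)
    expect_identical(cds_len %% 3L, 0L)
    r <- cds_tx_range(g)
    tr <- translate_cds(substr(gene_tx_seq(gm, g), r["start"], r["end"]))
    expect_true(tr$terminated)
    expect_false(grepl("*", tr$peptide, fixed = TRUE))
    expect_identical(nchar(tr$peptide), cds_len %/% 3L - 1L)
    # domains within the protein
    expect_true(all(g$domains$aa_start >= 1L))
    expect_true(all(g$domains$aa_end <= nchar(tr$peptide)))
  }

  # at least one same-chromosome pair at >= the configured separation,
  # and at least one cross-chromosome pair
  gstart <- vapply(gm$genes, function(g) min(g$exons[, "start"]), integer(1))
  same <- outer(chroms, chroms, "==") & upper.tri(diag(length(chroms)))
  seps <- abs(outer(gstart, gstart, "-"))[same]
  expect_true(any(seps >= synth_config()$min_intra_distance))
})

test_that("make_genome is deterministic and byte-identical on disk", {
  cfg <- synth_config(n_genes = 3L, chrom_length = 200000L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1, g2)

  d1 <- file.path(tempdir(), "gma"); d2 <- file.path(tempdir(), "gmb")
  p1 <- write_genome(g1, d1)
  p2 <- write_genome(g2, d2)
  for (f in names(p1))
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("make_genome raises a capacity error on impossible packing", {
  expect_error(
    make_genome(synth_config(n_chromosomes = 1L, chrom_length = 1000L,
                             n_genes = 50L)),
    "capacity"
  )
})

test_that("genome round-trips through FASTA/GTF/domains files", {
  gm <- tiny_genome()
  dir <- file.path(tempdir(), "gm_rt")
  p <- write_genome(gm, dir)
  back <- read_genome(p["fasta"], p["gtf"], p["domains"])
  expect_identical(back$chromosomes, gm$chromosomes)
  expect_setequal(names(back$genes), names(gm$genes))
  for (id in names(gm$genes)) {
    expect_identical(unname(back$genes[[id]]$exons), unname(gm$genes[[id]]$exons))
    expect_identical(unname(back$genes[[id]]$cds), unname(gm$genes[[id]]$cds))
    expect_identical(back$genes[[id]]$strand, gm$genes[[id]]$strand)
    expect_identical(gene_tx_seq(back, id), gene_tx_seq(gm, id))
  }
  unlink(dir, recursive = TRUE)
})

test_that("build_fusion_transcript concatenates prefix and suffix exactly", {
  gm <- tiny_genome()
  donor <- names(gm$genes)[1L]
  chroms <- vapply(gm$genes, function(g) g$chromosome, character(1))
  acceptor <- names(gm$genes)[chroms != chroms[[1L]]][1L]

  b5 <- 300L; a3 <- 101L
  ev <- fusion_event(gm, donor, acceptor, b5, a3)
  ft <- build_fusion_transcript(gm, ev)
  dtx <- gene_tx_seq(gm, donor); atx <- gene_tx_seq(gm, acceptor)
  expect_identical(nchar(ft$seq), b5 + (nchar(atx) - a3 + 1L))
  expect_identical(ft$junction_offset, b5)
  expect_identical(substr(ft$seq, 1L, b5), substr(dtx, 1L, b5))
  expect_identical(substr(ft$seq, b5 + 1L, nchar(ft$seq)),
                   substr(atx, a3, nchar(atx)))

  # out-of-transcript breakpoints raise coordinate errors
  expect_error(fusion_event(gm, donor, acceptor, nchar(dtx) + 1L, a3),
               "coordinate")
})

test_that("engineer_fusion controls the frame and removes microhomology", {
  gm <- tiny_genome()
  donor <- names(gm$genes)[1L]
  chroms <- vapply(gm$genes, function(g) g$chromosome, character(1))
  acceptor <- names(gm$genes)[chroms != chroms[[1L]]][1L]

  for (frame in c(TRUE, FALSE)) {
    ev <- engineer_fusion(gm, donor, acceptor, in_frame = frame)
    expect_identical(ev$expected_in_frame, frame)
    # the frame flag agrees with brute-force translation
    expect_identical(
      frame_oracle(gm, donor, acceptor,
                   ev$donor_break$transcript_offset,
                   ev$acceptor_break$transcript_offset),
      frame
    )
    # zero microhomology: shifting the junction by one base changes the seq
    b5 <- ev$donor_break$transcript_offset
    a3 <- ev$acceptor_break$transcript_offset
    dtx <- gene_tx_seq(gm, donor); atx <- gene_tx_seq(gm, acceptor)
    expect_false(substr(dtx, b5 + 1L, b5 + 1L) == substr(atx, a3, a3))
    expect_false(substr(atx, a3 - 1L, a3 - 1L) == substr(dtx, b5, b5))
  }
})

test_that("fusion frame flag agrees with brute-force translation on random specs", {
  gm <- tiny_genome(n_genes = 4L, chrom_length = 40000L)
  set.seed(101)
  for (i in 1:50) {
    sp <- random_fusion_spec(gm)
    ev <- fusion_event(gm, sp$donor, sp$acceptor, sp$b5, sp$a3)
    expect_identical(
      ev$expected_in_frame,
      frame_oracle(gm, sp$donor, sp$acceptor, sp$b5, sp$a3),
      info = sprintf("%s:%d -> %s:%d", sp$donor, sp$b5, sp$acceptor, sp$a3)
    )
  }
})

test_that("simulate_reads yields exact substrings at error rate 0", {
  gm <- tiny_genome()
  tx <- data.frame(
    id = names(gm$genes),
    seq = vapply(names(gm$genes), function(g) gene_tx_seq(gm, g), character(1)),
    abundance = 1, stringsAsFactors = FALSE
  )
  pairs <- simulate_reads(tx, 300L, read_len = 100L, error_rate = 0, seed = 7L)
  expect_identical(nrow(pairs), 300L)
  expect_true(all(nchar(pairs$seq1) == 100L))
  expect_true(all(nchar(pairs$seq2) == 100L))
  for (i in seq_len(nrow(pairs))) {
    src <- tx$seq[tx$id == pairs$source[i]]
    hit1 <- grepl(pairs$seq1[i], src, fixed = TRUE) ||
      grepl(revcomp(pairs$seq1[i]), src, fixed = TRUE)
    hit2 <- grepl(pairs$seq2[i], src, fixed = TRUE) ||
      grepl(revcomp(pairs$seq2[i]), src, fixed = TRUE)
    expect_true(hit1 && hit2)
  }
})

test_that("simulate_reads conserves record counts in the FASTQ files", {
  tx <- data.frame(id = "T1", seq = random_dna_fixed(1500L), abundance = 1,
                   stringsAsFactors = FALSE)
  pairs <- simulate_reads(tx, 1000L, seed = 3L)
  dir <- file.path(tempdir(), "fq")
  p <- write_read_pairs(pairs, dir)
  expect_identical(length(readLines(p["mate1"])) %/% 4L, 1000L)
  expect_identical(length(readLines(p["mate2"])) %/% 4L, 1000L)
  back <- read_read_pairs(p["mate1"], p["mate2"])
  expect_identical(back$seq1, pairs$seq1)
  expect_identical(back$seq2, pairs$seq2)
  unlink(dir, recursive = TRUE)
})

test_that("simulate_reads respects abundances (binomial oracle)", {
  tx <- data.frame(id = c("A", "B"),
                   seq = c(random_dna_fixed(2000L), random_dna_fixed(2000L)),
                   abundance = c(9, 1), stringsAsFactors = FALSE)
  pairs <- simulate_reads(tx, 10000L, seed = 14L)
  frac <- mean(pairs$source == "A")
  sd3 <- 3 * sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac - 0.9), sd3)
})

test_that("simulate_reads validates its inputs", {
  tx <- data.frame(id = "T", seq = random_dna_fixed(150L), abundance = 1,
                   stringsAsFactors = FALSE)
  expect_error(simulate_reads(tx, 10L, read_len = 200L), "shortest transcript")
  expect_error(simulate_reads(tx, 10L, read_len = 100L, frag_mean = 50))
  tx$abundance <- 0
  expect_error(simulate_reads(tx, 10L), "abundance")
})

test_that("junction-crossing truth labels follow fragment geometry", {
  tx <- data.frame(id = "F", seq = random_dna_fixed(2000L), abundance = 1,
                   junction = 1000L, stringsAsFactors = FALSE)
  pairs <- simulate_reads(tx, 500L, seed = 5L)
  for (i in seq_len(nrow(pairs))) {
    expect_identical(pairs$m1_crossing[i],
                     pairs$m1_start[i] <= 1000L && pairs$m1_end[i] >= 1001L)
    expect_identical(pairs$m2_crossing[i],
                     pairs$m2_start[i] <= 1000L && pairs$m2_end[i] >= 1001L)
  }
})

test_that("simulate_cohort_tables labels and self-reference behave", {
  sim <- simulate_cohort_tables(cohort_config())
  expect_identical(nrow(sim$truth), 38L)
  expect_identical(sum(sim$truth$label == "positive"), 1L)
  expect_identical(sim$truth$sample[sim$truth$label == "positive"], "S14R")

  q <- quantify_qpcr(sim$ct, "S14R")
  expect_equal(q$rel_level[q$sample == "S14R"], 1.0)

  # deterministic for a fixed seed
  sim2 <- simulate_cohort_tables(cohort_config())
  expect_identical(sim, sim2)
})

test_that("cohort background rpkm matches its configured mean (sampling oracle)", {
  cfg <- cohort_config()
  sim <- simulate_cohort_tables(cfg)
  cnt <- quantify_counts(sim$counts)
  bg <- cnt[cnt$gene_id == "ACCEPTOR_LIKE" &
              !cnt$sample %in% c("S14", "S14R"), ]
  se3 <- 3 * 10 / sqrt(nrow(bg))
  expect_lt(abs(mean(bg$rpkm) - 15), se3)
})
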