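# fabricate align_read-shaped results for classification tests
mk_full_res <- function(ref, strand, start, end, mm = 0L, n_best = 1L) {
  list(full = data.frame(
    ref = ref, strand = strand, target_start = start, target_end = end,
    read_start = 1L, read_end = end - start + 1L,
    matched = end - start + 1L - mm, mismatches = mm, stringsAsFactors = FALSE
  ), split = fusionscan:::empty_split_df(),
  n_best_full = n_best, n_best_split_pairs = 0L)
}
mk_split_res <- function(sa, n_pairs = 1L) {
  list(full = fusionscan:::empty_full_df(), split = sa,
       n_best_full = 0L, n_best_split_pairs = n_pairs)
}
mk_none_res <- function() {
  list(full = fusionscan:::empty_full_df(), split = fusionscan:::empty_split_df(),
       n_best_full = 0L, n_best_split_pairs = 0L)
}

test_that("build_index counts and queries k-mers on both strands", {
  idx <- build_index(c(R1 = "ACGTACGTACGTACGT"), k = 8L)
  hits <- query_index(idx, "ACGTACGT")
  fwd <- hits[hits$strand == "+", ]
  expect_identical(sort(fwd$pos), c(1L, 5L, 9L))
  # ACGTACGT is its own reverse complement, so the minus strand mirrors it
  expect_identical(sort(hits$pos[hits$strand == "-"]), c(1L, 5L, 9L))

  expect_identical(nrow(query_index(idx, "AAAAAAAA")), 0L)
  expect_error(build_index(character(0)), "empty")
  expect_error(build_index(c(R1 = "ACGTACGTACGT"), k = 4L), ">= 8")
  expect_error(query_index(idx, "ACGT"), "length")
})

test_that("indexed k-mers are sound: every stored position matches", {
  set.seed(11)
  refs <- c(A = random_dna(120L), B = random_dna(150L))
  idx <- build_index(refs, k = 13L)
  ext <- c(refs, revcomp(refs))
  strandof <- c("+", "+", "-", "-"); refof <- c("A", "B", "A", "B")
  kmers <- sample(ls(idx$env), 25L)
  for (km in kmers) {
    h <- query_index(idx, km)
    expect_gt(nrow(h), 0L)
    for (i in seq_len(nrow(h))) {
      t <- which(refof == h$ref[i] & strandof == h$strand[i])
      expect_identical(substr(ext[[t]], h$pos[i], h$pos[i] + 12L), km)
    }
  }
})

test_that("align_read places exact full-length reads on both strands", {
  gm <- tiny_genome()
  refs <- vapply(names(gm$genes), function(g) gene_tx_seq(gm, g), character(1))
  idx <- build_index(refs)
  g1 <- names(refs)[1L]

  read <- substr(refs[[g1]], 151L, 250L)
  res <- align_read(read, idx)
  expect_gte(nrow(res$full), 1L)
  top <- res$full[1L, ]
  expect_identical(top$ref, g1)
  expect_identical(top$strand, "+")
  expect_identical(c(top$target_start, top$target_end), c(151L, 250L))
  expect_identical(top$mismatches, 0L)
  expect_identical(nrow(res$split), 0L)

  rc <- align_read(revcomp(read), idx)
  rtop <- rc$full[1L, ]
  expect_identical(rtop$ref, g1)
  expect_identical(rtop$strand, "-")
  expect_identical(c(rtop$target_start, rtop$target_end), c(151L, 250L))

  expect_error(align_read(substr(read, 1L, 20L), idx), "shorter")
})

test_that("align_read recovers an exact 50|50 chimeric read", {
  gm <- tiny_genome()
  refs <- vapply(names(gm$genes), function(g) gene_tx_seq(gm, g), character(1))
  idx <- build_index(refs)
  gA <- names(refs)[1L]; gB <- names(refs)[2L]
  read <- paste0(substr(refs[[gA]], 201L, 250L), substr(refs[[gB]], 101L, 150L))

  res <- align_read(read, idx)
  expect_identical(nrow(res$full), 0L)
  expect_gte(nrow(res$split), 1L)
  top <- res$split[1L, ]
  expect_identical(top$strand, "+")
  expect_identical(c(top$left_ref, top$right_ref), c(gA, gB))
  expect_identical(c(top$left_matched, top$right_matched), c(50L, 50L))
  expect_identical(top$mismatches, 0L)
  expect_identical(top$left_target_end, 250L)
  expect_identical(top$right_target_start, 101L)

  # the reverse-complemented read yields the same junction on strand "-"
  rc <- align_read(revcomp(read), idx)
  rtop <- rc$split[1L, ]
  expect_identical(rtop$strand, "-")
  expect_identical(c(rtop$left_ref, rtop$right_ref), c(gB, gA))
  expect_identical(rtop$mismatches, 0L)
})

test_that("a chimeric read with 3 substitutions has no candidate (oracle agrees)", {
  gm <- tiny_genome()
  refs <- vapply(names(gm$genes), function(g) gene_tx_seq(gm, g), character(1))
  idx <- build_index(refs)
  gA <- names(refs)[1L]; gB <- names(refs)[2L]
  read <- paste0(substr(refs[[gA]], 201L, 250L), substr(refs[[gB]], 101L, 150L))
  flip <- function(s, i) {
    old <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1L]
    s
  }
  bad <- flip(flip(flip(read, 10L), 25L), 80L)

  res <- align_read(bad, idx, max_mismatches = 2L)
  expect_identical(nrow(res$full), 0L)
  expect_identical(nrow(res$split), 0L)
  expect_identical(oracle_align(bad, refs, max_mismatches = 2L)$type, "none")
})

test_that("filter_spanning_read applies the anchor and mismatch criteria", {
  acc <- function(l, r, lmm = 0L, rmm = 0L, ...)
    filter_spanning_read(split_alignment("A", "B", l, r, lmm, rmm), ...)
  expect_identical(acc(13L, 87L), list(accept = TRUE, reason = "ok"))
  expect_identical(acc(12L, 88L), list(accept = FALSE, reason = "anchor"))
  expect_identical(acc(20L, 77L, 2L, 1L), list(accept = FALSE, reason = "mismatch"))
  # per-side budget: 2 + 1 mismatches pass when counted per side
  expect_true(acc(20L, 77L, 2L, 1L, per_side_mismatches = TRUE)$accept)
  expect_false(acc(20L, 74L, 3L, 0L, per_side_mismatches = TRUE)$accept)
})

test_that("spanning-read acceptance is monotone and never violates bounds", {
  set.seed(21)
  recs <- lapply(1:200, function(i)
    split_alignment("A", "B",
                    sample(8:40, 1L), sample(8:40, 1L),
                    sample(0:3, 1L), sample(0:2, 1L)))
  acc <- function(a, m) vapply(recs, function(r)
    filter_spanning_read(r, min_anchor = a, max_mismatches = m)$accept,
    logical(1))
  base <- acc(13L, 2L)
  expect_true(all(acc(14L, 2L) <= base))   # raising the anchor never adds
  expect_true(all(acc(13L, 1L) <= base))   # tightening mismatches never adds
  for (i in which(base)) {
    r <- recs[[i]]
    expect_gte(r$left_matched, 13L)
    expect_gte(r$right_matched, 13L)
    expect_lte(r$mismatches, 2L)
  }
})

test_that("classify_pair routes pairs into the documented categories", {
  set.seed(31)
  gm <- plain_genome(c(80L, 80L, 80L))
  sa <- split_alignment("PG01", "PG02", 50L, 50L,
                        left_target_end = 60L, right_target_start = 40L)

  # split mate + full mate in the 3' partner: spanning read that also bridges
  cl <- classify_pair(mk_split_res(sa), mk_full_res("PG02", "-", 101L, 200L),
                      gm, "r1")
  expect_identical(cl$category, "spanning_read")
  expect_identical(cl$evidence$gene5, "PG01")
  expect_identical(cl$evidence$gene3, "PG02")
  expect_true(cl$evidence$bridges)
  # genomic breakpoints via the exon map (single-exon genes at known offsets)
  expect_identical(cl$evidence$bp5, tx_to_genome(gm$genes[["PG01"]], 60L))
  expect_identical(cl$evidence$bp3, tx_to_genome(gm$genes[["PG02"]], 40L))

  # split mate + full mate in an unrelated gene: spanning read, no bridge
  cl2 <- classify_pair(mk_split_res(sa), mk_full_res("PG03", "-", 1L, 100L),
                       gm, "r2")
  expect_identical(cl2$category, "spanning_read")
  expect_false(cl2$evidence$bridges)

  # both mates full-length in one gene: concordant
  cl3 <- classify_pair(mk_full_res("PG01", "+", 1L, 100L),
                       mk_full_res("PG01", "-", 151L, 250L), gm, "r3")
  expect_identical(cl3$category, "concordant")
  expect_null(cl3$evidence)

  # full-length mates in two genes, opposite orientations: spanning pair
  cl4 <- classify_pair(mk_full_res("PG01", "+", 200L, 299L),
                       mk_full_res("PG02", "-", 1L, 100L), gm, "r4")
  expect_identical(cl4$category, "spanning_pair")
  expect_identical(cl4$evidence$gene5, "PG01")
  expect_identical(cl4$evidence$gene3, "PG02")
  expect_true(is.na(cl4$evidence$bp5))

  # same orientation cannot come from one fused fragment: unassigned
  cl5 <- classify_pair(mk_full_res("PG01", "+", 200L, 299L),
                       mk_full_res("PG02", "+", 1L, 100L), gm, "r5")
  expect_identical(cl5$category, "unassigned")

  # implied fragment longer than max_pair_span: unassigned
  cl6 <- classify_pair(mk_full_res("PG01", "+", 1L, 100L),
                       mk_full_res("PG02", "-", 201L, 300L), gm, "r6",
                       max_pair_span = 300L)
  expect_identical(cl6$category, "unassigned")

  # ambiguous placements are dropped
  cl7 <- classify_pair(mk_full_res("PG01", "+", 1L, 100L, n_best = 2L),
                       mk_full_res("PG02", "-", 1L, 100L), gm, "r7")
  expect_identical(cl7$category, "multimapper")

  # unmapped mates
  cl8 <- classify_pair(mk_none_res(), mk_none_res(), gm, "r8")
  expect_identical(cl8$category, "unassigned")
})

test_that("error-free junction-crossing reads yield accepted spanning reads", {
  gm <- tiny_genome()
  chroms <- vapply(gm$genes, function(g) g$chromosome, character(1))
  donor <- names(gm$genes)[1L]
  acceptor <- names(gm$genes)[chroms != chroms[[1L]]][1L]
  ev <- engineer_fusion(gm, donor, acceptor)
  ft <- build_fusion_transcript(gm, ev)

  refs <- vapply(names(gm$genes), function(g) gene_tx_seq(gm, g), character(1))
  idx <- build_index(refs)
  pairs <- simulate_reads(
    data.frame(id = "F", seq = ft$seq, abundance = 1,
               junction = ft$junction_offset, stringsAsFactors = FALSE),
    60L, error_rate = 0, seed = 9L)
  crossing <- pairs[pairs$m1_crossing | pairs$m2_crossing, ]
  expect_gt(nrow(crossing), 0L)

  n_ok <- 0L
  for (i in seq_len(nrow(crossing))) {
    r1 <- align_read(crossing$seq1[i], idx)
    r2 <- align_read(crossing$seq2[i], idx)
    cl <- classify_pair(r1, r2, gm, crossing$read_id[i])
    if (cl$category == "spanning_read") {
      expect_identical(cl$evidence$gene5, donor)
      expect_identical(cl$evidence$gene3, acceptor)
      expect_identical(cl$evidence$bp5, ev$donor_break$genomic_coord)
      expect_identical(cl$evidence$bp3, ev$acceptor_break$genomic_coord)
      n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok, 1L)
})
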