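# Seeded toy-genome generator: random chromosomes carrying protein-coding
# genes with designed transcripts, so every downstream stage of the pipeline
# can run without any external reference.

#' Default configuration for the synthetic genome
#'
#' Sizes emulate a small multi-chromosome transcriptome: compact
#' multi-exon genes with UTRs, a coding region free of internal stop codons,
#' and enough spacing that intrachromosomal gene pairs sit at least the
#' fusion locus-distance threshold apart.
#'
#' @param ... overrides for any default field.
#' @return a named list of generator parameters.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_chromosomes = 2L,
    chrom_length = 500000L,
    n_genes = 6L,
    exons_per_gene = c(3L, 4L),
    exon_length = c(200L, 400L),
    intron_length = c(300L, 1500L),
    utr5_length = c(30L, 80L),
    utr3_length = c(60L, 150L),
    min_intra_distance = 100000L,
    seed = 14L
  )
  utils::modifyList(cfg, list(...))
}

#' Generate a seeded toy genome
#'
#' Chromosome sequences are random; each gene's transcript (5' UTR, a coding
#' region built from sense codons with a single terminal stop, 3' UTR) is
#' designed first and then written into the exon positions of the chromosome
#' (reverse-complemented for minus-strand genes), so the annotation and the
#' sequence always agree. Deterministic for a fixed seed.
#'
#' @param config a list from [synth_config()].
#' @return a `genome_model`.
#' @export
make_genome <- function(config = synth_config()) {
  stopifnot(config$n_chromosomes >= 1L, config$n_genes >= 1L,
            all(config$exon_length > 0L), all(config$intron_length > 0L))
  with_seed(config$seed, make_genome_impl(config))
}

make_genome_impl <- function(config) {
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  # chromosome assignment: round-robin, so >= 2 chromosomes always receive
  # genes when n_genes >= n_chromosomes
  gene_chrom <- rep_len(seq_len(config$n_chromosomes), config$n_genes)

  rint <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)

  plans <- lapply(seq_len(config$n_genes), function(i) {
    n_ex <- rint(config$exons_per_gene)
    exlen <- vapply(seq_len(n_ex), function(j) rint(config$exon_length), integer(1))
    inlen <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(j) rint(config$intron_length), integer(1))
    else integer(0)
    utr5 <- rint(config$utr5_length)
    utr3 <- rint(config$utr3_length)
    tx_len <- sum(exlen)
    cds_len <- tx_len - utr5 - utr3
    utr3 <- utr3 + cds_len %% 3L  # keep CDS a multiple of 3
    cds_len <- cds_len - cds_len %% 3L
    if (cds_len < 9L)
      stop("capacity error: exon/UTR ranges leave no room for a coding region")
    list(id = sprintf("GENE%02d", i), n_ex = n_ex, exlen = exlen, inlen = inlen,
         utr5 = utr5, utr3 = utr3, tx_len = tx_len, cds_len = cds_len,
         span = sum(exlen) + sum(inlen),
         strand = sample(c("+", "-"), 1L))
  })

  # placement: per chromosome, one gene per equal-width slot with a random
  # offset inside the slot; guarantees no overlap and, with >= 2 genes per
  # chromosome, inter-slot separations of at least one slot width
  starts <- integer(config$n_genes)
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(gene_chrom == ci)
    if (length(idx) == 0L) next
    slot <- config$chrom_length %/% length(idx)
    for (j in seq_along(idx)) {
      sp <- plans[[idx[j]]]$span
      if (sp + 2L >= slot)
        stop("capacity error: gene span (", sp,
             " bp) does not fit the chromosome slot (", slot, " bp)")
      # offsets are confined to the first half of the slot so consecutive
      # genes are always >= slot/2 apart
      off_max <- min(slot - sp - 1L, slot %/% 2L)
      starts[idx[j]] <- (j - 1L) * slot + 1L + sample.int(off_max, 1L)
    }
    if (length(idx) >= 2L) {
      sep <- diff(range(starts[idx]))
      if (sep < config$min_intra_distance)
        stop("capacity error: cannot place two genes ",
             config$min_intra_distance, " bp apart on a ",
             config$chrom_length, " bp chromosome")
    }
  }

  # chromosome sequences as base vectors (patched with gene sequence below)
  chroms <- lapply(chrom_names, function(cn)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(chroms) <- chrom_names

  genes <- vector("list", config$n_genes)
  codons <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_len(config$n_genes)) {
    p <- plans[[i]]
    cn <- chrom_names[gene_chrom[i]]
    # exon genomic intervals
    ex_start <- starts[i] + cumsum(c(0L, p$exlen[-p$n_ex] + p$inlen))
    exons <- cbind(start = ex_start, end = ex_start + p$exlen - 1L)
    # designed transcript: UTR5 + ATG + sense codons + stop + UTR3
    n_codons <- p$cds_len %/% 3L - 2L
    cds_seq <- paste0("ATG",
                      paste(sample(codons, n_codons, replace = TRUE), collapse = ""),
                      sample(stops, 1L))
    tx <- paste0(random_dna(p$utr5), cds_seq, random_dna(p$utr3))
    # patch the chromosome: genomic-order sequence of the exons
    gseq <- if (p$strand == "-") revcomp(tx) else tx
    gvec <- strsplit(gseq, "", fixed = TRUE)[[1]]
    off <- 0L
    for (e in seq_len(p$n_ex)) {
      w <- p$exlen[e]
      chroms[[cn]][exons[e, "start"]:exons[e, "end"]] <- gvec[(off + 1L):(off + w)]
      off <- off + w
    }
    # CDS genomic sub-intervals via the transcript map (unvalidated shell:
    # only the exon structure is needed for the coordinate mapping)
    g0 <- structure(list(gene_id = p$id, chromosome = cn, strand = p$strand,
                         exons = exons), class = "gene_model")
    cds_tx <- (p$utr5 + 1L):(p$utr5 + p$cds_len)
    cds_g <- sort(tx_to_genome(g0, cds_tx))
    cds <- positions_to_intervals(cds_g)
    # two domains on the encoded protein: an N-terminal and a C-terminal block
    prot_len <- p$cds_len %/% 3L - 1L
    third <- max(1L, prot_len %/% 3L)
    domains <- data.frame(
      name = paste0(p$id, c("_Nterm", "_Cterm")),
      aa_start = c(1L, prot_len - third + 1L),
      aa_end = c(third, prot_len)
    )
    genes[[i]] <- gene_model(p$id, cn, p$strand, exons, cds, domains)
  }

  chromosomes <- vapply(chroms, paste, character(1), collapse = "")
  gm <- genome_model(chromosomes, genes)

  # post-conditions promised to downstream stages
  if (config$n_chromosomes >= 2L &&
      length(unique(gene_chrom)) < 2L)
    stop("internal error: no interchromosomal gene pair")
  gm
}
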