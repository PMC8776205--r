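# Independent oracles and small fixture builders used across the suite.

# internal helpers used by fixtures/oracles
cds_tx_range <- fusionscan:::cds_tx_range
gene_protein <- fusionscan:::gene_protein
sense_codons <- fusionscan:::sense_codons
random_dna <- fusionscan:::random_dna

# deterministic random DNA, independent of the test's RNG stream
random_dna_fixed <- function(n, seed = n) {
  fusionscan:::with_seed(seed, random_dna(n))
}

# A tiny two-gene genome for alignment tests (one gene per chromosome).
tiny_genome <- function(seed = 14L, n_genes = 2L, n_chromosomes = 2L,
                        chrom_length = 20000L) {
  make_genome(synth_config(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    n_genes = n_genes, min_intra_distance = chrom_length %/% 4L, seed = seed
  ))
}

# Build a hand-made single-exon plus-strand gene whose CDS encodes
# `n_aa` residues (excluding the stop codon), flanked by UTRs. Returns the
# gene model and the chromosome sequence it lives on.
plain_gene <- function(gene_id, n_aa, utr5 = 30L, utr3 = 30L,
                       chromosome = "chrT", offset = 0L) {
  cds <- paste0("ATG",
                paste(sample(sense_codons(), n_aa - 1L, replace = TRUE),
                      collapse = ""),
                "TAA")
  tx <- paste0(random_dna(utr5), cds, random_dna(utr3))
  exons <- matrix(c(offset + 1L, offset + nchar(tx)), ncol = 2L)
  cds_iv <- matrix(c(offset + utr5 + 1L, offset + utr5 + nchar(cds)), ncol = 2L)
  list(gene = gene_model(gene_id, chromosome, "+", exons, cds_iv),
       seq = tx)
}

# Genome made of hand-built plain genes laid end to end on one chromosome.
plain_genome <- function(n_aa_list, gap = 50L) {
  offset <- 0L
  genes <- list(); chrom <- character(0)
  for (i in seq_along(n_aa_list)) {
    pg <- plain_gene(sprintf("PG%02d", i), n_aa_list[[i]], offset = offset)
    genes[[i]] <- pg$gene
    chrom <- c(chrom, pg$seq, random_dna(gap))
    offset <- offset + nchar(pg$seq) + gap
  }
  genome_model(c(chrT = paste(chrom, collapse = "")), genes)
}

# ---- exhaustive split-alignment oracle -------------------------------------
#
# Brute-force scan over every (partition point x left position x right
# position) triple for every reference on both strands, mirroring the
# aligner's conventions: full-length placements take precedence; split
# segments are at least `min_seg` long, share the read orientation, and
# map to different genes; best = fewest mismatches, then longest minimum
# side, then longer left segment, then lower left/right coordinates.

oracle_align <- function(read, refs, max_mismatches = 2L, min_seg = 13L) {
  L <- nchar(read)
  rraw <- charToRaw(read)
  targets <- list()
  for (nm in names(refs)) {
    targets[[length(targets) + 1L]] <- list(ref = nm, strand = "+", seq = refs[[nm]])
    targets[[length(targets) + 1L]] <- list(ref = nm, strand = "-",
                                            seq = revcomp(refs[[nm]]))
  }

  # per-target cumulative mismatch matrix: column d (read-diagonal, i.e.
  # target position of read base 1, possibly <= 0) holds cumsum over read
  # positions; out-of-range bases contribute 0 and are excluded via bounds
  per_target <- lapply(targets, function(tg) {
    Tlen <- nchar(tg$seq)
    traw <- charToRaw(tg$seq)
    dvals <- (2L - L):Tlen
    idx <- outer(0:(L - 1L), dvals, "+")  # target positions
    inr <- idx >= 1L & idx <= Tlen
    tb <- array(as.raw(0), dim(idx))
    tb[inr] <- traw[idx[inr]]
    neq <- (tb != rraw) & inr
    cs <- apply(neq, 2L, cumsum)
    list(ref = tg$ref, strand = tg$strand, Tlen = Tlen, dvals = dvals, cs = cs)
  })

  # full-length
  best_full <- NULL; n_best_full <- 0L
  for (pt in per_target) {
    ok <- which(pt$dvals >= 1L & pt$dvals + L - 1L <= pt$Tlen)
    if (length(ok) == 0L) next
    mm <- pt$cs[L, ok]
    hit <- ok[mm <= max_mismatches]
    for (h in hit) {
      rec <- list(mm = pt$cs[L, h], ref = pt$ref, strand = pt$strand,
                  d = pt$dvals[h])
      if (is.null(best_full) || rec$mm < best_full$mm) {
        best_full <- rec; n_best_full <- 1L
      } else if (rec$mm == best_full$mm) {
        n_best_full <- n_best_full + 1L
      }
    }
  }
  if (!is.null(best_full))
    return(list(type = "full", mm = best_full$mm, n_best_full = n_best_full))

  # split: for each partition and target, minimal left-prefix and
  # right-suffix mismatch placements
  best <- NULL
  better <- function(a, b) {  # TRUE if a sorts before b
    key <- function(x) list(x$mm, -min(x$p, L - x$p), -x$p, x$lref, x$lstart,
                            x$rref, x$rstart)
    ka <- key(a); kb <- key(b)
    for (i in seq_along(ka)) {
      if (is.character(ka[[i]])) {
        if (ka[[i]] < kb[[i]]) return(TRUE)
        if (ka[[i]] > kb[[i]]) return(FALSE)
      } else {
        if (ka[[i]] < kb[[i]]) return(TRUE)
        if (ka[[i]] > kb[[i]]) return(FALSE)
      }
    }
    FALSE
  }
  fwd <- function(q1, q2, strand, Tlen) {
    if (strand == "+") c(q1, q2) else c(Tlen - q2 + 1L, Tlen - q1 + 1L)
  }
  for (p in seq.int(min_seg, L - min_seg)) {
    for (a in per_target) {
      okL <- which(a$dvals >= 1L & a$dvals + p - 1L <= a$Tlen)
      if (length(okL) == 0L) next
      mmL <- a$cs[p, okL]
      okL <- okL[mmL <= max_mismatches]
      if (length(okL) == 0L) next
      for (b in per_target) {
        if (b$strand != a$strand || b$ref == a$ref) next
        okR <- which(b$dvals + p >= 1L & b$dvals + L - 1L <= b$Tlen)
        if (length(okR) == 0L) next
        mmR <- b$cs[L, okR] - b$cs[p, okR]
        okR <- okR[mmR <= max_mismatches]
        if (length(okR) == 0L) next
        for (da in okL) {
          for (db in okR) {
            tot <- a$cs[p, da] + (b$cs[L, db] - b$cs[p, db])
            if (tot > max_mismatches) next
            lf <- fwd(a$dvals[da], a$dvals[da] + p - 1L, a$strand, a$Tlen)
            rf <- fwd(b$dvals[db] + p, b$dvals[db] + L - 1L, b$strand, b$Tlen)
            rec <- list(mm = tot, p = p, lref = a$ref, rref = b$ref,
                        strand = a$strand,
                        lstart = lf[1], lend = lf[2],
                        rstart = rf[1], rend = rf[2])
            if (is.null(best) || better(rec, best)) best <- rec
          }
        }
      }
    }
  }
  if (is.null(best)) return(list(type = "none"))
  c(list(type = "split"), best)
}

# ---- brute-force reading-frame oracle --------------------------------------
#
# A junction is in frame iff the acceptor's downstream codons are read in
# their native frame. Brute-force check: translate the stitched sequence
# codon by codon from the donor start codon (keeping stop symbols), take the
# first 10 residues encoded entirely by acceptor bases (i.e. after the
# junction-spanning codon is completed), and test whether that 10-mer is a
# substring of the acceptor's native protein. In frame, it is a native
# stretch by construction; out of frame, a shifted-frame decamer (often
# containing stops) does not occur in the native protein.
frame_oracle <- function(genome, donor, acceptor, b5, a3) {
  dg <- genome$genes[[donor]]; ag <- genome$genes[[acceptor]]
  dtx <- gene_tx_seq(genome, dg); atx <- gene_tx_seq(genome, ag)
  dr <- cds_tx_range(dg)
  prefix <- substr(dtx, dr["start"], min(b5, dr["end"]))
  donor_len <- nchar(prefix)
  fill <- (3L - donor_len %% 3L) %% 3L   # bases completing the junction codon
  stitched <- paste0(prefix, substr(atx, a3, nchar(atx)))
  aa_full <- translate_keep_stops(stitched)
  pos_aa <- (donor_len + fill) %/% 3L + 1L
  probe <- substr(aa_full, pos_aa, pos_aa + 9L)
  p3 <- gene_protein(genome, ag)
  nchar(probe) == 10L && grepl(probe, p3, fixed = TRUE)
}

# full-length codon translation, stop codons kept as '*'
translate_keep_stops <- function(cds) {
  n3 <- nchar(cds) - nchar(cds) %% 3L
  if (n3 < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n3)), no.init.codon = TRUE)))
}

# Random fusion spec (breakpoints inside both CDSs, with enough coding
# sequence on each side for the frame oracle to be well defined).
random_fusion_spec <- function(genome) {
  ids <- names(genome$genes)
  pick <- sample(ids, 2L)
  dg <- genome$genes[[pick[1]]]; ag <- genome$genes[[pick[2]]]
  dr <- cds_tx_range(dg); ar <- cds_tx_range(ag)
  b5 <- sample(seq.int(dr["start"] + 17L, dr["end"] - 3L), 1L)
  a3 <- sample(seq.int(ar["start"], ar["end"] - 35L), 1L)
  list(donor = pick[1], acceptor = pick[2], b5 = b5, a3 = a3)
}
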