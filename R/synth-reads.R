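# Paired-end read simulator over an arbitrary transcriptome, with exact
# truth labels. Fragments are drawn per transcript proportional to
# abundance x length, fragment sizes are Gaussian, orientation of each
# fragment is flipped with probability 1/2 (the library is simulated
# strand-agnostically), and sequencing noise is substitution-only.

#' Simulate paired-end reads from a transcriptome
#'
#' @param transcriptome data.frame with columns `id`, `seq`, `abundance`,
#'   and optionally `junction` (transcript offset of the last 5'-partner
#'   base for fusion transcripts, `NA` otherwise).
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp (both mates).
#' @param frag_mean,frag_sd fragment-size distribution (bp).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return data.frame with one row per pair: `read_id`, `seq1`, `seq2`,
#'   `source` (transcript id), fragment coordinates, per-mate transcript
#'   intervals/strands, and per-mate `crossing` flags (whether the mate's
#'   transcript interval spans the junction).
#' @export
simulate_reads <- function(transcriptome, n_pairs, read_len = 100L,
                           frag_mean = 250, frag_sd = 30,
                           error_rate = 0, seed = 14L) {
  stopifnot(n_pairs >= 1L, read_len >= 1L, frag_mean >= read_len)
  if (is.null(transcriptome$junction)) transcriptome$junction <- NA_integer_
  len <- nchar(transcriptome$seq)
  if (read_len > min(len))
    stop("read length (", read_len, ") exceeds the shortest transcript (",
         min(len), " nt)")
  ab <- transcriptome$abundance
  if (any(ab < 0) || all(ab == 0)) stop("abundances must be >= 0 and not all zero")

  with_seed(seed, {
    src <- sample.int(nrow(transcriptome), n_pairs, replace = TRUE,
                      prob = ab * len)
    tlen <- len[src]
    fl <- pmin(tlen, pmax(read_len, round(stats::rnorm(n_pairs, frag_mean, frag_sd))))
    start <- 1L + floor(stats::runif(n_pairs) * (tlen - fl + 1))
    flip <- stats::runif(n_pairs) < 0.5

    frag <- substring(transcriptome$seq[src], start, start + fl - 1L)
    head_seq <- substring(frag, 1L, read_len)
    tail_rc <- revcomp(substring(frag, fl - read_len + 1L, fl))
    seq1 <- ifelse(flip, tail_rc, head_seq)
    seq2 <- ifelse(flip, head_seq, tail_rc)

    # per-mate transcript intervals (sense coordinates) and strands
    head_s <- start; head_e <- start + read_len - 1L
    tail_s <- as.integer(start + fl - read_len); tail_e <- as.integer(start + fl - 1L)
    m1 <- cbind(ifelse(flip, tail_s, head_s), ifelse(flip, tail_e, head_e))
    m2 <- cbind(ifelse(flip, head_s, tail_s), ifelse(flip, head_e, tail_e))
    strand1 <- ifelse(flip, "-", "+")
    strand2 <- ifelse(flip, "+", "-")

    j <- transcriptome$junction[src]
    crossing <- function(iv) !is.na(j) & iv[, 1L] <= j & iv[, 2L] >= j + 1L

    if (error_rate > 0) {
      seq1 <- add_substitutions(seq1, error_rate)
      seq2 <- add_substitutions(seq2, error_rate)
    }

    data.frame(
      read_id = sprintf("read%06d", seq_len(n_pairs)),
      seq1 = seq1, seq2 = seq2,
      source = transcriptome$id[src],
      frag_start = start, frag_len = as.integer(fl), flipped = flip,
      m1_start = m1[, 1L], m1_end = m1[, 2L], m1_strand = strand1,
      m2_start = m2[, 1L], m2_end = m2[, 2L], m2_strand = strand2,
      m1_crossing = crossing(m1), m2_crossing = crossing(m2),
      stringsAsFactors = FALSE
    )
  })
}

# Independent per-base substitutions; a substituted base is always changed.
add_substitutions <- function(seqs, rate) {
  rl <- nchar(seqs[1L])
  n_bases <- length(seqs) * rl
  hits <- which(stats::runif(n_bases) < rate)
  if (length(hits) == 0L) return(seqs)
  read_i <- (hits - 1L) %/% rl + 1L
  pos_i <- (hits - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (h in seq_along(hits)) {
    old <- substr(seqs[read_i[h]], pos_i[h], pos_i[h])
    new <- sample(setdiff(bases, old), 1L)
    substr(seqs[read_i[h]], pos_i[h], pos_i[h]) <- new
  }
  seqs
}

#' Write simulated pairs as a pair of FASTQ files plus a truth table
#'
#' Mate files are `<prefix>_1.fq` / `<prefix>_2.fq` with constant Phred+33
#' quality, and the truth labels go to `<prefix>_truth.tsv`.
#'
#' @param pairs output of [simulate_reads()].
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly, the paths written.
#' @export
write_read_pairs <- function(pairs, dir, prefix = "reads") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_1.fq"))
  p2 <- file.path(dir, paste0(prefix, "_2.fq"))
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fastq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  write_fastq(pairs$seq1, paste0(pairs$read_id, "/1"), p1)
  write_fastq(pairs$seq2, paste0(pairs$read_id, "/2"), p2)
  write_tsv(pairs[, setdiff(names(pairs), c("seq1", "seq2"))], pt)
  invisible(c(mate1 = p1, mate2 = p2, truth = pt))
}

#' Read a pair of FASTQ mate files
#'
#' @param mate1,mate2 FASTQ paths.
#' @return data.frame with `read_id`, `seq1`, `seq2`.
#' @export
read_read_pairs <- function(mate1, mate2) {
  r1 <- Biostrings::readDNAStringSet(mate1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(mate2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  data.frame(
    read_id = sub("/1$", "", sub("\\s.*$", "", names(r1))),
    seq1 = as.character(r1), seq2 = as.character(r2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
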