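# Aggregation of fusion evidence into candidates and the paper-style
# locus / support filters.

#' Aggregate fusion evidence into candidates
#'
#' One candidate per ordered (gene5, gene3) pair. The consensus breakpoint
#' is the modal joint spanning-read breakpoint, ties broken toward the
#' lowest coordinate pair; candidates supported only by pairs carry gene
#' midpoints as nominal coordinates and no junction.
#'
#' Counting modes for spanning pairs: `"inclusive"` (default) also counts a
#' pair whose split mate spans the junction while its other mate lies in
#' the partner gene, i.e. every fragment bridging the two genes;
#' `"exclusive"` counts only pairs with no junction-crossing mate.
#'
#' @param evidence data.frame of evidence records from [classify_pair()].
#' @param genome a `genome_model`.
#' @param pair_count_mode `"inclusive"` or `"exclusive"`.
#' @return data.frame of candidates (`gene5`, `gene3`, `chrom5`, `bp5`,
#'   `chrom3`, `bp3`, `spanning_reads`, `spanning_pairs`, `has_junction`).
#' @export
cluster_evidence <- function(evidence, genome,
                             pair_count_mode = c("inclusive", "exclusive")) {
  pair_count_mode <- match.arg(pair_count_mode)
  if (is.null(evidence) || nrow(evidence) == 0L) return(empty_candidate_df())
  key <- paste(evidence$gene5, evidence$gene3, sep = "\r")
  out <- lapply(split(evidence, key), function(ev) {
    sr <- ev[ev$kind == "spanning_read", , drop = FALSE]
    sp <- ev[ev$kind == "spanning_pair", , drop = FALSE]
    n_pairs <- nrow(sp) +
      if (pair_count_mode == "inclusive") sum(sr$bridges) else 0L
    g5 <- genome$genes[[ev$gene5[1L]]]
    g3 <- genome$genes[[ev$gene3[1L]]]
    if (nrow(sr) > 0L) {
      bp_key <- paste(sr$bp5, sr$bp3)
      tab <- table(bp_key)
      best <- names(tab)[tab == max(tab)]
      # ties -> lowest coordinate pair
      bp <- do.call(rbind, lapply(strsplit(best, " "), as.integer))
      bp <- bp[order(bp[, 1L], bp[, 2L]), , drop = FALSE][1L, ]
      has_junction <- TRUE
    } else {
      bp <- c(gene_midpoint(g5), gene_midpoint(g3))
      has_junction <- FALSE
    }
    data.frame(
      gene5 = ev$gene5[1L], gene3 = ev$gene3[1L],
      chrom5 = g5$chromosome, chrom3 = g3$chromosome,
      bp5 = bp[1L], bp3 = bp[2L],
      spanning_reads = nrow(sr), spanning_pairs = n_pairs,
      has_junction = has_junction, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

gene_midpoint <- function(g) {
  as.integer((min(g$exons[, "start"]) + max(g$exons[, "end"])) %/% 2L)
}

empty_candidate_df <- function() {
  data.frame(gene5 = character(0), gene3 = character(0),
             chrom5 = character(0), bp5 = integer(0),
             chrom3 = character(0), bp3 = integer(0),
             spanning_reads = integer(0), spanning_pairs = integer(0),
             has_junction = logical(0), stringsAsFactors = FALSE)
}

#' Locus filter: different chromosomes or far apart on one chromosome
#'
#' @param candidate one-row candidate data.frame (or list) with `chrom5`,
#'   `chrom3`, `bp5`, `bp3`.
#' @param min_intra_distance minimum same-chromosome breakpoint separation
#'   in bp (default 100 kbp).
#' @return `TRUE` when the candidate's two sides lie on different
#'   chromosomes, or on the same chromosome separated by at least
#'   `min_intra_distance`.
#' @export
locus_filter <- function(candidate, min_intra_distance = 100000L) {
  if (is.na(candidate$chrom5) || is.na(candidate$chrom3))
    stop("unannotated gene in candidate")
  if (candidate$chrom5 != candidate$chrom3) return(TRUE)
  abs(candidate$bp5 - candidate$bp3) >= min_intra_distance
}

#' Support filter: minimum spanning-read and spanning-pair counts
#'
#' @param candidate one-row candidate data.frame (or list) with
#'   `spanning_reads` and `spanning_pairs`.
#' @param min_spanning_reads,min_spanning_pairs support thresholds
#'   (default 10 and 10).
#' @export
support_filter <- function(candidate, min_spanning_reads = 10L,
                           min_spanning_pairs = 10L) {
  candidate$spanning_reads >= min_spanning_reads &&
    candidate$spanning_pairs >= min_spanning_pairs
}

#' Rank candidates by support
#'
#' Descending by spanning reads, then spanning pairs, then lexicographic
#' (gene5, gene3); stable and total.
#'
#' @param candidates candidate data.frame.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$spanning_reads, -candidates$spanning_pairs,
               candidates$gene5, candidates$gene3)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply locus, support and reading-frame filters to candidates
#'
#' Adds `locus_pass`, `support_pass`, `frame_status`, `protein_pass`,
#' `fail_reason` and an overall `pass` column, and attaches predicted
#' fusion proteins for in-frame candidates with a junction.
#'
#' @param candidates output of [cluster_evidence()].
#' @param genome a `genome_model`.
#' @param config threshold list, see [fusion_config()].
#' @return list with `candidates` (annotated, ranked data.frame) and
#'   `proteins` (named list of `fusion_protein` objects for passing
#'   candidates).
#' @export
filter_candidates <- function(candidates, genome, config = fusion_config()) {
  candidates <- rank_candidates(candidates)
  n <- nrow(candidates)
  locus <- logical(n); support <- logical(n)
  frame <- character(n); ppass <- logical(n); reason <- character(n)
  proteins <- list()
  for (i in seq_len(n)) {
    cand <- candidates[i, , drop = FALSE]
    locus[i] <- locus_filter(cand, config$min_intra_distance)
    support[i] <- support_filter(cand, config$min_spanning_reads,
                                 config$min_spanning_pairs)
    if (cand$has_junction) {
      g5 <- genome$genes[[cand$gene5]]
      g3 <- genome$genes[[cand$gene3]]
      orf <- assess_fusion_orf(genome, g5, g3,
                               genome_to_tx(g5, cand$bp5),
                               genome_to_tx(g3, cand$bp3),
                               config$min_partner_aa)
      frame[i] <- orf$frame_status
      ppass[i] <- orf$pass
      if (orf$pass)
        proteins[[paste(cand$gene5, cand$gene3, sep = "-")]] <- orf$protein
    } else {
      frame[i] <- "undetermined"
      ppass[i] <- FALSE
    }
    reason[i] <- if (!locus[i]) "locus"
      else if (!support[i]) "support"
      else if (frame[i] != "in_frame") "frame"
      else if (!ppass[i]) "protein_length"
      else "ok"
  }
  candidates$locus_pass <- locus
  candidates$support_pass <- support
  candidates$frame_status <- frame
  candidates$protein_pass <- ppass
  candidates$fail_reason <- reason
  candidates$pass <- locus & support & (frame == "in_frame") & ppass
  list(candidates = candidates, proteins = proteins)
}
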