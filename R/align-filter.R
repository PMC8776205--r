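# Spanning-read acceptance criteria and read-pair classification.

#' Construct a split alignment record
#'
#' Convenience constructor for a two-segment (chimeric) alignment, mainly
#' for building test inputs; [align_read()] produces the same shape.
#'
#' @param left_ref,right_ref reference (gene) names of the two segments.
#' @param left_matched,right_matched matched bases per segment.
#' @param left_mismatches,right_mismatches mismatches per segment.
#' @param strand shared read orientation (`"+"` or `"-"`).
#' @param left_target_end,right_target_start junction-adjacent reference
#'   coordinates.
#' @return one-row data.frame in the [align_read()] split layout.
#' @export
split_alignment <- function(left_ref, right_ref,
                            left_matched, right_matched,
                            left_mismatches = 0L, right_mismatches = 0L,
                            strand = "+",
                            left_target_end = left_matched + left_mismatches,
                            right_target_start = 1L) {
  left_len <- left_matched + left_mismatches
  right_len <- right_matched + right_mismatches
  data.frame(
    left_ref = left_ref, right_ref = right_ref, strand = strand,
    left_target_start = left_target_end - left_len + 1L,
    left_target_end = left_target_end,
    right_target_start = right_target_start,
    right_target_end = right_target_start + right_len - 1L,
    left_read_start = 1L, left_read_end = left_len,
    right_read_start = left_len + 1L, right_read_end = left_len + right_len,
    left_matched = left_matched, right_matched = right_matched,
    left_mismatches = left_mismatches, right_mismatches = right_mismatches,
    mismatches = left_mismatches + right_mismatches,
    left_diag = NA_integer_, right_diag = NA_integer_,
    partition = left_len, stringsAsFactors = FALSE
  )
}

#' Accept or reject a junction-spanning split read
#'
#' A split read is accepted when both segments carry at least `min_anchor`
#' matched bases and the read's total mismatch count does not exceed
#' `max_mismatches`. With `per_side_mismatches = TRUE` the mismatch budget
#' is applied to each segment separately instead of to the whole read.
#'
#' @param split a split alignment (one-row data.frame or list with
#'   `left_matched`, `right_matched`, `left_mismatches`,
#'   `right_mismatches`).
#' @param min_anchor minimum matched bases on each side of the junction.
#' @param max_mismatches mismatch budget.
#' @param per_side_mismatches apply the budget per side rather than per
#'   read.
#' @return list with `accept` (logical) and `reason` (`"ok"`, `"anchor"` or
#'   `"mismatch"`; the first failed criterion).
#' @export
filter_spanning_read <- function(split, min_anchor = 13L, max_mismatches = 2L,
                                 per_side_mismatches = FALSE) {
  lm <- split$left_matched; rm_ <- split$right_matched
  lmm <- split$left_mismatches; rmm <- split$right_mismatches
  if (lm < min_anchor || rm_ < min_anchor)
    return(list(accept = FALSE, reason = "anchor"))
  mm_ok <- if (per_side_mismatches)
    lmm <= max_mismatches && rmm <= max_mismatches
  else
    lmm + rmm <= max_mismatches
  if (!mm_ok) return(list(accept = FALSE, reason = "mismatch"))
  list(accept = TRUE, reason = "ok")
}

# Orientation-normalized junction of a split row: the 5' (donor) gene is
# the one the read enters first in fused-mRNA orientation.
split_junction <- function(split_row) {
  if (split_row$strand == "+") {
    list(gene5 = split_row$left_ref, bp5_tx = split_row$left_target_end,
         gene3 = split_row$right_ref, bp3_tx = split_row$right_target_start)
  } else {
    list(gene5 = split_row$right_ref, bp5_tx = split_row$right_target_end,
         gene3 = split_row$left_ref, bp3_tx = split_row$left_target_start)
  }
}

mate_status <- function(res, min_anchor, max_mismatches, per_side = FALSE) {
  if (nrow(res$full) > 0L) {
    if (res$n_best_full > 1L) return(list(status = "multi"))
    return(list(status = "full", hit = res$full[1L, , drop = FALSE]))
  }
  if (nrow(res$split) > 0L) {
    if (res$n_best_split_pairs > 1L) return(list(status = "multi"))
    for (i in seq_len(nrow(res$split))) {
      f <- filter_spanning_read(res$split[i, , drop = FALSE],
                                min_anchor, max_mismatches, per_side)
      if (f$accept)
        return(list(status = "split", hit = res$split[i, , drop = FALSE]))
    }
  }
  list(status = "none")
}

#' Classify a read pair as fusion evidence
#'
#' A pair yields at most one evidence record. A mate with an accepted split
#' alignment gives `spanning_read` evidence (with a junction); otherwise two
#' full-length mates in two different genes, one sense and one antisense
#' with an implied fragment no longer than `max_pair_span`, give
#' `spanning_pair` evidence. Both mates inside one gene are `concordant`;
#' ambiguous placements are dropped as `multimapper`; everything else is
#' `unassigned`.
#'
#' @param res1,res2 [align_read()] results for the two mates.
#' @param genome a `genome_model` (for transcript-to-genome conversion).
#' @param read_id identifier recorded in the evidence.
#' @param min_anchor,max_mismatches spanning-read acceptance criteria.
#' @param per_side_mismatches see [filter_spanning_read()].
#' @param max_pair_span upper bound on the implied fused-fragment length for
#'   spanning pairs, measured to the partner transcript ends (a permissive
#'   bound, since the junction is unknown at this stage).
#' @return list with `category` (`"spanning_read"`, `"spanning_pair"`,
#'   `"concordant"`, `"multimapper"`, `"unassigned"`) and `evidence` (one-row
#'   data.frame or `NULL`).
#' @export
classify_pair <- function(res1, res2, genome, read_id = NA_character_,
                          min_anchor = 13L, max_mismatches = 2L,
                          per_side_mismatches = FALSE,
                          max_pair_span = 10000L) {
  m <- list(mate_status(res1, min_anchor, max_mismatches, per_side_mismatches),
            mate_status(res2, min_anchor, max_mismatches, per_side_mismatches))
  st <- vapply(m, `[[`, character(1), "status")
  if (any(st == "multi"))
    return(list(category = "multimapper", evidence = NULL))

  ev_row <- function(kind, gene5, gene3, bp5_tx = NA, bp3_tx = NA, bridges = FALSE) {
    g5 <- genome$genes[[gene5]]; g3 <- genome$genes[[gene3]]
    data.frame(
      read_id = read_id, kind = kind, gene5 = gene5, gene3 = gene3,
      chrom5 = g5$chromosome, chrom3 = g3$chromosome,
      bp5_tx = as.integer(bp5_tx), bp3_tx = as.integer(bp3_tx),
      bp5 = if (is.na(bp5_tx)) NA_integer_ else tx_to_genome(g5, bp5_tx),
      bp3 = if (is.na(bp3_tx)) NA_integer_ else tx_to_genome(g3, bp3_tx),
      bridges = bridges, stringsAsFactors = FALSE
    )
  }

  split_i <- which(st == "split")
  if (length(split_i) > 0L) {
    i <- split_i[1L]
    j <- split_junction(m[[i]]$hit)
    other <- m[[3L - i]]
    bridges <- (other$status == "full" &&
                  other$hit$ref %in% c(j$gene5, j$gene3)) ||
      (other$status == "split" &&
         setequal(c(other$hit$left_ref, other$hit$right_ref),
                  c(j$gene5, j$gene3)))
    return(list(category = "spanning_read",
                evidence = ev_row("spanning_read", j$gene5, j$gene3,
                                  j$bp5_tx, j$bp3_tx, bridges)))
  }

  if (all(st == "full")) {
    h1 <- m[[1L]]$hit; h2 <- m[[2L]]$hit
    if (h1$ref == h2$ref)
      return(list(category = "concordant", evidence = NULL))
    strands <- c(h1$strand, h2$strand)
    if (setequal(strands, c("+", "-"))) {
      sense <- if (h1$strand == "+") h1 else h2
      anti <- if (h1$strand == "+") h2 else h1
      gene5 <- sense$ref; gene3 <- anti$ref
      implied <- (tx_length(genome$genes[[gene5]]) - sense$target_start + 1L) +
        anti$target_end
      if (implied <= max_pair_span)
        return(list(category = "spanning_pair",
                    evidence = ev_row("spanning_pair", gene5, gene3,
                                      bridges = TRUE)))
    }
    return(list(category = "unassigned", evidence = NULL))
  }

  list(category = "unassigned", evidence = NULL)
}
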