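# Expression quantification: rpkm from counts, cohort summaries
# (index samples vs background mean +/- SD), and delta-delta-Ct relative
# qPCR quantification with the positivity rule.

#' Reads per kilobase of exon model per million mapped reads
#'
#' @param read_count reads mapped to the gene (each mate counted
#'   separately; divide by 2 upstream for a fragment-based variant).
#' @param exon_model_length exon model length in nt.
#' @param total_mapped_reads total mapped reads in the sample.
#' @return rpkm value(s).
#' @export
compute_rpkm <- function(read_count, exon_model_length, total_mapped_reads) {
  if (any(exon_model_length <= 0) || any(total_mapped_reads <= 0))
    stop("exon model length and total mapped reads must be positive")
  read_count / ((exon_model_length / 1000) * (total_mapped_reads / 1e6))
}

#' Cohort summary: index values versus background mean and SD
#'
#' @param values named numeric vector of per-sample values (e.g. rpkm) for
#'   one gene.
#' @param index_samples names of the index samples, excluded from the
#'   background statistics.
#' @return list with `index` (named values), `background_mean`,
#'   `background_sd` (sample SD, n-1 denominator), `n_background`.
#' @export
cohort_summary <- function(values, index_samples = character(0)) {
  idx <- names(values) %in% index_samples
  bg <- values[!idx]
  if (length(bg) < 2L) stop("need at least 2 background samples")
  list(index = values[idx],
       background_mean = mean(bg),
       background_sd = stats::sd(bg),
       n_background = length(bg))
}

#' Relative expression by delta-delta-Ct
#'
#' `2^-((ct_target - ct_refgene) - reference_delta_ct)`, assuming 100%
#' amplification efficiency. An undetermined (NA) target Ct yields a
#' relative level of 0; an undetermined reference-gene Ct is an error (the
#' sample cannot be normalized).
#'
#' @param ct_target,ct_refgene Ct values (technical replicates already
#'   averaged on the Ct scale).
#' @param reference_delta_ct delta-Ct of the designated reference-positive
#'   sample.
#' @return relative level (fold of the reference sample).
#' @export
relative_expression <- function(ct_target, ct_refgene, reference_delta_ct) {
  if (any(is.na(ct_refgene)))
    stop("undetermined reference-gene Ct: sample invalid")
  out <- 2^-((ct_target - ct_refgene) - reference_delta_ct)
  out[is.na(ct_target)] <- 0
  out
}

#' Positivity call from a relative fusion-expression level
#'
#' Negative iff the level is strictly below `negative_cutoff` (default
#' 1/10 of the reference-positive sample); positive otherwise.
#'
#' @param rel_level relative level(s), >= 0.
#' @param negative_cutoff cutoff (default 0.1).
#' @return character vector `"positive"` / `"negative"`.
#' @export
call_positivity <- function(rel_level, negative_cutoff = 0.1) {
  if (any(rel_level < 0)) stop("relative levels must be >= 0")
  ifelse(rel_level < negative_cutoff, "negative", "positive")
}

#' Quantify a qPCR Ct table
#'
#' Averages technical replicates on the Ct scale, computes relative levels
#' against the designated reference sample, and calls positivity.
#'
#' @param ct data.frame with a `sample` column plus `target_ct_*` and
#'   `ref_ct_*` replicate columns (NA = undetermined).
#' @param reference_sample sample defining relative level 1.
#' @param negative_cutoff see [call_positivity()].
#' @return data.frame with `sample`, `ct_target`, `ct_reference`,
#'   `rel_level`, `call`.
#' @export
quantify_qpcr <- function(ct, reference_sample, negative_cutoff = 0.1) {
  tgt_cols <- grep("^target_ct", names(ct), value = TRUE)
  ref_cols <- grep("^ref_ct", names(ct), value = TRUE)
  if (length(tgt_cols) == 0L || length(ref_cols) == 0L)
    stop("Ct table must have target_ct_* and ref_ct_* columns")
  ct_t <- rowMeans(ct[, tgt_cols, drop = FALSE])
  ct_r <- rowMeans(ct[, ref_cols, drop = FALSE])
  ri <- match(reference_sample, ct$sample)
  if (is.na(ri)) stop("reference sample '", reference_sample, "' not in table")
  ref_delta <- ct_t[ri] - ct_r[ri]
  if (is.na(ref_delta)) stop("reference sample has undetermined Ct")
  rel <- relative_expression(ct_t, ct_r, ref_delta)
  data.frame(sample = ct$sample, ct_target = ct_t, ct_reference = ct_r,
             rel_level = rel, call = call_positivity(rel, negative_cutoff),
             stringsAsFactors = FALSE)
}

#' Per-gene rpkm table from a cohort counts table
#'
#' @param counts data.frame with `sample`, `gene_id`, `count`, `exon_len`,
#'   `total_mapped`.
#' @return the input with an `rpkm` column appended.
#' @export
quantify_counts <- function(counts) {
  counts$rpkm <- compute_rpkm(counts$count, counts$exon_len, counts$total_mapped)
  counts
}
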