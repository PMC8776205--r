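# Cohort-style tables: per-sample gene expression (counts convertible to
# rpkm) and RT-qPCR Ct triplicates for a fusion target normalized to a
# reference gene. The default layout mirrors a tumor cohort with one
# strongly fusion-positive index sample, its matched weakly-expressing
# primary, and a negative background.

#' Default configuration for the synthetic cohort generator
#'
#' The two default genes emulate the expression structure reported for the
#' fusion partners: one gene strongly over-expressed in the index samples
#' against a low background (mean 15, SD 10 rpkm), one with a wide
#' background (mean 202, SD 212 rpkm) and unremarkable index values.
#'
#' @param ... overrides for any default field.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_background = 36L,
    reference_sample = "S14R",     # fusion-positive index; defines rel level 1
    matched_sample = "S14",        # matched primary, weakly expressing
    matched_level = 0.02,
    background_level_range = c(1e-4, 0.03),  # relative fusion levels, all negative
    ref_ct_mean = 20, ref_ct_sd = 0.5,       # reference-gene Ct across samples
    target_delta_ct = 4,                     # index-sample delta-Ct (target - ref)
    rep_sd = 0.1,                            # technical-replicate Ct noise
    n_reps = 3L,
    total_mapped = 2e7,
    genes = data.frame(
      gene_id = c("ACCEPTOR_LIKE", "DONOR_LIKE"),
      exon_len = c(3500L, 2800L),
      background_mean = c(15, 202),
      background_sd = c(10, 212),
      index_matched = c(109, 210),
      index_reference = c(554, 31),
      stringsAsFactors = FALSE
    ),
    seed = 14L
  )
  utils::modifyList(cfg, list(...))
}

#' Simulate cohort expression and qPCR tables
#'
#' @param config a list from [cohort_config()].
#' @param dir optional output directory; when given, writes
#'   `cohort_counts.tsv`, `cohort_ct.tsv` and `cohort_truth.tsv`.
#' @return list with `counts` (sample, gene, count, exon_len, total_mapped),
#'   `ct` (sample + Ct replicate columns), and `truth` (sample, rel_level,
#'   label).
#' @export
simulate_cohort_tables <- function(config = cohort_config(), dir = NULL) {
  n_samples <- config$n_background + 2L
  if (n_samples < 3L) stop("need at least 3 samples")
  with_seed(config$seed, {
    samples <- c(config$reference_sample, config$matched_sample,
                 sprintf("BG%02d", seq_len(config$n_background)))
    lvl <- c(1.0, config$matched_level,
             exp(stats::runif(config$n_background,
                              log(config$background_level_range[1]),
                              log(config$background_level_range[2]))))
    truth <- data.frame(
      sample = samples, rel_level = lvl,
      label = ifelse(lvl >= 0.1, "positive", "negative"),
      stringsAsFactors = FALSE
    )

    # qPCR: ct_target - ct_ref = target_delta_ct - log2(level), so the
    # reference sample sits at relative level 1 by construction
    ref_ct <- stats::rnorm(n_samples, config$ref_ct_mean, config$ref_ct_sd)
    delta <- config$target_delta_ct - log2(lvl)
    reps <- function(mu) {
      m <- vapply(seq_len(config$n_reps), function(r)
        mu + stats::rnorm(n_samples, 0, config$rep_sd), numeric(n_samples))
      round(m, 3)
    }
    ct_ref <- reps(ref_ct)
    ct_tgt <- reps(ref_ct + delta)
    ct <- data.frame(sample = samples, ct_tgt, ct_ref, stringsAsFactors = FALSE)
    names(ct) <- c("sample",
                   paste0("target_ct_", seq_len(config$n_reps)),
                   paste0("ref_ct_", seq_len(config$n_reps)))

    # expression counts: index values fixed, background lognormal with the
    # configured mean/SD on the rpkm scale
    counts <- do.call(rbind, lapply(seq_len(nrow(config$genes)), function(gi) {
      g <- config$genes[gi, ]
      mu <- log(g$background_mean^2 / sqrt(g$background_sd^2 + g$background_mean^2))
      sdl <- sqrt(log(1 + (g$background_sd / g$background_mean)^2))
      rpkm <- c(g$index_reference, g$index_matched,
                stats::rlnorm(config$n_background, mu, sdl))
      data.frame(
        sample = samples, gene_id = g$gene_id,
        count = as.integer(round(rpkm * (g$exon_len / 1000) *
                                   (config$total_mapped / 1e6))),
        exon_len = g$exon_len, total_mapped = config$total_mapped,
        stringsAsFactors = FALSE
      )
    }))
    rownames(counts) <- NULL

    out <- list(counts = counts, ct = ct, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(counts, file.path(dir, "cohort_counts.tsv"))
      write_tsv(ct, file.path(dir, "cohort_ct.tsv"))
      write_tsv(truth, file.path(dir, "cohort_truth.tsv"))
    }
    out
  })
}
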