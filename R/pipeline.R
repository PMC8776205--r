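# Orchestration: simulate -> detect -> call -> annotate -> quantify.

#' Pipeline configuration with the discovery criteria as defaults
#'
#' The default thresholds are the published fusion-calling criteria:
#' spanning-read anchors of at least 13 matched bases per side with at most
#' 2 mismatches per read, partner loci on different chromosomes or at least
#' 100 kbp apart, at least 10 spanning reads and 10 spanning pairs, at
#' least 50 encoded amino acids per partner, and a qPCR negativity cutoff
#' of 1/10 of the reference-positive sample.
#'
#' @param ... overrides for any field.
#' @return a named list of thresholds and simulation parameters.
#' @export
fusion_config <- function(...) {
  cfg <- list(
    # detection thresholds
    min_anchor = 13L,
    max_mismatches = 2L,
    min_intra_distance = 100000L,
    min_spanning_reads = 10L,
    min_spanning_pairs = 10L,
    min_partner_aa = 50L,
    negative_cutoff = 0.1,
    per_side_mismatches = FALSE,
    pair_count_mode = "inclusive",
    max_pair_span = 10000L,
    seed_k = 13L,
    # simulation scenario
    scenario = c("default", "out_of_frame", "near_intra"),
    genome = synth_config(),
    read_len = 100L,
    frag_mean = 250,
    frag_sd = 30,
    error_rate = 0.001,
    junction_coverage = 30,
    n_pairs = 2500L,
    seed = 14L,
    # cohort
    cohort = cohort_config(),
    index_samples = c("S14", "S14R"),
    out_dir = NULL
  )
  cfg <- utils::modifyList(cfg, list(...))
  cfg$scenario <- match.arg(cfg$scenario, c("default", "out_of_frame", "near_intra"))
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [fusion_config()] defaults.
#' @export
read_run_config <- function(path) {
  do.call(fusion_config, yaml::read_yaml(path))
}

# Scenario setup: the genome, the engineered fusion event and the fusion
# transcript for each named scenario.
discovery_scenario <- function(config) {
  gcfg <- config$genome
  gcfg$seed <- config$seed
  if (config$scenario == "near_intra") {
    # two genes on one chromosome, forced closer than the locus threshold
    gcfg <- utils::modifyList(gcfg, list(
      n_chromosomes = 1L, n_genes = 2L, chrom_length = 100000L,
      min_intra_distance = 10000L
    ))
  }
  genome <- make_genome(gcfg)
  chroms <- vapply(genome$genes, function(g) g$chromosome, character(1))
  donor <- names(genome$genes)[1L]
  acceptor <- if (config$scenario == "near_intra") {
    names(genome$genes)[2L]
  } else {
    # first gene on a different chromosome
    names(genome$genes)[which(chroms != chroms[[donor]])[1L]]
  }
  event <- engineer_fusion(genome, donor, acceptor,
                           in_frame = config$scenario != "out_of_frame")
  fusion <- build_fusion_transcript(genome, event)
  list(genome = genome, event = event, fusion = fusion)
}

# Fusion abundance chosen so the expected number of junction-crossing
# mates equals the requested junction coverage.
fusion_abundance <- function(config, genome, fusion_len) {
  wt_len <- vapply(names(genome$genes), function(g)
    tx_length(genome$genes[[g]]), integer(1))
  placements <- fusion_len - config$frag_mean + 1
  n_fusion <- config$junction_coverage * placements / (2 * (config$read_len - 1))
  w_wt <- sum(wt_len)
  (n_fusion * w_wt) / (fusion_len * (config$n_pairs - n_fusion))
}

#' Run the single-sample fusion discovery pipeline on simulated reads
#'
#' Simulates a transcriptome carrying one engineered fusion, sequences it,
#' aligns every mate, classifies pairs into fusion evidence, aggregates and
#' filters candidates, and predicts the fusion protein and junction oligos
#' for passing candidates. Deterministic for a fixed seed.
#'
#' @param config a list from [fusion_config()].
#' @return a `discovery_report` list: `config`, `truth` (fusion event and
#'   transcript), `stage_counts`, `candidates`, `proteins`, `oligos`,
#'   `evidence`.
#' @export
run_discovery <- function(config = fusion_config()) {
  sc <- discovery_scenario(config)
  genome <- sc$genome
  fusion <- sc$fusion

  transcripts <- data.frame(
    id = names(genome$genes),
    seq = vapply(names(genome$genes), function(g)
      gene_tx_seq(genome, g), character(1)),
    abundance = 1,
    junction = NA_integer_,
    stringsAsFactors = FALSE
  )
  fus_row <- data.frame(
    id = "FUSION", seq = fusion$seq,
    abundance = fusion_abundance(config, genome, nchar(fusion$seq)),
    junction = fusion$junction_offset, stringsAsFactors = FALSE
  )
  transcriptome <- rbind(transcripts, fus_row)

  message("[simulate] ", config$n_pairs, " read pairs, scenario '",
          config$scenario, "'")
  pairs <- simulate_reads(transcriptome, config$n_pairs,
                          read_len = config$read_len,
                          frag_mean = config$frag_mean,
                          frag_sd = config$frag_sd,
                          error_rate = config$error_rate,
                          seed = config$seed)

  refs <- stats::setNames(transcripts$seq, transcripts$id)
  index <- build_index(refs, k = config$seed_k)

  message("[align] aligning ", 2L * nrow(pairs), " mates")
  counts <- c(concordant = 0L, spanning_read = 0L, spanning_pair = 0L,
              unassigned = 0L, multimapper = 0L)
  evidence <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r1 <- align_read(pairs$seq1[i], index, config$max_mismatches)
    r2 <- align_read(pairs$seq2[i], index, config$max_mismatches)
    cl <- classify_pair(r1, r2, genome, pairs$read_id[i],
                        min_anchor = config$min_anchor,
                        max_mismatches = config$max_mismatches,
                        per_side_mismatches = config$per_side_mismatches,
                        max_pair_span = config$max_pair_span)
    counts[cl$category] <- counts[cl$category] + 1L
    evidence[[i]] <- cl$evidence
  }
  evidence <- do.call(rbind, Filter(Negate(is.null), evidence))

  message("[call] ", counts["spanning_read"], " spanning reads, ",
          counts["spanning_pair"], " spanning pairs")
  candidates <- cluster_evidence(evidence, genome, config$pair_count_mode)
  filtered <- filter_candidates(candidates, genome, config)

  oligos <- list()
  for (nm in names(filtered$proteins)) {
    oligos[[nm]] <- design_junction_oligos(fusion$seq, fusion$junction_offset)
  }

  report <- structure(list(
    config = config,
    truth = list(event = fusion$event, junction_offset = fusion$junction_offset,
                 fusion_len = nchar(fusion$seq), in_frame = fusion$in_frame),
    genome = genome,
    stage_counts = c(pairs = nrow(pairs), counts),
    evidence = evidence,
    candidates = filtered$candidates,
    proteins = filtered$proteins,
    oligos = oligos
  ), class = "discovery_report")

  if (!is.null(config$out_dir)) write_discovery_report(report, config$out_dir)
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("discovery_report:", nrow(x$candidates), "candidate(s),",
      sum(x$candidates$pass), "passing all filters\n")
  invisible(x)
}

#' Write a discovery report to TSV/JSON/FASTA files
#'
#' @param report a `discovery_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_discovery_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    candidates = file.path(dir, "candidates.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    summary = file.path(dir, "report.json"),
    proteins = file.path(dir, "fusion_proteins.fa")
  )
  write_tsv(report$candidates, paths["candidates"])
  write_tsv(report$evidence %||%
              data.frame(read_id = character(0)), paths["evidence"])
  jsonlite::write_json(list(
    stage_counts = as.list(report$stage_counts),
    truth = list(donor = report$truth$event$donor_gene,
                 acceptor = report$truth$event$acceptor_gene,
                 bp5 = report$truth$event$donor_break$genomic_coord,
                 bp3 = report$truth$event$acceptor_break$genomic_coord,
                 in_frame = report$truth$in_frame),
    n_candidates = nrow(report$candidates),
    n_passing = sum(report$candidates$pass)
  ), paths["summary"], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(report$proteins) > 0L) {
    aa <- Biostrings::AAStringSet(vapply(report$proteins, `[[`, character(1),
                                         "sequence"))
    Biostrings::writeXStringSet(aa, paths["proteins"])
  } else {
    writeLines(character(0), paths["proteins"])
  }
  invisible(paths)
}

#' Run the cohort quantification pipeline
#'
#' Computes rpkm per gene and sample from a counts table, summarizes index
#' samples against the background cohort, and calls per-sample fusion
#' positivity from the Ct table by delta-delta-Ct against the designated
#' reference-positive sample.
#'
#' @param config a list from [fusion_config()]; `config$cohort` configures
#'   the simulated tables.
#' @param tables optional list with `counts` and `ct` data.frames (e.g.
#'   read from TSV); when `NULL`, tables are simulated from
#'   `config$cohort`.
#' @return a `cohort_report` list: `qpcr` (per-sample calls), `rpkm`
#'   (per-gene summaries), `truth` (when simulated).
#' @export
run_cohort <- function(config = fusion_config(), tables = NULL) {
  truth <- NULL
  if (is.null(tables)) {
    ccfg <- config$cohort
    ccfg$seed <- config$seed
    sim <- simulate_cohort_tables(ccfg)
    tables <- sim[c("counts", "ct")]
    truth <- sim$truth
  }
  if (nrow(tables$ct) == 0L) stop("empty cohort")
  reference <- config$cohort$reference_sample
  if (!reference %in% tables$ct$sample)
    stop("missing reference sample designation: ", reference)

  qpcr <- quantify_qpcr(tables$ct, reference, config$negative_cutoff)
  counts <- quantify_counts(tables$counts)
  rpkm_summaries <- lapply(split(counts, counts$gene_id), function(df) {
    cohort_summary(stats::setNames(df$rpkm, df$sample), config$index_samples)
  })
  report <- structure(list(
    qpcr = qpcr, rpkm = rpkm_summaries, truth = truth,
    n_positive = sum(qpcr$call == "positive")
  ), class = "cohort_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(qpcr, file.path(config$out_dir, "qpcr_calls.tsv"))
    jsonlite::write_json(
      lapply(rpkm_summaries, function(s)
        list(index = as.list(s$index), background_mean = s$background_mean,
             background_sd = s$background_sd, n_background = s$n_background)),
      file.path(config$out_dir, "rpkm_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report:", nrow(x$qpcr), "samples,", x$n_positive, "positive\n")
  invisible(x)
}
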