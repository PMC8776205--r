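# Engineered fusion transcripts: ground truth for the detection pipeline.

#' Describe a fusion event between two genes
#'
#' Breakpoints are transcript coordinates: `donor_break` is the last donor
#' base retained (5' side), `acceptor_break` the first acceptor base
#' retained (3' side). Exon indices and genomic coordinates are derived, and
#' the expected frame status is computed from the coding annotation.
#'
#' @param genome a `genome_model`.
#' @param donor_gene,acceptor_gene distinct gene ids.
#' @param donor_break,acceptor_break transcript coordinates of the junction.
#' @return an object of class `fusion_event`.
#' @export
fusion_event <- function(genome, donor_gene, acceptor_gene,
                         donor_break, acceptor_break) {
  if (identical(donor_gene, acceptor_gene))
    stop("donor and acceptor must be distinct genes")
  dg <- genome$genes[[donor_gene]]
  ag <- genome$genes[[acceptor_gene]]
  if (is.null(dg) || is.null(ag)) stop("unknown gene")
  if (donor_break < 1L || donor_break > tx_length(dg) ||
      acceptor_break < 1L || acceptor_break > tx_length(ag))
    stop("coordinate error: breakpoint outside transcript")
  in_frame <- tryCatch({
    st <- stitch_cds(genome, dg, ag, donor_break, acceptor_break)
    is_in_frame(st$donor_cds_len_included, st$acceptor_phase_at_break)
  }, error = function(e) FALSE)
  structure(list(
    donor_gene = donor_gene,
    donor_break = list(exon_index = tx_exon_index(dg, donor_break),
                       transcript_offset = as.integer(donor_break),
                       genomic_coord = tx_to_genome(dg, donor_break)),
    acceptor_gene = acceptor_gene,
    acceptor_break = list(exon_index = tx_exon_index(ag, acceptor_break),
                          transcript_offset = as.integer(acceptor_break),
                          genomic_coord = tx_to_genome(ag, acceptor_break)),
    expected_in_frame = in_frame
  ), class = "fusion_event")
}

#' Engineer a fusion event at an exon-exon join
#'
#' Starts from the end of the donor's exon `donor_exon` joined to the start
#' of the acceptor's exon `acceptor_exon` (the exon2-exon2 architecture),
#' then shifts the acceptor breakpoint by 0-2 nt to force the requested
#' frame status, and finally slides the acceptor breakpoint inward in codon
#' steps (preserving frame) until the junction has zero microhomology, so
#' the true breakpoint is identifiable at single-base resolution.
#'
#' @param genome a `genome_model`.
#' @param donor_gene,acceptor_gene distinct gene ids.
#' @param in_frame engineer an in-frame (`TRUE`) or frameshifted (`FALSE`)
#'   junction.
#' @param donor_exon,acceptor_exon exon indices of the join.
#' @return a `fusion_event`.
#' @export
engineer_fusion <- function(genome, donor_gene, acceptor_gene,
                            in_frame = TRUE,
                            donor_exon = 2L, acceptor_exon = 2L) {
  dg <- genome$genes[[donor_gene]]
  ag <- genome$genes[[acceptor_gene]]
  dw <- exon_widths(dg); if (dg$strand == "-") dw <- rev(dw)
  aw <- exon_widths(ag); if (ag$strand == "-") aw <- rev(aw)
  donor_break <- sum(dw[seq_len(donor_exon)])
  acceptor_break <- sum(aw[seq_len(acceptor_exon - 1L)]) + 1L

  st <- stitch_cds(genome, dg, ag, donor_break, acceptor_break)
  want_phase <- st$donor_cds_len_included %% 3L
  shift <- ((want_phase - st$acceptor_phase_at_break) %% 3L + 3L) %% 3L
  if (!in_frame) shift <- (shift + 1L) %% 3L
  acceptor_break <- acceptor_break + shift

  dtx <- gene_tx_seq(genome, dg)
  atx <- gene_tx_seq(genome, ag)
  no_homology <- function(b5, a3) {
    substr(dtx, b5 + 1L, b5 + 1L) != substr(atx, a3, a3) &&
      substr(atx, a3 - 1L, a3 - 1L) != substr(dtx, b5, b5)
  }
  for (step in seq(0L, 30L, by = 3L)) {
    if (no_homology(donor_break, acceptor_break + step)) {
      acceptor_break <- acceptor_break + step
      break
    }
  }
  fusion_event(genome, donor_gene, acceptor_gene, donor_break, acceptor_break)
}

#' Build the fusion mRNA for a fusion event
#'
#' @param genome a `genome_model`.
#' @param event a `fusion_event`.
#' @return list with `seq` (fusion mRNA), `junction_offset` (transcript
#'   position of the last donor base), `cds` (stitched coding sequence, or
#'   `NULL` for a non-coding junction), `in_frame`, and the `event` with its
#'   `expected_in_frame` recomputed.
#' @export
build_fusion_transcript <- function(genome, event) {
  dg <- genome$genes[[event$donor_gene]]
  ag <- genome$genes[[event$acceptor_gene]]
  if (is.null(dg) || is.null(ag)) stop("unknown gene in fusion event")
  b5 <- event$donor_break$transcript_offset
  a3 <- event$acceptor_break$transcript_offset
  dtx <- gene_tx_seq(genome, dg)
  atx <- gene_tx_seq(genome, ag)
  if (b5 < 1L || b5 > nchar(dtx) || a3 < 1L || a3 > nchar(atx))
    stop("coordinate error: breakpoint outside transcript")
  seq <- paste0(substr(dtx, 1L, b5), substr(atx, a3, nchar(atx)))
  st <- tryCatch(stitch_cds(genome, dg, ag, b5, a3), error = function(e) NULL)
  in_frame <- !is.null(st) &&
    is_in_frame(st$donor_cds_len_included, st$acceptor_phase_at_break)
  event$expected_in_frame <- in_frame
  list(seq = seq, junction_offset = b5, cds = st$cds %||% NULL,
       in_frame = in_frame, event = event)
}
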