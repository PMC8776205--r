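# Reading-frame arithmetic and fusion-protein prediction.
#
# A fusion joins a donor (5') transcript prefix to an acceptor (3')
# transcript suffix. Breakpoints are transcript coordinates: `donor_break`
# is the last donor base retained, `acceptor_break` the first acceptor base
# retained. The junction is in frame when the acceptor's downstream codons
# are read in their native frame, i.e. when the number of donor coding bases
# retained is congruent (mod 3) to the acceptor breakpoint's phase within
# its own coding region.

#' Stitch the coding sequence of a fusion transcript
#'
#' Concatenates the donor CDS prefix (from the donor start codon up to the
#' breakpoint, capped at the donor's own stop) with the acceptor transcript
#' from the breakpoint through its 3' end (which contains the acceptor's
#' native stop codon), and returns the two quantities frame arithmetic
#' needs.
#'
#' @param genome a `genome_model`.
#' @param donor,acceptor gene ids or `gene_model`s.
#' @param donor_break last retained donor transcript position.
#' @param acceptor_break first retained acceptor transcript position.
#' @return list with `cds` (stitched sequence), `donor_cds_len_included`,
#'   `acceptor_phase_at_break`, and bookkeeping fields used by
#'   [predict_fusion_protein()].
#' @export
stitch_cds <- function(genome, donor, acceptor, donor_break, acceptor_break) {
  dg <- if (inherits(donor, "gene_model")) donor else genome$genes[[donor]]
  ag <- if (inherits(acceptor, "gene_model")) acceptor else genome$genes[[acceptor]]
  if (is.null(dg) || is.null(ag)) stop("unknown gene")
  dtx <- gene_tx_seq(genome, dg)
  atx <- gene_tx_seq(genome, ag)
  if (donor_break < 1L || donor_break > nchar(dtx) ||
      acceptor_break < 1L || acceptor_break > nchar(atx))
    stop("coordinate error: breakpoint outside transcript")
  dr <- cds_tx_range(dg)
  ar <- cds_tx_range(ag)
  if (donor_break < dr["start"])
    stop("no coding prefix: donor breakpoint upstream of the start codon")
  donor_len <- as.integer(min(donor_break, dr["end"]) - dr["start"] + 1L)
  phase <- as.integer(((acceptor_break - ar["start"]) %% 3L + 3L) %% 3L)
  stitched <- paste0(
    substr(dtx, dr["start"], min(donor_break, dr["end"])),
    substr(atx, acceptor_break, nchar(atx))
  )
  list(
    cds = stitched,
    donor_cds_len_included = donor_len,
    acceptor_phase_at_break = phase,
    acceptor_cds_offset = as.integer(acceptor_break - ar["start"]),
    donor_gene = dg$gene_id, acceptor_gene = ag$gene_id
  )
}

#' Is a fusion junction in frame?
#'
#' @param donor_cds_len_included donor coding bases retained 5' of the
#'   junction.
#' @param acceptor_phase_at_break phase (0/1/2) of the acceptor breakpoint
#'   within the acceptor's coding region.
#' @return `TRUE` when the acceptor's downstream codons are read in their
#'   native frame.
#' @export
is_in_frame <- function(donor_cds_len_included, acceptor_phase_at_break) {
  donor_cds_len_included %% 3L == acceptor_phase_at_break %% 3L
}

#' Predict the fusion protein and apply the per-partner length filter
#'
#' Translates the stitched CDS from the donor start codon to the first stop,
#' attributes residues to each partner (the codon spanning the junction is
#' assigned to the 5' partner), maps the acceptor-derived residues to their
#' native coordinates in the acceptor protein, and computes the fraction of
#' each annotated domain retained in the fusion. The filter passes when both
#' partners contribute at least `min_partner_aa` residues; a premature stop
#' shortly after the junction therefore fails regardless of nominal exon
#' lengths.
#'
#' @param genome a `genome_model`.
#' @param stitched result of [stitch_cds()].
#' @param min_partner_aa minimum residues per partner (default 50).
#' @return list with `protein` (a `fusion_protein` list: `sequence`,
#'   `partner5_interval`, `partner3_interval`, `acceptor_native_interval`,
#'   `retained_domains`), `pass`, and `reason`.
#' @export
predict_fusion_protein <- function(genome, stitched, min_partner_aa = 50L) {
  if (!is_in_frame(stitched$donor_cds_len_included,
                   stitched$acceptor_phase_at_break))
    stop("contract violation: predict_fusion_protein requires an in-frame junction")
  tr <- translate_cds(stitched$cds)
  pep <- tr$peptide
  plen <- nchar(pep)
  donor_len <- stitched$donor_cds_len_included
  n5 <- min(as.integer(ceiling(donor_len / 3)), plen)
  n3 <- plen - n5

  dg <- genome$genes[[stitched$donor_gene]]
  ag <- genome$genes[[stitched$acceptor_gene]]

  # native acceptor residue span of the acceptor-derived part
  junction_fill <- (3L - donor_len %% 3L) %% 3L
  a_off <- stitched$acceptor_cds_offset
  native <- if (a_off >= 0L && n3 > 0L) {
    start <- (a_off + junction_fill) %/% 3L + 1L
    c(start = start, end = start + n3 - 1L)
  } else NULL

  retained <- retained_domain_fractions(
    donor_domains = dg$domains, donor_span = if (n5 > 0L) c(1L, n5) else NULL,
    acceptor_domains = ag$domains,
    acceptor_span = if (!is.null(native)) c(native["start"], native["end"]) else NULL
  )

  protein <- structure(list(
    sequence = pep,
    partner5_interval = if (n5 > 0L) c(start = 1L, end = n5) else NULL,
    partner3_interval = if (n3 > 0L) c(start = n5 + 1L, end = plen) else NULL,
    acceptor_native_interval = native,
    retained_domains = retained,
    donor_gene = dg$gene_id, acceptor_gene = ag$gene_id
  ), class = "fusion_protein")

  reason <- NULL
  if (n5 < min_partner_aa) reason <- "donor_aa"
  else if (n3 < min_partner_aa) reason <- "acceptor_aa"
  list(protein = protein, pass = is.null(reason), reason = reason %||% "ok")
}

retained_domain_fractions <- function(donor_domains, donor_span,
                                      acceptor_domains, acceptor_span) {
  frac <- function(domains, span) {
    if (is.null(span) || nrow(domains) == 0L) return(NULL)
    ov <- pmax(0L, pmin(domains$aa_end, span[2]) - pmax(domains$aa_start, span[1]) + 1L)
    data.frame(name = domains$name,
               fraction = ov / (domains$aa_end - domains$aa_start + 1L))
  }
  out <- rbind(frac(donor_domains, donor_span), frac(acceptor_domains, acceptor_span))
  if (is.null(out))
    out <- data.frame(name = character(0), fraction = numeric(0))
  out
}

#' Frame status and protein prediction for a transcript-coordinate junction
#'
#' Convenience wrapper combining [stitch_cds()], [is_in_frame()] and
#' [predict_fusion_protein()]; non-coding junctions (donor break in the
#' 5' UTR) are reported as failing rather than raising.
#'
#' @inheritParams stitch_cds
#' @param min_partner_aa minimum residues per partner.
#' @return list with `frame_status` (`"in_frame"`, `"out_of_frame"` or
#'   `"undetermined"`), `pass`, `reason`, and `protein` (or `NULL`).
#' @export
assess_fusion_orf <- function(genome, donor, acceptor, donor_break,
                              acceptor_break, min_partner_aa = 50L) {
  st <- tryCatch(
    stitch_cds(genome, donor, acceptor, donor_break, acceptor_break),
    error = function(e) e
  )
  if (inherits(st, "error")) {
    return(list(frame_status = "undetermined", pass = FALSE,
                reason = conditionMessage(st), protein = NULL, stitched = NULL))
  }
  if (!is_in_frame(st$donor_cds_len_included, st$acceptor_phase_at_break)) {
    return(list(frame_status = "out_of_frame", pass = FALSE,
                reason = "out_of_frame", protein = NULL, stitched = st))
  }
  pr <- predict_fusion_protein(genome, st, min_partner_aa)
  list(frame_status = "in_frame", pass = pr$pass, reason = pr$reason,
       protein = pr$protein, stitched = st)
}

#' Worked example: fusion protein from an external annotation
#'
#' Builds gene models for a donor and an acceptor gene from a genome FASTA
#' and GTF (plus an optional protein-domain TSV), joins the end of the
#' donor's exon `donor_exon` to the start of the acceptor's exon
#' `acceptor_exon`, and predicts the fusion protein. With human annotation
#' for SPON1 and TRIM29 this reproduces the exon2-exon2 fusion protein
#' (SPON1 residues 1-115 joined to TRIM29 residues 267-588).
#'
#' @param fasta,gtf,domains annotation files, as in [read_genome()].
#' @param donor,acceptor gene ids present in the GTF.
#' @param donor_exon,acceptor_exon 1-based exon indices in transcript order.
#' @param min_partner_aa minimum residues per partner.
#' @return the [assess_fusion_orf()] result.
#' @export
fusion_protein_from_annotation <- function(fasta, gtf, domains = NULL,
                                           donor, acceptor,
                                           donor_exon = 2L, acceptor_exon = 2L,
                                           min_partner_aa = 50L) {
  genome <- read_genome(fasta, gtf, domains)
  dg <- genome$genes[[donor]]
  ag <- genome$genes[[acceptor]]
  if (is.null(dg) || is.null(ag)) stop("donor/acceptor gene not in annotation")
  dw <- exon_widths(dg)
  if (dg$strand == "-") dw <- rev(dw)
  aw <- exon_widths(ag)
  if (ag$strand == "-") aw <- rev(aw)
  donor_break <- sum(dw[seq_len(donor_exon)])
  acceptor_break <- sum(aw[seq_len(acceptor_exon - 1L)]) + 1L
  assess_fusion_orf(genome, dg, ag, donor_break, acceptor_break, min_partner_aa)
}
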