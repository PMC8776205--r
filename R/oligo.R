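# Junction-spanning oligo design: RT-qPCR primers flanking the fusion
# point and siRNA cores covering it. Design is positional only (the
# source protocol reports sequences, not thermodynamic criteria).

#' Design junction-spanning primers and siRNAs for a fusion mRNA
#'
#' The forward primer lies wholly 5' of the junction (on the donor side)
#' and the reverse primer wholly 3' of it, so the amplicon always spans the
#' fusion point. Every siRNA candidate core covers the junction with at
#' least `sirna_min_overlap` bases on each side; the antisense strand is
#' the reverse complement of the sense core, and both are decorated with a
#' dTdT overhang in the output.
#'
#' @param mrna fusion mRNA sequence.
#' @param junction_offset transcript position of the last donor base.
#' @param primer_len primer length range (bp).
#' @param amplicon_max maximum amplicon length (bp).
#' @param sirna_len siRNA core length range (nt).
#' @param sirna_min_overlap minimum core overlap on each side of the
#'   junction (nt).
#' @return list with `valid`, `forward`, `reverse`, `amplicon`
#'   (data.frames/lists of sequence and coordinates) and `sirna`
#'   (data.frame of candidate cores); `valid = FALSE` with empty slots when
#'   the junction is too close to a transcript end.
#' @export
design_junction_oligos <- function(mrna, junction_offset,
                                   primer_len = c(18L, 22L),
                                   amplicon_max = 150L,
                                   sirna_len = c(19L, 21L),
                                   sirna_min_overlap = 5L) {
  L <- nchar(mrna)
  j <- as.integer(junction_offset)
  if (j < 1L || j >= L) stop("junction offset outside the transcript")

  no_design <- list(valid = FALSE, forward = NULL, reverse = NULL,
                    amplicon = NULL,
                    sirna = data.frame(sense = character(0),
                                       antisense = character(0),
                                       start = integer(0), end = integer(0),
                                       overlap5 = integer(0),
                                       overlap3 = integer(0)))

  # primers: the largest length in range that fits both flanks and the
  # amplicon bound, placed adjacent to the junction
  pl <- max(primer_len)
  while (pl >= min(primer_len) && (pl > j || pl > L - j || 2L * pl > amplicon_max))
    pl <- pl - 1L
  if (pl < min(primer_len)) return(no_design)
  fw <- substr(mrna, j - pl + 1L, j)
  rv_site <- substr(mrna, j + 1L, j + pl)
  res <- list(
    valid = TRUE,
    forward = list(seq = fw, start = j - pl + 1L, end = j),
    reverse = list(seq = revcomp(rv_site), start = j + 1L, end = j + pl),
    amplicon = list(start = j - pl + 1L, end = j + pl, length = 2L * pl)
  )

  # siRNA cores: all windows in the length range covering the junction with
  # the required overlap on both sides
  rows <- list()
  for (s in seq(min(sirna_len), max(sirna_len))) {
    a_lo <- max(1L, j + sirna_min_overlap - s + 1L)
    a_hi <- min(L - s + 1L, j - sirna_min_overlap + 1L)
    if (a_hi < a_lo) next
    for (a in a_lo:a_hi) {
      core <- substr(mrna, a, a + s - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sense = paste0(chartr("T", "U", core), "dTdT"),
        antisense = paste0(chartr("T", "U", revcomp(core)), "dTdT"),
        start = a, end = a + s - 1L,
        overlap5 = j - a + 1L, overlap3 = a + s - 1L - j,
        stringsAsFactors = FALSE
      )
    }
  }
  res$sirna <- if (length(rows) > 0L) do.call(rbind, rows) else no_design$sirna
  res
}
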