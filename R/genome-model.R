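# Gene and genome containers. Intervals are 1-based inclusive genomic
# coordinates, the IRanges/GTF convention used throughout the package.

#' Construct a gene model
#'
#' A gene model carries the exon structure of a single-transcript gene, the
#' coding region as genomic sub-intervals of the exons, and optional protein
#' domain intervals in amino-acid coordinates.
#'
#' @param gene_id gene identifier (also used as the transcript id).
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (1-based,
#'   inclusive), non-overlapping and sorted by genomic coordinate.
#' @param cds integer matrix of coding sub-intervals of the exons; the total
#'   coding length (including the stop codon) must be a multiple of 3.
#' @param domains data.frame with columns `name`, `aa_start`, `aa_end` on the
#'   encoded protein.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds,
                       domains = data.frame(name = character(0),
                                            aa_start = integer(0),
                                            aa_end = integer(0))) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  g <- structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         exons = exons, cds = cds, domains = domains),
    class = "gene_model"
  )
  validate_gene_model(g)
  g
}

validate_gene_model <- function(g) {
  ex <- g$exons
  if (nrow(ex) == 0L) stop("gene ", g$gene_id, ": no exons")
  if (any(ex[, "end"] < ex[, "start"])) stop("gene ", g$gene_id, ": malformed exon")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex[, "start"], strictly = TRUE))
      stop("gene ", g$gene_id, ": exons not sorted")
    if (any(ex[-1L, "start"] <= ex[-nrow(ex), "end"]))
      stop("gene ", g$gene_id, ": overlapping exons")
  }
  if (sum(g$cds[, "end"] - g$cds[, "start"] + 1L) %% 3L != 0L)
    stop("gene ", g$gene_id, ": CDS length not a multiple of 3")
  if (nrow(g$domains) > 0L) {
    if (any(g$domains$aa_start < 1L) || any(g$domains$aa_end < g$domains$aa_start))
      stop("gene ", g$gene_id, ": malformed domain interval")
  }
  invisible(g)
}

#' Construct a genome model
#'
#' @param chromosomes named character vector of chromosome sequences
#'   (alphabet A/C/G/T).
#' @param genes list of [gene_model()] objects.
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes) {
  names(genes) <- vapply(genes, function(g) g$gene_id, character(1))
  gm <- structure(list(chromosomes = chromosomes, genes = genes),
                  class = "genome_model")
  validate_genome_model(gm)
  gm
}

validate_genome_model <- function(gm) {
  if (any(grepl("[^ACGT]", gm$chromosomes)))
    stop("chromosome sequences must be over {A,C,G,T}")
  for (g in gm$genes) {
    validate_gene_model(g)
    if (!g$chromosome %in% names(gm$chromosomes))
      stop("gene ", g$gene_id, ": unknown chromosome ", g$chromosome)
    if (max(g$exons[, "end"]) > nchar(gm$chromosomes[[g$chromosome]]))
      stop("gene ", g$gene_id, ": exon beyond chromosome end")
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chromosomes), "chromosome(s) (",
      paste(nchar(x$chromosomes), collapse = ", "), "bp ),",
      length(x$genes), "gene(s)\n")
  invisible(x)
}

# ---- transcript coordinate machinery ---------------------------------------

exon_widths <- function(g) g$exons[, "end"] - g$exons[, "start"] + 1L

#' Transcript length of a gene
#' @param g a `gene_model`.
#' @export
tx_length <- function(g) sum(exon_widths(g))

# Genomic position of every transcript position, in transcript order
# (5' -> 3' of the mRNA; reversed exon traversal on the minus strand).
tx_genomic_positions <- function(g) {
  pos <- unlist(lapply(seq_len(nrow(g$exons)), function(i)
    seq.int(g$exons[i, "start"], g$exons[i, "end"])), use.names = FALSE)
  if (g$strand == "-") rev(pos) else pos
}

#' Map a transcript coordinate to a genomic coordinate
#' @param g a `gene_model`.
#' @param pos transcript position(s), 1-based.
#' @export
tx_to_genome <- function(g, pos) {
  map <- tx_genomic_positions(g)
  if (any(pos < 1L | pos > length(map))) stop("transcript coordinate out of range")
  map[pos]
}

#' Map a genomic coordinate to a transcript coordinate
#' @param g a `gene_model`.
#' @param gpos genomic position(s); must be exonic.
#' @export
genome_to_tx <- function(g, gpos) {
  map <- tx_genomic_positions(g)
  idx <- match(gpos, map)
  if (anyNA(idx)) stop("genomic coordinate not exonic in gene ", g$gene_id)
  idx
}

#' Spliced transcript sequence of a gene
#' @param genome a `genome_model`.
#' @param gene gene id or `gene_model`.
#' @export
gene_tx_seq <- function(genome, gene) {
  g <- if (inherits(gene, "gene_model")) gene else genome$genes[[gene]]
  if (is.null(g)) stop("unknown gene: ", gene)
  chrom <- genome$chromosomes[[g$chromosome]]
  parts <- substring(chrom, g$exons[, "start"], g$exons[, "end"])
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp(s) else s
}

# CDS as a contiguous transcript interval c(start, end) (includes the stop
# codon). The CDS genomic sub-intervals always splice to one contiguous
# transcript range for a single-transcript gene.
cds_tx_range <- function(g) {
  map <- tx_genomic_positions(g)
  cds_pos <- unlist(lapply(seq_len(nrow(g$cds)), function(i)
    seq.int(g$cds[i, "start"], g$cds[i, "end"])), use.names = FALSE)
  idx <- sort(match(cds_pos, map))
  if (anyNA(idx)) stop("gene ", g$gene_id, ": CDS not within exons")
  if (any(diff(idx) != 1L)) stop("gene ", g$gene_id, ": CDS not contiguous in transcript")
  c(start = idx[1L], end = idx[length(idx)])
}

# Encoded protein (stop codon trimmed).
gene_protein <- function(genome, gene) {
  g <- if (inherits(gene, "gene_model")) gene else genome$genes[[gene]]
  r <- cds_tx_range(g)
  translate_cds(substr(gene_tx_seq(genome, g), r["start"], r["end"]))$peptide
}

# Exon index (1-based, transcript order) containing a transcript position.
tx_exon_index <- function(g, pos) {
  w <- exon_widths(g)
  if (g$strand == "-") w <- rev(w)
  findInterval(pos - 1L, cumsum(c(0L, w)), rightmost.closed = FALSE)
}

# ---- file interfaces -------------------------------------------------------

#' Write a genome model to FASTA + GTF (+ domains TSV)
#'
#' Emits `genome.fa`, `annotation.gtf` (gene/exon/CDS features with
#' `gene_id`/`transcript_id` attributes, 1-based inclusive), and
#' `domains.tsv` (protein-domain intervals, which GTF cannot carry).
#'
#' @param genome a `genome_model`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  dom <- file.path(dir, "domains.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$chromosomes), fa)
  rtracklayer::export(genome_annotation_granges(genome), gtf, format = "gtf")
  dom_df <- do.call(rbind, lapply(genome$genes, function(g) {
    if (nrow(g$domains) == 0L) return(NULL)
    data.frame(gene_id = g$gene_id, g$domains)
  }))
  if (is.null(dom_df))
    dom_df <- data.frame(gene_id = character(0), name = character(0),
                         aa_start = integer(0), aa_end = integer(0))
  write_tsv(dom_df, dom)
  invisible(c(fasta = fa, gtf = gtf, domains = dom))
}

genome_annotation_granges <- function(genome) {
  si <- GenomeInfoDb::Seqinfo(names(genome$chromosomes),
                              nchar(genome$chromosomes))
  rows <- list()
  for (g in genome$genes) {
    mk <- function(type, ivs, phase = NA_integer_) {
      GenomicRanges::GRanges(
        seqnames = g$chromosome,
        ranges = IRanges::IRanges(ivs[, "start"], ivs[, "end"]),
        strand = g$strand, type = type,
        gene_id = g$gene_id, transcript_id = g$gene_id,
        phase = phase, seqinfo = si
      )
    }
    gene_iv <- matrix(c(min(g$exons[, "start"]), max(g$exons[, "end"])),
                      ncol = 2L, dimnames = list(NULL, c("start", "end")))
    rows[[length(rows) + 1L]] <- mk("gene", gene_iv)
    rows[[length(rows) + 1L]] <- mk("exon", g$exons)
    rows[[length(rows) + 1L]] <- mk("CDS", g$cds, phase = cds_phases(g))
  }
  gr <- do.call(c, rows)
  names(gr) <- NULL
  gr
}

# GTF frame/phase of each CDS sub-interval (genomic order): number of bases
# to skip at the interval's 5' end to reach the next codon boundary.
cds_phases <- function(g) {
  w <- g$cds[, "end"] - g$cds[, "start"] + 1L
  tx_order <- if (g$strand == "-") rev(seq_along(w)) else seq_along(w)
  prev <- cumsum(c(0L, w[tx_order]))[seq_along(w)]
  phase <- (3L - prev %% 3L) %% 3L
  phase[order(tx_order)]
}

#' Read a genome model from FASTA + GTF (+ optional domains TSV)
#'
#' @param fasta path to the genome FASTA.
#' @param gtf path to the annotation GTF (gene/exon/CDS features with
#'   `gene_id` attributes).
#' @param domains optional path to a protein-domain TSV
#'   (`gene_id`, `name`, `aa_start`, `aa_end`).
#' @return a `genome_model`.
#' @export
read_genome <- function(fasta, gtf, domains = NULL) {
  chrom <- Biostrings::readDNAStringSet(fasta)
  chromosomes <- stats::setNames(as.character(chrom),
                                 sub("\\s.*$", "", names(chrom)))
  gr <- rtracklayer::import(gtf, format = "gtf")
  dom_df <- if (!is.null(domains) && file.exists(domains)) read_tsv(domains) else NULL
  genes <- lapply(split(gr, gr$gene_id), function(feat) {
    ex <- feat[feat$type == "exon"]
    cd <- feat[feat$type == "CDS"]
    ex <- sort(ex)
    cd <- sort(cd)
    dm <- if (!is.null(dom_df)) dom_df[dom_df$gene_id == feat$gene_id[1L], -1L, drop = FALSE]
          else NULL
    if (is.null(dm) || nrow(dm) == 0L)
      dm <- data.frame(name = character(0), aa_start = integer(0), aa_end = integer(0))
    gene_model(
      gene_id = feat$gene_id[1L],
      chromosome = as.character(GenomicRanges::seqnames(feat))[1L],
      strand = as.character(GenomicRanges::strand(feat))[1L],
      exons = cbind(GenomicRanges::start(ex), GenomicRanges::end(ex)),
      cds = cbind(GenomicRanges::start(cd), GenomicRanges::end(cd)),
      domains = dm
    )
  })
  genome_model(chromosomes, unname(genes))
}
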