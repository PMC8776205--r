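#!/usr/bin/env Rscript
# Step 1 — simulate the study data.
#
# Builds the default toy genome (2 chromosomes x 500 kb, 6 multi-exon
# coding genes), engineers one inter-chromosomal in-frame fusion joining
# donor exon 2 to acceptor exon 2, and simulates 100 bp paired-end reads
# from the wild-type transcriptome plus the fusion transcript at an
# abundance chosen for 30x junction coverage. Everything is seeded, so the
# discovery step (02) regenerates the identical data set internally from
# the same configuration.
#
# Outputs:
#   scratch/data/      genome.fa / annotation.gtf / domains.tsv,
#                      reads_1.fq / reads_2.fq / reads_truth.tsv  (bulky)
#   results/01_truth.tsv   ground-truth fusion event, one row

library(fusionscan)

cfg <- fusion_config()
sc <- fusionscan:::discovery_scenario(cfg)
genome <- sc$genome
fusion <- sc$fusion
ev <- fusion$event

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
write_genome(genome, "scratch/data")

transcriptome <- rbind(
  data.frame(id = names(genome$genes),
             seq = vapply(names(genome$genes), function(g)
               gene_tx_seq(genome, g), character(1)),
             abundance = 1, junction = NA_integer_,
             stringsAsFactors = FALSE),
  data.frame(id = "FUSION", seq = fusion$seq,
             abundance = fusionscan:::fusion_abundance(cfg, genome,
                                                       nchar(fusion$seq)),
             junction = fusion$junction_offset, stringsAsFactors = FALSE)
)
pairs <- simulate_reads(transcriptome, cfg$n_pairs,
                        read_len = cfg$read_len, frag_mean = cfg$frag_mean,
                        frag_sd = cfg$frag_sd, error_rate = cfg$error_rate,
                        seed = cfg$seed)
write_read_pairs(pairs, "scratch/data")

dir.create("results", showWarnings = FALSE)
truth <- data.frame(
  donor_gene = ev$donor_gene, acceptor_gene = ev$acceptor_gene,
  donor_chrom = genome$genes[[ev$donor_gene]]$chromosome,
  acceptor_chrom = genome$genes[[ev$acceptor_gene]]$chromosome,
  donor_break_genomic = ev$donor_break$genomic_coord,
  acceptor_break_genomic = ev$acceptor_break$genomic_coord,
  donor_exon = ev$donor_break$exon_index,
  acceptor_exon = ev$acceptor_break$exon_index,
  in_frame = fusion$in_frame,
  fusion_length_nt = nchar(fusion$seq),
  junction_offset = fusion$junction_offset,
  n_read_pairs = cfg$n_pairs
)
fusionscan:::write_tsv(truth, "results/01_truth.tsv")
cat("simulated", cfg$n_pairs, "pairs;",
    "truth written to results/01_truth.tsv\n")
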