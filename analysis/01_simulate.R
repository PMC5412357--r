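#!/usr/bin/env Rscript
# Generate the five-genome synthetic panel that the downstream analyses use:
# GenBank records, FASTA, feature tables and truth sidecars under
# results/genomes/.

suppressMessages(library(mitocomp))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
out_dir <- "results/genomes"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

panel <- generate_genome_panel(generator_config(seed = seed, id = "SYNMT"),
                               n = 5)
for (i in seq_along(panel$genomes)) {
  g <- panel$genomes[[i]]
  write_genbank(g, file.path(out_dir, paste0(g$id, ".gb")))
  write_genome_fasta(g, file.path(out_dir, paste0(g$id, ".fasta")))
  write_feature_table(g, file.path(out_dir, paste0(g$id, ".features.tsv")))
  write_truth_sidecar(panel$truths[[i]],
                      file.path(out_dir, paste0(g$id, ".truth.tsv")))
  cat(sprintf("%s: %d bp, %d features\n", g$id, nchar(g$sequence),
              nrow(g$features)))
}
cat("Panel of", length(panel$genomes), "genomes written to", out_dir, "\n")
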