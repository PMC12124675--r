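#!/usr/bin/env Rscript
# Project consensus events onto the gene models: carrier matrices,
# ancestry-stratified frequencies, ancestral-event flags, burden tables.

suppressMessages(library(ycap))

samples <- read_samples("results/cohort/samples.tsv")
events <- read.delim("results/consensus_events.tsv")
genes <- read_genes(chry_model_file("genes"))

for (ti in c("blood", "tumor")) {
  gem <- annotate_events(events[events$tissue == ti, ], genes, samples)
  gem <- flag_ancestral(gem, samples)
  fr <- carrier_frequency(gem, samples)
  fr$ancestral <- gem$ancestral[paste(fr$gene, fr$call, sep = ":")]
  rates <- carrier_rates(gem, samples)
  burden <- summarize_burden(gem, samples, gene_class = "protein_coding")
  prefix <- file.path("results", paste0(ti, "_"))
  write.table(fr, paste0(prefix, "gene_frequencies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(burden, paste0(prefix, "burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gem$long, paste0(prefix, "oncoplot_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cat(sprintf("[%s] any-event carriers: ", ti))
  for (i in seq_len(nrow(rates)))
    if (rates$call[i] == "any")
      cat(sprintf("%s %d/%d (%.1f%%)  ", rates$stratum[i], rates$carriers[i],
                  rates$n[i], rates$pct[i]))
  cat("\n")
  anc <- names(gem$ancestral)[gem$ancestral]
  if (length(anc))
    cat("  likely ancestral (clade-fixed) columns:", paste(anc, collapse = ", "), "\n")
  top <- fr[order(-fr$carriers), ][1:3, ]
  cat(sprintf("  most frequent: %s\n",
              paste(sprintf("%s %s %d/%d", top$gene, top$call, top$carriers,
                            top$n), collapse = "; ")))
}
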