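#!/usr/bin/env Rscript
# Potentially-deleterious-variant cascade over the annotated variant
# table: nonsynonymous -> >= 1 damaging predictor -> not InterVar-benign,
# then rarity classification and the carrier-prevalence report.

suppressMessages(library(ycap))

ann <- read.delim("results/cohort/annotations.tsv", na.strings = c("NA", ""))
afs <- read.delim("results/cohort/af_table.tsv")
samples <- read_samples("results/cohort/samples.tsv")

res <- pdv_pipeline(ann, afs, samples)
write.table(res$pdv, "results/pdv.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$prevalence, "results/pdv_prevalence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d annotated variants -> %d nonsynonymous -> %d with a damaging verdict -> %d PDVs\n",
            nrow(ann), nrow(ann) - res$audit$removed[1],
            nrow(ann) - sum(res$audit$removed[1:2]), nrow(res$pdv)))
cat(sprintf("  rarity: %s\n",
            paste(names(table(res$pdv$rarity)), table(res$pdv$rarity),
                  collapse = ", ", sep = "=")))
p <- res$prevalence
for (i in seq_len(nrow(p)))
  cat(sprintf("  rare-PDV carriers, %s: %d/%d (%.1f%%), fold %s\n",
              p$ancestry[i], p$carriers[i], p$n[i], p$pct[i],
              format(p$fold_vs_min[i])))
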