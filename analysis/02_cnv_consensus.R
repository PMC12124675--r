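#!/usr/bin/env Rscript
# Multi-caller CNV consensus: germline (>= 2 of 3 callers) and somatic
# (2-of-2 intersection) merges, evaluated against the simulated truth.

suppressMessages(library(ycap))

in_dir <- "results/cohort"
calls <- do.call(rbind, lapply(list.files(file.path(in_dir, "calls"),
                                          full.names = TRUE), function(f)
  read_bed(f, col_names = c("call", "caller", "tissue", "sample_id"))))
truth <- read.delim(file.path(in_dir, "truth", "cnv.tsv"))

germ <- consensus_pipeline(calls[calls$tissue == "blood", ], "germline")
som <- consensus_pipeline(calls[calls$tissue == "tumor", ], "somatic")
events <- rbind(germ, som)
dir.create("results", showWarnings = FALSE)
write.table(events, "results/consensus_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (ti in c("blood", "tumor")) {
  ev <- events[events$tissue == ti, ]
  rec <- event_recovery(unique(truth[truth$tissue == ti, ]), ev,
                        min_len = 5000L)
  cat(sprintf("%s: %d calls -> %d consensus events (%d gains, %d losses)\n",
              ti, sum(calls$tissue == ti), nrow(ev),
              sum(ev$call == "gain"), sum(ev$call == "loss")))
  cat(sprintf("  truth events >= 5 kb recovered at Jaccard >= 0.9: %.1f%%\n",
              100 * mean(rec$jaccard >= 0.9)))
}
cat("consensus events written to results/consensus_events.tsv\n")
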