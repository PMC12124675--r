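#!/usr/bin/env Rscript
# Generate the default synthetic two-ancestry chrY cohort and write every
# pipeline input plus the truth files.  All downstream drivers re-derive
# their inputs from this directory.

suppressMessages(library(ycap))

seed <- 20260924L
out_dir <- "results/cohort"

cfg <- sim_config(seed = seed,
                  depth_model = list(bin = 10000L, autosomal_mean = 45,
                                     nb_size = 50, noise = TRUE))
coh <- simulate_cohort(cfg)
write_cohort(coh, out_dir)

cat("Synthetic cohort written to", out_dir, "\n")
cat(sprintf("  %d samples: %d African, %d European\n", nrow(coh$samples),
            sum(coh$samples$ancestry == "African"),
            sum(coh$samples$ancestry == "European")))
cat(sprintf("  haplogroup E within Africans: %.1f%%; R within Europeans: %.1f%%\n",
            100 * mean(grepl("^E", coh$samples$haplogroup[
              coh$samples$ancestry == "African"])),
            100 * mean(coh$samples$haplogroup[
              coh$samples$ancestry == "European"] == "R")))
cat(sprintf("  truth CNV rows: %d (%d germline, %d somatic)\n",
            nrow(coh$truth$cnv), sum(coh$truth$cnv$tissue == "blood"),
            sum(coh$truth$cnv$tissue == "tumor")))
cat(sprintf("  caller calls: %d; implanted LOY tumor: %s (true ploidy %.2f)\n",
            nrow(coh$calls),
            coh$truth$ploidy$sample_id[coh$truth$ploidy$ploidy_tumor < 1],
            min(coh$truth$ploidy$ploidy_tumor)))
cat(sprintf("  mean chrY SNVs: %.0f African vs %.0f European\n",
            mean(coh$snv_counts$n_snv[coh$snv_counts$ancestry == "African"]),
            mean(coh$snv_counts$n_snv[coh$snv_counts$ancestry == "European"])))
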