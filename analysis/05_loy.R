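#!/usr/bin/env Rscript
# Y-ploidy estimation from X-degenerate depth, tumor - blood deltas, the
# 4-SD partial-LOY outlier rule, and ploidy-vs-age regressions.

suppressMessages(library(ycap))

samples <- read_samples("results/cohort/samples.tsv")
xdeg <- read_bed(chry_model_file("xdeg"))
depth <- list()
for (sid in samples$sample_id) {
  depth[[sid]] <- list(
    blood = read.delim(file.path("results/cohort/depth",
                                 paste0(sid, ".blood.tsv"))),
    tumor = read.delim(file.path("results/cohort/depth",
                                 paste0(sid, ".tumor.tsv"))))
}

rec <- flag_loy(ploidy_records(depth, xdeg, samples))
write.table(rec, "results/ploidy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

by_anc <- split(rec, samples$ancestry[match(rec$sample_id, samples$sample_id)])
for (anc in names(by_anc))
  cat(sprintf("%s: median blood ploidy %.3f (min %.3f), median tumor %.3f (min %.3f)\n",
              anc, median(by_anc[[anc]]$ploidy_blood),
              min(by_anc[[anc]]$ploidy_blood),
              median(by_anc[[anc]]$ploidy_tumor),
              min(by_anc[[anc]]$ploidy_tumor)))
cat(sprintf("4-SD delta threshold: %.3f; flagged: %s\n",
            attr(rec, "loy_threshold"),
            paste(rec$sample_id[rec$loy_flag], collapse = ", ")))
for (anc in names(by_anc)) {
  sub <- samples[samples$ancestry == anc, ]
  fit <- ploidy_age_regression(rec[rec$sample_id %in% sub$sample_id, ],
                               sub, "blood")
  cat(sprintf("%s blood ploidy ~ age: slope %.5f, R2 = %.3f, p = %.3f (n = %d)\n",
              anc, fit$slope, fit$r_squared, fit$p_value, fit$n))
}
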