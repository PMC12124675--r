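#!/usr/bin/env Rscript
# Association layer: exact Fisher tests on the carrier tables (both the
# study's printed tables and the simulated cohort's), rank-sum
# comparisons of SNV counts, haplogroup x risk association, and the
# clade-marker concordance screen.

suppressMessages(library(ycap))

samples <- read_samples("results/cohort/samples.tsv")
snv <- read.delim("results/cohort/snv_counts.tsv")
ann <- read.delim("results/cohort/annotations.tsv", na.strings = c("NA", ""))
events <- read.delim("results/consensus_events.tsv")

rows <- list()
note <- function(comparison, test) {
  rows[[length(rows) + 1L]] <<- data.frame(
    comparison = comparison, p_value = test$p_value, method = test$method,
    stringsAsFactors = FALSE)
  cat(sprintf("%-52s p = %.4g\n", comparison, test$p_value))
}

# the study's printed carrier tables reproduce their p-values
note("printed: HRPCa SCNA carriers, African vs European",
     fisher_exact_2x2(matrix(c(21, 85, 7, 50), 2, byrow = TRUE)))
note("printed: protein-coding SCNA carriers by ancestry",
     fisher_exact_2x2(matrix(c(24, 82, 7, 50), 2, byrow = TRUE)))

# simulated cohort: somatic carrier status by ancestry
som <- events[events$tissue == "tumor", ]
tb <- build_carrier_table(samples, carriers = unique(som$sample_id))
note("simulated: somatic SCNA carriers by ancestry", fisher_exact_2x2(tb))

# simulated chrY SNV counts by ancestry
note("simulated: chrY SNV counts, African vs European",
     wilcoxon_rank_sum(snv$n_snv[snv$ancestry == "African"],
                       snv$n_snv[snv$ancestry == "European"]))

# major haplogroup x risk (r x c, exact by enumeration where feasible)
samples$major_hg <- sub("[^A-Za-z].*$", "", samples$haplogroup)
hg_tab <- build_carrier_table(samples, stratifier = "major_hg",
                              response = "risk")
note("simulated: major haplogroup x PCa risk",
     fisher_exact_rxc(hg_tab, seed = 99L))

stats_tab <- do.call(rbind, rows)
write.table(stats_tab, "results/stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# clade-marker concordance screen
geno <- genotype_matrix(ann, samples)
cc <- clade_marker_concordance(geno, samples$haplogroup)
write.table(cc, "results/clade_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
perfect <- cc[cc$concordant & !cc$cohort_fixed, ]
cat(sprintf("clade-concordant markers: %s\n",
            paste(sprintf("%s in clade %s (n=%d)", perfect$variant,
                          perfect$clade, perfect$clade_size), collapse = "; ")))
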