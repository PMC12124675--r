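toy_genes <- genomic_intervals("chrY", c(1000, 5000, 9000),
                               c(2000, 6000, 9500),
                               name = c("GENE1", "GENE2", "LNC1"),
                               gene_class = c("protein_coding",
                                              "protein_coding", "RNA"))

mk_events <- function(sample_id, start, end, call, tissue = "tumor") {
  data.frame(sample_id = sample_id, tissue = tissue, chrom = "chrY",
             start = start, end = end, call = call, n_support = 2L,
             stringsAsFactors = FALSE)
}

test_that("events mark genes under the any-overlap rule", {
  ev <- rbind(mk_events("s1", 900, 2100, "loss"),    # contains GENE1
              mk_events("s2", 1999, 3000, "loss"),   # 1 bp overlap with GENE1
              mk_events("s3", 2000, 3000, "loss"))   # bookended, no overlap
  gem <- annotate_events(ev, toy_genes)
  expect_true(gem$matrix["s1", "GENE1:loss"])
  expect_true(gem$matrix["s2", "GENE1:loss"])
  expect_false(gem$matrix["s3", "GENE1:loss"])
  expect_false(any(gem$matrix[, "GENE1:gain"]))
  expect_warning(annotate_events(ev, toy_genes[0, ]), "empty gene set")
})

test_that("a sample counts once per gene/type however its events are split", {
  whole <- mk_events("s1", 900, 2100, "loss")
  split3 <- rbind(mk_events("s1", 900, 1200, "loss"),
                  mk_events("s1", 1200, 1700, "loss"),
                  mk_events("s1", 1700, 2100, "loss"))
  samples <- data.frame(sample_id = "s1", ancestry = "African",
                        stringsAsFactors = FALSE)
  g1 <- annotate_events(whole, toy_genes, samples)
  g2 <- annotate_events(split3, toy_genes, samples)
  expect_identical(g1$matrix, g2$matrix)
  f1 <- carrier_frequency(g1, samples)
  f2 <- carrier_frequency(g2, samples)
  expect_identical(f1, f2)
})

test_that("carrier frequencies use full stratum sizes as denominators", {
  samples <- data.frame(
    sample_id = c(sprintf("a%03d", 1:106), sprintf("e%02d", 1:57)),
    ancestry = rep(c("African", "European"), c(106, 57)),
    stringsAsFactors = FALSE)
  ev <- mk_events(sprintf("a%03d", 1:88), 9000, 9600, "loss")
  gem <- annotate_events(ev, toy_genes, samples)
  fr <- carrier_frequency(gem, samples)
  row <- fr[fr$gene == "LNC1" & fr$call == "loss" & fr$stratum == "African", ]
  expect_equal(row$carriers, 88L)
  expect_equal(row$n, 106L)
  expect_equal(round(row$pct, 1), 83.0)
  eur <- fr[fr$gene == "LNC1" & fr$call == "loss" & fr$stratum == "European", ]
  expect_equal(eur$n, 57L)
  expect_equal(eur$carriers, 0L)
})

test_that("ancestral flagging is clade-driven and monotone in the threshold", {
  n <- 40L
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        ancestry = "African",
                        haplogroup = rep(c("E-V38", "R"), c(30, 10)),
                        stringsAsFactors = FALSE)
  # all 30 E-V38 samples share the loss; 1 R sample has a private gain
  ev <- rbind(mk_events(samples$sample_id[1:30], 9000, 9600, "loss"),
              mk_events("s31", 1000, 1500, "gain"))
  gem <- annotate_events(ev, toy_genes, samples)
  fl <- flag_ancestral(gem, samples)
  expect_true(fl$ancestral[["LNC1:loss"]])
  expect_false(fl$ancestral[["GENE1:gain"]])

  # unreachable threshold flags nothing
  none <- flag_ancestral(gem, samples, clade_threshold = 1.01)
  expect_false(any(none$ancestral))

  # monotonicity: raising the threshold never flags more columns
  ths <- c(0.5, 0.7, 0.9, 1.0)
  flags <- lapply(ths, function(t)
    flag_ancestral(gem, samples, clade_threshold = t)$ancestral)
  for (i in seq_len(length(ths) - 1L))
    expect_true(all(flags[[i]] | !flags[[i + 1L]]))

  # a small clade (< 5) never drives a flag
  tiny <- samples
  tiny$haplogroup <- c(rep("A", 4), rep("Q", 36))
  ev2 <- mk_events(tiny$sample_id[1:4], 9000, 9600, "loss")
  gem2 <- annotate_events(ev2, toy_genes, tiny)
  expect_false(any(flag_ancestral(gem2, tiny)$ancestral))
})

test_that("burden summaries report carrier-only means with sample SD", {
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        ancestry = "African", risk = "HRPCa",
                        stringsAsFactors = FALSE)
  # s1 hits GENE1+GENE2+LNC1 (3 genes), s2 hits GENE1..LNC1 via two events
  ev <- rbind(mk_events("s1", 900, 9600, "loss"),
              mk_events("s2", 900, 2100, "loss"),
              mk_events("s2", 4900, 9600, "loss"))
  gem <- annotate_events(ev, toy_genes, samples)
  b <- summarize_burden(gem, samples)
  row <- b[b$stratum == "African/HRPCa" & b$call == "loss", ]
  expect_equal(row$carriers, 2L)
  expect_equal(row$mean_genes, 3)
  expect_equal(row$sd_genes, 0)
  # hand case: carriers with gene counts {3, 5} -> mean 4, SD sqrt(2)
  ev2 <- rbind(mk_events("s1", 900, 9600, "loss"),          # 3 genes
               mk_events("s2", 900, 9600, "loss"),
               mk_events("s2", 900, 6000, "gain"))  # +2 gain columns -> 5 total
  gem2 <- annotate_events(ev2, toy_genes, samples)
  b2 <- summarize_burden(gem2, samples)
  any_row <- b2[b2$stratum == "African/HRPCa" & b2$call == "any", ]
  expect_equal(any_row$mean_genes, 4)
  expect_equal(any_row$sd_genes, sqrt(2))
  expect_equal(c(any_row$min_genes, any_row$max_genes), c(3, 5))
  # single carrier: SD undefined; empty stratum: all NA
  one <- summarize_burden(annotate_events(mk_events("s3", 900, 2100, "loss"),
                                          toy_genes, samples), samples)
  orow <- one[one$stratum == "African/HRPCa" & one$call == "loss", ]
  expect_equal(orow$carriers, 1L)
  expect_true(is.na(orow$sd_genes))
  expect_equal(orow$mean_genes, 1)
})
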