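# Small configurations keep the default test run fast; cohort-scale
# behaviour is exercised in the acceptance suite.
small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_african = 8L, n_european = 4L,
             depth_model = list(bin = 100000L, autosomal_mean = 45,
                                nb_size = 50, noise = TRUE), ...)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(small_cfg(seed = 5L)), d1)
  write_cohort(simulate_cohort(small_cfg(seed = 5L)), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_true(all(unname(h1) == unname(h2)))
})

test_that("noise-free caller files equal the truth intervals exactly", {
  cfg <- small_cfg(seed = 2L,
                   caller_error = list(fnr = 0, spurious_per_mb = 0,
                                       jitter_sd = 0, spurious_mean_len = 5000))
  coh <- simulate_cohort(cfg, depth = FALSE)
  for (cl in cfg$germline_callers) {
    got <- coh$calls[coh$calls$caller == cl & coh$calls$tissue == "blood", ]
    tr <- coh$truth$cnv[coh$truth$cnv$tissue == "blood", ]
    key <- function(d, type_col) sort(paste(d$sample_id, d$start, d$end, d[[type_col]]))
    expect_identical(key(got, "call"), key(tr, "type"))
  }
})

test_that("noise-free consensus reproduces the truth set exactly", {
  cfg <- small_cfg(seed = 3L,
                   caller_error = list(fnr = 0, spurious_per_mb = 0,
                                       jitter_sd = 0, spurious_mean_len = 5000))
  coh <- simulate_cohort(cfg, depth = FALSE)
  for (ti in c("blood", "tumor")) {
    mode <- if (ti == "blood") "germline" else "somatic"
    ev <- consensus_pipeline(coh$calls[coh$calls$tissue == ti, ], mode)
    tr <- unique(coh$truth$cnv[coh$truth$cnv$tissue == ti,
                               c("sample_id", "start", "end", "type")])
    got <- ev[order(ev$sample_id, ev$start), c("sample_id", "start", "end", "call")]
    want <- tr[order(tr$sample_id, tr$start), ]
    names(want)[4] <- "call"
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("caller corruption behaves at its limits and in expectation", {
  err0 <- list(fnr = 0, spurious_per_mb = 0, jitter_sd = 0,
               spurious_mean_len = 5000)
  truth <- data.frame(chrom = "chrY", start = c(1000, 9000), end = c(5000, 20000),
                      type = c("loss", "gain"), stringsAsFactors = FALSE)
  set.seed(42)
  ident <- corrupt_calls(truth, err0)
  expect_equal(ident$start, truth$start)
  expect_equal(ident$end, truth$end)
  expect_equal(ident$call, truth$type)

  # FNR = 1 leaves only spurious calls
  all_fn <- corrupt_calls(truth, list(fnr = 1, spurious_per_mb = 2,
                                      jitter_sd = 0, spurious_mean_len = 5000))
  expect_false(any(paste(all_fn$start, all_fn$end, all_fn$call) %in%
                   paste(truth$start, truth$end, truth$type)))

  # retention of 1000 intervals at FNR 0.1 within the binomial 99% interval
  big <- data.frame(chrom = "chrY", start = seq(0, by = 25000, length.out = 1000))
  big$end <- big$start + 20000
  big$type <- "loss"
  kept <- nrow(corrupt_calls(big, list(fnr = 0.1, spurious_per_mb = 0,
                                       jitter_sd = 0, spurious_mean_len = 5000)))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.9)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])

  expect_error(corrupt_calls(truth, list(fnr = 0.5, spurious_per_mb = 0,
                                         jitter_sd = -1,
                                         spurious_mean_len = 5000)))
})

test_that("simulated depth has the configured single-copy mean", {
  dm <- list(bin = 1000L, autosomal_mean = 60, nb_size = 50, noise = TRUE)
  set.seed(8)
  d <- simulate_depth(1.0, dm, autosomal_mean = 60, chry_length = 10e6)
  se <- sd(d$depth) / sqrt(nrow(d))
  expect_lt(abs(mean(d$depth) - 30), 3 * se)

  d2 <- simulate_depth(0.36, dm, autosomal_mean = 60, chry_length = 10e6)
  se2 <- sd(d2$depth) / sqrt(nrow(d2))
  expect_lt(abs(mean(d2$depth) - 10.8), 3 * se2)

  d0 <- simulate_depth(0, dm, autosomal_mean = 60, chry_length = 1e6)
  expect_true(all(d0$depth == 0))

  dn <- simulate_depth(0.5, list(bin = 1000L, nb_size = 50, noise = FALSE),
                       autosomal_mean = 60, chry_length = 1e6)
  expect_true(all(dn$depth == 15))
})

test_that("the implanted LOY tumor appears exactly once in the truth files", {
  coh <- simulate_cohort(sim_config(seed = 9L), depth = FALSE, calls = FALSE)
  loy <- coh$truth$ploidy[coh$truth$ploidy$ploidy_tumor < 1, ]
  expect_equal(nrow(loy), 1L)
  expect_equal(loy$ploidy_tumor, 0.36)
  expect_equal(loy$ploidy_blood, 1)
  expect_match(loy$sample_id, "^AFR")
})

test_that("haplogroup-linked carrier rules are realized exactly at fraction 1", {
  coh <- simulate_cohort(small_cfg(seed = 4L), depth = FALSE, calls = FALSE)
  ttty <- coh$truth$cnv[coh$truth$cnv$event_id == "g_ttty22_loss", ]
  full_clades <- coh$samples$sample_id[coh$samples$haplogroup %in% c("A", "E-V38")]
  expect_true(all(full_clades %in% ttty$sample_id))

  bad <- small_cfg(seed = 4L)
  bad$truth_cnv_catalog <- list(list(event_id = "x", tissue = "blood",
                                     start = 0, end = 10, type = "loss",
                                     rule = "haplogroup", clades = c(Z99 = 1)))
  expect_error(simulate_cohort(bad, depth = FALSE, calls = FALSE),
               "unknown haplogroup")
})

test_that("simulated SNV counts hit the configured population means", {
  cfg <- sim_config(seed = 10L, n_african = 200L, n_european = 200L)
  coh <- simulate_cohort(cfg, depth = FALSE, calls = FALSE)
  mean_afr <- mean(coh$snv_counts$n_snv[coh$snv_counts$ancestry == "African"])
  expect_lt(abs(mean_afr - 1010) / 1010, 0.05)
  # the European spread is configured wide; check the mean loosely at 3 SE
  eu <- coh$snv_counts$n_snv[coh$snv_counts$ancestry == "European"]
  expect_lt(abs(mean(eu) - 332), 3 * sd(eu) / sqrt(length(eu)))
})
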