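# Configuration of the synthetic two-ancestry chrY cohort.
#
# The defaults encode the study conditions being emulated: 106 African and
# 57 European patients, the observed haplogroup composition (E at 81.1%
# within the African cohort with 80 E-V38 lineages, R at 58% within the
# European cohort), chrY SNV count means of 1010 vs 332, a
# haplogroup-linked TTTY22-spanning germline loss carried by clades A and
# E-V38, risk-enriched somatic CNVs, and a single African tumor with true
# Y ploidy 0.36 (partial loss of Y).

#' Path to a packaged synthetic chrY model file
#'
#' @param which \code{"genes"}, \code{"mask"} or \code{"xdeg"}.
#' @return file path under the package's \code{extdata}.
#' @export
chry_model_file <- function(which = c("genes", "mask", "xdeg")) {
  which <- match.arg(which)
  system.file("extdata", paste0("synthetic_chrY_", which, ".bed"),
              package = "ycap", mustWork = TRUE)
}

#' Default truth CNV catalog
#'
#' One entry per event: interval, type, tissue, and a carrier rule —
#' \code{haplogroup} (per-clade carrier fractions), \code{population}
#' (fraction of one ancestry), \code{risk} (fractions per ancestry/risk
#' stratum) or \code{random} (cohort-wide fraction).  Germline events are
#' haplogroup-linked (the TTTY22-like loss is fixed in clades A and
#' E-V38); somatic events are enriched in high-risk and African tumors.
#'
#' @return list of event specifications.
#' @export
default_cnv_catalog <- function() {
  list(
    list(event_id = "g_ttty22_loss", tissue = "blood", start = 9550000,
         end = 9650000, type = "loss", rule = "haplogroup",
         clades = c(A = 1, `E-V38` = 1, `E-M75` = 1 / 3)),
    list(event_id = "g_lnc_loss", tissue = "blood", start = 9680000,
         end = 9760000, type = "loss", rule = "haplogroup",
         clades = c(A = 6 / 7, `E-V38` = 0.9, `E-M75` = 1 / 3)),
    list(event_id = "g_rbmy_gain", tissue = "blood", start = 21490000,
         end = 21550000, type = "gain", rule = "haplogroup",
         clades = c(A = 6 / 7)),
    list(event_id = "g_rbmy_loss", tissue = "blood", start = 21555000,
         end = 21670000, type = "loss", rule = "haplogroup",
         clades = c(A = 4 / 7, `E-V38` = 0.03)),
    list(event_id = "g_daz_gain", tissue = "blood", start = 22990000,
         end = 23940000, type = "gain", rule = "population",
         population = "African", fraction = 0),
    list(event_id = "g_eur_gain", tissue = "blood", start = 22990000,
         end = 23940000, type = "gain", rule = "population",
         population = "European", fraction = 1 / 57),
    list(event_id = "g_hsfy_loss", tissue = "blood", start = 18480000,
         end = 18560000, type = "loss", rule = "random", fraction = 0.05),
    list(event_id = "s_usp9y_ddx3y_loss", tissue = "tumor", start = 12690000,
         end = 12930000, type = "loss", rule = "risk",
         fractions = c(African.HRPCa = 0.08, African.LRPCa = 0.02,
                       European.HRPCa = 0.08, European.LRPCa = 0)),
    list(event_id = "s_pry_rbmy_loss", tissue = "tumor", start = 21600000,
         end = 22200000, type = "loss", rule = "risk",
         fractions = c(African.HRPCa = 0.11, African.LRPCa = 0.04,
                       European.HRPCa = 0.02, European.LRPCa = 0)),
    list(event_id = "s_kdm5d_loss", tissue = "tumor", start = 19690000,
         end = 19760000, type = "loss", rule = "risk",
         fractions = c(African.HRPCa = 0.09, African.LRPCa = 0,
                       European.HRPCa = 0.02, European.LRPCa = 0)),
    list(event_id = "s_rna_loss", tissue = "tumor", start = 15990000,
         end = 16300000, type = "loss", rule = "risk",
         fractions = c(African.HRPCa = 0.12, African.LRPCa = 0.04,
                       European.HRPCa = 0.12, European.LRPCa = 0.04)),
    list(event_id = "s_pcdh11y_gain", tissue = "tumor", start = 4890000,
         end = 5720000, type = "gain", rule = "risk",
         fractions = c(African.HRPCa = 0.03, African.LRPCa = 0,
                       European.HRPCa = 0, European.LRPCa = 0))
  )
}

#' Synthetic-cohort configuration
#'
#' Returns the default configuration, optionally overridden (shallow
#' merge of named arguments).
#'
#' @param ... overrides of top-level fields.
#' @return named list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_african = 106L,
    n_european = 57L,
    chry_length = 25e6,
    # within-population haplogroup composition (counts realized
    # deterministically by largest remainder, then shuffled over samples)
    haplogroup_freqs = list(
      African = c(A = 7 / 106, B = 13 / 106, `E-V38` = 80 / 106,
                  `E-M75` = 3 / 106, `E-M4217` = 3 / 106),
      European = c(R = 33 / 57, `E-M215` = 4 / 57, G = 5 / 57, I = 5 / 57,
                   J = 5 / 57, O = 5 / 57)),
    # chrY SNV counts: negative binomial per population; the African
    # size is effectively the Poisson limit (tight spread), the European
    # size is small (wide spread)
    snv_model = list(African = list(mean = 1010, size = 1e6),
                     European = list(mean = 332, size = 0.6)),
    hr_fraction = c(African = 88 / 106, European = 50 / 57),
    age_model = list(African = c(mean = 66.9, sd = 8.1),
                     European = c(mean = 61.7, sd = 8.1)),
    psa_model = list(African = c(meanlog = log(90), sdlog = 1.3),
                     European = c(meanlog = log(10), sdlog = 0.8)),
    truth_cnv_catalog = default_cnv_catalog(),
    germline_callers = c("gatk_gcnv", "cn_mops", "cnvkit"),
    somatic_callers = c("gatk_gcnv", "cnvkit"),
    caller_error = list(fnr = 0.1, spurious_per_mb = 0.04, jitter_sd = 200,
                        spurious_mean_len = 5000),
    depth_model = list(bin = 1000L, autosomal_mean = 45, nb_size = 50,
                       noise = TRUE),
    loy_fraction = 1 / 106,   # fraction of African samples with partial LOY
    loy_ploidy = 0.36,        # true tumor Y ploidy of the implanted outlier
    genes_bed = chry_model_file("genes"),
    mask_bed = chry_model_file("mask"),
    xdeg_bed = chry_model_file("xdeg")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$n_african >= 0, cfg$n_european >= 0,
            cfg$loy_fraction >= 0, cfg$loy_fraction <= 1,
            cfg$loy_ploidy >= 0)
  for (pop in names(cfg$haplogroup_freqs)) {
    f <- cfg$haplogroup_freqs[[pop]]
    stopifnot(all(f >= 0), abs(sum(f) - 1) < 1e-8)
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}
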