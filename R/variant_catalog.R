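# Default predictor-annotated variant catalog for the synthetic cohort.
#
# Structure emulated: 13 nonsynonymous chrY SNVs of which 5 carry no
# damaging verdict from any of the four predictors and 8 survive the PDV
# cascade; 5 of the 13 are absent from the reference AF table (3 carried
# by African, 2 by European samples); clade-marker variants are fixed
# within their haplogroup clades (a DDX3Y marker in clade A, a KDM5D
# marker in clade B, and a USP9Y variant fixed in all Africans that also
# appears in the European E-M215 clade); rare PDVs are carried by five
# European and two African patients.

#' Build the default annotated variant table for a simulated cohort
#'
#' @param samples simulated sample table (drives carrier assignment; uses
#'   the session RNG for the random carrier picks).
#' @return list: \code{annotations} (one row per variant, with predictor
#'   verdicts, InterVar class, carried-through scores and a
#'   comma-separated \code{carriers} column), \code{af_table} (reference
#'   allele frequencies for the known variants), \code{truth_pdv}
#'   (variant keys implanted as PDVs).
#' @export
default_variant_catalog <- function(samples) {
  afr <- samples$sample_id[samples$ancestry == "African"]
  eur <- samples$sample_id[samples$ancestry == "European"]
  eur_hr <- samples$sample_id[samples$ancestry == "European" &
                              samples$risk == "HRPCa"]
  clade <- function(cl) samples$sample_id[samples$haplogroup == cl]
  pick <- function(pool, n) if (length(pool) >= n) sample(pool, n) else pool

  pdv_eur <- pick(eur_hr, 5L)   # one rare PDV each
  pdv_afr <- pick(afr, 2L)
  unk_afr <- pick(setdiff(afr, pdv_afr), 2L)

  V <- function(pos, ref, alt, gene, consequence, rsid, sift, sift4g,
                hdiv, hvar, intervar, cadd, dann, carriers) {
    data.frame(pos = pos, ref = ref, alt = alt, gene = gene,
               consequence = consequence, rsid = rsid,
               sift = sift, sift4g = sift4g,
               polyphen2_hdiv = hdiv, polyphen2_hvar = hvar,
               intervar = intervar, cadd = cadd, dann = dann,
               carriers = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
  }
  tol <- "tolerated"; dmg <- "damaging"; pos_d <- "possibly_damaging"
  vus <- "Uncertain significance"

  ann <- rbind(
    # --- nonsynonymous, no damaging verdict (fail the cascade) ---
    V(12800000, "A", "G", "USP9Y", "missense", "rs7067496",
      tol, tol, tol, tol, "Likely benign", 3.1, 0.42,
      c(afr, clade("E-M215"))),
    V(12750000, "G", "A", "USP9Y", "missense", "rs9999901",
      tol, tol, tol, tol, vus, 5.2, 0.51, pick(afr, min(10L, length(afr)))),
    V(12760000, "C", "T", "USP9Y", "missense", NA,
      tol, tol, tol, tol, NA, 4.8, 0.39, unk_afr),
    V(19720000, "C", "T", "KDM5D", "missense", "rs35681523",
      tol, tol, tol, tol, "Likely benign", 7.4, 0.55, clade("B")),
    V(12910000, "G", "C", "DDX3Y", "missense", "rs111406208",
      tol, tol, tol, tol, vus, 6.9, 0.48, clade("A")),
    # --- potentially deleterious (pass the cascade) ---
    V(7000000, "T", "C", "TBL1Y", "missense", "rs373532788",
      tol, tol, dmg, dmg, vus, 22.2, 0.997,
      afr[stats::runif(length(afr)) < 0.7]),
    V(7074584, "A", "G", "TBL1Y", "missense", NA,
      dmg, tol, pos_d, tol, vus, 24.1, 0.98, pdv_eur[1L]),
    V(12842454, "C", "T", "USP9Y", "missense", NA,
      dmg, dmg, tol, tol, NA, 25.3, 0.99, pdv_eur[2L]),
    V(12859400, "A", "C", "USP9Y", "missense", NA,
      tol, tol, pos_d, pos_d, NA, 21.7, 0.96, pdv_eur[3L]),
    V(12850000, "C", "G", "USP9Y", "missense", "rs766658730",
      tol, dmg, tol, pos_d, vus, 23.8, 0.97, pdv_eur[4L]),
    V(13300000, "G", "A", "UTY", "missense", "rs200431840",
      dmg, tol, tol, tol, vus, 22.9, 0.95, pdv_eur[5L]),
    V(13355115, "T", "C", "UTY", "missense", NA,
      dmg, dmg, tol, tol, NA, 26.0, 0.99, pdv_afr[1L]),
    V(19744477, "T", "A", "KDM5D", "stopgain", NA,
      dmg, dmg, dmg, dmg, NA, 35.0, 0.995, pdv_afr[2L]),
    # --- non-nonsynonymous background (removed at the first stage) ---
    V(2785000, "G", "A", "SRY", "synonymous", "rs9999902",
      NA, NA, NA, NA, NA, 0.5, 0.1, pick(samples$sample_id, 8L)),
    V(6870000, "T", "C", "AMELY", "synonymous", "rs9999903",
      NA, NA, NA, NA, NA, 0.8, 0.12, pick(samples$sample_id, 12L)),
    V(13240000, "C", "G", "UTY", "synonymous", "rs9999904",
      NA, NA, NA, NA, NA, 1.1, 0.2, pick(samples$sample_id, 5L)),
    V(12905000, "A", "T", "DDX3Y", "splice_site", "rs9999905",
      NA, NA, NA, NA, vus, 12.0, 0.8, pick(samples$sample_id, 2L)),
    V(20910000, "G", "T", "EIF1AY", "UTR", "rs9999906",
      NA, NA, NA, NA, NA, 2.2, 0.3, pick(samples$sample_id, 6L)),
    V(9310000, "A", "G", "TSPY1", "synonymous", "rs9999907",
      NA, NA, NA, NA, NA, 0.3, 0.15, pick(samples$sample_id, 9L))
  )
  ann$chrom <- "chrY"

  AF <- function(pos, ref, alt, af_afr, af_eur, af_eas) {
    data.frame(pos = pos, ref = ref, alt = alt, af_afr = af_afr,
               af_eur = af_eur, af_eas = af_eas, stringsAsFactors = FALSE)
  }
  af_table <- rbind(
    AF(12800000, "A", "G", 1.0, 0.07, 0.02),      # fixed in Africans
    AF(12750000, "G", "A", 0.15, 0.08, 0.05),
    AF(19720000, "C", "T", 0.011, 0, 0),          # clade-B marker, rare in ref
    AF(12910000, "G", "C", 0.005, 0, 0),          # clade-A marker
    AF(7000000, "T", "C", 0.011, 0, 0),           # common in cohort, rare in ref
    AF(7074584, "A", "G", 6.1e-05, 3.0e-05, 0),
    AF(12850000, "C", "G", 0, 1.0e-05, 0),
    AF(13300000, "G", "A", 0, 2.0e-05, 0),
    AF(2785000, "G", "A", 0.2, 0.3, 0.25),
    AF(6870000, "T", "C", 0.4, 0.35, 0.3),
    AF(13240000, "C", "G", 0.1, 0.2, 0.12),
    AF(12905000, "A", "T", 0.02, 0.03, 0.01),
    AF(20910000, "G", "T", 0.3, 0.28, 0.33),
    AF(9310000, "A", "G", 0.22, 0.18, 0.2)
  )
  pdv_keys <- variant_key(ann[6:13, ])
  list(annotations = ann, af_table = af_table, truth_pdv = pdv_keys)
}
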