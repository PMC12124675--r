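# The potentially-deleterious-variant (PDV) filter cascade over an
# annotated nonsynonymous variant table, with known/unknown and
# rare/common classification against a reference allele-frequency table.
#
# Asymmetry, by design: a missing predictor verdict never counts as
# damaging, and a missing InterVar class never removes a row.

DAMAGING_LEVELS <- c("damaging", "possibly_damaging")
PREDICTOR_COLS <- c("sift", "sift4g", "polyphen2_hdiv", "polyphen2_hvar")
CONSEQUENCE_VOCAB <- c("missense", "stopgain", "stoploss", "nonstop",
                       "synonymous", "splice_site", "frameshift",
                       "nonframeshift", "intronic", "UTR")

variant_key <- function(tab) paste(tab$pos, tab$ref, tab$alt, sep = ":")

#' Keep nonsynonymous variants
#'
#' Retains rows whose consequence is in the configured whitelist.  A
#' consequence string outside the controlled vocabulary triggers a warning
#' and is treated as non-matching.
#'
#' @param tab annotated variant table (needs a \code{consequence} column).
#' @param whitelist retained consequences.
#' @return the surviving rows.
#' @export
filter_nonsynonymous <- function(tab,
                                 whitelist = c("missense", "stopgain",
                                               "stoploss", "nonstop")) {
  stopifnot("consequence" %in% names(tab))
  unknown <- setdiff(unique(tab$consequence), CONSEQUENCE_VOCAB)
  if (length(unknown))
    warning("unrecognized consequence(s) treated as non-matching: ",
            paste(unknown, collapse = ", "))
  out <- tab[tab$consequence %in% whitelist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep variants called damaging by at least one predictor
#'
#' A row survives iff at least one of SIFT, SIFT4G, PolyPhen2 HDIV or
#' PolyPhen2 HVAR calls it \code{damaging} or \code{possibly_damaging}.
#' Missing verdicts count as not damaging.
#'
#' @param tab variant table with the four predictor columns.
#' @return the surviving rows.
#' @export
apply_damaging_rule <- function(tab) {
  stopifnot(all(PREDICTOR_COLS %in% names(tab)))
  hit <- Reduce(`|`, lapply(PREDICTOR_COLS, function(cn) {
    v <- tab[[cn]]
    !is.na(v) & v %in% DAMAGING_LEVELS
  }))
  out <- tab[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants classified benign by InterVar
#'
#' Removes rows whose InterVar class is \code{Benign} or (by default)
#' \code{Likely benign}; a missing class never removes a row.
#'
#' @param tab variant table with an \code{intervar} column.
#' @param classes classes removed; set to \code{"Benign"} for the
#'   benign-only mode.
#' @return the surviving rows.
#' @export
remove_intervar_benign <- function(tab,
                                   classes = c("Benign", "Likely benign")) {
  stopifnot("intervar" %in% names(tab))
  drop <- !is.na(tab$intervar) & tab$intervar %in% classes
  out <- tab[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variant rarity against a reference AF table
#'
#' A variant absent from the reference table is \code{unknown}.  Otherwise
#' it is \code{rare} if its maximum allele frequency over reference
#' populations is below \code{rare_threshold}, \code{common} at or above
#' \code{common_threshold}, and \code{intermediate} between.
#'
#' @param tab variant table (keyed by \code{pos}, \code{ref}, \code{alt}).
#' @param ref_af_table reference AF table with the same key columns plus
#'   one or more \code{af_*} population columns.
#' @param rare_threshold,common_threshold max-AF cutoffs (defaults 0.01
#'   and 0.05).
#' @return \code{tab} with added columns \code{known}, \code{max_af},
#'   \code{rarity}.
#' @export
classify_rarity <- function(tab, ref_af_table, rare_threshold = 0.01,
                            common_threshold = 0.05) {
  stopifnot(rare_threshold <= common_threshold)
  af_cols <- grep("^af_", names(ref_af_table), value = TRUE)
  if (!length(af_cols)) stop("reference table has no af_* columns")
  afs <- as.matrix(ref_af_table[, af_cols, drop = FALSE])
  if (any(afs < 0 | afs > 1, na.rm = TRUE))
    stop("malformed allele frequency outside [0, 1] in reference table")
  max_af <- apply(afs, 1L, max, na.rm = TRUE)
  idx <- match(variant_key(tab), variant_key(ref_af_table))
  tab$known <- !is.na(idx)
  tab$max_af <- max_af[idx]
  tab$rarity <- ifelse(!tab$known, "unknown",
                ifelse(tab$max_af < rare_threshold, "rare",
                ifelse(tab$max_af >= common_threshold, "common",
                       "intermediate")))
  tab
}

#' Run the full PDV cascade and prevalence report
#'
#' Composition of [filter_nonsynonymous()], [apply_damaging_rule()],
#' [remove_intervar_benign()] and [classify_rarity()], with a per-stage
#' audit trail and a per-ancestry prevalence report for rare (including
#' unknown-to-reference) PDV carriers.
#'
#' @param tab annotated variant table; a \code{carriers} column holds
#'   comma-separated carrier sample ids.
#' @param ref_af_table reference AF table (see [classify_rarity()]).
#' @param samples sample table with \code{ancestry}.
#' @param ... passed to the stages (thresholds, whitelist, classes).
#' @return list with \code{pdv} (surviving classified rows), \code{audit}
#'   (rows removed per stage; input = output + sum removed), and
#'   \code{prevalence} (per-ancestry rare-PDV carrier counts and the
#'   carrier-prevalence fold ratio).
#' @export
pdv_pipeline <- function(tab, ref_af_table, samples, ...) {
  dots <- list(...)
  n0 <- nrow(tab)
  s1 <- filter_nonsynonymous(tab)
  s2 <- apply_damaging_rule(s1)
  s3 <- if (is.null(dots$classes)) remove_intervar_benign(s2) else
    remove_intervar_benign(s2, classes = dots$classes)
  pdv <- classify_rarity(s3, ref_af_table)
  audit <- data.frame(
    stage = c("nonsynonymous", "damaging_rule", "intervar_benign"),
    removed = c(n0 - nrow(s1), nrow(s1) - nrow(s2), nrow(s2) - nrow(s3)),
    stringsAsFactors = FALSE)
  rare <- pdv[pdv$rarity %in% c("rare", "unknown"), , drop = FALSE]
  carrier_ids <- unique(unlist(strsplit(rare$carriers, ",", fixed = TRUE)))
  prevalence <- do.call(rbind, lapply(split(samples, samples$ancestry),
    function(s) {
      car <- sum(s$sample_id %in% carrier_ids)
      data.frame(ancestry = s$ancestry[1L], carriers = car, n = nrow(s),
                 pct = 100 * car / nrow(s), stringsAsFactors = FALSE)
    }))
  rownames(prevalence) <- NULL
  prevalence$fold_vs_min <- prevalence_fold(prevalence$carriers, prevalence$n)
  list(pdv = pdv, audit = audit, prevalence = prevalence)
}

#' Carrier-prevalence fold ratios
#'
#' Each group's carrier prevalence divided by the smallest non-zero
#' prevalence across groups, reported to one decimal (the convention used
#' for "x-fold more likely" statements).
#'
#' @param carriers,n integer carrier counts and group sizes.
#' @return numeric fold ratios (NA where prevalence is zero everywhere).
#' @export
prevalence_fold <- function(carriers, n) {
  prev <- carriers / n
  pos <- prev[prev > 0]
  if (!length(pos)) return(rep(NA_real_, length(prev)))
  round(prev / min(pos), 1L)
}
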