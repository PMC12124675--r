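# Y-ploidy estimation from X-degenerate-region depth, tumor - blood
# ploidy deltas, the 4-SD loss-of-Y outlier rule, and ploidy-vs-age
# regression.

#' Estimate Y ploidy from binned depth
#'
#' Ploidy = base-weighted mean depth over the union of the X-degenerate
#' regions, divided by half the autosomal mean depth.  Bases with zero
#' depth contribute to the mean; weighting is per base, not per region.
#'
#' @param depth_bins \code{data.frame} with \code{start}, \code{end}
#'   (0-based half-open bins) and \code{depth} (mean reads/base in the
#'   bin); an optional \code{chrom} column is ignored (single-chromosome
#'   domain).
#' @param xdeg_regions X-degenerate interval table; normalized internally.
#' @param autosomal_mean autosomal mean depth (reads/base), > 0.
#' @return the ploidy estimate (unitless, >= 0; ~1 for a normal male).
#' @export
estimate_ploidy <- function(depth_bins, xdeg_regions, autosomal_mean) {
  if (!is.finite(autosomal_mean) || autosomal_mean <= 0)
    stop("autosomal_mean must be > 0")
  stopifnot(all(c("start", "end", "depth") %in% names(depth_bins)))
  xdeg <- normalize_mask(xdeg_regions)
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(as.integer(depth_bins$start) + 1L,
                     as.integer(depth_bins$end)),
    as_iranges(xdeg))
  if (!length(ov))
    stop("no depth bins overlap the X-degenerate regions")
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- pmin(depth_bins$end[qh], xdeg$end[sh]) -
       pmax(depth_bins$start[qh], xdeg$start[sh])
  sum(w * depth_bins$depth[qh]) / sum(w) / (0.5 * autosomal_mean)
}

#' Build per-sample ploidy records
#'
#' Runs [estimate_ploidy()] for blood and tumor depth of every sample and
#' forms the tumor - blood delta.
#'
#' @param depth named list: \code{depth[[sample_id]][[tissue]]} holds a
#'   depth-bin table.
#' @param xdeg_regions X-degenerate interval table.
#' @param samples sample table with \code{autosomal_mean_depth_blood} and
#'   \code{autosomal_mean_depth_tumor}.
#' @return \code{data.frame}: sample_id, ploidy_blood, ploidy_tumor,
#'   delta (\code{NA} when a tissue is missing).
#' @export
ploidy_records <- function(depth, xdeg_regions, samples) {
  rows <- lapply(samples$sample_id, function(sid) {
    d <- depth[[sid]]
    pb <- if (!is.null(d$blood))
      estimate_ploidy(d$blood, xdeg_regions,
                      samples$autosomal_mean_depth_blood[samples$sample_id == sid])
      else NA_real_
    pt <- if (!is.null(d$tumor))
      estimate_ploidy(d$tumor, xdeg_regions,
                      samples$autosomal_mean_depth_tumor[samples$sample_id == sid])
      else NA_real_
    data.frame(sample_id = sid, ploidy_blood = pb, ploidy_tumor = pt,
               delta = pt - pb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag loss-of-Y outliers by the 4-SD rule
#'
#' A sample is flagged iff its tumor - blood ploidy delta lies strictly
#' below the cohort mean delta minus \code{n_sd} sample standard
#' deviations (single pass: flagged samples are not excluded and the
#' moments are not recomputed).  One-sided: only ploidy loss flags.
#'
#' @param records output of [ploidy_records()].
#' @param n_sd number of SDs (default 4).
#' @return \code{records} with an added logical \code{loy_flag} (\code{NA}
#'   delta gives \code{FALSE}).
#' @export
flag_loy <- function(records, n_sd = 4) {
  d <- records$delta[!is.na(records$delta)]
  if (length(d) < 3L)
    stop("need at least 3 tumor-blood deltas for a stable SD")
  thr <- mean(d) - n_sd * stats::sd(d)
  records$loy_flag <- !is.na(records$delta) & records$delta < thr
  attr(records, "loy_threshold") <- thr
  records
}

#' Ordinary least squares of Y ploidy on age at diagnosis
#'
#' @param records output of [ploidy_records()].
#' @param samples sample table with \code{age_dx}.
#' @param tissue \code{"blood"} or \code{"tumor"}.
#' @return list: slope, intercept, r_squared, p_value (two-sided t test on
#'   the slope, n - 2 df), n.
#' @export
ploidy_age_regression <- function(records, samples, tissue = c("blood", "tumor")) {
  tissue <- match.arg(tissue)
  ploidy <- records[[paste0("ploidy_", tissue)]]
  age <- samples$age_dx[match(records$sample_id, samples$sample_id)]
  ok <- !is.na(ploidy) & !is.na(age)
  if (sum(ok) < 3L) stop("need at least 3 samples with age and ploidy")
  if (stats::sd(age[ok]) == 0) stop("zero variance in age")
  if (stats::sd(ploidy[ok]) == 0)  # constant response: flat line, no fit to test
    return(list(slope = 0, intercept = ploidy[ok][1L], r_squared = 0,
                p_value = 1, n = sum(ok)))
  fit <- stats::lm(ploidy[ok] ~ age[ok])
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = sum(ok))
}
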