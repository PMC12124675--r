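# Seeded generator for a full synthetic study: samples, haplogroups,
# truth CNVs, noisy multi-caller call sets, depth profiles with an
# implanted partial loss of Y, and a predictor-annotated variant table,
# plus truth files for evaluation.  All randomness flows through R's
# global RNG, seeded once from the configuration.

# deterministic largest-remainder apportionment of n among the freqs
apportion <- function(freqs, n) {
  raw <- freqs * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(freqs))
}

simulate_samples <- function(cfg) {
  pops <- list(African = cfg$n_african, European = cfg$n_european)
  rows <- list()
  for (pop in names(pops)) {
    n <- pops[[pop]]
    if (n == 0L) next
    prefix <- if (pop == "African") "AFR" else "EUR"
    hg <- rep(names(cfg$haplogroup_freqs[[pop]]),
              apportion(cfg$haplogroup_freqs[[pop]], n))
    hg <- sample(hg)
    n_hr <- round(cfg$hr_fraction[[pop]] * n)
    isup <- c(sample(3:5, n_hr, replace = TRUE),
              sample(1:2, n - n_hr, replace = TRUE))
    isup <- sample(isup)
    am <- cfg$age_model[[pop]]; pm <- cfg$psa_model[[pop]]
    rows[[pop]] <- data.frame(
      sample_id = sprintf("%s%03d", prefix, seq_len(n)),
      ancestry = pop,
      haplogroup = hg,
      isup = isup,
      risk = ifelse(isup >= 3, "HRPCa", "LRPCa"),
      age_dx = round(stats::rnorm(n, am[["mean"]], am[["sd"]]), 1),
      psa = round(stats::rlnorm(n, pm[["meanlog"]], pm[["sdlog"]]), 2),
      autosomal_mean_depth_blood = round(stats::rnorm(n, cfg$depth_model$autosomal_mean, 3), 2),
      autosomal_mean_depth_tumor = round(stats::rnorm(n, cfg$depth_model$autosomal_mean, 3), 2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# realize the carrier set of one catalog event
event_carriers <- function(ev, samples, known_haplogroups) {
  switch(ev$rule,
    haplogroup = {
      bad <- setdiff(names(ev$clades), known_haplogroups)
      if (length(bad))
        stop("truth CNV catalog references unknown haplogroup(s): ",
             paste(bad, collapse = ", "))
      ids <- character()
      for (cl in names(ev$clades)) {
        members <- samples$sample_id[samples$haplogroup == cl]
        frac <- ev$clades[[cl]]
        picked <- if (frac >= 1) members else
          members[stats::runif(length(members)) < frac]
        ids <- c(ids, picked)
      }
      ids
    },
    population = {
      members <- samples$sample_id[samples$ancestry == ev$population]
      members[stats::runif(length(members)) < ev$fraction]
    },
    risk = {
      key <- paste(samples$ancestry, samples$risk, sep = ".")
      frac <- ev$fractions[key]
      frac[is.na(frac)] <- 0
      samples$sample_id[stats::runif(nrow(samples)) < frac]
    },
    random = samples$sample_id[stats::runif(nrow(samples)) < ev$fraction],
    stop("unknown carrier rule: ", ev$rule))
}

#' Corrupt a truth call set with a caller error model
#'
#' Each truth interval is independently dropped with the false-negative
#' rate; surviving breakpoints are shifted by rounded Gaussian jitter
#' (clamped to the chromosome and to keep end > start); spurious calls
#' are placed uniformly with exponential lengths and random types.
#' Randomness is drawn from R's global RNG.
#'
#' @param truth interval table with a \code{type} column (gain/loss).
#' @param error list: \code{fnr}, \code{jitter_sd} (bp),
#'   \code{spurious_per_mb}, \code{spurious_mean_len}.
#' @param chry_length chromosome model length (bp).
#' @return interval table with \code{call} column (the corrupted call
#'   set, truth order first, then spurious calls).
#' @export
corrupt_calls <- function(truth, error, chry_length = 25e6) {
  stopifnot(error$jitter_sd >= 0, error$fnr >= 0, error$fnr <= 1)
  kept <- truth[stats::runif(nrow(truth)) >= error$fnr, , drop = FALSE]
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    call = character(), stringsAsFactors = FALSE)
  if (nrow(kept)) {
    s <- kept$start + round(stats::rnorm(nrow(kept), 0, error$jitter_sd))
    e <- kept$end + round(stats::rnorm(nrow(kept), 0, error$jitter_sd))
    s <- pmax(0, pmin(s, chry_length - 1))
    e <- pmax(s + 1, pmin(e, chry_length))
    out <- data.frame(chrom = kept$chrom, start = s, end = e,
                      call = kept$type, stringsAsFactors = FALSE)
  }
  n_spur <- stats::rpois(1L, error$spurious_per_mb * chry_length / 1e6)
  if (n_spur > 0L) {
    s <- floor(stats::runif(n_spur, 0, chry_length - 1))
    len <- pmax(1, round(stats::rexp(n_spur, 1 / error$spurious_mean_len)))
    e <- pmin(s + len, chry_length)
    out <- rbind(out, data.frame(chrom = "chrY", start = s, end = e,
                                 call = sample(c("gain", "loss"), n_spur,
                                               replace = TRUE),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Simulate binned depth over the chrY model
#'
#' Every bin's expected depth is \code{autosomal_mean * 0.5 * true_ploidy}
#' (single-copy model); per-bin noise is negative binomial with the
#' configured dispersion, or exact expectations when
#' \code{depth_model$noise} is \code{FALSE}.
#'
#' @param true_ploidy true Y ploidy of the tissue (>= 0).
#' @param depth_model list: \code{bin} (bp), \code{nb_size} (dispersion),
#'   \code{noise} (logical).
#' @param autosomal_mean the sample/tissue autosomal mean depth.
#' @param chry_length chromosome model length (bp).
#' @return depth-bin table: \code{chrom}, \code{start}, \code{end},
#'   \code{depth}.
#' @export
simulate_depth <- function(true_ploidy, depth_model, autosomal_mean,
                           chry_length = 25e6) {
  stopifnot(true_ploidy >= 0, autosomal_mean > 0)
  starts <- seq(0, chry_length - 1, by = depth_model$bin)
  ends <- pmin(starts + depth_model$bin, chry_length)
  mu <- autosomal_mean * 0.5 * true_ploidy
  depth <- if (isTRUE(depth_model$noise) && mu > 0)
    stats::rnbinom(length(starts), mu = mu, size = depth_model$nb_size)
  else rep(mu, length(starts))
  data.frame(chrom = "chrY", start = starts, end = ends, depth = depth,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic two-ancestry chrY cohort
#'
#' Produces, from a single seed, every input the pipeline consumes plus a
#' truth set for evaluation: sample metadata, per-caller blood and tumor
#' CNV call sets corrupted by the caller error model, binned depth with
#' one implanted partial-LOY tumor, chrY SNV counts, and a
#' predictor-annotated variant table with a reference AF table.
#'
#' @param cfg a [sim_config()].
#' @param depth simulate depth profiles (set \code{FALSE} to skip the
#'   most expensive component when not needed).
#' @param calls simulate the per-caller CNV call sets (set \code{FALSE}
#'   to skip when only depth or metadata are needed).
#' @return list of class \code{ycap_cohort}: \code{samples},
#'   \code{calls}, \code{depth}, \code{snv_counts}, \code{annotations},
#'   \code{af_table}, \code{truth} (\code{cnv}, \code{ploidy},
#'   \code{pdv}), \code{config}.
#' @export
simulate_cohort <- function(cfg = sim_config(), depth = TRUE, calls = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  samples <- simulate_samples(cfg)
  known_hg <- unlist(lapply(cfg$haplogroup_freqs, names), use.names = FALSE)

  # truth CNVs
  truth_rows <- list()
  for (ev in cfg$truth_cnv_catalog) {
    ids <- event_carriers(ev, samples, known_hg)
    if (!length(ids)) next
    truth_rows[[ev$event_id]] <- data.frame(
      sample_id = ids, tissue = ev$tissue, chrom = "chrY",
      start = ev$start, end = ev$end, type = ev$type,
      event_id = ev$event_id, stringsAsFactors = FALSE)
  }
  truth_cnv <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(sample_id = character(), tissue = character(),
               chrom = character(), start = numeric(), end = numeric(),
               type = character(), event_id = character(),
               stringsAsFactors = FALSE)
  rownames(truth_cnv) <- NULL

  # implanted partial LOY
  africans <- samples$sample_id[samples$ancestry == "African"]
  n_loy <- round(cfg$loy_fraction * length(africans))
  loy_ids <- if (n_loy > 0L) sample(africans, n_loy) else character()
  truth_ploidy <- data.frame(
    sample_id = samples$sample_id, ploidy_blood = 1,
    ploidy_tumor = ifelse(samples$sample_id %in% loy_ids, cfg$loy_ploidy, 1),
    stringsAsFactors = FALSE)

  # chrY SNV counts
  snv_counts <- data.frame(sample_id = samples$sample_id,
                           ancestry = samples$ancestry, stringsAsFactors = FALSE)
  snv_counts$n_snv <- NA_integer_
  for (pop in unique(samples$ancestry)) {
    m <- cfg$snv_model[[pop]]
    idx <- snv_counts$ancestry == pop
    snv_counts$n_snv[idx] <- stats::rnbinom(sum(idx), mu = m$mean, size = m$size)
  }

  # per-caller corrupted call sets
  call_rows <- list()
  if (isTRUE(calls)) {
    truth_by <- split(truth_cnv[, c("chrom", "start", "end", "type", "tissue")],
                      truth_cnv$sample_id)
    add_calls <- function(callers, tissue) {
      for (cl in callers) {
        for (sid in samples$sample_id) {
          tr <- truth_by[[sid]]
          tr <- if (is.null(tr)) truth_cnv[0L, c("chrom", "start", "end", "type")]
                else tr[tr$tissue == tissue, c("chrom", "start", "end", "type")]
          cc <- corrupt_calls(tr, cfg$caller_error, cfg$chry_length)
          if (!nrow(cc)) next
          cc$sample_id <- sid; cc$tissue <- tissue; cc$caller <- cl
          call_rows[[length(call_rows) + 1L]] <<- cc
        }
      }
    }
    add_calls(cfg$germline_callers, "blood")
    add_calls(cfg$somatic_callers, "tumor")
  }
  call_tab <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               call = character(), sample_id = character(),
               tissue = character(), caller = character(),
               stringsAsFactors = FALSE)
  call_tab <- call_tab[, c("sample_id", "tissue", "caller", "chrom", "start",
                           "end", "call")]
  rownames(call_tab) <- NULL

  # depth profiles
  depth_list <- NULL
  if (isTRUE(depth)) {
    depth_list <- list()
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]
      tp <- truth_ploidy[truth_ploidy$sample_id == sid, ]
      depth_list[[sid]] <- list(
        blood = simulate_depth(tp$ploidy_blood, cfg$depth_model,
                               samples$autosomal_mean_depth_blood[i],
                               cfg$chry_length),
        tumor = simulate_depth(tp$ploidy_tumor, cfg$depth_model,
                               samples$autosomal_mean_depth_tumor[i],
                               cfg$chry_length))
    }
  }

  ann <- default_variant_catalog(samples)

  structure(list(samples = samples, calls = call_tab, depth = depth_list,
                 snv_counts = snv_counts, annotations = ann$annotations,
                 af_table = ann$af_table,
                 truth = list(cnv = truth_cnv, ploidy = truth_ploidy,
                              pdv = ann$truth_pdv),
                 config = cfg),
            class = "ycap_cohort")
}

#' @export
print.ycap_cohort <- function(x, ...) {
  cat("ycap_cohort:", nrow(x$samples), "samples (",
      sum(x$samples$ancestry == "African"), "African /",
      sum(x$samples$ancestry == "European"), "European ),",
      nrow(x$calls), "caller calls,", nrow(x$truth$cnv), "truth CNV rows\n")
  invisible(x)
}

#' Write a simulated cohort to pipeline input files
#'
#' Emits every file in the formats the readers consume: samples.tsv,
#' calls/<caller>.<tissue>.bed (cols 4-6: call type, caller, tissue, then
#' sample id), depth/<sample>.<tissue>.tsv, annotations.tsv, af_table.tsv,
#' truth/{cnv,ploidy,pdv}.tsv and config.yaml (resolved configuration
#' including the seed).  Output is byte-deterministic under a fixed seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ycap_cohort"))
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  tsv <- function(x, path) utils::write.table(x, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  tsv(cohort$samples, file.path(dir, "samples.tsv"))
  for (cl in unique(cohort$calls$caller)) {
    for (ti in unique(cohort$calls$tissue[cohort$calls$caller == cl])) {
      sub <- cohort$calls[cohort$calls$caller == cl & cohort$calls$tissue == ti, ]
      write_bed(sub[, c("chrom", "start", "end", "call", "caller", "tissue",
                        "sample_id")],
                file.path(dir, "calls", paste0(cl, ".", ti, ".bed")))
    }
  }
  if (!is.null(cohort$depth)) {
    dir.create(file.path(dir, "depth"), showWarnings = FALSE)
    for (sid in names(cohort$depth)) {
      for (ti in names(cohort$depth[[sid]])) {
        tsv(cohort$depth[[sid]][[ti]],
            file.path(dir, "depth", paste0(sid, ".", ti, ".tsv")))
      }
    }
  }
  tsv(cohort$snv_counts, file.path(dir, "snv_counts.tsv"))
  tsv(cohort$annotations, file.path(dir, "annotations.tsv"))
  tsv(cohort$af_table, file.path(dir, "af_table.tsv"))
  tsv(cohort$truth$cnv, file.path(dir, "truth", "cnv.tsv"))
  tsv(cohort$truth$ploidy, file.path(dir, "truth", "ploidy.tsv"))
  tsv(data.frame(variant = cohort$truth$pdv), file.path(dir, "truth", "pdv.tsv"))
  cfg <- unclass(cohort$config)
  cfg$truth_cnv_catalog <- lapply(cfg$truth_cnv_catalog, function(ev)
    lapply(ev, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Build the sample x variant haploid genotype matrix
#'
#' @param annotations annotated variant table with a \code{carriers}
#'   column (comma-separated sample ids).
#' @param samples sample table.
#' @return 0/1 matrix, rownames sample ids, colnames variant labels
#'   (rsid where present, else pos:ref:alt).
#' @export
genotype_matrix <- function(annotations, samples) {
  lab <- ifelse(!is.na(annotations$rsid) & nzchar(annotations$rsid),
                annotations$rsid, variant_key(annotations))
  m <- matrix(0L, nrow = nrow(samples), ncol = nrow(annotations),
              dimnames = list(samples$sample_id, lab))
  for (j in seq_len(nrow(annotations))) {
    ids <- strsplit(annotations$carriers[j], ",", fixed = TRUE)[[1L]]
    m[samples$sample_id %in% ids, j] <- 1L
  }
  m
}
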