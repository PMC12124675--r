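# Projection of consensus CNV events onto gene models: per-sample carrier
# matrices, stratified carrier-frequency tables, ancestral-event flagging
# and per-group burden summaries.

#' Read gene models from a BED file
#'
#' Expects \code{chrom start end name class} with class in
#' \code{protein_coding}/\code{RNA}.
#'
#' @param path BED file path.
#' @return gene table with unique names.
#' @export
read_genes <- function(path) {
  g <- read_bed(path, col_names = c("name", "gene_class"))
  if (anyDuplicated(g$name)) stop("duplicate gene names in ", path)
  if (nrow(g) && any(is.na(g$gene_class)))
    stop("gene class column required in ", path)
  g
}

#' Annotate consensus events with the genes they hit
#'
#' A gene is marked as carrying an event of a given type for a sample iff
#' some consensus event of that type overlaps the gene span by at least
#' \code{min_overlap} bases (default 1).  A sample counts once per gene
#' per type regardless of how many segments hit it.
#'
#' @param events consensus event table (needs \code{sample_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{call}).
#' @param genes gene table from [read_genes()].
#' @param samples optional sample table fixing the row universe (otherwise
#'   the samples present in \code{events}).
#' @param min_overlap minimum overlap in bases.
#' @return object of class \code{gene_event_matrix}: a list with
#'   \code{matrix} (samples x gene:type logical), \code{long} (one row per
#'   sample/gene/type hit) and \code{genes}.
#' @export
annotate_events <- function(events, genes, samples = NULL, min_overlap = 1L) {
  validate_intervals(genes, "gene model")
  sample_ids <- if (!is.null(samples)) samples$sample_id else sort(unique(events$sample_id))
  cols <- if (nrow(genes)) {
    as.vector(outer(genes$name, CALL_TYPES, paste, sep = ":"))
  } else character()
  mat <- matrix(FALSE, nrow = length(sample_ids), ncol = length(cols),
                dimnames = list(sample_ids, cols))
  if (nrow(genes) == 0L) {
    warning("empty gene set: returning an empty carrier matrix")
    return(structure(list(matrix = mat,
                          long = data.frame(sample_id = character(),
                                            gene = character(),
                                            gene_class = character(),
                                            call = character(),
                                            stringsAsFactors = FALSE),
                          genes = genes),
                     class = "gene_event_matrix"))
  }
  long <- list()
  if (nrow(events)) {
    ev <- events[events$call %in% CALL_TYPES, , drop = FALSE]
    for (chr in unique(ev$chrom)) {
      e <- ev[ev$chrom == chr, , drop = FALSE]
      g <- genes[genes$chrom == chr, , drop = FALSE]
      if (!nrow(g)) next
      ov <- IRanges::findOverlaps(as_iranges(e), as_iranges(g),
                                  minoverlap = min_overlap)
      if (!length(ov)) next
      long[[length(long) + 1L]] <- data.frame(
        sample_id = e$sample_id[S4Vectors::queryHits(ov)],
        gene = g$name[S4Vectors::subjectHits(ov)],
        gene_class = g$gene_class[S4Vectors::subjectHits(ov)],
        call = e$call[S4Vectors::queryHits(ov)],
        stringsAsFactors = FALSE)
    }
  }
  long <- if (length(long)) unique(do.call(rbind, long)) else
    data.frame(sample_id = character(), gene = character(),
               gene_class = character(), call = character(),
               stringsAsFactors = FALSE)
  rownames(long) <- NULL
  if (nrow(long)) {
    long <- long[long$sample_id %in% sample_ids, , drop = FALSE]
    mat[cbind(match(long$sample_id, sample_ids),
              match(paste(long$gene, long$call, sep = ":"), cols))] <- TRUE
  }
  structure(list(matrix = mat, long = long, genes = genes),
            class = "gene_event_matrix")
}

#' @export
print.gene_event_matrix <- function(x, ...) {
  cat("gene_event_matrix:", nrow(x$matrix), "samples x",
      ncol(x$matrix), "gene:type columns;",
      sum(x$matrix), "carrier flags set\n")
  invisible(x)
}

#' Per-gene carrier-frequency table by stratum
#'
#' Counts carriers of each gene x type column within each level of a
#' sample stratifier (e.g. ancestry).  Percentages always use the full
#' stratum size as denominator.
#'
#' @param gem [annotate_events()] result.
#' @param samples sample table.
#' @param by stratifier column in \code{samples}.
#' @return long \code{data.frame}: gene, call, stratum, carriers, n, pct.
#' @export
carrier_frequency <- function(gem, samples, by = "ancestry") {
  stopifnot(inherits(gem, "gene_event_matrix"), by %in% names(samples))
  m <- gem$matrix[samples$sample_id, , drop = FALSE]
  strata <- split(seq_len(nrow(samples)), samples[[by]])
  out <- list()
  for (lev in names(strata)) {
    idx <- strata[[lev]]
    carriers <- colSums(m[idx, , drop = FALSE])
    gene_call <- strsplit(colnames(m), ":", fixed = TRUE)
    out[[lev]] <- data.frame(
      gene = vapply(gene_call, `[[`, "", 1L),
      call = vapply(gene_call, `[[`, "", 2L),
      stratum = lev,
      carriers = as.integer(carriers),
      n = length(idx),
      pct = 100 * carriers / length(idx),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Any-event carrier rates per stratum
#'
#' Fraction of samples in each stratum carrying at least one event
#' (overall and per call type).  Denominators are full stratum sizes.
#'
#' @inheritParams carrier_frequency
#' @param columns optional restriction to a subset of gene:type columns.
#' @return \code{data.frame}: stratum, call (\code{any}/gain/loss),
#'   carriers, n, pct.
#' @export
carrier_rates <- function(gem, samples, by = "ancestry", columns = NULL) {
  stopifnot(inherits(gem, "gene_event_matrix"), by %in% names(samples))
  m <- gem$matrix[samples$sample_id, , drop = FALSE]
  if (!is.null(columns)) m <- m[, intersect(colnames(m), columns), drop = FALSE]
  type_of <- vapply(strsplit(colnames(m), ":", fixed = TRUE), `[[`, "", 2L)
  strata <- split(seq_len(nrow(samples)), samples[[by]])
  out <- list()
  for (lev in names(strata)) {
    idx <- strata[[lev]]
    for (what in c("any", CALL_TYPES)) {
      cols <- if (what == "any") seq_along(type_of) else which(type_of == what)
      car <- sum(rowSums(m[idx, cols, drop = FALSE]) > 0L)
      out[[length(out) + 1L]] <- data.frame(
        stratum = lev, call = what, carriers = car, n = length(idx),
        pct = 100 * car / length(idx), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag likely haplogroup-ancestral gene events
#'
#' A gene x type column is flagged ancestral if, within any haplogroup
#' clade of at least \code{min_clade} samples, the carrier fraction
#' reaches \code{clade_threshold}.  Clades are the haplogroup labels plus
#' their major-letter prefixes.  Flagged columns are retained in the
#' matrix but excluded from individual-event summaries by downstream
#' callers.
#'
#' @param gem [annotate_events()] result.
#' @param samples sample table with a \code{haplogroup} column.
#' @param clade_threshold carrier fraction at/above which a clade-wide
#'   event is called ancestral (default 0.8).
#' @param min_clade smallest clade size considered (default 5).
#' @return \code{gem} with an added logical \code{ancestral} vector (one
#'   entry per matrix column).
#' @export
flag_ancestral <- function(gem, samples, clade_threshold = 0.8, min_clade = 5L) {
  stopifnot(inherits(gem, "gene_event_matrix"),
            "haplogroup" %in% names(samples))
  m <- gem$matrix[samples$sample_id, , drop = FALSE]
  major <- sub("[^A-Za-z].*$", "", samples$haplogroup)
  clades <- c(split(seq_len(nrow(samples)), samples$haplogroup),
              split(seq_len(nrow(samples)), major))
  clades <- clades[!duplicated(lapply(clades, sort))]
  flag <- rep(FALSE, ncol(m))
  for (idx in clades) {
    if (length(idx) < min_clade) next
    frac <- colSums(m[idx, , drop = FALSE]) / length(idx)
    flag <- flag | (frac >= clade_threshold)
  }
  gem$ancestral <- stats::setNames(flag, colnames(m))
  gem
}

#' Per-stratum CNV burden summary
#'
#' For each ancestry x risk stratum: number of carriers and mean, sample
#' SD (n - 1 denominator), and range of the number of genes affected
#' among carriers — gains and losses separately and combined.
#'
#' @param gem [annotate_events()] result.
#' @param samples sample table with \code{ancestry} and \code{risk}.
#' @param gene_class optional restriction (\code{"protein_coding"} or
#'   \code{"RNA"}).
#' @return \code{data.frame}, one row per stratum x call type; summary
#'   fields are \code{NA} where undefined (no carriers, or SD of one
#'   carrier).
#' @export
summarize_burden <- function(gem, samples, gene_class = NULL) {
  stopifnot(inherits(gem, "gene_event_matrix"))
  m <- gem$matrix[samples$sample_id, , drop = FALSE]
  gene_call <- strsplit(colnames(m), ":", fixed = TRUE)
  gene_nm <- vapply(gene_call, `[[`, "", 1L)
  type_of <- vapply(gene_call, `[[`, "", 2L)
  if (!is.null(gene_class)) {
    keep_genes <- gem$genes$name[gem$genes$gene_class == gene_class]
    sel <- gene_nm %in% keep_genes
    m <- m[, sel, drop = FALSE]; type_of <- type_of[sel]; gene_nm <- gene_nm[sel]
  }
  strat <- interaction(samples$ancestry, samples$risk, sep = "/", drop = FALSE)
  out <- list()
  for (lev in levels(strat)) {
    idx <- which(strat == lev)
    for (what in c("any", CALL_TYPES)) {
      cols <- if (what == "any") seq_along(type_of) else which(type_of == what)
      counts <- rowSums(m[idx, cols, drop = FALSE])
      counts <- counts[counts > 0L]
      out[[length(out) + 1L]] <- data.frame(
        stratum = lev, call = what, n = length(idx),
        carriers = length(counts),
        mean_genes = if (length(counts)) mean(counts) else NA_real_,
        sd_genes = if (length(counts) >= 2L) stats::sd(counts) else NA_real_,
        min_genes = if (length(counts)) min(counts) else NA_real_,
        max_genes = if (length(counts)) max(counts) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
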