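# Multi-caller CNV consensus: breakpoint atomization, conflict removal,
# k-of-n concurrence, and merging of adjacent same-type segments.
#
# The merge is deliberately conservative: a span of a call contradicted by
# an opposite-type call from any other caller is dropped at atom
# granularity, with no majority override, before the concurrence rule is
# applied.

CALL_TYPES <- c("gain", "loss")

#' Map integer copy numbers to call types
#'
#' Callers differ in whether they emit haploid- or diploid-baseline copy
#' numbers on chrY; the per-caller \code{baseline} handles both: with
#' baseline 1 (haploid), CN 0 is a loss and CN >= 2 a gain; with baseline
#' 2, CN < 2 is a loss and CN > 2 a gain.
#'
#' @param copy_number integer copy numbers.
#' @param baseline 1 (haploid, default) or 2 (diploid-style caller output).
#' @return character vector in \code{gain}/\code{loss}/\code{neutral}.
#' @export
copy_number_to_call <- function(copy_number, baseline = 1L) {
  stopifnot(baseline %in% c(1L, 2L), all(copy_number >= 0, na.rm = TRUE))
  ifelse(copy_number < baseline, "loss",
         ifelse(copy_number > baseline, "gain", "neutral"))
}

validate_calls <- function(calls) {
  need <- c("sample_id", "tissue", "caller", "chrom", "start", "end", "call")
  stopifnot(is.data.frame(calls), all(need %in% names(calls)))
  validate_intervals(calls, "caller call")
  bad <- setdiff(unique(calls$call), c(CALL_TYPES, "neutral"))
  if (length(bad)) stop("unknown call type(s): ", paste(bad, collapse = ", "))
  invisible(calls)
}

#' Atomize one sample/tissue's calls at every breakpoint
#'
#' Splits the union of all callers' gain/loss calls at the sorted union of
#' their breakpoints.  Each resulting atom records, per call type, the set
#' of callers covering it; a caller is counted at most once per atom per
#' type even if it emitted duplicate overlapping calls.  Neutral calls
#' carry no event semantics and are ignored.
#'
#' @param calls caller-call table for a single sample, tissue and
#'   chromosome.
#' @return \code{data.frame} with \code{chrom}, \code{start}, \code{end},
#'   list-columns \code{gain_callers}/\code{loss_callers} and counts
#'   \code{n_gain}/\code{n_loss}.  Atoms partition the union of the call
#'   footprints; no two atoms overlap.
#' @export
atomize <- function(calls) {
  validate_calls(calls)
  if (length(unique(calls$tissue)) > 1L)
    stop("atomize: calls mix tissues (", paste(unique(calls$tissue), collapse = ", "), ")")
  if (length(unique(calls$sample_id)) > 1L)
    stop("atomize: calls mix samples")
  calls <- calls[calls$call %in% CALL_TYPES, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_gain = integer(), n_loss = integer(),
                      stringsAsFactors = FALSE)
  empty$gain_callers <- list(); empty$loss_callers <- list()
  if (nrow(calls) == 0L) return(empty)
  if (length(unique(calls$chrom)) > 1L)
    stop("atomize: calls span more than one chromosome")
  ir <- as_iranges(calls)
  atoms_ir <- IRanges::disjoin(ir)
  atoms <- iranges_to_df(atoms_ir, chrom = calls$chrom[1L])
  ov <- IRanges::findOverlaps(atoms_ir, ir)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  sup <- function(type) {
    lapply(seq_len(nrow(atoms)), function(i) {
      j <- sh[qh == i]
      sort(unique(calls$caller[j][calls$call[j] == type]))
    })
  }
  atoms$gain_callers <- sup("gain")
  atoms$loss_callers <- sup("loss")
  atoms$n_gain <- lengths(atoms$gain_callers)
  atoms$n_loss <- lengths(atoms$loss_callers)
  atoms
}

#' Remove atoms with conflicting call types
#'
#' Drops every atom supported by at least one caller for gain and at least
#' one for loss, regardless of majority; all other atoms pass unchanged.
#'
#' @param atoms output of [atomize()].
#' @return the surviving atoms.
#' @export
resolve_conflicts <- function(atoms) {
  keep <- !(atoms$n_gain > 0L & atoms$n_loss > 0L)
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the k-of-n concurrence rule
#'
#' Keeps conflict-free atoms whose (single) present call type is supported
#' by at least \code{k} callers.  Germline mode uses k = 2 of 3 callers;
#' somatic mode k = 2 of 2, i.e. the caller intersection.
#'
#' @param atoms conflict-free atoms.
#' @param k minimum number of concurring callers (>= 1).
#' @param n_callers number of configured callers; supplying it enables the
#'   sanity check \code{k <= n_callers}.
#' @return the surviving atoms.
#' @export
apply_concurrence <- function(atoms, k, n_callers = NULL) {
  stopifnot(k >= 1L)
  if (!is.null(n_callers) && k > n_callers)
    stop("concurrence threshold k = ", k, " exceeds the ", n_callers,
         " configured callers")
  if (any(atoms$n_gain > 0L & atoms$n_loss > 0L))
    stop("apply_concurrence expects conflict-free atoms")
  keep <- pmax(atoms$n_gain, atoms$n_loss) >= k
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-type atoms into consensus events
#'
#' Overlapping or bookended atoms of the same call type are merged into
#' maximal events (reduce semantics; \code{max_gap} bases of separation are
#' tolerated, default 0).  Different types never merge.  The supporting
#' caller count of a merged event is the minimum (default) or maximum over
#' its constituent atoms.
#'
#' @param atoms surviving atoms.
#' @param max_gap largest gap (bases) still merged; 0 = overlap/bookend only.
#' @param support one of \code{"min"} (conservative, default) or
#'   \code{"max"}.
#' @return events \code{data.frame}: \code{chrom}, \code{start}, \code{end},
#'   \code{call}, \code{n_support}.
#' @export
merge_adjacent <- function(atoms, max_gap = 0L, support = c("min", "max")) {
  support <- match.arg(support)
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    call = character(), n_support = integer(),
                    stringsAsFactors = FALSE)
  for (type in CALL_TYPES) {
    n <- if (type == "gain") atoms$n_gain else atoms$n_loss
    sub <- atoms[n > 0L, , drop = FALSE]
    if (nrow(sub) == 0L) next
    red <- IRanges::reduce(as_iranges(sub), min.gapwidth = max_gap + 1L,
                           with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    nsup <- vapply(revmap, function(idx) {
      v <- if (type == "gain") sub$n_gain[idx] else sub$n_loss[idx]
      as.integer(if (support == "min") min(v) else max(v))
    }, integer(1L))
    ev <- iranges_to_df(red, chrom = sub$chrom[1L])
    ev$call <- type
    ev$n_support <- nsup
    out <- rbind(out, ev)
  }
  out <- out[order(out$start, out$end, out$call), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full consensus pipeline over a cohort call table
#'
#' Per sample and tissue: atomize at all callers' breakpoints, drop
#' conflicted atoms, apply the k-of-n concurrence rule, then merge
#' adjacent same-type atoms.  Germline mode expects three callers and
#' keeps spans with evidence in at least two; somatic mode keeps the
#' two-caller intersection.
#'
#' @param calls caller-call table (any number of samples/tissues).
#' @param mode \code{"germline"} (k = 2 of the configured callers, default
#'   3) or \code{"somatic"} (k = number of callers, default 2).
#' @param k override of the concurrence threshold.
#' @param callers caller set; defaults to the callers present in
#'   \code{calls}.
#' @param max_gap,support,min_len passed to / applied after
#'   [merge_adjacent()]; events shorter than \code{min_len} are dropped
#'   (default 0 = no length filter).
#' @return consensus events with \code{sample_id}, \code{tissue},
#'   \code{chrom}, \code{start}, \code{end}, \code{call}, \code{n_support}.
#' @export
consensus_pipeline <- function(calls, mode = c("germline", "somatic"),
                               k = NULL, callers = NULL, max_gap = 0L,
                               support = "min", min_len = 0L) {
  mode <- match.arg(mode)
  validate_calls(calls)
  if (is.null(callers)) callers <- sort(unique(calls$caller))
  if (is.null(k)) k <- if (mode == "germline") 2L else length(callers)
  if (k > length(callers))
    stop("concurrence threshold k = ", k, " exceeds the ",
         length(callers), " configured callers")
  out <- list()
  grp <- interaction(calls$sample_id, calls$tissue, calls$chrom, drop = TRUE)
  for (part in split(calls, grp)) {
    atoms <- atomize(part)
    atoms <- resolve_conflicts(atoms)
    atoms <- apply_concurrence(atoms, k = k, n_callers = length(callers))
    ev <- merge_adjacent(atoms, max_gap = max_gap, support = support)
    if (nrow(ev) == 0L) next
    ev$sample_id <- part$sample_id[1L]
    ev$tissue <- part$tissue[1L]
    out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(), tissue = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      call = character(), n_support = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[res$end - res$start >= min_len,
             c("sample_id", "tissue", "chrom", "start", "end", "call", "n_support"),
             drop = FALSE]
  rownames(res) <- NULL
  res
}
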