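# Evaluation of consensus calls against a simulated truth set.

#' Per-event Jaccard recovery of truth CNVs
#'
#' For every truth event, the best Jaccard index (intersection over
#' union of the base sets) against the consensus events of the same
#' sample, tissue and call type.  An unrecovered event scores 0.
#'
#' @param truth truth CNV table (\code{sample_id}, \code{tissue},
#'   \code{start}, \code{end}, \code{type}).
#' @param events consensus event table from [consensus_pipeline()].
#' @param min_len only truth events at least this long are evaluated.
#' @return \code{truth} (filtered to \code{min_len}) with an added
#'   \code{jaccard} column.
#' @export
event_recovery <- function(truth, events, min_len = 0L) {
  truth <- truth[truth$end - truth$start >= min_len, , drop = FALSE]
  jac <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ev <- events[events$sample_id == truth$sample_id[i] &
                 events$tissue == truth$tissue[i] &
                 events$call == truth$type[i], , drop = FALSE]
    if (!nrow(ev)) next
    inter <- pmax(0, pmin(ev$end, truth$end[i]) - pmax(ev$start, truth$start[i]))
    uni <- (ev$end - ev$start) + (truth$end[i] - truth$start[i]) - inter
    jac[i] <- max(inter / uni)
  }
  truth$jaccard <- jac
  rownames(truth) <- NULL
  truth
}
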