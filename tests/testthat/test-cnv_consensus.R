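mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = "s1", tissue = "blood", caller = r[[1]],
               chrom = "chrY", start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), call = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("atomization splits at every breakpoint and records support per caller", {
  calls <- mk_calls(list("A", 0, 100, "loss"), list("B", 50, 150, "loss"))
  at <- atomize(calls)
  expect_equal(at$start, c(0, 50, 100))
  expect_equal(at$end, c(50, 100, 150))
  expect_equal(at$n_loss, c(1L, 2L, 1L))
  expect_equal(at$loss_callers[[2]], c("A", "B"))
  expect_equal(at$n_gain, c(0L, 0L, 0L))

  # single call is its own atom
  single <- atomize(mk_calls(list("A", 10, 20, "loss")))
  expect_equal(single$start, 10)
  expect_equal(single$end, 20)

  # identical calls from three callers collapse to one atom
  tri <- atomize(mk_calls(list("A", 100, 200, "loss"),
                          list("B", 100, 200, "loss"),
                          list("C", 100, 200, "loss")))
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$loss_callers[[1]], c("A", "B", "C"))

  # duplicate overlapping calls from one caller count once
  dup <- atomize(mk_calls(list("A", 0, 100, "loss"), list("A", 50, 100, "loss")))
  expect_true(all(dup$n_loss == 1L))

  # neutral calls carry no event semantics
  neu <- atomize(mk_calls(list("A", 0, 100, "neutral")))
  expect_equal(nrow(neu), 0L)

  mixed <- mk_calls(list("A", 0, 10, "loss"))
  mixed$tissue <- "blood"
  mixed2 <- mixed; mixed2$tissue <- "tumor"
  expect_error(atomize(rbind(mixed, mixed2)), "mix tissues")
})

test_that("conflicted atoms are removed with no majority override", {
  calls <- mk_calls(list("A", 0, 100, "gain"), list("B", 0, 100, "loss"),
                    list("C", 0, 100, "loss"))
  at <- atomize(calls)
  expect_equal(nrow(resolve_conflicts(at)), 0L)  # 2-vs-1 still dropped

  ok <- atomize(mk_calls(list("A", 0, 100, "loss"), list("B", 0, 100, "loss")))
  expect_equal(nrow(resolve_conflicts(ok)), 1L)
})

test_that("the k-of-n concurrence rule keeps only well-supported atoms", {
  at <- atomize(mk_calls(list("A", 0, 100, "loss"), list("B", 50, 150, "loss")))
  kept <- apply_concurrence(at, k = 2L)
  expect_equal(kept$start, 50)
  expect_equal(kept$end, 100)
  expect_equal(nrow(apply_concurrence(at, k = 1L)), 3L)
  expect_error(apply_concurrence(at, k = 3L, n_callers = 2L), "exceeds")
})

test_that("adjacent same-type atoms merge; gaps and type changes do not", {
  at <- atomize(mk_calls(list("A", 50, 100, "loss"), list("A", 100, 130, "loss")))
  ev <- merge_adjacent(at)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(50, 130))

  gap <- atomize(mk_calls(list("A", 50, 100, "loss"), list("A", 101, 130, "loss")))
  expect_equal(nrow(merge_adjacent(gap)), 2L)
  expect_equal(nrow(merge_adjacent(gap, max_gap = 1L)), 1L)

  tw <- atomize(mk_calls(list("A", 50, 100, "loss"), list("A", 100, 130, "gain")))
  ev2 <- merge_adjacent(tw)
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$call, c("loss", "gain"))

  # merged support is the minimum over constituents by default
  mixed <- atomize(mk_calls(list("A", 0, 100, "loss"), list("B", 0, 50, "loss")))
  kept <- apply_concurrence(mixed, k = 1L)
  evm <- merge_adjacent(kept)
  expect_equal(evm$n_support, 1L)
  expect_equal(merge_adjacent(kept, support = "max")$n_support, 2L)
})

test_that("the composed pipeline reproduces the staged traces", {
  tri <- mk_calls(list("A", 100, 200, "loss"), list("B", 100, 200, "loss"),
                  list("C", 100, 200, "loss"))
  ev <- consensus_pipeline(tri, "germline")
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end, ev$n_support), c(100, 200, 3))

  two <- mk_calls(list("A", 0, 100, "loss"), list("B", 50, 150, "loss"))
  ev2 <- consensus_pipeline(two, "germline", callers = c("A", "B", "C"))
  expect_equal(c(ev2$start, ev2$end, ev2$n_support), c(50, 100, 2))

  conf <- mk_calls(list("A", 0, 100, "gain"), list("B", 0, 100, "loss"),
                   list("C", 0, 100, "loss"))
  expect_equal(nrow(consensus_pipeline(conf, "germline")), 0L)

  expect_error(consensus_pipeline(two, "germline", k = 4L), "exceeds")
})

test_that("pipeline equals the per-base brute-force vote on random instances", {
  set.seed(101)
  G <- 10000L
  for (rep in 1:60) {
    calls <- random_call_set(G)
    if (!nrow(calls)) next
    ev <- consensus_pipeline(calls, "germline", callers = c("A", "B", "C"))
    got <- event_cover(ev, G)
    want <- oracle_consensus_cover(calls, k = 2L, G)
    expect_identical(got$gain, want$gain)
    expect_identical(got$loss, want$loss)
  }
})

test_that("every output base is supported by >= k same-type callers and none opposite", {
  set.seed(202)
  G <- 10000L
  for (rep in 1:20) {
    calls <- random_call_set(G)
    if (!nrow(calls)) next
    ev <- consensus_pipeline(calls, "germline", callers = c("A", "B", "C"))
    vote <- oracle_consensus_cover(calls, k = 2L, G)
    cov <- event_cover(ev, G)
    expect_true(all(vote$gain[cov$gain]))
    expect_true(all(vote$loss[cov$loss]))
  }
})

test_that("consensus is idempotent at k = 1 and monotone in k", {
  set.seed(303)
  G <- 10000L
  for (rep in 1:10) {
    calls <- random_call_set(G)
    if (!nrow(calls)) next
    ev <- consensus_pipeline(calls, "germline", callers = c("A", "B", "C"))
    # feed the output back as a single caller's call set
    back <- ev
    back$caller <- "solo"
    ev2 <- consensus_pipeline(back[, names(calls)], "germline",
                              k = 1L, callers = "solo")
    expect_equal(ev2[, c("start", "end", "call")], ev[, c("start", "end", "call")])
    # raising k never adds covered bases
    cov2 <- event_cover(ev, G)
    ev3 <- consensus_pipeline(calls, "germline", k = 3L,
                              callers = c("A", "B", "C"))
    cov3 <- event_cover(ev3, G)
    expect_true(all(cov2$gain[cov3$gain]))
    expect_true(all(cov2$loss[cov3$loss]))
  }
})
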