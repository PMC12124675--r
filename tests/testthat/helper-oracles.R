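# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# per-base majority-free consensus vote on a small genome
oracle_consensus_cover <- function(calls, k, genome_len) {
  types <- c("gain", "loss")
  cover <- list()
  for (type in types) {
    votes <- integer(genome_len)
    sub <- calls[calls$call == type, , drop = FALSE]
    for (cl in unique(sub$caller)) {
      caller_cov <- logical(genome_len)
      cs <- sub[sub$caller == cl, , drop = FALSE]
      for (i in seq_len(nrow(cs))) {
        b <- (cs$start[i] + 1):cs$end[i]   # 1-based base indices
        caller_cov[b] <- TRUE              # caller counted once per base
      }
      votes <- votes + caller_cov
    }
    cover[[type]] <- votes
  }
  list(gain = cover$gain >= k & cover$loss == 0,
       loss = cover$loss >= k & cover$gain == 0)
}

# base cover of a consensus event table
event_cover <- function(events, genome_len) {
  out <- list(gain = logical(genome_len), loss = logical(genome_len))
  for (i in seq_len(nrow(events))) {
    b <- (events$start[i] + 1):events$end[i]
    out[[events$call[i]]][b] <- TRUE
  }
  out
}

random_call_set <- function(genome_len = 10000L, callers = c("A", "B", "C"),
                            max_calls = 50L) {
  rows <- list()
  for (cl in callers) {
    n <- sample(0:max_calls, 1L)
    if (n == 0L) next
    s <- sample(0:(genome_len - 2L), n, replace = TRUE)
    len <- pmax(1L, stats::rgeom(n, 1 / 300) + 1L)
    rows[[cl]] <- data.frame(
      sample_id = "s1", tissue = "blood", caller = cl, chrom = "chrY",
      start = s, end = pmin(s + len, genome_len),
      call = sample(c("gain", "loss"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample_id = character(), tissue = character(),
                      caller = character(), chrom = character(),
                      start = numeric(), end = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# two-sided Fisher p by direct enumeration with factorial arithmetic
# (no dhyper), point-probability convention
oracle_fisher_2x2 <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1]); N <- sum(tb)
  if (N == 0 || c1 == 0 || c1 == N || r1 == 0 || r2 == 0) return(1)
  lp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(N - c1) -
      lfactorial(N) - lfactorial(a) - lfactorial(b) - lfactorial(c) - lfactorial(d)
  }
  as <- max(0, c1 - r2):min(r1, c1)
  lps <- vapply(as, lp, numeric(1))
  lobs <- lp(tb[1, 1])
  min(1, sum(exp(lps[lps <= lobs + log(1 + 1e-7)])))
}

# exact two-sided rank-sum p by complete enumeration of rank subsets
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(N, n1)
  us <- apply(subsets, 2, function(s) sum(r[s])) - n1 * (n1 + 1) / 2
  lower <- mean(us <= u_obs); upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}
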