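# Cohort association layer.
#
# The exact tests are authored from first principles: the 2x2 Fisher test
# sums hypergeometric point probabilities no larger than the observed
# table's (the point-probability / minimum-likelihood convention, which
# is what reproduces the study's printed p-values), the r x c test
# enumerates tables with fixed margins (falling back to a seeded
# Monte-Carlo estimate past an enumeration bound), and the exact rank-sum
# null distribution is built by q-binomial polynomial convolution.
# stats::fisher.test / stats::wilcox.test are used only as independent
# cross-checks in the test suite.

REL_EPS <- 1 + 1e-7  # relative tolerance when comparing point probabilities

check_table <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("contingency table has negative counts")
  if (any(x != round(x))) stop("contingency table has non-integer counts")
  storage.mode(x) <- "double"
  x
}

#' Two-sided exact Fisher test for a 2x2 table
#'
#' Computes the two-sided p-value as the sum of hypergeometric point
#' probabilities (margins fixed) not exceeding the observed table's
#' probability, in log space.  This point-probability convention matches
#' standard statistical software.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list of class \code{ycap_test}: \code{p_value},
#'   \code{odds_ratio} (sample OR, \code{NA} on zero margins),
#'   \code{method}, \code{table}.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- check_table(table)
  stopifnot(all(dim(x) == c(2L, 2L)))
  m <- sum(x[1L, ]); n <- sum(x[2L, ]); K <- sum(x[, 1L])
  if (m + n == 0L || K == 0L || K == m + n) {
    p <- 1
  } else {
    k <- max(0, K - n):min(K, m)
    logp <- stats::dhyper(k, m, n, K, log = TRUE)
    logobs <- stats::dhyper(x[1L, 1L], m, n, K, log = TRUE)
    p <- min(1, sum(exp(logp[logp <= logobs + log(REL_EPS)])))
  }
  or <- if (x[1L, 2L] * x[2L, 1L] > 0) (x[1L, 1L] * x[2L, 2L]) / (x[1L, 2L] * x[2L, 1L]) else NA_real_
  structure(list(p_value = p, odds_ratio = or,
                 method = "Fisher exact (2x2, point probability)",
                 table = x),
            class = "ycap_test")
}

# log probability of an r x c table under fixed margins
log_prob_table <- function(x, lconst = NULL) {
  if (is.null(lconst))
    lconst <- sum(lfactorial(rowSums(x))) + sum(lfactorial(colSums(x))) -
      lfactorial(sum(x))
  lconst - sum(lfactorial(x))
}

# enumerate all tables with the given margins, calling fn(table);
# aborts (returns FALSE) when more than max_tables are visited
enumerate_tables <- function(row_margins, col_margins, fn, max_tables = Inf) {
  r <- length(row_margins); cc <- length(col_margins)
  x <- matrix(0, r, cc)
  count <- 0L
  rec <- function(i, j, row_left, col_left) {
    if (count > max_tables) return(FALSE)
    if (i == r && j == cc) {
      v <- min(row_left[i], col_left[j])
      if (row_left[i] == col_left[j]) {
        x[i, j] <<- v
        count <<- count + 1L
        if (count > max_tables) return(FALSE)
        fn(x)
      }
      return(TRUE)
    }
    ni <- if (j == cc) i + 1L else i
    nj <- if (j == cc) 1L else j + 1L
    last_in_row <- j == cc
    last_in_col <- i == r
    lo <- if (last_in_col) col_left[j] else 0
    lo <- max(lo, if (last_in_row) row_left[i] else 0)
    hi <- min(row_left[i], col_left[j])
    if (lo > hi) return(TRUE)
    for (v in lo:hi) {
      x[i, j] <<- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- cl[j] - v
      if (!rec(ni, nj, rl, cl)) return(FALSE)
    }
    TRUE
  }
  rec(1L, 1L, row_margins, col_margins)
}

#' Exact (or Monte-Carlo) Fisher test for an r x c table
#'
#' Enumerates every table with the observed margins and sums the
#' probabilities of those no more probable than the observed table.  If
#' the enumeration would visit more than \code{max_enumeration} tables, a
#' seeded Monte-Carlo estimate over \code{mc_reps} Patefield-sampled
#' tables is returned instead, with its standard error.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param max_enumeration enumeration bound (number of tables).
#' @param mc_reps Monte-Carlo replicates.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return \code{ycap_test} list: \code{p_value}, \code{method},
#'   \code{mc_se} (NA on the exact path), \code{table}.
#' @export
fisher_exact_rxc <- function(table, max_enumeration = 2e5, mc_reps = 1e4,
                             seed = NULL) {
  x <- check_table(table)
  if (all(dim(x) == c(2L, 2L))) {
    res <- fisher_exact_2x2(x)
    res$mc_se <- NA_real_
    return(res)
  }
  rm. <- rowSums(x); cm <- colSums(x)
  lconst <- sum(lfactorial(rm.)) + sum(lfactorial(cm)) - lfactorial(sum(x))
  lobs <- log_prob_table(x, lconst)
  acc <- 0
  done <- enumerate_tables(rm., cm, function(tb) {
    lp <- log_prob_table(tb, lconst)
    if (lp <= lobs + log(REL_EPS)) acc <<- acc + exp(lp)
  }, max_tables = max_enumeration)
  if (done) {
    return(structure(list(p_value = min(1, acc),
                          method = "Fisher exact (r x c, full enumeration)",
                          mc_se = NA_real_, table = x),
                     class = "ycap_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  sims <- stats::r2dtable(mc_reps, rm., cm)
  hits <- vapply(sims, function(tb) log_prob_table(tb, lconst) <= lobs + log(REL_EPS),
                 logical(1L))
  phat <- (1 + sum(hits)) / (mc_reps + 1)
  structure(list(p_value = phat,
                 method = "Fisher (r x c, Monte Carlo)",
                 mc_se = sqrt(phat * (1 - phat) / mc_reps), table = x),
            class = "ycap_test")
}

# counts of the Mann-Whitney U distribution for sample sizes n1, n2:
# coefficients of the Gaussian binomial [n1+n2, n1]_q, built by exact
# polynomial multiplication and synthetic division (integer-valued).
rank_sum_counts <- function(n1, n2) {
  poly <- 1
  for (i in seq_len(n1)) {
    # multiply by (1 - q^(n2 + i))
    p1 <- c(poly, rep(0, n2 + i)) - c(rep(0, n2 + i), poly)
    # divide by (1 - q^i): synthetic division, exact
    q <- numeric(length(p1) - i)
    r <- p1
    for (j in seq_along(q)) {
      q[j] <- r[j]
      r[j + i] <- r[j + i] + r[j]
    }
    poly <- q
  }
  poly  # length n1*n2 + 1; counts for U = 0..n1*n2
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value from the full rank-sum null distribution when
#' both samples have at most \code{exact_max} observations and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction.  Conventions match the standard two-sided
#' doubling of the smaller tail, capped at 1.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max largest per-sample size for the exact path (default
#'   50).
#' @return \code{ycap_test} list: \code{statistic} (Mann-Whitney U for
#'   \code{x}), \code{p_value}, \code{method}, \code{n}.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 50L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && n1 <= exact_max && n2 <= exact_max
  if (exact) {
    cnt <- rank_sum_counts(n1, n2)
    tot <- sum(cnt)
    lower <- sum(cnt[seq_len(u + 1)]) / tot          # P(U <= u)
    upper <- sum(cnt[(u + 1):length(cnt)]) / tot     # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "Wilcoxon rank-sum (exact)"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)          # continuity correction
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "Wilcoxon rank-sum (normal approximation, tie + continuity corrected)"
  }
  structure(list(statistic = u, p_value = p, method = method, n = c(n1, n2)),
            class = "ycap_test")
}

#' @export
print.ycap_test <- function(x, ...) {
  cat(x$method, "\n  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Build a carrier or cross-classification contingency table
#'
#' With \code{carriers}, returns the stratum x carrier/non-carrier table
#' (denominators are full stratum sizes).  With \code{response}, returns
#' the stratifier x response cross-classification (e.g. haplogroup x
#' risk).
#'
#' @param samples sample table.
#' @param stratifier column of \code{samples} defining the rows.
#' @param carriers character vector of carrier sample ids (or logical
#'   vector along \code{samples}).
#' @param response column of \code{samples} defining the columns instead
#'   of carrier status.
#' @return integer matrix with dimnames.
#' @export
build_carrier_table <- function(samples, stratifier = "ancestry",
                                carriers = NULL, response = NULL) {
  stopifnot(stratifier %in% names(samples))
  strata <- samples[[stratifier]]
  if (length(unique(strata)) < 2L)
    stop("stratifier '", stratifier, "' has fewer than two levels")
  if (is.null(response)) {
    if (is.null(carriers)) stop("supply carriers or response")
    is_car <- if (is.logical(carriers)) carriers else samples$sample_id %in% carriers
    tb <- table(strata, factor(ifelse(is_car, "carrier", "non_carrier"),
                               levels = c("carrier", "non_carrier")))
  } else {
    stopifnot(response %in% names(samples))
    tb <- table(strata, samples[[response]])
  }
  m <- matrix(as.integer(tb), nrow = nrow(tb), dimnames = dimnames(tb))
  names(dimnames(m)) <- NULL
  m
}

#' Screen variants for haplogroup-clade concordance
#'
#' For each clade, reports variants carried by (nearly) all clade members
#' and (nearly) no non-members: a variant is perfectly concordant with a
#' clade when mismatches (members without it plus non-members with it)
#' are zero, and near-concordant when mismatches do not exceed
#' \code{max_mismatch}.  Variants fixed in the whole cohort are flagged
#' \code{cohort_fixed} (they are concordant only with the root).
#'
#' @param geno samples x variants 0/1 haploid genotype matrix (rownames =
#'   sample ids).
#' @param clades character vector of clade labels along the rows of
#'   \code{geno} (a partition of the samples).
#' @param max_mismatch largest number of violations still reported.
#' @return \code{data.frame}: clade, variant, clade_size,
#'   carriers_in_clade, carriers_outside, mismatches, concordant,
#'   cohort_fixed.
#' @export
clade_marker_concordance <- function(geno, clades, max_mismatch = 0L) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == length(clades), all(geno %in% c(0L, 1L)))
  tot <- colSums(geno)
  fixed <- tot == nrow(geno)
  out <- list()
  for (cl in unique(clades)) {
    inside <- clades == cl
    car_in <- colSums(geno[inside, , drop = FALSE])
    car_out <- tot - car_in
    mism <- (sum(inside) - car_in) + car_out
    keep <- which(mism <= max_mismatch)
    if (!length(keep)) next
    out[[cl]] <- data.frame(
      clade = cl, variant = colnames(geno)[keep],
      clade_size = sum(inside),
      carriers_in_clade = as.integer(car_in[keep]),
      carriers_outside = as.integer(car_out[keep]),
      mismatches = as.integer(mism[keep]),
      concordant = mism[keep] == 0L,
      cohort_fixed = fixed[keep],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(clade = character(), variant = character(),
               clade_size = integer(), carriers_in_clade = integer(),
               carriers_outside = integer(), mismatches = integer(),
               concordant = logical(), cohort_fixed = logical(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
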