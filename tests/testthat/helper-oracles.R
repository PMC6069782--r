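# Independent brute-force oracles used to pin the fast implementations.
# These deliberately take the naive per-record route.

# Local tricube weighted-least-squares fit evaluated at one query point:
# pick the ceiling(span * n) records nearest to d, weight by tricube of
# scaled distance, fit a raw polynomial with lm.wfit, return its value at d.
oracle_loess_at <- function(D, M, d, span, degree) {
  n <- length(D)
  r <- abs(D - d)
  q <- min(ceiling(span * n), n)
  h <- sort(r)[q]
  if (h == 0) return(mean(M[r == 0]))
  w <- (1 - pmin(r / h, 1)^3)^3
  w[r >= h] <- 0
  keep <- w > 0
  xc <- D[keep] - d
  if (length(unique(xc)) <= degree) {
    return(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  X <- vapply(0:degree, function(k) xc^k, numeric(sum(keep)))
  fit <- stats::lm.wfit(X, M[keep], w[keep])
  unname(fit$coefficients[1L])
}

# Benjamini-Hochberg step-up by hand: sort, p * n / rank, cumulative min
# from the largest p down, cap at 1, unsort.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Matthews correlation coefficient straight from its defining formula.
oracle_mcc <- function(TP, FP, TN, FN) {
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

# Per-record interval-overlap filter: a record survives iff neither of its
# bins intersects any exclusion interval (0-based half-open arithmetic).
oracle_exclude <- function(records, resolution, intervals) {
  keep <- vapply(seq_len(nrow(records)), function(i) {
    s1 <- records$start1[i]; s2 <- records$start2[i]
    hit <- FALSE
    for (k in seq_len(nrow(intervals))) {
      a <- intervals$start[k]; b <- intervals$end[k]
      if ((s1 < b && s1 + resolution > a) ||
          (s2 < b && s2 + resolution > a)) hit <- TRUE
    }
    !hit
  }, logical(1))
  records[keep, , drop = FALSE]
}

# Small contact-table builder for literal fixtures.
ct <- function(start1, start2, IF, chrom = "chr1", res = 1e6) {
  contact_table(data.frame(start1 = start1, start2 = start2, IF = IF),
                chrom = chrom, resolution = res)
}
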