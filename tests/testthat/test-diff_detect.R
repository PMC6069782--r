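joint_with <- function(M, A, D = NULL) {
  n <- length(M)
  if (is.null(D)) D <- seq_len(n)
  start1 <- (stats::ave(D, D, FUN = seq_along) - 1) * 1e6
  IF1 <- pmax(2 * A / (1 + 2^M), 1e-6)
  IF2 <- 2 * A - IF1   # so (IF1+IF2)/2 = A and log2(IF2/IF1) = M
  t1 <- contact_table(data.frame(start1 = start1, start2 = start1 + D * 1e6,
                                 IF = IF1), "chr1", 1e6)
  t2 <- contact_table(data.frame(start1 = start1, start2 = start1 + D * 1e6,
                                 IF = IF2), "chr1", 1e6)
  join_pair(t1, t2)
}

test_that("Z-scores standardize retained M values", {
  j <- joint_with(M = c(1, 2, 3), A = c(20, 20, 20))
  res <- compute_zscores(j, diff_params(A_min = 15))
  expect_equal(res$joint$records$Z, c(-1, 0, 1))
  expect_equal(res$stats$M_bar, 2)
  expect_equal(res$stats$sigma_M, 1)  # sample (n-1) sd
  expect_equal(res$stats$n_retained, 3L)
})

test_that("filtering by A excludes records from both stats and testing", {
  j <- joint_with(M = c(1, 2, 3, 10), A = c(20, 20, 20, 5))
  res <- compute_zscores(j, diff_params(A_min = 15))
  rec <- res$joint$records[order(res$joint$records$A), ]
  low <- rec[1, ]
  expect_equal(low$Z, 0)
  expect_equal(low$status, "filtered")
  # mean/sd from the retained three only: M_bar = 2, sigma = 1
  expect_equal(sort(rec$Z), c(-1, 0, 0, 1))
  expect_equal(res$stats$n_filtered, 1L)

  # retained Z has sample mean 0, sd 1 by construction
  set.seed(6)
  j2 <- joint_with(M = rnorm(200), A = runif(200, 5, 50))
  r2 <- compute_zscores(j2, diff_params(A_min = 15))
  zt <- r2$joint$records$Z[r2$joint$records$status == "tested"]
  expect_equal(mean(zt), 0, tolerance = 1e-9)
  expect_equal(sd(zt), 1, tolerance = 1e-9)

  expect_error(compute_zscores(joint_with(M = c(1, 1, 1), A = rep(20, 3))),
               "no variability")
  # lowering A_min can only grow the tested set
  n_tested <- function(am) {
    r <- compute_zscores(j2, diff_params(A_min = am))
    sum(r$joint$records$status == "tested")
  }
  expect_true(all(diff(vapply(c(40, 25, 15, 5, 0), n_tested, numeric(1))) >= 0))
})

test_that("Z-scores map to two-sided normal p-values", {
  expect_equal(zscore_to_pvalue(0), 1)
  expect_equal(zscore_to_pvalue(1.959964), 0.05, tolerance = 1e-4)
  z <- rnorm(50)
  expect_equal(zscore_to_pvalue(z), zscore_to_pvalue(-z))
  # oracle: qnorm inverts the tail
  expect_equal(zscore_to_pvalue(stats::qnorm(1 - 0.01 / 2)), 0.01)
})

test_that("per-distance BH matches hand values and the step-up oracle", {
  j <- joint_with(M = c(2.4, 1.9, 0.1, -0.3, 0.2), A = rep(20, 5),
                  D = c(1, 1, 1, 2, 2))
  res <- compute_zscores(j, diff_params(A_min = 0))
  # force a known p layout through a stratum: check hand BH on [0.01, 0.04]
  expect_equal(oracle_bh(c(0.01, 0.04)), c(0.02, 0.04))
  adj <- adjust_pvalues(res$joint, diff_params(A_min = 0))
  rec <- adj$records
  for (d in unique(rec$D)) {
    at <- rec$D == d & rec$status == "tested"
    expect_equal(rec$p.adj[at], oracle_bh(rec$p[at]))
  }
  # single tested record in a stratum: p.adj == p
  single <- rec[rec$D == 2, ]
  if (nrow(single) == 1) expect_equal(single$p.adj, single$p)

  # random strata, exact agreement with the brute-force oracle
  set.seed(8)
  jr <- joint_with(M = rnorm(120), A = runif(120, 0, 40),
                   D = sample(1:6, 120, TRUE))
  rr <- compute_zscores(jr, diff_params(A_min = 15))
  ar <- adjust_pvalues(rr$joint, diff_params(A_min = 15))
  rec <- ar$records
  for (d in unique(rec$D)) {
    at <- rec$D == d & rec$status == "tested"
    if (any(at)) expect_identical(rec$p.adj[at], oracle_bh(rec$p[at]))
  }
  expect_true(all(is.na(rec$p.adj[rec$status != "tested"])))
  # BH never decreases a p-value and stays within [p, 1]
  t <- rec$status == "tested"
  expect_true(all(rec$p.adj[t] >= rec$p[t] - 1e-12))
  expect_true(all(rec$p.adj[t] <= 1))

  # per-chromosome scope: one family
  ac <- adjust_pvalues(rr$joint,
                       diff_params(A_min = 15, adjust_scope = "per_chromosome"))
  t <- ac$records$status == "tested"
  expect_equal(ac$records$p.adj[t], oracle_bh(ac$records$p[t]))
  # other methods route through p.adjust
  ab <- adjust_pvalues(rr$joint,
                       diff_params(A_min = 15, adjust_method = "bonferroni",
                                   adjust_scope = "per_chromosome"))
  t <- ab$records$status == "tested"
  expect_equal(ab$records$p.adj[t],
               pmin(ab$records$p[t] * sum(t), 1))
})

test_that("difference calling respects alpha and ordering", {
  set.seed(12)
  jr <- joint_with(M = rnorm(80), A = runif(80, 10, 40),
                   D = sample(1:4, 80, TRUE))
  rr <- compute_zscores(jr, diff_params(A_min = 15))
  ar <- adjust_pvalues(rr$joint, diff_params(A_min = 15))
  all_called <- call_differences(ar, diff_params(A_min = 15, alpha = 0.999999))
  # everything short of p.adj = 1 comes back, i.e. the full tested set except
  # records whose adjusted p-value was capped at 1
  expect_equal(nrow(all_called),
               sum(ar$records$p.adj < 0.999999, na.rm = TRUE))
  expect_true(!is.unsorted(all_called$p.adj))
  none <- call_differences(ar, diff_params(A_min = 15, alpha = 1e-12))
  expect_equal(nrow(none), 0L)
})
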