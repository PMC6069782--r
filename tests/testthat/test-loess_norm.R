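joint_from_dm <- function(D, M) {
  # build a joint table realizing a given (D, M) cloud: IF1 = 16,
  # IF2 = 16 * 2^M; duplicates of a distance are spread across start1 so
  # (bin1, bin2) keys stay unique
  start1 <- stats::ave(D, D, FUN = seq_along) - 1
  t1 <- contact_table(data.frame(start1 = start1 * 1e6,
                                 start2 = (start1 + D) * 1e6,
                                 IF = rep(16, length(D))), "chr1", 1e6)
  t2 <- contact_table(data.frame(start1 = start1 * 1e6,
                                 start2 = (start1 + D) * 1e6,
                                 IF = 16 * 2^M), "chr1", 1e6)
  join_pair(t1, t2)
}

test_that("constant M yields a constant trend; affine M is reproduced exactly", {
  D <- rep(0:19, each = 3)
  jc <- joint_from_dm(D, rep(0.7, length(D)))
  fit <- fit_trend(jc, span = 0.4)
  expect_equal(fit$fitted, rep(0.7, length(fit$distances)), tolerance = 1e-10)

  # local linear regression is exact on affine data at any span
  M <- 0.1 + 0.05 * D
  jl <- joint_from_dm(D, M)
  for (span in c(0.3, 0.75, 1)) {
    fit <- fit_trend(jl, span = span, degree = 1)
    expect_equal(fit$fitted, 0.1 + 0.05 * fit$distances, tolerance = 1e-8)
  }
})

test_that("fitted values match the brute-force tricube WLS oracle", {
  set.seed(31)
  for (case in 1:3) {
    n <- sample(80:200, 1)
    D <- sample(0:34, n, replace = TRUE)
    M <- sin(D / 6) + rnorm(n, sd = 0.3)
    j <- joint_from_dm(D, M)
    rec <- j$records
    for (degree in 1:2) {
      for (span in c(0.3, 0.5, 0.75)) {
        fit <- fit_trend(j, span = span, degree = degree)
        want <- vapply(fit$distances, function(d) {
          oracle_loess_at(rec$D, rec$M, d, span, degree)
        }, numeric(1))
        expect_equal(fit$fitted, want, tolerance = 1e-8)
      }
    }
  }
})

test_that("degenerate inputs are rejected", {
  j <- joint_from_dm(rep(3, 10), rnorm(10))
  expect_error(fit_trend(j, span = 0.5), "identical")
  j2 <- joint_from_dm(c(0, 1), c(0, 1))
  expect_error(fit_trend(j2, span = 0.5), "too few")
})

test_that("span cross-validation is deterministic and sane", {
  set.seed(5)
  D <- rep(0:39, each = 5)
  j <- joint_from_dm(D, sin(D / 5) + rnorm(length(D), sd = 0.2))
  expect_equal(select_span(j, candidate_spans = 0.42), 0.42)
  s1 <- select_span(j, c(0.2, 0.5, 1), k_folds = 4, seed = 7)
  s2 <- select_span(j, c(0.2, 0.5, 1), k_folds = 4, seed = 7)
  expect_identical(s1, s2)
  expect_true(s1 %in% c(0.2, 0.5, 1))
  # on strongly curved data, the huge span cannot win against the best
  cv_err <- function(sp) {
    fold <- with_seed(7, sample(rep_len(1:4, nrow(j$records))))
    fit <- fit_trend(j, span = sp)
    mean((j$records$M - predict(fit, j$records$D))^2)
  }
  expect_lt(cv_err(s1), cv_err(1) + 1e-9)
})

test_that("joint normalization follows the equation pair and the <1 drop rule", {
  # IF1 = 4, IF2 = 16, f(D) = 2 -> both sides land on 8, M' = 0
  j <- joint_from_dm(rep(c(1, 2), each = 4), rep(2, 8))  # M = 2 everywhere
  j$records[, `:=`(IF1 = 4, IF2 = 16)]
  fit <- fit_trend(j, span = 1)
  expect_equal(fit$fitted, rep(2, 2), tolerance = 1e-10)
  out <- apply_joint_normalization(j, fit)
  expect_equal(out$records$IF1, rep(8, 8))
  expect_equal(out$records$IF2, rep(8, 8))
  expect_equal(out$records$M, rep(0, 8), tolerance = 1e-12)

  # f = 0 is the identity
  f0 <- structure(list(distances = fit$distances,
                       fitted = c(0, 0), span = 1, degree = 1,
                       n_points = 8), class = "trend_fit")
  ident <- apply_joint_normalization(j, f0)
  expect_equal(ident$records$IF1, j$records$IF1)
  expect_equal(ident$records$IF2, j$records$IF2)
  expect_equal(ident$records$M, j$records$M)

  # a normalized IF of 0.5 < 1 drops the record
  jd <- joint_from_dm(c(1, 1, 2), c(0, 0, 0))
  jd$records[, `:=`(IF1 = c(2, 100, 100), IF2 = c(2, 100, 100))]
  fdrop <- structure(list(distances = c(1, 2), fitted = c(-4, -4),
                          span = 1, degree = 1, n_points = 3),
                     class = "trend_fit")
  # 2^(log2(2) - 4/2) = 0.5 on side 1
  dropped <- apply_joint_normalization(jd, fdrop)
  expect_equal(nrow(dropped$records), 2L)
  expect_equal(attr(dropped, "n_dropped"), 1L)

  # querying a distance with no fitted value is an error
  expect_error(apply_joint_normalization(joint_from_dm(c(1, 2, 3), 1:3), fit),
               "no fitted value")
})

test_that("normalization conserves the per-pair log sum and removes the trend", {
  bl <- default_bias_library()
  pair <- simulate_replicate_pair(
    sim_params(n_bins = 150, bias_fn = bl$linear_in_logD(0.4, 0.2)), seed = 13)
  j <- join_pair(pair$t1, pair$t2)
  fit <- fit_trend(j, span = 0.3)
  out <- apply_joint_normalization(j, fit)
  # surviving records keep their geometric mean exactly
  key <- paste(out$records$start1, out$records$start2)
  before <- j$records[match(key, paste(j$records$start1, j$records$start2)), ]
  expect_equal(log2(out$records$IF1) + log2(out$records$IF2),
               log2(before$IF1) + log2(before$IF2), tolerance = 1e-9)
  # M recentred: M' = M - f(D)
  expect_equal(out$records$M, before$M - predict(fit, out$records$D),
               tolerance = 1e-9)
  # the trend refit on normalized data is flat
  refit <- fit_trend(out, span = 0.3)
  expect_lt(max(abs(refit$fitted[refit$distances <= 37])), 0.05)
})

test_that("normalizing (t1,t2) and (t2,t1) are mirror images", {
  pair <- simulate_replicate_pair(sim_params(n_bins = 80, depth_ratio = 1.5),
                                  seed = 17)
  j12 <- join_pair(pair$t1, pair$t2)
  j21 <- join_pair(pair$t2, pair$t1)
  f12 <- fit_trend(j12, span = 0.5)
  f21 <- fit_trend(j21, span = 0.5)
  expect_equal(f12$fitted, -f21$fitted, tolerance = 1e-9)
  n12 <- apply_joint_normalization(j12, f12)
  n21 <- apply_joint_normalization(j21, f21)
  expect_equal(n12$records$M, -n21$records$M, tolerance = 1e-9)
  expect_equal(n12$records$IF1, n21$records$IF2, tolerance = 1e-9)
})

test_that("stats::loess agrees qualitatively with the trend fit", {
  # independent cross-check: same data, reference smoother, loose tolerance
  # (neighbourhood conventions differ slightly between implementations)
  set.seed(23)
  D <- rep(0:29, each = 10)
  M <- 0.8 * sin(D / 7) + rnorm(length(D), sd = 0.2)
  j <- joint_from_dm(D, M)
  fit <- fit_trend(j, span = 0.5)
  ref <- stats::loess(M ~ D, span = 0.5, degree = 1, family = "gaussian",
                      surface = "direct")
  expect_lt(max(abs(fit$fitted - predict(ref, data.frame(D = fit$distances)))),
            0.1)
})
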