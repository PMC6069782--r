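#' Fit the between-dataset bias trend f(D) by local regression
#'
#' Locally weighted polynomial regression of `M` on `D` over all records with
#' a defined `M`. At each query distance `d` the fitted value `f(d)` is the
#' value at `d` of a degree-`degree` polynomial estimated by weighted least
#' squares on the `ceiling(span * n)` points nearest to `d` by `|D - d|`,
#' with tricube weights
#' `w = (1 - (|D - d| / h)^3)^3`, `h` the largest neighbour distance. Points
#' at exactly `|D - d| = h` receive weight 0; if `h = 0` (the query distance
#' alone holds the whole neighbourhood) the fit degenerates to the local
#' mean. `D` is integer-valued and many records share each distance; every
#' record enters individually, which the implementation exploits by
#' aggregating per-distance moments, so the cost is driven by the number of
#' distinct distances rather than the number of records.
#'
#' @param joint a [join_pair()] result (normalized or not).
#' @param span fraction of the points in each local window, in (0, 1].
#' @param degree local polynomial degree, 1 (default; robust in the sparse
#'   far-distance tail) or 2.
#' @return a `trend_fit`: list with `distances` (sorted unique observed D),
#'   `fitted` (f at each), `span`, `degree`, `n_points`.
#' @seealso [apply_joint_normalization()], [select_span()]
#' @export
fit_trend <- function(joint, span = 0.75, degree = 1) {
  stopifnot(inherits(joint, "joint_table"),
            is.numeric(span), length(span) == 1L, span > 0, span <= 1,
            degree %in% c(1, 2))
  rec <- joint$records[joint$records$status == "ok", ]
  n <- nrow(rec)
  if (n < degree + 2) stop("too few points with defined M to fit a trend")
  if (length(unique(rec$D)) < 2L) {
    stop("all distances identical; no trend to fit")
  }
  if (ceiling(span * n) < degree + 1) stop("span window smaller than degree + 1")
  dist_stats <- rec[, list(n = .N, S = sum(M)), by = "D"]
  data.table::setorderv(dist_stats, "D")
  fitted <- .loess_predict(dist_stats, dist_stats$D, span, degree, n)
  structure(list(distances = dist_stats$D, fitted = fitted,
                 span = span, degree = degree, n_points = n),
            class = "trend_fit")
}

# Local WLS at arbitrary query distances, from per-distance sufficient
# statistics (counts n and M-sums S). Weights depend on D only, so the
# normal equations collapse onto per-distance moments.
.loess_predict <- function(dist_stats, query, span, degree, n_total) {
  u <- dist_stats$D
  nu <- dist_stats$n
  Su <- dist_stats$S
  q <- min(ceiling(span * n_total), n_total)
  vapply(query, function(d) {
    r <- abs(u - d)
    o <- order(r)
    cum <- cumsum(nu[o])
    k <- which(cum >= q)[1L]
    h <- r[o[k]]
    if (h == 0) {            # neighbourhood entirely at the query distance
      at <- which(r == 0)
      return(sum(Su[at]) / sum(nu[at]))
    }
    w <- (1 - pmin(r / h, 1)^3)^3
    w[r >= h] <- 0
    pos <- which(w > 0)
    xc <- u[pos] - d
    wn <- w[pos] * nu[pos]
    wS <- w[pos] * Su[pos]
    if (length(pos) <= degree) return(sum(wS) / sum(wn))
    if (degree == 1) {
      m0 <- sum(wn); m1 <- sum(wn * xc); m2 <- sum(wn * xc^2)
      v0 <- sum(wS); v1 <- sum(wS * xc)
      det <- m0 * m2 - m1^2
      if (abs(det) < 1e-12 * max(m0 * m2, 1)) return(v0 / m0)
      (m2 * v0 - m1 * v1) / det
    } else {
      m <- vapply(0:4, function(k) sum(wn * xc^k), numeric(1))
      v <- vapply(0:2, function(k) sum(wS * xc^k), numeric(1))
      Xt <- matrix(c(m[1], m[2], m[3],
                     m[2], m[3], m[4],
                     m[3], m[4], m[5]), 3, 3)
      b <- tryCatch(solve(Xt, v), error = function(e) NULL)
      if (is.null(b)) return(v[1] / m[1])
      b[1]
    }
  }, numeric(1))
}

#' Evaluate a fitted trend at given distances
#'
#' @param object a `trend_fit`
#' @param newdata numeric distances; must be among the fitted distances
#'   (the trend is estimated per observed distance; D is integer-valued so
#'   no interpolation is needed).
#' @param ... unused
#' @return fitted f at each distance
#' @export
predict.trend_fit <- function(object, newdata, ...) {
  idx <- match(newdata, object$distances)
  if (anyNA(idx)) {
    stop(sprintf("no fitted value at distance %g",
                 newdata[which(is.na(idx))[1L]]))
  }
  object$fitted[idx]
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: %d distances, span %.3g, degree %d, n = %d\n",
              length(x$distances), x$span, x$degree, x$n_points))
  invisible(x)
}

#' Serialize a trend fit to TSV (columns D, f)
#' @param fit a `trend_fit`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trend <- function(fit, path) {
  stopifnot(inherits(fit, "trend_fit"))
  data.table::fwrite(data.table::data.table(D = fit$distances, f = fit$fitted),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Choose the loess span by k-fold cross-validation
#'
#' Splits the M-defined records into `k_folds` folds (seeded, deterministic),
#' fits the trend on each training set for every candidate span, predicts the
#' held-out M values at their distances and returns the candidate minimizing
#' the mean held-out squared error. Ties break toward the smaller span.
#'
#' @param joint a `joint_table`
#' @param candidate_spans numeric candidates in (0, 1]
#' @param k_folds number of folds (>= 2)
#' @param seed integer seed controlling the fold split
#' @param degree local polynomial degree passed to the fit
#' @return the selected span (scalar)
#' @export
select_span <- function(joint, candidate_spans = c(0.1, 0.25, 0.5, 0.75, 1),
                        k_folds = 5, seed = 1, degree = 1) {
  stopifnot(inherits(joint, "joint_table"), length(candidate_spans) >= 1,
            all(candidate_spans > 0), all(candidate_spans <= 1), k_folds >= 2)
  if (length(candidate_spans) == 1L) return(candidate_spans)
  rec <- joint$records[joint$records$status == "ok", ]
  n <- nrow(rec)
  if (n < k_folds) stop("fewer records than folds")
  fold <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  cv_err <- vapply(sort(candidate_spans), function(sp) {
    se <- 0
    for (kf in seq_len(k_folds)) {
      train <- rec[fold != kf, ]
      test <- rec[fold == kf, ]
      ds <- train[, list(n = .N, S = sum(M)), by = "D"]
      data.table::setorderv(ds, "D")
      if (ceiling(sp * nrow(train)) < degree + 1 || nrow(ds) < 2L) {
        return(Inf)
      }
      uq <- sort(unique(test$D))
      fu <- .loess_predict(ds, uq, sp, degree, nrow(train))
      fhat <- fu[match(test$D, uq)]
      se <- se + sum((test$M - fhat)^2)
    }
    se / n
  }, numeric(1))
  sort(candidate_spans)[which.min(cv_err)]
}

#' Apply the symmetric joint normalization
#'
#' Removes the fitted between-dataset bias by moving each dataset half-way:
#' \deqn{log2(IF1') = log2(IF1) + f(D)/2, \quad log2(IF2') = log2(IF2) - f(D)/2}
#' then anti-logs. Per record the correction cancels, so
#' `log2 IF1' + log2 IF2'` equals `log2 IF1 + log2 IF2` exactly (the pair's
#' geometric mean is invariant), while `M` is recentred: `M' = M - f(D)`.
#' Any record whose normalized IF falls below 1 on either side is dropped
#' from further analysis; records carried with a zero IF
#' (`keep_partial_zeros`) pass through unmodified and stay flagged.
#'
#' @param joint a `joint_table`
#' @param fit a `trend_fit` covering every distance present in `joint`
#' @return a normalized `joint_table`; attribute `n_dropped` counts records
#'   removed by the IF < 1 rule.
#' @export
apply_joint_normalization <- function(joint, fit) {
  stopifnot(inherits(joint, "joint_table"), inherits(fit, "trend_fit"))
  rec <- data.table::copy(joint$records)
  ok <- rec$status == "ok"
  f <- predict(fit, rec$D[ok])
  IF1n <- 2^(log2(rec$IF1[ok]) + f / 2)
  IF2n <- 2^(log2(rec$IF2[ok]) - f / 2)
  rec[ok, `:=`(IF1 = IF1n, IF2 = IF2n,
               M = rec$M[ok] - f,
               A = (IF1n + IF2n) / 2)]
  drop <- ok & (rec$IF1 < 1 | rec$IF2 < 1)
  out <- rec[!drop, ]
  res <- structure(list(chrom = joint$chrom, resolution = joint$resolution,
                        zero_policy = joint$zero_policy, records = out),
                   class = "joint_table")
  attr(res, "n_dropped") <- sum(drop)
  res
}

#' Joint normalization in one call
#'
#' Fits the trend (optionally CV-selecting the span) and applies the
#' symmetric rescaling.
#'
#' @param joint a `joint_table`
#' @param span numeric span or `"auto"` for cross-validated selection
#' @param degree local polynomial degree
#' @param seed seed for the CV fold split when `span = "auto"`
#' @return list with elements `joint` (normalized table) and `fit`
#'   (the `trend_fit` used)
#' @export
normalize_joint <- function(joint, span = "auto", degree = 1, seed = 1) {
  if (identical(span, "auto")) {
    span <- select_span(joint, seed = seed, degree = degree)
  }
  fit <- fit_trend(joint, span = span, degree = degree)
  list(joint = apply_joint_normalization(joint, fit), fit = fit)
}
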