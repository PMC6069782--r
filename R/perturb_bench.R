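#' Inject controlled differences into a replicate pair
#'
#' Creates a ground-truth set of differential interactions between two
#' replicate contact tables: a specified number of bin pairs with positive
#' IFs in both tables is sampled uniformly without replacement; at each
#' sampled pair both IFs are set to their replicate average, and then one of
#' the two (chosen uniformly at random per entry) is multiplied by
#' `fold_change`. Pre-normalization, every injected pair therefore has
#' `|M| = log2(fold_change)` exactly. All other records are untouched.
#'
#' @param t1,t2 [contact_table()]s on the same chromosome/resolution
#' @param n_changes number of entries to alter
#' @param fold_change multiplier (> 0)
#' @param seed integer seed; same seed, same truth set and matrices
#' @return list with `t1`, `t2` (modified tables) and `truth`, a
#'   `data.table` with `start1`, `start2`, `side` (1 or 2, which matrix was
#'   multiplied) and `fold_change`. Injected IFs are kept as doubles
#'   (averaging can produce .5).
#' @export
inject_differences <- function(t1, t2, n_changes, fold_change, seed = 1) {
  stopifnot(inherits(t1, "contact_table"), inherits(t2, "contact_table"),
            fold_change > 0, n_changes >= 0)
  if (t1$chrom != t2$chrom || t1$resolution != t2$resolution) {
    stop("tables must match in chromosome and resolution")
  }
  a <- data.table::copy(t1$records)
  b <- data.table::copy(t2$records)
  shared <- merge(a, b, by = c("start1", "start2"), suffixes = c("1", "2"))
  shared <- shared[shared$IF1 > 0 & shared$IF2 > 0, ]
  if (n_changes > nrow(shared)) {
    stop(sprintf("n_changes (%d) exceeds the %d keys positive in both tables",
                 n_changes, nrow(shared)))
  }
  picked <- with_seed(seed, {
    idx <- sample.int(nrow(shared), n_changes)
    side <- sample(c(1L, 2L), n_changes, replace = TRUE)
    list(idx = idx, side = side)
  })
  truth <- shared[picked$idx, c("start1", "start2"), with = FALSE]
  avg <- (shared$IF1[picked$idx] + shared$IF2[picked$idx]) / 2
  truth[, `:=`(side = picked$side, fold_change = fold_change)]
  new1 <- ifelse(picked$side == 1L, avg * fold_change, avg)
  new2 <- ifelse(picked$side == 2L, avg * fold_change, avg)
  ka <- match(paste(truth$start1, truth$start2), paste(a$start1, a$start2))
  kb <- match(paste(truth$start1, truth$start2), paste(b$start1, b$start2))
  data.table::set(a, i = ka, j = "IF", value = new1)
  data.table::set(b, i = kb, j = "IF", value = new2)
  data.table::setorderv(truth, c("start1", "start2"))
  list(t1 = contact_table(a, t1$chrom, t1$resolution),
       t2 = contact_table(b, t2$chrom, t2$resolution),
       truth = truth)
}

#' Score detected differences against an injected truth set
#'
#' Confusion counts are taken over the tested pairs only: truth entries that
#' never reached testing (filtered by average expression, dropped by the
#' IF < 1 rule, or zero in one replicate) are reported separately as
#' `n_truth_untested` rather than silently counted as misses.
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as
#' 0 when any factor of the denominator is 0.
#'
#' @param called `data.table` (or data.frame) of called pairs with columns
#'   `start1`, `start2`; must be a subset of `tested`
#' @param tested same-shaped table of all tested pairs
#' @param truth the truth table from [inject_differences()]
#' @return list with `counts` (TP, FP, TN, FN, n_truth_untested) and
#'   `metrics` (MCC, TPR, FPR, precision)
#' @export
evaluate_detection <- function(called, tested, truth) {
  keyof <- function(x) paste(x$start1, x$start2)
  kc <- keyof(called); kt <- keyof(tested); kg <- keyof(truth)
  if (!all(kc %in% kt)) stop("called pairs must be a subset of tested pairs")
  kg_tested <- intersect(kg, kt)
  TP <- sum(kc %in% kg_tested)
  FP <- length(kc) - TP
  FN <- length(kg_tested) - TP
  TN <- length(kt) - TP - FP - FN
  counts <- list(TP = TP, FP = FP, TN = TN, FN = FN,
                 n_truth_untested = length(kg) - length(kg_tested))
  den <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  metrics <- list(
    MCC = mcc,
    TPR = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
    FPR = if (FP + TN == 0) NA_real_ else FP / (FP + TN),
    precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP))
  list(counts = counts, metrics = metrics)
}

#' Controlled-difference detection benchmark
#'
#' For each fold change: inject `n_changes` controlled differences into the
#' replicate pair, join, jointly normalize, test, call at
#' `params$alpha`, and score against the injected truth. The same seed is
#' used for every fold change so the altered entries coincide across rows,
#' making the fold-change series directly comparable.
#'
#' @param t1,t2 replicate [contact_table()]s
#' @param n_changes number of injected differences (e.g. 200)
#' @param fold_changes numeric vector of fold changes (e.g. `c(2, 3, 4)`)
#' @param seed integer seed (injection sampling and span CV)
#' @param params a [diff_params()]
#' @param span loess span or `"auto"`
#' @return `data.table` with one row per fold change: fold_change, TP, FP,
#'   TN, FN, n_truth_untested, MCC, TPR, FPR, precision, n_tested
#' @export
run_benchmark <- function(t1, t2, n_changes = 200, fold_changes = c(2, 3, 4),
                          seed = 1, params = diff_params(), span = "auto") {
  rows <- lapply(fold_changes, function(fc) {
    inj <- inject_differences(t1, t2, n_changes, fc, seed = seed)
    joint <- join_pair(inj$t1, inj$t2, zero_policy = "drop_any_zero")
    norm <- normalize_joint(joint, span = span, seed = seed)
    z <- compute_zscores(norm$joint, params)
    adj <- adjust_pvalues(z$joint, params)
    called <- call_differences(adj, params)
    tested <- adj$records[adj$records$status == "tested", ]
    ev <- evaluate_detection(called, tested, inj$truth)
    data.table::data.table(fold_change = fc,
                           TP = ev$counts$TP, FP = ev$counts$FP,
                           TN = ev$counts$TN, FN = ev$counts$FN,
                           n_truth_untested = ev$counts$n_truth_untested,
                           MCC = ev$metrics$MCC, TPR = ev$metrics$TPR,
                           FPR = ev$metrics$FPR,
                           precision = ev$metrics$precision,
                           n_tested = nrow(tested))
  })
  data.table::rbindlist(rows)
}
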