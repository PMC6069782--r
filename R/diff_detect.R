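#' Parameters for differential interaction detection
#'
#' @param A_min minimum average expression a pair needs to be tested.
#'   Pairs with `A < A_min` carry little read support: an M of 3.32 from
#'   IFs (1, 10) is far less trustworthy than the same M from (10, 100).
#'   Filtered pairs get `Z = 0` and are excluded from testing; the default
#'   of 15 is deliberately user-visible and should be tuned to the depth of
#'   the data.
#' @param adjust_scope `"per_distance"` (default): multiple-testing
#'   correction applied independently within each distance stratum, so deep
#'   short-range traces do not drown sparse long-range ones; or
#'   `"per_chromosome"` for a single family.
#' @param adjust_method `"BH"` (default), `"holm"`, `"bonferroni"` or
#'   `"none"`.
#' @param alpha significance level on the adjusted p-value.
#' @return a `diff_params` list
#' @export
diff_params <- function(A_min = 15,
                        adjust_scope = c("per_distance", "per_chromosome"),
                        adjust_method = c("BH", "holm", "bonferroni", "none"),
                        alpha = 0.05) {
  adjust_scope <- match.arg(adjust_scope)
  adjust_method <- match.arg(adjust_method)
  stopifnot(A_min >= 0, alpha > 0, alpha < 1)
  structure(list(A_min = A_min, adjust_scope = adjust_scope,
                 adjust_method = adjust_method, alpha = alpha),
            class = "diff_params")
}

#' Convert M values to Z-scores with average-expression filtering
#'
#' The jointly normalized M values on a chromosome are approximately normal
#' and centred, so each pair is scored as `Z = (M - M_bar) / sigma_M` where
#' `M_bar` and `sigma_M` are the mean and (sample, n-1) standard deviation of
#' the M values on the chromosome. Filtering is applied first: pairs with
#' `A < A_min` are set to `Z = 0` and marked `filtered`, and `M_bar` and
#' `sigma_M` are computed only from the M values remaining after filtering.
#'
#' @param joint a normalized `joint_table`
#' @param params a [diff_params()]
#' @return list with `joint` (records gain `Z` and `status` in
#'   `tested`/`filtered`/`zero`) and `stats` (`M_bar`, `sigma_M`,
#'   `n_retained`, `n_filtered`)
#' @export
compute_zscores <- function(joint, params = diff_params()) {
  stopifnot(inherits(joint, "joint_table"), inherits(params, "diff_params"))
  rec <- data.table::copy(joint$records)
  ok <- rec$status == "ok"
  keep <- ok & rec$A >= params$A_min
  if (sum(keep) < 2L) stop("fewer than 2 records pass the A filter")
  M_bar <- mean(rec$M[keep])
  sigma_M <- stats::sd(rec$M[keep])
  if (sigma_M == 0) stop("no variability after filtering (sigma_M = 0)")
  rec[, "Z" := 0]
  rec[keep, "Z" := (rec$M[keep] - M_bar) / sigma_M]
  rec[ok & !keep, "status" := "filtered"]
  rec[keep, "status" := "tested"]
  out <- structure(list(chrom = joint$chrom, resolution = joint$resolution,
                        zero_policy = joint$zero_policy, records = rec),
                   class = "joint_table")
  stats <- list(M_bar = M_bar, sigma_M = sigma_M,
                n_retained = sum(keep), n_filtered = sum(ok & !keep))
  list(joint = out, stats = stats)
}

#' Two-sided normal p-value for a Z-score
#'
#' `p = 2 * (1 - Phi(|Z|))`; differences in either direction are of
#' interest. Vectorized.
#'
#' @param Z finite Z-scores
#' @return two-sided p-values
#' @export
zscore_to_pvalue <- function(Z) {
  stopifnot(all(is.finite(Z)))
  2 * stats::pnorm(-abs(Z))
}

#' Attach p-values and multiple-testing-adjusted p-values
#'
#' Tested records get a two-sided normal p-value; untested records
#' (`filtered`, `zero`) get `NA` rather than p = 1 so downstream counts stay
#' unambiguous. Adjustment is applied per distance stratum by default
#' (independent Benjamini-Hochberg families per D), or over the whole
#' chromosome.
#'
#' @param joint output `joint` of [compute_zscores()]
#' @param params a [diff_params()]
#' @return the `joint_table` with `p` and `p.adj` columns
#' @export
adjust_pvalues <- function(joint, params = diff_params()) {
  stopifnot(inherits(joint, "joint_table"), inherits(params, "diff_params"))
  rec <- data.table::copy(joint$records)
  if (!"Z" %in% names(rec)) stop("run compute_zscores() first")
  tested <- rec$status == "tested"
  rec[, "p" := NA_real_]
  rec[tested, "p" := zscore_to_pvalue(rec$Z[tested])]
  rec[, "p.adj" := NA_real_]
  method <- if (params$adjust_method == "none") "none" else params$adjust_method
  if (params$adjust_scope == "per_chromosome") {
    rec[tested, "p.adj" := stats::p.adjust(rec$p[tested], method = method)]
  } else {
    idx <- which(tested)
    padj <- rep(NA_real_, length(idx))
    for (d in unique(rec$D[idx])) {
      at <- rec$D[idx] == d
      padj[at] <- stats::p.adjust(rec$p[idx][at], method = method)
    }
    rec[idx, "p.adj" := padj]
  }
  structure(list(chrom = joint$chrom, resolution = joint$resolution,
                 zero_policy = joint$zero_policy, records = rec),
            class = "joint_table")
}

#' Call differential chromatin interactions
#'
#' Subsets records with `p.adj < alpha` (FDR < 0.05 by default), sorted by
#' adjusted p-value then by `|Z|` descending.
#'
#' @param joint a `joint_table` with `p.adj`
#' @param params a [diff_params()]
#' @return `data.table` of called records
#' @export
call_differences <- function(joint, params = diff_params()) {
  stopifnot(inherits(joint, "joint_table"))
  rec <- joint$records
  if (!"p.adj" %in% names(rec)) stop("run adjust_pvalues() first")
  hits <- rec[!is.na(rec$p.adj) & rec$p.adj < params$alpha, ]
  hits[order(hits$p.adj, -abs(hits$Z)), ]
}
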