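#' Full joint-normalization and differential-detection pipeline
#'
#' One chromosome end to end: optional region exclusion, join on the MD
#' plane, joint loess normalization, Z-score testing with
#' average-expression filtering and stratified FDR control, and difference
#' calling.
#'
#' @param t1,t2 [contact_table()]s for one chromosome
#' @param params a [diff_params()]
#' @param span loess span or `"auto"` (cross-validated)
#' @param degree local polynomial degree
#' @param zero_policy see [join_pair()]
#' @param exclude optional `GRanges` of regions to drop first
#' @param seed seed for span cross-validation
#' @return list with `joint` (annotated `joint_table`), `fit`
#'   (`trend_fit`), `stats` (Z-score statistics) and `differences`
#'   (called records)
#' @examples
#' pair <- simulate_replicate_pair(sim_params(n_bins = 120), seed = 7)
#' res <- hic_compare(pair$t1, pair$t2, span = 0.5)
#' nrow(res$differences)
#' @export
hic_compare <- function(t1, t2, params = diff_params(), span = "auto",
                        degree = 1, zero_policy = "drop_any_zero",
                        exclude = NULL, seed = 1) {
  if (!is.null(exclude)) {
    t1 <- exclude_regions(t1, exclude)
    t2 <- exclude_regions(t2, exclude)
  }
  joint <- join_pair(t1, t2, zero_policy = zero_policy)
  norm <- normalize_joint(joint, span = span, degree = degree, seed = seed)
  z <- compute_zscores(norm$joint, params)
  adj <- adjust_pvalues(z$joint, params)
  list(joint = adj, fit = norm$fit, stats = z$stats,
       differences = call_differences(adj, params))
}

#' Per-chromosome parallel comparison
#'
#' Runs [hic_compare()] independently on each chromosome of two named lists
#' of contact tables. Chromosomes never share state (normalization and
#' testing are chromosome-local by construction), so they may run
#' concurrently; each chromosome gets a seed derived deterministically from
#' `seed` and its position, making results identical for any `n_workers`.
#'
#' @param tables1,tables2 named lists of [contact_table()]s; names must match
#' @param n_workers number of worker processes (forked; 1 = serial)
#' @param ... passed to [hic_compare()]
#' @param seed base seed
#' @return named list of [hic_compare()] results
#' @export
hic_compare_chromosomes <- function(tables1, tables2, n_workers = 1,
                                    seed = 1, ...) {
  stopifnot(length(tables1) == length(tables2),
            !is.null(names(tables1)),
            setequal(names(tables1), names(tables2)))
  chroms <- sort(names(tables1))
  runs <- seq_along(chroms)
  one <- function(k) {
    ch <- chroms[k]
    # seed depends on the chromosome name only, so results for a chromosome
    # are invariant to which other chromosomes are in the run
    chseed <- (seed + sum(utf8ToInt(ch) * seq_along(utf8ToInt(ch)))) %% .Machine$integer.max
    hic_compare(tables1[[ch]], tables2[[ch]], seed = chseed, ...)
  }
  res <- if (n_workers > 1) {
    parallel::mclapply(runs, one, mc.cores = n_workers)
  } else {
    lapply(runs, one)
  }
  names(res) <- chroms
  res
}

#' MD plot
#'
#' Scatter of M against D with the fitted trend overlaid; the plain-text
#' `(D, M)` table from [md_points()] and the trend TSV from [write_trend()]
#' are the canonical outputs, the plot is a convenience.
#'
#' @param joint a `joint_table`
#' @param fit optional `trend_fit` to overlay
#' @param ... passed to [graphics::plot()]
#' @return invisibly, the plotted points
#' @export
plot_md <- function(joint, fit = NULL, ...) {
  pts <- md_points(joint)
  graphics::plot(pts$D, pts$M, pch = ".", col = "#00000044",
                 xlab = "D (unit-length distance)", ylab = "M = log2(IF2/IF1)",
                 ...)
  graphics::abline(h = 0, col = "grey60")
  if (!is.null(fit)) {
    graphics::lines(fit$distances, fit$fitted, col = "red", lwd = 2)
  }
  invisible(pts)
}
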