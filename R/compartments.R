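#' A/B compartment profile of a contact matrix
#'
#' Standard eigenvector construction: densify the table, mask bins with a
#' zero marginal, divide each entry by the mean of its off-diagonal trace
#' (observed/expected, removing the distance decay and any per-distance
#' scaling), take the Pearson correlation matrix over unmasked bins, and
#' extract its leading eigenvector. The sign of the first principal
#' component labels each bin A (positive) or B (negative); masked or
#' zero-variance bins are `NA`.
#'
#' @param table a [contact_table()]
#' @param n_bins bin count; defaults to covering the largest coordinate
#' @return a `compartment_profile`: list with `starts` (bin starts), `pc1`
#'   (unit-length, `NA` at masked bins) and `labels` (`"A"`/`"B"`/`NA`)
#' @export
compartment_profile <- function(table, n_bins = NULL) {
  stopifnot(inherits(table, "contact_table"))
  m <- as_dense_matrix(table, n_bins)
  n <- nrow(m)
  usable <- rowSums(m) > 0
  if (sum(usable) < 10L) stop("fewer than 10 non-empty bins")
  w <- m[usable, usable, drop = FALSE]
  k <- nrow(w)
  # observed / expected per off-diagonal (distance measured on the
  # unmasked grid)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  expd <- vapply(0:(k - 1), function(dd) mean(w[d == dd]), numeric(1))
  oe <- w / expd[d + 1L]
  oe[!is.finite(oe)] <- 0
  cm <- suppressWarnings(stats::cor(oe))
  zerovar <- apply(oe, 2, stats::sd) == 0
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  ev <- eigen(cm, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  v[zerovar] <- NA_real_
  pc1 <- rep(NA_real_, n)
  pc1[usable] <- v
  nrm <- sqrt(sum(pc1^2, na.rm = TRUE))
  if (nrm == 0) stop("degenerate correlation structure; no leading component")
  pc1 <- pc1 / nrm
  labels <- ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
  structure(list(starts = (seq_len(n) - 1) * table$resolution,
                 pc1 = pc1, labels = labels),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf("compartment_profile: %d bins (%d A, %d B, %d masked)\n",
              length(x$pc1), sum(x$labels == "A", na.rm = TRUE),
              sum(x$labels == "B", na.rm = TRUE), sum(is.na(x$pc1))))
  invisible(x)
}

#' Similarity between two compartment profiles
#'
#' The eigenvector sign is arbitrary, so profile `b` is first sign-aligned
#' to `a` (flipped if their Pearson correlation over jointly unmasked bins
#' is negative). Reported, all in [0, 1]:
#' \itemize{
#'   \item `abs_correlation` -- absolute Pearson correlation of the PC1
#'     vectors;
#'   \item `sign_match_proportion` -- proportion of jointly unmasked bins
#'     with matching compartment sign after alignment;
#'   \item `jaccard_A`, `jaccard_B` -- Jaccard overlap of the A (resp. B)
#'     bin sets of the two label vectors.
#' }
#'
#' @param a,b `compartment_profile`s on the same bin grid
#' @return list with the four metrics
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "compartment_profile"),
            inherits(b, "compartment_profile"))
  if (length(a$pc1) != length(b$pc1) || !all(a$starts == b$starts)) {
    stop("profiles are on different bin grids")
  }
  both <- !is.na(a$pc1) & !is.na(b$pc1)
  if (sum(both) < 2L) stop("fewer than 2 jointly unmasked bins")
  r <- stats::cor(a$pc1[both], b$pc1[both])
  bpc <- if (!is.na(r) && r < 0) -b$pc1 else b$pc1
  la <- a$labels
  lb <- ifelse(is.na(bpc), NA_character_, ifelse(bpc > 0, "A", "B"))
  jac <- function(lab) {
    sa <- which(la == lab); sb <- which(lb == lab)
    u <- union(sa, sb)
    if (length(u) == 0L) return(1)
    length(intersect(sa, sb)) / length(u)
  }
  list(abs_correlation = abs(r),
       sign_match_proportion = mean(la[both] == lb[both]),
       jaccard_A = jac("A"),
       jaccard_B = jac("B"))
}

#' Serialize a compartment profile to TSV (start, pc1, label)
#' @param profile a `compartment_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "compartment_profile"))
  data.table::fwrite(data.table::data.table(start = profile$starts,
                                            pc1 = profile$pc1,
                                            label = profile$labels),
                     path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
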