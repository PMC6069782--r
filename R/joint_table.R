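#' Join two contact tables on the MD plane
#'
#' Pairs the records of two chromosome-matched contact tables by bin pair and
#' derives the distance-centric quantities on which the whole method runs:
#' \itemize{
#'   \item `D` -- unit-length distance `(start2 - start1) / resolution`,
#'     i.e. which off-diagonal trace of the matrix the pair sits on;
#'   \item `M = log2(IF2 / IF1)` -- the log difference between the datasets;
#'   \item `A = (IF1 + IF2) / 2` -- the average expression of the pair.
#' }
#'
#' Hi-C matrices are sparse, and a zero IF cannot be told apart from missing
#' data, so by default (`zero_policy = "drop_any_zero"`) only pairs non-zero
#' in both datasets are kept. Under `"keep_partial_zeros"` pairs non-zero in
#' exactly one dataset are carried with the missing side recorded as 0 and
#' `M` undefined (`NA`, `status = "zero"`); such records are bookkeeping only
#' and never enter trend fitting or testing.
#'
#' @param t1,t2 [contact_table()]s on the same chromosome and resolution.
#' @param zero_policy `"drop_any_zero"` (default) or `"keep_partial_zeros"`.
#' @return a `joint_table`: list with `chrom`, `resolution`, `zero_policy`
#'   and `records`, a `data.table` with columns `start1`, `start2`, `IF1`,
#'   `IF2`, `D`, `M`, `A`, `status` sorted by `(D, start1)`.
#' @examples
#' t1 <- contact_table(data.frame(start1 = 0, start2 = 1e6, IF = 1), "chr1", 1e6)
#' t2 <- contact_table(data.frame(start1 = 0, start2 = 1e6, IF = 10), "chr1", 1e6)
#' join_pair(t1, t2)$records$M  # 3.32
#' @export
join_pair <- function(t1, t2,
                      zero_policy = c("drop_any_zero", "keep_partial_zeros")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(t1, "contact_table"), inherits(t2, "contact_table"))
  if (t1$chrom != t2$chrom) stop("chromosome mismatch between tables")
  if (t1$resolution != t2$resolution) stop("resolution mismatch between tables")
  a <- data.table::copy(t1$records)
  b <- data.table::copy(t2$records)
  data.table::setnames(a, "IF", "IF1")
  data.table::setnames(b, "IF", "IF2")
  rec <- merge(a, b, by = c("start1", "start2"), all = TRUE)
  rec[is.na(rec$IF1), "IF1"] <- 0
  rec[is.na(rec$IF2), "IF2"] <- 0
  if (zero_policy == "drop_any_zero") {
    rec <- rec[rec$IF1 > 0 & rec$IF2 > 0, ]
  } else {
    rec <- rec[rec$IF1 > 0 | rec$IF2 > 0, ]
  }
  res <- t1$resolution
  rec[, `:=`(D = (rec$start2 - rec$start1) / res,
             M = ifelse(rec$IF1 > 0 & rec$IF2 > 0,
                        log2(rec$IF2 / rec$IF1), NA_real_),
             A = (rec$IF1 + rec$IF2) / 2,
             status = ifelse(rec$IF1 > 0 & rec$IF2 > 0, "ok", "zero"))]
  data.table::setorderv(rec, c("D", "start1"))
  structure(list(chrom = t1$chrom, resolution = res,
                 zero_policy = zero_policy, records = rec),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat(sprintf("joint_table: %s @ %g bp, %d records (%s)\n",
              x$chrom, x$resolution, nrow(x$records), x$zero_policy))
  if (nrow(x$records)) print(utils::head(x$records, 6L))
  invisible(x)
}

#' MD-plot points
#'
#' Extracts the `(D, M)` point cloud of a joint table: the scatter of
#' log differences against unit-length distance that the bias model is fit
#' on. Records with undefined `M` (zero policy bookkeeping) are excluded.
#' Ordering is stable: by `D`, then `start1`.
#'
#' @param joint a [join_pair()] result
#' @return `data.table` with columns `D`, `M`
#' @export
md_points <- function(joint) {
  stopifnot(inherits(joint, "joint_table"))
  rec <- joint$records[joint$records$status == "ok", ]
  data.table::setorderv(rec, c("D", "start1"))
  rec[, c("D", "M"), with = FALSE]
}

#' Average expression of an interaction pair
#'
#' `A = (IF1 + IF2) / 2`. An M value of 3.32 can come from IFs (1, 10) or
#' (10, 100); their average expressions 5.5 and 55 distinguish how well the
#' difference is supported by reads, which is why testing filters on A.
#'
#' @param IF1,IF2 non-negative interaction frequencies (vectorized)
#' @return `(IF1 + IF2) / 2`
#' @export
average_expression <- function(IF1, IF2) {
  stopifnot(all(IF1 >= 0), all(IF2 >= 0))
  (IF1 + IF2) / 2
}

#' Serialize a joint table to TSV
#'
#' Columns: chrom, start1, end1, start2, end2, IF1, IF2, D, M, A and, when
#' present, Z, p, p.adj, status.
#'
#' @param joint a `joint_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_joint_table <- function(joint, path) {
  stopifnot(inherits(joint, "joint_table"))
  rec <- joint$records
  res <- joint$resolution
  out <- data.table::data.table(chrom = rep(joint$chrom, nrow(rec)),
                                start1 = rec$start1, end1 = rec$start1 + res,
                                start2 = rec$start2, end2 = rec$start2 + res)
  for (cl in intersect(c("IF1", "IF2", "D", "M", "A", "Z", "p", "p.adj",
                         "status"), names(rec))) {
    out[[cl]] <- rec[[cl]]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Split a normalized joint table back into two contact tables
#'
#' Rebuilds per-dataset sparse tables from the `IF1`/`IF2` columns, e.g. for
#' compartment profiling of normalized matrices. Records with a zero side
#' are dropped from that side (sparse semantics).
#'
#' @param joint a `joint_table`
#' @return list of two [contact_table()]s
#' @export
split_joint_table <- function(joint) {
  stopifnot(inherits(joint, "joint_table"))
  rec <- joint$records
  mk <- function(col) {
    keep <- rec[[col]] > 0
    contact_table(data.table::data.table(start1 = rec$start1[keep],
                                         start2 = rec$start2[keep],
                                         IF = rec[[col]][keep]),
                  chrom = joint$chrom, resolution = joint$resolution)
  }
  list(mk("IF1"), mk("IF2"))
}
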