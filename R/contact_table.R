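#' Sparse upper-triangular contact table
#'
#' A `contact_table` holds the intra-chromosomal interaction frequencies (IFs)
#' of a single chromosome at a fixed bin resolution, in sparse
#' upper-triangular form: one record per pair of genomic bins with
#' `start1 <= start2`. Bins are 0-based half-open intervals of width
#' `resolution`, so a record `(start1, start2, IF)` stands for the matrix cell
#' linking bins `[start1, start1 + resolution)` and `[start2, start2 + resolution)`.
#'
#' @param records a `data.frame`/`data.table` with numeric columns `start1`,
#'   `start2` and `IF`. Records with `start1 > start2` are mirrored into the
#'   upper triangle.
#' @param chrom chromosome name (single string).
#' @param resolution bin size in bp (positive integer-valued scalar).
#'
#' @return An object of class `contact_table`: a list with elements `chrom`,
#'   `resolution` and `records` (a keyed `data.table` with columns `start1`,
#'   `start2`, `IF`, sorted by `start1`, `start2`).
#'
#' @details Duplicate `(start1, start2)` keys after mirroring are an error:
#' silently summing duplicates would hide upstream bugs. Coordinates must be
#' non-negative multiples of `resolution`; IFs must be non-negative and finite.
#'
#' @examples
#' contact_table(data.frame(start1 = 0, start2 = 1e6, IF = 5),
#'               chrom = "chr1", resolution = 1e6)
#' @export
contact_table <- function(records, chrom, resolution) {
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  rec <- data.table::as.data.table(records)
  required <- c("start1", "start2", "IF")
  if (!all(required %in% names(rec))) {
    stop("records must have columns start1, start2, IF")
  }
  rec <- rec[, required, with = FALSE]
  # IF is canonically double so round trips compare cleanly
  for (cl in required) data.table::set(rec, j = cl, value = as.numeric(rec[[cl]]))
  if (nrow(rec)) {
    if (any(!is.finite(rec$start1)) || any(!is.finite(rec$start2)) ||
        any(!is.finite(rec$IF))) {
      stop("non-finite values in contact records")
    }
    if (any(rec$start1 < 0) || any(rec$start2 < 0)) {
      stop("negative bin coordinates")
    }
    if (any(rec$start1 %% resolution != 0) || any(rec$start2 %% resolution != 0)) {
      stop("bin start not a multiple of the resolution")
    }
    if (any(rec$IF < 0)) stop("negative interaction frequencies")
    # mirror lower-triangular records into the upper triangle
    flip <- rec$start1 > rec$start2
    if (any(flip)) {
      tmp <- rec$start1[flip]
      rec[flip, `:=`(start1 = rec$start2[flip])]
      rec[flip, `:=`(start2 = tmp)]
    }
    if (anyDuplicated(rec, by = c("start1", "start2"))) {
      stop("duplicate (bin1, bin2) keys in contact table")
    }
  }
  data.table::setkeyv(rec, c("start1", "start2"))
  structure(list(chrom = chrom, resolution = as.numeric(resolution),
                 records = rec),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table: %s @ %g bp, %d records\n",
              x$chrom, x$resolution, nrow(x$records)))
  if (nrow(x$records)) print(utils::head(x$records, 6L))
  invisible(x)
}

#' Number of records in a contact table
#' @param x a `contact_table`
#' @return integer record count
#' @export
n_contacts <- function(x) {
  stopifnot(inherits(x, "contact_table"))
  nrow(x$records)
}

#' Convert a contact table to a dense symmetric matrix
#'
#' Test/diagnostic adapter: the sparse form is canonical. The matrix spans
#' bins 0 .. `n_bins - 1`; absent pairs are 0.
#'
#' @param table a `contact_table`
#' @param n_bins number of bins; defaults to the smallest count covering the
#'   largest coordinate present.
#' @return a dense symmetric `n_bins x n_bins` matrix
#' @export
as_dense_matrix <- function(table, n_bins = NULL) {
  stopifnot(inherits(table, "contact_table"))
  res <- table$resolution
  rec <- table$records
  if (is.null(n_bins)) {
    n_bins <- if (nrow(rec)) max(rec$start2) / res + 1 else 0L
  }
  n_bins <- as.integer(n_bins)
  m <- matrix(0, n_bins, n_bins)
  if (nrow(rec)) {
    i <- rec$start1 / res + 1L
    j <- rec$start2 / res + 1L
    m[cbind(i, j)] <- rec$IF
    m[cbind(j, i)] <- rec$IF
  }
  m
}

#' Build a contact table from a dense symmetric matrix
#'
#' Inverse of [as_dense_matrix()]; zero cells are dropped (sparse semantics).
#' Only the upper triangle (including the diagonal) is read.
#'
#' @param m square matrix of non-negative counts
#' @inheritParams contact_table
#' @return a `contact_table`
#' @export
from_dense_matrix <- function(m, chrom, resolution) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  keep <- upper.tri(m, diag = TRUE) & m != 0
  idx <- which(keep, arr.ind = TRUE)
  contact_table(data.table::data.table(start1 = (idx[, 1] - 1) * resolution,
                                       start2 = (idx[, 2] - 1) * resolution,
                                       IF = m[idx]),
                chrom = chrom, resolution = resolution)
}
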