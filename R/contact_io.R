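#' Read a sparse upper-triangular Hi-C matrix from text
#'
#' Two dialects of whitespace/TAB-delimited sparse text are supported:
#' \describe{
#'   \item{`triplet3`}{three columns `start1 start2 IF`; the file carries no
#'     chromosome, so `chrom` is required and all records are assigned to it.}
#'   \item{`bedpe7`}{seven columns `chr1 start1 end1 chr2 start2 end2 IF`;
#'     both anchors must be on the same chromosome (trans contacts are out of
#'     scope) and each `end` must equal `start + resolution`.}
#' }
#' Records below the diagonal are mirrored into the upper triangle; duplicate
#' pairs are an error.
#'
#' @param path input file. A header line is detected (non-numeric first
#'   field in column `start1`/`IF` position) and skipped.
#' @param dialect `"triplet3"` or `"bedpe7"`.
#' @param resolution bin size in bp.
#' @param chrom chromosome name; required for `triplet3`, checked against the
#'   file for `bedpe7` when given.
#' @return a [contact_table()]
#' @export
read_sparse_contacts <- function(path, dialect = c("triplet3", "bedpe7"),
                                 resolution, chrom = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = "auto", fill = TRUE,
                          colClasses = NULL, showProgress = FALSE)
  if (nrow(dt) == 0L) {
    if (dialect == "triplet3" && is.null(chrom)) {
      stop("triplet3 input requires an explicit chrom")
    }
    return(contact_table(data.table::data.table(start1 = numeric(0),
                                                start2 = numeric(0),
                                                IF = numeric(0)),
                         chrom = if (is.null(chrom)) "chr" else chrom,
                         resolution = resolution))
  }
  if (dialect == "triplet3") {
    if (is.null(chrom)) stop("triplet3 input requires an explicit chrom")
    if (ncol(dt) != 3L) {
      stop(sprintf("triplet3 file must have 3 columns, found %d", ncol(dt)))
    }
    data.table::setnames(dt, c("start1", "start2", "IF"))
    .check_numeric_cols(dt, c("start1", "start2", "IF"), path)
    out <- dt
  } else {
    if (ncol(dt) != 7L) {
      stop(sprintf("bedpe7 file must have 7 columns, found %d", ncol(dt)))
    }
    data.table::setnames(dt, c("chr1", "start1", "end1",
                               "chr2", "start2", "end2", "IF"))
    .check_numeric_cols(dt, c("start1", "end1", "start2", "end2", "IF"), path)
    bad <- which(dt$chr1 != dt$chr2)
    if (length(bad)) {
      stop(sprintf(paste0("line %d: inter-chromosomal record (%s vs %s); ",
                          "trans contacts are not supported"),
                   bad[1L], dt$chr1[bad[1L]], dt$chr2[bad[1L]]))
    }
    if (length(unique(dt$chr1)) > 1L) {
      stop("bedpe7 file mixes chromosomes; one chromosome per file")
    }
    if (!is.null(chrom) && dt$chr1[1L] != chrom) {
      stop(sprintf("file chromosome %s does not match requested %s",
                   dt$chr1[1L], chrom))
    }
    badend <- which(dt$end1 - dt$start1 != resolution |
                    dt$end2 - dt$start2 != resolution)
    if (length(badend)) {
      stop(sprintf("line %d: bin end does not equal start + resolution",
                   badend[1L]))
    }
    chrom <- dt$chr1[1L]
    out <- dt[, c("start1", "start2", "IF"), with = FALSE]
  }
  bad <- which(out$start1 %% resolution != 0 | out$start2 %% resolution != 0)
  if (length(bad)) {
    stop(sprintf("line %d: bin start not a multiple of resolution %g",
                 bad[1L], resolution))
  }
  contact_table(out, chrom = chrom, resolution = resolution)
}

.check_numeric_cols <- function(dt, cols, path) {
  for (cl in cols) {
    v <- dt[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("%s: line %d: cannot parse '%s' in column %s",
                     basename(path), bad[1L], v[bad[1L]], cl))
      }
      data.table::set(dt, j = cl, value = vn)
    }
    if (anyNA(dt[[cl]])) {
      stop(sprintf("%s: missing value in column %s", basename(path), cl))
    }
  }
  invisible(dt)
}

#' Write a contact table as sparse text
#'
#' Output is TAB-delimited with a header, in stable `(start1, start2)` order.
#' Floating-point IFs (e.g. post-normalization) are written with 15
#' significant digits so that a read/write round trip is lossless for
#' integers and accurate to better than 1e-9 relative for doubles.
#'
#' @param table a [contact_table()]
#' @param path output file
#' @param dialect `"triplet3"` or `"bedpe7"`
#' @return `path`, invisibly
#' @export
write_sparse_contacts <- function(table, path,
                                  dialect = c("triplet3", "bedpe7")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "contact_table"))
  rec <- table$records
  ifout <- format(rec$IF, digits = 15, scientific = FALSE, trim = TRUE)
  if (dialect == "triplet3") {
    out <- data.table::data.table(start1 = rec$start1, start2 = rec$start2,
                                  IF = ifout)
  } else {
    res <- table$resolution
    out <- data.table::data.table(chr1 = rep(table$chrom, nrow(rec)),
                                  start1 = rec$start1, end1 = rec$start1 + res,
                                  chr2 = rep(table$chrom, nrow(rec)),
                                  start2 = rec$start2, end2 = rec$start2 + res,
                                  IF = ifout)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read genomic exclusion regions from a BED file
#'
#' Reads a BED3+ file (0-based, half-open) of regions to drop from the
#' analysis -- typically copy-number-variant calls or blacklisted artifact
#' regions detected upstream. Overlapping or adjacent intervals are unioned
#' per chromosome.
#'
#' @param path BED file with at least columns chrom, start, end.
#' @return a `GRanges` of reduced (unioned) intervals.
#' @export
read_regions_bed <- function(path) {
  stopifnot(file.exists(path))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0L) {
    return(GenomicRanges::GRanges())
  }
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          showProgress = FALSE,
                          col.names = c("chrom", "start", "end"))
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  if (any(dt$start >= dt$end)) {
    stop("BED interval with start >= end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    # BED is 0-based half-open; GRanges is 1-based closed
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end))
  GenomicRanges::reduce(gr)
}

#' Remove contacts overlapping excluded regions
#'
#' Drops every record whose bin1 or bin2 overlaps any interval of `regions`
#' on the table's chromosome. Problematic regions (CNVs, blacklist) bias
#' both normalization and testing, so they are removed before either step.
#'
#' @param table a [contact_table()]
#' @param regions a `GRanges`, e.g. from [read_regions_bed()]
#' @return a filtered `contact_table` (possibly empty)
#' @export
exclude_regions <- function(table, regions) {
  stopifnot(inherits(table, "contact_table"),
            methods::is(regions, "GRanges"))
  rec <- table$records
  if (nrow(rec) == 0L || length(regions) == 0L) return(table)
  res <- table$resolution
  bins <- function(s) GenomicRanges::GRanges(
    seqnames = table$chrom,
    ranges = IRanges::IRanges(start = s + 1L, end = s + res))
  hit1 <- IRanges::overlapsAny(bins(rec$start1), regions)
  hit2 <- IRanges::overlapsAny(bins(rec$start2), regions)
  contact_table(rec[!(hit1 | hit2)], chrom = table$chrom,
                resolution = table$resolution)
}
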