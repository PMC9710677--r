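#' Construct a set of include regions
#'
#' A region set names the genomic intervals — typically chromosome ends —
#' where telomeric reads are expected to map. Coordinates are 1-based
#' inclusive throughout (the samtools region-string convention). Regions are
#' returned sorted by (chromosome, start); overlapping regions are permitted
#' but flagged with a message, since a read overlapping two regions is
#' attributed to the first in sorted order.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive, `end >= start`.
#' @param label Character vector of unique region labels.
#' @return A data frame of class `region_set`, sorted by (chrom, start),
#'   with columns `label`, `chrom`, `start`, `end`.
#' @examples
#' region_set("chr1", 1, 10000, "chr1_tel")
#' @export
region_set <- function(chrom, start, end, label) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  label <- as.character(label)
  n <- length(chrom)
  if (!all(lengths(list(start, end, label)) == n)) {
    stop("configuration error: chrom, start, end, label must have equal length",
         call. = FALSE)
  }
  if (n == 0L) {
    stop("configuration error: no regions defined", call. = FALSE)
  }
  if (anyNA(start) || anyNA(end) || any(start < 1L)) {
    stop("configuration error: region coordinates must be integers >= 1",
         call. = FALSE)
  }
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    stop(sprintf("configuration error: region '%s' has end (%d) < start (%d)",
                 label[bad], end[bad], start[bad]), call. = FALSE)
  }
  if (anyDuplicated(label)) {
    stop(sprintf("configuration error: duplicate region label '%s'",
                 label[duplicated(label)][1L]), call. = FALSE)
  }
  ord <- order(chrom, start, end, label)
  rs <- data.frame(label = label[ord], chrom = chrom[ord],
                   start = start[ord], end = end[ord],
                   stringsAsFactors = FALSE)
  # flag (but allow) overlaps within a chromosome
  if (n > 1L) {
    same <- rs$chrom[-1L] == rs$chrom[-n]
    olap <- same & rs$start[-1L] <= rs$end[-n]
    if (any(olap)) {
      i <- which(olap)[1L] + 1L
      message(sprintf(
        "note: include regions overlap (e.g. '%s' and '%s'); overlapping reads are counted once",
        rs$label[i - 1L], rs$label[i]))
    }
  }
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Parse a samtools-style region string
#'
#' @param x Region string `"chrom:start-end"` with 1-based inclusive
#'   coordinates; commas in numbers are tolerated.
#' @return List with `chrom`, `start`, `end`.
#' @export
parse_region_string <- function(x) {
  x <- gsub(",", "", trimws(x))
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("configuration error: malformed region string '%s' (expected chrom:start-end)",
                 x), call. = FALSE)
  }
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Build the region set from a parsed configuration
#'
#' Reads the `[INCLUDES]` entries of a parsed configuration (see
#' [parse_config()]): one region per line, `label` and `chrom:start-end`
#' separated by whitespace.
#'
#' @param config A `run_config` object from [parse_config()], or any list
#'   with an `includes` data frame of `label`, `region`, `line` columns.
#' @return A [region_set()].
#' @export
load_regions <- function(config) {
  inc <- config$includes
  if (is.null(inc) || nrow(inc) == 0L) {
    stop("configuration error: no regions defined in [INCLUDES]",
         call. = FALSE)
  }
  parsed <- vector("list", nrow(inc))
  for (i in seq_len(nrow(inc))) {
    parsed[[i]] <- tryCatch(parse_region_string(inc$region[i]),
      error = function(e) {
        stop(sprintf("configuration error at line %d: %s",
                     inc$line[i], conditionMessage(e)), call. = FALSE)
      })
  }
  region_set(chrom = vapply(parsed, `[[`, "", "chrom"),
             start = vapply(parsed, `[[`, 1L, "start"),
             end = vapply(parsed, `[[`, 1L, "end"),
             label = inc$label)
}

#' Import include regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention used everywhere else in this package. The BED name
#' column supplies labels; unnamed intervals are labelled
#' `chrom_start_end`.
#'
#' @param path Path to a BED file (first three columns required).
#' @return A [region_set()].
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input error: BED file '%s' not found", path), call. = FALSE)
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 3L) {
    stop("input error: BED file needs at least chrom, start, end columns",
         call. = FALSE)
  }
  start1 <- as.integer(bed[[2]]) + 1L  # 0-based half-open -> 1-based inclusive
  end1 <- as.integer(bed[[3]])
  auto <- sprintf("%s_%d_%d", bed[[1]], start1, end1)
  labels <- if (ncol(bed) >= 4L) {
    given <- as.character(bed[[4]])
    ifelse(is.na(given) | !nzchar(given), auto, given)
  } else auto
  region_set(chrom = as.character(bed[[1]]), start = start1, end = end1,
             label = labels)
}
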