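#' Total record count of a BAM from index statistics
#'
#' The denominator for depth normalisation: mapped plus unmapped records,
#' before any policy filtering, obtained from the BAM index without a full
#' pass over the file. If the index is missing, falls back to a counting
#' pass with a warning, or errors in strict mode.
#'
#' @param bam Path to a BAM file.
#' @param strict Logical; if `TRUE` a missing index is an error rather than
#'   triggering the slow counting fallback.
#' @return Non-negative integer count with attribute `method` (`"idxstats"`
#'   or `"count_pass"`).
#' @export
total_read_count <- function(bam, strict = FALSE) {
  if (!file.exists(bam)) {
    stop(sprintf("input error: BAM file '%s' not found", bam), call. = FALSE)
  }
  has_index <- any(file.exists(c(paste0(bam, ".bai"),
                                 sub("\\.bam$", ".bai", bam),
                                 paste0(bam, ".csi"))))
  if (has_index) {
    st <- Rsamtools::idxstatsBam(bam)
    n <- sum(st$mapped) + sum(st$unmapped)
    return(structure(as.integer(n), method = "idxstats"))
  }
  if (strict) {
    stop(sprintf("input error: no index for '%s' (strict mode)", bam),
         call. = FALSE)
  }
  warning(sprintf("no index for '%s'; counting records with a full pass", bam),
          call. = FALSE)
  cnt <- Rsamtools::countBam(bam,
    param = Rsamtools::ScanBamParam(flag = Rsamtools::scanBamFlag()))
  structure(as.integer(cnt$records), method = "count_pass")
}

#' Summarise a sample's telomeric read content
#'
#' Collects the raw telomeric read count (stage-2 passes) from a scan
#' report over the chosen categories, together with the sample's total
#' record count for normalisation.
#'
#' @param report A `scan_report` from [telomere_scan()].
#' @param bam Path to the scanned BAM (for [total_read_count()]); defaults
#'   to the path recorded in the report.
#' @param label Sample label.
#' @param categories Which report categories contribute to the raw count;
#'   default includes + unmapped. Categories absent from the report (e.g.
#'   `genomic` in region mode) are ignored.
#' @return An object of class `sample_summary` with `label`, `total_records`,
#'   `raw_telomeric`, `categories` and the `report`.
#' @export
sample_summary <- function(report, bam = report$bam, label = basename(bam),
                           categories = c("includes", "unmapped")) {
  stopifnot(inherits(report, "scan_report"))
  present <- intersect(categories, names(report$categories))
  raw <- sum(vapply(report$categories[present], function(x) x$stage2, 0L))
  total <- total_read_count(bam)
  if (raw > total) {
    stop("internal error: raw telomeric count exceeds total record count",
         call. = FALSE)
  }
  structure(list(label = label, total_records = as.integer(total),
                 raw_telomeric = as.integer(raw), categories = present,
                 report = report),
            class = "sample_summary")
}

#' Depth-normalised telomere content estimate
#'
#' Scales the raw telomeric read count by the sequencing depth:
#' `scaled = raw * S / total`. With the default scaling constant
#' `S = 1e6` the result is telomeric reads per million records — a relative
#' content measure, deliberately not converted to absolute telomere length
#' in base pairs.
#'
#' @param raw Non-negative integer: stage-2-passing read count.
#' @param total Positive integer: total records in the BAM (see
#'   [total_read_count()]).
#' @param S Positive scaling constant; default `1e6`.
#' @return An object of class `telomere_estimate` with fields `raw`,
#'   `total`, `S` and `scaled`.
#' @examples
#' scale_counts(100, 50e6)$scaled  # 2 telomeric reads per million
#' @export
scale_counts <- function(raw, total, S = 1e6) {
  if (length(total) != 1L || is.na(total) || total <= 0) {
    stop("quantification error: total record count must be > 0", call. = FALSE)
  }
  if (length(raw) != 1L || is.na(raw) || raw < 0) {
    stop("quantification error: raw count must be >= 0", call. = FALSE)
  }
  if (length(S) != 1L || is.na(S) || S <= 0) {
    stop("quantification error: scaling constant S must be > 0", call. = FALSE)
  }
  structure(list(raw = as.numeric(raw), total = as.numeric(total),
                 S = as.numeric(S),
                 scaled = as.numeric(raw) * as.numeric(S) / as.numeric(total)),
            class = "telomere_estimate")
}

#' Telomere content estimate for a summarised sample
#'
#' Convenience wrapper: [scale_counts()] applied to a [sample_summary()].
#'
#' @param summary A `sample_summary`.
#' @param S Scaling constant, default `1e6`.
#' @return A `telomere_estimate`.
#' @export
estimate_content <- function(summary, S = 1e6) {
  stopifnot(inherits(summary, "sample_summary"))
  scale_counts(summary$raw_telomeric, summary$total_records, S)
}

#' Tumour/normal log2 telomere content ratio
#'
#' The headline pair statistic: `log2(tumour scaled / normal scaled)`.
#' Antisymmetric — swapping tumour and normal negates the ratio. A zero
#' scaled count on either side is an error naming the offending sample;
#' optionally a pseudocount is added to both scaled values instead (off by
#' default).
#'
#' @param tumour,normal `telomere_estimate` objects (see [scale_counts()]).
#' @param pseudocount Non-negative value added to both scaled estimates
#'   before the ratio; default 0 (strict).
#' @return An object of class `pair_ratio` with `tumour`, `normal` and
#'   `log2_ratio`.
#' @examples
#' t <- scale_counts(400, 1e6); n <- scale_counts(200, 1e6)
#' telomere_ratio(t, n)$log2_ratio  # 1
#' @export
telomere_ratio <- function(tumour, normal, pseudocount = 0) {
  stopifnot(inherits(tumour, "telomere_estimate"),
            inherits(normal, "telomere_estimate"),
            pseudocount >= 0)
  ts <- tumour$scaled + pseudocount
  ns <- normal$scaled + pseudocount
  if (ts <= 0) {
    stop("quantification error: tumour sample has zero telomeric content; use a pseudocount to proceed",
         call. = FALSE)
  }
  if (ns <= 0) {
    stop("quantification error: normal sample has zero telomeric content; use a pseudocount to proceed",
         call. = FALSE)
  }
  structure(list(tumour = tumour, normal = normal,
                 pseudocount = pseudocount,
                 log2_ratio = log2(ts / ns)),
            class = "pair_ratio")
}

#' @export
print.telomere_estimate <- function(x, ...) {
  cat(sprintf("telomere content: %.6g telomeric reads per %g records (raw %g / total %g)\n",
              x$scaled, x$S, x$raw, x$total))
  invisible(x)
}

#' @export
print.pair_ratio <- function(x, ...) {
  cat(sprintf("tumour/normal log2 telomere content ratio: %.4f (tumour %.6g, normal %.6g)\n",
              x$log2_ratio, x$tumour$scaled, x$normal$scaled))
  invisible(x)
}
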