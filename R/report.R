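#' Write JSON and TSV reports for a scan
#'
#' The JSON report carries full provenance: the resolved configuration
#' echo, the motif spec with its serialized stage-2 patterns, per-region
#' and per-category tallies, motif-variant substring counts, the content
#' estimate, tool version and an MD5 checksum of the input BAM. The TSV is
#' a flat table with one row per region plus one summary row per category
#' present. Both round-trip losslessly through the bundled readers.
#'
#' The JSON is deterministic for a given scan result: it contains no
#' timestamps, and execution details that cannot affect the tallies (such
#' as the worker count) are excluded from the configuration echo.
#'
#' @param report A `scan_report` from [telomere_scan()].
#' @param summary Optional [sample_summary()] for the sample.
#' @param estimate Optional [scale_counts()] estimate.
#' @param json,tsv Output paths (either may be `NULL` to skip).
#' @param config Optional `run_config` to echo for provenance.
#' @return Invisibly, a list with the paths written.
#' @export
write_reports <- function(report, summary = NULL, estimate = NULL,
                          json = NULL, tsv = NULL, config = NULL) {
  stopifnot(inherits(report, "scan_report"))
  for (p in c(json, tsv)) {
    dir <- dirname(p)
    if (!dir.exists(dir)) {
      stop(sprintf("output error: directory '%s' does not exist", dir),
           call. = FALSE)
    }
    ok <- file.access(dir, mode = 2) == 0
    if (!ok) {
      stop(sprintf("output error: directory '%s' is not writable", dir),
           call. = FALSE)
    }
  }
  if (!is.null(json)) .write_json_report(report, summary, estimate, json, config)
  if (!is.null(tsv)) .write_tsv_report(report, tsv)
  invisible(list(json = json, tsv = tsv))
}

.config_echo <- function(config) {
  if (is.null(config)) return(NULL)
  keep <- c("motif", "stage1_repeats", "stage2_min_repeats",
            "wildcard_prefix", "strands", "mode", "scale",
            "exclude_duplicates", "exclude_secondary",
            "exclude_supplementary", "exclude_qcfail", "min_read_length")
  echo <- config[intersect(keep, names(config))]
  if (!is.null(config$includes) && nrow(config$includes)) {
    echo$includes <- config$includes[, c("label", "region")]
  }
  echo
}

.report_payload <- function(report, summary, estimate, config) {
  spec <- report$motif_spec
  variants <- report$motif_variants
  payload <- list(
    tool = "telomotif",
    version = as.character(utils::packageVersion("telomotif")),
    mode = report$mode,
    input = list(bam = report$bam,
                 md5 = unname(tools::md5sum(report$bam))),
    config = .config_echo(config),
    motif_spec = list(
      canonical_motif = spec$canonical_motif,
      stage1_repeat_count = spec$stage1_repeat_count,
      stage1_strings = as.list(spec$stage1_strings),
      stage2_min_repeats = spec$stage2_min_repeats,
      stage2_wildcard_prefix = spec$stage2_wildcard_prefix,
      strands = spec$strands,
      stage2_patterns = as.list(spec$stage2_patterns)),
    policy = unclass(report$policy),
    total_examined = report$total_examined,
    categories = report$categories,
    regions = report$regions,
    motif_variants = if (length(variants)) as.list(variants) else
      structure(list(), names = character(0))
  )
  if (!is.null(summary)) {
    payload$sample <- list(label = summary$label,
                           total_records = summary$total_records,
                           raw_telomeric = summary$raw_telomeric,
                           categories = summary$categories)
  }
  if (!is.null(estimate)) {
    payload$estimate <- unclass(estimate)
  }
  payload
}

.write_json_report <- function(report, summary, estimate, path, config) {
  payload <- .report_payload(report, summary, estimate, config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.write_tsv_report <- function(report, path) {
  reg <- report$regions
  rows <- data.frame(
    type = rep("region", nrow(reg)),
    label = reg$label, chrom = reg$chrom,
    start = reg$start, end = reg$end,
    examined = reg$examined, stage1 = reg$stage1, stage2 = reg$stage2,
    filtered = reg$filtered, stringsAsFactors = FALSE)
  for (cat_name in names(report$categories)) {
    ct <- report$categories[[cat_name]]
    rows <- rbind(rows, data.frame(
      type = "category", label = cat_name, chrom = NA_character_,
      start = NA_integer_, end = NA_integer_,
      examined = ct$examined, stage1 = ct$stage1, stage2 = ct$stage2,
      filtered = ct$filtered, stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a JSON scan report back into memory
#'
#' Reconstructs the `scan_report` (and, when present, the sample summary
#' and estimate) written by [write_reports()]. Writing and re-reading a
#' report is lossless for every tallied quantity.
#'
#' @param path Path to a JSON report.
#' @return A list with elements `report` (a `scan_report`), and when
#'   present in the file, `sample`, `estimate`, `config`, `version`.
#' @export
read_json_report <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input error: report '%s' not found", path), call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- do.call(rbind, lapply(x$regions, function(r) {
    data.frame(label = r$label, chrom = r$chrom, start = as.integer(r$start),
               end = as.integer(r$end), examined = as.integer(r$examined),
               stage1 = as.integer(r$stage1), stage2 = as.integer(r$stage2),
               filtered = as.integer(r$filtered), stringsAsFactors = FALSE)
  }))
  categories <- lapply(x$categories, function(ct) {
    list(examined = as.integer(ct$examined), stage1 = as.integer(ct$stage1),
         stage2 = as.integer(ct$stage2), filtered = as.integer(ct$filtered))
  })
  variants <- vapply(x$motif_variants, function(v) as.integer(v), 0L)
  ms <- x$motif_spec
  spec <- build_motif_spec(ms$canonical_motif,
                           as.integer(ms$stage1_repeat_count),
                           as.integer(ms$stage2_min_repeats),
                           as.integer(ms$stage2_wildcard_prefix),
                           ms$strands)
  pol <- do.call(read_filter_policy, lapply(x$policy, function(v) v))
  report <- .new_scan_report(mode = x$mode, spec = spec, policy = pol,
                             region_tallies = regions,
                             categories = categories,
                             variants = variants, bam = x$input$bam)
  out <- list(report = report, version = x$version)
  if (!is.null(x$sample)) out$sample <- x$sample
  if (!is.null(x$estimate)) {
    out$estimate <- scale_counts(x$estimate$raw, x$estimate$total,
                                 x$estimate$S)
  }
  if (!is.null(x$config)) out$config <- x$config
  out
}

#' Read a TSV scan report
#'
#' @param path Path to a TSV written by [write_reports()].
#' @return Data frame with one row per region and per category.
#' @export
read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
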