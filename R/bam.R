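#' Read filter policy
#'
#' Which alignment records are excluded from telomere counting. Input BAMs
#' are expected to be duplicate-marked precisely so PCR/optical duplicates
#' can be excluded; secondary, supplementary and vendor-QC-failed records
#' are likewise excluded by default so each sequenced fragment is counted
#' at most once. All switches are explicit — there are no implicit defaults
#' at the scan call site.
#'
#' @param exclude_duplicates,exclude_secondary,exclude_supplementary,exclude_qcfail
#'   Logical switches; all default `TRUE`.
#' @param min_read_length Minimum stored-sequence length for a record to be
#'   counted (default 0 = no minimum).
#' @return An object of class `read_filter_policy`.
#' @export
read_filter_policy <- function(exclude_duplicates = TRUE,
                               exclude_secondary = TRUE,
                               exclude_supplementary = TRUE,
                               exclude_qcfail = TRUE,
                               min_read_length = 0L) {
  stopifnot(is.logical(exclude_duplicates), is.logical(exclude_secondary),
            is.logical(exclude_supplementary), is.logical(exclude_qcfail))
  structure(list(exclude_duplicates = exclude_duplicates,
                 exclude_secondary = exclude_secondary,
                 exclude_supplementary = exclude_supplementary,
                 exclude_qcfail = exclude_qcfail,
                 min_read_length = as.integer(min_read_length)),
            class = "read_filter_policy")
}

.policy_from_config <- function(cfg) {
  read_filter_policy(cfg$exclude_duplicates, cfg$exclude_secondary,
                     cfg$exclude_supplementary, cfg$exclude_qcfail,
                     cfg$min_read_length)
}

# SAM flag bits
.FLAG_UNMAPPED <- 0x4L
.FLAG_SECONDARY <- 0x100L
.FLAG_QCFAIL <- 0x200L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

# apply a policy to a record frame; returns list(kept, n_filtered)
.apply_policy <- function(rec, policy) {
  if (!nrow(rec)) return(list(kept = rec, n_filtered = 0L))
  drop <- rep(FALSE, nrow(rec))
  if (policy$exclude_duplicates) drop <- drop | bitwAnd(rec$flag, .FLAG_DUP) > 0L
  if (policy$exclude_secondary) drop <- drop | bitwAnd(rec$flag, .FLAG_SECONDARY) > 0L
  if (policy$exclude_supplementary) drop <- drop | bitwAnd(rec$flag, .FLAG_SUPPLEMENTARY) > 0L
  if (policy$exclude_qcfail) drop <- drop | bitwAnd(rec$flag, .FLAG_QCFAIL) > 0L
  if (policy$min_read_length > 0L) drop <- drop | nchar(rec$seq) < policy$min_read_length
  list(kept = rec[!drop, , drop = FALSE], n_filtered = sum(drop))
}

.check_bam <- function(bam) {
  if (!file.exists(bam)) {
    stop(sprintf("input error: BAM file '%s' not found", bam), call. = FALSE)
  }
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam),
           paste0(bam, ".csi"))
  if (!any(file.exists(idx))) {
    stop(sprintf(
      "input error: no index found for '%s'; create one with samtools index or Rsamtools::indexBam()",
      bam), call. = FALSE)
  }
  invisible(bam)
}

.bam_chromosomes <- function(bam) {
  names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
}

.scan_what <- c("qname", "flag", "rname", "pos", "cigar", "seq")

.records_frame <- function(res) {
  data.frame(qname = res$qname,
             flag = res$flag,
             rname = as.character(res$rname),
             pos = res$pos,
             cigar = res$cigar,
             seq = as.character(res$seq),
             stringsAsFactors = FALSE)
}

#' Fetch policy-passing records overlapping one include region
#'
#' Uses the BAM index to retrieve every mapped record whose alignment
#' overlaps the region by at least one base (1-based inclusive
#' coordinates). Records with the unmapped flag are never returned here —
#' placed-unmapped mates are collected exclusively by [unmapped_reads()],
#' so no record can be counted in two categories.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param region One-row [region_set()] (or list with `chrom`, `start`,
#'   `end`).
#' @param policy A [read_filter_policy()].
#' @return Data frame of records (`qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `seq`) with attribute `n_filtered` = number of records the policy
#'   removed.
#' @export
region_reads <- function(bam, region, policy = read_filter_policy()) {
  .check_bam(bam)
  chroms <- .bam_chromosomes(bam)
  if (!region$chrom %in% chroms) {
    stop(sprintf(
      "input error: chromosome '%s' not in BAM header (available: %s)",
      region$chrom, paste(chroms, collapse = ", ")), call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(region$chrom,
                                   IRanges::IRanges(region$start, region$end)),
    what = .scan_what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- .records_frame(Rsamtools::scanBam(bam, param = param)[[1]])
  out <- .apply_policy(rec, policy)
  structure(out$kept, n_filtered = out$n_filtered)
}

#' Fetch all policy-passing unmapped records
#'
#' Returns every record with the unmapped flag set, including unmapped
#' mates stored with a placement coordinate next to their mapped mate.
#' These carry telomeric reads that do not align to the reference (reference
#' telomere assemblies are incomplete), so they are always scanned in
#' addition to the include regions.
#'
#' @inheritParams region_reads
#' @return Data frame of records with attribute `n_filtered`.
#' @export
unmapped_reads <- function(bam, policy = read_filter_policy()) {
  .check_bam(bam)
  param <- Rsamtools::ScanBamParam(
    what = .scan_what,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  rec <- .records_frame(Rsamtools::scanBam(bam, param = param)[[1]])
  out <- .apply_policy(rec, policy)
  structure(out$kept, n_filtered = out$n_filtered)
}

# record identity for global de-duplication across overlapping regions
.record_key <- function(rec) {
  paste(rec$qname, rec$flag, ifelse(is.na(rec$rname), "*", rec$rname),
        ifelse(is.na(rec$pos), 0L, rec$pos), sep = "\r")
}

# classify a vector of sequences; returns per-read stage1/stage2 logical and
# a tally of matched substrings
.classify_batch <- function(seqs, spec) {
  n <- length(seqs)
  s1 <- if (n) stage1_match(seqs, spec) else logical(0)
  s2 <- logical(n)
  variants <- character(0)
  for (i in which(s1)) {
    hits <- stage2_find(seqs[i], spec)
    if (nrow(hits)) {
      s2[i] <- TRUE
      variants <- c(variants, hits$matched_substring)
    }
  }
  list(stage1 = s1, stage2 = s2, variants = variants)
}

.tally_variants <- function(variants) {
  if (!length(variants)) return(integer(0))
  tab <- table(variants)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

.merge_variants <- function(a, b) {
  all <- c(a, b)
  if (!length(all)) return(integer(0))
  out <- tapply(all, names(all), sum)
  res <- as.integer(out)
  names(res) <- names(out)
  res[order(names(res))]
}

#' Scan a BAM for telomeric reads
#'
#' The main entry point. In `"regions"` mode (the default, and the fast
#' path) only reads overlapping the include regions plus all unmapped reads
#' are examined; in `"full"` mode every record in the file is examined and
#' stage-2-passing mapped reads outside all include regions are tallied
#' under an additional `"genomic"` category. Full mode is the validation
#' oracle for region mode: restricted to the includes and unmapped
#' categories the two agree exactly.
#'
#' Each record is counted once: a read overlapping several include regions
#' is attributed to the first containing region in (chromosome, start)
#' order, and placed-unmapped mates are only ever counted in the unmapped
#' category. A read counts once toward the stage-2 tally regardless of how
#' many motif runs it contains; per-run substrings are tallied separately
#' in `motif_variants`.
#'
#' @param bam Path to a duplicate-marked, coordinate-sorted, indexed BAM.
#' @param regions A [region_set()] of include regions.
#' @param spec A [build_motif_spec()]; default matcher if omitted.
#' @param policy A [read_filter_policy()]; defaults exclude duplicate,
#'   secondary, supplementary and QC-failed records.
#' @param workers Number of parallel workers used to fetch regions
#'   (forked processes). The report is a pure function of the inputs;
#'   `workers` only changes wall-clock time.
#' @param mode `"regions"` (default) or `"full"`.
#' @return An object of class `scan_report`: run mode, the motif spec used,
#'   per-region tallies (`examined`, `stage1`, `stage2`, `filtered`),
#'   aggregate category tallies (`includes`, `unmapped`, and in full mode
#'   `genomic`), sorted per-variant substring counts, and the total number
#'   of reads examined.
#' @examples
#' \donttest{
#' fx <- generate_fixture(fixture_spec(seed = 1), tempfile())
#' rep <- telomere_scan(fx$bam, fx$regions)
#' rep$categories$includes$stage2
#' }
#' @export
telomere_scan <- function(bam, regions, spec = build_motif_spec(),
                          policy = read_filter_policy(), workers = 1L,
                          mode = c("regions", "full")) {
  mode <- match.arg(mode)
  if (mode == "full") {
    return(telomere_full_scan(bam, regions, spec, policy))
  }
  .check_bam(bam)
  stopifnot(inherits(regions, "region_set"), workers >= 1L)
  workers <- as.integer(workers)

  # fetch raw (pre-policy) records so that global de-duplication across
  # overlapping regions happens before filtering: each record identity is
  # examined or filtered exactly once, in its first containing region
  chroms <- .bam_chromosomes(bam)
  missing <- setdiff(unique(regions$chrom), chroms)
  if (length(missing)) {
    stop(sprintf(
      "input error: chromosome '%s' not in BAM header (available: %s)",
      missing[1], paste(chroms, collapse = ", ")), call. = FALSE)
  }
  fetch_one <- function(i) {
    param <- Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges(regions$chrom[i],
                                     IRanges::IRanges(regions$start[i],
                                                      regions$end[i])),
      what = .scan_what,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    .records_frame(Rsamtools::scanBam(bam, param = param)[[1]])
  }
  idx <- seq_len(nrow(regions))
  if (workers > 1L) {
    per_region <- parallel::mclapply(idx, fetch_one, mc.cores = workers)
    err <- vapply(per_region, inherits, TRUE, "try-error")
    if (any(vapply(per_region, is.null, TRUE)) || any(err)) {
      stop("runtime error: a scan worker failed", call. = FALSE)
    }
  } else {
    per_region <- lapply(idx, fetch_one)
  }

  # global de-duplication in sorted region order: first containing region wins
  seen <- character(0)
  region_tallies <- vector("list", nrow(regions))
  includes <- list(examined = 0L, stage1 = 0L, stage2 = 0L, filtered = 0L)
  variants <- integer(0)
  for (i in idx) {
    raw <- per_region[[i]]
    keys <- .record_key(raw)
    new <- !keys %in% seen & !duplicated(keys)
    seen <- c(seen, keys[new])
    pol <- .apply_policy(raw[new, , drop = FALSE], policy)
    rec <- pol$kept
    nf <- pol$n_filtered
    cl <- .classify_batch(rec$seq, spec)
    region_tallies[[i]] <- data.frame(
      label = regions$label[i], chrom = regions$chrom[i],
      start = regions$start[i], end = regions$end[i],
      examined = nrow(rec), stage1 = sum(cl$stage1), stage2 = sum(cl$stage2),
      filtered = nf, stringsAsFactors = FALSE)
    includes$examined <- includes$examined + nrow(rec)
    includes$stage1 <- includes$stage1 + sum(cl$stage1)
    includes$stage2 <- includes$stage2 + sum(cl$stage2)
    includes$filtered <- includes$filtered + nf
    variants <- .merge_variants(variants, .tally_variants(cl$variants))
  }

  um <- unmapped_reads(bam, policy)
  cl <- .classify_batch(um$seq, spec)
  unmapped <- list(examined = nrow(um), stage1 = sum(cl$stage1),
                   stage2 = sum(cl$stage2),
                   filtered = attr(um, "n_filtered"))
  variants <- .merge_variants(variants, .tally_variants(cl$variants))

  .new_scan_report(mode = "regions", spec = spec, policy = policy,
                   region_tallies = do.call(rbind, region_tallies),
                   categories = list(includes = includes, unmapped = unmapped),
                   variants = variants, bam = bam)
}

#' Scan every record in a BAM (validation oracle mode)
#'
#' Examines every record in the file. Mapped, policy-passing,
#' stage-2-passing reads outside all include regions populate the
#' `"genomic"` category, which region mode never sees. Used to validate
#' that restricting the scan to include regions plus unmapped reads loses
#' nothing.
#'
#' @inheritParams telomere_scan
#' @return A `scan_report` with an additional `genomic` category.
#' @export
telomere_full_scan <- function(bam, regions, spec = build_motif_spec(),
                               policy = read_filter_policy()) {
  .check_bam(bam)
  stopifnot(inherits(regions, "region_set"))
  param <- Rsamtools::ScanBamParam(what = .scan_what)
  rec <- .records_frame(Rsamtools::scanBam(bam, param = param)[[1]])

  is_um <- bitwAnd(rec$flag, .FLAG_UNMAPPED) > 0L
  um <- .apply_policy(rec[is_um, , drop = FALSE], policy)
  mp <- .apply_policy(rec[!is_um, , drop = FALSE], policy)
  mrec <- mp$kept

  # attribute each mapped record to the first overlapping region in sorted
  # order, or to the genomic pool; reference span from the CIGAR
  region_idx <- rep(NA_integer_, nrow(mrec))
  if (nrow(mrec)) {
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(mrec$cigar)
    rend <- mrec$pos + width - 1L
    for (i in seq_len(nrow(regions))) {
      hit <- is.na(region_idx) & mrec$rname == regions$chrom[i] &
        mrec$pos <= regions$end[i] & rend >= regions$start[i]
      region_idx[hit] <- i
    }
  }

  region_tallies <- vector("list", nrow(regions))
  includes <- list(examined = 0L, stage1 = 0L, stage2 = 0L, filtered = 0L)
  variants <- integer(0)
  for (i in seq_len(nrow(regions))) {
    rr <- mrec[!is.na(region_idx) & region_idx == i, , drop = FALSE]
    cl <- .classify_batch(rr$seq, spec)
    region_tallies[[i]] <- data.frame(
      label = regions$label[i], chrom = regions$chrom[i],
      start = regions$start[i], end = regions$end[i],
      examined = nrow(rr), stage1 = sum(cl$stage1), stage2 = sum(cl$stage2),
      filtered = 0L, stringsAsFactors = FALSE)
    includes$examined <- includes$examined + nrow(rr)
    includes$stage1 <- includes$stage1 + sum(cl$stage1)
    includes$stage2 <- includes$stage2 + sum(cl$stage2)
    variants <- .merge_variants(variants, .tally_variants(cl$variants))
  }
  includes$filtered <- mp$n_filtered

  grec <- mrec[is.na(region_idx), , drop = FALSE]
  cl <- .classify_batch(grec$seq, spec)
  genomic <- list(examined = nrow(grec), stage1 = sum(cl$stage1),
                  stage2 = sum(cl$stage2), filtered = 0L)
  variants <- .merge_variants(variants, .tally_variants(cl$variants))

  clu <- .classify_batch(um$kept$seq, spec)
  unmapped <- list(examined = nrow(um$kept), stage1 = sum(clu$stage1),
                   stage2 = sum(clu$stage2), filtered = um$n_filtered)
  variants <- .merge_variants(variants, .tally_variants(clu$variants))

  .new_scan_report(mode = "full", spec = spec, policy = policy,
                   region_tallies = do.call(rbind, region_tallies),
                   categories = list(includes = includes, unmapped = unmapped,
                                     genomic = genomic),
                   variants = variants, bam = bam)
}

.new_scan_report <- function(mode, spec, policy, region_tallies, categories,
                             variants, bam) {
  total <- sum(vapply(categories, function(x) x$examined, 0L))
  structure(list(
    mode = mode,
    motif_spec = spec,
    policy = policy,
    regions = region_tallies,
    categories = categories,
    motif_variants = variants,
    total_examined = total,
    bam = bam
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("telomere scan report (%s mode)\n", x$mode))
  cat(sprintf("  total reads examined: %d\n", x$total_examined))
  for (cat_name in names(x$categories)) {
    ct <- x$categories[[cat_name]]
    cat(sprintf("  %-9s examined=%d stage1=%d stage2=%d filtered=%d\n",
                cat_name, ct$examined, ct$stage1, ct$stage2, ct$filtered))
  }
  cat(sprintf("  %d region(s), %d distinct motif variant(s)\n",
              nrow(x$regions), length(x$motif_variants)))
  invisible(x)
}
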