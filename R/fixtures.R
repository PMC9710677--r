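#' Specification for a synthetic BAM fixture
#'
#' Describes a small whole-genome-sequencing-like BAM with planted,
#' analytically known telomeric content, used to test every other layer of
#' the package without external data. Read classes:
#'
#' \describe{
#'   \item{pure forward / pure reverse}{whole-motif tilings of `TTAGGG` /
#'     `CCCTAA` — pass both matcher stages.}
#'   \item{degenerate}{a run of three exact canonical repeats (so the
#'     stage-1 gate passes) followed by repeat units whose first three
#'     bases are randomised — emulates telomere-variant repeats.}
#'   \item{near miss}{isolated canonical repeats separated by spacers, so
#'     no run reaches the stage-1 threshold; fails the default matcher.}
#'   \item{background}{uniform random sequence, rejection-sampled until it
#'     contains no stage-1 run and no stage-2 window on either strand, so
#'     expected counts are exact rather than probabilistic.}
#'   \item{unmapped telomeric}{pure forward reads with the unmapped flag;
#'     optionally stored with a placement coordinate like the unmapped
#'     mate of a mapped read.}
#'   \item{duplicate telomeric}{pure forward reads flagged as PCR
#'     duplicates at an existing coordinate; excluded by the default
#'     policy.}
#'   \item{genomic telomeric}{pure forward reads mapped outside every
#'     include region; visible only to the full scan.}
#' }
#'
#' Class membership is verified at generation time by a naive
#' substring/window checker that is independent of the package's matcher.
#' The same seed regenerates the fixture byte-for-byte.
#'
#' @param seed Integer random seed fixing the fixture.
#' @param read_length Read length in bases (default 100).
#' @param chromosomes Named integer vector of chromosome lengths.
#' @param regions [region_set()] of include regions; must lie within
#'   `chromosomes`.
#' @param n_pure_forward,n_pure_reverse,n_degenerate,n_near_miss Counts of
#'   planted reads of each class placed inside include regions.
#' @param n_background_in,n_background_out Background read counts placed
#'   inside include regions / elsewhere on the reference.
#' @param n_unmapped_telomeric,n_unmapped_background Unmapped read counts.
#' @param n_duplicate_telomeric Duplicate-flagged telomeric reads.
#' @param n_genomic_telomeric Telomeric reads mapped outside all include
#'   regions.
#' @param unmapped_with_coord Logical; store unmapped telomeric reads with
#'   a placement coordinate inside the first include region (as aligners do
#'   for the unmapped mate of a mapped read).
#' @param motif Canonical motif used for planted reads (default `TTAGGG`).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         read_length = 100L,
                         chromosomes = c(chr1 = 200000L, chr2 = 100000L),
                         regions = NULL,
                         n_pure_forward = 5L,
                         n_pure_reverse = 5L,
                         n_degenerate = 0L,
                         n_near_miss = 0L,
                         n_background_in = 10L,
                         n_background_out = 10L,
                         n_unmapped_telomeric = 4L,
                         n_unmapped_background = 0L,
                         n_duplicate_telomeric = 0L,
                         n_genomic_telomeric = 0L,
                         unmapped_with_coord = FALSE,
                         motif = "TTAGGG") {
  if (is.null(regions)) {
    regions <- suppressMessages(
      region_set("chr1", 1L, 10000L, "chr1_tel"))
  }
  counts <- c(n_pure_forward = n_pure_forward, n_pure_reverse = n_pure_reverse,
              n_degenerate = n_degenerate, n_near_miss = n_near_miss,
              n_background_in = n_background_in,
              n_background_out = n_background_out,
              n_unmapped_telomeric = n_unmapped_telomeric,
              n_unmapped_background = n_unmapped_background,
              n_duplicate_telomeric = n_duplicate_telomeric,
              n_genomic_telomeric = n_genomic_telomeric)
  if (any(counts < 0)) stop("fixture error: read counts must be >= 0",
                            call. = FALSE)
  if (read_length < 6L * 2L) {
    stop("fixture error: read_length too short for two repeat units",
         call. = FALSE)
  }
  for (i in seq_len(nrow(regions))) {
    if (!regions$chrom[i] %in% names(chromosomes) ||
        regions$end[i] > chromosomes[[regions$chrom[i]]]) {
      stop(sprintf("fixture error: region '%s' outside the reference layout",
                   regions$label[i]), call. = FALSE)
    }
  }
  structure(c(list(seed = as.integer(seed),
                   read_length = as.integer(read_length),
                   chromosomes = chromosomes, regions = regions,
                   unmapped_with_coord = isTRUE(unmapped_with_coord),
                   motif = toupper(motif)),
              as.list(stats::setNames(as.integer(counts), names(counts)))),
            class = "fixture_spec")
}

# ---- independent naive checker (no regex, no calls into the matcher) ----

.naive_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

# does s contain `gate` as an exact substring? (character-by-character)
.naive_contains <- function(s, gate) {
  n <- nchar(s); m <- nchar(gate)
  if (m > n) return(FALSE)
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == gate) return(TRUE)
  }
  FALSE
}

# does any window of >= min_repeats contiguous units match the degenerate
# unit scheme (first `wild` bases free, remainder fixed) on either strand?
.naive_stage2_any <- function(s, motif = "TTAGGG", min_repeats = 2L,
                              wild = 3L) {
  s <- toupper(s)
  L <- nchar(motif)
  suf <- substr(motif, wild + 1L, L)
  rev_pre <- .naive_revcomp(suf)
  unit_ok <- function(u, strand) {
    if (grepl("N", u, fixed = TRUE)) return(FALSE)
    if (strand == "f") substr(u, wild + 1L, L) == suf
    else substr(u, 1L, L - wild) == rev_pre
  }
  n <- nchar(s)
  need <- L * min_repeats
  if (n < need) return(FALSE)
  for (i in seq_len(n - need + 1L)) {
    for (strand in c("f", "r")) {
      ok <- TRUE
      for (k in seq_len(min_repeats)) {
        u <- substr(s, i + (k - 1L) * L, i + k * L - 1L)
        if (!unit_ok(u, strand)) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

.naive_telomeric <- function(s, motif = "TTAGGG", gate_repeats = 3L,
                             min_repeats = 2L, wild = 3L) {
  gate_f <- strrep(motif, gate_repeats)
  gate_r <- .naive_revcomp(gate_f)
  (.naive_contains(s, gate_f) || .naive_contains(s, gate_r)) &&
    .naive_stage2_any(s, motif, min_repeats, wild)
}

# ---- read constructors ----

.tile <- function(unit, len) substr(strrep(unit, ceiling(len / nchar(unit))),
                                    1L, len)

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Construct a read sequence of a given fixture class
#'
#' Each returned sequence provably belongs to its class: membership (or,
#' for near-miss and background classes, non-membership) is verified by a
#' naive substring/window checker independent of the package matcher, with
#' rejection sampling where the construction is stochastic.
#'
#' @param cls One of `"pure_forward"`, `"pure_reverse"`, `"degenerate"`,
#'   `"near_miss"`, `"background"`.
#' @param read_length Read length in bases.
#' @param motif Canonical motif (default `TTAGGG`).
#' @return A DNA string of length `read_length`. Uses the current RNG
#'   state; seed externally for reproducibility.
#' @export
make_telomeric_read <- function(cls = c("pure_forward", "pure_reverse",
                                        "degenerate", "near_miss",
                                        "background"),
                                read_length = 100L, motif = "TTAGGG") {
  cls <- match.arg(cls)
  L <- nchar(motif)
  if (read_length < 2L * L) {
    stop(sprintf("fixture error: class '%s' impossible at read length %d",
                 cls, read_length), call. = FALSE)
  }
  switch(cls,
    pure_forward = .tile(motif, read_length),
    pure_reverse = .tile(.naive_revcomp(motif), read_length),
    degenerate = {
      if (read_length < 3L * L) {
        stop(sprintf("fixture error: class 'degenerate' impossible at read length %d",
                     read_length), call. = FALSE)
      }
      gate <- strrep(motif, 3L)
      suf <- substr(motif, 4L, L)
      repeat {
        n_units <- ceiling((read_length - nchar(gate)) / L)
        units <- vapply(seq_len(n_units), function(i) {
          paste0(paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                       collapse = ""), suf)
        }, "")
        s <- substr(paste0(gate, paste(units, collapse = "")), 1L,
                    read_length)
        if (.naive_telomeric(s, motif)) return(s)
      }
    },
    near_miss = {
      # isolated single repeats separated by spacers; must fail the
      # 3-repeat gate AND contain no 2-unit degenerate window
      repeat {
        parts <- character(0); len <- 0L
        while (len < read_length) {
          parts <- c(parts, motif, .random_dna(L))
          len <- len + 2L * L
        }
        s <- substr(paste(parts, collapse = ""), 1L, read_length)
        if (!.naive_telomeric(s, motif) &&
            !.naive_contains(s, strrep(motif, 3L)) &&
            !.naive_contains(s, .naive_revcomp(strrep(motif, 3L)))) {
          return(s)
        }
      }
    },
    background = {
      repeat {
        s <- .random_dna(read_length)
        if (!.naive_stage2_any(s, motif) &&
            !.naive_contains(s, strrep(motif, 3L)) &&
            !.naive_contains(s, .naive_revcomp(strrep(motif, 3L)))) {
          return(s)
        }
      }
    })
}

# ---- fixture generation ----

.random_pos_in_region <- function(region, read_length, n) {
  lo <- region$start
  hi <- max(region$start, region$end - read_length + 1L)
  if (n == 0L) return(integer(0))
  sort(lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
}

#' Generate a synthetic BAM fixture with known truth
#'
#' Writes a SAM file (inspectable as text), converts it to a
#' coordinate-sorted indexed BAM, and serialises a truth table computed
#' analytically from the construction — never by running the matcher under
#' test. Planted telomeric reads are distributed round-robin over the
#' include regions; duplicate-flagged copies share the coordinate of an
#' existing telomeric read.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param name Base name for the output files.
#' @return A list with paths `sam`, `bam`, `truth_json`, the `regions`
#'   [region_set()] and the in-memory `truth` list. The truth table gives
#'   the expected per-category `examined`/`stage1`/`stage2` tallies under
#'   the default matcher and default filter policy, for both scan modes,
#'   plus the expected total record count.
#' @export
generate_fixture <- function(spec, dir, name = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  rl <- spec$read_length
  regions <- spec$regions
  motif <- spec$motif

  rows <- list()
  rid <- 0L
  add <- function(flag, rname, pos, cigar, seq) {
    rid <<- rid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      qname = sprintf("read%05d", rid), flag = flag, rname = rname,
      pos = pos, cigar = cigar, seq = seq, stringsAsFactors = FALSE)
  }

  in_region_classes <- c(rep("pure_forward", spec$n_pure_forward),
                         rep("pure_reverse", spec$n_pure_reverse),
                         rep("degenerate", spec$n_degenerate),
                         rep("near_miss", spec$n_near_miss),
                         rep("background", spec$n_background_in))
  first_telomeric <- NULL
  if (length(in_region_classes)) {
    reg_idx <- rep(seq_len(nrow(regions)),
                   length.out = length(in_region_classes))
    for (j in seq_along(in_region_classes)) {
      r <- regions[reg_idx[j], ]
      pos <- .random_pos_in_region(r, rl, 1L)
      s <- make_telomeric_read(in_region_classes[j], rl, motif)
      add(0L, r$chrom, pos, sprintf("%dM", rl), s)
      if (is.null(first_telomeric) &&
          in_region_classes[j] %in% c("pure_forward", "pure_reverse")) {
        first_telomeric <- list(chrom = r$chrom, pos = pos)
      }
    }
  }

  # duplicates: telomeric sequence at an existing telomeric coordinate
  if (spec$n_duplicate_telomeric > 0L) {
    anchor <- first_telomeric
    if (is.null(anchor)) {
      r <- regions[1L, ]
      anchor <- list(chrom = r$chrom,
                     pos = .random_pos_in_region(r, rl, 1L))
    }
    for (j in seq_len(spec$n_duplicate_telomeric)) {
      add(1024L, anchor$chrom, anchor$pos, sprintf("%dM", rl),
          make_telomeric_read("pure_forward", rl, motif))
    }
  }

  # mapped reads outside every include region
  out_classes <- c(rep("pure_forward", spec$n_genomic_telomeric),
                   rep("background", spec$n_background_out))
  if (length(out_classes)) {
    # place on the last chromosome, away from any include region there
    chrom <- names(spec$chromosomes)[length(spec$chromosomes)]
    clen <- spec$chromosomes[[chrom]]
    on_chrom <- regions[regions$chrom == chrom, , drop = FALSE]
    lo <- if (nrow(on_chrom)) max(on_chrom$end) + 1000L else 1L
    hi <- clen - rl + 1L
    if (hi <= lo) stop("fixture error: no room outside include regions",
                       call. = FALSE)
    for (cls in out_classes) {
      add(0L, chrom, lo + sample.int(hi - lo + 1L, 1L) - 1L,
          sprintf("%dM", rl), make_telomeric_read(cls, rl, motif))
    }
  }

  # unmapped pool
  um_classes <- c(rep("pure_forward", spec$n_unmapped_telomeric),
                  rep("background", spec$n_unmapped_background))
  for (cls in um_classes) {
    s <- make_telomeric_read(cls, rl, motif)
    if (spec$unmapped_with_coord) {
      r <- regions[1L, ]
      add(4L, r$chrom, .random_pos_in_region(r, rl, 1L), "*", s)
    } else {
      add(4L, "*", 0L, "*", s)
    }
  }

  recs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), cigar = character(0), seq = character(0),
               stringsAsFactors = FALSE)

  sam <- file.path(dir, paste0(name, ".sam"))
  .write_sam(recs, spec$chromosomes, sam)
  bam <- .sam_to_indexed_bam(sam, file.path(dir, name))

  truth <- .fixture_truth(spec)
  truth_json <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(sam = sam, bam = bam, truth_json = truth_json,
       regions = regions, truth = truth)
}

# expected tallies computed analytically from the construction
.fixture_truth <- function(spec) {
  n_tel_in <- spec$n_pure_forward + spec$n_pure_reverse + spec$n_degenerate
  includes_examined <- n_tel_in + spec$n_near_miss + spec$n_background_in
  total_records <- includes_examined + spec$n_duplicate_telomeric +
    spec$n_genomic_telomeric + spec$n_background_out +
    spec$n_unmapped_telomeric + spec$n_unmapped_background
  list(
    seed = spec$seed,
    counts = spec[grep("^n_", names(spec))],
    total_records = total_records,
    includes = list(examined = includes_examined,
                    stage1 = n_tel_in, stage2 = n_tel_in,
                    filtered = spec$n_duplicate_telomeric),
    unmapped = list(examined = spec$n_unmapped_telomeric +
                      spec$n_unmapped_background,
                    stage1 = spec$n_unmapped_telomeric,
                    stage2 = spec$n_unmapped_telomeric,
                    filtered = 0L),
    genomic = list(examined = spec$n_genomic_telomeric +
                     spec$n_background_out,
                   stage1 = spec$n_genomic_telomeric,
                   stage2 = spec$n_genomic_telomeric,
                   filtered = 0L)
  )
}

.write_sam <- function(recs, chromosomes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromosomes),
                   as.integer(chromosomes)))
  # coordinate order: mapped (and placed-unmapped) by (rname, pos) in
  # header chromosome order, unplaced-unmapped last
  unplaced <- recs$rname == "*"
  body <- recs[order(unplaced,
                     match(recs$rname, names(chromosomes)),
                     recs$pos), , drop = FALSE]
  mapq <- ifelse(bitwAnd(body$flag, 4L) > 0L, 0L, 60L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   body$qname, body$flag, body$rname, body$pos, mapq,
                   body$cigar, body$seq)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.sam_to_indexed_bam <- function(sam, dest) {
  raw <- Rsamtools::asBam(sam, paste0(dest, "_unsorted"), overwrite = TRUE,
                          indexDestination = FALSE)
  bam <- Rsamtools::sortBam(raw, dest)
  file.remove(raw)
  Rsamtools::indexBam(bam)
  bam
}

#' Generate a tumour/normal fixture pair with planted telomeric fractions
#'
#' For ratio-recovery experiments: each sample gets a binomially sampled
#' telomeric read count `k ~ Binomial(n_reads, f)` planted in the include
#' region, with the remaining reads as background, so the expected
#' log2 content ratio is `log2(f_tumour / f_normal)` up to binomial
#' sampling error.
#'
#' @param n_reads Total records per sample.
#' @param f_tumour,f_normal Planted telomeric fractions in (0, 1).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param read_length Read length (default 100).
#' @return List with `tumour` and `normal` fixture lists (as from
#'   [generate_fixture()]), the planted `k_tumour`/`k_normal`, and
#'   `expected_log2` = `log2(f_tumour / f_normal)`.
#' @export
generate_ratio_pair <- function(n_reads, f_tumour, f_normal, seed = 1L,
                                dir, read_length = 100L) {
  stopifnot(f_tumour > 0, f_tumour < 1, f_normal > 0, f_normal < 1)
  set.seed(seed)
  k_t <- stats::rbinom(1L, n_reads, f_tumour)
  k_n <- stats::rbinom(1L, n_reads, f_normal)
  mk <- function(k, sub, sd) {
    generate_fixture(fixture_spec(
      seed = sd, read_length = read_length,
      n_pure_forward = k, n_pure_reverse = 0L,
      n_background_in = 0L, n_background_out = n_reads - k,
      n_unmapped_telomeric = 0L), file.path(dir, sub), sub)
  }
  tumour <- mk(k_t, "tumour", seed * 2L + 1L)
  normal <- mk(k_n, "normal", seed * 2L + 2L)
  list(tumour = tumour, normal = normal, k_tumour = k_t, k_normal = k_n,
       n_reads = n_reads,
       expected_log2 = log2(f_tumour / f_normal))
}
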