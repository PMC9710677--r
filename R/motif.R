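#' Build a two-stage telomere motif specification
#'
#' Constructs the matcher used throughout the package. Stage 1 is a fast
#' exact-substring gate: a read passes if it contains `stage1_repeats`
#' concurrent copies of the canonical motif (default `TTAGGG`) on either
#' strand. Stage 2 is a regular-expression confirmation run only on reads
#' that pass stage 1: it extracts every run of `stage2_min_repeats` or more
#' contiguous repeat units in which the first `wildcard_prefix` bases of each
#' unit may be any of A/C/G/T while the remainder of the unit must match the
#' canonical motif exactly. Both strands are matched: the reverse-strand
#' pattern is the exact reverse complement of the forward unit scheme, so
#' with defaults the forward units are `NNNGGG` and the reverse units
#' `CCCNNN`.
#'
#' @param canonical_motif Single DNA string over A/C/G/T. Default `"TTAGGG"`,
#'   the canonical human telomere repeat.
#' @param stage1_repeats Number of concurrent exact copies of the motif
#'   required by the stage-1 gate. Default 3.
#' @param stage2_min_repeats Minimum number of contiguous (possibly
#'   degenerate) repeat units a stage-2 hit must contain. Default 2.
#' @param wildcard_prefix Number of leading bases of each repeat unit allowed
#'   to vary in stage 2. Must be smaller than the motif length. Default 3.
#' @param strands Which strands to match: `"both"` (default), `"forward"`
#'   (motif as given) or `"reverse"` (its reverse complement).
#'
#' @return An object of class `motif_spec` with components
#'   `canonical_motif`, `motif_length`, `stage1_repeat_count`,
#'   `stage1_strings` (character vector of exact gate strings),
#'   `stage2_min_repeats`, `stage2_wildcard_prefix`, `strands` and
#'   `stage2_patterns` (named character vector of PCRE patterns, serialized
#'   into reports for provenance).
#'
#' @examples
#' spec <- build_motif_spec()
#' spec$stage1_strings
#' stage1_match(strrep("TTAGGG", 4), spec)
#' stage2_find("AAATTAGGGTTAGGGAAA", spec)
#' @export
build_motif_spec <- function(canonical_motif = "TTAGGG",
                             stage1_repeats = 3L,
                             stage2_min_repeats = 2L,
                             wildcard_prefix = 3L,
                             strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  if (!is.character(canonical_motif) || length(canonical_motif) != 1L ||
      !nzchar(canonical_motif)) {
    stop("configuration error: canonical_motif must be a non-empty DNA string",
         call. = FALSE)
  }
  canonical_motif <- toupper(canonical_motif)
  bad <- regmatches(canonical_motif,
                    regexpr("[^ACGT]", canonical_motif))
  if (length(bad) && nzchar(bad)) {
    stop(sprintf(
      "configuration error: canonical_motif contains invalid character '%s' (alphabet is A/C/G/T)",
      bad), call. = FALSE)
  }
  stage1_repeats <- .check_count(stage1_repeats, "stage1_repeats", min = 1L)
  stage2_min_repeats <- .check_count(stage2_min_repeats, "stage2_min_repeats",
                                     min = 1L)
  wildcard_prefix <- .check_count(wildcard_prefix, "wildcard_prefix", min = 0L)
  L <- nchar(canonical_motif)
  if (wildcard_prefix >= L) {
    stop(sprintf(
      "configuration error: wildcard_prefix (%d) must be smaller than the motif length (%d)",
      wildcard_prefix, L), call. = FALSE)
  }

  fwd_gate <- strrep(canonical_motif, stage1_repeats)
  rev_gate <- revcomp(fwd_gate)
  stage1_strings <- switch(strands,
    both    = unique(c(fwd_gate, rev_gate)),
    forward = fwd_gate,
    reverse = rev_gate)

  fixed_suffix <- substr(canonical_motif, wildcard_prefix + 1L, L)
  unit_fwd <- if (wildcard_prefix > 0L) {
    sprintf("[ACGT]{%d}%s", wildcard_prefix, fixed_suffix)
  } else {
    canonical_motif
  }
  unit_rev <- if (wildcard_prefix > 0L) {
    sprintf("%s[ACGT]{%d}", revcomp(fixed_suffix), wildcard_prefix)
  } else {
    revcomp(canonical_motif)
  }
  pat <- function(unit) sprintf("(?:%s){%d,}", unit, stage2_min_repeats)
  stage2_patterns <- switch(strands,
    both    = c(forward = pat(unit_fwd), reverse = pat(unit_rev)),
    forward = c(forward = pat(unit_fwd)),
    reverse = c(reverse = pat(unit_rev)))
  # fixed (non-wildcard) part of each repeat unit, precomputed for the
  # unit-scanner in stage2_find
  stage2_fixed <- c(forward = fixed_suffix, reverse = revcomp(fixed_suffix))

  structure(list(
    canonical_motif       = canonical_motif,
    motif_length          = L,
    stage1_repeat_count   = stage1_repeats,
    stage1_strings        = stage1_strings,
    stage2_min_repeats    = stage2_min_repeats,
    stage2_wildcard_prefix = wildcard_prefix,
    strands               = strands,
    stage2_patterns       = stage2_patterns,
    stage2_fixed          = stage2_fixed
  ), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("Two-stage telomere motif specification\n")
  cat("  canonical motif :", x$canonical_motif, "\n")
  cat("  stage 1 gate    :", paste(x$stage1_strings, collapse = ", "),
      sprintf("(%d concurrent repeats)\n", x$stage1_repeat_count))
  cat("  stage 2 patterns:",
      paste(sprintf("%s=%s", names(x$stage2_patterns), x$stage2_patterns),
            collapse = ", "), "\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, any case).
#' @return Character vector of reverse complements, uppercased.
#' @examples
#' revcomp("TTAGGG")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

.check_count <- function(x, what, min) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("configuration error: %s must be a single integer >= %d",
                 what, min), call. = FALSE)
  }
  as.integer(x)
}

#' Stage-1 exact-substring gate
#'
#' Fast pre-filter: `TRUE` iff any of the spec's exact stage-1 strings
#' (the canonical motif repeated `stage1_repeat_count` times, forward and/or
#' reverse complement) occurs as a contiguous substring of `sequence`.
#' `N` bases never match. Pure function.
#'
#' @param sequence Character vector of read sequences (A/C/G/T/N; case is
#'   normalised internally).
#' @param spec A [build_motif_spec()] object.
#' @return Logical vector, one element per sequence; empty sequences give
#'   `FALSE`.
#' @export
stage1_match <- function(sequence, spec) {
  s <- toupper(sequence)
  out <- rep(FALSE, length(s))
  for (g in spec$stage1_strings) {
    out <- out | grepl(g, s, fixed = TRUE)
  }
  out & nzchar(s)
}

#' Stage-2 regex confirmation: extract all motif runs
#'
#' Finds every maximal run of contiguous repeat units in a read sequence.
#' A hit is a chain of `stage2_min_repeats` or more contiguous units in
#' which the first `wildcard_prefix` bases of each unit may vary over
#' A/C/G/T while the rest must match the canonical motif (forward) or its
#' reverse complement (reverse); a chain is maximal when it cannot be
#' extended by another whole valid unit at either end. The two strands are
#' scanned independently and the union of their hits is returned, ordered
#' by offset (forward before reverse at ties).
#'
#' Maximal chains are direction-neutral: the hit set is exactly mirrored
#' (with strand classes swapped) on the reverse complement of the read. In
#' degenerate G/C-rich stretches, chains in different unit phases — or a
#' forward and a reverse chain over the same span — can overlap; each is
#' reported. On ordinary telomeric reads chains are unique and
#' non-overlapping, and the output coincides with a leftmost-greedy match
#' of the serialized stage-2 regular expressions.
#'
#' @inheritParams stage1_match
#' @param sequence A single read sequence.
#' @return A data frame with one row per hit and columns `start_offset`
#'   (0-based offset within the read), `matched_substring`, `repeat_count`
#'   (matched length divided by the motif length) and `strand_class`
#'   (`"forward"` or `"reverse"`). Zero rows when nothing matches.
#' @export
stage2_find <- function(sequence, spec) {
  stopifnot(length(sequence) == 1L)
  s <- toupper(sequence)
  n <- nchar(s)
  L <- spec$motif_length
  m <- spec$stage2_min_repeats
  w <- spec$stage2_wildcard_prefix
  if (n < m * L) return(.empty_hits())

  starts <- integer(0); lens <- integer(0); strand <- character(0)
  idx <- seq_len(n - L + 1L)
  for (cls in names(spec$stage2_fixed)) {
    if (!cls %in% names(spec$stage2_patterns)) next
    fixed <- spec$stage2_fixed[[cls]]
    # valid[i]: a repeat unit of this strand starts at position i
    if (cls == "forward") {
      fixed_ok <- substring(s, idx + w, idx + L - 1L) == fixed
      wild <- substring(s, idx, idx + w - 1L)
    } else {
      fixed_ok <- substring(s, idx, idx + (L - w) - 1L) == fixed
      wild <- substring(s, idx + (L - w), idx + L - 1L)
    }
    valid <- fixed_ok & (w == 0L | !grepl("[^ACGT]", wild))
    for (i in idx[valid]) {
      if (i - L >= 1L && valid[i - L]) next  # not left-maximal
      k <- 1L
      while (i + k * L <= n - L + 1L && valid[i + k * L]) k <- k + 1L
      if (k >= m) {
        starts <- c(starts, i)
        lens <- c(lens, k * L)
        strand <- c(strand, cls)
      }
    }
  }
  if (!length(starts)) return(.empty_hits())
  ord <- order(starts, match(strand, c("forward", "reverse")))
  starts <- starts[ord]; lens <- lens[ord]; strand <- strand[ord]
  data.frame(
    start_offset      = starts - 1L,
    matched_substring = substring(s, starts, starts + lens - 1L),
    repeat_count      = as.integer(lens / L),
    strand_class      = strand,
    stringsAsFactors  = FALSE
  )
}

.empty_hits <- function() {
  data.frame(start_offset = integer(0), matched_substring = character(0),
             repeat_count = integer(0), strand_class = character(0),
             stringsAsFactors = FALSE)
}

#' Classify a read through the two-stage matcher
#'
#' Runs the stage-1 gate; only on a pass is the slower stage-2 regex
#' evaluated. A read whose sequence would satisfy stage 2 in isolation but
#' lacks a stage-1 exact run is therefore rejected — this gate semantics is
#' what makes whole-genome scanning fast.
#'
#' @inheritParams stage2_find
#' @return A list of class `match_result` with elements `stage1_passed`,
#'   `stage2_passed` (both logical) and `hits` (the [stage2_find()] data
#'   frame; zero rows unless `stage2_passed`).
#' @export
classify_read <- function(sequence, spec) {
  stopifnot(length(sequence) == 1L)
  s1 <- stage1_match(sequence, spec)
  if (s1) {
    hits <- stage2_find(sequence, spec)
  } else {
    hits <- .empty_hits()
  }
  structure(list(stage1_passed = unname(s1),
                 stage2_passed = nrow(hits) > 0L,
                 hits = hits),
            class = "match_result")
}
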