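# Independent oracles for the two-stage matcher, built from character
# comparisons only (no regex, no calls into the matcher under test).

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(x)), "")[[1]]),
        collapse = "")
}

# naive exact-substring search
oracle_contains <- function(s, needle) {
  n <- nchar(s); m <- nchar(needle)
  if (m == 0L || m > n) return(FALSE)
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == needle) return(TRUE)
  }
  FALSE
}

oracle_stage1 <- function(s, motif = "TTAGGG", repeats = 3L) {
  gate <- strrep(motif, repeats)
  oracle_contains(toupper(s), gate) ||
    oracle_contains(toupper(s), oracle_revcomp(gate))
}

# one repeat unit of the degenerate scheme: first `wild` bases free over
# A/C/G/T, remainder fixed (forward: motif suffix; reverse: reverse
# complement of that suffix leading the unit)
oracle_unit_ok <- function(u, strand, motif, wild) {
  L <- nchar(motif)
  if (nchar(u) != L || grepl("[^ACGT]", u)) return(FALSE)
  if (strand == "forward") {
    substr(u, wild + 1L, L) == substr(motif, wild + 1L, L)
  } else {
    rc <- oracle_revcomp(motif)
    substr(u, 1L, L - wild) == substr(rc, 1L, L - wild)
  }
}

# brute-force window enumeration: every window of k >= m whole units, on
# either strand, is checked unit-by-unit; a window is a hit iff all its
# units are valid and it cannot be extended by one more whole valid unit
# on either side. Quadratic and entirely substring-based.
oracle_stage2 <- function(s, motif = "TTAGGG", m = 2L, wild = 3L) {
  s <- toupper(s)
  L <- nchar(motif); n <- nchar(s)
  cand <- list()
  if (n >= m * L) {
    for (st in c("forward", "reverse")) {
      for (i in seq_len(n - m * L + 1L)) {
        for (k in seq.int(m, (n - i + 1L) %/% L)) {
          units_ok <- TRUE
          for (u in seq_len(k)) {
            if (!oracle_unit_ok(substr(s, i + (u - 1L) * L, i + u * L - 1L),
                                st, motif, wild)) {
              units_ok <- FALSE
              break
            }
          }
          if (!units_ok) break  # longer windows at i share this bad unit
          left_ext <- i - L >= 1L &&
            oracle_unit_ok(substr(s, i - L, i - 1L), st, motif, wild)
          right_ext <- i + (k + 1L) * L - 1L <= n &&
            oracle_unit_ok(substr(s, i + k * L, i + (k + 1L) * L - 1L),
                           st, motif, wild)
          if (!left_ext && !right_ext) {
            cand[[length(cand) + 1L]] <- list(start = i, len = k * L,
                                              strand = st)
          }
        }
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start_offset = integer(0), matched_substring = character(0),
                      repeat_count = integer(0), strand_class = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- vapply(cand, `[[`, 1L, "start")
  lens <- vapply(cand, `[[`, 1L, "len")
  strand <- vapply(cand, `[[`, "", "strand")
  ord <- order(starts, match(strand, c("forward", "reverse")))
  starts <- starts[ord]; lens <- lens[ord]; strand <- strand[ord]
  data.frame(start_offset = starts - 1L,
             matched_substring = substring(s, starts, starts + lens - 1L),
             repeat_count = as.integer(lens / L),
             strand_class = strand,
             stringsAsFactors = FALSE)
}

# random sequences enriched for near-telomeric content so the matcher is
# actually exercised: mixes uniform bases, motif fragments and Ns
random_telomere_like <- function(len,
                                 alphabet = c("A", "C", "G", "T"),
                                 frag_prob = 0.35, n_prob = 0.02) {
  out <- character(0)
  frags <- c("TTAGGG", "CCCTAA", "GGG", "CCC", "TTA", "TAA")
  while (sum(nchar(out)) < len) {
    if (stats::runif(1) < frag_prob) {
      out <- c(out, sample(frags, 1L))
    } else {
      b <- sample(alphabet, 1L)
      if (stats::runif(1) < n_prob) b <- "N"
      out <- c(out, b)
    }
  }
  substr(paste(out, collapse = ""), 1L, len)
}

# default-spec singleton shared across tests
default_spec <- telomotif::build_motif_spec()

# tiny fixture helper with most classes switched off unless asked for
quick_fixture <- function(dir, seed = 1L, ...) {
  telomotif::generate_fixture(telomotif::fixture_spec(seed = seed, ...), dir)
}

expect_hits_equal <- function(got, want) {
  rownames(got) <- NULL; rownames(want) <- NULL
  expect_equal(got, want)
}
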