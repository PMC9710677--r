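test_that("motif spec construction builds gate strings and patterns", {
  spec <- build_motif_spec("TTAGGG", 3, 2, 3)
  expect_setequal(spec$stage1_strings,
                  c("TTAGGGTTAGGGTTAGGG", "CCCTAACCCTAACCCTAA"))
  expect_true(all(nchar(spec$stage1_strings) == 6 * 3))
  # closed under reverse complement
  expect_setequal(revcomp(spec$stage1_strings), spec$stage1_strings)
  expect_named(spec$stage2_patterns, c("forward", "reverse"))

  # degenerate parameters collapse to exact repeats
  spec1 <- build_motif_spec("TTAGGG", 1, 1, 0)
  expect_setequal(spec1$stage1_strings, c("TTAGGG", "CCCTAA"))
  expect_equal(unname(spec1$stage2_patterns["forward"]), "(?:TTAGGG){1,}")

  spec2 <- build_motif_spec("AC", 2, 2, 1)
  expect_setequal(spec2$stage1_strings, c("ACAC", "GTGT"))

  # every stage-1 string is itself matched by a default stage-2 pattern
  for (g in spec$stage1_strings) {
    expect_gt(nrow(stage2_find(g, spec)), 0)
  }
})

test_that("motif spec rejects invalid parameters", {
  expect_error(build_motif_spec("TTAXGG"), "invalid character 'X'")
  expect_error(build_motif_spec("TTAGGG", wildcard_prefix = 6),
               "wildcard_prefix")
  expect_error(build_motif_spec(""), "non-empty")
  expect_error(build_motif_spec("TTAGGG", stage1_repeats = 0),
               "stage1_repeats")
})

test_that("stage-1 gate matches exact runs only", {
  spec <- default_spec
  expect_true(stage1_match("AAAATTAGGGTTAGGGTTAGGGAAAA", spec))
  expect_false(stage1_match("TTAGGGTTAGGG", spec))  # two repeats < gate
  expect_true(stage1_match("CCCTAACCCTAACCCTAA", spec))
  expect_false(stage1_match("", spec))
  # case is normalised; N never matches
  expect_true(stage1_match("ttaggGTTAGGGttaggg", spec))
  expect_false(stage1_match("TTAGGGTTAGGGTTAGGN", spec))
})

test_that("stage-1 gate agrees with a naive substring oracle on random reads", {
  set.seed(42)
  for (i in 1:1000) {
    s <- random_telomere_like(100)
    expect_identical(stage1_match(s, default_spec), oracle_stage1(s),
                     info = s)
  }
})

test_that("stage-2 extracts maximal leftmost-greedy motif runs", {
  spec <- default_spec
  h <- stage2_find("AAATTAGGGTTAGGGAAA", spec)
  expect_equal(h$start_offset, 3L)
  expect_equal(h$matched_substring, "TTAGGGTTAGGG")
  expect_equal(h$repeat_count, 2L)
  expect_equal(h$strand_class, "forward")

  # repeats present but not concurrent
  expect_equal(nrow(stage2_find("TTAGGGAAATTAGGG", spec)), 0)

  # variation allowed in the first three bases of each unit
  h2 <- stage2_find("GGCGGGTTAGGGTAAGGG", spec)
  expect_equal(h2$start_offset, 0L)
  expect_equal(h2$repeat_count, 3L)
  expect_equal(h2$strand_class, "forward")

  # reverse-strand run
  h3 <- stage2_find("TTCCCTAACCCGATGG", spec)
  expect_equal(h3$start_offset, 2L)
  expect_equal(h3$repeat_count, 2L)
  expect_equal(h3$strand_class, "reverse")

  # hit invariants
  for (h in list(h2, h3)) {
    expect_true(all(nchar(h$matched_substring) %% 6 == 0))
    expect_true(all(h$repeat_count >= spec$stage2_min_repeats))
  }
})

test_that("stage-2 agrees with the brute-force window-enumeration oracle", {
  set.seed(7)
  n_cases <- 2000
  for (i in seq_len(n_cases)) {
    s <- random_telomere_like(sample(12:30, 1))
    expect_hits_equal(stage2_find(s, default_spec), oracle_stage2(s))
  }
  # hand-built edge cases: boundary runs, N interruptions, exact-threshold
  edge <- c(
    strrep("TTAGGG", 2),                 # exactly at threshold
    strrep("TTAGGG", 5),                 # whole-sequence run
    paste0(strrep("TTAGGG", 2), "N", strrep("TTAGGG", 2)),
    paste0("N", strrep("CCCTAA", 3)),
    paste0(strrep("CCCTAA", 2), strrep("TTAGGG", 2)),  # abutting strands
    "CCCGGGCCCGGG",                      # matches both strand patterns
    paste0(strrep("TTAGG", 4)),          # 5-mers, never aligned
    strrep("N", 30),
    "TTAGGGTTAGG",                       # one base short of threshold
    paste0("ACG", strrep("TTAGGG", 2), "ACG"))
  for (s in edge) {
    expect_hits_equal(stage2_find(s, default_spec), oracle_stage2(s))
  }
})

test_that("classify_read evaluates stage 2 only behind the stage-1 gate", {
  spec <- default_spec
  r1 <- classify_read("TTAGGGTTAGGGTTAGGG", spec)
  expect_true(r1$stage1_passed)
  expect_true(r1$stage2_passed)
  expect_equal(r1$hits$repeat_count, 3L)

  r2 <- classify_read("ACGTACGTACGT", spec)
  expect_false(r2$stage1_passed)
  expect_false(r2$stage2_passed)
  expect_equal(nrow(r2$hits), 0)

  # would satisfy stage 2 in isolation, but the gate rejects it
  r3 <- classify_read("TTAGGGTTAGGG", spec)
  expect_false(r3$stage1_passed)
  expect_false(r3$stage2_passed)
  expect_equal(nrow(r3$hits), 0)
  expect_equal(nrow(stage2_find("TTAGGGTTAGGG", spec)), 1)

  # stage2_passed <=> hits non-empty on a batch of random reads
  set.seed(11)
  for (i in 1:200) {
    res <- classify_read(random_telomere_like(60), spec)
    expect_identical(res$stage2_passed, nrow(res$hits) > 0)
    if (res$stage2_passed) expect_true(res$stage1_passed)
  }
})

test_that("matcher output is deterministic across repeated calls", {
  set.seed(3)
  seqs <- replicate(50, random_telomere_like(80))
  a <- lapply(seqs, stage2_find, spec = default_spec)
  b <- lapply(seqs, stage2_find, spec = default_spec)
  expect_identical(a, b)
})
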