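# The generator's truth tables are computed analytically from the
# construction; these tests check the construction itself using the
# independent oracles from helper-oracles.R.

test_that("planted read classes provably belong to their class", {
  expect_equal(make_telomeric_read("pure_forward", 18), strrep("TTAGGG", 3))
  expect_equal(make_telomeric_read("pure_reverse", 18), strrep("CCCTAA", 3))
  set.seed(1)
  for (i in 1:25) {
    d <- make_telomeric_read("degenerate", 100)
    expect_true(oracle_stage1(d))
    expect_gt(nrow(oracle_stage2(d)), 0)
    nm <- make_telomeric_read("near_miss", 100)
    expect_false(oracle_stage1(nm))  # fails the gate, so fails the matcher
    bg <- make_telomeric_read("background", 100)
    expect_false(oracle_stage1(bg))
    expect_equal(nrow(oracle_stage2(bg)), 0)  # not even a gated stage-2 run
  }
  expect_error(make_telomeric_read("degenerate", 10), "impossible")
})

test_that("fixture generation is byte-reproducible under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  args <- list(seed = 33, n_pure_forward = 4, n_pure_reverse = 2,
               n_degenerate = 2, n_background_in = 5, n_background_out = 3,
               n_unmapped_telomeric = 2)
  fx1 <- do.call(quick_fixture, c(list(d1), args))
  fx2 <- do.call(quick_fixture, c(list(d2), args))
  expect_identical(readLines(fx1$sam), readLines(fx2$sam))
  expect_identical(fx1$truth, fx2$truth)
})

test_that("fixtures differing only in seed share the same expected tallies", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  args <- list(n_pure_forward = 7, n_pure_reverse = 3, n_background_in = 6,
               n_background_out = 2, n_unmapped_telomeric = 2)
  fx1 <- do.call(quick_fixture, c(list(d1), c(seed = 101, args)))
  fx2 <- do.call(quick_fixture, c(list(d2), c(seed = 202, args)))
  expect_false(identical(readLines(fx1$sam), readLines(fx2$sam)))
  expect_identical(fx1$truth[c("includes", "unmapped", "genomic",
                               "total_records")],
                   fx2$truth[c("includes", "unmapped", "genomic",
                               "total_records")])
})

test_that("truth tables encode filter and placement rules analytically", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 12, n_pure_forward = 3, n_pure_reverse = 1,
                      n_degenerate = 2, n_near_miss = 3, n_background_in = 4,
                      n_background_out = 2, n_unmapped_telomeric = 2,
                      n_duplicate_telomeric = 2, n_genomic_telomeric = 1)
  tr <- fx$truth
  expect_equal(tr$includes$stage2, 6L)      # pure fwd + rev + degenerate
  expect_equal(tr$includes$examined, 13L)   # + near-miss + background-in
  expect_equal(tr$includes$filtered, 2L)    # duplicates excluded by policy
  expect_equal(tr$unmapped$stage2, 2L)
  expect_equal(tr$genomic$stage2, 1L)
  expect_equal(tr$total_records, 20L)
  # the truth file round-trips
  js <- jsonlite::read_json(fx$truth_json, simplifyVector = TRUE)
  expect_equal(js$includes$stage2, tr$includes$stage2)
  # SAM text is inspectable and header matches the layout
  sam <- readLines(fx$sam)
  expect_true(any(grepl("^@SQ\tSN:chr1\tLN:200000$", sam)))
  expect_equal(sum(!startsWith(sam, "@")), tr$total_records)
})

test_that("impossible fixture specs are rejected", {
  expect_error(fixture_spec(read_length = 10), "read_length")
  expect_error(fixture_spec(n_pure_forward = -1), "counts")
  expect_error(fixture_spec(regions = region_set("chr9", 1, 100, "x")),
               "outside the reference layout")
})

test_that("tumour/normal pairs plant binomial telomeric fractions", {
  d <- withr::local_tempdir()
  pair <- generate_ratio_pair(n_reads = 300, f_tumour = 0.2,
                              f_normal = 0.1, seed = 6, dir = d)
  expect_equal(pair$expected_log2, 1)
  expect_equal(as.integer(total_read_count(pair$tumour$bam)), 300L)
  expect_equal(as.integer(total_read_count(pair$normal$bam)), 300L)
  expect_equal(pair$tumour$truth$includes$stage2, pair$k_tumour)
  expect_equal(pair$normal$truth$includes$stage2, pair$k_normal)
})
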