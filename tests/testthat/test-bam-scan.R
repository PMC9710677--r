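# Fixtures are generated on the fly; every expectation is against the
# analytically computed truth table, never against the matcher under test.

test_that("region iterator yields overlapping records and filters duplicates", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 21, n_pure_forward = 3, n_pure_reverse = 1,
                      n_background_in = 1, n_background_out = 0,
                      n_unmapped_telomeric = 0, n_duplicate_telomeric = 1)
  reg <- fx$regions[1, ]
  rec <- region_reads(fx$bam, reg)
  expect_equal(nrow(rec), 5)              # 5 primary records
  expect_equal(attr(rec, "n_filtered"), 1)  # the duplicate
  # permissive policy keeps the duplicate
  rec2 <- region_reads(fx$bam, reg, read_filter_policy(exclude_duplicates = FALSE))
  expect_equal(nrow(rec2), 6)
  # region with no overlapping reads
  empty <- region_reads(fx$bam,
                        list(chrom = "chr2", start = 1L, end = 1000L))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_filtered"), 0)
  # unknown chromosome names the available ones
  expect_error(region_reads(fx$bam, list(chrom = "chrZ", start = 1, end = 2)),
               "available: chr1, chr2")
})

test_that("a read spanning the region boundary is yielded", {
  d <- withr::local_tempdir()
  # the region is shorter than the read: the only placement starts inside
  # chr1:1-50 and ends at base 100, outside the region
  rs <- region_set("chr1", 1, 50, "edge")
  fx <- quick_fixture(d, seed = 5, regions = rs, n_pure_forward = 1,
                      n_pure_reverse = 0, n_background_in = 0,
                      n_background_out = 0, n_unmapped_telomeric = 0)
  rec <- region_reads(fx$bam, rs[1, ])
  expect_equal(nrow(rec), 1)
  expect_lte(rec$pos, 50)       # starts inside
  expect_gt(rec$pos + 99, 50)   # ends outside
  # interval-overlap oracle: the record overlaps [1,50] by >= 1 base
  expect_true(rec$pos <= 50 && rec$pos + 99 >= 1)
})

test_that("unmapped iterator returns every unmapped record exactly once", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 8, n_pure_forward = 2, n_pure_reverse = 0,
                      n_background_in = 2, n_background_out = 2,
                      n_unmapped_telomeric = 3, n_unmapped_background = 2)
  um <- unmapped_reads(fx$bam)
  expect_equal(nrow(um), 5)
  expect_true(all(bitwAnd(um$flag, 4L) > 0))
})

test_that("placed-unmapped mates go to the unmapped category and are never double-counted", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 13, n_pure_forward = 4, n_pure_reverse = 0,
                      n_background_in = 3, n_background_out = 0,
                      n_unmapped_telomeric = 3, unmapped_with_coord = TRUE)
  # the unmapped records carry a coordinate inside the include region
  um <- unmapped_reads(fx$bam)
  expect_equal(nrow(um), 3)
  expect_true(all(um$rname == "chr1" | is.na(um$rname)))
  # ...but the region iterator never yields them
  rec <- region_reads(fx$bam, fx$regions[1, ])
  expect_equal(nrow(rec), 7)
  # and the scan counts them once, in the unmapped category
  rep <- telomere_scan(fx$bam, fx$regions)
  expect_equal(rep$categories$unmapped$stage2, fx$truth$unmapped$stage2)
  expect_equal(rep$categories$includes$stage2, fx$truth$includes$stage2)
  expect_equal(rep$total_examined,
               fx$truth$includes$examined + fx$truth$unmapped$examined)
})

test_that("region-mode scan reproduces the planted truth table", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 2, n_pure_forward = 10, n_pure_reverse = 0,
                      n_background_in = 20, n_background_out = 0,
                      n_unmapped_telomeric = 4)
  rep <- telomere_scan(fx$bam, fx$regions)
  expect_equal(rep$categories$includes$stage2, 10L)
  expect_equal(rep$categories$unmapped$stage2, 4L)
  expect_equal(rep$categories$includes$stage2 +
                 rep$categories$unmapped$stage2, 14L)
  # per-region stage-2 sums equal the includes aggregate
  expect_equal(sum(rep$regions$stage2), rep$categories$includes$stage2)
  # region mode never reports a genomic category
  expect_false("genomic" %in% names(rep$categories))
  # tally ordering invariants
  for (ct in rep$categories) {
    expect_lte(ct$stage2, ct$stage1)
    expect_lte(ct$stage1, ct$examined)
  }
})

test_that("overlapping include regions count each read once, attributed to the first", {
  d <- withr::local_tempdir()
  rs <- suppressMessages(region_set(c("chr1", "chr1"), c(1, 5000),
                                    c(8000, 12000), c("telA", "telB")))
  fx <- quick_fixture(d, seed = 31, regions = rs, n_pure_forward = 6,
                      n_pure_reverse = 2, n_background_in = 6,
                      n_background_out = 4, n_unmapped_telomeric = 2)
  rep <- telomere_scan(fx$bam, rs)
  # global single-counting: aggregate equals planted truth despite overlap
  expect_equal(rep$categories$includes$stage2, fx$truth$includes$stage2)
  expect_equal(rep$categories$includes$examined, fx$truth$includes$examined)
  expect_equal(sum(rep$regions$stage2), rep$categories$includes$stage2)
  # and full scan agrees
  full <- telomere_full_scan(fx$bam, rs)
  expect_equal(full$categories$includes$stage2, rep$categories$includes$stage2)
})

test_that("full scan finds telomeric reads outside include regions", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 17, n_pure_forward = 3, n_pure_reverse = 0,
                      n_background_in = 2, n_background_out = 5,
                      n_unmapped_telomeric = 1, n_genomic_telomeric = 2)
  full <- telomere_full_scan(fx$bam, fx$regions)
  expect_equal(full$categories$genomic$stage2, 2L)
  expect_equal(full$categories$genomic$examined, 7L)
  # region mode equals full scan on includes + unmapped
  rep <- telomere_scan(fx$bam, fx$regions)
  for (cat_name in c("includes", "unmapped")) {
    for (k in c("examined", "stage1", "stage2")) {
      expect_equal(rep$categories[[cat_name]][[k]],
                   full$categories[[cat_name]][[k]])
    }
  }
})

test_that("an empty BAM scans to all-zero tallies without error", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 99, n_pure_forward = 0, n_pure_reverse = 0,
                      n_background_in = 0, n_background_out = 0,
                      n_unmapped_telomeric = 0)
  rep <- telomere_scan(fx$bam, fx$regions)
  expect_equal(rep$total_examined, 0L)
  expect_equal(rep$categories$includes$stage2, 0L)
  full <- telomere_full_scan(fx$bam, fx$regions)
  expect_equal(full$total_examined, 0L)
})

test_that("adding one planted telomeric read raises its category count by exactly one", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  base <- list(seed = 4, n_pure_forward = 5L, n_pure_reverse = 3L,
               n_background_in = 8L, n_background_out = 4L,
               n_unmapped_telomeric = 2L)
  fx1 <- do.call(quick_fixture, c(list(d1), base))
  base$n_pure_forward <- base$n_pure_forward + 1L
  fx2 <- do.call(quick_fixture, c(list(d2), base))
  r1 <- telomere_scan(fx1$bam, fx1$regions)
  r2 <- telomere_scan(fx2$bam, fx2$regions)
  expect_equal(r2$categories$includes$stage2,
               r1$categories$includes$stage2 + 1L)
  expect_equal(r2$categories$unmapped$stage2, r1$categories$unmapped$stage2)
})

test_that("worker count changes nothing in the report", {
  d <- withr::local_tempdir()
  rs <- region_set(c("chr1", "chr1", "chr2"), c(1, 20001, 1),
                   c(10000, 30000, 5000), c("telA", "telB", "telC"))
  fx <- quick_fixture(d, seed = 23, regions = rs, n_pure_forward = 6,
                      n_pure_reverse = 6, n_background_in = 9,
                      n_background_out = 5, n_unmapped_telomeric = 3)
  r1 <- telomere_scan(fx$bam, rs, workers = 1)
  r2 <- telomere_scan(fx$bam, rs, workers = 2)
  r4 <- telomere_scan(fx$bam, rs, workers = 4)
  expect_identical(r1, r2)
  expect_identical(r1, r4)
})

test_that("a missing index is reported with instructions", {
  d <- withr::local_tempdir()
  fx <- quick_fixture(d, seed = 3, n_pure_forward = 1, n_pure_reverse = 0,
                      n_background_in = 0, n_background_out = 0,
                      n_unmapped_telomeric = 0)
  file.remove(paste0(fx$bam, ".bai"))
  expect_error(telomere_scan(fx$bam, fx$regions), "index")
})
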