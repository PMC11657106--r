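test_that("genome_spec enforces its invariants", {
  expect_s3_class(toy, "genome_spec")
  expect_error(genome_spec(data.frame(name = c("A", "A"), length = 1e6,
                                      cen_start = 1e5, cen_end = 2e5)),
               "duplicate")
  expect_error(genome_spec(data.frame(name = "A", length = 1e6,
                                      cen_start = 5e5, cen_end = 2e6)),
               "centromere")
  expect_error(genome_spec(data.frame(name = "A", length = 1e6,
                                      cen_start = 0, cen_end = 2e5)),
               "centromere")
})

test_that("read_genome round-trips the shipped default spec", {
  g <- default_genome()
  expect_equal(nrow(g), 22)
  expect_true(all(g$cen_start < g$cen_end & g$cen_end < g$length))
  arms <- genome_arms(g)
  expect_equal(nrow(arms), 44)
  expect_equal(sum(arms$len) + sum(g$cen_end - g$cen_start), sum(g$length))
})

test_that("segment_profile validates ordering, bounds and copy numbers", {
  expect_error(mk_profile(seg("A", 0, 100, 1, 2)), "minor_cn > major_cn")
  expect_error(mk_profile(seg("A", 0, 100, 1, 1), seg("A", 90, 200, 1, 0)),
               "overlap")
  expect_error(mk_profile(seg("A", 0, 100, 1, 1), seg("A", 101, 200, 1, 0)),
               "gap")
  expect_error(mk_profile(seg("A", 0, 100, 1, 1), seg("A", 100, 201, 1, 0)),
               "beyond")
  expect_error(mk_profile(seg("A", 0, 100, 1.5, 1)), "integers")
  # valid two-segment tiling passes
  p <- mk_profile(seg("A", 0, 100, 1, 1), seg("A", 100, 200, 1, 0),
                  seg("B", 0, 150, 1, 1), seg("C", 0, 100, 2, 1))
  expect_true(p$valid)
  expect_equal(nrow(p$segments), 4)
})

test_that("read_seg parses a valid file and flags structural errors by line", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "s1\tA\t0\t100000000\t1\t1",
               "s1\tA\t100000000\t200000000\t1\t0",
               "s1\tB\t0\t150000000\t2\t1",
               "s1\tC\t0\t100000000\t1\t1"), path)
  profs <- read_seg(path, toy)
  expect_named(profs, "s1")
  expect_equal(nrow(profs$s1$segments), 4)

  bad <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "s1\tA\t0\t99999999\t1\t1",
               "s1\tA\t100000000\t200000000\t1\t0",
               "s1\tB\t0\t150000000\t1\t1",
               "s1\tC\t0\t100000000\t1\t1"), bad)
  expect_error(read_seg(bad, toy), "line 3.*gap")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "s1\tZ\t0\t1000\t1\t1"), bad)
  expect_error(read_seg(bad, toy), "unknown chromosome")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "s1\tA\t0\t2e8x\t1\t1"), bad)
  expect_error(read_seg(bad, toy), "line 2.*malformed")
})

test_that("assay-failure samples round-trip through SEG files", {
  path <- withr::local_tempfile(fileext = ".seg")
  p_ok <- flat_profile("ok")
  p_bad <- segment_profile("failed", NULL, valid = FALSE)
  write_seg(list(p_ok, p_bad), path)
  back <- read_seg(path, toy)
  expect_true(back$ok$valid)
  expect_false(back$failed$valid)
  expect_equal(nrow(back$failed$segments), 0)
})

test_that("write_seg(read_seg(f)) reproduces a canonical file byte-for-byte", {
  path <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tmajor_cn\tminor_cn",
               "s1\tA\t0\t100000000\t1\t1",
               "s1\tA\t100000000\t200000000\t1\t0",
               "s1\tB\t0\t150000000\t2\t1",
               "s1\tC\t0\t100000000\t1\t1",
               "s2\tA\t0\t200000000\t2\t2",
               "s2\tB\t0\t150000000\t1\t1",
               "s2\tC\t0\t100000000\t1\t1"), path)
  out <- withr::local_tempfile(fileext = ".seg")
  write_seg(read_seg(path, toy), out)
  expect_identical(readLines(out), readLines(path))
})

test_that("normalize_profile merges equal states and is idempotent", {
  p <- mk_profile(seg("A", 0, 50, 1, 1), seg("A", 50, 200, 1, 1),
                  seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  np <- normalize_profile(p)
  expect_equal(nrow(np$segments), 3)
  expect_equal(np$segments$end[np$segments$chrom == "A"], 200e6)
  # differing states do not merge
  q <- mk_profile(seg("A", 0, 50, 2, 1), seg("A", 50, 200, 1, 1),
                  seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(nrow(normalize_profile(q)$segments), 4)
  # idempotence and split-recovery on random profiles
  set.seed(101)
  for (i in 1:25) {
    r <- random_profile()
    n1 <- normalize_profile(r)
    expect_identical(normalize_profile(n1)$segments, n1$segments)
    expect_identical(normalize_profile(refine_profile(r, 4))$segments,
                     n1$segments)
  }
})

test_that("split_by_arm clips at the centromere and conserves length", {
  p <- mk_profile(seg("A", 0, 200, 1, 0), seg("B", 0, 150, 1, 1),
                  seg("C", 0, 100, 1, 1))
  arms <- split_by_arm(p, toy)
  expect_equal(arms$A_p$start, 0)
  expect_equal(arms$A_p$end, 90e6)
  expect_equal(arms$A_q$start, 100e6)
  expect_equal(arms$A_q$end, 200e6)
  # segment wholly inside the centromere is dropped
  q <- mk_profile(seg("A", 0, 90, 1, 1), seg("A", 90, 100, 3, 1),
                  seg("A", 100, 200, 1, 1), seg("B", 0, 150, 1, 1),
                  seg("C", 0, 100, 1, 1))
  arms_q <- split_by_arm(q, toy)
  expect_false(any(arms_q$A_p$major_cn == 3))
  expect_false(any(arms_q$A_q$major_cn == 3))
  # length conservation: clipped total = total - centromere overlap
  set.seed(7)
  for (i in 1:20) {
    r <- random_profile()
    arms_r <- split_by_arm(r, toy)
    clipped <- sum(vapply(arms_r, function(a) sum(a$end - a$start),
                          numeric(1)))
    cen_total <- sum(toy$cen_end - toy$cen_start)
    expect_equal(clipped, sum(r$segments$end - r$segments$start) - cen_total)
  }
  # no emitted segment crosses a centromere boundary
  for (an in names(arms_q)) {
    ch <- sub("_[pq]$", "", an)
    g <- toy[toy$name == ch, ]
    expect_false(any(arms_q[[an]]$start < g$cen_start &
                       arms_q[[an]]$end > g$cen_start))
    expect_false(any(arms_q[[an]]$start < g$cen_end &
                       arms_q[[an]]$end > g$cen_end))
  }
})
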