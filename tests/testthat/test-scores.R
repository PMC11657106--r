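test_that("loh_score counts long non-whole-chromosome LOH runs", {
  # all heterozygous: nothing to count
  expect_equal(loh_score(flat_profile(), toy, default_cfg), 0L)
  # 20 Mb run on A counts; fully-LOH chromosome B is excluded
  p <- mk_profile(seg("A", 0, 20, 1, 0), seg("A", 20, 200, 1, 1),
                  seg("B", 0, 150, 1, 0), seg("C", 0, 100, 1, 1))
  expect_equal(loh_score(p, toy, default_cfg), 1L)
  # boundary: exactly 15 Mb does not qualify (strict >)
  p15 <- mk_profile(seg("A", 10, 25, 1, 0), seg("A", 0, 10, 1, 1),
                    seg("A", 25, 200, 1, 1), seg("B", 0, 150, 1, 1),
                    seg("C", 0, 100, 1, 1))
  expect_equal(loh_score(p15, toy, default_cfg), 0L)
  # runs may cross the centromere (A cen 90-100)
  pc <- mk_profile(seg("A", 80, 110, 2, 0), seg("A", 0, 80, 1, 1),
                   seg("A", 110, 200, 1, 1), seg("B", 0, 150, 1, 1),
                   seg("C", 0, 100, 1, 1))
  expect_equal(loh_score(pc, toy, default_cfg), 1L)
  # homozygous deletion (0/0) is not LOH and breaks a run
  pd <- mk_profile(seg("A", 0, 20, 1, 0), seg("A", 20, 22, 0, 0),
                   seg("A", 22, 40, 1, 0), seg("A", 40, 200, 1, 1),
                   seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(loh_score(pd, toy, default_cfg), 2L)
})

test_that("tai_score counts subtelomeric imbalance not crossing the centromere", {
  # telomeric 20 Mb imbalance at the q end of A (cen 90-100)
  p <- mk_profile(seg("A", 0, 180, 1, 1), seg("A", 180, 200, 2, 1),
                  seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(tai_score(p, toy, default_cfg), 1L)
  # whole-chromosome imbalance crosses the centromere: excluded
  pw <- mk_profile(seg("A", 0, 200, 2, 1), seg("B", 0, 150, 1, 1),
                   seg("C", 0, 100, 1, 1))
  expect_equal(tai_score(pw, toy, default_cfg), 0L)
  # interior imbalance reaches no subtelomere
  pi <- mk_profile(seg("A", 0, 30, 1, 1), seg("A", 30, 80, 2, 1),
                   seg("A", 80, 200, 1, 1), seg("B", 0, 150, 1, 1),
                   seg("C", 0, 100, 1, 1))
  expect_equal(tai_score(pi, toy, default_cfg), 0L)
  # boundary: exactly 11 Mb does not qualify
  p11 <- mk_profile(seg("A", 0, 11, 2, 1), seg("A", 11, 200, 1, 1),
                    seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(tai_score(p11, toy, default_cfg), 0L)
  # p-side 12 Mb qualifies; LOH states are imbalance too
  p12 <- mk_profile(seg("A", 0, 12, 1, 0), seg("A", 12, 200, 1, 1),
                    seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(tai_score(p12, toy, default_cfg), 1L)
})

test_that("lst_score counts junctions between long regions after 3 Mb filtering", {
  # single state per arm: no junctions
  expect_equal(lst_score(flat_profile(), toy, default_cfg), 0L)
  # p-arm of A (90 Mb): 40 Mb 1/1 then 50 Mb 2/1 -> one junction
  p <- mk_profile(seg("A", 0, 40, 1, 1), seg("A", 40, 200, 2, 1),
                  seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  # note q-arm of A is all 2/1: no junction there; but [40,200) also spans
  # the centromere: clipped independently, so exactly 1 junction on p
  expect_equal(lst_score(p, toy, default_cfg), 1L)
  # inserting a 2 Mb sliver at the junction leaves the count unchanged
  ps <- mk_profile(seg("A", 0, 40, 1, 1), seg("A", 40, 42, 3, 0),
                   seg("A", 42, 200, 2, 1), seg("B", 0, 150, 1, 1),
                   seg("C", 0, 100, 1, 1))
  expect_equal(lst_score(ps, toy, default_cfg), 1L)
  # flanks must both exceed 10 Mb: 9 Mb flank does not count
  pf <- mk_profile(seg("A", 0, 9, 1, 1), seg("A", 9, 90, 2, 1),
                   seg("A", 90, 200, 1, 1), seg("B", 0, 150, 1, 1),
                   seg("C", 0, 100, 1, 1))
  expect_equal(lst_score(pf, toy, default_cfg), 0L)
  # filtering re-merges: short sliver inside one state leaves zero junctions
  pm <- mk_profile(seg("A", 0, 44, 1, 1), seg("A", 44, 46, 2, 2),
                   seg("A", 46, 90, 1, 1), seg("A", 90, 200, 1, 1),
                   seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  expect_equal(lst_score(pm, toy, default_cfg), 0L)
})

test_that("gis combines, caps and propagates invalidity; classify_hrd partitions", {
  p <- flat_profile()
  sc <- gis(p, toy, default_cfg)
  expect_equal(sc$gis, 0)
  expect_true(sc$valid)
  # additive combination and the cap: this profile has LOH 1 (interior run
  # on A), TAI 1 (q-telomeric imbalance) and LST 3 (both edges of the LOH
  # tract and the imbalance junction all have long flanks), raw sum 5
  busy <- mk_profile(seg("A", 0, 20, 1, 1), seg("A", 20, 40, 1, 0),
                     seg("A", 40, 180, 1, 1), seg("A", 180, 200, 2, 1),
                     seg("B", 0, 150, 1, 1), seg("C", 0, 100, 1, 1))
  bsc0 <- gis(busy, toy, default_cfg)
  expect_equal(c(bsc0$loh, bsc0$tai, bsc0$lst), c(1L, 1L, 3L))
  expect_equal(bsc0$gis, 5)
  capped <- scoring_config(gis_cap = 3, hrd_cutoff = 2)
  csc <- gis(busy, toy, capped)
  expect_equal(csc$gis, 3)
  expect_equal(csc$gis_raw, 5)
  # invalid profile: everything undefined, flag carries the information
  bad <- segment_profile("x", NULL, valid = FALSE)
  bsc <- gis(bad, toy, default_cfg)
  expect_false(bsc$valid)
  expect_true(is.na(bsc$gis) && is.na(bsc$loh))
  # HRD triage: cutoff inclusive, tBRCAm overrides, unknown only when both
  at_cut <- structure(list(sample_id = "c", loh = 42L, tai = 0L, lst = 0L,
                           gis = 42, gis_raw = 42, valid = TRUE),
                      class = "scar_scores")
  expect_equal(classify_hrd(at_cut, FALSE), "positive")
  below <- structure(list(sample_id = "c", loh = 41L, tai = 0L, lst = 0L,
                          gis = 41, gis_raw = 41, valid = TRUE),
                     class = "scar_scores")
  expect_equal(classify_hrd(below, FALSE), "negative")
  expect_equal(classify_hrd(bsc, TRUE), "positive")
  expect_equal(classify_hrd(bsc, FALSE), "unknown")
  # partition: every combination lands in exactly one state
  for (s in list(at_cut, below, bsc)) for (tb in c(TRUE, FALSE))
    expect_length(classify_hrd(s, tb), 1)
})

test_that("scores match the brute-force oracles on random toy profiles", {
  set.seed(2024)
  for (i in 1:150) {
    p <- random_profile()
    expect_equal(loh_score(p, toy, default_cfg), oracle_loh(p, toy, default_cfg))
    expect_equal(tai_score(p, toy, default_cfg), oracle_tai(p, toy, default_cfg))
    expect_equal(lst_score(p, toy, default_cfg), oracle_lst(p, toy, default_cfg))
  }
})

test_that("scores are representation independent and component-monotone", {
  set.seed(77)
  for (i in 1:40) {
    p <- random_profile()
    r <- refine_profile(p, 5)
    n <- normalize_profile(p)
    for (f in list(loh_score, tai_score, lst_score)) {
      expect_equal(f(r, toy, default_cfg), f(p, toy, default_cfg))
      expect_equal(f(n, toy, default_cfg), f(p, toy, default_cfg))
    }
  }
  # adding one disjoint qualifying LOH run raises loh and gis by exactly 1
  # (the run straddles C's centromere so neither clipped piece has two
  # long flanks -- no incidental LST -- and it reaches no telomere)
  base <- mk_profile(seg("A", 0, 200, 1, 1), seg("B", 0, 150, 1, 1),
                     seg("C", 0, 100, 1, 1))
  plus <- mk_profile(seg("A", 0, 200, 1, 1), seg("B", 0, 150, 1, 1),
                     seg("C", 0, 35, 1, 1), seg("C", 35, 55, 1, 0),
                     seg("C", 55, 100, 1, 1))
  b <- gis(base, toy, default_cfg); a <- gis(plus, toy, default_cfg)
  expect_equal(a$loh, b$loh + 1L)
  expect_equal(a$gis, b$gis + 1)
})
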