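# Scar scores: smoothing, LST, HRD-LOH, NtAI, the sum identity, and
# purity-decile summaries.

one_chr_build <- function(len = 2e8, cen = c(9.5e7, 1.05e8)) {
  genome_build(data.frame(contig = "chr1", length = len,
                          cen_start = cen[1], cen_end = cen[2]))
}

seg <- function(start, end, tcn, lcn, contig = "chr1") {
  data.frame(contig = contig, start = start, end = end, total_cn = tcn,
             minor_cn = lcn, stringsAsFactors = FALSE)
}

test_that("smoothing removes sub-3Mb spikes and merges equal-state neighbours", {
  p <- segment_profile(rbind(seg(1, 2e7, 2, 1),
                             seg(2e7 + 1, 2.1e7, 3, 1),      # 1 Mb spike
                             seg(2.1e7 + 1, 4.1e7, 2, 1)))
  sm <- smooth_profile(p)
  expect_equal(nrow(sm$segments), 1L)
  expect_equal(sm$segments$start, 1)
  expect_equal(sm$segments$end, 4.1e7)
  # an already-smooth profile is unchanged
  p2 <- segment_profile(rbind(seg(1, 2e7, 2, 1), seg(2e7 + 1, 5e7, 3, 1)))
  expect_equal(smooth_profile(p2)$segments, p2$segments)
  # empty profile passes through
  p0 <- segment_profile(seg(1, 1, 2, 1)[0, ])
  expect_equal(nrow(smooth_profile(p0)$segments), 0L)
})

test_that("LST counts only >=10Mb same-arm transitions", {
  b <- one_chr_build()
  # p-arm: three qualifying transitions (all flanks >= 10 Mb) and two
  # blocked by a sub-10Mb flank (the 4 Mb piece)
  p <- segment_profile(rbind(
    seg(1, 1.5e7, 2, 1),            # 15 Mb
    seg(1.5e7 + 1, 3e7, 3, 1),      # 15 Mb    -> LST 1
    seg(3e7 + 1, 4.5e7, 2, 0),      # 15 Mb    -> LST 2
    seg(4.5e7 + 1, 4.9e7, 4, 2),    # 4 Mb     -> blocks both its edges
    seg(4.9e7 + 1, 6.4e7, 2, 1),    # 15 Mb
    seg(6.4e7 + 1, 9.4e7, 3, 0)))   # 30 Mb    -> LST 3
  expect_equal(lst_score(p, b), 3L)
  # a state change straddling the centromere does not count
  p2 <- segment_profile(rbind(seg(1, 9.5e7 - 1, 2, 1),
                              seg(9.5e7, 1.8e8, 4, 2),
                              seg(1.8e8 + 1, 2e8, 4, 2)))
  expect_equal(lst_score(p2, b), 0L)
  # fully balanced diploid genome scores zero
  expect_equal(lst_score(segment_profile(seg(1, 2e8, 2, 1)), b), 0L)
})

test_that("HRD-LOH counts >15Mb LOH segments that are not whole-chromosome", {
  b <- one_chr_build()
  p <- segment_profile(rbind(
    seg(1, 2e7, 2, 0),                   # 20 Mb LOH, telomeric -> counts
    seg(2e7 + 1, 3e7, 2, 1),
    seg(3e7 + 1, 5e7, 2, 0),             # 20 Mb LOH -> counts
    seg(5e7 + 1, 8e7, 2, 1),
    seg(8e7 + 1, 9e7, 2, 0)))            # 10 Mb: below threshold
  expect_equal(hrd_loh_score(p, b), 2L)
  # whole-chromosome LOH contributes nothing
  expect_equal(hrd_loh_score(segment_profile(seg(1, 2e8, 2, 0)), b), 0L)
  expect_equal(hrd_loh_score(segment_profile(seg(1, 2e8, 2, 1)), b), 0L)
})

test_that("NtAI counts telomeric imbalanced segments not crossing the centromere", {
  b <- one_chr_build()
  # balanced genome: zero
  expect_equal(ntai_score(segment_profile(seg(1, 2e8, 2, 1)), b), 0L)
  # AI segment touching the p-terminus, ending before the centromere
  p <- segment_profile(rbind(seg(1, 8e6, 3, 1), seg(8e6 + 1, 2e8, 2, 1)))
  expect_equal(ntai_score(p, b), 1L)
  # AI spanning the centromere out to a telomere is excluded
  p2 <- segment_profile(rbind(seg(1, 9e7, 2, 1), seg(9e7 + 1, 2e8, 3, 1)))
  expect_equal(ntai_score(p2, b), 0L)
  # interior AI segment is not telomeric
  p3 <- segment_profile(rbind(seg(1, 3e7, 2, 1), seg(3e7 + 1, 4e7, 3, 1),
                              seg(4e7 + 1, 2e8, 2, 1)))
  expect_equal(ntai_score(p3, b), 0L)
})

test_that("the HRD sum is exactly the sum of its components", {
  build <- hrd_toy_build()
  set.seed(8)
  for (rep in 1:10) {
    tgt <- sample(0:6, 3, TRUE)
    sp <- simulate_segment_profile(tgt, purity = 1, build = build, sens = 1)
    sc <- hrd_sum(sp$profile, build)
    expect_equal(sc$hrd_sum, sc$lst + sc$hrd_loh + sc$ntai)
    expect_equal(c(sc$lst, sc$hrd_loh, sc$ntai), unname(tgt))
  }
})

test_that("scores are invariant under segment reordering and equal-state splits", {
  build <- hrd_toy_build()
  sp <- simulate_segment_profile(c(3, 2, 4), purity = 1, build = build,
                                 sens = 1)
  base <- hrd_sum(sp$profile, build)
  shuf <- sp$profile
  set.seed(3)
  shuf$segments <- shuf$segments[sample(nrow(shuf$segments)), ]
  shuf <- segment_profile(shuf$segments, purity = shuf$purity)
  expect_equal(unclass(hrd_sum(shuf, build)), unclass(base))
  # split the first big segment into two equal-state halves
  s <- sp$profile$segments
  i <- which(s$end - s$start > 4e7)[1]
  mid <- floor((s$start[i] + s$end[i]) / 2)
  split <- rbind(s[seq_len(i - 1), ],
                 transform(s[i, ], end = mid),
                 transform(s[i, ], start = mid + 1),
                 s[seq(i + 1, nrow(s)), ])
  expect_equal(unclass(hrd_sum(segment_profile(split), build)),
               unclass(base))
})

test_that("purity-decile summaries bin correctly and reject tiny inputs", {
  rec <- data.frame(purity = seq(0.05, 0.95, length.out = 40), hrd_sum = 7)
  ds <- purity_decile_summary(rec)
  expect_equal(nrow(ds), 10L)
  expect_true(all(ds$median == 7))
  expect_true(all(ds$n == 4))
  # exactly 10 records: one per decile
  r10 <- data.frame(purity = runif(10), hrd_sum = 1:10)
  expect_true(all(purity_decile_summary(r10)$n == 1))
  expect_error(purity_decile_summary(rec[1:9, ]), "at least 10")
})
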