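toy <- load_genome_build("toy")

diploid <- function() {
  data.frame(sample = "D", chrom = paste0("chr", 1:3), start = 1, end = 100e6,
             n_major = 1, n_minor = 1)
}

test_that("LOH counting follows the >15 Mb / not-whole-chromosome rule", {
  expect_equal(count_loh(diploid(), toy), 0L)

  # 20 Mb interior LOH block
  seg <- data.frame(sample = "A", chrom = "chr1",
                    start = c(1, 10e6 + 1, 30e6 + 1),
                    end = c(10e6, 30e6, 100e6),
                    n_major = 1, n_minor = c(1, 0, 1))
  expect_equal(count_loh(seg, toy), 1L)

  # whole chromosome at (2,0) is excluded
  whole <- data.frame(sample = "A", chrom = "chr2", start = 1, end = 100e6,
                      n_major = 2, n_minor = 0)
  expect_equal(count_loh(whole, toy), 0L)

  # exactly 15 Mb is not "larger than 15 Mb"
  seg15 <- data.frame(sample = "A", chrom = "chr1",
                      start = c(1, 10e6 + 1, 25e6 + 1),
                      end = c(10e6, 25e6, 100e6),
                      n_major = 1, n_minor = c(1, 0, 1))
  expect_equal(count_loh(seg15, toy), 0L)

  # abutting LOH segments merge before the length test
  split2 <- data.frame(sample = "A", chrom = "chr1",
                       start = c(1, 10e6 + 1, 20e6 + 1, 30e6 + 1),
                       end = c(10e6, 20e6, 30e6, 100e6),
                       n_major = c(1, 1, 2, 1), n_minor = c(1, 0, 0, 1))
  expect_equal(count_loh(split2, toy), 1L)

  # homozygous deletions break an LOH run
  homdel <- data.frame(sample = "A", chrom = "chr1",
                       start = c(1, 10e6 + 1, 20e6 + 1, 22e6 + 1, 32e6 + 1),
                       end = c(10e6, 20e6, 22e6, 32e6, 100e6),
                       n_major = c(1, 1, 0, 1, 1), n_minor = c(1, 0, 0, 0, 1))
  expect_equal(count_loh(homdel, toy), 0L)
})

test_that("segment smoothing fills gaps at the midpoint and conserves span", {
  prof <- data.frame(sample = "A", chrom = "chr1",
                     start = c(1, 12e6 + 1, 14e6 + 1),
                     end = c(12e6, 14e6, 26e6),
                     n_major = c(1, 2, 1), n_minor = c(1, 1, 1))
  sm <- smooth_segments(prof, 3e6)
  expect_equal(nrow(sm), 1L)
  expect_equal(c(sm$start, sm$end), c(1, 26e6))

  prof2 <- prof
  prof2$n_major[3] <- 2; prof2$n_minor[3] <- 2
  sm2 <- smooth_segments(prof2, 3e6)
  expect_equal(sm2$end[1], 13e6)
  expect_equal(sm2$start[2], 13e6 + 1)
  expect_equal(sum(sm2$end - sm2$start + 1), 26e6)

  # fixpoint: nothing below the threshold
  expect_equal(smooth_segments(prof, 1e6)[, names(prof)], prof)
})

test_that("LST counting uses arms, the 10 Mb floor and the 3 Mb gap rule", {
  two <- data.frame(sample = "A", chrom = "chr1",
                    start = c(1, 20e6 + 1), end = c(20e6, 45e6),
                    n_major = c(1, 2), n_minor = c(1, 1))
  expect_equal(count_lst(two, toy), 1L)

  small <- transform(two, end = c(20e6, 28e6))
  expect_equal(count_lst(small, toy), 0L)

  # one segment per arm -> no breakpoints
  expect_equal(count_lst(diploid(), toy), 0L)

  # a 2 Mb insert is smoothed away and does not hide the transition
  smoothed <- data.frame(sample = "A", chrom = "chr1",
                         start = c(1, 20e6 + 1, 22e6 + 1),
                         end = c(20e6, 22e6, 45e6),
                         n_major = c(1, 3, 2), n_minor = c(1, 0, 1))
  expect_equal(count_lst(smoothed, toy), 1L)

  # breaks across the centromere midpoint do not count (arm split)
  cen_break <- data.frame(sample = "A", chrom = "chr1",
                          start = c(1, 50e6 + 1), end = c(50e6, 100e6),
                          n_major = c(1, 2), n_minor = c(1, 1))
  expect_equal(count_lst(cen_break, toy), 0L)
})

test_that("TAI requires a telomere, no centromere crossing, not whole-chromosome", {
  expect_equal(count_tai(diploid(), toy), 0L)

  p_tel <- data.frame(sample = "A", chrom = "chr1",
                      start = c(1, 25e6 + 1), end = c(25e6, 100e6),
                      n_major = c(2, 1), n_minor = 1)
  expect_equal(count_tai(p_tel, toy), 1L)

  crossing <- data.frame(sample = "A", chrom = "chr1",
                         start = c(1, 40e6 + 1, 60e6 + 1),
                         end = c(40e6, 60e6, 100e6),
                         n_major = c(1, 2, 1), n_minor = 1)
  expect_equal(count_tai(crossing, toy), 0L)

  whole <- data.frame(sample = "A", chrom = "chr1", start = 1, end = 100e6,
                      n_major = 2, n_minor = 1)
  expect_equal(count_tai(whole, toy), 0L)

  both_tels <- data.frame(sample = "A", chrom = "chr1",
                          start = c(1, 10e6 + 1, 90e6 + 1),
                          end = c(10e6, 90e6, 100e6),
                          n_major = c(2, 1, 3), n_minor = c(1, 1, 1))
  expect_equal(count_tai(both_tels, toy), 2L)
})

test_that("the HRD score is the unweighted sum of the three signatures", {
  p <- simulate_profile(toy, 2, 3, 1, 0, seed = 99)
  s <- score_sample(p$segments, toy)
  expect_equal(s$hrd, s$loh + s$lst + s$tai)
  expect_equal(unlist(s[, c("loh", "lst", "tai")], use.names = FALSE), c(2, 3, 1))
  s0 <- score_sample(diploid(), toy)
  expect_equal(unlist(s0[, 2:5], use.names = FALSE), c(0, 0, 0, 0))
})

test_that("fast scorers agree with brute-force oracles on random profiles", {
  set.seed(202)
  for (i in 1:150) {
    prof <- random_profile(toy)
    if (!nrow(prof)) next
    prof <- validate_ascn_segments(prof)
    expect_identical(count_loh(prof, toy), oracle_loh(prof, toy))
    expect_identical(count_tai(prof, toy), oracle_tai(prof, toy))
    expect_identical(count_lst(prof, toy), oracle_lst(prof, toy))
  }
})

test_that("raising thresholds never increases counts (monotonicity)", {
  set.seed(7)
  for (i in 1:25) {
    prof <- validate_ascn_segments(random_profile(toy))
    if (!nrow(prof)) next
    l1 <- count_loh(prof, toy, scar_params(loh_min_len = 10e6))
    l2 <- count_loh(prof, toy, scar_params(loh_min_len = 20e6))
    expect_lte(l2, l1)
    s1 <- count_lst(prof, toy, scar_params(lst_min_segment = 8e6))
    s2 <- count_lst(prof, toy, scar_params(lst_min_segment = 14e6))
    expect_lte(s2, s1)
  }
})

test_that("scores are invariant to input row order", {
  set.seed(11)
  prof <- validate_ascn_segments(random_profile(toy))
  shuffled <- prof[sample.int(nrow(prof)), ]
  expect_equal(score_sample(shuffled, toy), score_sample(prof, toy))
})
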