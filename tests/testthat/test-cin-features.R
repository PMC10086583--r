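toy <- load_genome_build("toy")

test_that("segment calls use strict thresholds in both modes", {
  ascn <- data.frame(sample = "A", chrom = "chr1",
                     start = c(1, 11, 21), end = c(10, 20, 30),
                     n_major = c(1, 2, 1), n_minor = c(1, 1, 0))
  calls <- classify_segments(ascn)$call
  expect_equal(calls, c("neutral", "gain", "loss"))

  l2r <- data.frame(sample = "A", chrom = "chr1",
                    start = 1:6, end = 1:6,
                    l2r = c(0.1, 0.11, -0.1, -0.11, 0.8, -0.8))
  cls <- classify_segments(l2r)
  expect_equal(cls$call, c("neutral", "gain", "neutral", "loss", "gain", "loss"))
  expect_equal(cls$high_level,
               c("none", "none", "none", "none", "amplification", "deep_deletion"))

  both <- cbind(ascn, l2r = 0)
  expect_error(classify_segments(both), "mixed")
})

test_that("per-chromosome CIN counts segments, with a merged-run variant", {
  seg <- data.frame(sample = "A", chrom = "chr1",
                    start = c(1, 10e6 + 1, 20e6 + 1, 40e6 + 1),
                    end = c(10e6, 20e6, 30e6, 50e6),
                    n_major = c(2, 2, 1, 0), n_minor = c(1, 1, 1, 0))
  cls <- classify_segments(seg)
  cc <- chromosome_cin(cls, toy)
  chr1 <- cc[cc$chrom == "chr1", ]
  expect_equal(c(chr1$gains, chr1$losses, chr1$total), c(2, 1, 3))

  # two abutting gains merge into one event under merge_runs
  ccm <- chromosome_cin(cls, toy, merge_runs = TRUE)
  chr1m <- ccm[ccm$chrom == "chr1", ]
  expect_equal(c(chr1m$gains, chr1m$losses, chr1m$total), c(1, 1, 2))

  neutral <- classify_segments(data.frame(sample = "A", chrom = "chr2",
                                          start = 1, end = 100e6,
                                          n_major = 1, n_minor = 1))
  expect_true(all(chromosome_cin(neutral, toy)$total == 0))
})

test_that("fraction of genome altered uses build-wide genome length", {
  gain30 <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                         start = 1, end = 30e6,
                                         n_major = 2, n_minor = 1))
  f <- fraction_genome_altered(gain30, toy)
  expect_equal(f$fga$fga_gain, 0.1)
  expect_equal(f$fga$fga_total, 0.1)

  lost1 <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                        start = 1, end = 100e6,
                                        n_major = 1, n_minor = 0))
  f2 <- fraction_genome_altered(lost1, toy)
  expect_equal(f2$fga$fga_loss, 1 / 3)
  chr1 <- f2$per_chromosome[f2$per_chromosome$chrom == "chr1", ]
  expect_equal(chr1$frac_altered, 1.0)

  neutral <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                          start = 1, end = 100e6,
                                          n_major = 1, n_minor = 1))
  expect_equal(unlist(fraction_genome_altered(neutral, toy)$fga[, 2:4],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("fga components always sum: gain + loss == total", {
  set.seed(5)
  for (i in 1:20) {
    prof <- validate_ascn_segments(random_profile(toy))
    if (!nrow(prof)) next
    f <- fraction_genome_altered(classify_segments(prof), toy)$fga
    expect_equal(f$fga_gain + f$fga_loss, f$fga_total)
    expect_true(all(f[, 2:4] >= 0 & f[, 2:4] <= 1))
  }
})

test_that("aneuploidy flags chromosomes above the 90% fraction", {
  mk <- function(frac_gain, frac_loss = 0) {
    rows <- data.frame(sample = "A", chrom = "chr1",
                       start = 1, end = frac_gain * 100e6,
                       n_major = 2, n_minor = 1)
    if (frac_loss > 0)
      rows <- rbind(rows, data.frame(sample = "A", chrom = "chr1",
                                     start = frac_gain * 100e6 + 1,
                                     end = (frac_gain + frac_loss) * 100e6,
                                     n_major = 1, n_minor = 0))
    classify_segments(rows)
  }
  expect_equal(aneuploidy_events(mk(0.95), toy)$counts$aneuploidy_count, 1L)
  expect_equal(aneuploidy_events(mk(0.80), toy)$counts$aneuploidy_count, 0L)
  # half gained + half lost: neither class exceeds 90%
  expect_equal(aneuploidy_events(mk(0.5, 0.5), toy)$counts$aneuploidy_count, 0L)
  # exactly 90% is not "greater than 90%"
  expect_equal(aneuploidy_events(mk(0.9), toy)$counts$aneuploidy_count, 0L)
})

test_that("cytoband CIN counts >=1 bp overlaps per band", {
  # gain spanning the p1/q1 boundary of toy chr1 (bands are 10 Mb)
  spanning <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                           start = 45e6, end = 55e6,
                                           n_major = 2, n_minor = 1))
  cb <- cytoband_cin(spanning, toy)
  hit <- cb[cb$gains > 0, ]
  expect_equal(nrow(hit), 2L)
  expect_equal(sort(hit$band), c("p1", "q1"))

  # gain ending exactly at a band boundary touches only its own band
  flush <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                        start = 1, end = 10e6,
                                        n_major = 2, n_minor = 1))
  cb2 <- cytoband_cin(flush, toy)
  expect_equal(sum(cb2$gains > 0), 1L)
  expect_equal(cb2$band[cb2$gains > 0], "p5")

  neutral <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                          start = 1, end = 100e6,
                                          n_major = 1, n_minor = 1))
  cb3 <- cytoband_cin(neutral, toy)
  expect_true(all(cb3$gains == 0 & cb3$losses == 0))
})

test_that("HRR-CIN counts per-gene gain and loss events, max 2 per gene", {
  catalog <- hrr_gene_catalog(toy)
  neutral <- classify_segments(data.frame(sample = "A", chrom = "chr1",
                                          start = 1, end = 100e6,
                                          n_major = 1, n_minor = 1))
  expect_equal(hrr_cin_score(neutral, catalog)$hrr_cin, 0L)

  # one loss covering genes 1-3 on chr1 plus gene 4 on chr2
  loss_region <- classify_segments(data.frame(
    sample = "A", chrom = c("chr1", "chr2"),
    start = c(1, 1), end = c(80e6, 20e6), n_major = 1, n_minor = 0))
  expect_equal(hrr_cin_score(loss_region, catalog)$hrr_cin, 4L)

  # gene overlapped by both a gain and a loss contributes 2
  both <- classify_segments(data.frame(
    sample = "A", chrom = "chr1",
    start = c(10.2e6, 10.3e6 + 1), end = c(10.3e6, 10.5e6),
    n_major = c(2, 1), n_minor = c(1, 0)))
  expect_equal(hrr_cin_score(both, catalog)$hrr_cin, 2L)
  expect_error(hrr_cin_score(both, catalog[0, ]), "empty")
})

test_that("HRR-CIN matches the brute-force overlap oracle and its bound", {
  catalog <- hrr_gene_catalog(toy)
  set.seed(31)
  for (i in 1:20) {
    prof <- validate_ascn_segments(random_profile(toy))
    if (!nrow(prof)) next
    cls <- classify_segments(prof)
    fast <- hrr_cin_score(cls, catalog)$hrr_cin
    expect_identical(as.integer(fast), oracle_hrr_cin(cls, catalog))
    expect_lte(fast, 2L * nrow(catalog))
  }
})

test_that("CIN features are invariant to input row order", {
  set.seed(13)
  prof <- validate_ascn_segments(random_profile(toy))
  cls <- classify_segments(prof)
  shuf <- cls[sample.int(nrow(cls)), ]
  expect_equal(fraction_genome_altered(shuf, toy)$fga,
               fraction_genome_altered(cls, toy)$fga)
  expect_equal(hrr_cin_score(shuf, hrr_gene_catalog(toy)),
               hrr_cin_score(cls, hrr_gene_catalog(toy)))
  expect_equal(chromosome_cin(shuf, toy, merge_runs = TRUE),
               chromosome_cin(cls, toy, merge_runs = TRUE))
})
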