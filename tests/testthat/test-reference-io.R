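test_that("toy genome build matches its fixture definition", {
  g <- load_genome_build("toy")
  expect_equal(nrow(g$chromosomes), 3L)
  expect_true(all(g$chromosomes$length == 100e6))
  expect_equal(unname(centromere_interval(g, "chr1")), c(45e6, 55e6))
  expect_equal(centromere_mid(g, "chr2"), 50e6)
})

test_that("genome builds reject structural violations", {
  g <- load_genome_build("toy")
  bad_cyto <- g$cytobands
  bad_cyto$start[2] <- bad_cyto$start[2] - 5e6  # overlap with band 1
  expect_error(genome_build("bad", g$chromosomes, g$centromeres, bad_cyto),
               "overlap|tile")
  bad_cen <- g$centromeres
  bad_cen$end[1] <- 200e6
  expect_error(genome_build("bad", g$chromosomes, bad_cen, g$cytobands),
               "centromere")
  expect_error(load_genome_build("no-such-build"), "unknown")
})

test_that("UCSC-layout cytoband files are parsed with acen centromeres", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t40000000\tp2\tgneg",
               "chr1\t40000000\t50000000\tp1\tacen",
               "chr1\t50000000\t60000000\tq1\tacen",
               "chr1\t60000000\t100000000\tq2\tgpos50"), path)
  g <- load_genome_build(path)
  expect_equal(chrom_length(g, "chr1"), 100e6)
  expect_equal(unname(centromere_interval(g, "chr1")), c(40000001, 60000000))
  expect_equal(nrow(g$cytobands), 4L)
})

test_that("chrY and chrM are dropped, chrX kept, names chr-prefixed", {
  g <- load_genome_build("hg38")
  expect_true("chrX" %in% g$chromosomes$chrom)
  expect_false(any(c("chrY", "chrM") %in% g$chromosomes$chrom))
  seg <- data.frame(sample = "A", chrom = c("1", "Y"), start = c(1, 1),
                    end = c(10e6, 10e6), n_major = c(1, 1), n_minor = c(1, 0))
  v <- validate_ascn_segments(seg)
  expect_equal(v$chrom, "chr1")
})

test_that("the hg38 HRR catalog has 70 loci including the core genes", {
  g <- load_genome_build("hg38")
  cat70 <- hrr_gene_catalog(g)
  expect_equal(nrow(cat70), 70L)
  expect_true(all(c("BRCA1", "BRCA2", "RAD51", "FANCA") %in% cat70$symbol))
  expect_true(all(cat70$start >= 1 &
                    cat70$end <= chrom_length(g, cat70$chrom)))
  expect_equal(nrow(hrr_gene_catalog(load_genome_build("toy"))), 10L)
})

test_that("ASCN segments round-trip through write/read and are validated", {
  toy <- load_genome_build("toy")
  seg <- simulate_profile(toy, 1, 2, 1, 0, seed = 42)$segments
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ascn_segments(seg, path)
  back <- read_ascn_segments(path)
  expect_equal(back, seg)

  # header-only file -> empty collection
  writeLines("sample\tchrom\tstart\tend\tn_major\tn_minor", path)
  expect_equal(nrow(read_ascn_segments(path)), 0L)
})

test_that("the ASCN reader rejects each invariant violation", {
  base <- data.frame(sample = "A", chrom = "chr1", start = 1, end = 10e6,
                     n_major = 1, n_minor = 1)
  write_row <- function(df) {
    p <- tempfile(fileext = ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  bad <- base; bad$n_minor <- 2
  expect_error(read_ascn_segments(write_row(bad)), "n_minor > n_major")
  bad <- base; bad$start <- -5
  expect_error(read_ascn_segments(write_row(bad)), "coordinates")
  bad <- rbind(base, transform(base, start = 5e6, end = 20e6))
  expect_error(read_ascn_segments(write_row(bad)), "overlap")
  bad <- base; bad$n_major <- -1
  expect_error(read_ascn_segments(write_row(bad)), "negative")
  expect_error(read_ascn_segments(write_row(base[, -6])), "columns")
})

test_that("MAF reader applies the PASS quality filter", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(paste("Hugo_Symbol", "Tumor_Sample_Barcode",
                     "Variant_Classification", "FILTER", sep = "\t"),
               "BRCA1\tS1\tMissense_Mutation\tPASS",
               "BRCA2\tS1\tNonsense_Mutation\tartifact",
               "RAD51\tS2\tSplice_Site\tPASS"), path)
  expect_equal(nrow(read_maf_minimal(path, require_pass = TRUE)), 2L)
  expect_equal(nrow(read_maf_minimal(path, require_pass = FALSE)), 3L)
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tFILTER",
               "BRCA1\tS1\tPASS"), path)
  expect_error(read_maf_minimal(path), "Variant_Classification")
})

test_that("expression matrices load from TSV and MatrixMarket", {
  m <- matrix(c(0, 4, 2.5, 10, 1, 7), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, tsv)
  expect_equal(read_expression_matrix(tsv), m)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  stem <- sub("\\.mtx$", "", mtx)
  writeLines(rownames(m), paste0(stem, ".rows.txt"))
  writeLines(colnames(m), paste0(stem, ".cols.txt"))
  expect_equal(read_expression_matrix(mtx), m)

  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup)[4] <- "g1"
  write_expression_matrix(dup, tsv)
  expect_error(read_expression_matrix(tsv), "duplicate")
})
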