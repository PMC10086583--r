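#' Genome build: chromosome, centromere and cytoband model
#'
#' A `GenomeBuild` holds the coordinate scaffold every scoring function
#' works on: ordered chromosome lengths, one centromere interval per
#' chromosome, and cytobands tiling each chromosome. All coordinates are
#' 1-based inclusive; interval lengths are `end - start + 1`.
#'
#' Chromosome names are normalised to the "chr" prefix. chrY and the
#' mitochondrial chromosome are dropped from scoring scope (single-copy /
#' non-nuclear ploidy is ambiguous for allele-specific calls); chrX is
#' retained.
#'
#' @param name label for the build.
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param centromeres data.frame with columns `chrom`, `start`, `end`.
#' @param cytobands data.frame with columns `chrom`, `band`, `start`, `end`.
#' @return An object of class `GenomeBuild`.
#' @export
genome_build <- function(name, chromosomes, centromeres, cytobands) {
  chromosomes$chrom <- normalize_chrom(chromosomes$chrom)
  centromeres$chrom <- normalize_chrom(centromeres$chrom)
  cytobands$chrom <- normalize_chrom(cytobands$chrom)
  keep <- !(chromosomes$chrom %in% c("chrY", "chrM"))
  chromosomes <- chromosomes[keep, , drop = FALSE]
  centromeres <- centromeres[centromeres$chrom %in% chromosomes$chrom, , drop = FALSE]
  cytobands <- cytobands[cytobands$chrom %in% chromosomes$chrom, , drop = FALSE]

  gb <- structure(
    list(name = name,
         chromosomes = chromosomes[, c("chrom", "length")],
         centromeres = centromeres[, c("chrom", "start", "end")],
         cytobands = cytobands[, c("chrom", "band", "start", "end")],
         coordinates = "1-based inclusive"),
    class = "GenomeBuild")
  validate_genome_build(gb)
  gb
}

normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^(chr)?", "chr", x)
  x[x %in% c("chrMT")] <- "chrM"
  x
}

validate_genome_build <- function(gb) {
  chr <- gb$chromosomes
  if (nrow(chr) == 0L) stop("GenomeBuild has no chromosomes")
  if (anyDuplicated(chr$chrom)) stop("duplicate chromosome names")
  if (any(chr$length <= 0)) stop("all chromosome lengths must be > 0")
  cen <- gb$centromeres
  if (!all(chr$chrom %in% cen$chrom)) stop("every chromosome needs a centromere interval")
  len <- stats::setNames(chr$length, chr$chrom)
  if (any(cen$start < 1 | cen$end > len[cen$chrom] | cen$start > cen$end))
    stop("centromere interval must lie within its chromosome")
  cb <- gb$cytobands
  for (cc in chr$chrom) {
    b <- cb[cb$chrom == cc, , drop = FALSE]
    if (nrow(b) == 0L) stop("chromosome ", cc, " has no cytobands")
    b <- b[order(b$start), , drop = FALSE]
    if (b$start[1] != 1L || b$end[nrow(b)] != len[[cc]])
      stop("cytobands of ", cc, " do not tile the chromosome")
    if (nrow(b) > 1L && any(b$start[-1] != b$end[-nrow(b)] + 1))
      stop("cytobands of ", cc, " overlap or leave gaps")
  }
  invisible(gb)
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat(sprintf("GenomeBuild '%s': %d chromosomes, %d cytobands, %s\n",
              x$name, nrow(x$chromosomes), nrow(x$cytobands), x$coordinates))
  invisible(x)
}

#' Load a packaged or file-based genome build
#'
#' `"toy"` is an arithmetic-friendly fixture: 3 chromosomes of 100 Mb with
#' the centromere at (45 Mb, 55 Mb) and ten 10-Mb cytobands each.
#' `"hg38"` packages the GRCh38 chromosome lengths with approximate
#' centromere intervals and coarse arm-level bands (see
#' `inst/extdata/hg38_centromeres_synthetic.tsv`; the annotation is a
#' curated approximation suitable for Mb-scale overlap, not an
#' authoritative cytogenetic map). Any other value is treated as a path
#' to a UCSC-layout cytoBand file (`chrom start end band stain`, 0-based
#' half-open), from which lengths and centromeres (acen bands) are
#' derived.
#'
#' @param name_or_path `"toy"`, `"hg38"`, or a cytoband file path.
#' @return A [genome_build()] object.
#' @export
load_genome_build <- function(name_or_path) {
  if (identical(name_or_path, "toy")) return(toy_genome_build())
  if (identical(name_or_path, "hg38")) return(hg38_genome_build())
  if (!file.exists(name_or_path)) stop("unknown genome build: ", name_or_path)
  read_cytoband_genome(name_or_path)
}

toy_genome_build <- function() {
  chroms <- paste0("chr", 1:3)
  chromosomes <- data.frame(chrom = chroms, length = rep(100e6, 3L))
  centromeres <- data.frame(chrom = chroms, start = rep(45e6, 3L), end = rep(55e6, 3L))
  band_starts <- seq(1, 90e6 + 1, by = 10e6)
  bands <- c(paste0("p", 5:1), paste0("q", 1:5))
  cytobands <- data.frame(
    chrom = rep(chroms, each = 10L),
    band = rep(bands, times = 3L),
    start = rep(band_starts, times = 3L),
    end = rep(band_starts + 10e6 - 1, times = 3L))
  genome_build("toy", chromosomes, centromeres, cytobands)
}

hg38_genome_build <- function() {
  sizes <- utils::read.delim(
    system.file("extdata", "hg38_chrom_sizes.tsv", package = "hrdscape"),
    stringsAsFactors = FALSE)
  cen <- utils::read.delim(
    system.file("extdata", "hg38_centromeres_synthetic.tsv", package = "hrdscape"),
    stringsAsFactors = FALSE)
  # coarse arm-level bands: p = [1, centromere midpoint], q = rest
  mid <- floor((cen$start + cen$end) / 2)
  len <- stats::setNames(sizes$length, sizes$chrom)
  cytobands <- rbind(
    data.frame(chrom = cen$chrom, band = "p", start = 1, end = mid),
    data.frame(chrom = cen$chrom, band = "q", start = mid + 1,
               end = as.numeric(len[cen$chrom])))
  genome_build("hg38", sizes, cen, cytobands)
}

read_cytoband_genome <- function(path) {
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "band", "stain"))
  if (nrow(cb) == 0L) stop("malformed cytoband file: no rows")
  cb$chrom <- normalize_chrom(cb$chrom)
  cb$start <- cb$start + 1L  # UCSC 0-based half-open -> 1-based inclusive
  chromosomes <- stats::aggregate(end ~ chrom, data = cb, FUN = max)
  names(chromosomes)[2] <- "length"
  acen <- cb[cb$stain == "acen", , drop = FALSE]
  if (nrow(acen) == 0L) stop("cytoband file has no acen (centromere) bands")
  cen <- do.call(rbind, lapply(split(acen, acen$chrom), function(b)
    data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end))))
  genome_build(basename(path), chromosomes, cen,
               cb[, c("chrom", "band", "start", "end")])
}

#' @rdname genome_accessors
#' @param genome a [genome_build()] object.
#' @param chrom chromosome name.
#' @export
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) stop("chromosome not in build: ",
                     paste(chrom[is.na(i)], collapse = ", "))
  genome$chromosomes$length[i]
}

#' Accessors for a GenomeBuild
#'
#' `chrom_length()` returns chromosome length(s) in bp;
#' `centromere_interval()` the (start, end) of the centromere;
#' `centromere_mid()` its midpoint, used as the p/q arm boundary.
#' @name genome_accessors
#' @export
centromere_interval <- function(genome, chrom) {
  i <- match(chrom, genome$centromeres$chrom)
  if (anyNA(i)) stop("chromosome not in build: ", chrom)
  c(start = genome$centromeres$start[i], end = genome$centromeres$end[i])
}

#' @rdname genome_accessors
#' @export
centromere_mid <- function(genome, chrom) {
  ce <- centromere_interval(genome, chrom)
  floor((ce[["start"]] + ce[["end"]]) / 2)
}

#' The catalog of homologous recombination repair (HRR) genes
#'
#' For the `"hg38"` build this returns 70 loci covering the core HRR and
#' Fanconi anaemia pathway (BRCA1, BRCA2, RAD51, the RAD51 paralogs, the
#' FANC genes, ATM/ATR signalling, resolvases and accessory factors).
#' Coordinates are packaged approximations (see
#' `inst/extdata/hrr_catalog_hg38_synthetic.tsv`), adequate for Mb-scale
#' segment overlap. The `"toy"` build carries 10 synthetic loci named
#' HRRT01..HRRT10 spread over its 3 chromosomes.
#'
#' @param genome a [genome_build()] object ("toy" or "hg38").
#' @return data.frame with columns `symbol`, `chrom`, `start`, `end`.
#' @export
hrr_gene_catalog <- function(genome) {
  if (identical(genome$name, "toy")) {
    cat10 <- data.frame(
      symbol = sprintf("HRRT%02d", 1:10),
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
                "chr3", "chr3", "chr3", "chr3"),
      start = c(10.2, 30.5, 70.4, 15.3, 40.1, 80.2, 12.7, 35.9, 62.3, 88.8) * 1e6)
    cat10$end <- cat10$start + 2e5 - 1
    return(validate_catalog(cat10, genome))
  }
  if (identical(genome$name, "hg38")) {
    cat70 <- utils::read.delim(
      system.file("extdata", "hrr_catalog_hg38_synthetic.tsv", package = "hrdscape"),
      stringsAsFactors = FALSE)
    return(validate_catalog(cat70, genome))
  }
  stop("no HRR catalog packaged for build '", genome$name, "'")
}

validate_catalog <- function(catalog, genome) {
  catalog$chrom <- normalize_chrom(catalog$chrom)
  if (anyDuplicated(catalog$symbol)) stop("duplicate gene symbols in catalog")
  len <- chrom_length(genome, catalog$chrom)
  if (any(catalog$start < 1 | catalog$end > len | catalog$start > catalog$end))
    stop("catalog locus outside chromosome bounds")
  catalog[, c("symbol", "chrom", "start", "end")]
}
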