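#' Read allele-specific copy-number segments
#'
#' Expects a tab-separated file with header columns
#' `sample chrom start end n_major n_minor` (1-based inclusive
#' coordinates; ASCAT/SEG convention). Chromosome names are normalised
#' to the "chr" prefix; chrY and chrM rows are dropped. Segments are
#' returned sorted by sample, chromosome and start, and validated:
#' `start <= end`, `start >= 1`, integer non-negative allele copies with
#' `n_minor <= n_major`, and no overlap between segments of one sample
#' on one chromosome.
#'
#' @param path file path.
#' @return data.frame of validated segments.
#' @export
read_ascn_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "n_major", "n_minor")
  if (!all(need %in% names(seg)))
    stop("ASCN table must have columns: ", paste(need, collapse = ", "))
  validate_ascn_segments(seg[need])
}

#' @rdname read_ascn_segments
#' @param segments an ASCN segment data.frame.
#' @export
validate_ascn_segments <- function(segments) {
  if (nrow(segments) == 0L) return(segments)
  segments$chrom <- normalize_chrom(segments$chrom)
  segments <- segments[!(segments$chrom %in% c("chrY", "chrM")), , drop = FALSE]
  with(segments, {
    if (any(start < 1 | end < start)) stop("invalid coordinates: need 1 <= start <= end")
    if (any(n_major < 0 | n_minor < 0)) stop("negative allele copy numbers")
    if (any(n_major != round(n_major) | n_minor != round(n_minor)))
      stop("allele copy numbers must be integers")
    if (any(n_minor > n_major)) stop("n_minor > n_major violates the major/minor convention")
  })
  segments <- segments[order(segments$sample, segments$chrom, segments$start), , drop = FALSE]
  if (nrow(segments) > 1L) {
    n <- nrow(segments)
    same <- segments$sample[-1] == segments$sample[-n] &
      segments$chrom[-1] == segments$chrom[-n]
    bad <- same & segments$start[-1] <= segments$end[-n]
    if (any(bad)) {
      i <- which(bad)[1] + 1L
      stop("overlapping segments for sample ", segments$sample[i],
           " on ", segments$chrom[i])
    }
  }
  rownames(segments) <- NULL
  segments
}

#' @rdname read_ascn_segments
#' @export
write_ascn_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read log2-ratio segments
#'
#' Tab-separated with header `sample chrom start end l2r`. Coordinates
#' are validated as for [read_ascn_segments()]; `l2r` must be finite.
#'
#' @param path file path.
#' @return data.frame of validated segments.
#' @export
read_l2r_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "l2r")
  if (!all(need %in% names(seg)))
    stop("L2R table must have columns: ", paste(need, collapse = ", "))
  seg <- seg[need]
  if (nrow(seg)) {
    seg$chrom <- normalize_chrom(seg$chrom)
    seg <- seg[!(seg$chrom %in% c("chrY", "chrM")), , drop = FALSE]
    if (any(seg$start < 1 | seg$end < seg$start)) stop("invalid coordinates")
    if (any(!is.finite(seg$l2r))) stop("non-finite l2r values")
    seg <- seg[order(seg$sample, seg$chrom, seg$start), , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

#' Read a minimal somatic-variant table (MAF columns)
#'
#' Requires the standard MAF columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification` and `FILTER`.
#' With `require_pass = TRUE` (the default) only records whose FILTER is
#' exactly "PASS" are retained, matching the quality filter applied to
#' somatic calls before oncoprint construction.
#'
#' @param path file path.
#' @param require_pass keep only FILTER == "PASS" records.
#' @return data.frame with columns `sample`, `gene`, `classification`,
#'   `filter`.
#' @export
read_maf_minimal <- function(path, require_pass = TRUE) {
  maf <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification", "FILTER")
  missing <- setdiff(need, names(maf))
  if (length(missing)) stop("MAF lacks mandatory column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(sample = maf$Tumor_Sample_Barcode,
                    gene = maf$Hugo_Symbol,
                    classification = maf$Variant_Classification,
                    filter = maf$FILTER,
                    stringsAsFactors = FALSE)
  if (require_pass) out <- out[out$filter == "PASS", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genes-by-samples expression matrix
#'
#' Either a TSV whose first column holds gene symbols and whose
#' remaining columns are samples, or a MatrixMarket `.mtx` file with
#' companion row (`<stem>.rows.txt`) and column (`<stem>.cols.txt`)
#' label files. Duplicate gene symbols and negative values are rejected.
#'
#' @param path file path (`.tsv`/`.txt` or `.mtx`).
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rows.txt"))
    colnames(m) <- readLines(paste0(stem, ".cols.txt"))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene symbols in expression matrix")
  if (any(m < 0)) stop("negative expression values")
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param mat genes-by-samples matrix.
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
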