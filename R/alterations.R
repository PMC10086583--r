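#' Map MAF variant classifications to oncoprint categories
#'
#' Standard MAF vocabulary: missense mutations map to `missense`;
#' nonsense and frameshift events to `truncating`; splice-site to
#' `splice`; everything else to `other_variant`. The mapping is
#' configurable.
#'
#' @param classification character vector of `Variant_Classification`
#'   values.
#' @param mapping named character vector overriding the default map.
#' @return character vector of categories.
#' @export
variant_category <- function(classification,
                             mapping = c(Missense_Mutation = "missense",
                                         Nonsense_Mutation = "truncating",
                                         Frame_Shift_Ins = "truncating",
                                         Frame_Shift_Del = "truncating",
                                         Splice_Site = "splice")) {
  out <- unname(mapping[classification])
  out[is.na(out)] <- "other_variant"
  out
}

#' Categorise a gene-level copy-number value
#'
#' In `"l2r"` mode the cBioPortal-style thresholds apply: amplification
#' above 0.7, deep deletion below -0.7, otherwise gain above 0.1 or
#' loss below -0.1, else none. In `"gdc"` mode the categorical codes
#' -2..2 map to deep_deletion, loss, none, gain, amplification.
#'
#' @param value numeric vector of log2 ratios or GDC codes.
#' @param mode `"l2r"` or `"gdc"`.
#' @param params a [cin_params()] (thresholds for l2r mode).
#' @return character vector of categories (`"none"` when unaltered).
#' @export
classify_gene_cn <- function(value, mode = c("l2r", "gdc"), params = cin_params()) {
  mode <- match.arg(mode)
  if (mode == "l2r") {
    stopifnot(all(is.finite(value)))
    ifelse(value > params$l2r_amp, "amplification",
           ifelse(value > params$l2r_gain, "gain",
                  ifelse(value < params$l2r_deepdel, "deep_deletion",
                         ifelse(value < params$l2r_loss, "loss", "none"))))
  } else {
    if (!all(value %in% -2:2)) stop("GDC codes must be integers in -2..2")
    c("deep_deletion", "loss", "none", "gain", "amplification")[value + 3L]
  }
}

alteration_categories <- c("missense", "truncating", "splice", "other_variant",
                           "amplification", "deep_deletion", "gain", "loss")

#' Build a gene-by-sample alteration (oncoprint) matrix
#'
#' Combines PASS-filtered somatic variants (see [read_maf_minimal()])
#' with per-gene copy-number categories into a set-valued gene-by-sample
#' matrix. Cells hold the union of variant and copy-number categories;
#' samples with no events are retained as empty columns. The per-gene
#' altered fraction is the number of roster samples with any event in
#' the gene divided by the roster size.
#'
#' @param variants data.frame with columns `sample`, `gene`,
#'   `classification` (may be empty).
#' @param gene_cn data.frame with columns `sample`, `gene`, `value`
#'   (log2 ratio or GDC code; may be NULL or empty).
#' @param genes character vector of catalog genes (rows), or a catalog
#'   data.frame with a `symbol` column.
#' @param samples character roster of samples (columns).
#' @param cn_mode `"l2r"` or `"gdc"` for `gene_cn$value`.
#' @param params a [cin_params()].
#' @return object of class `AlterationMatrix`: `events` (long
#'   data.frame `sample, gene, category`), `genes`, `samples`,
#'   `totals` (per-sample event counts), `gene_altered_fraction`.
#' @export
build_alteration_matrix <- function(variants, gene_cn, genes, samples,
                                    cn_mode = "l2r", params = cin_params()) {
  if (is.data.frame(genes)) genes <- genes$symbol
  if (!length(genes)) stop("empty gene catalog")
  ev <- data.frame(sample = character(0), gene = character(0),
                   category = character(0), stringsAsFactors = FALSE)
  if (!is.null(variants) && nrow(variants)) {
    bad <- setdiff(unique(variants$sample), samples)
    if (length(bad)) stop("variant sample(s) absent from roster: ",
                          paste(bad, collapse = ", "))
    ev <- rbind(ev, data.frame(sample = variants$sample, gene = variants$gene,
                               category = variant_category(variants$classification),
                               stringsAsFactors = FALSE))
  }
  if (!is.null(gene_cn) && nrow(gene_cn)) {
    bad <- setdiff(unique(gene_cn$sample), samples)
    if (length(bad)) stop("copy-number sample(s) absent from roster: ",
                          paste(bad, collapse = ", "))
    cat_cn <- classify_gene_cn(gene_cn$value, mode = cn_mode, params = params)
    keep <- cat_cn != "none"
    ev <- rbind(ev, data.frame(sample = gene_cn$sample[keep],
                               gene = gene_cn$gene[keep],
                               category = cat_cn[keep], stringsAsFactors = FALSE))
  }
  ev <- ev[ev$gene %in% genes, , drop = FALSE]
  ev <- unique(ev)
  ev <- ev[order(ev$sample, ev$gene, ev$category), , drop = FALSE]
  rownames(ev) <- NULL
  totals <- table(factor(ev$sample, levels = samples))
  altered <- unique(ev[, c("sample", "gene")])
  frac <- table(factor(altered$gene, levels = genes)) / length(samples)
  structure(list(events = ev, genes = genes, samples = samples,
                 totals = stats::setNames(as.integer(totals), samples),
                 gene_altered_fraction = stats::setNames(as.numeric(frac), genes)),
            class = "AlterationMatrix")
}

#' Per-sample total alteration counts
#'
#' Counts (gene, category) events per sample; this is the quantity
#' whose cohort distribution is bimodal and feeds cut-off inference.
#'
#' @param matrix an [build_alteration_matrix()] result.
#' @return named integer vector over the sample roster.
#' @export
total_alterations <- function(matrix) {
  stopifnot(inherits(matrix, "AlterationMatrix"))
  matrix$totals
}

#' @export
print.AlterationMatrix <- function(x, ...) {
  cat(sprintf("AlterationMatrix: %d genes x %d samples, %d events\n",
              length(x$genes), length(x$samples), nrow(x$events)))
  invisible(x)
}

#' Write an alteration matrix as a long TSV
#'
#' @param matrix an [build_alteration_matrix()] result.
#' @param path output path.
#' @export
write_alteration_matrix <- function(matrix, path) {
  utils::write.table(matrix$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
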