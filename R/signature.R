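#' The SARC-HRD 10-gene expression signature
#'
#' Ten genes up-regulated in HRD-high sarcoma: BRCA1, BRCA2, BLM, EME1,
#' FANCB, FANCD2, FANCI, RAD51, RAD54L and XRCC2.
#'
#' @return list of class `SignatureDefinition` (`name`, `genes`,
#'   `direction`).
#' @export
sarc_hrd_signature <- function() {
  structure(list(name = "SARC-HRD",
                 genes = c("BRCA1", "BRCA2", "BLM", "EME1", "FANCB",
                           "FANCD2", "FANCI", "RAD51", "RAD54L", "XRCC2"),
                 direction = "up"),
            class = "SignatureDefinition")
}

#' Per-sample signature score
#'
#' Scores each sample as the mean across signature genes of the
#' per-gene z-score (computed on `log2(x + 1)` values across samples).
#' The cohort mean of scores is therefore ~0 and the score is invariant
#' to per-gene affine rescaling of the input. At least half of the
#' signature genes must be present; missing genes are reported, and
#' zero-variance gene rows are dropped with a warning.
#'
#' Note: the signature itself is a gene list with an "up" direction;
#' mean-z scoring is this package's operationalisation of it as a
#' per-sample number.
#'
#' @param expr genes-by-samples numeric matrix (non-negative counts or
#'   normalised expression).
#' @param signature a signature definition (default [sarc_hrd_signature()]).
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, signature = sarc_hrd_signature()) {
  genes <- signature$genes
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes) / 2)
    stop("fewer than half of the signature genes present in the matrix (",
         length(present), "/", length(genes), ")")
  missing <- setdiff(genes, present)
  if (length(missing))
    message("signature genes absent from matrix: ", paste(missing, collapse = ", "))
  m <- log2(expr[present, , drop = FALSE] + 1)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance signature gene(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) == 0L) stop("no signature gene with nonzero variance")
  }
  z <- t(scale(t(m)))
  colMeans(z)
}

#' Differential-expression threshold filter
#'
#' Flags genes with at least a `fc_threshold`-fold change (i.e.
#' `|log2FC| >= log2(fc_threshold)`) and a p-value at or below
#' `p_threshold`; both boundaries are inclusive.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `p`.
#' @param fc_threshold fold-change threshold (default 2).
#' @param p_threshold p-value threshold (default 0.05).
#' @return character vector of flagged gene symbols.
#' @export
de_filter <- function(records, fc_threshold = 2, p_threshold = 0.05) {
  if (!nrow(records)) return(character(0))
  stopifnot(all(is.finite(records$log2fc)),
            all(records$p >= 0 & records$p <= 1))
  flagged <- abs(records$log2fc) >= log2(fc_threshold) & records$p <= p_threshold
  records$gene[flagged]
}
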