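#' Parameters for chromosomal-instability calling
#'
#' Allele-specific segments are called against a neutral total copy
#' number (gain iff total > 2, loss iff total < 2). Log2-ratio segments
#' use strict thresholds: gain above 0.1, loss below -0.1, with
#' high-level amplification above 0.7 and deep deletion below -0.7
#' (cBioPortal convention). A chromosome with more than 90% of its
#' length gained (or lost) is an aneuploidy event.
#'
#' @param ascn_neutral_cn neutral total copy number for ASCN calls.
#' @param l2r_gain,l2r_loss,l2r_amp,l2r_deepdel log2-ratio thresholds.
#' @param aneuploidy_frac chromosome fraction above which a gain/loss is
#'   an aneuploidy event.
#' @return list of class `CINParams`.
#' @export
cin_params <- function(ascn_neutral_cn = 2, l2r_gain = 0.1, l2r_loss = -0.1,
                       l2r_amp = 0.7, l2r_deepdel = -0.7, aneuploidy_frac = 0.9) {
  stopifnot(l2r_loss < 0, 0 < l2r_gain, l2r_deepdel < l2r_loss,
            l2r_gain < l2r_amp, aneuploidy_frac > 0, aneuploidy_frac <= 1)
  structure(list(ascn_neutral_cn = ascn_neutral_cn, l2r_gain = l2r_gain,
                 l2r_loss = l2r_loss, l2r_amp = l2r_amp,
                 l2r_deepdel = l2r_deepdel, aneuploidy_frac = aneuploidy_frac),
            class = "CINParams")
}

#' Classify segments as gain / loss / neutral
#'
#' Mode is inferred from the columns: `n_major`/`n_minor` selects ASCN
#' mode (gain iff total copy number strictly exceeds
#' `ascn_neutral_cn`, loss iff strictly below), `l2r` selects
#' log2-ratio mode (strict thresholds; amplification / deep-deletion
#' flags at the high-level thresholds). All inequalities are strict.
#'
#' @param segments ASCN or L2R segment table (any number of samples).
#' @param params a [cin_params()].
#' @return input with added `call` and `high_level` columns.
#' @export
classify_segments <- function(segments, params = cin_params()) {
  has_ascn <- all(c("n_major", "n_minor") %in% names(segments))
  has_l2r <- "l2r" %in% names(segments)
  if (has_ascn && has_l2r) stop("mixed segment types: both allele copies and l2r present")
  if (!has_ascn && !has_l2r) stop("segments must carry n_major/n_minor or l2r")
  if (has_ascn) {
    total <- segments$n_major + segments$n_minor
    segments$call <- ifelse(total > params$ascn_neutral_cn, "gain",
                            ifelse(total < params$ascn_neutral_cn, "loss", "neutral"))
    segments$high_level <- "none"
  } else {
    segments$call <- ifelse(segments$l2r > params$l2r_gain, "gain",
                            ifelse(segments$l2r < params$l2r_loss, "loss", "neutral"))
    segments$high_level <- ifelse(segments$l2r > params$l2r_amp, "amplification",
                                  ifelse(segments$l2r < params$l2r_deepdel,
                                         "deep_deletion", "none"))
  }
  segments
}

ensure_sample_col <- function(segments) {
  if (!"sample" %in% names(segments)) segments$sample <- "sample"
  segments
}

# merge abutting same-call segments within sample x chromosome
merge_call_runs <- function(cls) {
  parts <- split(cls, list(cls$sample, cls$chrom), drop = TRUE)
  out <- lapply(parts, function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) return(s)
    keep <- rep(TRUE, nrow(s))
    for (k in 2:nrow(s)) {
      prev <- max(which(keep[1:(k - 1)]))
      if (s$call[k] == s$call[prev] && s$start[k] == s$end[prev] + 1) {
        s$end[prev] <- s$end[k]
        keep[k] <- FALSE
      }
    }
    s[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome CIN counts
#'
#' Counts gain and loss segments per sample and chromosome;
#' `total = gains + losses`. With `merge_runs = TRUE` abutting same-call
#' segments are first merged, removing sensitivity to segmentation
#' granularity (the pipeline default).
#'
#' @param classified output of [classify_segments()].
#' @param genome a [genome_build()].
#' @param merge_runs merge abutting same-call segments before counting.
#' @return data.frame `sample, chrom, gains, losses, total` covering all
#'   build chromosomes.
#' @export
chromosome_cin <- function(classified, genome, merge_runs = FALSE) {
  cls <- ensure_sample_col(classified)
  if (merge_runs && nrow(cls)) cls <- merge_call_runs(cls)
  samples <- unique(cls$sample)
  if (!length(samples)) samples <- character(0)
  grid <- expand.grid(sample = samples, chrom = genome$chromosomes$chrom,
                      stringsAsFactors = FALSE)
  cnt <- function(call) {
    sub <- cls[cls$call == call, , drop = FALSE]
    if (!nrow(sub)) return(integer(nrow(grid)))
    tab <- table(factor(paste(sub$sample, sub$chrom),
                        levels = paste(grid$sample, grid$chrom)))
    as.integer(tab)
  }
  grid$gains <- cnt("gain")
  grid$losses <- cnt("loss")
  grid$total <- grid$gains + grid$losses
  grid
}

altered_len_by <- function(cls, genome, call) {
  sub <- cls[cls$call == call, , drop = FALSE]
  grid <- expand.grid(sample = unique(cls$sample),
                      chrom = genome$chromosomes$chrom, stringsAsFactors = FALSE)
  key <- paste(grid$sample, grid$chrom)
  len <- numeric(nrow(grid))
  if (nrow(sub)) {
    agg <- tapply(sub$end - sub$start + 1, paste(sub$sample, sub$chrom), sum)
    i <- match(names(agg), key)
    len[i] <- as.numeric(agg)
  }
  len
}

#' Fraction of genome altered (FGA)
#'
#' Summed lengths of gain (respectively loss) segments divided by the
#' total genome length in scope (sum of chromosome lengths of the
#' build); uncovered genome counts as neutral. Also returns the altered
#' fraction of every chromosome.
#'
#' @inheritParams chromosome_cin
#' @return list with `fga` (per sample: `fga_gain, fga_loss, fga_total`)
#'   and `per_chromosome` (per sample and chromosome: `frac_gain,
#'   frac_loss, frac_altered`).
#' @export
fraction_genome_altered <- function(classified, genome) {
  cls <- ensure_sample_col(classified)
  genome_len <- sum(genome$chromosomes$length)
  grid <- expand.grid(sample = unique(cls$sample),
                      chrom = genome$chromosomes$chrom, stringsAsFactors = FALSE)
  clen <- chrom_length(genome, grid$chrom)
  grid$frac_gain <- altered_len_by(cls, genome, "gain") / clen
  grid$frac_loss <- altered_len_by(cls, genome, "loss") / clen
  grid$frac_altered <- grid$frac_gain + grid$frac_loss
  fga <- do.call(rbind, lapply(split(cls, cls$sample), function(s) {
    g <- sum((s$end - s$start + 1)[s$call == "gain"])
    l <- sum((s$end - s$start + 1)[s$call == "loss"])
    data.frame(sample = s$sample[1], fga_gain = g / genome_len,
               fga_loss = l / genome_len, fga_total = (g + l) / genome_len,
               stringsAsFactors = FALSE)
  }))
  rownames(fga) <- NULL
  list(fga = fga, per_chromosome = grid)
}

#' Aneuploidy events
#'
#' A chromosome is an aneuploidy event when more than
#' `aneuploidy_frac` (default 90%) of its length is gained, or more than
#' that fraction is lost.
#'
#' @inheritParams chromosome_cin
#' @param params a [cin_params()].
#' @return list with `counts` (per sample) and `flags` (per sample and
#'   chromosome, with the gained/lost fractions).
#' @export
aneuploidy_events <- function(classified, genome, params = cin_params()) {
  cls <- ensure_sample_col(classified)
  grid <- expand.grid(sample = unique(cls$sample),
                      chrom = genome$chromosomes$chrom, stringsAsFactors = FALSE)
  clen <- chrom_length(genome, grid$chrom)
  grid$frac_gain <- altered_len_by(cls, genome, "gain") / clen
  grid$frac_loss <- altered_len_by(cls, genome, "loss") / clen
  grid$aneuploid <- grid$frac_gain > params$aneuploidy_frac |
    grid$frac_loss > params$aneuploidy_frac
  counts <- stats::aggregate(aneuploid ~ sample, data = grid, FUN = sum)
  names(counts)[2] <- "aneuploidy_count"
  list(counts = counts, flags = grid)
}

segments_granges <- function(seg, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(seg$chrom)
  GenomicRanges::GRanges(factor(seg$chrom, levels = seqlevels),
                         IRanges::IRanges(seg$start, seg$end))
}

#' Per-cytoband CIN
#'
#' For every cytoband of the build, counts gain and loss segments
#' overlapping the band by at least one base (1-based inclusive
#' overlap).
#'
#' @inheritParams chromosome_cin
#' @return data.frame `sample, chrom, band, gains, losses`.
#' @export
cytoband_cin <- function(classified, genome) {
  cls <- ensure_sample_col(classified)
  bands <- genome$cytobands
  lv <- genome$chromosomes$chrom
  band_gr <- GenomicRanges::GRanges(factor(bands$chrom, levels = lv),
                                    IRanges::IRanges(bands$start, bands$end))
  samples <- unique(cls$sample)
  nb <- nrow(bands)
  res <- data.frame(sample = rep(samples, each = nb),
                    chrom = rep(bands$chrom, length(samples)),
                    band = rep(bands$band, length(samples)),
                    gains = 0L, losses = 0L, stringsAsFactors = FALSE)
  for (call in c("gain", "loss")) {
    sub <- cls[cls$call == call, , drop = FALSE]
    if (!nrow(sub)) next
    hits <- GenomicRanges::findOverlaps(band_gr, segments_granges(sub, lv))
    if (!length(hits)) next
    idx <- (match(sub$sample[S4Vectors::subjectHits(hits)], samples) - 1L) * nb +
      S4Vectors::queryHits(hits)
    counts <- tabulate(idx, nbins = nb * length(samples))
    if (call == "gain") res$gains <- counts else res$losses <- counts
  }
  res
}

#' HRR-CIN score
#'
#' Chromosomal instability restricted to the homologous recombination
#' repair gene catalog: each catalog gene contributes 1 if any gain
#' segment overlaps its locus and 1 if any loss segment overlaps it
#' (at most 2 per gene); the score is the sum over genes, so it is
#' bounded by twice the catalog size (0-140 for the 70-gene catalog).
#'
#' @inheritParams chromosome_cin
#' @param catalog gene catalog from [hrr_gene_catalog()].
#' @return data.frame `sample, hrr_cin`.
#' @export
hrr_cin_score <- function(classified, catalog) {
  if (nrow(catalog) == 0L) stop("empty HRR gene catalog")
  cls <- ensure_sample_col(classified)
  samples <- unique(cls$sample)
  lv <- unique(c(catalog$chrom, cls$chrom))
  gene_gr <- GenomicRanges::GRanges(factor(catalog$chrom, levels = lv),
                                    IRanges::IRanges(catalog$start, catalog$end))
  res <- data.frame(sample = samples, hrr_cin = 0L, stringsAsFactors = FALSE)
  for (call in c("gain", "loss")) {
    sub <- cls[cls$call == call, , drop = FALSE]
    if (!nrow(sub)) next
    hits <- GenomicRanges::findOverlaps(gene_gr, segments_granges(sub, lv))
    if (!length(hits)) next
    # distinct (gene, sample) pairs hit by this call class
    pair <- unique(cbind(S4Vectors::queryHits(hits),
                         match(sub$sample[S4Vectors::subjectHits(hits)], samples)))
    res$hrr_cin <- res$hrr_cin + tabulate(pair[, 2], nbins = length(samples))
  }
  res
}

#' Full CIN profile of a cohort
#'
#' Convenience orchestrator combining segment calls, per-chromosome
#' counts (on merged runs by default, for cross-cohort comparability),
#' fraction of genome altered, aneuploidy events, per-cytoband CIN and
#' the HRR-CIN score.
#'
#' @param segments ASCN or L2R segment table.
#' @param genome a [genome_build()].
#' @param catalog HRR gene catalog (default from the build).
#' @param params a [cin_params()].
#' @param merge_runs merge abutting same-call segments for the
#'   per-chromosome counts.
#' @return list with `per_sample` wide table, `per_chromosome`,
#'   `per_cytoband`, and `classified` segments.
#' @export
cin_profile <- function(segments, genome, catalog = hrr_gene_catalog(genome),
                        params = cin_params(), merge_runs = TRUE) {
  cls <- classify_segments(ensure_sample_col(segments), params)
  fga <- fraction_genome_altered(cls, genome)
  aneu <- aneuploidy_events(cls, genome, params)
  hrr <- hrr_cin_score(cls, catalog)
  chrom <- chromosome_cin(cls, genome, merge_runs = merge_runs)
  per_sample <- Reduce(function(a, b) merge(a, b, by = "sample"),
                       list(fga$fga, aneu$counts, hrr))
  list(per_sample = per_sample,
       per_chromosome = chrom,
       per_cytoband = cytoband_cin(cls, genome),
       classified = cls)
}
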