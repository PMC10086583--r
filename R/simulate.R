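#' @name simulate_profile
#' @title Simulate an ASCN profile with an exact scar-truth ledger
#'
#' @description
#' Builds a diploid heterozygous (1,1) genome and implants scar events
#' so that the implanted counts are exact by construction:
#' \itemize{
#'   \item LOH blocks, (1,0), 16-40 Mb, placed in an arm interior with
#'     sub-10-Mb flanks (or directly closing an LST chain), so they
#'     neither reach a telomere nor create unplanned large-scale
#'     transitions;
#'   \item LST breakpoints as telomere-anchored chains of balanced
#'     blocks (alternating (2,2)/(3,3), each 10.5-12 Mb) followed by a
#'     >= 10.5 Mb background segment or an LOH block - each adjacency is
#'     exactly one transition;
#'   \item TAI blocks as telomere-anchored (2,1) segments of 5-9 Mb
#'     (below the LST segment minimum, so they add no transition);
#'   \item aneuploidy as whole-chromosome (2,1) gains on dedicated
#'     chromosomes (a whole-chromosome imbalance is excluded from TAI
#'     by definition).
#' }
#' Events are packed greedily onto chromosome arms; an infeasible
#' request errors rather than silently under-implanting.
#'
#' @param genome a [genome_build()].
#' @param loh_events,lst_events,tai_events,aneuploid_chromosomes
#'   requested event counts.
#' @param seed integer seed (bit-reproducible output).
#' @param sample sample identifier.
#' @return list with `segments` (validated ASCN data.frame) and `truth`
#'   (requested counts, the per-arm plan, and the seed).
NULL

# arm inventory: virtual coordinates run telomere -> centromere
arm_table <- function(genome) {
  chroms <- genome$chromosomes$chrom
  mids <- vapply(chroms, function(cc) centromere_mid(genome, cc), numeric(1))
  lens <- genome$chromosomes$length
  rbind(data.frame(chrom = chroms, arm = "p", start = 1, end = mids,
                   alen = mids, stringsAsFactors = FALSE),
        data.frame(chrom = chroms, arm = "q", start = mids + 1, end = lens,
                   alen = lens - mids, stringsAsFactors = FALSE))
}

MB <- 1e6

# capacity (in breaks) of an arm for a telomere-anchored LST chain
chain_capacity <- function(alen) {
  max(0L, min(3L, floor((alen - 10.5 * MB) / (12 * MB))))
}

runi <- function(n, lo, hi) round(stats::runif(n, lo, hi))

# materialise one arm plan in virtual coordinates (telomere at 1);
# returns data.frame(start, end, n_major, n_minor) of non-background
# blocks. A 4-6 Mb balanced (2,2) "guard" block caps the
# centromere-facing side of an LOH block so that neither the LOH block
# nor the remaining background can form an unplanned large-scale
# transition, whatever the arm length.
build_arm_blocks <- function(alen, tel = c("none", "tai", "chain"),
                             n_breaks = 0L, loh = FALSE) {
  tel <- match.arg(tel)
  blocks <- NULL
  pos <- 1
  guard_cn <- c(2, 2)
  if (tel == "tai") {
    L <- runi(1, 5 * MB, 9 * MB)
    blocks <- rbind(blocks, data.frame(start = 1, end = L, n_major = 2, n_minor = 1))
    pos <- L + 1 + runi(1, 4 * MB, 6 * MB)   # sub-10 Mb background gap
  } else if (tel == "chain") {
    state <- 0L
    for (k in seq_len(n_breaks)) {
      L <- runi(1, 10.5 * MB, 12 * MB)
      cn <- if (state %% 2L == 0L) c(2, 2) else c(3, 3)
      blocks <- rbind(blocks, data.frame(start = pos, end = pos + L - 1,
                                         n_major = cn[1], n_minor = cn[2]))
      pos <- pos + L
      state <- state + 1L
    }
    guard_cn <- if (n_breaks %% 2L == 0L) c(2, 2) else c(3, 3)
  }
  if (loh) {
    # the block before the LOH is either the last chain block (>= 10 Mb,
    # providing the chain's closing break) or a sub-10 Mb background gap
    if (tel == "none") pos <- 1 + runi(1, 4 * MB, 9 * MB)
    avail <- alen - (pos - 1) - 5 * MB   # always leave room for the guard
    if (avail < 16 * MB) stop("simulate_profile: infeasible packing (LOH does not fit)")
    L <- runi(1, 16 * MB, min(40 * MB, avail))
    blocks <- rbind(blocks, data.frame(start = pos, end = pos + L - 1,
                                       n_major = 1, n_minor = 0))
    pos <- pos + L
    G <- min(runi(1, 4 * MB, 6 * MB), alen - pos + 1)
    blocks <- rbind(blocks, data.frame(start = pos, end = pos + G - 1,
                                       n_major = guard_cn[1], n_minor = guard_cn[2]))
    pos <- pos + G
  } else if (tel == "chain" && n_breaks > 0L) {
    if (alen - pos + 1 < 10.5 * MB)
      stop("simulate_profile: infeasible packing (no room for closing segment)")
  }
  if (!is.null(blocks) && blocks$end[nrow(blocks)] > alen)
    stop("simulate_profile: infeasible packing (arm overflow)")
  blocks
}

#' @rdname simulate_profile
#' @export
simulate_profile <- function(genome, loh_events = 0L, lst_events = 0L,
                             tai_events = 0L, aneuploid_chromosomes = 0L,
                             seed = 1L, sample = "S1") {
  stopifnot(loh_events >= 0, lst_events >= 0, tai_events >= 0,
            aneuploid_chromosomes >= 0)
  set.seed(seed)
  chroms <- genome$chromosomes$chrom
  if (aneuploid_chromosomes > length(chroms))
    stop("simulate_profile: infeasible packing (more aneuploid chromosomes than chromosomes)")
  aneu_chroms <- if (aneuploid_chromosomes > 0)
    sample(chroms, aneuploid_chromosomes) else character(0)

  arms <- arm_table(genome)
  arms <- arms[!(arms$chrom %in% aneu_chroms), , drop = FALSE]
  arms <- arms[sample.int(nrow(arms)), , drop = FALSE]
  arms$tel <- "none"; arms$breaks <- 0L; arms$loh <- FALSE

  # TAI: one telomere-anchored block per arm
  need <- tai_events
  for (i in seq_len(nrow(arms))) {
    if (need == 0L) break
    if (arms$alen[i] >= 15 * MB) { arms$tel[i] <- "tai"; need <- need - 1L }
  }
  if (need > 0L) stop("simulate_profile: infeasible packing (TAI events)")

  # LST: telomere chains on arms without a TAI block
  need <- lst_events
  for (i in seq_len(nrow(arms))) {
    if (need == 0L) break
    if (arms$tel[i] != "none") next
    cap <- chain_capacity(arms$alen[i])
    if (cap > 0L) {
      arms$tel[i] <- "chain"
      arms$breaks[i] <- min(cap, need)
      need <- need - arms$breaks[i]
    }
  }
  if (need > 0L) stop("simulate_profile: infeasible packing (LST events)")

  # LOH: interior blocks; may close an LST chain, follow a TAI block,
  # or sit alone with small flanks
  need <- loh_events
  for (i in seq_len(nrow(arms))) {
    if (need == 0L) break
    used <- switch(arms$tel[i],
                   none = 9 * MB,
                   tai = 9 * MB + 6 * MB,
                   chain = arms$breaks[i] * 12 * MB)
    if (arms$alen[i] - used >= 22 * MB) {
      arms$loh[i] <- TRUE
      need <- need - 1L
    }
  }
  if (need > 0L) stop("simulate_profile: infeasible packing (LOH events)")

  blocks <- list()
  for (cc in aneu_chroms)
    blocks[[length(blocks) + 1L]] <-
      data.frame(chrom = cc, start = 1, end = chrom_length(genome, cc),
                 n_major = 2, n_minor = 1)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    if (a$tel == "none" && !a$loh) next
    b <- build_arm_blocks(a$alen, a$tel, a$breaks, a$loh)
    if (is.null(b)) next
    if (a$arm == "p") {
      b$start <- a$start - 1 + b$start
      b$end <- a$start - 1 + b$end
    } else {
      tmp <- b
      b$start <- a$end + 1 - tmp$end
      b$end <- a$end + 1 - tmp$start
    }
    b <- data.frame(chrom = a$chrom, b)
    blocks[[length(blocks) + 1L]] <- b
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_major = numeric(0), n_minor = numeric(0))
  segments <- fill_background(blocks, genome, sample)
  truth <- list(sample = sample, loh_events = loh_events,
                lst_events = lst_events, tai_events = tai_events,
                aneuploid_chromosomes = aneuploid_chromosomes,
                aneuploid_chroms = aneu_chroms, seed = seed)
  list(segments = segments, truth = truth)
}

# complete a block set to a full diploid-background genome profile
fill_background <- function(blocks, genome, sample) {
  out <- list()
  for (k in seq_len(nrow(genome$chromosomes))) {
    cc <- genome$chromosomes$chrom[k]
    clen <- genome$chromosomes$length[k]
    b <- blocks[blocks$chrom == cc, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    pos <- 1
    rows <- list()
    for (i in seq_len(nrow(b))) {
      if (b$start[i] > pos)
        rows[[length(rows) + 1L]] <- data.frame(chrom = cc, start = pos,
                                                end = b$start[i] - 1,
                                                n_major = 1, n_minor = 1)
      rows[[length(rows) + 1L]] <- b[i, c("chrom", "start", "end", "n_major", "n_minor")]
      pos <- b$end[i] + 1
    }
    if (pos <= clen)
      rows[[length(rows) + 1L]] <- data.frame(chrom = cc, start = pos, end = clen,
                                              n_major = 1, n_minor = 1)
    out[[k]] <- do.call(rbind, rows)
  }
  seg <- do.call(rbind, out)
  seg <- data.frame(sample = sample, seg, stringsAsFactors = FALSE)
  validate_ascn_segments(seg)
}

#' Simulate a bimodal HRD cohort
#'
#' Generates `n_high` HRD-high and `n_low` HRD-low samples on the given
#' genome (default the packaged hg38 build with its 70-gene HRR
#' catalog). Each sample receives implanted scar events correlated with
#' its group, plus gene-level gain/loss segments placed on catalog loci
#' so that the HRR-CIN score equals a per-sample target drawn from
#' round-N(50, 8^2) (high, truncated to the attainable range) or
#' round-N(8, 3^2) (low, truncated at 0). A genes-by-samples expression
#' matrix is emitted with a +1 log2 shift of the 10 SARC-HRD signature
#' genes in the high group over a log-normal baseline with log2-scale
#' standard deviation 0.5.
#'
#' @param n_high,n_low group sizes (`n_high + n_low >= 20`).
#' @param genome a [genome_build()] with an HRR catalog.
#' @param seed integer seed.
#' @return list with `segments`, `truth` (per-sample data.frame with
#'   exact implanted counts and `hrr_cin`), `expression`,
#'   `gene_events`, and `catalog`.
#' @export
simulate_cohort <- function(n_high, n_low, genome = load_genome_build("hg38"),
                            seed = 1L) {
  if (n_high + n_low < 20) stop("cohort too small: need n_high + n_low >= 20")
  if (nrow(genome$chromosomes) < 12)
    stop("cohort simulation needs a genome with at least 12 chromosomes ",
         "to pack HRD-high event loads (use the packaged hg38 build)")
  catalog <- hrr_gene_catalog(genome)
  set.seed(seed)
  groups <- c(rep("hrd_high", n_high), rep("hrd_low", n_low))
  ids <- sprintf("SIM%03d", seq_along(groups))
  sample_seeds <- sample.int(.Machine$integer.max, length(groups))

  seg_list <- list(); truth_list <- list(); gene_ev_list <- list()
  for (s in seq_along(groups)) {
    set.seed(sample_seeds[s])
    if (groups[s] == "hrd_high") {
      ev <- c(loh = min(14L, max(0L, round(stats::rnorm(1, 10, 2)))),
              lst = min(20L, max(0L, round(stats::rnorm(1, 14, 3)))),
              tai = min(10L, max(0L, round(stats::rnorm(1, 8, 2)))),
              aneu = min(6L, max(0L, round(stats::rnorm(1, 4, 1)))))
      target <- round(stats::rnorm(1, 50, 8))
    } else {
      ev <- c(loh = stats::rpois(1, 0.7), lst = stats::rpois(1, 1),
              tai = stats::rpois(1, 0.7), aneu = stats::rpois(1, 0.3))
      target <- round(stats::rnorm(1, 8, 3))
    }
    target <- max(0L, min(target, 2L * nrow(catalog)))
    prof <- simulate_profile(genome, ev[["loh"]], ev[["lst"]], ev[["tai"]],
                             ev[["aneu"]], seed = sample_seeds[s], sample = ids[s])
    res <- implant_gene_events(prof$segments, catalog, target)
    seg_list[[s]] <- res$segments
    gene_ev_list[[s]] <- if (nrow(res$events))
      data.frame(sample = ids[s], res$events) else NULL
    truth_list[[s]] <- data.frame(
      sample = ids[s], group = groups[s],
      loh = ev[["loh"]], lst = ev[["lst"]], tai = ev[["tai"]],
      hrd = sum(ev[c("loh", "lst", "tai")]),
      aneuploid = ev[["aneu"]], hrr_cin = res$hrr_cin,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  set.seed(seed + 1L)
  sig <- sarc_hrd_signature()
  genes <- c(sig$genes, sprintf("BG%03d", seq_len(190)))
  mu <- stats::runif(length(genes), 3, 8)
  logm <- matrix(stats::rnorm(length(genes) * length(ids), 0, 0.5),
                 nrow = length(genes)) + mu
  shift <- outer(genes %in% sig$genes, groups == "hrd_high", "&")
  expr <- 2^(logm + shift)
  dimnames(expr) <- list(genes, ids)

  list(segments = do.call(rbind, seg_list), truth = truth,
       expression = expr,
       gene_events = do.call(rbind, gene_ev_list),
       catalog = catalog, seed = seed)
}

# count (gene, class) events already produced by the implanted scar
# blocks, then add gene-sized gain/loss segments on clear catalog loci
# until the HRR-CIN score reaches `target` (exact; errors if impossible)
implant_gene_events <- function(segments, catalog, target) {
  non_bg <- segments[!(segments$n_major == 1 & segments$n_minor == 1), , drop = FALSE]
  base_hits <- matrix(FALSE, nrow(catalog), 2,
                      dimnames = list(catalog$symbol, c("gain", "loss")))
  blocked <- rep(FALSE, nrow(catalog))
  margin <- 1 * MB
  for (g in seq_len(nrow(catalog))) {
    on_c <- non_bg[non_bg$chrom == catalog$chrom[g], , drop = FALSE]
    if (!nrow(on_c)) next
    ov <- on_c$start <= catalog$end[g] & on_c$end >= catalog$start[g]
    base_hits[g, "gain"] <- any(ov & (on_c$n_major + on_c$n_minor) > 2)
    base_hits[g, "loss"] <- any(ov & (on_c$n_major + on_c$n_minor) < 2)
    near <- on_c$start <= catalog$end[g] + margin & on_c$end >= catalog$start[g] - margin
    blocked[g] <- any(near)
  }
  base <- sum(base_hits)
  target <- max(target, base)
  need <- target - base
  events <- data.frame(gene = character(0), class = character(0),
                       stringsAsFactors = FALSE)
  if (need > 0) {
    elig <- which(!blocked)
    cand <- rbind(data.frame(g = elig, class = "gain", stringsAsFactors = FALSE),
                  data.frame(g = elig, class = "loss", stringsAsFactors = FALSE))
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    if (nrow(cand) < need)
      stop("cannot reach HRR-CIN target: too few clear catalog loci")
    cand <- cand[seq_len(need), , drop = FALSE]
    new_rows <- list()
    for (k in seq_len(nrow(cand))) {
      g <- cand$g[k]
      both <- sum(cand$g == g) == 2L
      locus <- c(catalog$start[g], catalog$end[g])
      if (both) {
        mid <- floor(mean(locus))
        span <- if (cand$class[k] == "gain") c(locus[1], mid) else c(mid + 1, locus[2])
      } else span <- locus
      cn <- if (cand$class[k] == "gain") c(2, 1) else c(1, 0)
      new_rows[[k]] <- data.frame(sample = segments$sample[1],
                                  chrom = catalog$chrom[g],
                                  start = span[1], end = span[2],
                                  n_major = cn[1], n_minor = cn[2])
      events <- rbind(events, data.frame(gene = catalog$symbol[g],
                                         class = cand$class[k]))
    }
    segments <- insert_blocks(segments, do.call(rbind, new_rows))
  }
  list(segments = segments, hrr_cin = target, events = events)
}

# carve new blocks out of the (1,1) background segments they fall in
insert_blocks <- function(segments, new_blocks) {
  for (k in seq_len(nrow(new_blocks))) {
    nb <- new_blocks[k, ]
    host <- which(segments$chrom == nb$chrom & segments$start <= nb$start &
                    segments$end >= nb$end &
                    segments$n_major == 1 & segments$n_minor == 1)
    if (!length(host))
      stop("internal: gene event does not fall in clear background")
    h <- host[1]
    left <- right <- segments[h, ]
    left$end <- nb$start - 1
    right$start <- nb$end + 1
    keep <- rbind(if (left$start <= left$end) left,
                  nb[names(segments)],
                  if (right$start <= right$end) right)
    segments <- rbind(segments[-h, ], keep)
  }
  validate_ascn_segments(segments)
}

#' Simulate a two-drug dose matrix under a reference null model
#'
#' The expected-inhibition surface is computed analytically from the
#' true monotherapy 4PL curves under the chosen reference model;
#' observed inhibition is expectation plus Gaussian noise, clipped to
#' [0, 1]. The monotherapy row and column receive the same noise. The
#' truth ledger records the model and curve parameters.
#'
#' @param model reference model the matrix is null under.
#' @param pars1,pars2 4PL viability parameters
#'   `list(bottom, top, ic50, hill)` per drug (hill > 0: decreasing
#'   viability).
#' @param d1,d2 dose vectors (0 prepended automatically if absent).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return list with `matrix` (a [dose_matrix()]) and `truth`.
#' @export
simulate_dose_matrix <- function(model = c("bliss", "hsa", "loewe", "zip"),
                                 pars1 = list(bottom = 0, top = 1, ic50 = 1e-6, hill = 1),
                                 pars2 = list(bottom = 0, top = 1, ic50 = 1e-6, hill = 1),
                                 d1 = NULL, d2 = NULL,
                                 noise_sd = 0.02, seed = 1L) {
  model <- match.arg(model)
  set.seed(seed)
  if (is.null(d1)) d1 <- pars1$ic50 * 10^seq(-2, 2, length.out = 6)
  if (is.null(d2)) d2 <- pars2$ic50 * 10^seq(-2, 2, length.out = 6)
  if (d1[1] != 0) d1 <- c(0, d1)
  if (d2[1] != 0) d2 <- c(0, d2)
  inh <- function(p, x) 1 - predict_4pl_pars(x, p$bottom, p$top, p$ic50, p$hill)
  i1 <- inh(pars1, d1); i2 <- inh(pars2, d2)
  E <- switch(model,
    bliss = ,
    zip = outer(i1, i2, function(a, b) a + b - a * b),
    hsa = outer(i1, i2, pmax),
    loewe = {
      m <- outer(i1, i2, function(a, b) pmax(a, b))
      f1 <- structure(list(bottom = 1 - pars1$top, top = 1 - pars1$bottom,
                           ic50 = pars1$ic50, hill = -pars1$hill, converged = TRUE),
                      class = "DoseResponseCurve")
      f2 <- structure(list(bottom = 1 - pars2$top, top = 1 - pars2$bottom,
                           ic50 = pars2$ic50, hill = -pars2$hill, converged = TRUE),
                      class = "DoseResponseCurve")
      for (i in seq_along(d1)) for (j in seq_along(d2)) {
        if (d1[i] > 0 && d2[j] > 0) {
          e <- loewe_cell(d1[i], d2[j], f1, f2)
          if (is.finite(e)) m[i, j] <- e
        }
      }
      m[, 1] <- i1; m[1, ] <- i2; m[1, 1] <- 0
      m
    })
  E[, 1] <- i1; E[1, ] <- i2
  obs <- pmin(pmax(E + stats::rnorm(length(E), 0, noise_sd), 0), 1)
  obs <- matrix(obs, nrow = length(d1))
  mat <- dose_matrix(d1, d2, 1 - obs)
  list(matrix = mat,
       truth = list(model = model, pars1 = pars1, pars2 = pars2,
                    noise_sd = noise_sd, seed = seed))
}
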