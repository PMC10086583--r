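#' Parameters for genomic scar scoring
#'
#' Defaults follow the established scar definitions: LOH regions must
#' exceed 15 Mb (without covering a whole chromosome), large-scale
#' transitions require adjacent segments of at least 10 Mb after
#' smoothing away segments shorter than 3 Mb, and telomeric allelic
#' imbalance has no minimum length.
#'
#' @param loh_min_len minimum merged LOH run length in bp (strict `>`).
#' @param lst_min_segment minimum flanking-segment length for an LST, bp.
#' @param lst_smooth_len smoothing threshold and maximum inter-breakage
#'   distance, bp.
#' @param tai_min_len minimum TAI run length in bp (strict `>`).
#' @return list of class `ScarParams`.
#' @export
scar_params <- function(loh_min_len = 15e6, lst_min_segment = 10e6,
                        lst_smooth_len = 3e6, tai_min_len = 0) {
  stopifnot(loh_min_len >= 0, lst_min_segment >= 0,
            lst_smooth_len >= 0, tai_min_len >= 0,
            lst_smooth_len < lst_min_segment)
  structure(list(loh_min_len = loh_min_len, lst_min_segment = lst_min_segment,
                 lst_smooth_len = lst_smooth_len, tai_min_len = tai_min_len),
            class = "ScarParams")
}

one_sample <- function(segments) {
  if ("sample" %in% names(segments) && length(unique(segments$sample)) > 1L)
    stop("expected segments of a single sample; use score_cohort() for many")
  segments[order(segments$chrom, segments$start), , drop = FALSE]
}

# maximal runs of consecutive abutting member segments (vectorised);
# returns chrom / start / end of the merged runs
member_runs <- function(ch, s, e, member) {
  n <- length(s)
  if (!any(member)) return(list(chrom = character(0), start = numeric(0),
                                end = numeric(0)))
  cont <- if (n > 1L) member[-1] & member[-n] & ch[-1] == ch[-n] &
    s[-1] == e[-n] + 1 else logical(0)
  grp <- cumsum(c(TRUE, !cont))
  g <- grp[member]
  first <- !duplicated(g)
  list(chrom = ch[member][first],
       start = as.numeric(tapply(s[member], g, min)),
       end = as.numeric(tapply(e[member], g, max)))
}

#' Count loss-of-heterozygosity (LOH) scar events
#'
#' An LOH event is a maximal run of contiguous (abutting) segments with
#' `n_minor == 0` and `n_major >= 1` whose merged length exceeds
#' `loh_min_len` and which does not cover the whole chromosome.
#' Homozygous deletions (0,0) carry no allele signal and do not join
#' LOH runs.
#'
#' @param segments ASCN profile of one sample (columns `chrom`, `start`,
#'   `end`, `n_major`, `n_minor`).
#' @param genome a [genome_build()].
#' @param params a [scar_params()].
#' @return integer count.
#' @export
count_loh <- function(segments, genome, params = scar_params()) {
  seg <- one_sample(segments)
  if (!nrow(seg)) return(0L)
  runs <- member_runs(seg$chrom, seg$start, seg$end,
                      seg$n_minor == 0 & seg$n_major >= 1)
  if (!length(runs$start)) return(0L)
  clen <- chrom_length(genome, runs$chrom)
  sum((runs$end - runs$start + 1) > params$loh_min_len &
        !(runs$start == 1 & runs$end == clen))
}

# smoothing of one sorted unit (chromosome arm), on parallel vectors:
# iteratively drop the shortest segment below min_len, splitting its
# span at the midpoint between both neighbors (absorbed wholly by the
# single neighbor at a unit end), then merge abutting segments with
# identical allele copy numbers
smooth_unit <- function(s, e, mj, mn, min_len) {
  merge_same <- function(s, e, mj, mn) {
    n <- length(s)
    if (n < 2L) return(list(s = s, e = e, mj = mj, mn = mn))
    cont <- mj[-1] == mj[-n] & mn[-1] == mn[-n] & s[-1] == e[-n] + 1
    grp <- cumsum(c(TRUE, !cont))
    first <- !duplicated(grp)
    list(s = s[first], e = as.numeric(tapply(e, grp, max)),
         mj = mj[first], mn = mn[first])
  }
  u <- merge_same(s, e, mj, mn)
  repeat {
    n <- length(u$s)
    if (n <= 1L) break
    lens <- u$e - u$s + 1
    short <- which(lens < min_len)
    if (!length(short)) break
    i <- short[which.min(lens[short])]
    if (i > 1L && i < n) {
      mid <- floor((u$s[i] + u$e[i]) / 2)
      u$e[i - 1L] <- mid
      u$s[i + 1L] <- mid + 1
    } else if (i == 1L) {
      u$s[2L] <- u$s[1L]
    } else {
      u$e[i - 1L] <- u$e[i]
    }
    u <- merge_same(u$s[-i], u$e[-i], u$mj[-i], u$mn[-i])
  }
  u
}

#' Smooth an ASCN profile
#'
#' Iteratively removes segments shorter than `min_len`: the removed
#' span is split at its midpoint between the two flanking segments (or
#' absorbed by the single neighbor at a chromosome end) and abutting
#' segments that then share identical `(n_major, n_minor)` are merged.
#' Total covered span is conserved. This is the pre-processing step of
#' the LST count, exposed for inspection.
#'
#' @param segments ASCN profile (one sample).
#' @param min_len smoothing threshold in bp.
#' @return smoothed profile.
#' @export
smooth_segments <- function(segments, min_len) {
  seg <- one_sample(segments)
  out <- lapply(unique(seg$chrom), function(cc) {
    i <- seg$chrom == cc
    u <- smooth_unit(seg$start[i], seg$end[i], seg$n_major[i], seg$n_minor[i],
                     min_len)
    data.frame(chrom = cc, start = u$s, end = u$e,
               n_major = u$mj, n_minor = u$mn, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if ("sample" %in% names(seg) && nrow(seg))
    res <- data.frame(sample = seg$sample[1], res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Count large-scale transitions (LST)
#'
#' Segments are split at the centromere midpoint and processed per
#' chromosome arm. After smoothing (see [smooth_segments()]) with
#' `lst_smooth_len`, an LST is a pair of adjacent segments within an arm
#' with different `(n_major, n_minor)`, both at least `lst_min_segment`
#' long, separated by a gap of at most `lst_smooth_len`.
#'
#' @inheritParams count_loh
#' @return integer count.
#' @export
count_lst <- function(segments, genome, params = scar_params()) {
  seg <- one_sample(segments)
  total <- 0L
  for (cc in unique(seg$chrom)) {
    i <- seg$chrom == cc
    s <- seg$start[i]; e <- seg$end[i]
    mj <- seg$n_major[i]; mn <- seg$n_minor[i]
    mid <- centromere_mid(genome, cc)
    cross <- which(s <= mid & e > mid)
    if (length(cross)) {
      s <- c(s, rep(mid + 1, length(cross))); e <- c(e, e[cross]); e[cross] <- mid
      mj <- c(mj, mj[cross]); mn <- c(mn, mn[cross])
      o <- order(s)
      s <- s[o]; e <- e[o]; mj <- mj[o]; mn <- mn[o]
    }
    for (arm in c("p", "q")) {
      a <- if (arm == "p") e <= mid else s > mid
      if (!any(a)) next
      u <- smooth_unit(s[a], e[a], mj[a], mn[a], params$lst_smooth_len)
      n <- length(u$s)
      if (n < 2L) next
      lens <- u$e - u$s + 1
      gaps <- u$s[-1] - u$e[-n] - 1
      differs <- u$mj[-1] != u$mj[-n] | u$mn[-1] != u$mn[-n]
      total <- total + sum(differs & lens[-n] >= params$lst_min_segment &
                             lens[-1] >= params$lst_min_segment &
                             gaps <= params$lst_smooth_len)
    }
  }
  total
}

#' Count telomeric allelic imbalances (TAI)
#'
#' A TAI is a maximal run of contiguous allelic-imbalance segments
#' (`n_major != n_minor`, any copy numbers, merged when abutting) that
#' reaches a telomere (run starts at base 1 or ends at the chromosome
#' length), does not cross the centromere (does not span the entire
#' centromere interval), does not cover the whole chromosome, and is
#' longer than `tai_min_len`.
#'
#' @inheritParams count_loh
#' @return integer count.
#' @export
count_tai <- function(segments, genome, params = scar_params()) {
  seg <- one_sample(segments)
  if (!nrow(seg)) return(0L)
  runs <- member_runs(seg$chrom, seg$start, seg$end,
                      seg$n_major != seg$n_minor)
  if (!length(runs$start)) return(0L)
  clen <- chrom_length(genome, runs$chrom)
  ci <- match(runs$chrom, genome$centromeres$chrom)
  cs <- genome$centromeres$start[ci]; ce <- genome$centromeres$end[ci]
  touches <- runs$start == 1 | runs$end == clen
  whole <- runs$start == 1 & runs$end == clen
  crosses <- runs$start < cs & runs$end > ce
  sum(touches & !whole & !crosses &
        (runs$end - runs$start + 1) > params$tai_min_len)
}

#' Scar scores of one sample
#'
#' The HRD score is the unweighted, linear sum of the three genomic
#' instability signatures: `hrd = loh + lst + tai`.
#'
#' @inheritParams count_loh
#' @return one-row data.frame `sample, loh, lst, tai, hrd`.
#' @export
score_sample <- function(segments, genome, params = scar_params()) {
  segments <- one_sample(segments)
  id <- if ("sample" %in% names(segments) && nrow(segments))
    segments$sample[1] else NA_character_
  loh <- count_loh(segments, genome, params)
  lst <- count_lst(segments, genome, params)
  tai <- count_tai(segments, genome, params)
  data.frame(sample = id, loh = loh, lst = lst, tai = tai,
             hrd = loh + lst + tai, stringsAsFactors = FALSE)
}

#' @rdname score_sample
#' @param segments for `score_cohort`, a multi-sample segment table with
#'   a `sample` column.
#' @export
score_cohort <- function(segments, genome, params = scar_params()) {
  segments <- validate_ascn_segments(segments)
  out <- do.call(rbind, lapply(split(segments, segments$sample),
                               score_sample, genome = genome, params = params))
  rownames(out) <- NULL
  out[order(out$sample), , drop = FALSE]
}
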