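# Independent brute-force re-implementations of the scar rules, written
# as naive loops over individual segments. These deliberately share no
# code with the package internals and serve as oracles in the
# equivalence tests.

oracle_loh <- function(segments, genome, params = scar_params()) {
  count <- 0L
  for (cc in unique(segments$chrom)) {
    seg <- segments[segments$chrom == cc, ]
    seg <- seg[order(seg$start), ]
    is_loh <- seg$n_minor == 0 & seg$n_major >= 1
    # naive merge: grow a run segment by segment
    i <- 1
    while (i <= nrow(seg)) {
      if (!is_loh[i]) { i <- i + 1; next }
      run_start <- seg$start[i]; run_end <- seg$end[i]
      while (i < nrow(seg) && is_loh[i + 1] && seg$start[i + 1] == run_end + 1) {
        i <- i + 1
        run_end <- seg$end[i]
      }
      len <- run_end - run_start + 1
      clen <- genome$chromosomes$length[genome$chromosomes$chrom == cc]
      if (len > params$loh_min_len && !(run_start == 1 && run_end == clen))
        count <- count + 1L
      i <- i + 1
    }
  }
  count
}

oracle_tai <- function(segments, genome, params = scar_params()) {
  count <- 0L
  for (cc in unique(segments$chrom)) {
    seg <- segments[segments$chrom == cc, ]
    seg <- seg[order(seg$start), ]
    ai <- seg$n_major != seg$n_minor
    clen <- genome$chromosomes$length[genome$chromosomes$chrom == cc]
    cen <- genome$centromeres[genome$centromeres$chrom == cc, ]
    i <- 1
    while (i <= nrow(seg)) {
      if (!ai[i]) { i <- i + 1; next }
      run_start <- seg$start[i]; run_end <- seg$end[i]
      while (i < nrow(seg) && ai[i + 1] && seg$start[i + 1] == run_end + 1) {
        i <- i + 1
        run_end <- seg$end[i]
      }
      touches <- run_start == 1 || run_end == clen
      whole <- run_start == 1 && run_end == clen
      crosses <- run_start < cen$start && run_end > cen$end
      if (touches && !whole && !crosses &&
          run_end - run_start + 1 > params$tai_min_len)
        count <- count + 1L
      i <- i + 1
    }
  }
  count
}

# naive smoothing on a per-arm data.frame: repeatedly scan the whole
# table for the shortest sub-threshold segment
oracle_smooth <- function(arm, min_len) {
  glue <- function(a) {
    repeat {
      if (nrow(a) < 2) return(a)
      merged <- FALSE
      for (k in 2:nrow(a)) {
        if (a$start[k] == a$end[k - 1] + 1 && a$n_major[k] == a$n_major[k - 1] &&
            a$n_minor[k] == a$n_minor[k - 1]) {
          a$end[k - 1] <- a$end[k]
          a <- a[-k, ]
          merged <- TRUE
          break
        }
      }
      if (!merged) return(a)
    }
  }
  arm <- glue(arm[order(arm$start), ])
  repeat {
    if (nrow(arm) <= 1) return(arm)
    lens <- arm$end - arm$start + 1
    if (all(lens >= min_len)) return(arm)
    i <- which(lens == min(lens[lens < min_len]) & lens < min_len)[1]
    if (i == 1) {
      arm$start[2] <- arm$start[1]
    } else if (i == nrow(arm)) {
      arm$end[i - 1] <- arm$end[i]
    } else {
      mid <- floor((arm$start[i] + arm$end[i]) / 2)
      arm$end[i - 1] <- mid
      arm$start[i + 1] <- mid + 1
    }
    arm <- glue(arm[-i, ])
  }
}

oracle_lst <- function(segments, genome, params = scar_params()) {
  count <- 0L
  for (cc in unique(segments$chrom)) {
    seg <- segments[segments$chrom == cc, c("start", "end", "n_major", "n_minor")]
    seg <- seg[order(seg$start), ]
    cen <- genome$centromeres[genome$centromeres$chrom == cc, ]
    mid <- floor((cen$start + cen$end) / 2)
    pieces <- NULL
    for (k in seq_len(nrow(seg))) {
      row <- seg[k, ]
      if (row$start <= mid && row$end > mid) {
        left <- row; left$end <- mid
        right <- row; right$start <- mid + 1
        pieces <- rbind(pieces, left, right)
      } else pieces <- rbind(pieces, row)
    }
    for (arm_name in c("p", "q")) {
      arm <- pieces[if (arm_name == "p") pieces$end <= mid else pieces$start > mid, ]
      if (is.null(arm) || nrow(arm) == 0) next
      arm <- oracle_smooth(arm, params$lst_smooth_len)
      if (nrow(arm) < 2) next
      for (k in 1:(nrow(arm) - 1)) {
        l1 <- arm$end[k] - arm$start[k] + 1
        l2 <- arm$end[k + 1] - arm$start[k + 1] + 1
        gap <- arm$start[k + 1] - arm$end[k] - 1
        if ((arm$n_major[k] != arm$n_major[k + 1] ||
             arm$n_minor[k] != arm$n_minor[k + 1]) &&
            l1 >= params$lst_min_segment && l2 >= params$lst_min_segment &&
            gap <= params$lst_smooth_len)
          count <- count + 1L
      }
    }
  }
  count
}

# per-base-free brute-force overlap check used by the CIN oracles
oracle_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start <= b_end & a_end >= b_start
}

oracle_hrr_cin <- function(classified, catalog) {
  score <- 0L
  for (g in seq_len(nrow(catalog))) {
    for (call in c("gain", "loss")) {
      sub <- classified[classified$call == call &
                          classified$chrom == catalog$chrom[g], ]
      hit <- FALSE
      for (k in seq_len(nrow(sub)))
        if (sub$start[k] <= catalog$end[g] && sub$end[k] >= catalog$start[g])
          hit <- TRUE
      if (hit) score <- score + 1L
    }
  }
  score
}

# random Mb-aligned single-sample profiles exercising gaps, ties and
# boundary cases on the toy genome
random_profile <- function(genome, max_segs = 8L) {
  rows <- list()
  for (cc in genome$chromosomes$chrom) {
    clen <- genome$chromosomes$length[genome$chromosomes$chrom == cc]
    n <- sample.int(max_segs, 1)
    cuts <- sort(sample(seq(1e6, clen - 1e6, by = 1e6), n - 1))
    bounds <- c(0, cuts, clen)
    for (k in seq_len(length(bounds) - 1)) {
      if (stats::runif(1) < 0.1) next  # leave an uncovered gap
      mj <- sample(0:3, 1)
      mn <- sample(0:mj, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = "R", chrom = cc, start = bounds[k] + 1, end = bounds[k + 1],
        n_major = mj, n_minor = mn)
    }
  }
  if (!length(rows)) return(data.frame(sample = character(0), chrom = character(0),
                                       start = numeric(0), end = numeric(0),
                                       n_major = numeric(0), n_minor = numeric(0)))
  do.call(rbind, rows)
}
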