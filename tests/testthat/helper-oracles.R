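# Independent brute-force oracles. The scar oracles materialize per-megabase
# state vectors (valid because the fixture profiles sit on the 1 Mb lattice);
# the segmentation oracle recomputes the penalized optimum with plain
# subvector arithmetic; the concordance oracles enumerate pairs/thresholds.

.mb_states <- function(profile_chrom, len_mb) {
  # value of (cn_major, cn_minor) for each 1 Mb bin, encoded as strings
  maj <- integer(len_mb); mn <- integer(len_mb)
  for (i in seq_len(nrow(profile_chrom))) {
    lo <- profile_chrom$start[i] / 1e6 + 1
    hi <- profile_chrom$end[i] / 1e6
    maj[lo:hi] <- profile_chrom$cn_major[i]
    mn[lo:hi] <- profile_chrom$cn_minor[i]
  }
  list(maj = maj, mn = mn)
}

oracle_loh <- function(profile, build, min_mb = 15) {
  total <- 0
  for (ci in seq_len(nrow(build))) {
    p <- profile[profile$chrom == build$chrom[ci], , drop = FALSE]
    p <- p[order(p$start), ]
    len_mb <- build$length[ci] / 1e6
    st <- .mb_states(p, len_mb)
    flag <- st$mn == 0 & st$maj >= 1
    r <- rle(flag)
    runs <- r$lengths[r$values]
    total <- total + sum(runs > min_mb & runs < len_mb)
  }
  total
}

oracle_tai <- function(profile, build) {
  total <- 0
  for (ci in seq_len(nrow(build))) {
    b <- build[ci, ]
    p <- profile[profile$chrom == b$chrom, , drop = FALSE]
    p <- p[order(p$start), ]
    len_mb <- b$length / 1e6
    st <- .mb_states(p, len_mb)
    flag <- st$maj != st$mn
    cen_bins <- (b$cen_start / 1e6 + 1):(b$cen_end / 1e6)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      touches <- starts[k] == 1 || ends[k] == len_mb
      whole <- starts[k] == 1 && ends[k] == len_mb
      olap <- any(cen_bins >= starts[k] & cen_bins <= ends[k])
      if (touches && !whole && !olap) total <- total + 1
    }
  }
  total
}

# recursive list-based smoothing + breakpoint count (independent of the
# vectorized implementation in the package)
.oracle_smooth <- function(segs, filter_bp) {
  # segs: list of list(start, end, key)
  collapse <- function(s) {
    if (length(s) < 2) return(s)
    out <- list(s[[1]])
    for (k in 2:length(s)) {
      last <- out[[length(out)]]
      if (identical(last$key, s[[k]]$key)) {
        last$end <- s[[k]]$end
        out[[length(out)]] <- last
      } else out[[length(out) + 1]] <- s[[k]]
    }
    out
  }
  segs <- collapse(segs)
  if (length(segs) <= 1) return(segs)
  lens <- vapply(segs, function(x) x$end - x$start, numeric(1))
  if (min(lens) >= filter_bp) return(segs)
  k <- which.min(lens)
  n <- length(segs)
  if (k == 1) {
    segs[[2]]$start <- segs[[1]]$start
    segs <- segs[-1]
  } else if (k == n) {
    segs[[n - 1]]$end <- segs[[n]]$end
    segs <- segs[-n]
  } else if (identical(segs[[k - 1]]$key, segs[[k + 1]]$key)) {
    segs[[k - 1]]$end <- segs[[k + 1]]$end
    segs <- segs[-c(k, k + 1)]
  } else {
    mid <- (segs[[k]]$start + segs[[k]]$end) / 2
    segs[[k - 1]]$end <- mid
    segs[[k + 1]]$start <- mid
    segs <- segs[-k]
  }
  .oracle_smooth(segs, filter_bp)
}

oracle_lst <- function(profile, build, flank_mb = 10, filter_mb = 3) {
  total <- 0
  for (ci in seq_len(nrow(build))) {
    b <- build[ci, ]
    p <- profile[profile$chrom == b$chrom, , drop = FALSE]
    p <- p[order(p$start), ]
    for (arm in list(c(0, b$cen_start), c(b$cen_end, b$length))) {
      segs <- list()
      for (i in seq_len(nrow(p))) {
        s <- max(p$start[i], arm[1]); e <- min(p$end[i], arm[2])
        if (e > s)
          segs[[length(segs) + 1]] <-
            list(start = s, end = e, key = c(p$cn_major[i], p$cn_minor[i]))
      }
      if (!length(segs)) next
      sm <- .oracle_smooth(segs, filter_mb * 1e6)
      if (length(sm) < 2) next
      for (k in 2:length(sm)) {
        l1 <- sm[[k - 1]]$end - sm[[k - 1]]$start
        l2 <- sm[[k]]$end - sm[[k]]$start
        if (l1 >= flank_mb * 1e6 && l2 >= flank_mb * 1e6)
          total <- total + 1
      }
    }
  }
  total
}

# exact penalized two-channel optimum by plain bottom-up recursion on raw
# subvectors (no prefix sums)
oracle_dp <- function(y1, y2, het, penalty) {
  n <- length(y1)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  cost <- function(i, j) {
    v2 <- y2[i:j][het[i:j] == 1]
    sse(y1[i:j]) + sse(v2)
  }
  F <- c(-penalty, rep(Inf, n))
  back <- integer(n)
  for (j in seq_len(n)) {
    cand <- vapply(0:(j - 1), function(i) F[i + 1] + cost(i + 1, j) + penalty,
                   numeric(1))
    F[j + 1] <- min(cand)
    back[j] <- which.min(cand) - 1L
  }
  ends <- integer(0)
  j <- n
  while (j > 0) { ends <- c(j, ends); j <- back[j] }
  ends
}

# exhaustive search over every changepoint subset (tiny n only)
oracle_dp_exhaustive <- function(y1, y2, het, penalty) {
  n <- length(y1)
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  cost <- function(i, j) {
    v2 <- y2[i:j][het[i:j] == 1]
    sse(y1[i:j]) + sse(v2)
  }
  best <- Inf; best_ends <- n
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    ends <- c(cuts, n)
    starts <- c(1, head(ends, -1) + 1)
    tot <- sum(mapply(cost, starts, ends)) + penalty * (length(ends) - 1)
    if (tot < best - 1e-12) { best <- tot; best_ends <- ends }
  }
  best_ends
}

# Mann-Whitney pair counting
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# threshold-enumerating average precision
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
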