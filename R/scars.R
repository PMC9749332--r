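#' Count LOH scar regions
#'
#' LOH regions are maximal runs of adjacent segments with one parental allele
#' fully lost (`cn_minor == 0`, `cn_major >= 1`; copy-neutral and amplified
#' LOH count, homozygous deletions do not). A run scores when its length is
#' strictly greater than `min_mb` (default 15 Mb) and strictly shorter than
#' the whole chromosome.
#'
#' @param profile ASCN profile data.frame (`chrom,start,end,cn_major,cn_minor`).
#' @param build a `genome_build`.
#' @param min_mb minimum region length in Mb (strict inequality).
#' @return integer count.
#' @export
score_loh <- function(profile, build, min_mb = 15) {
  total <- 0L
  for (ci in seq_len(nrow(build))) {
    p <- profile[profile$chrom == build$chrom[ci], , drop = FALSE]
    if (!nrow(p)) next
    p <- p[order(p$start), , drop = FALSE]
    runs <- .merge_state_runs(p$start, p$end,
                              p$cn_minor == 0 & p$cn_major >= 1)
    len <- runs$end - runs$start
    total <- total + sum(runs$state & len > min_mb * 1e6 &
                           len < build$length[ci])
  }
  as.integer(total)
}

#' Count telomeric allelic imbalance (TAI) regions
#'
#' Allelic imbalance means `cn_major != cn_minor`. Maximal imbalanced runs
#' score when they include a chromosome terminus (start at 0 or end at the
#' chromosome length), do not overlap the centromere interval, and do not
#' span the whole chromosome; at most two can score per chromosome.
#'
#' @param profile ASCN profile data.frame.
#' @param build a `genome_build`.
#' @param tai_min_mb optional minimum region length in Mb (default 0: no
#'   length floor, matching the original region-count definition).
#' @return integer count.
#' @export
score_tai <- function(profile, build, tai_min_mb = 0) {
  total <- 0L
  for (ci in seq_len(nrow(build))) {
    b <- build[ci, ]
    p <- profile[profile$chrom == b$chrom, , drop = FALSE]
    if (!nrow(p)) next
    p <- p[order(p$start), , drop = FALSE]
    runs <- .merge_state_runs(p$start, p$end, p$cn_major != p$cn_minor)
    runs <- runs[runs$state, , drop = FALSE]
    if (!nrow(runs)) next
    touches <- runs$start == 0 | runs$end == b$length
    whole <- runs$start == 0 & runs$end == b$length
    cen_olap <- runs$start < b$cen_end & runs$end > b$cen_start
    long_enough <- (runs$end - runs$start) > tai_min_mb * 1e6
    total <- total + sum(touches & !whole & !cen_olap & long_enough)
  }
  as.integer(total)
}

#' Count large-scale state transitions (LST)
#'
#' Computed per chromosome arm (segments are split at the centromere and the
#' centromere interval discarded). Each arm's segmentation is first smoothed:
#' while any segment is shorter than `filter_mb` (default 3 Mb), the shortest
#' such segment (leftmost on ties) is deleted; its interval is reassigned to
#' the flanking segments — merged into one when the flanks share the same
#' `(cn_major, cn_minor)` state, otherwise split evenly between them (or
#' absorbed entirely by the single neighbor at an arm edge). LST is then the
#' number of breakpoints between adjacent smoothed segments that differ in
#' state and are both at least `flank_mb` (default 10 Mb) long.
#'
#' @param profile ASCN profile data.frame.
#' @param build a `genome_build`.
#' @param flank_mb minimum flanking-segment length in Mb (non-strict).
#' @param filter_mb segments strictly shorter than this are smoothed away.
#' @return integer count.
#' @export
score_lst <- function(profile, build, flank_mb = 10, filter_mb = 3) {
  total <- 0L
  for (ci in seq_len(nrow(build))) {
    b <- build[ci, ]
    p <- profile[profile$chrom == b$chrom, , drop = FALSE]
    if (!nrow(p)) next
    p <- p[order(p$start), , drop = FALSE]
    for (arm in list(c(0, b$cen_start), c(b$cen_end, b$length))) {
      keep <- p$end > arm[1] & p$start < arm[2]
      a <- p[keep, , drop = FALSE]
      if (!nrow(a)) next
      a$start <- pmax(a$start, arm[1])
      a$end <- pmin(a$end, arm[2])
      s <- .smooth_arm(a$start, a$end, a$cn_major, a$cn_minor,
                       filter_bp = filter_mb * 1e6)
      if (length(s$start) < 2) next
      len <- s$end - s$start
      ok <- len[-length(len)] >= flank_mb * 1e6 & len[-1] >= flank_mb * 1e6
      total <- total + sum(ok)
    }
  }
  as.integer(total)
}

# collapse adjacent segments sharing a logical state into maximal runs
.merge_state_runs <- function(start, end, state) {
  r <- rle(state)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  data.frame(start = start[idx_start], end = end[idx_end], state = r$values)
}

# iterative small-segment smoothing of one arm's segment list
.smooth_arm <- function(start, end, maj, mn, filter_bp) {
  merge_equal <- function(s, e, a, b) {
    n <- length(s)
    if (n < 2) return(list(start = s, end = e, maj = a, mn = b))
    same <- c(FALSE, a[-1] == a[-n] & b[-1] == b[-n])
    first <- which(!same)
    last <- c(first[-1] - 1L, n)
    list(start = s[first], end = e[last], maj = a[first], mn = b[first])
  }
  z <- merge_equal(start, end, maj, mn)
  repeat {
    n <- length(z$start)
    if (n <= 1) break
    len <- z$end - z$start
    if (min(len) >= filter_bp) break
    k <- which.min(len)  # leftmost on ties
    if (k == 1) {
      z$start[2] <- z$start[1]
      z <- lapply(z, function(v) v[-1])
    } else if (k == n) {
      z$end[n - 1] <- z$end[n]
      z <- lapply(z, function(v) v[-n])
    } else if (z$maj[k - 1] == z$maj[k + 1] && z$mn[k - 1] == z$mn[k + 1]) {
      z$end[k - 1] <- z$end[k + 1]
      z <- lapply(z, function(v) v[-c(k, k + 1)])
    } else {
      mid <- (z$start[k] + z$end[k]) / 2
      z$end[k - 1] <- mid
      z$start[k + 1] <- mid
      z <- lapply(z, function(v) v[-k])
    }
    z <- merge_equal(z$start, z$end, z$maj, z$mn)
  }
  z
}

#' Score one sample: LOH, TAI, LST and the HRD sum
#'
#' The aggregate HRD metric is the unweighted sum of the three components.
#'
#' @param profile ASCN profile data.frame.
#' @param build a `genome_build`.
#' @param sample_id label for the output row.
#' @param ... passed through to the component scorers
#'   ([score_loh()], [score_tai()], [score_lst()]).
#' @return one-row data.frame `sample_id, loh, tai, lst, hrd_sum`.
#' @export
score_sample <- function(profile, build, sample_id = "sample", ...) {
  dots <- list(...)
  loh <- do.call(score_loh, c(list(profile, build),
                              dots[names(dots) %in% "min_mb"]))
  tai <- do.call(score_tai, c(list(profile, build),
                              dots[names(dots) %in% "tai_min_mb"]))
  lst <- do.call(score_lst, c(list(profile, build),
                              dots[names(dots) %in% c("flank_mb", "filter_mb")]))
  data.frame(sample_id = sample_id, loh = loh, tai = tai, lst = lst,
             hrd_sum = loh + tai + lst, stringsAsFactors = FALSE)
}

#' Dichotomize an HRD sum at the clinical cut-off
#'
#' @param hrd_sum numeric vector of HRD sum scores (or a data.frame with an
#'   `hrd_sum` column).
#' @param cutoff non-negative threshold; the clinical cut-off is 42 and the
#'   rule is inclusive (`hrd_sum >= cutoff` is positive).
#' @return character vector `"positive"`/`"negative"`.
#' @export
classify_hrd <- function(hrd_sum, cutoff = 42) {
  if (is.data.frame(hrd_sum)) hrd_sum <- hrd_sum$hrd_sum
  if (cutoff < 0) stop("cutoff must be >= 0")
  ifelse(hrd_sum >= cutoff, "positive", "negative")
}
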