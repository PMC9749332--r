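#' GC-wave correction of the LRR channel
#'
#' Removes smooth GC-content artifacts by residualizing LRR on GC with a
#' robust local-linear smoother (`stats::lowess`), then re-centers the
#' residuals so the genome-wide median LRR is preserved. BAF is untouched.
#' With a constant GC column there is nothing to fit and the signal is
#' returned unchanged with a warning.
#'
#' @param signal a `marker_signal` data.frame (`chrom,pos,lrr,baf,gc`).
#' @param span smoother span (fraction of points; default 0.3).
#' @return the signal with a corrected `lrr` column.
#' @export
gc_correct <- function(signal, span = 0.3) {
  if (!all(c("lrr", "gc") %in% names(signal))) stop("signal needs lrr and gc")
  if (anyNA(signal$gc)) stop("gc must be present for all markers")
  if (stats::sd(signal$gc) == 0) {
    warning("constant GC column: correction is a no-op")
    return(signal)
  }
  fit <- lowess(signal$gc, signal$lrr, f = span)
  trend <- approx(fit$x, fit$y, xout = signal$gc, rule = 2, ties = "ordered")$y
  resid <- signal$lrr - trend
  signal$lrr <- resid - median(resid) + median(signal$lrr)
  signal
}

# robust per-channel noise scale from within-chromosome first differences:
# for Gaussian noise, median |x_i+1 - x_i| = sigma * sqrt(2) * qnorm(0.75)
.sigma_from_diffs <- function(values, chrom) {
  d <- unlist(lapply(split(values, chrom), diff), use.names = FALSE)
  if (!length(d)) return(0)
  median(abs(d)) / (sqrt(2) * qnorm(0.75))
}

#' Default segmentation penalty
#'
#' BIC-like self-tuning default: `2 * (sigma_lrr^2 + sigma_baf^2) * log(n)`,
#' with the per-channel noise scales estimated robustly from median absolute
#' first differences within chromosomes, floored at `penalty_min` so that
#' near-noiseless input is not shattered into marker-level segments.
#'
#' @param signal a `marker_signal`.
#' @param het_range raw-BAF interval used to flag heterozygous markers.
#' @param penalty_min lower bound on the penalty.
#' @return a positive scalar penalty.
#' @export
default_penalty <- function(signal, het_range = c(0.15, 0.85),
                            penalty_min = 0.05) {
  het <- signal$baf >= het_range[1] & signal$baf <= het_range[2]
  s1 <- .sigma_from_diffs(signal$lrr, signal$chrom)
  folded <- 0.5 + abs(signal$baf[het] - 0.5)
  s2 <- .sigma_from_diffs(folded, signal$chrom[het])
  max(2 * (s1^2 + s2^2) * log(nrow(signal)), penalty_min)
}

#' Joint two-channel changepoint segmentation
#'
#' Per chromosome, finds the changepoint set minimizing total within-segment
#' squared error of the two channels — LRR at every marker, and the mirrored
#' BAF (folded to `[0.5, 1]`) of heterozygous markers — plus
#' `penalty * (number of changepoints)`. The optimum is computed exactly by
#' dynamic programming (optimal partitioning). Heterozygous markers are those
#' with raw BAF inside `het_range` (no matched normal is assumed).
#'
#' Segment boundaries are placed at 0, the chromosome length, and the
#' midpoints between the markers flanking each changepoint, so segments tile
#' each chromosome.
#'
#' @param signal a `marker_signal`, markers sorted by (chrom, pos).
#' @param build a `genome_build` covering the signal's chromosomes.
#' @param penalty positive penalty per changepoint; `NULL` uses
#'   [default_penalty()].
#' @param het_range raw-BAF interval flagging heterozygous markers.
#' @return data.frame (class `segmentation_result`) with columns `chrom,
#'   start, end, n_markers, n_het, mean_lrr, mean_baf, m2_baf` (mirrored-BAF
#'   mean and mean squared deviation from 0.5 over het markers; `NA` when a
#'   segment has none) plus attributes `penalty`, `sigma_lrr`, `sigma_baf`,
#'   `sample_id`.
#' @export
segment_joint <- function(signal, build, penalty = NULL,
                          het_range = c(0.15, 0.85)) {
  stopifnot(nrow(signal) >= 1)
  if (is.null(penalty)) penalty <- default_penalty(signal, het_range)
  if (penalty <= 0) stop("penalty must be > 0")
  het_all <- signal$baf >= het_range[1] & signal$baf <= het_range[2]
  folded_all <- 0.5 + abs(signal$baf - 0.5)
  out <- list()
  for (ch in unique(signal$chrom)) {
    row <- .build_row(build, ch)
    mi <- which(signal$chrom == ch)
    pos <- signal$pos[mi]
    if (is.unsorted(pos)) stop("markers must be sorted by position")
    lrr <- signal$lrr[mi]
    het <- het_all[mi]
    folded <- folded_all[mi]
    ends <- if (length(mi) < 2) length(mi) else
      .dp_segment_cpp(lrr, folded, as.integer(het), penalty)
    starts <- c(1L, head(ends, -1) + 1L)
    bp_start <- c(0, (pos[head(ends, -1)] + pos[head(ends, -1) + 1]) / 2)
    bp_end <- c(bp_start[-1], row$length)
    seg <- data.frame(chrom = ch, start = floor(bp_start), end = floor(bp_end),
                      stringsAsFactors = FALSE)
    seg$end[nrow(seg)] <- row$length
    seg$n_markers <- ends - starts + 1L
    seg$n_het <- vapply(seq_along(ends), function(k)
      sum(het[starts[k]:ends[k]]), integer(1))
    seg$mean_lrr <- vapply(seq_along(ends), function(k)
      mean(lrr[starts[k]:ends[k]]), numeric(1))
    seg$mean_baf <- vapply(seq_along(ends), function(k) {
      v <- folded[starts[k]:ends[k]][het[starts[k]:ends[k]]]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    seg$m2_baf <- vapply(seq_along(ends), function(k) {
      idx <- starts[k]:ends[k]
      v <- signal$baf[mi][idx][het[idx]]
      if (length(v)) mean((v - 0.5)^2) else NA_real_
    }, numeric(1))
    out[[length(out) + 1]] <- seg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "penalty") <- penalty
  attr(res, "sigma_lrr") <- .sigma_from_diffs(signal$lrr, signal$chrom)
  attr(res, "sigma_baf") <- .sigma_from_diffs(folded_all[het_all],
                                              signal$chrom[het_all])
  attr(res, "sample_id") <- attr(signal, "sample_id")
  class(res) <- c("segmentation_result", "data.frame")
  res
}

# noise-corrected mirrored-BAF estimate per segment: the folded mean is biased
# upward by |noise| folding near 0.5; the second moment about 0.5 subtracts
# the noise variance instead
.bhat <- function(m2_baf, sigma_baf) {
  0.5 + sqrt(pmax(m2_baf - sigma_baf^2, 0))
}

# continuous allele-specific copy numbers for all segments at a candidate
# (rho, D); D = rho * psi + 2 (1 - rho) is the denominator ploidy term
.continuous_ascn <- function(seg, rho, D, gamma, lrr_offset, sigma_baf,
                             min_het) {
  t2 <- 2^((seg$mean_lrr - lrr_offset) / gamma)
  nT <- (D * t2 - 2 * (1 - rho)) / rho
  bhat <- .bhat(seg$m2_baf, sigma_baf)
  informative <- !is.na(bhat) & seg$n_het >= min_het
  nMaj <- ifelse(!is.na(bhat),
                 (bhat * D * t2 - (1 - rho)) / rho,
                 NA_real_)
  list(nT = nT, nMaj = nMaj, nMin = nT - nMaj, informative = informative)
}

#' Fit tumor purity and ploidy by grid search
#'
#' Inverts the allele-specific signal model on the segment means over a grid
#' of candidate (purity, ploidy) pairs. Segment LRR means are first centered
#' at their marker-weighted median (array LRR is defined only up to a
#' normalization constant); for each candidate the continuous allele-specific
#' copy numbers of every heterozygous-informative segment (at least `min_het`
#' het markers) are computed, and the candidate distance is the
#' marker-weighted mean squared deviation from the nearest non-negative
#' integers. The reported fit minimizes this distance; exact ties are broken
#' toward the smallest ploidy, then the largest purity (the conventional
#' preference against whole-genome-duplication solutions). The reported
#' `ploidy` is the length-weighted mean total copy number of the fitted
#' profile; the grid ploidy of the optimum is kept as `ploidy_grid`.
#'
#' @param segres a `segmentation_result`.
#' @param gamma platform compression factor (must match the assay/simulation).
#' @param purity_grid,ploidy_grid candidate grids.
#' @param min_het minimum heterozygous markers for a segment to inform the
#'   allele-specific distance.
#' @return list of class `purity_ploidy_fit`: `purity`, `ploidy`,
#'   `ploidy_grid`, `goodness` (the minimized distance), `lrr_offset`,
#'   `gamma`, `sigma_baf`, `min_het`, and `grid` (data.frame of all evaluated
#'   `purity, ploidy, distance`).
#' @export
fit_purity_ploidy <- function(segres, gamma = 0.55,
                              purity_grid = seq(0.10, 1.00, by = 0.01),
                              ploidy_grid = seq(1.0, 5.0, by = 0.05),
                              min_het = 10) {
  sigma_baf <- attr(segres, "sigma_baf")
  if (is.null(sigma_baf)) sigma_baf <- 0
  informative <- !is.na(segres$m2_baf) & segres$n_het >= min_het
  if (!any(informative))
    stop("uninformative sample: no segment with >= ", min_het,
         " heterozygous markers")
  w_all <- segres$n_markers
  lrr_offset <- .weighted_median(segres$mean_lrr, w_all)
  inf <- segres[informative, , drop = FALSE]
  w <- inf$n_markers
  t2 <- 2^((inf$mean_lrr - lrr_offset) / gamma)
  bhat <- .bhat(inf$m2_baf, sigma_baf)
  # candidates ordered by (ploidy asc, purity desc): which.min then honors
  # the tie-break rule
  grid <- expand.grid(purity = rev(purity_grid), ploidy = ploidy_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rho <- grid$purity
  D <- rho * grid$ploidy + 2 * (1 - rho)
  # distance matrix computed blockwise: candidates x segments
  TT <- outer(D, t2)                       # rho nT + 2(1-rho) per candidate
  nT <- (TT - 2 * (1 - rho)) / rho
  nMaj <- (sweep(TT, 2, bhat, `*`) - (1 - rho)) / rho
  nMin <- nT - nMaj
  dev <- (nMaj - pmax(round(nMaj), 0))^2 + (nMin - pmax(round(nMin), 0))^2
  dist <- as.vector(dev %*% w) / sum(w)
  # near-degenerate optima (e.g. the genome-doubled twin of a solution) can
  # differ only at the fraction-of-a-percent level; treat candidates within
  # 1% of the minimum as tied and let the grid ordering break the tie toward
  # the smallest ploidy, then the largest purity
  mind <- min(dist)
  k <- which(dist <= mind + pmax(1e-9, 0.01 * mind))[1]
  fit <- list(purity = grid$purity[k], ploidy_grid = grid$ploidy[k],
              goodness = dist[k], lrr_offset = lrr_offset, gamma = gamma,
              sigma_baf = sigma_baf, min_het = min_het,
              grid = data.frame(purity = grid$purity, ploidy = grid$ploidy,
                                distance = dist))
  # reported ploidy: length-weighted mean total copy number of the called fit
  called <- .call_segments(segres, fit)
  fit$ploidy <- sum((called$end - called$start) * (called$cn_major + called$cn_minor)) /
    sum(called$end - called$start)
  class(fit) <- "purity_ploidy_fit"
  fit
}

# integer calls for every segment under a fit (before merging)
.call_segments <- function(segres, fit) {
  rho <- fit$purity
  D <- rho * fit$ploidy_grid + 2 * (1 - rho)
  cc <- .continuous_ascn(segres, rho, D, fit$gamma, fit$lrr_offset,
                         fit$sigma_baf, fit$min_het)
  nT_int <- pmax(round(cc$nT), 0)
  maj <- integer(nrow(segres)); mn <- integer(nrow(segres))
  has_baf <- !is.na(cc$nMaj)
  maj[has_baf] <- pmax(round(cc$nMaj[has_baf]), 0)
  mn[has_baf] <- pmax(round(cc$nMin[has_baf]), 0)
  # no BAF information: split the total as evenly as possible
  maj[!has_baf] <- ceiling(nT_int[!has_baf] / 2)
  mn[!has_baf] <- floor(nT_int[!has_baf] / 2)
  swap <- maj < mn
  tmp <- maj[swap]; maj[swap] <- mn[swap]; mn[swap] <- tmp
  data.frame(chrom = segres$chrom, start = segres$start, end = segres$end,
             cn_major = maj, cn_minor = mn, stringsAsFactors = FALSE)
}

#' Call integer allele-specific copy numbers
#'
#' Rounds the per-segment continuous allele-specific copy numbers implied by
#' a purity/ploidy fit to the nearest non-negative integers (major >= minor
#' enforced by sorting), then merges adjacent segments with identical states
#' so the output satisfies the ASCN profile invariants.
#'
#' @param segres a `segmentation_result`.
#' @param fit a `purity_ploidy_fit`.
#' @return ASCN profile data.frame `chrom,start,end,cn_major,cn_minor`.
#' @export
call_integer_ascn <- function(segres, fit) {
  called <- .call_segments(segres, fit)
  out <- list()
  for (ch in unique(called$chrom)) {
    p <- called[called$chrom == ch, , drop = FALSE]
    n <- nrow(p)
    same <- c(FALSE, p$cn_major[-1] == p$cn_major[-n] &
                p$cn_minor[-1] == p$cn_minor[-n])
    first <- which(!same)
    last <- c(first[-1] - 1L, n)
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = p$start[first], end = p$end[last],
      cn_major = p$cn_major[first], cn_minor = p$cn_minor[first],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full per-sample copy-number pipeline
#'
#' Convenience wrapper: GC correction, joint segmentation, purity/ploidy fit,
#' integer calling and scar scoring for one marker signal.
#'
#' @param signal a `marker_signal`.
#' @param build a `genome_build`.
#' @param penalty segmentation penalty (`NULL`: self-tuning default).
#' @param gamma platform compression factor.
#' @param cutoff clinical HRD cut-off for the status column.
#' @param ... passed to [fit_purity_ploidy()].
#' @return list: `scores` (one-row data.frame with `hrd_status` appended),
#'   `profile`, `fit`, `segments`.
#' @export
hrd_pipeline <- function(signal, build, penalty = NULL, gamma = 0.55,
                         cutoff = 42, ...) {
  corrected <- gc_correct(signal)
  segres <- segment_joint(corrected, build, penalty = penalty)
  fit <- fit_purity_ploidy(segres, gamma = gamma, ...)
  profile <- call_integer_ascn(segres, fit)
  id <- attr(signal, "sample_id")
  if (is.null(id)) id <- "sample"
  scores <- score_sample(profile, build, sample_id = id)
  scores$hrd_status <- classify_hrd(scores$hrd_sum, cutoff)
  list(scores = scores, profile = profile, fit = fit, segments = segres)
}
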