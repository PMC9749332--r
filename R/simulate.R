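#' Simulation parameters
#'
#' Bundles every knob of the synthetic cohort generator. Event classes are
#' chosen so that each scar metric can be dosed independently:
#'
#' * `rate_interstitial_loh` — interstitial one-copy deletions (cn 1+0),
#'   log-uniform length `len_loh_mb` (default 16–40 Mb, safely above the
#'   15 Mb LOH threshold); each also contributes two large-segment
#'   breakpoints (LST).
#' * `rate_telomeric_ai` — single-copy gains (cn 2+1) anchored at a
#'   chromosome end and stopped well before the centromere, length
#'   `len_tai_mb` (default 11–30 Mb); each contributes one TAI region and
#'   one LST breakpoint.
#' * `rate_focal` — focal deletions (cn 1+0) shorter than 3 Mb
#'   (`len_focal_mb`, default 0.5–2.5 Mb); they qualify under no metric and
#'   exercise the LST small-segment filter.
#' * `rate_whole_chrom_loh` — whole-chromosome LOH; qualifies under no
#'   metric (LOH requires "shorter than the whole chromosome").
#'
#' Rates are expected event counts per genome (Poisson); for samples of class
#' `"hrd"` all rates are multiplied by `hrd_multiplier`. Events are placed
#' within single chromosome arms, separated from arm boundaries and from each
#' other by at least `margin_mb`, so that every injected event's qualifying
#' contributions can be derived exactly at injection time (the event ledger).
#'
#' @param n_samples cohort size.
#' @param class_mix fraction of "hrd" (scar-rich) samples in `[0, 1]`.
#' @param purity_range tumor purity range, sampled uniformly per sample,
#'   within (0, 1].
#' @param base_ploidy background total copy number (even integer; 2 gives a
#'   1+1 diploid background).
#' @param rate_interstitial_loh,rate_telomeric_ai,rate_focal,rate_whole_chrom_loh
#'   expected event counts per genome for the scar-poor class.
#' @param hrd_multiplier rate multiplier for the "hrd" class.
#' @param len_loh_mb,len_tai_mb,len_focal_mb per-class log-uniform length
#'   bounds in Mb.
#' @param margin_mb minimum separation (Mb) between events and from arm
#'   boundaries.
#' @param noise_sd_lrr,noise_sd_baf Gaussian marker noise (LRR / BAF units);
#'   BAF noise is clipped with the signal into `[0, 1]`.
#' @param gc_wave_amplitude amplitude (LRR units, one GC standard deviation)
#'   of the additive GC wave artifact.
#' @param gamma platform compression factor of the LRR response.
#' @param hom_fraction fraction of markers that are germline homozygous.
#' @param seed integer master seed; all cohort randomness derives from it.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 40, class_mix = 0.5,
                       purity_range = c(0.4, 0.9), base_ploidy = 2,
                       rate_interstitial_loh = 1, rate_telomeric_ai = 1,
                       rate_focal = 2, rate_whole_chrom_loh = 0.5,
                       hrd_multiplier = 10,
                       len_loh_mb = c(16, 40), len_tai_mb = c(11, 30),
                       len_focal_mb = c(0.5, 2.5), margin_mb = 10.5,
                       noise_sd_lrr = 0.15, noise_sd_baf = 0.03,
                       gc_wave_amplitude = 0.1, gamma = 0.55,
                       hom_fraction = 0.6, seed = 1L) {
  p <- list(n_samples = n_samples, class_mix = class_mix,
            purity_range = sort(purity_range), base_ploidy = base_ploidy,
            rate_interstitial_loh = rate_interstitial_loh,
            rate_telomeric_ai = rate_telomeric_ai, rate_focal = rate_focal,
            rate_whole_chrom_loh = rate_whole_chrom_loh,
            hrd_multiplier = hrd_multiplier, len_loh_mb = len_loh_mb,
            len_tai_mb = len_tai_mb, len_focal_mb = len_focal_mb,
            margin_mb = margin_mb, noise_sd_lrr = noise_sd_lrr,
            noise_sd_baf = noise_sd_baf,
            gc_wave_amplitude = gc_wave_amplitude, gamma = gamma,
            hom_fraction = hom_fraction, seed = as.integer(seed))
  rates <- c(p$rate_interstitial_loh, p$rate_telomeric_ai, p$rate_focal,
             p$rate_whole_chrom_loh)
  if (p$n_samples < 0) stop("n_samples must be >= 0")
  if (p$class_mix < 0 || p$class_mix > 1) stop("class_mix must be in [0, 1]")
  if (any(rates < 0)) stop("event rates must be >= 0")
  if (p$noise_sd_lrr < 0 || p$noise_sd_baf < 0) stop("noise SDs must be >= 0")
  if (p$purity_range[1] <= 0 || p$purity_range[2] > 1)
    stop("purity must lie within (0, 1]")
  if (p$hom_fraction < 0 || p$hom_fraction >= 1)
    stop("hom_fraction must lie in [0, 1)")
  class(p) <- "sim_params"
  p
}

# log-uniform length draw, in bp
.rlen_bp <- function(n, bounds_mb) {
  exp(runif(n, log(bounds_mb[1] * 1e6), log(bounds_mb[2] * 1e6)))
}

# gap between [s1,e1) and [s2,e2)
.interval_gap <- function(s1, e1, s2, e2) pmax(s2 - e1, s1 - e2)

#' Simulate a truth allele-specific copy-number profile
#'
#' Starts from a uniform background and injects Poisson-drawn counts of the
#' four event classes at random non-overlapping loci honoring class geometry
#' (see [sim_params()]). Returns both the tiled profile and an event ledger
#' listing, for each injected event, whether it qualifies under each scar
#' metric's rules — derived by direct rule application to the injection
#' geometry, so that truth scores can be audited event by event.
#'
#' Placement re-draws an event up to 100 times when it cannot be positioned
#' without violating the separation margins, then skips it with a warning.
#'
#' @param build a `genome_build`.
#' @param params a `sim_params`.
#' @param sample_class `"stable"` or `"hrd"`.
#' @param seed integer seed for this sample.
#' @return list with elements `profile` (data.frame `chrom,start,end,
#'   cn_major,cn_minor`, tiling every chromosome) and `ledger` (data.frame
#'   `chrom,start,end,class,cn_major,cn_minor,q_loh,q_tai,q_lst`).
#' @export
simulate_truth_profile <- function(build, params, sample_class = "stable",
                                   seed = params$seed) {
  validate_build(build)
  stopifnot(sample_class %in% c("stable", "hrd"))
  mult <- if (sample_class == "hrd") params$hrd_multiplier else 1
  m <- params$margin_mb * 1e6
  bmaj <- ceiling(params$base_ploidy / 2)
  bmin <- floor(params$base_ploidy / 2)

  .with_seed(seed, {
    n_wc  <- rpois(1, params$rate_whole_chrom_loh * mult)
    n_loh <- rpois(1, params$rate_interstitial_loh * mult)
    n_tel <- rpois(1, params$rate_telomeric_ai * mult)
    n_foc <- rpois(1, params$rate_focal * mult)

    events <- list()
    # whole-chromosome LOH first: those chromosomes are blocked for placement
    n_wc <- min(n_wc, nrow(build))
    wc_chroms <- if (n_wc > 0) sample(build$chrom, n_wc) else character(0)
    for (ch in wc_chroms) {
      row <- .build_row(build, ch)
      events[[length(events) + 1]] <- data.frame(
        chrom = ch, start = 0, end = row$length,
        cn_major = max(bmaj, 1), cn_minor = 0, class = "whole_chrom_loh",
        stringsAsFactors = FALSE)
    }
    open <- setdiff(build$chrom, wc_chroms)

    placed_ok <- function(ch, s, e) {
      for (ev in events) {
        if (ev$chrom == ch && .interval_gap(s, e, ev$start, ev$end) < m)
          return(FALSE)
      }
      TRUE
    }
    place_interstitial <- function(L, cn_major, cn_minor, cls) {
      if (!length(open)) return(FALSE)
      for (try in seq_len(100)) {
        arms <- do.call(rbind, lapply(open, function(ch) {
          row <- .build_row(build, ch)
          rbind(data.frame(chrom = ch, lo = m, hi = row$cen_start - m - L),
                data.frame(chrom = ch, lo = row$cen_end + m,
                           hi = row$length - m - L))
        }))
        arms <- arms[arms$hi > arms$lo, , drop = FALSE]
        if (!nrow(arms)) return(FALSE)
        k <- sample.int(nrow(arms), 1, prob = arms$hi - arms$lo)
        s <- runif(1, arms$lo[k], arms$hi[k])
        if (placed_ok(arms$chrom[k], s, s + L)) {
          events[[length(events) + 1]] <<- data.frame(
            chrom = arms$chrom[k], start = s, end = s + L,
            cn_major = cn_major, cn_minor = cn_minor, class = cls,
            stringsAsFactors = FALSE)
          return(TRUE)
        }
      }
      FALSE
    }
    place_telomeric <- function(L) {
      if (!length(open)) return(FALSE)
      for (try in seq_len(100)) {
        ends <- do.call(rbind, lapply(open, function(ch) {
          row <- .build_row(build, ch)
          rbind(data.frame(chrom = ch, side = "p",
                           ok = L <= row$cen_start - m),
                data.frame(chrom = ch, side = "q",
                           ok = L <= row$length - row$cen_end - m))
        }))
        ends <- ends[ends$ok, , drop = FALSE]
        if (!nrow(ends)) return(FALSE)
        k <- sample.int(nrow(ends), 1)
        row <- .build_row(build, ends$chrom[k])
        if (ends$side[k] == "p") { s <- 0; e <- L }
        else { s <- row$length - L; e <- row$length }
        if (placed_ok(ends$chrom[k], s, e)) {
          events[[length(events) + 1]] <<- data.frame(
            chrom = ends$chrom[k], start = s, end = e,
            cn_major = bmaj + 1, cn_minor = bmin, class = "telomeric_ai",
            stringsAsFactors = FALSE)
          return(TRUE)
        }
      }
      FALSE
    }

    skipped <- 0
    for (L in .rlen_bp(n_loh, params$len_loh_mb))
      if (!place_interstitial(L, max(bmaj, 1), 0, "interstitial_loh"))
        skipped <- skipped + 1
    for (L in .rlen_bp(n_tel, params$len_tai_mb))
      if (!place_telomeric(L)) skipped <- skipped + 1
    for (L in .rlen_bp(n_foc, params$len_focal_mb))
      if (!place_interstitial(L, max(bmaj, 1), 0, "focal"))
        skipped <- skipped + 1
    if (skipped > 0)
      warning(skipped, " event(s) could not be placed and were skipped")

    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 cn_major = integer(0), cn_minor = integer(0),
                 class = character(0), stringsAsFactors = FALSE)
    ledger <- .qualify_events(ev, build, c(bmaj, bmin))
    profile <- .tile_profile(ev, build, c(bmaj, bmin))
    list(profile = profile, ledger = ledger)
  })
}

# derive per-event qualifying counts under each scar rule from placement
# geometry (focal events are transparent for LST flanks: the < 3 Mb filter
# removes them before breakpoints are counted)
.qualify_events <- function(ev, build, background) {
  n <- nrow(ev)
  q_loh <- q_tai <- q_lst <- integer(n)
  if (n == 0)
    return(cbind(ev, q_loh = q_loh, q_tai = q_tai, q_lst = q_lst))
  balanced_bg <- background[1] == background[2]
  for (i in seq_len(n)) {
    row <- .build_row(build, ev$chrom[i])
    L <- ev$end[i] - ev$start[i]
    whole <- ev$start[i] <= 0 && ev$end[i] >= row$length
    # LOH: minor copy lost, > 15 Mb, shorter than the whole chromosome
    q_loh[i] <- as.integer(ev$cn_minor[i] == 0 && ev$cn_major[i] >= 1 &&
                             L > 15e6 && !whole)
    # TAI: imbalanced, reaches a terminus, does not overlap the centromere,
    # not the whole chromosome
    imb <- ev$cn_major[i] != ev$cn_minor[i]
    telo <- ev$start[i] <= 0 || ev$end[i] >= row$length
    cen_olap <- ev$start[i] < row$cen_end && ev$end[i] > row$cen_start
    q_tai[i] <- as.integer(imb && telo && !cen_olap && !whole && balanced_bg)
    # LST: count this event's breakpoints whose two flanking smoothed
    # segments are both >= 10 Mb (flanks are background runs bounded by the
    # arm edges and the nearest non-focal neighbor)
    if (ev$class[i] %in% c("interstitial_loh", "telomeric_ai")) {
      arm <- if (ev$end[i] <= row$cen_start) c(0, row$cen_start)
             else c(row$cen_end, row$length)
      same <- ev[ev$chrom == ev$chrom[i] & ev$class != "focal" &
                   seq_len(n) != i, , drop = FALSE]
      same <- same[same$start >= arm[1] & same$end <= arm[2], , drop = FALSE]
      left_lim  <- max(c(arm[1], same$end[same$end <= ev$start[i]]))
      right_lim <- min(c(arm[2], same$start[same$start >= ev$end[i]]))
      nb <- 0L
      if (ev$start[i] > arm[1])  # interior breakpoint on the left
        nb <- nb + as.integer(L >= 10e6 && ev$start[i] - left_lim >= 10e6)
      if (ev$end[i] < arm[2])    # interior breakpoint on the right
        nb <- nb + as.integer(L >= 10e6 && right_lim - ev$end[i] >= 10e6)
      q_lst[i] <- nb
    }
  }
  cbind(ev, q_loh = q_loh, q_tai = q_tai, q_lst = q_lst)
}

# tile every chromosome completely: events override the uniform background
.tile_profile <- function(ev, build, background) {
  segs <- lapply(seq_len(nrow(build)), function(ci) {
    row <- build[ci, ]
    e <- ev[ev$chrom == row$chrom, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    starts <- c(); ends <- c(); maj <- c(); mn <- c()
    cur <- 0
    for (k in seq_len(nrow(e))) {
      if (e$start[k] > cur) {
        starts <- c(starts, cur); ends <- c(ends, e$start[k])
        maj <- c(maj, background[1]); mn <- c(mn, background[2])
      }
      starts <- c(starts, e$start[k]); ends <- c(ends, e$end[k])
      maj <- c(maj, e$cn_major[k]); mn <- c(mn, e$cn_minor[k])
      cur <- e$end[k]
    }
    if (cur < row$length) {
      starts <- c(starts, cur); ends <- c(ends, row$length)
      maj <- c(maj, background[1]); mn <- c(mn, background[2])
    }
    data.frame(chrom = row$chrom, start = starts, end = ends,
               cn_major = maj, cn_minor = mn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Validate an allele-specific copy-number profile
#'
#' Checks the tiling invariant (segments sorted, non-overlapping, covering
#' every base of every chromosome of the build exactly once) and
#' `cn_major >= cn_minor >= 0`.
#'
#' @param profile data.frame `chrom,start,end,cn_major,cn_minor`.
#' @param build a `genome_build`.
#' @return the profile, invisibly; errors on violation.
#' @export
validate_profile <- function(profile, build) {
  stopifnot(all(c("chrom", "start", "end", "cn_major", "cn_minor") %in%
                  names(profile)))
  if (any(profile$cn_minor < 0) || any(profile$cn_major < profile$cn_minor))
    stop("need cn_major >= cn_minor >= 0")
  for (ci in seq_len(nrow(build))) {
    p <- profile[profile$chrom == build$chrom[ci], , drop = FALSE]
    if (!nrow(p)) stop("chromosome not covered: ", build$chrom[ci])
    p <- p[order(p$start), , drop = FALSE]
    if (p$start[1] != 0 || p$end[nrow(p)] != build$length[ci] ||
        any(p$start >= p$end) ||
        (nrow(p) > 1 && any(p$end[-nrow(p)] != p$start[-1])))
      stop("segments do not tile chromosome ", build$chrom[ci])
  }
  invisible(profile)
}

#' Render marker-level LRR/BAF signals from a truth profile
#'
#' Forward signal model (the standard allele-specific array model): for a
#' marker in a segment with allele copies `(nA, nB)` and total `nT = nA + nB`,
#' at tumor purity `rho`,
#' \deqn{LRR = \gamma \log_2\frac{\rho nT + 2(1-\rho)}{2}, \quad
#'       BAF = \frac{\rho n_B + (1-\rho)}{\rho n_T + 2(1-\rho)}}
#' with the B allele assigned to the major or minor haplotype at random per
#' heterozygous marker; a `hom_fraction` of markers are germline homozygous
#' (BAF at 0 or 1). A GC wave `amplitude * (gc - mean(gc)) / sd(gc)` is added
#' to LRR, then Gaussian noise on both channels; BAF is clipped to `[0, 1]`.
#'
#' @param profile truth ASCN profile tiling the genome.
#' @param map a `marker_map`.
#' @param purity tumor cell fraction in (0, 1].
#' @param params a `sim_params` (noise, wave, gamma, hom_fraction).
#' @param seed integer seed.
#' @param sample_id label attached to the output.
#' @return data.frame (class `marker_signal`) with columns
#'   `chrom,pos,lrr,baf,gc` and attributes `sample_id`, `purity`.
#' @export
render_markers <- function(profile, map, purity, params, seed,
                           sample_id = "sample") {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  .with_seed(seed, {
    n <- nrow(map)
    nA <- nB_seg <- numeric(n)
    for (ch in unique(map$chrom)) {
      mi <- which(map$chrom == ch)
      p <- profile[profile$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      si <- findInterval(map$pos[mi], p$start)
      nA[mi] <- p$cn_major[si]
      nB_seg[mi] <- p$cn_minor[si]
    }
    nT <- nA + nB_seg
    denom <- purity * nT + 2 * (1 - purity)
    lrr <- params$gamma * log2(pmax(denom, 0.01) / 2)
    is_het <- runif(n) >= params$hom_fraction
    b_on_major <- runif(n) < 0.5
    nB <- ifelse(b_on_major, nA, nB_seg)
    mu <- (purity * nB + (1 - purity)) / denom
    mu[!is_het] <- ifelse(runif(sum(!is_het)) < 0.5, 0, 1)
    if (params$gc_wave_amplitude > 0 && stats::sd(map$gc) > 0)
      lrr <- lrr + params$gc_wave_amplitude *
        (map$gc - mean(map$gc)) / stats::sd(map$gc)
    if (params$noise_sd_lrr > 0) lrr <- lrr + rnorm(n, 0, params$noise_sd_lrr)
    baf <- mu
    if (params$noise_sd_baf > 0)
      baf <- .clip(baf + rnorm(n, 0, params$noise_sd_baf), 0, 1)
    out <- data.frame(chrom = map$chrom, pos = map$pos, lrr = lrr, baf = baf,
                      gc = map$gc, stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    attr(out, "purity") <- purity
    class(out) <- c("marker_signal", "data.frame")
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws class labels by `class_mix`, per-sample purities from
#' `purity_range`, truth profiles, truth scar scores (via [score_sample()] on
#' the truth profile) and rendered marker signals. All per-sample seeds derive
#' deterministically from `params$seed`, so the same parameters reproduce a
#' byte-identical cohort.
#'
#' @param build a `genome_build`.
#' @param map a `marker_map`.
#' @param params a `sim_params`.
#' @return list with `samples` (per-sample list: `sample_id`, `class`,
#'   `purity`, `signal`, `truth`, `ledger`, `truth_scores`) and `cohort`
#'   (summary data.frame `sample_id, class, purity, truth_loh, truth_tai,
#'   truth_lst, truth_hrd`).
#' @export
simulate_cohort <- function(build, map, params) {
  n <- params$n_samples
  if (n == 0)
    return(list(samples = list(),
                cohort = data.frame(sample_id = character(0),
                                    class = character(0), purity = numeric(0),
                                    truth_loh = integer(0),
                                    truth_tai = integer(0),
                                    truth_lst = integer(0),
                                    truth_hrd = integer(0))))
  n_hrd <- round(n * params$class_mix)
  classes <- .with_seed(.derive_seed(params$seed, 1),
                        sample(c(rep("hrd", n_hrd), rep("stable", n - n_hrd))))
  purities <- .with_seed(.derive_seed(params$seed, 2),
                         runif(n, params$purity_range[1],
                               params$purity_range[2]))
  samples <- lapply(seq_len(n), function(i) {
    id <- sprintf("S%03d", i)
    tr <- simulate_truth_profile(build, params, classes[i],
                                 seed = .derive_seed(params$seed, 100 + i))
    sc <- score_sample(tr$profile, build, sample_id = id)
    sig <- render_markers(tr$profile, map, purities[i], params,
                          seed = .derive_seed(params$seed, 10000 + i),
                          sample_id = id)
    list(sample_id = id, class = classes[i], purity = purities[i],
         signal = sig, truth = tr$profile, ledger = tr$ledger,
         truth_scores = sc)
  })
  cohort <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, class = s$class, purity = s$purity,
               truth_loh = s$truth_scores$loh, truth_tai = s$truth_scores$tai,
               truth_lst = s$truth_scores$lst,
               truth_hrd = s$truth_scores$hrd_sum,
               stringsAsFactors = FALSE)))
  list(samples = samples, cohort = cohort)
}

#' Write a simulated cohort to a directory
#'
#' Layout: `markers/<sample>.tsv` (chrom, pos, lrr, baf, gc),
#' `truth/<sample>.seg.tsv` (chrom, start, end, cn_major, cn_minor) and
#' `cohort.tsv` (sample_id, class, purity, truth scores). All files are
#' tab-delimited with a header row; coordinates 0-based half-open.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "markers"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$samples) {
    write_marker_tsv(s$signal, file.path(dir, "markers",
                                         paste0(s$sample_id, ".tsv")))
    write_seg_tsv(s$truth, file.path(dir, "truth",
                                     paste0(s$sample_id, ".seg.tsv")))
  }
  co <- cohort$cohort
  co$purity <- sprintf("%.6f", co$purity)
  write.table(co, file.path(dir, "cohort.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
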