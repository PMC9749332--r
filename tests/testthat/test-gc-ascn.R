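test_that("GC correction residualizes a linear wave and is gentle otherwise", {
  b <- toy_build_1()
  m <- make_marker_map(b, 6000, seed = 2)
  set.seed(10)
  # pure linear GC effect plus white noise
  sig <- data.frame(chrom = m$chrom, pos = m$pos,
                    lrr = 1.0 * m$gc + rnorm(nrow(m), 0, 0.05),
                    baf = runif(nrow(m)), gc = m$gc)
  corrected <- gc_correct(sig)
  expect_lt(abs(cor(corrected$lrr, corrected$gc)), 0.05)
  expect_equal(median(corrected$lrr), median(sig$lrr))

  # nothing to remove: flat LRR barely changes
  sig0 <- sig; sig0$lrr <- rnorm(nrow(m), 0, 0.15)
  expect_lt(median(abs(gc_correct(sig0)$lrr - sig0$lrr)), 0.02)

  # idempotence on noise-free input
  sign <- sig; sign$lrr <- 0.8 * sign$gc
  c1 <- gc_correct(sign); c2 <- gc_correct(c1)
  expect_lt(max(abs(c2$lrr - c1$lrr)), 1e-6)

  # constant GC: warned no-op
  sigc <- sig; sigc$gc <- 0.5
  expect_warning(out <- gc_correct(sigc), "constant GC")
  expect_identical(out$lrr, sigc$lrr)
})

test_that("joint segmentation finds exact changepoints in clean series", {
  b <- toy_build_1()
  pos <- seq(0, 99.9e6, length.out = 1000)
  sig <- data.frame(chrom = "chr1", pos = pos,
                    lrr = c(rep(0, 500), rep(1, 500)),
                    baf = rep(0.5, 1000), gc = 0.5)
  seg <- segment_joint(sig, b, penalty = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(500L, 500L))
  expect_equal(seg$start[2], floor((pos[500] + pos[501]) / 2))
  expect_equal(seg$end, c(seg$start[2], 100e6))

  # constant series: one segment for any positive penalty
  sigc <- sig; sigc$lrr <- 0.3
  expect_equal(nrow(segment_joint(sigc, b, penalty = 0.01)), 1)
  expect_error(segment_joint(sig, b, penalty = 0))
})

test_that("noisy segmentation recovers large-event breakpoints genome-wide", {
  # default-noise samples on the 22-autosome frame: boundaries of >= 10 Mb
  # events should be recovered within +/- 5 marker spacings with at most one
  # spurious changepoint per genome
  b <- default_build()
  m <- make_marker_map(b, 10000, seed = 3)
  p <- sim_params(seed = 4)  # noise 0.15 / 0.03, wave 0.1
  for (s in 1:3) {
    tr <- simulate_truth_profile(b, p, "hrd", seed = 100 + s)
    sig <- render_markers(tr$profile, m, 0.7, p, seed = 200 + s)
    seg <- segment_joint(gc_correct(sig), b)
    big <- tr$ledger[tr$ledger$class %in%
                       c("interstitial_loh", "telomeric_ai"), ]
    matched <- 0; n_big_bp <- 0; spurious <- 0
    for (ch in unique(seg$chrom)) {
      clen <- b$length[b$chrom == ch]
      tol <- clen / sum(m$chrom == ch) * 5
      found <- seg$start[seg$chrom == ch][-1]
      e <- big[big$chrom == ch, ]
      tb <- c(e$start[e$start > 0], e$end[e$end < clen])
      n_big_bp <- n_big_bp + length(tb)
      for (t in tb)
        if (length(found) && min(abs(found - t)) <= tol)
          matched <- matched + 1
      allt <- tr$profile$start[tr$profile$chrom == ch][-1]
      for (f in found)
        if (!length(allt) || min(abs(allt - f)) > tol)
          spurious <- spurious + 1
    }
    expect_gte(matched / n_big_bp, 0.9)
    expect_lte(spurious, 1)
  }
})

test_that("dynamic program equals the brute-force penalized optimum", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    k <- sample(0:3, 1)
    bp <- sort(sample(2:(n - 1), k))
    means <- cumsum(c(0, runif(k, -2, 2)))
    grp <- findInterval(seq_len(n), bp + 1) + 1
    y1 <- means[grp] + rnorm(n, 0, 0.4)
    het <- rbinom(n, 1, 0.4)
    y2 <- 0.5 + 0.2 * (grp %% 2) * het + rnorm(n, 0, 0.05)
    pen <- runif(1, 0.5, 4)
    ours <- hrdscar:::.dp_segment_cpp(y1, y2, as.integer(het), pen)
    expect_equal(ours, oracle_dp(y1, y2, het, pen), info = i)
  }
  # tiny series: full exhaustive enumeration over all changepoint subsets
  for (i in 1:10) {
    n <- sample(5:11, 1)
    y1 <- rnorm(n); y2 <- rnorm(n, 0.6, 0.1); het <- rbinom(n, 1, 0.5)
    pen <- runif(1, 0.2, 2)
    expect_equal(hrdscar:::.dp_segment_cpp(y1, y2, as.integer(het), pen),
                 oracle_dp_exhaustive(y1, y2, het, pen), info = i)
  }
})

test_that("purity/ploidy fit inverts the signal model", {
  b <- default_build()
  m <- make_marker_map(b, 8000, seed = 7)
  p0 <- params_noise_free(seed = 8)

  # unrearranged diploid at purity 1: perfect fit at (1.0, 2.0)
  prof <- do.call(rbind, lapply(seq_len(nrow(b)), function(i)
    data.frame(chrom = b$chrom[i], start = 0, end = b$length[i],
               cn_major = 1, cn_minor = 1)))
  sig <- render_markers(prof, m, 1, p0, seed = 9)
  fit <- fit_purity_ploidy(segment_joint(sig, b))
  expect_equal(fit$purity, 1.0)
  expect_equal(fit$ploidy_grid, 2.0)
  expect_lt(fit$goodness, 1e-12)
  expect_equal(fit$ploidy, 2.0)

  # known purity recovery on a rearranged noise-free sample
  tr <- simulate_truth_profile(b, p0, "hrd", seed = 10)
  sig2 <- render_markers(tr$profile, m, 0.7, p0, seed = 11)
  fit2 <- fit_purity_ploidy(segment_joint(sig2, b))
  expect_lt(abs(fit2$purity - 0.7), 0.05 + 1e-9)
  truth_ploidy <- with(tr$profile,
                       sum((end - start) * (cn_major + cn_minor)) /
                         sum(end - start))
  expect_lt(abs(fit2$ploidy - truth_ploidy), 0.1 + 1e-9)

  # all-homozygous input is uninformative
  sig3 <- sig
  sig3$baf <- round(sig3$baf)
  expect_error(fit_purity_ploidy(segment_joint(sig3, b)), "uninformative")
})

test_that("integer calling rounds, orders and merges", {
  b <- toy_build_1()
  segres <- data.frame(chrom = "chr1",
                       start = c(0, 40e6, 70e6),
                       end = c(40e6, 70e6, 100e6),
                       n_markers = c(400L, 300L, 300L),
                       n_het = c(150L, 120L, 110L),
                       mean_lrr = c(0, 0, 0), mean_baf = c(0.5, 0.5, 0.5),
                       m2_baf = c(0, 0, 0))
  attr(segres, "sigma_baf") <- 0
  fit <- fit_purity_ploidy(segres)
  prof <- call_integer_ascn(segres, fit)
  expect_equal(nrow(prof), 1)                 # merged identical neighbors
  expect_equal(prof$cn_major, 1)
  expect_equal(prof$cn_minor, 1)
  expect_equal(c(prof$start, prof$end), c(0, 100e6))

  # rounding rule: continuous (1.51, 0.49) -> (2, 0)
  expect_equal(pmax(round(c(1.51, 0.49)), 0), c(2, 0))
})

test_that("noise-free pipelines recover truth scores end-to-end", {
  b <- default_build()
  m <- make_marker_map(b, 10000, seed = 12)
  p0 <- params_noise_free(seed = 13)
  for (i in 1:3) {
    tr <- simulate_truth_profile(b, p0, c("stable", "hrd")[1 + i %% 2],
                                 seed = 60 + i)
    sig <- render_markers(tr$profile, m, 1, p0, seed = 70 + i)
    res <- hrd_pipeline(sig, b)
    truth <- score_sample(tr$profile, b)
    expect_equal(res$scores[, c("loh", "tai", "lst", "hrd_sum")],
                 truth[, c("loh", "tai", "lst", "hrd_sum")])
  }
})
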