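# Shared fixtures: small builds and random lattice profiles for oracle tests.
# Profile boundaries are kept on a whole-megabase lattice so that the
# per-megabase counting oracles are exact.

toy_build_1 <- function() make_toy_build(1, 100e6, 0.5)

# random build with integer-Mb centromeres (3 Mb wide)
rand_build <- function(seed, n_chrom = NULL) {
  set.seed(seed)
  if (is.null(n_chrom)) n_chrom <- sample(2:4, 1)
  len_mb <- sample(60:160, n_chrom, replace = TRUE)
  cen_mb <- vapply(len_mb, function(L) sample(seq(20, L - 23), 1), numeric(1))
  genome_build(paste0("chr", seq_len(n_chrom)), len_mb * 1e6,
               cen_mb * 1e6, (cen_mb + 3) * 1e6)
}

# random segment profile on the 1 Mb lattice, <= max_segs segments total
rand_profile <- function(build, seed, max_segs = 30) {
  set.seed(seed)
  states <- list(c(1, 1), c(1, 0), c(2, 0), c(2, 1), c(2, 2), c(3, 1),
                 c(0, 0), c(3, 0), c(4, 2))
  per_chrom <- max(1, floor(max_segs / nrow(build)))
  segs <- lapply(seq_len(nrow(build)), function(ci) {
    L <- build$length[ci] / 1e6
    k <- sample(0:(per_chrom - 1), 1)
    bp <- sort(sample(seq_len(L - 1), k))
    starts <- c(0, bp) * 1e6
    ends <- c(bp, L) * 1e6
    st <- states[sample(length(states), k + 1, replace = TRUE)]
    data.frame(chrom = build$chrom[ci], start = starts, end = ends,
               cn_major = vapply(st, `[`, numeric(1), 1),
               cn_minor = vapply(st, `[`, numeric(1), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

# quiet params for noise-free simulations
params_noise_free <- function(seed = 1L, ...) {
  sim_params(noise_sd_lrr = 0, noise_sd_baf = 0, gc_wave_amplitude = 0,
             purity_range = c(1, 1), seed = seed, ...)
}
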