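#' The prespecified downsampling proportion grid
#'
#' 0.25%, 0.5%, 1%, 2.5%, 5%, 10%, 20%, 30%, 40%, 50%, 60%, 70%, 80%, 90%.
#'
#' @return numeric vector of 14 proportions.
#' @export
downsampling_grid <- function() {
  c(0.0025, 0.005, 0.01, 0.025, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
    0.60, 0.70, 0.80, 0.90)
}

#' Randomly downsample SNP markers
#'
#' Uniform random subset without replacement of `round(proportion * n)`
#' markers, genomic order preserved; deterministic under `seed`.
#'
#' @param signal a `marker_signal`.
#' @param proportion fraction in (0, 1].
#' @param seed integer seed.
#' @return the subset `marker_signal` (attributes preserved).
#' @export
downsample_markers <- function(signal, proportion, seed) {
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0, 1]")
  n <- nrow(signal)
  k <- round(proportion * n)
  if (k >= n) return(signal)
  idx <- sort(.with_seed(seed, sample.int(n, k)))
  if (k < 2 * length(unique(signal$chrom)))
    warning("downsampled to fewer than 2 markers per chromosome on average; ",
            "samples may become unevaluable")
  out <- signal[idx, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample_id", "purity", "class")] <-
    attributes(signal)[c("sample_id", "purity", "class")]
  class(out) <- class(signal)
  out
}

#' Marker-downsampling experiment
#'
#' For every proportion of the grid and each of `n_reps` seeded random
#' replicates, downsamples every sample's markers, reruns the full pipeline
#' (GC correction, joint segmentation, purity/ploidy fit, integer calling,
#' scar scoring) and computes the Spearman correlation of the resulting HRD
#' sums against a fixed reference score over the evaluable samples. Samples
#' whose fit fails (e.g. no heterozygous-informative segment left) are
#' dropped from that replicate's correlation and counted against
#' evaluability. The reported statistic per proportion is the median over the
#' replicates; a replicate with fewer than 3 evaluable reference pairs has an
#' undefined correlation (NA).
#'
#' The optimal proportion is the smallest one maximizing median rho among
#' proportions whose median evaluability is at least `evaluability_floor`.
#'
#' @param signals named list of `marker_signal` objects (full density).
#' @param build a `genome_build`.
#' @param reference named numeric vector of reference scores (names =
#'   sample ids); e.g. truth HRD sums, or the full-density pipeline's own
#'   scores.
#' @param proportions proportion grid (default [downsampling_grid()]).
#' @param n_reps replicates per proportion (default 10).
#' @param base_seed integer; replicate seeds derive deterministically from it
#'   and the (proportion, replicate) pair.
#' @param evaluability_floor minimum median evaluable fraction for a
#'   proportion to be eligible as the optimum.
#' @param penalty,gamma passed to the pipeline stages.
#' @return list of class `downsampling_curve`: `curve` (data.frame
#'   `proportion, rep, rho, evaluable_frac`), `summary` (per-proportion
#'   `median_rho, median_evaluable`), `optimal_proportion`.
#' @export
run_downsampling_experiment <- function(signals, build, reference,
                                        proportions = downsampling_grid(),
                                        n_reps = 10, base_seed = 1L,
                                        evaluability_floor = 0.95,
                                        penalty = NULL, gamma = 0.55) {
  stopifnot(length(signals) > 0, !is.null(names(signals)))
  rows <- list()
  for (p in proportions) {
    for (rep_i in seq_len(n_reps)) {
      hrd <- rep(NA_real_, length(signals))
      names(hrd) <- names(signals)
      for (si in seq_along(signals)) {
        seed <- .derive_seed(base_seed, p * 1e6, rep_i, si)
        sub <- suppressWarnings(downsample_markers(signals[[si]], p, seed))
        res <- tryCatch(
          hrd_pipeline(sub, build, penalty = penalty, gamma = gamma),
          error = function(e) NULL)
        if (!is.null(res)) hrd[si] <- res$scores$hrd_sum
      }
      ok <- !is.na(hrd) & names(hrd) %in% names(reference)
      rho <- if (sum(ok) >= 3 && stats::sd(hrd[ok]) > 0 &&
                 stats::sd(reference[names(hrd)[ok]]) > 0)
        cor(hrd[ok], reference[names(hrd)[ok]], method = "spearman")
      else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        proportion = p, rep = rep_i, rho = rho,
        evaluable_frac = mean(!is.na(hrd)))
    }
  }
  curve <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(curve, curve$proportion), function(d)
    data.frame(proportion = d$proportion[1],
               median_rho = if (all(is.na(d$rho))) NA_real_ else
                 median(d$rho, na.rm = TRUE),
               median_evaluable = median(d$evaluable_frac))))
  summ <- summ[order(summ$proportion), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(curve = curve, summary = summ,
                 optimal_proportion = .select_optimal(summ,
                                                      evaluability_floor)),
            class = "downsampling_curve")
}

# optimal (minimum) proportion: smallest proportion attaining the maximum
# median rho among proportions with evaluability above the floor
.select_optimal <- function(summ, evaluability_floor) {
  eligible <- summ[!is.na(summ$median_rho) &
                     summ$median_evaluable >= evaluability_floor, ,
                   drop = FALSE]
  if (!nrow(eligible)) return(NA_real_)
  best <- max(eligible$median_rho)
  min(eligible$proportion[eligible$median_rho >= best - 1e-12])
}

#' Write a downsampling curve to TSV
#'
#' Replicate rows first, then a summary block (rep = "median") with the
#' per-proportion medians.
#'
#' @param dcurve a `downsampling_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(dcurve, path) {
  cv <- dcurve$curve
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  out <- data.frame(proportion = sprintf("%.4f", cv$proportion),
                    rep = as.character(cv$rep), rho = num(cv$rho),
                    evaluable_frac = num(cv$evaluable_frac))
  sm <- dcurve$summary
  out <- rbind(out, data.frame(proportion = sprintf("%.4f", sm$proportion),
                               rep = "median", rho = num(sm$median_rho),
                               evaluable_frac = num(sm$median_evaluable)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
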