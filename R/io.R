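#' Read and write marker-signal TSV files
#'
#' Tab-delimited, header `chrom pos lrr baf gc`, UTF-8, '.' decimal,
#' positions 0-based. Reals are written with 6 decimals, so write-then-read
#' round-trips values to 6 decimal places and integers exactly. Schema
#' violations are reported with the offending line number (header = line 1).
#'
#' @param path file path.
#' @param sample_id attached to the returned signal.
#' @return `read_marker_tsv` returns a `marker_signal` data.frame.
#' @export
read_marker_tsv <- function(path, sample_id = NULL) {
  d <- .read_tsv_checked(path, c(chrom = "character", pos = "numeric",
                                 lrr = "numeric", baf = "numeric",
                                 gc = "numeric"))
  bad <- which(d$baf < 0 | d$baf > 1 | d$gc < 0 | d$gc > 1 | d$pos < 0)
  if (length(bad))
    stop(path, ": value out of range at line ", bad[1] + 1)
  o <- order(d$chrom, d$pos)
  if (is.unsorted(o)) d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  if (is.null(sample_id))
    sample_id <- sub("\\.tsv$", "", basename(path))
  attr(d, "sample_id") <- sample_id
  class(d) <- c("marker_signal", "data.frame")
  d
}

#' @rdname read_marker_tsv
#' @param signal a `marker_signal`.
#' @export
write_marker_tsv <- function(signal, path) {
  d <- data.frame(chrom = signal$chrom,
                  pos = format(signal$pos, scientific = FALSE, trim = TRUE),
                  lrr = sprintf("%.6f", signal$lrr),
                  baf = sprintf("%.6f", signal$baf),
                  gc = sprintf("%.6f", signal$gc))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SEG-like segment TSV files
#'
#' Tab-delimited allele-specific segment tables with 0-based half-open
#' coordinates (stated in a `#` header comment on write). Columns: `chrom
#' start end cn_major cn_minor` plus optional numeric extras (`n_markers`,
#' `mean_lrr`, ...). Coordinate violations (end <= start, overlap within a
#' chromosome) are validation errors naming the line.
#'
#' @param path file path.
#' @return `read_seg_tsv` returns a segment data.frame.
#' @export
read_seg_tsv <- function(path) {
  d <- .read_tsv_checked(path, c(chrom = "character", start = "numeric",
                                 end = "numeric", cn_major = "numeric",
                                 cn_minor = "numeric"), allow_extra = TRUE)
  bad <- which(d$end <= d$start)
  if (length(bad))
    stop(path, ": end <= start at line ", bad[1] + 1)
  for (ch in unique(d$chrom)) {
    p <- d[d$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop(path, ": overlapping segments on ", ch)
  }
  d
}

#' @rdname read_seg_tsv
#' @param seg a segment data.frame.
#' @export
write_seg_tsv <- function(seg, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# coordinates: 0-based, half-open [start, end)", con)
  d <- seg
  d$start <- format(d$start, scientific = FALSE, trim = TRUE)
  d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  for (col in setdiff(names(d), c("chrom", "start", "end", "cn_major",
                                  "cn_minor", "n_markers", "n_het",
                                  "sample_id")))
    if (is.numeric(d[[col]])) d[[col]] <- sprintf("%.6f", d[[col]])
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write scar-score TSV files
#'
#' Columns `sample_id loh tai lst hrd_sum` plus optional `hrd_status`.
#'
#' @param path file path.
#' @return `read_scores_tsv` returns a data.frame.
#' @export
read_scores_tsv <- function(path) {
  d <- .read_tsv_checked(path, c(sample_id = "character", loh = "numeric",
                                 tai = "numeric", lst = "numeric",
                                 hrd_sum = "numeric"), allow_extra = TRUE)
  bad <- which(d$hrd_sum != d$loh + d$tai + d$lst)
  if (length(bad))
    stop(path, ": hrd_sum != loh + tai + lst at line ", bad[1] + 1)
  d
}

#' @rdname read_scores_tsv
#' @param scores a scar-score data.frame.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared checked TSV reader
.read_tsv_checked <- function(path, schema, allow_extra = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(names(schema), names(d))
  if (length(missing_cols))
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!allow_extra && length(setdiff(names(d), names(schema))))
    stop(path, ": unexpected column(s): ",
         paste(setdiff(names(d), names(schema)), collapse = ", "))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(d[[col]]))
      bad <- which(is.na(v) & !is.na(d[[col]]))
      if (length(bad))
        stop(path, ": malformed value in column '", col, "' at line ",
             bad[1] + 1)
      if (anyNA(v))
        stop(path, ": missing value in column '", col, "' at line ",
             which(is.na(v))[1] + 1)
      d[[col]] <- v
    } else d[[col]] <- as.character(d[[col]])
  }
  d
}

#' Default pipeline configuration
#'
#' Every parameter of the end-to-end pipeline with its documented default.
#' Unknown keys in a user config are rejected (with a nearest-key
#' suggestion). The structure mirrors the pipeline stages: a `simulate` block
#' (the [sim_params()] fields plus `n_markers`, `n_chrom`, `use_default_build`),
#' stage parameters, and a `downsample` block.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "hrdscar_run",
    simulate = list(n_samples = 10, class_mix = 0.5,
                    purity_range = c(0.4, 0.9), base_ploidy = 2,
                    rate_interstitial_loh = 1, rate_telomeric_ai = 1,
                    rate_focal = 2, rate_whole_chrom_loh = 0.5,
                    hrd_multiplier = 10, noise_sd_lrr = 0.15,
                    noise_sd_baf = 0.03, gc_wave_amplitude = 0.1,
                    hom_fraction = 0.6, n_markers = 10000,
                    use_default_build = TRUE, n_chrom = 22,
                    chrom_length = 1e8),
    gamma = 0.55,
    smoother_span = 0.3,
    penalty = NULL,
    het_range = c(0.15, 0.85),
    purity_grid = c(0.10, 1.00, 0.01),
    ploidy_grid = c(1.0, 5.0, 0.05),
    loh_min_mb = 15, lst_flank_mb = 10, lst_filter_mb = 3, tai_min_mb = 0,
    cutoff = 42,
    downsample = list(enabled = FALSE, proportions = downsampling_grid(),
                      n_reps = 10, evaluability_floor = 0.95),
    log_level = "INFO"
  )
}

#' Read a pipeline configuration (JSON)
#'
#' Values present in the file override [default_config()]; unknown keys are
#' rejected with a suggestion for the nearest known key.
#'
#' @param path JSON file; `NULL` returns the defaults.
#' @return validated config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_checked <- function(base, upd, prefix = "") {
    for (key in names(upd)) {
      if (!key %in% names(base)) {
        near <- agrep(key, names(base), max.distance = 0.3, value = TRUE)
        hint <- if (length(near)) paste0(" -- did you mean '", near[1], "'?")
                else ""
        stop("unknown config key '", prefix, key, "'", hint)
      }
      if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
        base[[key]] <- merge_checked(base[[key]], as.list(upd[[key]]),
                                     paste0(prefix, key, "."))
      } else base[[key]] <- upd[[key]]
    }
    base
  }
  merge_checked(cfg, as.list(user))
}

#' Run the full pipeline from a configuration
#'
#' Stage order: simulate cohort, GC correction, joint segmentation,
#' purity/ploidy fit, integer calling, scar scoring, concordance panel
#' against the truth, and (optionally) the downsampling experiment. Writes
#' all artifacts under `config$out_dir`: the simulated cohort, per-sample
#' SEG tables and fit JSONs, `scores.tsv`, `concordance.tsv`, `curve.tsv`
#' and a `manifest.json` recording inputs, parameters, seeds and per-stage
#' row counts. All randomness flows from `config$seed`, so a rerun with the
#' same config is byte-identical.
#'
#' @param config list as returned by [read_config()] / [default_config()].
#' @return the output directory, invisibly.
#' @export
pipeline_run <- function(config = default_config()) {
  cfg <- config
  info <- function(...) if (identical(cfg$log_level, "INFO")) message(...)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- cfg$simulate
  build <- if (isTRUE(sc$use_default_build)) default_build() else
    make_toy_build(sc$n_chrom, sc$chrom_length)
  params <- sim_params(n_samples = sc$n_samples, class_mix = sc$class_mix,
                       purity_range = sc$purity_range,
                       base_ploidy = sc$base_ploidy,
                       rate_interstitial_loh = sc$rate_interstitial_loh,
                       rate_telomeric_ai = sc$rate_telomeric_ai,
                       rate_focal = sc$rate_focal,
                       rate_whole_chrom_loh = sc$rate_whole_chrom_loh,
                       hrd_multiplier = sc$hrd_multiplier,
                       noise_sd_lrr = sc$noise_sd_lrr,
                       noise_sd_baf = sc$noise_sd_baf,
                       gc_wave_amplitude = sc$gc_wave_amplitude,
                       hom_fraction = sc$hom_fraction, gamma = cfg$gamma,
                       seed = cfg$seed)
  map <- make_marker_map(build, sc$n_markers, seed = .derive_seed(cfg$seed, 7))
  info("simulating cohort of ", sc$n_samples, " samples, ", sc$n_markers,
       " markers")
  cohort <- simulate_cohort(build, map, params)
  write_cohort(cohort, file.path(out, "cohort"))
  write_build_tsv(build, file.path(out, "build.tsv"))

  pg <- seq(cfg$purity_grid[1], cfg$purity_grid[2], by = cfg$purity_grid[3])
  qg <- seq(cfg$ploidy_grid[1], cfg$ploidy_grid[2], by = cfg$ploidy_grid[3])
  dir.create(file.path(out, "segments"), showWarnings = FALSE)
  dir.create(file.path(out, "fits"), showWarnings = FALSE)
  scores <- list(); n_fail <- 0
  signals <- list()
  for (s in cohort$samples) {
    signals[[s$sample_id]] <- s$signal
    res <- tryCatch({
      corrected <- gc_correct(s$signal, span = cfg$smoother_span)
      segres <- segment_joint(corrected, build, penalty = cfg$penalty,
                              het_range = cfg$het_range)
      fit <- fit_purity_ploidy(segres, gamma = cfg$gamma, purity_grid = pg,
                               ploidy_grid = qg)
      profile <- call_integer_ascn(segres, fit)
      sscore <- score_sample(profile, build, sample_id = s$sample_id,
                             min_mb = cfg$loh_min_mb,
                             tai_min_mb = cfg$tai_min_mb,
                             flank_mb = cfg$lst_flank_mb,
                             filter_mb = cfg$lst_filter_mb)
      sscore$hrd_status <- classify_hrd(sscore$hrd_sum, cfg$cutoff)
      seg_out <- cbind(sample_id = s$sample_id, profile)
      write_seg_tsv(seg_out, file.path(out, "segments",
                                       paste0(s$sample_id, ".seg.tsv")))
      jsonlite::write_json(
        list(sample_id = s$sample_id, purity = fit$purity,
             ploidy = fit$ploidy, goodness = fit$goodness),
        file.path(out, "fits", paste0(s$sample_id, ".json")),
        auto_unbox = TRUE, digits = 8)
      sscore
    }, error = function(e) {
      info("sample ", s$sample_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_fail <- n_fail + 1 else
      scores[[length(scores) + 1]] <- res
  }
  score_df <- do.call(rbind, scores)
  write_scores_tsv(score_df, file.path(out, "scores.tsv"))
  info("scored ", nrow(score_df), " of ", length(cohort$samples),
       " samples (", n_fail, " unevaluable)")

  reference <- data.frame(sample_id = cohort$cohort$sample_id,
                          score = cohort$cohort$truth_hrd)
  labels <- data.frame(sample_id = cohort$cohort$sample_id,
                       label = as.integer(cohort$cohort$class == "hrd"))
  conc <- suppressMessages(run_concordance_panel(
    list(pipeline = score_df), reference, labels, cutoff = cfg$cutoff))
  num_cols <- vapply(conc, is.numeric, logical(1))
  conc[num_cols] <- lapply(conc[num_cols], function(x)
    ifelse(is.na(x), NA, round(x, 6)))
  write.table(conc, file.path(out, "concordance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$downsample$enabled)) {
    info("running downsampling experiment")
    ref_vec <- stats::setNames(reference$score, reference$sample_id)
    dcurve <- run_downsampling_experiment(
      signals, build, ref_vec, proportions = cfg$downsample$proportions,
      n_reps = cfg$downsample$n_reps,
      base_seed = .derive_seed(cfg$seed, 99),
      evaluability_floor = cfg$downsample$evaluability_floor,
      penalty = cfg$penalty, gamma = cfg$gamma)
    write_curve_tsv(dcurve, file.path(out, "curve.tsv"))
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_samples_simulated = length(cohort$samples),
    n_samples_scored = if (is.null(score_df)) 0L else nrow(score_df),
    n_samples_failed = n_fail,
    n_markers = nrow(map),
    coordinate_convention = "0-based half-open")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, null = "null",
                       pretty = TRUE)
  invisible(out)
}
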