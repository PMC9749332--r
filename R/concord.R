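#' AUROC with confidence interval
#'
#' Area under the ROC curve between continuous scores and binary labels,
#' computed by the Mann-Whitney estimator (ties count one half) via the pROC
#' package with a fixed direction (higher score = positive class), and a 95%
#' CI by the DeLong variance method (pROC's default) or by seeded bootstrap.
#' Following the interpretation convention for this descriptive statistic, the
#' result carries a flag for whether the CI overlaps 0.5.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or two-level factor).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param conf confidence level.
#' @param boot_n bootstrap resamples (bootstrap method only).
#' @param boot_seed seed for the bootstrap resampling.
#' @return list: `estimate`, `ci_low`, `ci_high`, `overlaps_half`, `n`,
#'   `n_positive`.
#' @export
auroc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                  conf = 0.95, boot_n = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  if (length(scores) != length(y) || length(y) < 2)
    stop("scores and labels must have equal length >= 2")
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  est <- as.numeric(r$auc)
  ci <- if (ci_method == "delong") {
    suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf,
                                             method = "delong")))
  } else {
    .with_seed(boot_seed,
      suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf,
                                               method = "bootstrap",
                                               boot.n = boot_n,
                                               progress = "none"))))
  }
  list(estimate = est, ci_low = ci[1], ci_high = ci[3],
       overlaps_half = ci[1] <= 0.5 && ci[3] >= 0.5,
       n = length(y), n_positive = sum(y == 1))
}

.as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2) stop("labels must be binary")
    labels <- as.integer(labels == lv[length(lv)])
    # convention: "positive" > "negative" alphabetically reversed; map
    # explicitly when the two standard words are used
    if (all(lv %in% c("negative", "positive")) && length(lv) == 2)
      labels <- labels  # "positive" sorts last, already the positive class
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise precision-recall integration in the average-precision
#' convention: thresholds at each distinct score (descending), contribution
#' `(recall_k - recall_{k-1}) * precision_k`. The chance baseline is the
#' class prevalence, not 0.5.
#'
#' @inheritParams auroc
#' @return list: `estimate`, `baseline` (prevalence), `n`, `n_positive`.
#' @export
auprc <- function(scores, labels) {
  y <- .as_binary(labels)
  if (length(unique(y)) < 2) stop("degenerate labels: both classes required")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  # group end indices of distinct thresholds
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  k <- grp_end
  prec <- tp / k
  rec <- tp / sum(y)
  ap <- sum(diff(c(0, rec)) * prec)
  list(estimate = ap, baseline = sum(y) / length(y),
       n = length(y), n_positive = sum(y))
}

#' Spearman and Pearson correlations with Fisher-z confidence intervals
#'
#' Spearman rho uses average ranks for ties; both coefficients get a 95% CI
#' by the Fisher z-transform with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @param conf confidence level.
#' @return list with `spearman` and `pearson`, each `estimate, ci_low,
#'   ci_high`, plus `n`.
#' @export
correlations <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  fisher_ci <- function(est) {
    if (abs(est) >= 1) return(c(est, est))
    z <- atanh(est)
    hw <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    tanh(c(z - hw, z + hw))
  }
  rho <- cor(x, y, method = "spearman")
  r <- cor(x, y, method = "pearson")
  list(spearman = list(estimate = rho, ci_low = fisher_ci(rho)[1],
                       ci_high = fisher_ci(rho)[2]),
       pearson = list(estimate = r, ci_low = fisher_ci(r)[1],
                      ci_high = fisher_ci(r)[2]),
       n = n)
}

#' Concordance panel over platforms, metrics and labels
#'
#' For each platform's scar-score table, computes per metric (loh, tai, lst,
#' hrd_sum): AUROC and AUPRC against (a) the supplied binary labels and (b)
#' the reference score dichotomized at `cutoff`, plus Spearman/Pearson
#' correlation of the continuous metric against the continuous reference
#' score. Samples are matched by `sample_id`; samples missing from a platform
#' are dropped pairwise (per-platform evaluable counts are reported via
#' `message()`), never imputed.
#'
#' @param platform_scores named list of scar-score data.frames
#'   (`sample_id, loh, tai, lst, hrd_sum`).
#' @param reference data.frame `sample_id, score` — the continuous reference
#'   metric.
#' @param labels optional data.frame `sample_id, label` (binary); when
#'   `NULL`, only the reference dichotomization is used.
#' @param cutoff clinical cut-off applied to the reference score (default 42).
#' @return data.frame: `platform, metric, comparison, type, estimate, ci_low,
#'   ci_high, baseline, n, n_positive`.
#' @export
run_concordance_panel <- function(platform_scores, reference, labels = NULL,
                                  cutoff = 42) {
  stopifnot(is.list(platform_scores), length(platform_scores) > 0,
            !is.null(names(platform_scores)))
  rows <- list()
  metrics <- c("loh", "tai", "lst", "hrd_sum")
  for (pl in names(platform_scores)) {
    sc <- platform_scores[[pl]]
    ids <- intersect(sc$sample_id, reference$sample_id)
    if (!length(ids)) stop("no overlapping sample ids for platform ", pl)
    message("platform ", pl, ": ", length(ids), " evaluable of ",
            nrow(reference), " reference samples")
    sc <- sc[match(ids, sc$sample_id), , drop = FALSE]
    ref <- reference$score[match(ids, reference$sample_id)]
    comps <- list(reference_cutoff = as.integer(ref >= cutoff))
    if (!is.null(labels)) {
      lab <- labels$label[match(ids, labels$sample_id)]
      comps$label <- .as_binary(lab)
    }
    for (metric in metrics) {
      v <- sc[[metric]]
      for (cname in names(comps)) {
        a <- tryCatch(auroc(v, comps[[cname]]), error = function(e) NULL)
        p <- tryCatch(auprc(v, comps[[cname]]), error = function(e) NULL)
        if (is.null(a) || is.null(p)) {
          message("platform ", pl, ", metric ", metric, " vs ", cname,
                  ": degenerate labels, skipped")
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          platform = pl, metric = metric, comparison = cname,
          type = "auroc", estimate = a$estimate, ci_low = a$ci_low,
          ci_high = a$ci_high, baseline = 0.5, n = a$n,
          n_positive = a$n_positive, stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          platform = pl, metric = metric, comparison = cname,
          type = "auprc", estimate = p$estimate, ci_low = NA_real_,
          ci_high = NA_real_, baseline = p$baseline, n = p$n,
          n_positive = p$n_positive, stringsAsFactors = FALSE)
      }
      cc <- tryCatch(correlations(v, ref), error = function(e) NULL)
      if (is.null(cc)) {
        message("platform ", pl, ", metric ", metric,
                ": constant values, correlation skipped")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        platform = pl, metric = metric, comparison = "reference_continuous",
        type = "spearman", estimate = cc$spearman$estimate,
        ci_low = cc$spearman$ci_low, ci_high = cc$spearman$ci_high,
        baseline = NA_real_, n = cc$n, n_positive = NA_integer_,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        platform = pl, metric = metric, comparison = "reference_continuous",
        type = "pearson", estimate = cc$pearson$estimate,
        ci_low = cc$pearson$ci_low, ci_high = cc$pearson$ci_high,
        baseline = NA_real_, n = cc$n, n_positive = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
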