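test_that("AUROC handles separation, ties and degenerate input", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$estimate, 1.0)
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.4), c(1, 0, 1, 0))$estimate, 0.5)
  expect_equal(auroc(rep(0.7, 6), c(1, 0, 1, 0, 1, 0))$estimate, 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "degenerate")

  a <- auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_true(a$ci_low <= a$estimate && a$estimate <= a$ci_high)
  expect_equal(a$n_positive, 2)

  ab <- auroc(c(3, 1, 2, 0, 5, 4), c(1, 0, 1, 0, 1, 0),
              ci_method = "bootstrap", boot_n = 200, boot_seed = 4)
  expect_true(ab$ci_low <= ab$estimate && ab$estimate <= ab$ci_high)
})

test_that("AUROC matches pair counting and obeys the reflection identity", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    est <- auroc(s, y)$estimate
    expect_equal(est, oracle_auroc(s, y), info = i)
    expect_equal(est + auroc(-s, y)$estimate, 1.0, info = i)
  }
})

test_that("average precision matches hand computation and brute force", {
  r <- auprc(c(0.9, 0.8, 0.3, 0.4), c(1, 0, 1, 0))
  expect_equal(r$estimate, 0.75)
  expect_equal(r$baseline, 0.5)
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$estimate, 1.0)
  # 1 positive of 10 ranked last
  s <- 10:1; y <- c(rep(0, 9), 1)
  r2 <- auprc(s, y)
  expect_equal(r2$estimate, 0.1)
  expect_equal(r2$baseline, 0.1)

  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auprc(s, y)$estimate, oracle_auprc(s, y), info = i)
  }
})

test_that("correlations follow closed forms and Fisher-z intervals", {
  x <- c(1, 3, 4, 7, 9, 12)
  cc <- correlations(x, 2 * x + 1)
  expect_equal(cc$pearson$estimate, 1.0)
  expect_equal(cc$spearman$estimate, 1.0)
  cc2 <- correlations(x, exp(x))
  expect_equal(cc2$spearman$estimate, 1.0)
  expect_lt(cc2$pearson$estimate, 1.0)

  cc3 <- correlations(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(cc3$spearman$estimate, 0.6)
  # Fisher z half-width at n = 4: tanh(atanh(r) +/- 1.96)
  expect_equal(cc3$spearman$ci_low, tanh(atanh(0.6) - qnorm(0.975)))

  expect_error(correlations(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlations(c(1, 2), c(1, 2)))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(22)
  x <- runif(30); y <- runif(30)
  base <- correlations(x, y)$spearman$estimate
  expect_equal(correlations(exp(3 * x), y)$spearman$estimate, base)
  expect_equal(correlations(x, y^3)$spearman$estimate, base)
})

test_that("the concordance panel mirrors the per-metric statistics", {
  set.seed(23)
  n <- 60
  truth <- pmax(0, round(rnorm(n, 30, 25)))
  ids <- sprintf("S%03d", 1:n)
  sc <- data.frame(sample_id = ids,
                   loh = pmax(0, truth %/% 3 + rpois(n, 2)),
                   tai = pmax(0, truth %/% 3 + rpois(n, 2)),
                   lst = pmax(0, truth %/% 3 + rpois(n, 2)))
  sc$hrd_sum <- sc$loh + sc$tai + sc$lst
  ref <- data.frame(sample_id = ids, score = truth)
  lab <- data.frame(sample_id = ids, label = as.integer(truth >= 42))
  tab <- suppressMessages(run_concordance_panel(list(A = sc), ref, lab))
  expect_true(all(c("auroc", "auprc", "spearman", "pearson") %in% tab$type))
  row <- tab[tab$metric == "hrd_sum" & tab$comparison == "reference_cutoff" &
               tab$type == "auroc", ]
  direct <- auroc(sc$hrd_sum, as.integer(truth >= 42))
  expect_equal(row$estimate, direct$estimate)
  expect_equal(row$baseline, 0.5)

  # the reference as its own predictor separates its own dichotomization
  self <- data.frame(sample_id = ids, loh = 0, tai = 0, lst = 0,
                     hrd_sum = truth)
  tab2 <- suppressMessages(run_concordance_panel(list(R = self), ref,
                                                 labels = NULL))
  srow <- tab2[tab2$metric == "hrd_sum" & tab2$type == "auroc", ]
  expect_equal(srow$estimate, 1.0)

  # empty id intersection errors
  bad <- sc; bad$sample_id <- paste0("X", ids)
  expect_error(suppressMessages(run_concordance_panel(list(A = bad), ref)),
               "no overlapping")
})

test_that("random scores give null-level AUROC", {
  set.seed(24)
  hits <- vapply(1:20, function(i) {
    s <- runif(200); y <- rbinom(200, 1, 0.5)
    a <- auroc(s, y)$estimate
    a >= 0.4 && a <= 0.6
  }, logical(1))
  expect_gte(sum(hits), 19)
})
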