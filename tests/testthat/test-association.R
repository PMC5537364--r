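test_that("modal 2x2 tables give an exact two-sided Fisher p of 1", {
  # cohort-characteristics tables whose observed configuration is the
  # most probable one for its margins
  expect_identical(fisher_two_sided(matrix(c(20, 26, 14, 17), 2,
                                           byrow = TRUE)), 1)
  expect_identical(fisher_two_sided(matrix(c(27, 6, 21, 4), 2,
                                           byrow = TRUE)), 1)
  expect_identical(fisher_two_sided(matrix(c(23, 10, 18, 7), 2,
                                           byrow = TRUE)), 1)
})

test_that("extreme diagonal table enumerates to 2/252", {
  expect_equal(fisher_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / 252, tolerance = 1e-12)
})

test_that("Fisher p matches enumeration oracle and reference implementation", {
  n_checked <- 0
  for (seed in 1:60) {
    tabs <- withr::with_seed(seed, {
      replicate(4, matrix(rpois(4, sample(1:8, 1)), 2), simplify = FALSE)
    })
    for (tb in tabs) {
      if (sum(tb) == 0) next
      p <- fisher_two_sided(tb)
      expect_equal(p, oracle_fisher(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                   tolerance = 1e-10)
      if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) {
        expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
      }
      # invariance under transposition and row+column swap
      expect_equal(p, fisher_two_sided(t(tb)), tolerance = 1e-12)
      expect_equal(p, fisher_two_sided(tb[2:1, 2:1]), tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("p is exactly 1 whenever the observed table is modal", {
  for (seed in 1:40) {
    tb <- withr::with_seed(seed, matrix(sample(0:30, 4, replace = TRUE), 2))
    if (sum(tb) == 0) next
    m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
    if (m == 0 || n == 0 || k == 0 || sum(tb[, 2]) == 0) next
    xs <- max(0, k - n):min(k, m)
    modal_a <- xs[which.max(dhyper(xs, m, n, k))]
    modal_tab <- matrix(c(modal_a, m - modal_a, k - modal_a,
                          n - (k - modal_a)), 2, byrow = TRUE)
    expect_identical(fisher_two_sided(modal_tab), 1)
  }
})

test_that("exact test is conservative under label permutation", {
  prof <- c(rep(TRUE, 12), rep(FALSE, 18))
  labels <- c(rep(1, 14), rep(0, 16))
  ps <- withr::with_seed(42, {
    vapply(seq_len(2000), function(i) {
      y <- sample(labels)
      a <- sum(prof & y == 1); b <- sum(prof & y == 0)
      fisher_two_sided(matrix(c(a, b, sum(!prof & y == 1),
                                sum(!prof & y == 0)), 2, byrow = TRUE))
    }, numeric(1))
  })
  expect_lte(mean(ps <= 0.05), 0.05)
  expect_lte(mean(ps <= 0.01), 0.01)
})

test_that("odds ratio uses the cross product with optional zero correction", {
  or <- odds_ratio(matrix(c(44, 6, 25, 7), 2, byrow = TRUE))
  expect_equal(or$estimate, 44 * 7 / (6 * 25))
  expect_equal(odds_ratio(matrix(c(5, 5, 5, 5), 2))$log_or, 0)
  corr <- odds_ratio(matrix(c(10, 0, 5, 5), 2, byrow = TRUE),
                     zero_correction = TRUE)
  expect_equal(corr$estimate, (10.5 * 5.5) / (0.5 * 5.5))
  raw <- odds_ratio(matrix(c(10, 0, 5, 5), 2, byrow = TRUE),
                    zero_correction = FALSE)
  expect_identical(raw$estimate, Inf)
})

test_that("rank AUC counts wins and half-ties, complements swap", {
  expect_equal(rank_auc(c(3, 4), c(1, 2))$auc, 1)
  expect_equal(rank_auc(c(1, 2), c(1, 2))$auc, 0.5)
  expect_equal(rank_auc(c(2, 3, 4), c(1, 2, 3))$auc, 7 / 9)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      a <- sample(1:6, sample(2:6, 1), replace = TRUE)
      b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    })
    expect_equal(rank_auc(a, b)$auc + rank_auc(b, a)$auc, 1)
  }
  expect_error(rank_auc(numeric(), 1:3), "non-empty")
})

test_that("Spearman rho uses mid-ranks and the t approximation", {
  expect_equal(spearman_assoc(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_assoc(1:3, c(30, 20, 10))$rho, -1)
  # mid-rank value for the tied example, cross-checked against cor()
  sp <- spearman_assoc(c(1, 2, 2, 4), c(2, 1, 3, 4))
  expect_equal(sp$rho, 0.6324555, tolerance = 1e-6)
  expect_equal(sp$rho, cor(c(1, 2, 2, 4), c(2, 1, 3, 4),
                           method = "spearman"), tolerance = 1e-12)
  expect_null(spearman_assoc(c(1, 1, 1), 1:3)) # constant: undefined
})

test_that("associate dispatches on feature and outcome type", {
  co <- tiny_corpus(c(c1 = "x", c2 = "x", c3 = "y", c4 = "y"),
                    labels = binary_labels(paste0("c", 1:4), c(1, 1, 0, 0)))
  f <- enumerate_ngrams(co, min_support = 2)
  res <- associate(f, co, "out")
  x_row <- res[res$pattern == "x", ]
  expect_equal(x_row$stat, "OR")
  expect_equal(x_row$estimate, 25) # (2.5 * 2.5) / (0.5 * 0.5)
  expect_equal(x_row$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(x_row$n_used, 4L)

  # binary feature x numeric outcome -> AUC of split outcome values
  co_num <- attach_labels(co, tibble::tibble(
    case_id = paste0("c", 1:4), outcome = "age", value = c(5, 6, 1, 2),
    kind = "numeric"))
  res_num <- associate(f, co_num, "age")
  expect_equal(res_num$stat[res_num$pattern == "x"], "AUC")
  expect_equal(res_num$estimate[res_num$pattern == "x"], 1)

  # numeric feature x binary outcome -> AUC
  co2 <- annotate_numbers(tiny_corpus(
    c(c1 = "v 9 u", c2 = "v 8 u", c3 = "v 1 u", c4 = "v 2 u"),
    labels = binary_labels(paste0("c", 1:4), c(1, 1, 0, 0))))
  nf <- extract_numeric_features(co2, min_support = 2)
  resn <- associate(nf, co2, "out")
  expect_equal(resn$stat[resn$pattern == "v <NUM> u"], "AUC")
  expect_equal(resn$estimate[resn$pattern == "v <NUM> u"], 1)
})

test_that("numeric features use complete cases only", {
  co <- annotate_numbers(tiny_corpus(
    c(c1 = "v 1 u", c2 = "v 2 u", c3 = "none", c4 = "v 9 u")))
  co <- attach_labels(co, tibble::tibble(
    case_id = paste0("c", 1:4), outcome = "sev", value = c(2, 3, 99, 8),
    kind = "numeric"))
  nf <- extract_numeric_features(co, min_support = 2)
  res <- associate(nf, co, "sev")
  row <- res[res$pattern == "v <NUM> u", ]
  expect_equal(row$n_used, 3L)
  expect_equal(row$stat, "rho")
  expect_equal(row$estimate, 1)
})

test_that("degenerate splits are skipped, not reported", {
  co <- tiny_corpus(c(c1 = "z q", c2 = "z q"),
                    labels = binary_labels(c("c1", "c2"), c(1, 0)))
  f <- enumerate_ngrams(co, min_support = 2)
  res <- associate(f, co, "out") # every pattern present in both cases
  expect_equal(nrow(res), 0)
})

test_that("Monte-Carlo RxC test matches the exact 2x2 answer", {
  tb <- matrix(c(12, 3, 4, 11), 2, byrow = TRUE)
  exact <- fisher_two_sided(tb)
  mc <- fisher_rxc_montecarlo(tb, replicates = 1e4, seed = 7)
  se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(mc - exact), 3 * se + 2e-4)
  # all-zero rows are dropped before testing
  tb3 <- rbind(c(3, 4), c(0, 0), c(2, 1))
  expect_equal(fisher_rxc_montecarlo(tb3, replicates = 2e3, seed = 1),
               fisher_rxc_montecarlo(tb3[-2, ], replicates = 2e3, seed = 1))
  # reproducible under the same seed
  expect_identical(fisher_rxc_montecarlo(tb, 2e3, seed = 5),
                   fisher_rxc_montecarlo(tb, 2e3, seed = 5))
})
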