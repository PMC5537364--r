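# Classification of cases from discovered patterns: UPGMA clustering
# decorrelates the (heavily overlapping) features, one representative per
# cluster is kept, and predictive value is estimated by out-of-bag AUC
# over bootstrap resamples in which feature discovery itself is re-run —
# so selection never sees the evaluation cases.

#' Cluster feature occurrence profiles (UPGMA)
#'
#' Average-linkage (UPGMA) agglomerative clustering of the features'
#' occurrence-profile vectors under Euclidean distance, cut into
#' `k = max(2, floor(n_cases / 10))` clusters — roughly one feature per
#' ten cases, which keeps the downstream classifier's covariate count in
#' line with the sample size.
#'
#' @param results Association results (or feature tibble) with a
#'   `profile` list-column.
#' @param n_cases Number of cases, used for the default cut.
#' @param k Override the number of clusters.
#' @return `results` with an integer `cluster` column appended.
#' @export
cluster_features <- function(results, n_cases, k = NULL) {
  if (is.null(k)) k <- max(2L, floor(n_cases / 10))
  nf <- nrow(results)
  if (nf == 0) abort("no features to cluster")
  if (nf <= k) {
    results$cluster <- seq_len(nf) # fewer features than clusters
    return(results)
  }
  x <- do.call(rbind, lapply(results$profile, as.numeric))
  hc <- hclust(dist(x, method = "euclidean"), method = "average")
  results$cluster <- unname(cutree(hc, k = k))
  results
}

#' Pick one representative feature per cluster
#'
#' The feature with the smallest p-value in each cluster; ties broken by
#' larger support, then by pattern rendering.
#'
#' @param clustered Output of [cluster_features()] with a `p_value`
#'   column.
#' @return One row per cluster, ordered by cluster id.
#' @export
select_representatives <- function(clustered) {
  stopifnot(all(c("cluster", "p_value") %in% names(clustered)))
  picks <- clustered %>%
    group_by(.data$cluster) %>%
    arrange(.data$p_value, -.data$support, .data$pattern,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  picks[order(picks$cluster), ]
}

#' Bernoulli naive Bayes with Laplace smoothing
#'
#' Fits class-conditional Bernoulli probabilities with add-one smoothing,
#' `P(x = 1 | y) = (n_{1,y} + 1) / (n_y + 2)`, and unsmoothed class
#' priors. Scores are posterior probabilities of class 1.
#'
#' @param x Binary feature matrix (rows = cases).
#' @param y Binary labels (0/1).
#' @return An object of class `patwas_nb` with a `predict` method.
#' @export
naive_bayes_fit <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  p1 <- (colSums(x[y == 1, , drop = FALSE]) + 1) / (n1 + 2)
  p0 <- (colSums(x[y == 0, , drop = FALSE]) + 1) / (n0 + 2)
  structure(list(prior1 = n1 / (n1 + n0), p1 = p1, p0 = p0),
            class = "patwas_nb")
}

#' @rdname naive_bayes_fit
#' @param object A fitted `patwas_nb`.
#' @param newdata Binary feature matrix to score.
#' @param ... Unused.
#' @export
predict.patwas_nb <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  l1 <- log(object$prior1) +
    x %*% log(object$p1) + (1 - x) %*% log(1 - object$p1)
  l0 <- log(1 - object$prior1) +
    x %*% log(object$p0) + (1 - x) %*% log(1 - object$p0)
  as.numeric(1 / (1 + exp(l0 - l1)))
}

.lr_fit <- function(x, y) {
  d <- as.data.frame(x)
  d$.y <- y
  suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
}
.lr_score <- function(fit, x) {
  suppressWarnings(
    as.numeric(stats::predict(fit, newdata = as.data.frame(x),
                              type = "response")))
}

.resolve_classifier <- function(classifier) {
  if (is.list(classifier)) {
    stopifnot(all(c("fit", "score") %in% names(classifier)))
    return(classifier)
  }
  switch(classifier,
    nb = list(fit = naive_bayes_fit,
              score = function(fit, x) predict(fit, x)),
    lr = list(fit = .lr_fit, score = .lr_score),
    abort(paste("unknown classifier:", classifier))
  )
}

# run discovery + ranking on a (sub)corpus; falls back to the full
# ranked list when nothing passes the threshold, so a resample always
# yields covariates
.discover_for_classification <- function(corpus, outcome, alpha, min_support,
                                         max_len) {
  feats <- enumerate_ngrams(corpus, min_support = min_support,
                            max_len = max_len)
  if (nrow(feats) == 0) return(feats)
  res <- associate(feats, corpus, outcome)
  if (nrow(res) == 0) return(res)
  kept <- filter_threshold(res, alpha)
  if (nrow(kept) == 0) kept <- filter_threshold(res, 1)
  remove_redundant(kept)
}

#' Bootstrap out-of-bag evaluation of pattern-based classification
#'
#' Per run: draw a bootstrap sample of labelled cases with replacement;
#' run feature discovery, threshold filtering, redundancy removal, UPGMA
#' clustering and representative selection on the bootstrap sample ONLY
#' (`nested = TRUE`, the default — out-of-bag labels can then never leak
#' into feature selection); train the classifier on the bootstrap rows;
#' score the out-of-bag cases by re-matching the selected patterns in
#' their documents; record the AUC of out-of-bag scores against labels.
#' A run whose out-of-bag set lacks both classes is redrawn. With
#' `nested = FALSE` features are selected once on all labelled cases (an
#' optimistic variant, provided for comparison).
#'
#' @param corpus A `patwas_corpus`.
#' @param outcome Name of a binary outcome.
#' @param alpha Significance threshold for feature filtering.
#' @param min_support,max_len Passed to [enumerate_ngrams()].
#' @param k Number of feature clusters (default `max(2, floor(N/10))`).
#' @param classifier `"nb"` (built-in Bernoulli naive Bayes), `"lr"`
#'   (logistic regression via [stats::glm()]), or a
#'   `list(fit = function(x, y), score = function(fit, x))` contract.
#' @param n_runs Number of bootstrap runs (default 25).
#' @param seed Integer seed; per-run seeds are derived by a counter.
#' @param nested Re-run feature discovery inside every bootstrap sample.
#' @return A `patwas_bootstrap` object: list with `auc` (per-run vector),
#'   `mean_auc`, `n_runs`, `seed` and the configuration; see
#'   [tidy.patwas_bootstrap()].
#' @export
bootstrap_evaluate <- function(corpus, outcome, alpha = 0.0025,
                               min_support = 2, max_len = Inf, k = NULL,
                               classifier = "nb", n_runs = 25, seed = 1L,
                               nested = TRUE) {
  oc <- corpus_outcome(corpus, outcome)
  if (oc$kind != "binary") abort("bootstrap evaluation needs a binary outcome")
  clf <- .resolve_classifier(classifier)
  ids <- corpus$cases$case_id
  lab <- oc$values[match(ids, names(oc$values))]
  labelled <- sort(ids[!is.na(lab)], method = "radix") # case-order invariant
  y_all <- setNames(lab[match(labelled, ids)], labelled)
  if (length(unique(y_all)) < 2) abort("outcome is constant across cases")

  pooled <- NULL
  if (!nested) {
    pooled <- .discover_for_classification(
      subset_corpus(corpus, labelled), oc, alpha, min_support, max_len)
  }

  aucs <- numeric(n_runs)
  redraws <- 0L
  for (run in seq_len(n_runs)) {
    repeat {
      bag <- withr::with_seed(seed + run + redraws, {
        sample(labelled, length(labelled), replace = TRUE)
      })
      oob <- setdiff(labelled, unique(bag))
      ok <- length(unique(y_all[bag])) == 2 &&
        length(unique(y_all[oob])) == 2
      if (ok) break
      redraws <- redraws + 1L
      if (redraws > 100L) abort("could not draw a usable bootstrap sample")
    }
    bag_corpus <- subset_corpus(corpus, unique(bag))
    res <- if (nested) {
      .discover_for_classification(bag_corpus, oc, alpha, min_support,
                                   max_len)
    } else {
      pooled
    }
    if (nrow(res) == 0) { aucs[run] <- 0.5; next }
    clus <- cluster_features(res, n_cases = length(bag))
    sel <- select_representatives(clus)
    # profiles on the bag corpus (its case order), mapped to bag rows
    bag_ids <- bag_corpus$cases$case_id
    prof_mat <- vapply(sel$pattern, function(p) {
      build_profile(p, bag_corpus)
    }, logical(length(bag_ids)))
    prof_mat <- matrix(as.numeric(prof_mat), nrow = length(bag_ids),
                       dimnames = list(bag_ids, NULL))
    x_train <- prof_mat[bag, , drop = FALSE]
    y_train <- y_all[bag]
    # drop constant columns (invariant covariates carry no signal)
    keep_col <- apply(x_train, 2, function(cc) length(unique(cc)) > 1)
    if (!any(keep_col)) { aucs[run] <- 0.5; next }
    x_train <- x_train[, keep_col, drop = FALSE]
    oob_corpus <- subset_corpus(corpus, oob)
    x_oob <- vapply(sel$pattern[keep_col], function(p) {
      build_profile(p, oob_corpus)
    }, logical(length(oob)))
    x_oob <- matrix(as.numeric(x_oob), nrow = length(oob))
    rownames(x_oob) <- oob_corpus$cases$case_id
    fit <- clf$fit(x_train, unname(y_train))
    scores <- clf$score(fit, x_oob)
    y_oob <- y_all[rownames(x_oob)]
    aucs[run] <- rank_auc(scores[y_oob == 1], scores[y_oob == 0])$auc
  }
  structure(list(
    auc = aucs, mean_auc = mean(aucs), n_runs = n_runs, seed = seed,
    outcome = outcome, alpha = alpha, classifier =
      if (is.character(classifier)) classifier else "custom",
    nested = nested, n_redraws = redraws
  ), class = "patwas_bootstrap")
}

#' @export
print.patwas_bootstrap <- function(x, ...) {
  cat("<patwas_bootstrap> ", x$n_runs, " runs, outcome '", x$outcome,
      "', classifier ", x$classifier, "\n", sep = "")
  cat("  mean out-of-bag AUC: ", format(x$mean_auc, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Per-run bootstrap AUCs
#'
#' @param x A `patwas_bootstrap`.
#' @param ... Unused.
#' @return Tibble with one row per bootstrap run.
#' @method tidy patwas_bootstrap
#' @export
tidy.patwas_bootstrap <- function(x, ...) {
  tibble(run = seq_len(x$n_runs), auc = x$auc)
}

#' One-row bootstrap summary
#'
#' @param x A `patwas_bootstrap`.
#' @param ... Unused.
#' @return Tibble with `n_runs`, `mean_auc`, `sd_auc`, `seed`,
#'   `classifier`, `alpha`, `nested`.
#' @method glance patwas_bootstrap
#' @export
glance.patwas_bootstrap <- function(x, ...) {
  tibble(n_runs = x$n_runs, mean_auc = x$mean_auc,
         sd_auc = stats::sd(x$auc), seed = x$seed,
         classifier = x$classifier, alpha = x$alpha, nested = x$nested)
}
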