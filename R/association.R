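# Univariate non-parametric association statistics between features and
# outcomes: the pattern-wide association scan.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the sum-of-small-probabilities
#' convention: the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (within relative tolerance 1e-7) — the convention of
#' mainstream statistical software. A table with a zero margin carries no
#' information and returns p = 1.
#'
#' @param table A 2x2 matrix of counts `[[a, b], [c, d]]` with rows =
#'   feature present/absent and columns = outcome positive/negative (any
#'   orientation gives the same p).
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' fisher_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))  # 2/252
fisher_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  p0 <- dhyper(a, m, n, k)
  inc <- pr <= p0 * (1 + 1e-7)
  if (all(inc)) return(1) # observed table is modal: exactly 1
  min(1, sum(pr[inc]))
}

# memoised scalar version used by the feature scan (many features share
# the same table)
.fisher_cache <- new.env(parent = emptyenv())
.fisher_p <- function(a, b, c, d) {
  key <- paste(a, b, c, d)
  hit <- .fisher_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- fisher_two_sided(matrix(c(a, b, c, d), 2, byrow = TRUE))
  .fisher_cache[[key]] <- p
  p
}

#' Odds ratio of a 2x2 table
#'
#' Sample (cross-product) odds ratio `ad/bc`. With `zero_correction`
#' (the default) a table containing any zero cell gets 0.5 added to all
#' four cells (Haldane-Anscombe) before computing, keeping the estimate
#' finite. The log odds ratio is the natural log.
#'
#' @param table 2x2 count matrix.
#' @param zero_correction Apply the Haldane-Anscombe correction when any
#'   cell is zero.
#' @return A list with `estimate` and `log_or`.
#' @export
odds_ratio <- function(table, zero_correction = TRUE) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (any(c(a, b, c, d) == 0) && zero_correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a * d) / (b * c) # Inf when bc == 0 and no correction
  list(estimate = est, log_or = log(est))
}

#' Rank AUC and Mann-Whitney test for two value groups
#'
#' AUC is the probability that a random positive-group value exceeds a
#' random negative-group value, with ties counting half. The p-value uses
#' the tie-corrected normal approximation to the Mann-Whitney U statistic
#' with continuity correction.
#'
#' @param group_pos,group_neg Numeric vectors (both non-empty).
#' @return A list with `auc` and `p_value`.
#' @export
#' @examples
#' rank_auc(c(2, 3, 4), c(1, 2, 3))  # auc = 7/9
rank_auc <- function(group_pos, group_neg) {
  n1 <- length(group_pos); n0 <- length(group_neg)
  if (n1 == 0 || n0 == 0) abort("rank_auc: both groups must be non-empty")
  r <- rank(c(group_pos, group_neg))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  p <- suppressWarnings(
    wilcox.test(group_pos, group_neg, exact = FALSE, correct = TRUE)$p.value
  )
  if (is.nan(p)) p <- 1 # all values tied: no evidence
  list(auc = auc, p_value = p)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the
#' p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A list with `rho` and `p_value`, or `NULL` when either vector
#'   is constant (rho undefined).
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NULL)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Monte-Carlo Freeman-Halton exact test for an RxC table
#'
#' Estimates the generalised Fisher exact p-value by sampling
#' `replicates` tables from the fixed-margin null distribution (Patefield
#' algorithm, via [stats::r2dtable()]) and comparing their conditional
#' probabilities with the observed table:
#' `p = (1 + #\{prob <= observed\}) / (replicates + 1)`. All-zero rows or
#' columns are dropped first.
#'
#' @param table An RxC count matrix (R, C >= 2 after dropping empty
#'   rows/columns).
#' @param replicates Number of Monte-Carlo tables (default 1e5).
#' @param seed Integer seed for reproducibility.
#' @return The Monte-Carlo p-value.
#' @export
fisher_rxc_montecarlo <- function(table, replicates = 1e5, seed = 1L) {
  stopifnot(is.matrix(table), all(table >= 0))
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2 || ncol(table) < 2) return(1)
  rs <- rowSums(table); cs <- colSums(table)
  # log conditional probability of a table given margins, up to the
  # margin-only constant (identical across tables, so it cancels)
  lp <- function(m) -sum(lgamma(m + 1))
  obs <- lp(table)
  withr::with_seed(seed, {
    sims <- r2dtable(replicates, rs, cs)
    hits <- sum(vapply(sims, lp, numeric(1)) <= obs + log1p(1e-7))
  })
  (1 + hits) / (replicates + 1)
}

#' Associate features with an outcome
#'
#' The pattern-wide association scan: each feature is tested against the
#' outcome with the statistic matching its type —
#' binary feature x binary outcome: odds ratio + Fisher's exact test;
#' binary feature x numeric outcome: AUC of outcome values split by
#' feature presence + Mann-Whitney test;
#' numeric feature x binary outcome: AUC + Mann-Whitney test;
#' numeric feature x numeric outcome: Spearman's rho.
#' Cases with a missing outcome — and, for numeric features, cases
#' without an extracted value — are excluded (complete-case analysis);
#' `n_used` records the cases actually tested. Features with a degenerate
#' split (all informative cases on one side) are skipped.
#'
#' Raw p-values are reported without multiple-testing correction:
#' exhaustively enumerated patterns are heavily dependent, so
#' Bonferroni/Benjamini-Hochberg-style corrections are not meaningful
#' here; `bh = TRUE` appends an optional reference `p_bh` column.
#'
#' @param features Feature tibble from [enumerate_ngrams()],
#'   [enumerate_tagged_patterns()] or [extract_numeric_features()] (or a
#'   row-bound combination).
#' @param corpus The `patwas_corpus` the features were computed on.
#' @param outcome An outcome name (looked up in the corpus labels) or the
#'   value of [corpus_outcome()].
#' @param zero_correction Haldane-Anscombe correction for the odds ratio.
#' @param bh Also report Benjamini-Hochberg adjusted p-values.
#' @return A tibble with columns `pattern`, `type`, `stat` (`"OR"`,
#'   `"AUC"` or `"rho"`), `estimate`, `log_or`, `p_value`, `support`,
#'   `n_used`, `direction`, plus the feature `profile`/`values` columns
#'   (kept so downstream reduction and clustering need no re-matching).
#' @export
associate <- function(features, corpus, outcome, zero_correction = TRUE,
                      bh = FALSE) {
  if (is.character(outcome)) outcome <- corpus_outcome(corpus, outcome)
  ids <- corpus$cases$case_id
  lab <- outcome$values[match(ids, names(outcome$values))]
  labelled <- !is.na(lab)
  if (sum(labelled) < 2 || length(unique(lab[labelled])) < 2) {
    abort(paste0("outcome '", outcome$name,
                 "' has fewer than 2 distinct values among labelled cases"))
  }
  binary_outcome <- outcome$kind == "binary"
  is_num_feat <- features$type == "numeric"

  parts <- list()

  # binary features x binary outcome: fully vectorised 2x2 path with a
  # memoised Fisher p per distinct table
  bin_idx <- which(!is_num_feat)
  if (length(bin_idx) > 0 && binary_outcome) {
    pm <- vapply(features$profile[bin_idx], function(p) p[labelled],
                 logical(sum(labelled)))
    pm <- matrix(pm, ncol = length(bin_idx))
    y <- lab[labelled]
    a <- as.integer(colSums(pm[y == 1, , drop = FALSE]))
    b <- as.integer(colSums(pm[y == 0, , drop = FALSE]))
    c <- sum(y == 1) - a
    d <- sum(y == 0) - b
    ok <- (a + b) > 0 & (c + d) > 0 # non-degenerate split
    if (any(ok)) {
      aa <- a[ok]; bb <- b[ok]; cc <- c[ok]; dd <- d[ok]
      corr <- zero_correction & (aa == 0 | bb == 0 | cc == 0 | dd == 0)
      est <- ((aa + 0.5 * corr) * (dd + 0.5 * corr)) /
        ((bb + 0.5 * corr) * (cc + 0.5 * corr))
      p <- vapply(seq_along(aa), function(i) {
        .fisher_p(aa[i], bb[i], cc[i], dd[i])
      }, numeric(1))
      sel <- bin_idx[ok]
      parts[[length(parts) + 1L]] <- tibble(
        pattern = features$pattern[sel], type = features$type[sel],
        stat = "OR", estimate = est, log_or = log(est), p_value = p,
        support = features$support[sel], n_used = sum(labelled),
        direction = sign(log(est)), profile = features$profile[sel]
      )
    }
  }

  # binary features x numeric outcome: AUC of outcome split by presence
  if (length(bin_idx) > 0 && !binary_outcome) {
    for (i in bin_idx) {
      prof <- features$profile[[i]]
      f <- prof[labelled]; y <- lab[labelled]
      if (length(unique(f)) < 2) next
      ra <- rank_auc(y[f], y[!f])
      parts[[length(parts) + 1L]] <- tibble(
        pattern = features$pattern[i], type = features$type[i],
        stat = "AUC", estimate = ra$auc, log_or = NA_real_,
        p_value = ra$p_value, support = features$support[i],
        n_used = sum(labelled), direction = sign(ra$auc - 0.5),
        profile = features$profile[i]
      )
    }
  }

  # numeric features: complete-case analysis over cases with a value
  for (i in which(is_num_feat)) {
    vals <- features$values[[i]]
    use_ids <- intersect(names(vals), ids[labelled])
    n_used <- length(use_ids)
    if (n_used < 2) next
    v <- vals[use_ids]
    y <- lab[match(use_ids, ids)]
    if (binary_outcome) {
      if (length(unique(y)) < 2) next
      ra <- rank_auc(v[y == 1], v[y == 0])
      parts[[length(parts) + 1L]] <- tibble(
        pattern = features$pattern[i], type = features$type[i],
        stat = "AUC", estimate = ra$auc, log_or = NA_real_,
        p_value = ra$p_value, support = features$support[i],
        n_used = n_used, direction = sign(ra$auc - 0.5),
        profile = features$profile[i], values = features$values[i]
      )
    } else {
      if (n_used < 3) next
      sp <- spearman_assoc(unname(v), unname(y))
      if (is.null(sp)) next
      parts[[length(parts) + 1L]] <- tibble(
        pattern = features$pattern[i], type = features$type[i],
        stat = "rho", estimate = sp$rho, log_or = NA_real_,
        p_value = sp$p_value, support = features$support[i],
        n_used = n_used, direction = sign(sp$rho),
        profile = features$profile[i], values = features$values[i]
      )
    }
  }

  res <- bind_rows(parts)
  if (nrow(res) == 0) {
    res <- tibble(pattern = character(), type = character(),
                  stat = character(), estimate = numeric(),
                  log_or = numeric(), p_value = numeric(),
                  support = integer(), n_used = integer(),
                  direction = numeric(), profile = list())
  }
  if (bh) res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res
}
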