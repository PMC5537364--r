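# End-to-end discovery orchestration and result writers.

#' Run the full pattern-discovery pipeline
#'
#' annotate -> enumerate -> associate -> filter -> reduce ->
#' (optionally) induce regexes and re-score. The returned object is a
#' ranked tibble of association results carrying its configuration and
#' per-stage counts as attributes.
#'
#' Induced regexes are ranked among the n-gram results without a second
#' threshold pass: an induced expression is reported even when its p is
#' worse than its best member, so overfitted aggregates remain visible
#' (and flagged via `informative`) rather than silently dropped.
#'
#' @param corpus A `patwas_corpus`.
#' @param outcome Outcome name.
#' @param annotate Character subset of `c("num", "stem")`: built-in
#'   token-level annotators to run. POS tags and parse groups come from
#'   [apply_preannotations()] / [annotate_parse_groups()] applied
#'   beforehand.
#' @param vocabulary Optional vocabulary data frame for
#'   [annotate_vocabulary()] (applied destructively).
#' @param min_support,max_len Passed to [enumerate_ngrams()].
#' @param tagged Also run the combinatorial token/tag search
#'   (annotations are pruned first).
#' @param tagged_max_len Length cap for the tagged search.
#' @param numeric_features Extract `A <NUM> B` features (runs the number
#'   annotator implicitly).
#' @param max_flank_len Flank cap for numeric features.
#' @param alpha Significance threshold.
#' @param regex_induction Consolidate and re-score token regexes.
#' @param keep_ties Passed to [remove_redundant()].
#' @return A `patwas_results` tibble (see [associate()] for columns),
#'   ranked by ascending p.
#' @export
discover <- function(corpus, outcome, annotate = "num", vocabulary = NULL,
                     min_support = 2, max_len = Inf, tagged = FALSE,
                     tagged_max_len = 5, numeric_features = TRUE,
                     max_flank_len = 3, alpha = 0.0025,
                     regex_induction = TRUE, keep_ties = TRUE) {
  oc <- corpus_outcome(corpus, outcome)
  if (!is.null(vocabulary)) {
    corpus <- annotate_vocabulary(corpus, vocabulary)
  }
  if ("num" %in% annotate || numeric_features) {
    corpus <- annotate_numbers(corpus)
  }
  if ("stem" %in% annotate) corpus <- annotate_stems(corpus)

  counts <- list()
  feats <- enumerate_ngrams(corpus, min_support = min_support,
                            max_len = max_len)
  counts$ngrams <- nrow(feats)
  if (tagged) {
    corpus <- prune_annotations(corpus)
    counts$tags_pruned <- attr(corpus, "n_pruned")
    tg <- enumerate_tagged_patterns(corpus, min_support = min_support,
                                    max_len = tagged_max_len)
    counts$tagged <- nrow(tg)
    feats <- bind_rows(feats, tg)
  }
  if (numeric_features) {
    nf <- extract_numeric_features(corpus, max_flank_len = max_flank_len,
                                   min_support = min_support)
    counts$numeric <- nrow(nf)
    feats <- bind_rows(feats, nf)
  }
  if (nrow(feats) == 0) {
    warn("no features generated")
    res <- associate(feats[0, ], corpus, oc)
  } else {
    res <- associate(feats, corpus, oc)
  }
  counts$tested <- nrow(res)
  res <- filter_threshold(res, alpha)
  counts$past_threshold <- nrow(res)
  res <- remove_redundant(res, keep_ties = keep_ties)
  counts$redundant_removed <- attr(res, "n_removed")
  if (regex_induction && nrow(res) > 0) {
    res <- induce_and_rescore(res, corpus, oc)
    counts$regexes <- sum(res$type == "regex")
  }
  if (nrow(res) == 0) warn("no features past the significance threshold")
  structure(
    res,
    class = c("patwas_results", class(res)),
    config = list(outcome = outcome, annotate = annotate,
                  min_support = min_support, max_len = max_len,
                  tagged = tagged, numeric_features = numeric_features,
                  max_flank_len = max_flank_len, alpha = alpha,
                  regex_induction = regex_induction),
    counts = counts
  )
}

#' @export
print.patwas_results <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- attr(x, "counts")
  cat("<patwas_results> outcome '", cfg$outcome, "', alpha ", cfg$alpha,
      "\n", sep = "")
  cat("  ", paste(names(counts), unlist(counts), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  print(as_tibble(x))
  invisible(x)
}

#' Flat tidy view of discovery results
#'
#' @param x A `patwas_results`.
#' @param ... Unused.
#' @return The ranked result tibble without list-columns.
#' @method tidy patwas_results
#' @export
tidy.patwas_results <- function(x, ...) {
  keep <- setdiff(names(x), c("profile", "values"))
  out <- as_tibble(x)[, keep]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(keep, "rank"))]
}

#' One-row summary of a discovery run
#'
#' @param x A `patwas_results`.
#' @param ... Unused.
#' @return Tibble with stage counts and the configuration echo.
#' @method glance patwas_results
#' @export
glance.patwas_results <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- attr(x, "counts")
  tibble(
    outcome = cfg$outcome, alpha = cfg$alpha,
    n_ngrams = counts$ngrams %||% 0L,
    n_numeric = counts$numeric %||% 0L,
    n_tested = counts$tested %||% 0L,
    n_past_threshold = counts$past_threshold %||% 0L,
    n_regexes = counts$regexes %||% 0L,
    n_reported = nrow(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ranked results table writer
#'
#' TSV columns: `rank pattern pattern_type stat estimate log_or p_value
#' support n_used direction`, preceded by `#`-prefixed header lines
#' echoing the configuration for provenance.
#'
#' @param results A `patwas_results` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- tidy.patwas_results(results)
  out <- rename(out, pattern_type = "type")
  cfg <- attr(results, "config")
  hdr <- if (!is.null(cfg)) {
    paste0("# ", names(cfg), " = ",
           vapply(cfg, function(v) paste(v, collapse = ","), ""))
  } else {
    character()
  }
  writeLines(c(hdr, paste(names(out), collapse = "\t")), path)
  readr::write_tsv(out, path, col_names = FALSE, append = TRUE)
  invisible(path)
}

#' Volcano table of association results
#'
#' One row per result: `x` is the effect size (log OR for OR results,
#' `AUC - 0.5` for AUC results, rho for correlations), `y` is
#' `-log10(p)`. A p of exactly 0 is clamped to the smallest positive
#' double and flagged in `clamped`.
#'
#' @param results Association results.
#' @return Tibble `pattern, type, x, y, support, clamped`.
#' @export
volcano_table <- function(results) {
  res <- as_tibble(results)
  if (nrow(res) == 0) {
    return(tibble(pattern = character(), type = character(), x = numeric(),
                  y = numeric(), support = integer(), clamped = logical()))
  }
  x <- ifelse(res$stat == "OR", res$log_or,
              ifelse(res$stat == "AUC", res$estimate - 0.5, res$estimate))
  clamped <- res$p_value == 0
  p <- ifelse(clamped, .Machine$double.xmin, res$p_value)
  tibble(pattern = res$pattern, type = res$type, x = x, y = -log10(p),
         support = res$support, clamped = clamped)
}

#' @rdname volcano_table
#' @param path Output TSV path.
#' @export
write_volcano <- function(results, path) {
  readr::write_tsv(volcano_table(results), path)
  invisible(path)
}

#' Volcano plot of discovery results
#'
#' Effect size against `-log10(p)`, point size proportional to support,
#' shape distinguishing n-gram fragments from induced regexes.
#'
#' @param object A `patwas_results`.
#' @param label_alpha Label points with `p` below this threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot patwas_results
#' @export
autoplot.patwas_results <- function(object, label_alpha = 0.002, ...) {
  v <- volcano_table(object)
  gg <- ggplot2::ggplot(v, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$support,
                                     shape = .data$type),
                        alpha = 0.7) +
    ggplot2::scale_shape_manual(
      values = c(ngram = 16, tagged = 17, numeric = 15, regex = 18)) +
    ggplot2::labs(x = "effect (log OR / AUC - 0.5 / rho)",
                  y = expression(-log[10](p)),
                  size = "support", shape = "feature type") +
    ggplot2::theme_minimal()
  lab <- v[v$y > -log10(label_alpha), ]
  if (nrow(lab) > 0) {
    gg <- gg + ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$pattern),
      vjust = -0.6, size = 2.6, check_overlap = TRUE)
  }
  gg
}
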