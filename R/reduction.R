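# Threshold filtering and redundancy removal. The significance threshold
# is deliberately an investigator-set parameter: exhaustively enumerated
# patterns are not independent tests, so no automatic correction is
# applied (see the methods vignette).

#' Filter association results by a significance threshold
#'
#' Retains results with `p_value <= alpha`, sorted by ascending p; ties
#' broken by effect size (|log OR|, or |AUC - 0.5|, or |rho|) descending,
#' then by pattern rendering.
#'
#' @param results Tibble from [associate()].
#' @param alpha Significance threshold in (0, 1]. The default 0.0025
#'   matches the order of magnitude at which discovered clinical patterns
#'   separate cleanly from noise in corpora of ~100 cases; it should be
#'   chosen per analysis.
#' @return The filtered, ranked tibble.
#' @export
filter_threshold <- function(results, alpha = 0.0025) {
  stopifnot(alpha > 0, alpha <= 1)
  res <- results[!is.na(results$p_value) & results$p_value <= alpha, ]
  if (nrow(res) == 0) return(res)
  effect <- ifelse(res$stat == "OR", abs(res$log_or),
                   ifelse(res$stat == "AUC", abs(res$estimate - 0.5),
                          abs(res$estimate)))
  res[order(res$p_value, -effect, res$pattern, method = "radix"), ]
}

#' Remove features made redundant by longer patterns
#'
#' Within each group of features sharing a bit-identical occurrence
#' profile, only the longest patterns are kept: a short fragment carries
#' no information beyond the longer, more specific phrase occurring in
#' exactly the same cases, and the longer phrase is the more interpretable
#' one. Association statistics are untouched — they depend only on the
#' profile, which is preserved.
#'
#' @param features A feature or association tibble with `pattern` and
#'   `profile` columns (binary features; rows of type `"numeric"` are
#'   passed through untouched).
#' @param keep_ties Keep all equal-length longest patterns of a profile
#'   group (default); otherwise keep the lexicographically first.
#' @return The reduced tibble, with the number of removed rows in
#'   `attr(, "n_removed")`.
#' @export
remove_redundant <- function(features, keep_ties = TRUE) {
  if (nrow(features) == 0) {
    attr(features, "n_removed") <- 0L
    return(features)
  }
  binary <- features$type != "numeric"
  n_len <- if ("n_len" %in% names(features)) {
    features$n_len
  } else {
    vapply(features$pattern, function(p) length(.parse_elements(p)),
           integer(1), USE.NAMES = FALSE)
  }
  key <- vapply(features$profile, function(p) paste(as.integer(p),
                                                    collapse = ""),
                character(1))
  keep <- rep(TRUE, nrow(features))
  for (k in unique(key[binary])) {
    idx <- which(binary & key == k)
    if (length(idx) < 2) next
    maxlen <- max(n_len[idx])
    longest <- idx[n_len[idx] == maxlen]
    if (!keep_ties && length(longest) > 1) {
      longest <- longest[order(features$pattern[longest],
                               method = "radix")][1]
    }
    keep[setdiff(idx, longest)] <- FALSE
  }
  out <- features[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}
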