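# Synthetic corpora with known statistical structure. Background tokens
# are i.i.d. Zipf draws over an artificial vocabulary; planted phrases
# are inserted with class-conditional probabilities, so every downstream
# stage (search, association, induction, classification) can be tested
# against exact ground truth without any patient data.

#' Specification of a synthetic case-labelled corpus
#'
#' The defaults describe the reference validation conditions used
#' throughout the test-suite: 80 cases, balanced classes, one document of
#' four sentences each, a 60-token Zipf(1.1) background vocabulary, one
#' planted binary phrase at within-class insertion probabilities 0.8 vs
#' 0.1 and one planted numeric pattern with class means 20 vs 10 (sd 3).
#' Planted tokens are reserved out-of-vocabulary strings by default so
#' ground-truth counts are unambiguous; `collide = TRUE` mixes them into
#' the background vocabulary for realism.
#'
#' @param n_cases Number of cases.
#' @param docs_per_case,sentences_per_doc Corpus shape.
#' @param sentence_len Length bounds (uniform) of background sentences,
#'   in tokens.
#' @param vocab_size Background vocabulary size (>= 10).
#' @param zipf_exponent Zipf exponent of background token frequencies.
#' @param class_balance Fraction of class-1 cases.
#' @param binary_patterns Data frame `pattern` (space-joined tokens),
#'   `p1`, `p0` (insertion probability per class-1/class-0 case).
#' @param numeric_patterns Data frame `left`, `right` (flank phrases),
#'   `mean1`, `mean0`, `sd` (per-class value distribution), and
#'   optionally `p1`, `p0` (insertion probabilities, default 1).
#' @param collide Draw background tokens from a vocabulary that includes
#'   the planted tokens.
#' @param seed Mandatory integer seed.
#' @return A `patwas_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cases = 80, docs_per_case = 1,
                           sentences_per_doc = 4, sentence_len = c(6, 12),
                           vocab_size = 60, zipf_exponent = 1.1,
                           class_balance = 0.5,
                           binary_patterns = tibble(
                             pattern = "hxa hxb", p1 = 0.8, p0 = 0.1),
                           numeric_patterns = tibble(
                             left = "qleft", right = "qright",
                             mean1 = 20, mean0 = 10, sd = 3),
                           collide = FALSE, seed) {
  if (missing(seed)) abort("a seed is mandatory for synthetic corpora")
  stopifnot(vocab_size >= 10, n_cases >= 2,
            length(sentence_len) == 2, sentence_len[1] <= sentence_len[2],
            class_balance >= 0, class_balance <= 1)
  binary_patterns <- as_tibble(binary_patterns)
  numeric_patterns <- as_tibble(numeric_patterns)
  if (nrow(binary_patterns) > 0) {
    stopifnot(all(binary_patterns$p1 >= 0 & binary_patterns$p1 <= 1),
              all(binary_patterns$p0 >= 0 & binary_patterns$p0 <= 1))
  }
  if (nrow(numeric_patterns) > 0) {
    if (!"p1" %in% names(numeric_patterns)) numeric_patterns$p1 <- 1
    if (!"p0" %in% names(numeric_patterns)) numeric_patterns$p0 <- 1
  }
  structure(list(
    n_cases = n_cases, docs_per_case = docs_per_case,
    sentences_per_doc = sentences_per_doc, sentence_len = sentence_len,
    vocab_size = vocab_size, zipf_exponent = zipf_exponent,
    class_balance = class_balance, binary_patterns = binary_patterns,
    numeric_patterns = numeric_patterns, collide = collide, seed = seed
  ), class = "patwas_synthetic_spec")
}

#' Generate a synthetic corpus with planted associations
#'
#' Background tokens are drawn i.i.d. from a Zipf distribution over the
#' vocabulary; each planted binary pattern is independently inserted as a
#' contiguous phrase at a random sentence position with its
#' class-conditional probability; numeric patterns are inserted as
#' `left <value> right` with the value drawn
#' Normal(mean_class, sd) and rounded to one decimal. The ground-truth
#' table lists every planted pattern with its realised per-class
#' insertion counts and the implied (Haldane-corrected when needed) log
#' odds ratio.
#'
#' @param spec A [synthetic_spec()].
#' @param build_corpus Tokenise the rendered documents into a
#'   `patwas_corpus` (set `FALSE` when only the ground truth is needed,
#'   e.g. for calibration simulations over many seeds).
#' @return A list with `corpus` (a `patwas_corpus`, outcome `"class"`, or
#'   `NULL`), `docs` (document text tibble), `labels`, and `truth`.
#' @export
generate_corpus <- function(spec, build_corpus = TRUE) {
  stopifnot(inherits(spec, "patwas_synthetic_spec"))
  vocab <- sprintf("w%03d", seq_len(spec$vocab_size))
  planted_toks <- unique(c(
    unlist(strsplit(spec$binary_patterns$pattern, " ", fixed = TRUE)),
    unlist(strsplit(spec$numeric_patterns$left, " ", fixed = TRUE)),
    unlist(strsplit(spec$numeric_patterns$right, " ", fixed = TRUE))
  ))
  if (!spec$collide && any(planted_toks %in% vocab)) {
    warn("planted tokens collide with the background vocabulary; ground-truth counts may be diluted")
  }
  bg <- if (spec$collide) unique(c(vocab, planted_toks)) else vocab
  prob <- seq_along(bg)^(-spec$zipf_exponent)
  prob <- prob / sum(prob)

  withr::with_seed(spec$seed, {
    n1 <- round(spec$n_cases * spec$class_balance)
    cls <- sample(c(rep(1, n1), rep(0, spec$n_cases - n1)))
    ids <- sprintf("case%03d", seq_len(spec$n_cases))

    nb <- nrow(spec$binary_patterns)
    nq <- nrow(spec$numeric_patterns)
    bin_hits <- matrix(FALSE, spec$n_cases, max(nb, 1))
    num_hits <- matrix(FALSE, spec$n_cases, max(nq, 1))
    num_vals <- matrix(NA_real_, spec$n_cases, max(nq, 1))

    docs <- vector("list", spec$n_cases)
    for (i in seq_len(spec$n_cases)) {
      sents <- list()
      for (d in seq_len(spec$docs_per_case)) {
        for (s in seq_len(spec$sentences_per_doc)) {
          len <- spec$sentence_len[1] +
            sample.int(spec$sentence_len[2] - spec$sentence_len[1] + 1L,
                       1) - 1L
          sents[[length(sents) + 1L]] <- sample(bg, len, replace = TRUE,
                                                prob = prob)
        }
      }
      insert_phrase <- function(phrase) {
        s <- sample(length(sents), 1)
        at <- sample(0:length(sents[[s]]), 1)
        sents[[s]] <<- append(sents[[s]], phrase, after = at)
      }
      if (nb > 0) {
        for (b in seq_len(nb)) {
          p <- if (cls[i] == 1) spec$binary_patterns$p1[b] else
            spec$binary_patterns$p0[b]
          if (runif(1) < p) {
            insert_phrase(strsplit(spec$binary_patterns$pattern[b], " ",
                                   fixed = TRUE)[[1]])
            bin_hits[i, b] <- TRUE
          }
        }
      }
      if (nq > 0) {
        for (q in seq_len(nq)) {
          p <- if (cls[i] == 1) spec$numeric_patterns$p1[q] else
            spec$numeric_patterns$p0[q]
          if (runif(1) < p) {
            mu <- if (cls[i] == 1) spec$numeric_patterns$mean1[q] else
              spec$numeric_patterns$mean0[q]
            v <- round(rnorm(1, mu, spec$numeric_patterns$sd[q]), 1)
            insert_phrase(c(
              strsplit(spec$numeric_patterns$left[q], " ", fixed = TRUE)[[1]],
              sprintf("%.1f", v),
              strsplit(spec$numeric_patterns$right[q], " ",
                       fixed = TRUE)[[1]]
            ))
            num_hits[i, q] <- TRUE
            num_vals[i, q] <- v
          }
        }
      }
      # render documents: sentences terminated by ". "
      per_doc <- split(sents, rep(seq_len(spec$docs_per_case),
                                  each = spec$sentences_per_doc))
      docs[[i]] <- tibble(
        case_id = ids[i],
        doc_id = sprintf("%s_d%02d", ids[i], seq_len(spec$docs_per_case)),
        doc_type = "other",
        text = vapply(per_doc, function(ss) {
          paste(vapply(ss, function(tk) paste(c(tk, "."), collapse = " "),
                       character(1)), collapse = " ")
        }, character(1))
      )
    }
  })

  docs <- bind_rows(docs)
  labels <- tibble(case_id = ids, outcome = "class", value = cls,
                   kind = "binary")
  corpus <- if (build_corpus) corpus_from_texts(docs, labels = labels) else NULL

  truth <- list()
  if (nb > 0) {
    for (b in seq_len(nb)) {
      a <- sum(bin_hits[cls == 1, b]); cc <- sum(bin_hits[cls == 0, b])
      truth[[length(truth) + 1L]] <- tibble(
        pattern = spec$binary_patterns$pattern[b], type = "binary",
        n1_with = a, n1_total = sum(cls == 1),
        n0_with = cc, n0_total = sum(cls == 0),
        log_or = odds_ratio(matrix(c(a, sum(cls == 1) - a,
                                     cc, sum(cls == 0) - cc),
                                   2, byrow = TRUE))$log_or
      )
    }
  }
  if (nq > 0) {
    for (q in seq_len(nq)) {
      truth[[length(truth) + 1L]] <- tibble(
        pattern = paste(spec$numeric_patterns$left[q], "<NUM>",
                        spec$numeric_patterns$right[q]),
        type = "numeric",
        n1_with = sum(num_hits[cls == 1, q]), n1_total = sum(cls == 1),
        n0_with = sum(num_hits[cls == 0, q]), n0_total = sum(cls == 0),
        log_or = NA_real_
      )
    }
  }
  list(corpus = corpus, docs = docs, labels = labels,
       truth = bind_rows(truth))
}

#' Write a generated corpus to disk
#'
#' Emits `manifest.tsv`, `labels.tsv`, one text file per document under
#' `docs/`, and `truth.json` — the on-disk layout [read_corpus()]
#' ingests.
#'
#' @param sim Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_files <- function(sim, dir) {
  dir.create(file.path(dir, "docs"), recursive = TRUE, showWarnings = FALSE)
  manifest <- sim$docs %>%
    mutate(path = file.path("docs", paste0(.data$doc_id, ".txt"))) %>%
    select("case_id", "doc_id", "doc_type", "path")
  for (i in seq_len(nrow(sim$docs))) {
    writeLines(sim$docs$text[i],
               file.path(dir, manifest$path[i]), useBytes = TRUE)
  }
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$labels, file.path(dir, "labels.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
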