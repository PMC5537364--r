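# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (quadratic scans, exhaustive enumeration) and share
# no code with the implementation paths they check.

# quick corpus from a named character vector: one case per element, one
# document each
tiny_corpus <- function(texts, labels = NULL) {
  docs <- tibble::tibble(
    case_id = names(texts),
    doc_id = paste0(names(texts), "_d1"),
    doc_type = "other",
    text = unname(texts)
  )
  corpus_from_texts(docs, labels = labels)
}

binary_labels <- function(ids, values, outcome = "out") {
  tibble::tibble(case_id = ids, outcome = outcome, value = values,
                 kind = "binary")
}

# random corpus over a small alphabet; sentences terminated "."
random_corpus <- function(n_cases, n_sent = 2, sent_len = 10,
                          alphabet = letters[1:6], seed = 1) {
  withr::with_seed(seed, {
    texts <- vapply(seq_len(n_cases), function(i) {
      paste(vapply(seq_len(n_sent), function(s) {
        paste(c(sample(alphabet, sent_len, replace = TRUE), "."),
              collapse = " ")
      }, character(1)), collapse = " ")
    }, character(1))
  })
  names(texts) <- sprintf("c%02d", seq_len(n_cases))
  tiny_corpus(texts)
}

# per-sentence token lists of a corpus, with case index
corpus_sentences <- function(corpus) {
  sids <- unique(corpus$tokens$sent_id)
  lapply(sids, function(s) {
    rows <- corpus$tokens[corpus$tokens$sent_id == s, ]
    rows <- rows[order(rows$pos), ]
    case <- corpus$sentences$case_id[corpus$sentences$sent_id == s]
    list(tokens = rows$surface, tags = rows$tags,
         case = match(case, corpus$cases$case_id))
  })
}

# brute-force n-gram enumeration: every sentence substring, case-support
# filtered
oracle_ngrams <- function(corpus, min_support = 2, max_len = Inf) {
  sents <- corpus_sentences(corpus)
  rows <- list()
  for (s in sents) {
    n <- length(s$tokens)
    for (i in seq_len(n)) {
      for (j in i:min(n, i + max_len - 1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          key = paste(s$tokens[i:j], collapse = " "),
          len = j - i + 1L, case = s$case
        )
      }
    }
  }
  d <- dplyr::distinct(dplyr::bind_rows(rows))
  agg <- d |>
    dplyr::group_by(key, len) |>
    dplyr::summarise(support = dplyr::n(),
                     cases = list(sort(unique(case))), .groups = "drop") |>
    dplyr::filter(support >= min_support)
  agg$display <- vapply(strsplit(agg$key, " ", fixed = TRUE),
                        patwas:::.render_elements, character(1))
  agg[order(agg$len, agg$display, method = "radix"), ]
}

# brute-force profile of a surface/tag element vector
oracle_profile <- function(elems, corpus) {
  sents <- corpus_sentences(corpus)
  prof <- logical(nrow(corpus$cases))
  L <- length(elems)
  is_tag <- grepl("^<.*>$", elems)
  val <- ifelse(is_tag, substr(elems, 2, nchar(elems) - 1), elems)
  for (s in sents) {
    n <- length(s$tokens)
    if (n < L) next
    for (i in seq_len(n - L + 1)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        ok <- if (is_tag[k]) val[k] %in% s$tags[[i + k - 1]] else
          s$tokens[i + k - 1] == val[k]
        if (!ok) break
      }
      if (ok) { prof[s$case] <- TRUE; break }
    }
  }
  prof
}

# brute-force tagged-pattern enumeration (no group tokens): cross-product
# of per-position representations over every window
oracle_tagged <- function(corpus, min_support = 2, max_len = 5) {
  sents <- corpus_sentences(corpus)
  rows <- list()
  for (s in sents) {
    n <- length(s$tokens)
    reps <- lapply(seq_len(n), function(i) {
      c(s$tokens[i],
        if (length(s$tags[[i]]) > 0) paste0("<", s$tags[[i]], ">"))
    })
    pure <- lapply(seq_len(n), function(i) {
      c(TRUE, rep(FALSE, length(s$tags[[i]])))
    })
    for (i in seq_len(n)) {
      for (j in i:min(n, i + max_len - 1)) {
        grid <- expand.grid(reps[i:j], stringsAsFactors = FALSE)
        pgrid <- expand.grid(pure[i:j])
        for (g in seq_len(nrow(grid))) {
          rows[[length(rows) + 1L]] <- data.frame(
            key = paste(unlist(grid[g, ]), collapse = " "),
            len = j - i + 1L, case = s$case,
            pure = all(unlist(pgrid[g, ]))
          )
        }
      }
    }
  }
  d <- dplyr::bind_rows(rows)
  agg <- d |>
    dplyr::group_by(key, len) |>
    dplyr::summarise(support = dplyr::n_distinct(case),
                     all_pure = all(pure), .groups = "drop") |>
    dplyr::filter(support >= min_support, !all_pure)
  agg$display <- vapply(strsplit(agg$key, " ", fixed = TRUE),
                        patwas:::.render_elements, character(1))
  agg[order(agg$len, agg$display, method = "radix"), ]
}

# full-enumeration 2x2 Fisher oracle from binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(c1, r1)
  pr <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1))
  obs <- exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# naive O(n^3) UPGMA: average pairwise distance between clusters
oracle_upgma <- function(x, k) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  cut_assign <- NULL
  avg <- function(ci, cj) mean(d[ci, cj])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- avg(clusters[[i]], clusters[[j]])
        if (a < best[1]) best <- c(a, i, j)
      }
    }
    heights <- c(heights, best[1])
    if (length(clusters) == k) {
      cut_assign <- integer(nrow(x))
      for (ci in seq_along(clusters)) cut_assign[clusters[[ci]]] <- ci
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  attr(heights, "cut_assign") <- cut_assign
  heights
}

# expand a token regex into every concrete token sequence it can match
oracle_regex_expand <- function(regex) {
  seqs <- list(character(0))
  for (e in regex$elements) {
    pieces <- if (e$kind == "lit") list(e$value) else {
      v <- e$variants
      if (isTRUE(e$optional)) v <- c(v, list(character(0)))
      v
    }
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(pieces, function(p) c(s, p))
    }), recursive = FALSE)
  }
  unique(seqs)
}

# random well-formed token regex for round-trip / matching properties
random_regex <- function(seed, alphabet = letters[1:5]) {
  withr::with_seed(seed, {
    n_el <- sample(3:5, 1)
    elements <- vector("list", n_el)
    for (i in seq_len(n_el)) {
      if (i == 1 || i == n_el || runif(1) < 0.4) {
        elements[[i]] <- list(kind = "lit", value = sample(alphabet, 1))
      } else {
        nv <- sample(2:3, 1)
        repeat {
          variants <- lapply(seq_len(nv), function(...) {
            sample(alphabet, sample(1:2, 1), replace = TRUE)
          })
          if (!anyDuplicated(vapply(variants, paste, "",
                                    collapse = " "))) break
        }
        elements[[i]] <- list(kind = "alt", variants = variants,
                              optional = runif(1) < 0.5)
      }
    }
    patwas:::new_patwas_regex(elements)
  })
}

# set a tag on every token with the given surface (test fixture tool)
set_tag <- function(corpus, surface, tag) {
  idx <- which(corpus$tokens$surface == surface)
  for (i in idx) {
    corpus$tokens$tags[[i]] <- union(corpus$tokens$tags[[i]], tag)
  }
  corpus
}
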