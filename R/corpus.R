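#' Split document text into sentence spans
#'
#' Rule-based sentence chunker: a sentence ends after `.`, `!`, `?` or `:`
#' when followed by whitespace, or at a blank line. No abbreviation
#' dictionary is used, so e.g. `"Dr. Smith"` splits after `"Dr."`; this
#' naive behaviour is deliberate and documented — clinical narratives are
#' dominated by short formulaic sentences where a deterministic rule is
#' preferable to a trained model.
#'
#' @param text A single character string (may be empty).
#' @return A tibble with columns `start`, `end`: 0-based half-open
#'   character offsets into `text`. Concatenating the spans recovers every
#'   non-whitespace character of the source.
#' @export
#' @examples
#' chunk_sentences("Tumour is T2. No nodes seen.")
chunk_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  nc <- nchar(text)
  if (is.na(text) || nc == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  cuts <- integer()
  term <- gregexpr("[.!?:](?=[[:space:]])", text, perl = TRUE)[[1]]
  if (term[1] != -1) cuts <- c(cuts, as.integer(term) + 1L) # cut after terminator
  blank <- gregexpr("\n[\t ]*\n", text, perl = TRUE)[[1]]
  if (blank[1] != -1) cuts <- c(cuts, as.integer(blank) + 1L) # cut inside the blank run
  bounds <- sort(unique(c(1L, cuts, nc + 1L)))
  spans <- lapply(seq_len(length(bounds) - 1L), function(i) {
    seg_start <- bounds[i]
    seg_end <- bounds[i + 1L] - 1L
    seg <- substr(text, seg_start, seg_end)
    m <- regexpr("[^[:space:]]", seg)
    if (m == -1) return(NULL) # all whitespace
    first <- seg_start + as.integer(m) - 1L
    last_rel <- regexpr("[^[:space:]][[:space:]]*$", seg)
    last <- seg_start + as.integer(last_rel) - 1L
    c(first - 1L, last) # 0-based half-open
  })
  spans <- do.call(rbind, spans)
  if (is.null(spans)) return(tibble(start = integer(), end = integer()))
  tibble(start = spans[, 1], end = spans[, 2])
}

# Word tokens are maximal alnum/underscore runs with internal hyphens;
# decimal numbers (optional thousands commas, optional decimal point) are
# kept whole; every other non-space character is its own token.
.token_regex <- paste0(
  "[0-9]+(?:,[0-9]{3})+(?:\\.[0-9]+)?", "|", # 1,000 / 12,345.6
  "[0-9]+\\.[0-9]+", "|",                    # 2.5
  "[[:alnum:]_]+(?:-[[:alnum:]_]+)*", "|",   # words incl. M0, p16, non-keratinising
  "[^[:space:]]"                             # single punctuation mark
)

#' Tokenize sentence text into word and punctuation tokens
#'
#' @param sentence_text A character string.
#' @return Character vector of token surfaces (case preserved, never
#'   containing whitespace). Punctuation marks are standalone tokens;
#'   decimal numbers such as `"2.5"` and hyphenated words such as
#'   `"non-keratinising"` stay whole.
#' @export
#' @examples
#' tokenize("M0, N2b")  # "M0" "," "N2b"
tokenize <- function(sentence_text) {
  stopifnot(is.character(sentence_text), length(sentence_text) == 1)
  if (is.na(sentence_text) || nchar(sentence_text) == 0) return(character())
  m <- gregexpr(.token_regex, sentence_text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  as.character(regmatches(sentence_text, list(m))[[1]])
}

#' Mask identifying terms in text
#'
#' Replaces every case-insensitive occurrence of each term with the fixed
#' mask `"XXXX"`, longest term first. Plain substring matching is used, so
#' a term embedded in a longer word is also masked (a documented
#' limitation of string-matching redaction).
#'
#' @param text Character string.
#' @param terms Character vector of terms to mask.
#' @return The redacted text.
#' @export
redact <- function(text, terms) {
  stopifnot(is.character(text), length(text) == 1)
  if (length(terms) == 0) return(text)
  stopifnot(all(nzchar(terms)))
  for (term in terms[order(-nchar(terms))]) {
    text <- gsub(term, "XXXX", text, ignore.case = TRUE, fixed = FALSE,
                 perl = TRUE)
  }
  text
}

#' Build a corpus from in-memory document texts
#'
#' The workhorse constructor behind [read_corpus()]; also used by the
#' synthetic-corpus generator and throughout the test-suite so that no
#' intermediate files are needed.
#'
#' @param docs A data frame with columns `case_id`, `doc_id`, `doc_type`,
#'   `text` (one row per document). Case order is the order of first
#'   appearance and fixes the coordinates of all occurrence profiles.
#' @param labels Optional data frame with columns `case_id`, `outcome`,
#'   `value`, `kind` (`kind` is `"binary"` or `"numeric"`).
#' @param fold_case If `TRUE`, lower-case all token surfaces.
#' @return A `patwas_corpus` object: a list with tibbles `cases`, `docs`,
#'   `sentences`, `tokens`, `groups` and the label table `labels`.
#' @export
corpus_from_texts <- function(docs, labels = NULL, fold_case = FALSE) {
  docs <- as_tibble(docs)
  required <- c("case_id", "doc_id", "doc_type", "text")
  if (!all(required %in% names(docs))) {
    abort(paste("docs must have columns:", paste(required, collapse = ", ")))
  }
  if (nrow(docs) == 0) abort("no cases: the document table is empty")
  if (anyDuplicated(docs$doc_id)) {
    abort(paste("duplicate doc_id:", docs$doc_id[duplicated(docs$doc_id)][1]))
  }
  case_ids <- unique(docs$case_id)

  sent_rows <- vector("list", nrow(docs))
  tok_rows <- vector("list", nrow(docs))
  sent_counter <- 0L
  for (i in seq_len(nrow(docs))) {
    spans <- chunk_sentences(docs$text[i])
    if (nrow(spans) == 0) next
    ids <- sent_counter + seq_len(nrow(spans))
    sent_counter <- sent_counter + nrow(spans)
    sent_rows[[i]] <- tibble(
      sent_id = ids, doc_id = docs$doc_id[i], case_id = docs$case_id[i],
      start = spans$start, end = spans$end
    )
    toks <- lapply(seq_len(nrow(spans)), function(j) {
      s <- substr(docs$text[i], spans$start[j] + 1L, spans$end[j])
      surf <- tokenize(s)
      if (fold_case) surf <- tolower(surf)
      if (length(surf) == 0) return(NULL)
      tibble(sent_id = ids[j], pos = seq_along(surf), surface = surf)
    })
    tok_rows[[i]] <- bind_rows(toks)
  }
  tokens <- bind_rows(tok_rows)
  if (nrow(tokens) == 0) {
    tokens <- tibble(sent_id = integer(), pos = integer(), surface = character())
  }
  tokens$tags <- rep(list(character()), nrow(tokens))
  tokens$num_value <- rep(NA_real_, nrow(tokens))

  corpus <- structure(
    list(
      cases = tibble(case_id = case_ids),
      docs = docs[, c("case_id", "doc_id", "doc_type")],
      sentences = bind_rows(sent_rows),
      tokens = tokens,
      groups = tibble(sent_id = integer(), start = integer(), end = integer(),
                      surface = character(), tag = character()),
      labels = tibble(case_id = character(), outcome = character(),
                      value = numeric(), kind = character()),
      fold_case = fold_case
    ),
    class = "patwas_corpus"
  )
  if (!is.null(labels)) corpus <- attach_labels(corpus, labels)
  corpus
}

#' Attach an outcome label table to a corpus
#'
#' @param corpus A `patwas_corpus`.
#' @param labels Data frame with columns `case_id`, `outcome`, `value`,
#'   `kind`. Binary values must be 0/1; numeric values must be finite.
#'   Cases without a label row are allowed and are skipped by labelled
#'   analyses.
#' @return The corpus with labels attached.
#' @export
attach_labels <- function(corpus, labels) {
  labels <- as_tibble(labels)
  required <- c("case_id", "outcome", "value", "kind")
  if (!all(required %in% names(labels))) {
    abort(paste("labels must have columns:", paste(required, collapse = ", ")))
  }
  labels$value <- as.numeric(labels$value)
  unknown <- setdiff(labels$case_id, corpus$cases$case_id)
  if (length(unknown) > 0) {
    abort(paste("label refers to unknown case id:", unknown[1]))
  }
  dup <- duplicated(labels[, c("case_id", "outcome")])
  if (any(dup)) {
    abort(paste0("duplicate label for (case, outcome): (",
                 labels$case_id[dup][1], ", ", labels$outcome[dup][1], ")"))
  }
  bad_kind <- setdiff(unique(labels$kind), c("binary", "numeric"))
  if (length(bad_kind) > 0) abort(paste("unknown outcome kind:", bad_kind[1]))
  bin <- labels$kind == "binary"
  if (any(bin & !labels$value %in% c(0, 1))) {
    abort("binary outcome values must be 0 or 1")
  }
  if (any(!is.finite(labels$value))) abort("outcome values must be finite")
  corpus$labels <- labels
  corpus
}

#' Load a corpus from a manifest and a labels file
#'
#' @param manifest_path Path to a TSV with header columns
#'   `case_id  doc_id  doc_type  path`; each `path` points to a UTF-8
#'   plain-text document (relative paths are resolved against the
#'   manifest's directory).
#' @param labels_path Optional path to a TSV with header columns
#'   `case_id  outcome  value  kind`.
#' @param fold_case Lower-case all token surfaces (matching becomes
#'   case-insensitive). Default `FALSE`: printed clinical patterns are
#'   case-bearing ("He", "SCC"), so case-sensitive matching is the default.
#' @return A `patwas_corpus`.
#' @export
read_corpus <- function(manifest_path, labels_path = NULL, fold_case = FALSE) {
  manifest <- readr::read_tsv(manifest_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  required <- c("case_id", "doc_id", "doc_type", "path")
  if (!all(required %in% names(manifest))) {
    abort(paste("manifest must have columns:", paste(required, collapse = ", ")))
  }
  if (nrow(manifest) == 0) abort("no cases: manifest is empty")
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                  file.path(base, manifest$path))
  missing <- !file.exists(paths)
  if (any(missing)) {
    i <- which(missing)[1]
    abort(paste0("manifest row ", i, ": file not found: ", manifest$path[i]))
  }
  manifest$text <- vapply(paths, function(p) {
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1))
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readr::read_tsv(labels_path, col_types = readr::cols(
      case_id = readr::col_character(), outcome = readr::col_character(),
      value = readr::col_double(), kind = readr::col_character()
    ))
  }
  corpus_from_texts(manifest[, c("case_id", "doc_id", "doc_type", "text")],
                    labels = labels, fold_case = fold_case)
}

#' Inverted token index of a corpus
#'
#' @param corpus A `patwas_corpus`.
#' @return A tibble `surface, doc_id, sent_id, pos` listing every position
#'   of every token surface; used to seed pattern matching.
#' @export
corpus_index <- function(corpus) {
  sent2doc <- setNames(corpus$sentences$doc_id, corpus$sentences$sent_id)
  tibble(
    surface = corpus$tokens$surface,
    doc_id = unname(sent2doc[as.character(corpus$tokens$sent_id)]),
    sent_id = corpus$tokens$sent_id,
    pos = corpus$tokens$pos
  ) %>% arrange(.data$surface, .data$sent_id, .data$pos)
}

#' Extract one outcome from a corpus
#'
#' @param corpus A `patwas_corpus`.
#' @param name Outcome name as it appears in the labels table.
#' @return A list with `name`, `kind` and `values` (a numeric vector named
#'   by case id, covering labelled cases only).
#' @export
corpus_outcome <- function(corpus, name) {
  rows <- corpus$labels[corpus$labels$outcome == name, ]
  if (nrow(rows) == 0) abort(paste("no labels for outcome:", name))
  list(name = name, kind = rows$kind[1],
       values = setNames(rows$value, rows$case_id))
}

#' Restrict a corpus to a subset of cases
#'
#' Keeps corpus case order. Used by the bootstrap evaluator so that
#' feature discovery inside a resample never sees out-of-bag documents.
#'
#' @param corpus A `patwas_corpus`.
#' @param case_ids Case ids to keep.
#' @return A `patwas_corpus` over the selected cases.
#' @export
subset_corpus <- function(corpus, case_ids) {
  keep_cases <- corpus$cases$case_id[corpus$cases$case_id %in% case_ids]
  keep_sent <- corpus$sentences$case_id %in% keep_cases
  sent_ids <- corpus$sentences$sent_id[keep_sent]
  out <- corpus
  out$cases <- tibble(case_id = keep_cases)
  out$docs <- corpus$docs[corpus$docs$case_id %in% keep_cases, ]
  out$sentences <- corpus$sentences[keep_sent, ]
  out$tokens <- corpus$tokens[corpus$tokens$sent_id %in% sent_ids, ]
  out$groups <- corpus$groups[corpus$groups$sent_id %in% sent_ids, ]
  out$labels <- corpus$labels[corpus$labels$case_id %in% keep_cases, ]
  out
}

#' @export
print.patwas_corpus <- function(x, ...) {
  cat("<patwas_corpus> ", nrow(x$cases), " cases, ", nrow(x$docs),
      " documents, ", nrow(x$sentences), " sentences, ", nrow(x$tokens),
      " tokens\n", sep = "")
  if (nrow(x$labels) > 0) {
    for (o in unique(x$labels$outcome)) {
      k <- x$labels$kind[x$labels$outcome == o][1]
      cat("  outcome ", o, " (", k, "): ",
          sum(x$labels$outcome == o), " labelled cases\n", sep = "")
    }
  }
  invisible(x)
}

n_cases <- function(corpus) nrow(corpus$cases)
case_ids <- function(corpus) corpus$cases$case_id
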