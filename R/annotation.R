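#' Tag cardinal-number tokens
#'
#' Tokens whose surface parses as a decimal number (optional sign,
#' optional decimal point, optional thousands commas) gain the `NUM` tag
#' and a `num_value`. Alphanumeric codes such as `"T2"` are not cardinals
#' and are left untouched; neither are spelled-out numbers ("three").
#'
#' @param corpus A `patwas_corpus`.
#' @return The corpus with `NUM` tags attached.
#' @export
annotate_numbers <- function(corpus) {
  surf <- corpus$tokens$surface
  is_num <- grepl("^[+-]?[0-9]+(,[0-9]{3})*(\\.[0-9]+)?$", surf)
  if (any(is_num)) {
    vals <- as.numeric(gsub(",", "", surf[is_num], fixed = TRUE))
    corpus$tokens$num_value[is_num] <- vals
    idx <- which(is_num)
    corpus$tokens$tags[idx] <- lapply(corpus$tokens$tags[idx], function(t) {
      union(t, "NUM")
    })
  }
  corpus
}

#' Tag alphabetic tokens with their Porter stem
#'
#' Each purely alphabetic token gains a `STEM:<stem>` tag computed by
#' [porter_stem()] on the lower-cased surface. Raising recall this way
#' lets the tagged pattern search match, e.g., "smokes", "smoked" and
#' "smoking" with a single `<STEM:smoke>` element.
#'
#' @param corpus A `patwas_corpus`.
#' @return The corpus with `STEM` tags attached.
#' @export
annotate_stems <- function(corpus) {
  surf <- corpus$tokens$surface
  is_alpha <- grepl("^[A-Za-z]+$", surf)
  if (any(is_alpha)) {
    stems <- paste0("STEM:", porter_stem(surf[is_alpha]))
    idx <- which(is_alpha)
    for (k in seq_along(idx)) {
      i <- idx[k]
      corpus$tokens$tags[[i]] <- union(corpus$tokens$tags[[i]], stems[k])
    }
  }
  corpus
}

#' Read CoNLL-style token annotations
#'
#' Lines of `token<TAB>POS[<TAB>lemma]`, blank line between sentences.
#'
#' @param path File path.
#' @return List of tibbles (one per sentence) with columns `token`, `pos`
#'   and (optionally) `lemma`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sent_break <- !nzchar(trimws(lines))
  grp <- cumsum(sent_break)
  out <- lapply(split(lines[!sent_break], grp[!sent_break]), function(ls) {
    parts <- strsplit(ls, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2)) abort(paste("malformed CoNLL line:", ls[which(nf < 2)[1]]))
    tb <- tibble(token = vapply(parts, `[[`, "", 1),
                 pos = vapply(parts, `[[`, "", 2))
    if (all(nf >= 3)) tb$lemma <- vapply(parts, `[[`, "", 3)
    tb
  })
  unname(out)
}

#' Attach pre-computed token annotations (POS tags, lemmas)
#'
#' Part-of-speech tagging and lemmatisation are consumed from external
#' pre-annotation files rather than computed in-package: any tagger that
#' can emit CoNLL-style columns can feed this step. Tags are attached as
#' `POS:<tag>`; lemmas (when present) as `STEM:<lemma>`.
#'
#' @param corpus A `patwas_corpus`.
#' @param conll Named list: `doc_id` -> either a path to a CoNLL file or
#'   the value of [read_conll()]. Documents not named are left untagged
#'   with a warning.
#' @return The annotated corpus.
#' @export
apply_preannotations <- function(corpus, conll) {
  untouched <- setdiff(corpus$docs$doc_id, names(conll))
  if (length(untouched) > 0) {
    warn(paste("no pre-annotations for document(s):",
               paste(untouched, collapse = ", ")))
  }
  for (doc in intersect(names(conll), corpus$docs$doc_id)) {
    ann <- conll[[doc]]
    if (is.character(ann)) ann <- read_conll(ann)
    sents <- corpus$sentences$sent_id[corpus$sentences$doc_id == doc]
    if (length(sents) != length(ann)) {
      abort(paste0("pre-annotation sentence count mismatch for doc ", doc,
                   ": corpus has ", length(sents), ", file has ", length(ann)))
    }
    for (j in seq_along(sents)) {
      rows <- which(corpus$tokens$sent_id == sents[j])
      if (length(rows) != nrow(ann[[j]])) {
        abort(paste0("token count mismatch in doc ", doc, " sentence ", j,
                     ": corpus has ", length(rows), " tokens, file has ",
                     nrow(ann[[j]])))
      }
      new <- paste0("POS:", ann[[j]]$pos)
      if ("lemma" %in% names(ann[[j]])) {
        new <- cbind(new, paste0("STEM:", ann[[j]]$lemma))
      } else {
        new <- cbind(new, NA_character_)
      }
      for (k in seq_along(rows)) {
        add <- new[k, !is.na(new[k, ])]
        corpus$tokens$tags[[rows[k]]] <-
          union(corpus$tokens$tags[[rows[k]]], add)
      }
    }
  }
  corpus
}

#' Parse a Penn-bracketed constituency tree
#'
#' @param text One bracketed tree, e.g.
#'   `"(NP (NN base) (PP (IN of) (NP (NN tongue))))"`.
#' @return A nested list with elements `label`, and either `word` (leaf)
#'   or `children`.
#' @export
parse_penn <- function(text) {
  toks <- strsplit(gsub("([()])", " \\1 ", text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  pos <- 1L
  parse_node <- function() {
    if (pos > length(toks) || toks[pos] != "(") {
      abort(paste("malformed bracketing at token", pos))
    }
    pos <<- pos + 1L
    if (pos > length(toks)) abort("malformed bracketing: unexpected end")
    label <- toks[pos]; pos <<- pos + 1L
    if (pos <= length(toks) && toks[pos] == "(") {
      children <- list()
      while (pos <= length(toks) && toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      }
      if (pos > length(toks) || toks[pos] != ")") {
        abort("malformed bracketing: missing ')'")
      }
      pos <<- pos + 1L
      list(label = label, children = children)
    } else {
      if (pos > length(toks) || toks[pos] == ")") {
        abort("malformed bracketing: leaf without word")
      }
      word <- toks[pos]; pos <<- pos + 1L
      if (pos > length(toks) || toks[pos] != ")") {
        abort("malformed bracketing: missing ')' after leaf")
      }
      pos <<- pos + 1L
      list(label = label, word = word)
    }
  }
  node <- parse_node()
  if (pos <= length(toks)) abort("malformed bracketing: trailing input")
  node
}

.penn_leaves <- function(node) {
  if (!is.null(node$word)) return(node$word)
  unlist(lapply(node$children, .penn_leaves))
}

#' Register parse-derived group tokens
#'
#' For every internal node of a constituency tree spanning two or more
#' tokens, a synthetic group token is registered: its surface is the
#' underscore-join of the span and it carries tag `GRP:<nodelabel>`.
#' Group tokens coexist with their constituent tokens; the tagged pattern
#' search may use either, with the group occupying a single pattern
#' position covering its whole span.
#'
#' @param corpus A `patwas_corpus`.
#' @param trees Named list: `doc_id` -> character vector of Penn-bracketed
#'   trees, one per sentence of that document.
#' @return The corpus with group tokens registered.
#' @export
annotate_parse_groups <- function(corpus, trees) {
  new_groups <- list()
  for (doc in intersect(names(trees), corpus$docs$doc_id)) {
    sents <- corpus$sentences$sent_id[corpus$sentences$doc_id == doc]
    tr <- trees[[doc]]
    if (length(sents) != length(tr)) {
      abort(paste0("parse tree count mismatch for doc ", doc))
    }
    for (j in seq_along(sents)) {
      surf <- corpus$tokens$surface[corpus$tokens$sent_id == sents[j]]
      node <- parse_penn(tr[j])
      leaves <- .penn_leaves(node)
      if (length(leaves) != length(surf) || !all(leaves == surf)) {
        abort(paste0("parse leaves do not match tokens in doc ", doc,
                     " sentence ", j))
      }
      collect <- function(node, start) {
        if (!is.null(node$word)) return(1L)
        width <- 0L
        for (ch in node$children) {
          width <- width + collect(ch, start + width)
        }
        if (width >= 2L) {
          span <- surf[start:(start + width - 1L)]
          new_groups[[length(new_groups) + 1L]] <<- tibble(
            sent_id = sents[j], start = start, end = start + width - 1L,
            surface = paste(span, collapse = "_"),
            tag = paste0("GRP:", node$label)
          )
        }
        width
      }
      collect(node, 1L)
    }
  }
  if (length(new_groups) > 0) {
    corpus$groups <- distinct(bind_rows(corpus$groups, bind_rows(new_groups)))
  }
  corpus
}

#' Read a vocabulary file
#'
#' Plain TSV, one `phrase<TAB>concept_id` per line, no header.
#'
#' @param path File path.
#' @return Tibble with columns `phrase`, `concept_id`.
#' @export
read_vocabulary <- function(path) {
  readr::read_tsv(path, col_names = c("phrase", "concept_id"),
                  col_types = "cc")
}

#' Aggregate vocabulary concepts into single tokens
#'
#' Left-to-right longest-string matching: at each position the longest
#' vocabulary phrase whose token surfaces match the upcoming tokens
#' (case-insensitively) is replaced by a single token — its surface the
#' underscore-join of the matched surfaces, tagged `CONCEPT:<id>` —
#' and scanning resumes after the match. Replacement is destructive by
#' default (the multi-token phrase becomes a unigram, e.g.
#' `"head of pancreas"` -> `"head_of_pancreas"`); `keep_original = TRUE`
#' registers the concept as a parallel group token instead.
#'
#' @param corpus A `patwas_corpus`.
#' @param vocabulary Data frame with columns `phrase`, `concept_id`; no
#'   duplicate phrases.
#' @param keep_original Register concepts as group tokens instead of
#'   replacing the constituent tokens.
#' @return The corpus with concepts aggregated.
#' @export
annotate_vocabulary <- function(corpus, vocabulary, keep_original = FALSE) {
  vocabulary <- as_tibble(vocabulary)
  if (anyDuplicated(tolower(vocabulary$phrase))) {
    abort("duplicate phrase in vocabulary")
  }
  vtoks <- lapply(vocabulary$phrase, function(p) tolower(tokenize(p)))
  stopifnot(all(lengths(vtoks) >= 1))
  ord <- order(-lengths(vtoks)) # longest phrase first
  vtoks <- vtoks[ord]
  vids <- vocabulary$concept_id[ord]

  out_tokens <- list()
  new_groups <- list()
  for (sid in unique(corpus$tokens$sent_id)) {
    rows <- corpus$tokens[corpus$tokens$sent_id == sid, ]
    surf_l <- tolower(rows$surface)
    n <- nrow(rows)
    keep <- rep(TRUE, n)
    repl <- list() # position -> replacement row
    i <- 1L
    while (i <= n) {
      hit <- 0L
      for (v in seq_along(vtoks)) {
        L <- length(vtoks[[v]])
        if (i + L - 1L <= n && all(surf_l[i:(i + L - 1L)] == vtoks[[v]])) {
          hit <- v
          break
        }
      }
      if (hit > 0L) {
        L <- length(vtoks[[hit]])
        joined <- paste(rows$surface[i:(i + L - 1L)], collapse = "_")
        if (keep_original) {
          if (L >= 2L) {
            new_groups[[length(new_groups) + 1L]] <- tibble(
              sent_id = sid, start = i, end = i + L - 1L,
              surface = joined, tag = paste0("CONCEPT:", vids[hit])
            )
          } else {
            repl[[as.character(i)]] <- tibble(
              sent_id = sid, pos = NA_integer_, surface = rows$surface[i],
              tags = list(union(rows$tags[[i]],
                                paste0("CONCEPT:", vids[hit]))),
              num_value = rows$num_value[i]
            )
          }
        } else {
          keep[i:(i + L - 1L)] <- FALSE
          repl[[as.character(i)]] <- tibble(
            sent_id = sid, pos = NA_integer_, surface = joined,
            tags = list(paste0("CONCEPT:", vids[hit])),
            num_value = NA_real_
          )
        }
        i <- i + L
      } else {
        i <- i + 1L
      }
    }
    if (length(repl) == 0 && all(keep)) {
      out_tokens[[length(out_tokens) + 1L]] <- rows
    } else {
      pieces <- list()
      for (j in seq_len(n)) {
        key <- as.character(j)
        if (!is.null(repl[[key]])) pieces[[length(pieces) + 1L]] <- repl[[key]]
        if (keep[j] && is.null(repl[[key]])) {
          pieces[[length(pieces) + 1L]] <- rows[j, ]
        }
      }
      sent <- bind_rows(pieces)
      sent$pos <- seq_len(nrow(sent))
      out_tokens[[length(out_tokens) + 1L]] <- sent
    }
  }
  corpus$tokens <- bind_rows(out_tokens)
  if (length(new_groups) > 0) {
    corpus$groups <- distinct(bind_rows(corpus$groups, bind_rows(new_groups)))
  }
  corpus
}

#' Prune annotations unique to a single token surface
#'
#' A tag value attached to exactly one distinct token surface in the whole
#' corpus carries no generalisation power — any pattern using it is
#' equivalent to the surface pattern — so it is removed everywhere. On
#' richly annotated corpora this removes the large majority of tags and
#' keeps the combinatorial tagged search tractable.
#'
#' @param corpus A `patwas_corpus`.
#' @return The corpus with unique tags removed; the number of removed
#'   (tag, token) assignments is in `attr(, "n_pruned")`.
#' @export
prune_annotations <- function(corpus) {
  tag_list <- corpus$tokens$tags
  if (all(lengths(tag_list) == 0)) {
    attr(corpus, "n_pruned") <- 0L
    return(corpus)
  }
  pairs <- tibble(
    tag = unlist(tag_list),
    surface = rep(corpus$tokens$surface, lengths(tag_list))
  )
  multi <- pairs %>%
    distinct(.data$tag, .data$surface) %>%
    count(.data$tag) %>%
    filter(.data$n >= 2) %>%
    pull(.data$tag)
  n_before <- sum(lengths(tag_list))
  corpus$tokens$tags <- lapply(tag_list, function(t) t[t %in% multi])
  attr(corpus, "n_pruned") <- n_before - sum(lengths(corpus$tokens$tags))
  corpus
}
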