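# Regular-expression induction: syntactically similar n-grams sharing
# boundary tokens are consolidated, via Needleman-Wunsch global
# alignment, into linear non-recursive token expressions —
# "extensive (bone|liver) metastasis" — which are then re-scored as
# ordinary binary features. Global (not local) alignment is used
# deliberately: a wildcard at either end of an expression would match
# non-discriminantly and destroy specificity, so induced expressions
# always begin and end with the shared literal boundary tokens.

new_patwas_regex <- function(elements, members = character()) {
  structure(list(elements = elements, members = members),
            class = "patwas_regex")
}

#' @export
print.patwas_regex <- function(x, ...) {
  cat("<patwas_regex> ", render_regex(x), "\n", sep = "")
  if (length(x$members) > 0) {
    cat("  induced from ", length(x$members), " member n-grams\n", sep = "")
  }
  invisible(x)
}

#' Global alignment of two token sequences
#'
#' Needleman-Wunsch with configurable scores (defaults: match +1,
#' mismatch -1, gap -1) and a deterministic traceback preferring
#' diagonal over up (gap in `seq_b`) over left (gap in `seq_a`).
#'
#' @param seq_a,seq_b Non-empty character vectors of tokens.
#' @param match,mismatch,gap Alignment scores.
#' @return A list with `a` and `b` (aligned rows, `NA` marking gaps) and
#'   `score`.
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -1) {
  n <- length(seq_a); m <- length(seq_b)
  stopifnot(n >= 1, m >= 1)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n)
  f[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    s_row <- ifelse(seq_a[i] == seq_b, match, mismatch)
    for (j in seq_len(m)) {
      f[i + 1, j + 1] <- max(f[i, j] + s_row[j],
                             f[i, j + 1] + gap,
                             f[i + 1, j] + gap)
    }
  }
  # traceback, diagonal > up > left
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        f[i + 1, j + 1] ==
          f[i, j] + (if (seq_a[i] == seq_b[j]) match else mismatch)) {
      ai <- c(seq_a[i], ai); bi <- c(seq_b[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && f[i + 1, j + 1] == f[i, j + 1] + gap) {
      ai <- c(seq_a[i], ai); bi <- c(NA_character_, bi); i <- i - 1
    } else {
      ai <- c(NA_character_, ai); bi <- c(seq_b[j], bi); j <- j - 1
    }
  }
  list(a = ai, b = bi, score = f[n + 1, m + 1])
}

#' Group n-gram features sharing boundary tokens
#'
#' Candidate sets for regex induction: all n-gram patterns (length >= 2)
#' sharing the same first and last token form one group; groups with at
#' least two members are returned. Each pattern belongs to exactly one
#' group (its boundary key).
#'
#' @param features Feature or association tibble with n-gram rows.
#' @return Named list of character vectors of member patterns, keyed
#'   `"<first> ... <last>"`, in deterministic order.
#' @export
group_candidates <- function(features) {
  rows <- features[features$type == "ngram", ]
  if (nrow(rows) == 0) return(list())
  elems <- lapply(rows$pattern, .parse_elements)
  len_ok <- lengths(elems) >= 2
  rows <- rows[len_ok, ]; elems <- elems[len_ok]
  if (nrow(rows) == 0) return(list())
  key <- vapply(elems, function(e) {
    paste(e[1], "...", e[length(e)])
  }, character(1))
  groups <- split(rows$pattern, key)
  groups <- groups[vapply(groups, function(g) length(unique(g)) >= 2,
                          logical(1))]
  groups <- lapply(groups, unique)
  groups[order(names(groups), method = "radix")]
}

# merge a pairwise (center, member) alignment into the running star
# alignment; cmap maps master columns to ungapped center positions
.star_merge <- function(master, cmap, pair_center, pair_member) {
  M <- ncol(master); P <- length(pair_center)
  cols <- list(); new_cmap <- integer(0)
  i <- 1L; j <- 1L
  while (i <= M || j <= P) {
    if (i <= M && is.na(cmap[i])) {
      cols[[length(cols) + 1L]] <- c(master[, i], NA_character_)
      new_cmap <- c(new_cmap, NA_integer_)
      i <- i + 1L
    } else if (j <= P && is.na(pair_center[j])) {
      cols[[length(cols) + 1L]] <- c(rep(NA_character_, nrow(master)),
                                     pair_member[j])
      new_cmap <- c(new_cmap, NA_integer_)
      j <- j + 1L
    } else {
      cols[[length(cols) + 1L]] <- c(master[, i], pair_member[j])
      new_cmap <- c(new_cmap, cmap[i])
      i <- i + 1L; j <- j + 1L
    }
  }
  list(master = do.call(cbind, cols), cmap = new_cmap)
}

#' Consolidate aligned n-grams into a token regular expression
#'
#' Star alignment against the longest member (ties broken
#' lexicographically): every member is globally aligned to the centre
#' with [align_pair()] and the pairwise alignments are merged into one
#' multiple alignment. Columns where all members agree become literal
#' anchors; each maximal run of non-anchor columns becomes a single
#' element holding the members' gap-stripped subsequences across the run
#' — an alternation `(v1|v2)` when several distinct non-empty variants
#' occur, an optional group `(v)?` when one variant alternates with
#' emptiness, an optional alternation `(v1|v2)?` for both. Variants are
#' ordered by descending member support, ties by first appearance among
#' the members.
#'
#' @param group Character vector of member n-gram patterns (length >= 2,
#'   shared first and last tokens, not all identical).
#' @param supports Optional numeric vector of member supports (used only
#'   to order alternation variants).
#' @param scores Named list of alignment scores passed to [align_pair()].
#' @return A `patwas_regex` object.
#' @export
#' @examples
#' render_regex(consolidate(c("extensive bone metastasis",
#'                            "extensive liver metastasis")))
consolidate <- function(group, supports = NULL,
                        scores = list(match = 1, mismatch = -1, gap = -1)) {
  stopifnot(length(group) >= 2)
  seqs <- lapply(group, .parse_elements)
  if (is.null(supports)) supports <- rep(1, length(seqs))
  stopifnot(length(supports) == length(seqs))
  if (length(unique(vapply(seqs, paste, "", collapse = "\x1f"))) == 1) {
    abort("all members are identical: nothing to consolidate")
  }
  firsts <- vapply(seqs, function(s) s[1], "")
  lasts <- vapply(seqs, function(s) s[length(s)], "")
  if (length(unique(firsts)) != 1 || length(unique(lasts)) != 1) {
    abort("members must share their first and last tokens")
  }

  rendered <- vapply(seqs, paste, "", collapse = " ")
  center_i <- order(-lengths(seqs), rendered, method = "radix")[1]
  center <- seqs[[center_i]]
  master <- matrix(center, nrow = 1)
  cmap <- seq_along(center)
  row_members <- center_i
  for (k in setdiff(seq_along(seqs), center_i)) {
    al <- align_pair(center, seqs[[k]], scores$match, scores$mismatch,
                     scores$gap)
    st <- .star_merge(master, cmap, al$a, al$b)
    master <- st$master; cmap <- st$cmap
    row_members <- c(row_members, k)
  }

  anchor <- apply(master, 2, function(col) {
    !anyNA(col) && length(unique(col)) == 1
  })
  if (!anchor[1] || !anchor[length(anchor)]) {
    abort("consolidation failed to anchor the shared boundary tokens")
  }

  elements <- list()
  runs <- rle(anchor)
  col <- 1L
  for (r in seq_along(runs$lengths)) {
    span <- col:(col + runs$lengths[r] - 1L)
    if (runs$values[r]) {
      for (cc in span) {
        elements[[length(elements) + 1L]] <-
          list(kind = "lit", value = master[1, cc])
      }
    } else {
      # gap-stripped subsequence of each member across the run, in
      # original member order (first appearance breaks support ties)
      per_member <- lapply(seq_along(seqs), function(k) {
        v <- master[match(k, row_members), span]
        v[!is.na(v)]
      })
      vkey <- vapply(per_member, paste, "", collapse = " ")
      first_seen <- !duplicated(vkey)
      vsup <- vapply(vkey[first_seen], function(k) {
        max(supports[vkey == k])
      }, numeric(1))
      variants <- per_member[first_seen]
      ord <- order(-vsup, seq_along(variants))
      variants <- variants[ord]
      optional <- any(lengths(variants) == 0)
      variants <- variants[lengths(variants) > 0]
      if (length(variants) == 1 && !optional) {
        for (tok in variants[[1]]) {
          elements[[length(elements) + 1L]] <- list(kind = "lit", value = tok)
        }
      } else {
        elements[[length(elements) + 1L]] <-
          list(kind = "alt", variants = variants, optional = optional)
      }
    }
    col <- col + runs$lengths[r]
  }
  new_patwas_regex(elements, members = group)
}

#' Render a token regex in alternation/optional notation
#'
#' Literals are space-joined; alternations render as `(v1|v2|...)`, an
#' optional single variant as `(v)?`, an optional alternation as
#' `(v1|v2)?`.
#'
#' @param regex A `patwas_regex`.
#' @return The rendered expression string.
#' @export
render_regex <- function(regex) {
  parts <- vapply(regex$elements, function(e) {
    if (e$kind == "lit") return(e$value)
    body <- paste(vapply(e$variants, paste, "", collapse = " "),
                  collapse = "|")
    paste0("(", body, ")", if (isTRUE(e$optional)) "?" else "")
  }, character(1))
  paste(parts, collapse = " ")
}

#' Parse a token regex from its rendered notation
#'
#' Inverse of [render_regex()]: `parse_regex(render_regex(r))` recovers
#' `r`'s elements.
#'
#' @param text Expression string, e.g. `"a (b|c d) e"`.
#' @return A `patwas_regex`.
#' @export
parse_regex <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- gregexpr("\\([^()]*\\)\\??|[^ ()]+|[()]", text, perl = TRUE)[[1]]
  if (m[1] == -1) abort("parse error: empty expression")
  units <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m)
  elements <- list()
  for (k in seq_along(units)) {
    u <- units[k]
    if (u %in% c("(", ")")) {
      abort(paste0("parse error at position ", starts[k],
                   ": unbalanced parenthesis"))
    }
    if (startsWith(u, "(")) {
      optional <- endsWith(u, "?")
      body <- sub("^\\(", "", sub("\\)\\??$", "", u))
      vars <- strsplit(body, "|", fixed = TRUE)[[1]]
      if (length(vars) == 0 || any(!nzchar(trimws(vars)))) {
        abort(paste0("parse error at position ", starts[k],
                     ": empty variant"))
      }
      variants <- lapply(vars, function(v) {
        strsplit(trimws(v), " +")[[1]]
      })
      vkey <- vapply(variants, paste, "", collapse = " ")
      if (anyDuplicated(vkey)) {
        abort(paste0("parse error at position ", starts[k],
                     ": duplicate variant"))
      }
      if (length(variants) == 1 && !optional) {
        abort(paste0("parse error at position ", starts[k],
                     ": single-variant group must be optional"))
      }
      elements[[length(elements) + 1L]] <-
        list(kind = "alt", variants = variants, optional = optional)
    } else {
      elements[[length(elements) + 1L]] <- list(kind = "lit", value = u)
    }
  }
  if (length(elements) == 0 ||
      elements[[1]]$kind != "lit" ||
      elements[[length(elements)]]$kind != "lit") {
    abort("parse error: expression must begin and end with a literal")
  }
  new_patwas_regex(elements)
}

# does the element list match the token vector starting at i, using up
# tokens greedily with backtracking over variants?
.regex_match_at <- function(elements, toks, i) {
  if (length(elements) == 0) return(TRUE)
  e <- elements[[1]]
  rest <- elements[-1]
  if (e$kind == "lit") {
    if (i <= length(toks) && toks[i] == e$value) {
      return(.regex_match_at(rest, toks, i + 1L))
    }
    return(FALSE)
  }
  for (v in e$variants) {
    L <- length(v)
    if (i + L - 1L <= length(toks) && all(toks[i:(i + L - 1L)] == v)) {
      if (.regex_match_at(rest, toks, i + L)) return(TRUE)
    }
  }
  if (isTRUE(e$optional) && .regex_match_at(rest, toks, i)) return(TRUE)
  FALSE
}

#' Occurrence profile of an induced regex
#'
#' A case's bit is set iff some sentence of the case contains a
#' contiguous token subsequence matched by the expression (alternation =
#' any one variant, optional = variant or empty).
#'
#' @param regex A `patwas_regex`.
#' @param corpus A `patwas_corpus`.
#' @return Logical vector in corpus case order.
#' @export
match_regex <- function(regex, corpus) {
  a <- .sent_arrays(corpus)
  prof <- logical(a$n_case)
  if (length(a$surface) == 0) return(prof)
  first_lit <- regex$elements[[1]]$value
  starts <- which(a$surface == first_lit)
  for (i in starts) {
    s <- a$sidx[i]
    ci <- a$case_of_sent[s]
    if (prof[ci]) next
    toks <- a$surface[a$sstart[s]:a$send[s]]
    if (.regex_match_at(regex$elements, toks, i - a$sstart[s] + 1L)) {
      prof[ci] <- TRUE
    }
  }
  prof
}

#' Induce regexes from ranked n-gram results and re-score them
#'
#' Groups the n-gram patterns by shared boundary tokens, consolidates
#' each group into a token regex, rebuilds its occurrence profile by
#' matching against the corpus, and re-runs the association test. The
#' induced expressions are returned merged with the input results,
#' flagged `type = "regex"`; `informative` is `FALSE` for a regex whose
#' profile is identical to one of its members' (pooling added no new
#' cases). An induced expression may match token combinations unseen in
#' any member, so its support can exceed the union of member supports.
#'
#' @param results Association results (from [associate()]) containing
#'   n-gram rows.
#' @param corpus The `patwas_corpus`.
#' @param outcome Outcome name or [corpus_outcome()] value.
#' @param scores Alignment scores for [consolidate()].
#' @return Results tibble with regex rows appended, re-sorted by
#'   ascending p (ties as in [filter_threshold()]).
#' @export
induce_and_rescore <- function(results, corpus, outcome,
                               scores = list(match = 1, mismatch = -1,
                                             gap = -1)) {
  groups <- group_candidates(results)
  if (length(groups) == 0) {
    out <- results
    out$informative <- TRUE
    return(filter_threshold(out, 1))
  }
  feat_rows <- list()
  for (g in groups) {
    sup <- results$support[match(g, results$pattern)]
    rx <- tryCatch(consolidate(g, supports = sup, scores = scores),
                   error = function(e) NULL)
    if (is.null(rx)) next
    prof <- match_regex(rx, corpus)
    if (!any(prof)) next
    member_profiles <- results$profile[match(g, results$pattern)]
    informative <- !any(vapply(member_profiles, function(mp) {
      identical(mp, prof)
    }, logical(1)))
    feat_rows[[length(feat_rows) + 1L]] <- tibble(
      pattern = render_regex(rx), type = "regex",
      n_len = length(rx$elements), support = sum(prof),
      profile = list(prof), informative = informative
    )
  }
  base <- results
  base$informative <- TRUE
  if (length(feat_rows) == 0) return(filter_threshold(base, 1))
  feats <- bind_rows(feat_rows)
  feats <- feats[!duplicated(feats$pattern), ]
  rescored <- associate(feats[, c("pattern", "type", "n_len", "support",
                                  "profile")],
                        corpus, outcome)
  rescored$informative <- feats$informative[match(rescored$pattern,
                                                  feats$pattern)]
  merged <- bind_rows(base, rescored)
  filter_threshold(merged, 1)
}
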