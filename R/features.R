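# Exhaustive within-sentence pattern enumeration. Patterns are grown one
# token at a time; a candidate is abandoned as soon as its corpus-wide
# occurrence count falls below max(2, min_support), which bounds the
# search because occurrence counts are anti-monotone under elongation.

# flat per-corpus arrays used by all search loops
.sent_arrays <- function(corpus) {
  tk <- corpus$tokens
  ord <- order(tk$sent_id, tk$pos)
  tk <- tk[ord, ]
  sent_ids <- unique(tk$sent_id)
  sidx <- match(tk$sent_id, sent_ids)
  slen <- tabulate(sidx, nbins = length(sent_ids))
  sstart <- cumsum(c(1L, slen[-length(slen)]))
  s2case <- corpus$sentences$case_id[match(sent_ids, corpus$sentences$sent_id)]
  case_idx <- match(s2case, corpus$cases$case_id)
  list(
    surface = tk$surface, tags = tk$tags, num_value = tk$num_value,
    sidx = sidx,                     # sentence index per flat token
    sent_ids = sent_ids,
    sstart = sstart, slen = slen,    # flat offset / length per sentence
    send = sstart + slen - 1L,       # flat index of last token per sentence
    case_of_sent = case_idx,         # case index per sentence
    n_case = nrow(corpus$cases)
  )
}

.is_punct_tok <- function(tok) {
  nchar(tok) == 1L & !grepl("[[:alnum:]_]", tok)
}

# display rendering: elements joined with spaces, no space before a
# punctuation literal; tag elements appear as <NS:value>
.render_elements <- function(tokens) {
  if (length(tokens) == 0) return("")
  sep <- ifelse(.is_punct_tok(tokens[-1]), "", " ")
  paste0(tokens[1], paste0(sep, tokens[-1], collapse = ""))
}

# inverse of .render_elements: element vector from a display string
.parse_elements <- function(pattern) {
  units <- regmatches(pattern,
    gregexpr("<[A-Z]+(:[^> ]*)?>|[^ ]+", pattern))[[1]]
  out <- lapply(units, function(u) {
    if (grepl("^<[A-Z]+(:[^> ]*)?>$", u)) u else tokenize(u)
  })
  unlist(out)
}

.profile_from_cases <- function(case_idx, n_case) {
  p <- logical(n_case)
  p[unique(case_idx)] <- TRUE
  p
}

#' Enumerate surface n-gram features
#'
#' Every distinct surface n-gram occurring within a single sentence in at
#' least `min_support` cases is returned exactly once with its case-level
#' occurrence profile. Patterns never span sentence or document
#' boundaries. Elongation of a candidate stops once its corpus-wide
#' occurrence count drops below `max(2, min_support)`, so the unbounded
#' default for `max_len` is safe: support pruning bounds the search.
#'
#' @param corpus A `patwas_corpus`.
#' @param min_support Minimum number of distinct cases containing the
#'   pattern (default 2: a pattern seen in one case cannot reach
#'   significance).
#' @param max_len Maximum pattern length in tokens (default unbounded).
#' @return Tibble with columns `pattern` (display rendering), `type`
#'   (`"ngram"`), `n_len`, `support` and `profile` (list-column of logical
#'   vectors in corpus case order), sorted by length then pattern.
#' @export
enumerate_ngrams <- function(corpus, min_support = 2, max_len = Inf) {
  stopifnot(min_support >= 1)
  a <- .sent_arrays(corpus)
  if (length(a$surface) == 0) {
    return(tibble(pattern = character(), type = character(),
                  n_len = integer(), support = integer(), profile = list()))
  }
  thr <- max(2, min_support)
  occ_start <- seq_along(a$surface)
  occ_sent <- a$sidx
  key <- a$surface
  out <- list()
  n <- 1L
  repeat {
    uk <- unique(key)
    kid <- match(key, uk)
    occ_n <- tabulate(kid, nbins = length(uk))
    # emit features with enough case support at this length
    cases <- a$case_of_sent[occ_sent]
    sup_tab <- tibble(kid = kid, case = cases) %>% distinct() %>% count(.data$kid)
    sup <- integer(length(uk)); sup[sup_tab$kid] <- sup_tab$n
    emit <- which(sup >= min_support)
    if (length(emit) > 0) {
      profs <- lapply(emit, function(k) {
        .profile_from_cases(cases[kid == k], a$n_case)
      })
      out[[n]] <- tibble(key = uk[emit], n_len = n, support = sup[emit],
                         profile = profs)
    }
    if (n >= max_len) break
    # elongate candidates still occurring often enough
    keep <- occ_n[kid] >= thr
    pos_in_sent <- occ_start - a$sstart[occ_sent] + 1L
    keep <- keep & (pos_in_sent + n <= a$slen[occ_sent])
    if (!any(keep)) break
    occ_start <- occ_start[keep]
    occ_sent <- occ_sent[keep]
    key <- paste(key[keep], a$surface[occ_start + n])
    n <- n + 1L
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(pattern = character(), type = character(),
                  n_len = integer(), support = integer(), profile = list()))
  }
  res$pattern <- vapply(strsplit(res$key, " ", fixed = TRUE),
                        .render_elements, character(1))
  res <- res[order(res$n_len, res$pattern, method = "radix"), ]
  tibble(pattern = res$pattern, type = "ngram", n_len = res$n_len,
         support = res$support, profile = res$profile)
}

#' Enumerate combinatorial token/tag patterns
#'
#' Like [enumerate_ngrams()], but at each position the pattern element may
#' be either the token surface or any of its tags (rendered `<NS:value>`),
#' and registered group tokens may occupy a single position covering their
#' whole span. Patterns consisting purely of token surfaces duplicate the
#' n-gram enumeration and are dropped. Run [prune_annotations()] first:
#' the search space grows exponentially in the number of alternative
#' representations per position.
#'
#' @inheritParams enumerate_ngrams
#' @param max_len Maximum pattern length (default 5; the combinatorial
#'   space makes an unbounded search impractical).
#' @return Tibble as in [enumerate_ngrams()], `type = "tagged"`.
#' @export
enumerate_tagged_patterns <- function(corpus, min_support = 2, max_len = 5) {
  stopifnot(min_support >= 1, is.finite(max_len))
  a <- .sent_arrays(corpus)
  empty <- tibble(pattern = character(), type = character(),
                  n_len = integer(), support = integer(), profile = list())
  if (length(a$surface) == 0) return(empty)
  thr <- max(2, min_support)

  # alternative representations per flat position: surface + tags
  reps <- lapply(seq_along(a$surface), function(i) {
    c(a$surface[i], if (length(a$tags[[i]]) > 0) paste0("<", a$tags[[i]], ">"))
  })
  # groups: keyed by flat start position
  grp_by_start <- list()
  if (nrow(corpus$groups) > 0) {
    g <- corpus$groups
    gs <- match(g$sent_id, a$sent_ids)
    ok <- !is.na(gs)
    g <- g[ok, ]; gs <- gs[ok]
    flat_start <- a$sstart[gs] + g$start - 1L
    flat_end <- a$sstart[gs] + g$end - 1L
    for (i in seq_len(nrow(g))) {
      k <- as.character(flat_start[i])
      grp_by_start[[k]] <- c(grp_by_start[[k]], list(
        list(end = flat_end[i], reps = c(g$surface[i], paste0("<", g$tag[i], ">")))
      ))
    }
  }

  # occurrence state: start, end (flat), sentence, key, pure-surface flag
  o_start <- integer(); o_end <- integer(); o_sent <- integer()
  o_key <- character(); o_pure <- logical()
  for (i in seq_along(a$surface)) {
    r <- reps[[i]]
    o_start <- c(o_start, rep(i, length(r)))
    o_end <- c(o_end, rep(i, length(r)))
    o_sent <- c(o_sent, rep(a$sidx[i], length(r)))
    o_key <- c(o_key, r)
    o_pure <- c(o_pure, r == a$surface[i])
  }
  for (k in names(grp_by_start)) {
    i <- as.integer(k)
    for (gr in grp_by_start[[k]]) {
      o_start <- c(o_start, rep(i, length(gr$reps)))
      o_end <- c(o_end, rep(gr$end, length(gr$reps)))
      o_sent <- c(o_sent, rep(a$sidx[i], length(gr$reps)))
      o_key <- c(o_key, gr$reps)
      o_pure <- c(o_pure, rep(FALSE, length(gr$reps)))
    }
  }

  out <- list()
  n <- 1L
  repeat {
    uk <- unique(o_key)
    kid <- match(o_key, uk)
    occ_n <- tabulate(kid, nbins = length(uk))
    cases <- a$case_of_sent[o_sent]
    stats <- tibble(kid = kid, case = cases, pure = o_pure) %>%
      group_by(.data$kid) %>%
      summarise(support = dplyr::n_distinct(.data$case),
                all_pure = all(.data$pure), .groups = "drop")
    emit <- stats$kid[stats$support >= min_support & !stats$all_pure]
    if (length(emit) > 0) {
      profs <- lapply(emit, function(k) {
        .profile_from_cases(cases[kid == k], a$n_case)
      })
      out[[n]] <- tibble(key = uk[emit], n_len = n,
                         support = stats$support[match(emit, stats$kid)],
                         profile = profs)
    }
    if (n >= max_len) break
    keep <- which(occ_n[kid] >= thr & o_end < a$send[o_sent])
    if (length(keep) == 0) break
    ns <- integer(); ne <- integer(); nsent <- integer()
    nkey <- character(); npure <- logical()
    for (j in keep) {
      nxt <- o_end[j] + 1L
      r <- reps[[nxt]]
      ns <- c(ns, rep(o_start[j], length(r)))
      ne <- c(ne, rep(nxt, length(r)))
      nsent <- c(nsent, rep(o_sent[j], length(r)))
      nkey <- c(nkey, paste(o_key[j], r))
      npure <- c(npure, o_pure[j] & r == a$surface[nxt])
      grs <- grp_by_start[[as.character(nxt)]]
      for (gr in grs) {
        ns <- c(ns, rep(o_start[j], length(gr$reps)))
        ne <- c(ne, rep(gr$end, length(gr$reps)))
        nsent <- c(nsent, rep(o_sent[j], length(gr$reps)))
        nkey <- c(nkey, paste(o_key[j], gr$reps))
        npure <- c(npure, rep(FALSE, length(gr$reps)))
      }
    }
    o_start <- ns; o_end <- ne; o_sent <- nsent; o_key <- nkey; o_pure <- npure
    n <- n + 1L
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) return(empty)
  res$pattern <- vapply(strsplit(res$key, " ", fixed = TRUE),
                        .render_elements, character(1))
  res <- res[order(res$n_len, res$pattern, method = "radix"), ]
  tibble(pattern = res$pattern, type = "tagged", n_len = res$n_len,
         support = res$support, profile = res$profile)
}

#' Extract numeric "A <NUM> B" features
#'
#' For every `NUM`-tagged token, all pairs of flanking n-grams (each of
#' length 1 to `max_flank_len`, within the sentence) are candidate
#' features. A candidate becomes a feature if it matches in at least
#' `min_support` cases; if the flank pair matches more than once within
#' any single case, the whole feature is discarded to avoid ambiguity.
#' The per-case value is the matched token's numeric value.
#'
#' @param corpus A `patwas_corpus` with [annotate_numbers()] applied.
#' @param max_flank_len Maximum flank length in tokens (default 3).
#' @param min_support Minimum number of cases with a match.
#' @return Tibble with columns `pattern`, `type` (`"numeric"`), `n_len`,
#'   `support`, `profile` (cases with a value) and `values` (list-column
#'   of numeric vectors named by case id).
#' @export
extract_numeric_features <- function(corpus, max_flank_len = 3,
                                     min_support = 2) {
  stopifnot(max_flank_len >= 1, min_support >= 1)
  a <- .sent_arrays(corpus)
  empty <- tibble(pattern = character(), type = character(),
                  n_len = integer(), support = integer(), profile = list(),
                  values = list())
  num_pos <- which(vapply(a$tags, function(t) "NUM" %in% t, logical(1)))
  if (length(num_pos) == 0) return(empty)

  cand <- list()
  for (i in num_pos) {
    s <- a$sidx[i]
    p <- i - a$sstart[s] + 1L
    max_l <- min(max_flank_len, p - 1L)
    max_r <- min(max_flank_len, a$slen[s] - p)
    if (max_l < 1L || max_r < 1L) next
    for (la in seq_len(max_l)) {
      left <- a$surface[(i - la):(i - 1L)]
      for (ra in seq_len(max_r)) {
        right <- a$surface[(i + 1L):(i + ra)]
        cand[[length(cand) + 1L]] <- tibble(
          key = paste(paste(left, collapse = " "), "\x1f",
                      paste(right, collapse = " ")),
          left = paste(left, collapse = " "),
          right = paste(right, collapse = " "),
          case = a$case_of_sent[s],
          value = a$num_value[i]
        )
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- bind_rows(cand)
  per_case <- cand %>% count(.data$key, .data$case)
  ambiguous <- unique(per_case$key[per_case$n > 1])
  sup <- per_case %>% count(.data$key, name = "support")
  keep_keys <- setdiff(sup$key[sup$support >= min_support], ambiguous)
  if (length(keep_keys) == 0) return(empty)

  cand <- cand[cand$key %in% keep_keys, ]
  rows <- lapply(split(cand, cand$key), function(d) {
    ltoks <- strsplit(d$left[1], " ", fixed = TRUE)[[1]]
    rtoks <- strsplit(d$right[1], " ", fixed = TRUE)[[1]]
    prof <- .profile_from_cases(d$case, a$n_case)
    tibble(
      pattern = paste(.render_elements(ltoks), "<NUM>",
                      .render_elements(rtoks)),
      n_len = length(ltoks) + length(rtoks) + 1L,
      support = nrow(d),
      profile = list(prof),
      values = list(setNames(d$value, corpus$cases$case_id[d$case]))
    )
  })
  res <- bind_rows(rows)
  res <- res[order(res$n_len, res$pattern, method = "radix"), ]
  tibble(pattern = res$pattern, type = "numeric", n_len = res$n_len,
         support = res$support, profile = res$profile, values = res$values)
}

# match a literal/tag element vector starting at flat position i of
# sentence s; returns vector of possible end positions (flat, exclusive)
.match_elems_at <- function(elems, a, grp_by_start, i, send) {
  if (length(elems) == 0) return(i)
  e <- elems[1]
  ends <- integer()
  if (i > send) return(ends)
  is_tag <- grepl("^<[A-Z]+(:[^> ]*)?>$", e)
  val <- if (is_tag) substr(e, 2L, nchar(e) - 1L) else e
  # plain token at position i
  hit <- if (is_tag) val %in% a$tags[[i]] else a$surface[i] == val
  if (hit) {
    ends <- c(ends, .match_elems_at(elems[-1], a, grp_by_start, i + 1L, send))
  }
  # group starting at position i
  for (gr in grp_by_start[[as.character(i)]]) {
    ghit <- if (is_tag) val == gr$tag else gr$surface == val
    if (ghit && gr$end <= send) {
      ends <- c(ends, .match_elems_at(elems[-1], a, grp_by_start,
                                      gr$end + 1L, send))
    }
  }
  ends
}

#' Occurrence profile of a pattern
#'
#' A case's bit is set iff the pattern matches a contiguous token
#' subsequence of some sentence in any of the case's documents.
#'
#' @param pattern A display-rendered pattern string (literals and
#'   `<NS:value>` tag elements) or a character vector of elements.
#' @param corpus A `patwas_corpus`.
#' @return Logical vector in corpus case order.
#' @export
build_profile <- function(pattern, corpus) {
  elems <- if (length(pattern) == 1) .parse_elements(pattern) else pattern
  a <- .sent_arrays(corpus)
  prof <- logical(a$n_case)
  if (length(elems) == 0 || length(a$surface) == 0) return(prof)
  grp_by_start <- .groups_by_start(corpus, a)
  for (s in seq_along(a$sent_ids)) {
    ci <- a$case_of_sent[s]
    if (prof[ci]) next
    for (i in a$sstart[s]:a$send[s]) {
      if (length(.match_elems_at(elems, a, grp_by_start, i, a$send[s])) > 0) {
        prof[ci] <- TRUE
        break
      }
    }
  }
  prof
}

.groups_by_start <- function(corpus, a) {
  grp_by_start <- list()
  if (nrow(corpus$groups) > 0) {
    g <- corpus$groups
    gs <- match(g$sent_id, a$sent_ids)
    ok <- !is.na(gs)
    g <- g[ok, ]; gs <- gs[ok]
    fs <- a$sstart[gs] + g$start - 1L
    fe <- a$sstart[gs] + g$end - 1L
    for (i in seq_len(nrow(g))) {
      k <- as.character(fs[i])
      grp_by_start[[k]] <- c(grp_by_start[[k]], list(
        list(end = fe[i], surface = g$surface[i], tag = g$tag[i])
      ))
    }
  }
  grp_by_start
}
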