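test_that("pairwise global alignment is optimal and deterministic", {
  al <- align_pair(c("a", "b", "c"), c("a", "c"))
  expect_equal(al$score, 1)
  expect_equal(al$a, c("a", "b", "c"))
  expect_equal(al$b, c("a", NA, "c"))

  ident <- align_pair(letters[1:4], letters[1:4])
  expect_equal(ident$score, 4)
  expect_false(anyNA(c(ident$a, ident$b)))

  # single mismatched tokens: the mismatch column (-1) beats two gaps (-2)
  mm <- align_pair("a", "b")
  expect_equal(mm$score, -1)
  expect_equal(mm$a, "a")
  expect_equal(mm$b, "b")
})

test_that("alignment score equals exhaustive-search optimum on short pairs", {
  brute_score <- function(a, b) {
    # plain recursion over the three moves; no shared code with the DP
    if (length(a) == 0 && length(b) == 0) return(0)
    best <- -Inf
    if (length(a) > 0 && length(b) > 0) {
      s <- if (a[1] == b[1]) 1 else -1
      best <- max(best, s + brute_score(a[-1], b[-1]))
    }
    if (length(a) > 0) best <- max(best, -1 + brute_score(a[-1], b))
    if (length(b) > 0) best <- max(best, -1 + brute_score(a, b[-1]))
    best
  }
  for (seed in 1:30) {
    withr::with_seed(seed, {
      a <- sample(letters[1:3], sample(1:6, 1), replace = TRUE)
      b <- sample(letters[1:3], sample(1:6, 1), replace = TRUE)
    })
    al <- align_pair(a, b)
    expect_equal(al$score, brute_score(a, b))
    # removing gaps from each row recovers the sequences
    expect_equal(al$a[!is.na(al$a)], a)
    expect_equal(al$b[!is.na(al$b)], b)
  }
})

test_that("candidate groups are keyed by shared boundary tokens", {
  f <- tibble::tibble(
    pattern = c("a b c", "a d c", "a c", "a b", "c b"),
    type = "ngram", n_len = c(3, 3, 2, 2, 2), support = 2,
    profile = replicate(5, c(TRUE, TRUE), simplify = FALSE))
  g <- group_candidates(f)
  expect_length(g, 1)
  expect_setequal(g[[1]], c("a b c", "a d c", "a c"))

  f2 <- f[f$pattern %in% c("a b", "c b"), ]
  expect_length(group_candidates(f2), 0) # different starts: no group

  f3 <- tibble::tibble(
    pattern = c("extensive bone metastasis", "extensive liver metastasis"),
    type = "ngram", n_len = 3, support = 2,
    profile = replicate(2, TRUE, simplify = FALSE))
  expect_length(group_candidates(f3), 1)
})

test_that("consolidation reproduces the canonical induced expressions", {
  expect_equal(
    render_regex(consolidate(c("extensive bone metastasis",
                               "extensive liver metastasis"))),
    "extensive (bone|liver) metastasis")
  expect_equal(
    render_regex(consolidate(c("a reformed cigarette smoker",
                               "a cigarette smoker"))),
    "a (reformed)? cigarette smoker")
  expect_equal(
    render_regex(consolidate(c("SCC of the right tonsil -",
                               "SCC of the right base of tongue -",
                               "SCC of the right glossotonsillar sulcus -"))),
    "SCC of the right (tonsil|base of tongue|glossotonsillar sulcus) -")
  # empty variant plus several non-empty ones: optional alternation
  expect_equal(render_regex(consolidate(c("a b c", "a d c", "a c"))),
               "a (b|d)? c")
  expect_error(consolidate(c("a b", "a b")), "identical")
  expect_error(consolidate(c("a b", "c b")), "share")
})

test_that("alternation variants order by support then first appearance", {
  rx <- consolidate(c("x low y", "x high y"), supports = c(2, 9))
  expect_equal(render_regex(rx), "x (high|low) y")
})

test_that("regex rendering and parsing round-trip", {
  txt <- "irradiation (and|with) (or without|concurrent) chemotherapy"
  rx <- parse_regex(txt)
  expect_length(rx$elements, 4)
  expect_equal(rx$elements[[2]]$kind, "alt")
  expect_equal(render_regex(rx), txt)

  expect_equal(render_regex(parse_regex("a (b|c d) e")), "a (b|c d) e")
  expect_error(parse_regex("a tail head ("), "parenthesis")
  expect_error(parse_regex("a (b|b) c"), "duplicate")
})

test_that("expressions must start and end with literals", {
  expect_error(parse_regex("(a|b) x"), "literal")
  expect_error(parse_regex("x (a|b)"), "literal")
})

test_that("round-trip identity holds for random regexes", {
  for (seed in 1:200) {
    rx <- random_regex(seed)
    txt <- render_regex(rx)
    back <- parse_regex(txt)
    expect_equal(back$elements, rx$elements)
  }
})

test_that("regex matching follows alternation and optional semantics", {
  rx <- parse_regex("a (b|c) d")
  co <- tiny_corpus(c(c1 = "x a c d y", c2 = "a b d", c3 = "a d"))
  expect_equal(match_regex(rx, co), c(TRUE, TRUE, FALSE))

  rx2 <- parse_regex("a (b)? d")
  co2 <- tiny_corpus(c(c1 = "a d", c2 = "a b d", c3 = "a c d"))
  expect_equal(match_regex(rx2, co2), c(TRUE, TRUE, FALSE))
})

test_that("regex profiles equal the expansion oracle", {
  n_checked <- 0
  for (seed in 1:70) {
    rx <- random_regex(seed)
    co <- random_corpus(n_cases = 5, n_sent = 2, sent_len = 8,
                        alphabet = letters[1:5], seed = seed + 500)
    got <- match_regex(rx, co)
    variants <- oracle_regex_expand(rx)
    want <- Reduce(`|`, lapply(variants, function(v) oracle_profile(v, co)))
    expect_equal(got, want)
    n_checked <- n_checked + 1
    # soundness: the regex matches every one of its expansions when they
    # are planted as sentences
    if (seed <= 30) {
      plant <- tiny_corpus(setNames(
        vapply(variants, paste, "", collapse = " "),
        paste0("p", seq_along(variants))))
      expect_true(all(match_regex(rx, plant)))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 70)
})

test_that("induced regexes keep boundaries and dominate member profiles", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      first <- "s"; last <- "e"
      members <- unique(replicate(3, paste(
        c(first, sample(letters[1:4], sample(1:3, 1), replace = TRUE), last),
        collapse = " ")))
    })
    if (length(members) < 2) next
    rx <- consolidate(members)
    expect_equal(rx$elements[[1]], list(kind = "lit", value = "s"))
    expect_equal(rx$elements[[length(rx$elements)]],
                 list(kind = "lit", value = "e"))
    # soundness: matches every member
    plant <- tiny_corpus(setNames(members, paste0("m", seq_along(members))))
    expect_true(all(match_regex(rx, plant)))
  }
})

test_that("induction pools disjoint member profiles and improves p", {
  # two member phrases, each in 3 distinct positive cases; 6 negatives
  texts <- c(
    p1 = "x a y", p2 = "x a y", p3 = "x a y",
    p4 = "x b y", p5 = "x b y", p6 = "x b y",
    n1 = "z z", n2 = "z z", n3 = "z z", n4 = "z z", n5 = "z z", n6 = "z z")
  co <- tiny_corpus(texts, labels = binary_labels(
    names(texts), c(rep(1, 6), rep(0, 6))))
  f <- enumerate_ngrams(co, min_support = 2)
  res <- associate(f, co, "out")
  merged <- induce_and_rescore(res, co, "out")
  rx_row <- merged[merged$pattern == "x (a|b) y", ]
  expect_equal(nrow(rx_row), 1)
  expect_equal(rx_row$support, 6L)
  member_p <- res$p_value[res$pattern == "x a y"]
  expect_lt(rx_row$p_value, member_p)
  # exact values: members 3/0 vs outcome 6/6; regex 6/0
  expect_equal(member_p, fisher_two_sided(matrix(c(3, 0, 3, 6), 2,
                                                 byrow = TRUE)))
  expect_equal(rx_row$p_value, fisher_two_sided(matrix(c(6, 0, 0, 6), 2,
                                                       byrow = TRUE)))
  expect_true(rx_row$informative)
})

test_that("a regex identical to one member's profile is flagged uninformative", {
  # both member phrases co-occur in the same cases, so pooling them
  # cannot change the occurrence profile
  texts <- c(p1 = "s a e . s b e", p2 = "s a e . s b e",
             n1 = "w", n2 = "w")
  co <- tiny_corpus(texts, labels = binary_labels(names(texts),
                                                  c(1, 1, 0, 0)))
  f <- enumerate_ngrams(co, min_support = 2)
  res <- associate(f, co, "out")
  merged <- induce_and_rescore(res, co, "out")
  rx_rows <- merged[merged$type == "regex", ]
  expect_true(nrow(rx_rows) >= 1)
  expect_true(all(!rx_rows$informative)) # same cases as members
})

test_that("planted grade variants rank the induced regex above the members", {
  # "grade (1|2|3) tumour" spread across positives, absent in negatives
  texts <- c(
    p1 = "grade 1 tumour", p2 = "grade 1 tumour",
    p3 = "grade 2 tumour", p4 = "grade 2 tumour",
    p5 = "grade 3 tumour", p6 = "grade 3 tumour",
    n1 = "clear scan", n2 = "clear scan", n3 = "clear scan",
    n4 = "clear scan", n5 = "clear scan", n6 = "clear scan")
  co <- tiny_corpus(texts, labels = binary_labels(
    names(texts), c(rep(1, 6), rep(0, 6))))
  f <- enumerate_ngrams(co, min_support = 2)
  res <- associate(f, co, "out")
  merged <- induce_and_rescore(res, co, "out")
  rx_row <- merged[merged$pattern == "grade (1|2|3) tumour", ]
  expect_equal(nrow(rx_row), 1)
  member_ps <- res$p_value[res$pattern %in% c("grade 1 tumour",
                                              "grade 2 tumour",
                                              "grade 3 tumour")]
  expect_length(member_ps, 3)
  expect_true(all(rx_row$p_value < member_ps))
  # and the regex therefore outranks every individual variant
  expect_lt(match("grade (1|2|3) tumour", merged$pattern),
            min(match(c("grade 1 tumour", "grade 2 tumour",
                        "grade 3 tumour"), merged$pattern)))
})
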