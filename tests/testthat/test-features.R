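test_that("n-gram enumeration returns exactly the shared within-sentence patterns", {
  co <- tiny_corpus(c(case1 = "the right tonsil", case2 = "the right base"))
  f <- enumerate_ngrams(co, min_support = 2)
  expect_setequal(f$pattern, c("the", "right", "the right"))
  expect_true(all(vapply(f$profile, function(p) all(p), logical(1))))
  expect_true(all(f$support == 2))
})

test_that("patterns never cross sentence boundaries", {
  co <- tiny_corpus(c(c1 = "a b. c", c2 = "a b. c"))
  f <- enumerate_ngrams(co, min_support = 1)
  expect_false("b c" %in% f$pattern)
  expect_true("a b" %in% f$pattern)
})

test_that("n-gram enumeration equals the brute-force oracle", {
  for (seed in 1:8) {
    co <- random_corpus(n_cases = 5, n_sent = 1, sent_len = 20, seed = seed)
    f <- enumerate_ngrams(co, min_support = 2)
    o <- oracle_ngrams(co, min_support = 2)
    expect_equal(f$pattern, o$display)
    expect_equal(f$support, o$support)
    expect_equal(lapply(f$profile, which), o$cases, ignore_attr = TRUE)
  }
  # higher support threshold and length cap
  co <- random_corpus(n_cases = 6, n_sent = 2, sent_len = 15,
                      alphabet = letters[1:4], seed = 99)
  f <- enumerate_ngrams(co, min_support = 3, max_len = 3)
  o <- oracle_ngrams(co, min_support = 3, max_len = 3)
  expect_equal(f$support, o$support)
  expect_equal(f$pattern, o$display)
})

test_that("support is anti-monotone under pattern elongation", {
  co <- random_corpus(n_cases = 6, n_sent = 2, sent_len = 18, seed = 3)
  f <- enumerate_ngrams(co, min_support = 1)
  sup <- setNames(f$support, f$pattern)
  for (i in seq_len(nrow(f))) {
    if (f$n_len[i] < 2) next
    toks <- patwas:::.parse_elements(f$pattern[i])
    for (sub in list(toks[-1], toks[-length(toks)])) {
      key <- patwas:::.render_elements(sub)
      expect_gte(sup[[key]], f$support[i])
    }
  }
})

test_that("enumeration output order is deterministic", {
  co <- random_corpus(n_cases = 4, n_sent = 2, sent_len = 12, seed = 7)
  expect_identical(enumerate_ngrams(co), enumerate_ngrams(co))
  f <- enumerate_ngrams(co)
  expect_equal(order(f$n_len, f$pattern, method = "radix"),
               seq_len(nrow(f)))
})

test_that("tagged search generalises over annotations and drops pure-surface duplicates", {
  co <- tiny_corpus(c(c1 = "right tonsil", c2 = "left tonsil"))
  co <- set_tag(co, "right", "POS:JJ")
  co <- set_tag(co, "left", "POS:JJ")
  f <- enumerate_tagged_patterns(co, min_support = 2)
  hit <- f[f$pattern == "<POS:JJ> tonsil", ]
  expect_equal(nrow(hit), 1)
  expect_true(all(hit$profile[[1]]))
  # pure-surface combinations are not repeated here
  expect_false("tonsil" %in% f$pattern)

  # with no tags at all the extra set is empty
  co2 <- tiny_corpus(c(c1 = "a b", c2 = "a b"))
  expect_equal(nrow(enumerate_tagged_patterns(co2, min_support = 2)), 0)
})

test_that("tagged enumeration equals the representation cross-product oracle", {
  for (seed in 1:6) {
    co <- random_corpus(n_cases = 3, n_sent = 2, sent_len = 6,
                        alphabet = letters[1:4], seed = seed)
    # two tag namespaces assigned deterministically from the seed
    withr::with_seed(seed + 100, {
      for (surf in sample(letters[1:4], 2)) {
        co <- set_tag(co, surf, paste0("POS:", toupper(surf)))
      }
      co <- set_tag(co, sample(letters[1:4], 1), "STEM:x")
    })
    f <- enumerate_tagged_patterns(co, min_support = 2, max_len = 4)
    o <- oracle_tagged(co, min_support = 2, max_len = 4)
    expect_equal(f$pattern, o$display)
    expect_equal(f$support, o$support)
  }
})

test_that("group tokens participate as single-position alternatives", {
  co <- tiny_corpus(c(c1 = "base of tongue seen", c2 = "base of tongue seen"))
  co <- annotate_parse_groups(
    co, list(c1_d1 = "(S (NP (NN base) (IN of) (NN tongue)) (VB seen))",
             c2_d1 = "(S (NP (NN base) (IN of) (NN tongue)) (VB seen))"))
  f <- enumerate_tagged_patterns(co, min_support = 2, max_len = 3)
  # the group surface covers its span in a single position
  expect_true("base_of_tongue seen" %in% f$pattern)
  expect_true("<GRP:NP> seen" %in% f$pattern)
})

test_that("numeric features extract flanked cardinal values", {
  co <- annotate_numbers(tiny_corpus(c(
    c1 = "scan contains 3 metastatic nodes",
    c2 = "scan contains 7 metastatic nodes")))
  nf <- extract_numeric_features(co, min_support = 2)
  hit <- nf[nf$pattern == "contains <NUM> metastatic nodes", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$values[[1]], c(c1 = 3, c2 = 7))

  # ambiguity within one case discards the whole feature
  co2 <- annotate_numbers(tiny_corpus(c(
    c1 = "contains 3 metastatic nodes and contains 5 metastatic nodes",
    c2 = "contains 7 metastatic nodes")))
  nf2 <- extract_numeric_features(co2, min_support = 2)
  expect_false("contains <NUM> metastatic nodes" %in% nf2$pattern)

  # four cases, one value each
  co3 <- annotate_numbers(tiny_corpus(setNames(
    sprintf("age %d years", c(10, 20, 30, 40)), paste0("c", 1:4))))
  nf3 <- extract_numeric_features(co3, min_support = 2)
  hit3 <- nf3[nf3$pattern == "age <NUM> years", ]
  expect_equal(unname(hit3$values[[1]]), c(10, 20, 30, 40))
  expect_equal(hit3$support, 4L)
})

test_that("profiles from build_profile agree with a brute-force scan", {
  co <- tiny_corpus(c(c1 = "x a b y", c2 = "a b", c3 = "a c b"))
  expect_equal(build_profile("a b", co), c(TRUE, TRUE, FALSE))
  # longer than any sentence: all-zero
  expect_equal(build_profile(paste(rep("a", 10), collapse = " "), co),
               rep(FALSE, 3))
  # randomized agreement
  n_checked <- 0
  for (seed in 1:5) {
    co <- random_corpus(n_cases = 4, n_sent = 2, sent_len = 10, seed = seed)
    withr::with_seed(seed, {
      pats <- replicate(10, paste(sample(letters[1:6], sample(1:3, 1),
                                         replace = TRUE), collapse = " "))
    })
    for (p in pats) {
      elems <- strsplit(p, " ")[[1]]
      expect_equal(build_profile(p, co), oracle_profile(elems, co))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("tag elements and group tokens match in build_profile", {
  co <- tiny_corpus(c(c1 = "right tonsil", c2 = "left ear"))
  co <- set_tag(co, "right", "POS:JJ")
  co <- set_tag(co, "left", "POS:JJ")
  expect_equal(build_profile("<POS:JJ> tonsil", co), c(TRUE, FALSE))
  co3 <- annotate_parse_groups(
    tiny_corpus(c(c1 = "base of tongue seen", c2 = "other text")),
    list(c1_d1 = "(S (NP (NN base) (IN of) (NN tongue)) (VB seen))"))
  expect_equal(build_profile("base_of_tongue seen", co3), c(TRUE, FALSE))
  expect_equal(build_profile("<GRP:NP> seen", co3), c(TRUE, FALSE))
})
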