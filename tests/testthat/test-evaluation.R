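test_that("document and window co-occurrence counts are correct", {
  docs <- list(c("a", "b"), "a", c("b", "c"))
  cc <- count_cooccurrence(docs, c("a", "b", "c"), window = 10)
  expect_equal(unname(cc$doc_freq), c(2, 2, 1))
  expect_equal(cc$pair_doc_freq["a", "b"], 1)
  expect_equal(cc$pair_doc_freq["a", "c"], 0)
  expect_equal(cc$n_docs, 3)

  # window wider than every document: window stats equal document stats
  expect_equal(cc$n_windows, 3)
  expect_equal(unname(cc$window_freq), unname(cc$doc_freq))
  expect_equal(cc$pair_window_freq, cc$pair_doc_freq)

  # sliding windows step one token at a time
  cc2 <- count_cooccurrence(list(c("a", "x", "b", "x", "a")), c("a", "b"),
                            window = 2)
  # windows: ax, xb, bx, xa -> P(a) = 2/4, P(b) = 2/4, P(a,b) = 0
  expect_equal(cc2$n_windows, 4)
  expect_equal(unname(cc2$window_freq), c(2, 2))
  expect_equal(cc2$pair_window_freq["a", "b"], 0)

  # containment bound on random corpora
  set.seed(55)
  for (rep in 1:5) {
    docs_r <- replicate(8, sample(letters[1:6], sample(2:12, 1),
                                  replace = TRUE), simplify = FALSE)
    ccr <- count_cooccurrence(docs_r, letters[1:6], window = 4)
    pw <- ccr$pair_window_freq / ccr$n_windows
    p <- ccr$window_freq / ccr$n_windows
    expect_true(all(pw <= outer(p, p, pmin) + 1e-12))
    expect_true(all(ccr$pair_doc_freq <=
                      outer(ccr$doc_freq, ccr$doc_freq, pmin) + 1e-12))
  }
})

test_that("coherence formulas behave at their limit cases", {
  # two words that always co-occur: umass pair term log((D+eps)/D) ~ 0
  docs <- list(c("flu", "cough"), c("flu", "cough"), c("flu", "cough"))
  cc <- count_cooccurrence(docs, c("flu", "cough"), window = 10)
  um <- coherence(list(c("flu", "cough")), cc, "umass")
  expect_equal(um$mean, log((3 + 1e-12) / 3), tolerance = 1e-15)
  expect_lt(abs(um$mean), 1e-9)

  # perfect association with p < 1: npmi ~ 1
  docs2 <- list(c("flu", "cough"), c("mg", "dose"), c("mg", "dose"))
  cc2 <- count_cooccurrence(docs2, c("flu", "cough"), window = 10)
  np <- coherence(list(c("flu", "cough")), cc2, "npmi")
  expect_equal(np$mean, 1, tolerance = 1e-6)

  # words in every window: degenerate pair scored 0
  cc3 <- count_cooccurrence(docs, c("flu", "cough"), window = 10)
  np3 <- coherence(list(c("flu", "cough")), cc3, "npmi")
  expect_equal(np3$mean, 0)
})

test_that("umass matches hand-counted document frequencies", {
  docs <- list(c("flu", "cough"), c("flu", "cough", "fever"),
               c("mg", "dose"))
  cc <- count_cooccurrence(docs, c("flu", "cough"), window = 10)
  # D(flu) = 2, D(cough) = 2, D(flu, cough) = 2; ordered pair (cough, flu)
  expected <- log((2 + 1e-12) / 2)
  got <- coherence(list(c("flu", "cough")), cc, "umass")$mean
  expect_equal(got, expected, tolerance = 1e-15)
})

test_that("all three measures match the brute-force pair-enumeration oracle", {
  set.seed(66)
  words <- c("flu", "cough", "fever", "mg", "dose", "bp")
  for (rep in 1:4) {
    docs <- replicate(sample(3:5, 1),
                      sample(words, sample(2:9, 1), replace = TRUE),
                      simplify = FALSE)
    topics <- list(sample(words, 3), sample(words, 2))
    cc <- count_cooccurrence(docs, words, window = 5)
    for (m in c("umass", "uci", "npmi")) {
      mine <- coherence(topics, cc, m)
      ref <- oracle_coherence(topics, docs, m, window = 5)
      expect_equal(mine$per_topic, ref$per_topic, tolerance = 1e-9)
      expect_equal(mine$mean, ref$mean, tolerance = 1e-9)
    }
  }
})

test_that("npmi pair scores stay within [-1, 1]", {
  set.seed(91)
  words <- letters[1:8]
  docs <- replicate(12, sample(words, sample(3:10, 1), replace = TRUE),
                    simplify = FALSE)
  cc <- count_cooccurrence(docs, words, window = 4)
  topics <- list(words[1:4], words[5:8], c("a", "e", "h"))
  np <- coherence(topics, cc, "npmi")
  expect_true(all(np$per_topic >= -1 - 1e-9))
  expect_true(all(np$per_topic <= 1 + 1e-9))
})

test_that("topic diversity counts unique words in the bag", {
  K <- 50
  redundant <- topic_bag(rep(list(c("flu", "shot", "arm", "due", "oct")),
                             K))
  d <- topic_diversity(redundant)
  expect_equal(d$n_total, 250)
  expect_equal(d$n_unique, 5)
  expect_equal(d$percent, 2)

  distinct <- topic_bag(split(sprintf("w%03d", 1:250), rep(1:50, each = 5)))
  expect_equal(topic_diversity(distinct)$percent, 100)

  # diversity bounds: L/(K*L) <= diversity <= 1
  expect_gte(d$diversity, 5 / 250)
  expect_lte(topic_diversity(distinct)$diversity, 1)
})

test_that("jaccard concordance satisfies its set identities", {
  b1 <- c("a", "b", "c")
  b2 <- c("b", "c", "d")
  j <- jaccard_concordance(list(m1 = b1, m2 = b2))
  expect_equal(j["m1", "m2"], 0.5)
  expect_equal(diag(j), c(m1 = 1, m2 = 1))
  expect_equal(j, t(j))

  expect_equal(jaccard_concordance(list(x = b1, y = b1))["x", "y"], 1)
  expect_equal(jaccard_concordance(list(x = b1, y = c("z", "q")))["x", "y"],
               0)

  # triangle-like bound J(a,c) >= J(a,b) + J(b,c) - 1 on random sets
  set.seed(12)
  for (rep in 1:20) {
    sets <- replicate(3, sample(letters, sample(3:10, 1)),
                      simplify = FALSE)
    jj <- jaccard_concordance(sets)
    expect_gte(jj[1, 3], jj[1, 2] + jj[2, 3] - 1 - 1e-12)
  }
})

test_that("recurring words rank bag multiplicities with alphabetical ties", {
  bag <- topic_bag(list(c("pain", "pain"), c("mg", "bp")))
  rw <- recurring_words(bag, 1)
  expect_equal(rw$word, "pain")
  expect_equal(rw$count, 2L)

  bag2 <- topic_bag(list(c("back", "bp"), c("pain", "back")))
  rw2 <- recurring_words(bag2, 3)
  expect_equal(rw2$word, c("back", "bp", "pain"))
  expect_equal(rw2$count, c(2L, 1L, 1L))

  # all-unique bag: every count 1, alphabetical
  bag3 <- topic_bag(list(c("c", "a"), c("b", "d")))
  rw3 <- recurring_words(bag3, 4)
  expect_equal(rw3$word, c("a", "b", "c", "d"))
  expect_true(all(rw3$count == 1L))
})
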