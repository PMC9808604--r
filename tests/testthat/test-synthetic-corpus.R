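test_that("planted topics are row-stochastic and concentration controls sparsity", {
  phi1 <- make_topics(1, 3, 1, seed = 11)
  expect_equal(dim(phi1), c(1L, 3L))
  expect_true(all(phi1 >= 0))
  expect_equal(sum(phi1), 1, tolerance = 1e-12)

  # Monte-Carlo: sparse Dirichlet rows (low concentration) have strictly
  # lower mean entropy than diffuse ones, over 50 replicate seeds
  entropy <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  ent <- vapply(1:50, function(s) {
    sparse <- make_topics(5, 200, 0.05, seed = s)
    diffuse <- make_topics(5, 200, 5.0, seed = s)
    c(mean(apply(sparse, 1, entropy)), mean(apply(diffuse, 1, entropy)))
  }, numeric(2))
  expect_lt(mean(ent[1, ]), mean(ent[2, ]))

  expect_error(make_topics(5, 200, 0), "positive")
  expect_error(make_topics(5, 3, 1), "vocab_size")
})

test_that("prevalence curves follow the planted cosine trends", {
  # all-constant topics: perfectly symmetric mixture
  flat <- make_prevalence_curves(6, rep(list(trend_constant()), 4))
  expect_true(all(abs(flat - 0.25) < 1e-12))

  # amplitude 0 is identical to declaring the topic constant
  a0 <- make_prevalence_curves(8, list(trend_seasonal(0, 4, 0),
                                       trend_constant()))
  cc <- make_prevalence_curves(8, list(trend_constant(),
                                       trend_constant()))
  expect_equal(a0, cc)

  # seasonal topic peaks where the cosine peaks: quarters 1 and 5 for
  # period 4, phase 0, over T=8
  curves <- make_prevalence_curves(8, list(trend_seasonal(0.5, 4, 0),
                                           trend_constant()))
  expected_raw <- 1 + 0.5 * cos(2 * pi * ((1:8 - 1) - 0) / 4)
  expected <- expected_raw / (expected_raw + 1)
  expect_equal(unname(curves[, 1]), expected, tolerance = 1e-12)
  expect_setequal(which(curves[, 1] == max(curves[, 1])), c(1L, 5L))
  expect_true(all(abs(rowSums(curves) - 1) < 1e-12))

  expect_error(trend_seasonal(1.0), "amplitude")
  expect_error(make_prevalence_curves(4, list()), "nonempty")
})

test_that("generate_corpus draws the designed number of notes and tokens", {
  phi <- matrix(c(0.5, 0.3, 0.2), 1, 3,
                dimnames = list("topic_1", c("aa", "bb", "cc")))
  curves <- matrix(1, 2, 1, dimnames = list(c("q1", "q2"), "topic_1"))
  truth <- synthetic_ground_truth(phi, curves)
  spec <- cohort_spec(2, 2, notes_per_patient_quarter = 1, doc_length = 5,
                      seed = 42)
  corpus <- generate_corpus(spec, truth)
  expect_s3_class(corpus, "raw_corpus")
  expect_equal(nrow(corpus), 4L)
  expect_true(all(lengths(strsplit(corpus$text, " ")) == 5L))
  expect_equal(anyDuplicated(corpus$doc_id), 0L)

  # shape error when curves and cohort disagree
  spec3 <- cohort_spec(2, 3, seed = 1)
  expect_error(generate_corpus(spec3, truth), "n_quarters")
})

test_that("empirical word frequencies converge to the planted mixture", {
  phi <- matrix(c(0.5, 0.3, 0.2), 1, 3,
                dimnames = list("topic_1", c("aa", "bb", "cc")))
  truth <- synthetic_ground_truth(
    phi, matrix(1, 1, 1, dimnames = list("q1", "topic_1")))
  spec <- cohort_spec(10, 1, notes_per_patient_quarter = 10,
                      doc_length = 1000, seed = 9)  # 100,000 tokens
  corpus <- generate_corpus(spec, truth)
  toks <- unlist(strsplit(corpus$text, " "))
  expect_length(toks, 100000L)
  freq <- table(toks)[c("aa", "bb", "cc")] / length(toks)
  expect_true(all(abs(freq - c(0.5, 0.3, 0.2)) < 0.01))
})

test_that("simulation is reproducible and honors the closed-cohort design", {
  phi <- make_topics(3, 40, 0.2, seed = 5)
  trends <- list(trend_seasonal(0.4), trend_constant(), trend_constant())
  truth <- synthetic_ground_truth(phi, make_prevalence_curves(6, trends),
                                  trend_specs = trends, seed = 5)
  spec <- cohort_spec(7, 6, seed = 17)
  c1 <- generate_corpus(spec, truth)
  c2 <- generate_corpus(spec, truth)
  expect_identical(c1, c2)

  # every patient has at least one note in every quarter
  tab <- table(c1$patient_id, c1$quarter)
  expect_true(all(tab >= 1))
  expect_equal(dim(tab), c(7L, 6L))

  # jitter and noise options still yield valid corpora
  cj <- generate_corpus(spec, truth, doc_jitter = 10, noise = 0.2)
  expect_equal(sort(unique(cj$patient_id)), sort(unique(c1$patient_id)))
  tokj <- tokenize_corpus(cj)
  expect_true(all(unlist(tokj$tokens) %in% colnames(phi)))
})

test_that("corpus and ground truth round-trip through their text formats", {
  phi <- make_topics(2, 10, 0.5, seed = 2)
  trends <- list(trend_seasonal(0.3), trend_constant())
  truth <- synthetic_ground_truth(phi, make_prevalence_curves(4, trends),
                                  trend_specs = trends, seed = 2)
  spec <- cohort_spec(3, 4, seed = 8)
  corpus <- generate_corpus(spec, truth)

  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "corpus.jsonl")
  write_corpus_jsonl(corpus, p)
  back <- read_corpus_jsonl(p)
  expect_identical(as.data.frame(back), as.data.frame(corpus))

  write_ground_truth(truth, file.path(tmp, "truth"))
  tback <- read_ground_truth(file.path(tmp, "truth"))
  expect_equal(tback$phi_true, truth$phi_true, tolerance = 1e-12)
  expect_equal(tback$prevalence_curves, truth$prevalence_curves,
               tolerance = 1e-12)
})
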