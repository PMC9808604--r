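test_that("tokenizer applies the whitespace/lowercase/alpha/length rules", {
  expect_equal(tokenize_note("BP 120/80 today!"), c("bp", "today"))
  expect_equal(tokenize_note(""), character(0))
  expect_equal(tokenize_note("a I x2 flu\tflu"), c("flu", "flu"))
  expect_equal(tokenize_note("Chest\r\npain,  severe."),
               c("chest", "pain", "severe"))
  # idempotence: re-tokenizing the space-join returns the same sequence
  for (txt in c("BP 120/80 today!", "Flu shot DUE - Oct.",
                "a1c 7.2% up; diet r/v")) {
    toks <- tokenize_note(txt)
    expect_identical(tokenize_note(paste(toks, collapse = " ")), toks)
  }
})

test_that("dates map to chronological calendar-quarter indices", {
  expect_equal(quarter_index(c("2011-01-01", "2011-03-31", "2011-04-01",
                               "2011-12-31", "2015-10-01"), 2011),
               c(1L, 1L, 2L, 4L, 20L))
})

test_that("closed-cohort filter keeps only fully observed patients", {
  tok <- toy_tokenized(
    rep(list(c("flu", "shot")), 7),
    patient = c(rep("A", 4), rep("B", 3)),
    quarter = c(1, 2, 3, 4, 1, 2, 4))  # B misses quarter 3
  kept <- filter_closed_cohort(tok, 4)
  expect_setequal(unique(kept$patient_id), "A")
  expect_equal(nrow(kept), 4L)

  # all complete -> identity; empty corpus -> empty corpus
  all_ok <- filter_closed_cohort(tok[tok$patient_id == "A", ], 4)
  expect_equal(nrow(all_ok), 4L)
  empty <- tok[0, ]
  expect_equal(nrow(filter_closed_cohort(empty, 4)), 0L)
})

test_that("vocabulary construction ranks, filters, and breaks ties", {
  tok <- toy_tokenized(list(c("flu", "flu", "flu", "pain", "pain", "rare")))
  v <- build_vocabulary(tok, min_count = 2)
  expect_equal(v$token, c("flu", "pain"))
  expect_equal(v$count, c(3L, 2L))

  v2 <- build_vocabulary(tok, min_count = 2, stoplist = "flu")
  expect_equal(v2$token, "pain")

  # equal counts: alphabetical order
  tok3 <- toy_tokenized(list(c("zeta", "beta", "alpha")))
  v3 <- build_vocabulary(tok3)
  expect_equal(v3$token, c("alpha", "beta", "zeta"))

  expect_error(build_vocabulary(tok, min_count = 100), "empty vocabulary")
  expect_equal(nrow(build_vocabulary(tok, max_size = 1)), 1L)
})

test_that("DTM counts tokens at note and patient-quarter level", {
  tok <- toy_tokenized(list(c("flu", "flu", "pain"), "pain"),
                       patient = c("A", "A"), quarter = c(1, 1))
  vocab <- build_vocabulary(tok)
  # vocab order: flu(2)? counts flu=2 pain=2 -> alphabetical: flu, pain
  expect_equal(vocab$token, c("flu", "pain"))

  note_dtm <- build_dtm(tok, vocab, level = "note")
  expect_equal(unname(as.matrix(note_dtm$counts)),
               matrix(c(2, 0, 1, 1), 2, 2))

  pq <- build_dtm(tok, vocab, level = "patient_quarter", n_quarters = 1)
  expect_equal(unname(as.matrix(pq$counts)), matrix(c(2, 2), 1, 2))
  expect_equal(pq$row_meta$unit_id, "A_q1")

  # OOV-only notes become all-zero rows; grid stays complete
  tok2 <- toy_tokenized(list(c("flu", "pain"), "unseen"),
                        patient = c("A", "A"), quarter = c(1, 2))
  pq2 <- build_dtm(tok2, vocab, level = "patient_quarter", n_quarters = 2)
  expect_equal(nrow(pq2$counts), 2L)
  expect_equal(sum(pq2$counts[2, ]), 0)
})

test_that("DTM conservation and aggregation-consistency invariants hold", {
  set.seed(404)
  words <- c("flu", "pain", "cough", "mg", "bp")
  docs <- replicate(12, sample(words, sample(3:8, 1), replace = TRUE),
                    simplify = FALSE)
  pats <- sample(c("A", "B", "C"), 12, replace = TRUE)
  qs <- sample(1:2, 12, replace = TRUE)
  tok <- toy_tokenized(docs, patient = pats, quarter = qs)
  vocab <- build_vocabulary(tok, min_count = 2)

  note_dtm <- build_dtm(tok, vocab, level = "note")
  in_vocab <- sum(unlist(docs) %in% vocab$token)
  expect_equal(sum(note_dtm$counts), in_vocab)

  pq_dtm <- build_dtm(tok, vocab, level = "patient_quarter",
                      n_quarters = 2)
  # patient-quarter DTM equals the 0/1 aggregation map times the note DTM
  agg <- matrix(0, nrow(pq_dtm$counts), nrow(note_dtm$counts))
  key <- paste0(tok$patient_id, "_q", tok$quarter)
  agg[cbind(match(key, pq_dtm$row_meta$unit_id),
            seq_len(nrow(note_dtm$counts)))] <- 1
  expect_equal(unname(as.matrix(pq_dtm$counts)),
               unname(agg %*% as.matrix(note_dtm$counts)))
})

test_that("corpus summary reports sparsity and top-term shares", {
  tok <- toy_tokenized(list(c("flu", "flu", "flu", "pain")))
  vocab <- build_vocabulary(tok)
  dtm <- build_dtm(tok, vocab, level = "note")
  s <- summarize_corpus(dtm, top_n = 1)
  expect_equal(s$top_terms$token, "flu")
  expect_equal(s$top_terms$count, 3)
  expect_equal(s$top_terms$share, 0.75)

  # 2x3 matrix with one nonzero entry -> sparsity 5/6
  m <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(2, 3),
                            dimnames = list(NULL, c("aa", "bb", "cc")))
  dtm2 <- structure(
    list(counts = m,
         row_meta = data.frame(unit_id = c("u1", "u2"),
                               patient_id = c("p1", "p2"),
                               quarter = c(1L, 1L)),
         level = "note",
         vocabulary = structure(
           data.frame(token = c("aa", "bb", "cc"), count = c(2L, 0L, 0L)),
           class = c("vocabulary", "data.frame"))),
    class = "dtm")
  expect_equal(summarize_corpus(dtm2)$sparsity, 5 / 6)

  # dense all-ones matrix -> sparsity 0
  m3 <- methods::as(Matrix::Matrix(1, 2, 2,
                                   dimnames = list(NULL, c("aa", "bb"))),
                    "CsparseMatrix")
  dtm3 <- dtm2
  dtm3$counts <- m3
  dtm3$row_meta <- dtm2$row_meta
  expect_equal(summarize_corpus(dtm3)$sparsity, 0)
})

test_that("DTM round-trips through Matrix Market + TSV files", {
  tok <- toy_tokenized(list(c("flu", "pain", "flu"), c("mg", "pain")),
                       patient = c("A", "B"), quarter = c(1, 1))
  vocab <- build_vocabulary(tok)
  dtm <- build_dtm(tok, vocab, level = "note")
  tmp <- withr::local_tempdir()
  write_dtm(dtm, tmp)
  back <- read_dtm(tmp)
  expect_equal(as.matrix(back$counts), as.matrix(dtm$counts))
  expect_equal(back$row_meta, dtm$row_meta)
  expect_equal(back$vocabulary$token, dtm$vocabulary$token)
  expect_equal(back$level, "note")
})
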