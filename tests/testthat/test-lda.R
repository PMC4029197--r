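# LDA engine: derived matrices, determinism, separability, top terms.

test_that("config invariants are enforced", {
  expect_error(lda_config(k = 1), "k must be")
  expect_error(lda_config(k = 3, alpha = 0), "alpha")
  expect_error(lda_config(k = 3, eta = -1), "eta")
  expect_error(lda_config(k = 3, iterations = 10, burn_in = 10),
               "iterations > burn_in")
  cfg <- lda_config(k = 4)
  expect_equal(cfg$alpha, 50 / 4)
  expect_equal(cfg$eta, 0.1)
})

test_that("proportions normalize per document (100-token worked case)", {
  fit <- genetopics:::lda_fit_from_assignments(
    list(d1 = c(rep(1L, 40), rep(2L, 60))), k = 3)
  expect_equal(unname(topic_proportions(fit)[1, ]), c(0.4, 0.6, 0))
  expect_equal(unname(word_count_matrix(fit)[1, ]), c(40, 60, 0))
})

test_that("degenerate single-word document gets a unit proportion row", {
  corpus <- preprocess_corpus(text_corpus("kinase"),
                              stopwords = character(0))
  tdm <- term_document_matrix(corpus)
  w <- capture_warnings(
    fit <- fit_lda(tdm, lda_config(k = 2, iterations = 5, burn_in = 0,
                                   seed = 3)))
  expect_true(any(grepl("degenerate", w)))
  p <- unname(topic_proportions(fit)[1, ])
  expect_true(identical(p, c(1, 0)) || identical(p, c(0, 1)))
})

test_that("fits are reproducible under a fixed seed", {
  fx <- small_planted_fixture()
  ws <- build_working_set(fx$genes, fx$index, seed = 1)
  corpus <- preprocess_corpus(assemble_corpus(ws, fx$index, 5))
  tdm <- term_document_matrix(corpus)
  f1 <- fit_lda(tdm, fast_lda(3, seed = 99))
  f2 <- fit_lda(tdm, fast_lda(3, seed = 99))
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$topic_word_counts, f2$topic_word_counts)
  f3 <- fit_lda(tdm, fast_lda(3, seed = 100))
  expect_false(identical(f1$assignments, f3$assignments))
})

test_that("two disjoint vocabularies separate cleanly at k = 2", {
  set.seed(4)
  vocabA <- sprintf("alpha%02d", 1:20)
  vocabB <- sprintf("beta%02d", 1:20)
  texts <- c(
    replicate(15, paste(sample(vocabA, 30, TRUE), collapse = " ")),
    replicate(15, paste(sample(vocabB, 30, TRUE), collapse = " ")))
  corpus <- preprocess_corpus(text_corpus(texts),
                              stopwords = character(0))
  tdm <- term_document_matrix(corpus)
  fit <- fit_lda(tdm, lda_config(k = 2, iterations = 300, burn_in = 150,
                                 seed = 11))
  dominant <- apply(topic_proportions(fit), 1, max)
  expect_true(all(dominant > 0.9))
})

test_that("word counts match a brute-force tally of assignments", {
  fx <- small_planted_fixture(seed = 6)
  ws <- build_working_set(fx$genes, fx$index, seed = 2)
  corpus <- preprocess_corpus(assemble_corpus(ws, fx$index, 4))
  tdm <- term_document_matrix(corpus)
  fit <- fit_lda(tdm, fast_lda(4, seed = 5))
  wcm <- word_count_matrix(fit)
  for (d in seq_along(fit$assignments))
    expect_equal(unname(wcm[d, ]),
                 tabulate(fit$assignments[[d]], nbins = 4))
  # conservation across all derived matrices
  total <- sum(tdm)
  expect_equal(sum(wcm), total)
  expect_equal(sum(fit$topic_word_counts), total)
  expect_equal(unname(rowSums(topic_proportions(fit))),
               rep(1, nrow(wcm)), tolerance = 1e-12)
})

test_that("top terms rank by count with ascending-stem tie-break", {
  twc <- matrix(c(5L, 3L, 3L, 0L,
                  1L, 0L, 2L, 4L), nrow = 2, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  fit <- structure(list(k = 2L, topic_word_counts = twc,
                        word_count_matrix = matrix(1, 1, 2)),
                   class = "lda_fit")
  expect_identical(top_terms(fit, 1, 3), c("a", "b", "c"))
  # n beyond the nonzero stems truncates
  expect_identical(top_terms(fit, 1, 10), c("a", "b", "c"))
  # full-sort oracle on the second topic
  cnt <- twc[2, ]; cnt <- cnt[cnt > 0]
  oracle <- names(cnt)[order(-cnt, names(cnt))]
  expect_identical(top_terms(fit, 2, 10), oracle)
  # surface mapping
  expect_identical(top_terms(fit, 1, 2,
                             stem_to_surface = c(a = "alpha", b = "beta")),
                   c("alpha", "beta"))
})

test_that("k not smaller than the token count warns of degeneracy", {
  corpus <- preprocess_corpus(text_corpus("kinase tumor"),
                              stopwords = character(0))
  tdm <- term_document_matrix(corpus)
  expect_warning(fit_lda(tdm, lda_config(k = 2, iterations = 5,
                                         burn_in = 0)),
                 "degenerate")
})

test_that("argmax assignment mode is deterministic and conserves tokens", {
  fx <- small_planted_fixture(seed = 12)
  ws <- build_working_set(fx$genes, fx$index, seed = 3)
  corpus <- preprocess_corpus(assemble_corpus(ws, fx$index, 4))
  tdm <- term_document_matrix(corpus)
  cfg <- lda_config(k = 3, iterations = 100, burn_in = 50, seed = 7,
                    assignment_mode = "argmax")
  f1 <- fit_lda(tdm, cfg)
  f2 <- fit_lda(tdm, cfg)
  expect_identical(f1$assignments, f2$assignments)
  expect_equal(sum(word_count_matrix(f1)), sum(tdm))
})

test_that("planted topics are recovered with high term overlap", {
  # corpus generated from K true topics with well-separated word
  # distributions; greedy matching of fitted to true topics by top-20
  # term overlap must reach a mean Jaccard of at least 0.5
  K <- 3
  fx <- generate_fixture(fixture_spec(
    n_topics_true = K, vocab_size = 300, topic_concentration = 0.05,
    n_gene_groups = 3, genes_per_group = 6, n_background_genes = 6,
    docs_per_gene = 10, doc_length_mean = 50, purity = 0.95, seed = 21))
  ws <- suppressWarnings(build_working_set(fx$genes, fx$index, seed = 4))
  corpus <- preprocess_corpus(assemble_corpus(ws, fx$index, 10))
  tdm <- term_document_matrix(corpus)
  fit <- fit_lda(tdm, lda_config(k = K, iterations = 500, burn_in = 250,
                                 seed = 17))
  true_top <- lapply(seq_len(K), function(t)
    colnames(fx$truth$topic_word_dists)[
      order(-fx$truth$topic_word_dists[t, ])][1:20])
  fit_top <- lapply(seq_len(K), function(t) top_terms(fit, t, 20))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  jm <- outer(seq_len(K), seq_len(K),
              Vectorize(function(i, j) jac(fit_top[[i]], true_top[[j]])))
  best <- numeric(0)
  for (i in seq_len(K)) {
    idx <- which(jm == max(jm), arr.ind = TRUE)[1, ]
    best <- c(best, jm[idx[1], idx[2]])
    jm[idx[1], ] <- -1; jm[, idx[2]] <- -1
  }
  expect_gte(mean(best), 0.5)
})
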