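# Working-set construction, corpus assembly, preprocessing and the
# term-document matrix.

test_that("random genes match usable input count and are disjoint", {
  idx <- random_index(n_genes = 30, n_docs = 80, seed = 3)
  input <- sprintf("G%02d", 1:10)
  ws <- build_working_set(input, idx, seed = 5)
  expect_length(ws$random_genes, 10)
  expect_length(intersect(tolower(ws$input_genes),
                          tolower(ws$random_genes)), 0)
  # determinism
  ws2 <- build_working_set(input, idx, seed = 5)
  expect_identical(ws2$random_genes, ws$random_genes)
})

test_that("input genes without documents are excluded, not scored", {
  idx <- tiny_index()
  ws <- build_working_set(c("AKT1", "GHOST"), idx, seed = 1)
  expect_identical(ws$excluded_genes, "GHOST")
  expect_identical(ws$input_genes, "AKT1")
  expect_error(build_working_set("GHOST", idx), "no input gene")
})

test_that("an undersized background pool is used whole, with a warning", {
  idx <- random_index(n_genes = 12, seed = 2)
  input <- sprintf("G%02d", 1:10)
  expect_warning(ws <- build_working_set(input, idx, seed = 1),
                 "smaller than input set")
  expect_length(ws$random_genes, 2)
})

test_that("random draw is uniform over the eligible pool across seeds", {
  idx <- random_index(n_genes = 12, n_docs = 60, seed = 9)
  input <- c("G01", "G02")  # pool = 10 genes, draw 2 per seed
  n_seeds <- 1000
  draws <- unlist(lapply(seq_len(n_seeds), function(s)
    build_working_set(input, idx, seed = s)$random_genes))
  tab <- table(factor(draws, levels = sprintf("G%02d", 3:12)))
  # chi-square against uniform selection frequency
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("corpus deduplicates shared documents and keeps both genes", {
  links <- data.frame(gene = c("A", "B", "B"),
                      doc_id = c("d1", "d1", "d2"), relevancy = 1)
  docs <- data.frame(doc_id = c("d1", "d2"), year = 2000L,
                     title = c("one", "two"), abstract = c("x", "y"))
  idx <- gene_doc_index(links, docs)
  ws <- suppressWarnings(build_working_set("A", idx, seed = 1))
  corpus <- assemble_corpus(ws, idx, n_docs = 50)
  expect_setequal(corpus$doc_ids, c("d1", "d2"))
  expect_setequal(corpus$doc_genes[["d1"]], c("A", "B"))
})

test_that("disjoint literatures concatenate without loss", {
  links <- data.frame(gene = rep(c("A", "B"), each = 3),
                      doc_id = sprintf("d%d", 1:6), relevancy = 1)
  docs <- data.frame(doc_id = sprintf("d%d", 1:6), year = 2000L,
                     title = paste("t", 1:6), abstract = paste("a", 1:6))
  idx <- gene_doc_index(links, docs)
  ws <- suppressWarnings(build_working_set("A", idx, seed = 1))
  corpus <- assemble_corpus(ws, idx, n_docs = 3)
  expect_length(corpus$doc_ids, 6)
})

test_that("corpus size accounts exactly for duplicate selections", {
  fx <- generate_fixture(fixture_spec(
    n_topics_true = 3, vocab_size = 200, n_gene_groups = 1,
    genes_per_group = 5, n_background_genes = 10, docs_per_gene = 6,
    doc_length_mean = 30, seed = 8), shared_docs = TRUE)
  ws <- build_working_set(fx$genes, fx$index, seed = 2)
  corpus <- assemble_corpus(ws, fx$index, n_docs = 6)
  selections <- sum(lengths(corpus$gene_docs))
  dups <- selections - length(corpus$doc_ids)
  # set-union counting oracle
  all_sel <- unlist(corpus$gene_docs, use.names = FALSE)
  expect_equal(dups, sum(duplicated(all_sel)))
})

test_that("preprocessing lowercases, strips punctuation, stems", {
  corpus <- text_corpus("Glycolysis and gluconeogenesis.")
  out <- preprocess_corpus(corpus, stopwords = "and")
  expect_identical(out$tokens[[1]], c("glycolysi", "gluconeogenesi"))
})

test_that("numerals are retained through preprocessing", {
  corpus <- text_corpus("95% confidence")
  out <- preprocess_corpus(corpus, stopwords = character(0))
  expect_identical(out$tokens[[1]], c("95", "confid"))
})

test_that("hyphenated terms fuse into single tokens", {
  corpus <- text_corpus("enoyl-CoA and acyl-CoA/thiolase")
  out <- preprocess_corpus(corpus, stopwords = "and")
  expect_identical(out$tokens[[1]], c("enoylcoa", "acylcoathiolas"))
})

test_that("documents reduced to zero tokens are dropped with a warning", {
  corpus <- text_corpus(c("A", "kinase signaling"),
                        doc_ids = c("empty", "ok"),
                        genes = c("G1", "G1"))
  expect_warning(out <- preprocess_corpus(corpus, stopwords = "a"),
                 "zero tokens")
  expect_identical(out$doc_ids, "ok")
  expect_false("empty" %in% names(out$doc_genes))
  expect_identical(out$gene_docs[["G1"]], "ok")
})

test_that("stem display form is the most frequent surface, ties lexical", {
  corpus <- text_corpus(c("activated activated activation kinase",
                          "activates activating"))
  out <- preprocess_corpus(corpus, stopwords = character(0))
  expect_identical(unname(out$stem_to_surface[["activ"]]), "activated")
  # tie between two singletons resolves lexicographically
  corpus2 <- text_corpus("studies studied")
  out2 <- preprocess_corpus(corpus2, stopwords = character(0))
  expect_identical(unname(out2$stem_to_surface[["studi"]]), "studied")
  # every stem in the vocabulary has a surface form
  expect_true(all(out$vocab %in% names(out$stem_to_surface)))
})

test_that("term-document matrix counts match a dense brute-force tally", {
  texts <- c("kinase kinase tumor", "tumor growth factor",
             "kinase growth growth", "factor", "tumor tumor tumor kinase")
  corpus <- preprocess_corpus(text_corpus(texts),
                              stopwords = character(0))
  tdm <- term_document_matrix(corpus)
  expect_equal(unname(Matrix::colSums(tdm)),
               unname(lengths(corpus$tokens)))
  expect_equal(sum(tdm), sum(lengths(corpus$tokens)))
  dense <- matrix(0, length(corpus$vocab), length(texts),
                  dimnames = list(corpus$vocab, corpus$doc_ids))
  for (d in seq_along(texts))
    for (w in corpus$tokens[[d]])
      dense[w, d] <- dense[w, d] + 1
  expect_equal(as.matrix(tdm), dense)
})

test_that("a single stemmed document yields the expected column", {
  corpus <- preprocess_corpus(text_corpus("alpha beta alpha"),
                              stopwords = character(0))
  tdm <- term_document_matrix(corpus)
  expect_equal(as.vector(tdm[c("alpha", "beta"), 1]), c(2, 1))
})

test_that("the packaged stopword list is usable and contains basics", {
  sw <- default_stopwords()
  expect_true(all(c("and", "the", "of", "a") %in% sw))
})
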