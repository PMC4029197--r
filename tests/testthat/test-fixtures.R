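# Synthetic fixture generator and recovery metrics.

test_that("invalid specs are rejected with the offending fields listed", {
  expect_error(fixture_spec(n_topics_true = 1), "n_topics_true")
  expect_error(fixture_spec(purity = 0), "purity")
  expect_error(fixture_spec(n_gene_groups = 6, n_topics_true = 5),
               "n_gene_groups <= n_topics_true")
  expect_warning(fixture_spec(n_topics_true = 4, purity = 0.2),
                 "no signal")
})

test_that("a fixed seed gives byte-identical fixture files", {
  spec <- fixture_spec(n_topics_true = 3, vocab_size = 120,
                       n_gene_groups = 1, genes_per_group = 4,
                       n_background_genes = 8, docs_per_gene = 4,
                       doc_length_mean = 20, seed = 77)
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  f1 <- generate_fixture(spec, out_dir = t1)
  f2 <- generate_fixture(spec, out_dir = t2)
  for (i in seq_along(f1$paths))
    expect_identical(readLines(f1$paths[i]), readLines(f2$paths[i]))
})

test_that("null fixtures plant nothing and still name an input set", {
  fx <- generate_fixture(fixture_spec(
    n_topics_true = 3, vocab_size = 100, n_gene_groups = 0,
    n_background_genes = 10, docs_per_gene = 3, doc_length_mean = 15,
    seed = 5))
  expect_true(all(is.na(unlist(fx$truth$gene_home_topic))))
  expect_true(length(fx$genes) >= 1)
  expect_true(all(fx$genes %in% fx$index$background))
})

test_that("full purity concentrates document tokens on the home topic", {
  fx <- generate_fixture(fixture_spec(
    n_topics_true = 4, vocab_size = 200, n_gene_groups = 2,
    genes_per_group = 3, n_background_genes = 4, docs_per_gene = 4,
    doc_length_mean = 30, purity = 1, seed = 13))
  home <- unlist(fx$truth$gene_home_topic)
  for (g in names(home)[!is.na(home)]) {
    docs <- fx$index$links$doc_id[fx$index$links$gene == g]
    tok <- fx$truth$doc_topic_token_counts[docs, , drop = FALSE]
    frac_home <- sum(tok[, home[[g]]]) / sum(tok)
    expect_gte(frac_home, 0.8)
  }
})

test_that("generated corpora satisfy every upstream precondition", {
  fx <- small_planted_fixture(seed = 3)
  # all genes documented
  expect_true(all(lengths(split(fx$index$links$doc_id,
                                fx$index$links$gene)) >= 1))
  # years pass the default filter; relevancies are 1
  expect_true(all(fx$index$docs$year >= 1996))
  expect_true(all(fx$index$links$relevancy == 1))
  # no document preprocesses to zero tokens
  ws <- build_working_set(fx$genes, fx$index, seed = 1)
  corpus <- expect_no_warning(
    preprocess_corpus(assemble_corpus(ws, fx$index, 10)))
  expect_true(all(lengths(corpus$tokens) > 0))
  # pseudo-words are fixed points of the stemmer
  expect_identical(porter_stem(corpus$vocab), corpus$vocab)
})

test_that("fixture files load back into an equal index", {
  td <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(
    n_topics_true = 3, vocab_size = 100, n_gene_groups = 1,
    genes_per_group = 3, n_background_genes = 6, docs_per_gene = 3,
    doc_length_mean = 15, seed = 19), out_dir = td)
  idx <- load_index(fx$paths[1], fx$paths[2])
  expect_equal(idx$links, fx$index$links)
  expect_equal(idx$docs, fx$index$docs)
  expect_identical(read_gene_list(fx$paths[3]), fx$genes)
})

test_that("recovery metrics match hand-computed values on a toy truth", {
  truth <- structure(list(
    topic_word_dists = matrix(0.5, 2, 2),
    gene_home_topic = list(a1 = 1L, a2 = 1L, a3 = 1L,
                           b1 = 2L, b2 = 2L, bg = NA_integer_),
    doc_mixtures = NULL, doc_topic_token_counts = NULL),
    class = "fixture_truth")
  mk_report <- function(topics) structure(
    list(run_manifest = list(), selected_k = 4L, topics = topics),
    class = "genetopics_report")
  mk_topic <- function(j, genes) list(
    topic = j, p_raw = 0.001, p_bonferroni = 0.004, n_input_high =
      length(genes), n_input = 5L, prop_random = 0, top_terms = list(),
    members = lapply(genes, function(g)
      list(gene = g, score = 0.9, supporting_doc_ids = list())))

  # perfect recovery
  rec <- evaluate_recovery(mk_report(list(
    mk_topic(1L, c("a1", "a2", "a3")), mk_topic(2L, c("b1", "b2")))),
    truth)
  expect_equal(rec$topic_match_rate, 1)
  expect_equal(rec$gene_precision, 1)
  expect_equal(rec$gene_recall, 1)
  expect_equal(rec$false_topic_count, 0)

  # partial overlap, one unmatched (false) topic; exhaustive check:
  # topic 1 carries {a1, a2, b1}, topic 3 carries {bg} only.
  # Greedy matching pairs topic 1 with group 1 (overlap 2, precision 2/3,
  # recall 2/3); group 2's best remaining overlap via topic 3 is 0, so
  # topic 3 stays unmatched.
  rec2 <- evaluate_recovery(mk_report(list(
    mk_topic(1L, c("a1", "a2", "b1")), mk_topic(3L, "bg"))), truth)
  expect_equal(rec2$pairs$topic, 1L)
  expect_equal(rec2$pairs$group, 1L)
  expect_equal(rec2$topic_match_rate, 0.5)
  expect_equal(rec2$gene_precision, 2 / 3)
  expect_equal(rec2$gene_recall, 2 / 5)
  expect_equal(rec2$false_topic_count, 1)

  # empty report on a null truth
  null_truth <- truth
  null_truth$gene_home_topic <- list(x = NA_integer_)
  rec3 <- evaluate_recovery(mk_report(list()), null_truth)
  expect_equal(rec3$false_topic_count, 0)
  expect_true(is.na(rec3$topic_match_rate))
})

test_that("recovery improves with purity (monotone trend)", {
  purities <- c(0.35, 0.5, 0.65, 0.8, 0.95)
  mean_recall <- vapply(purities, function(p) {
    recalls <- vapply(1:4, function(s) {
      fx <- generate_fixture(fixture_spec(
        n_topics_true = 3, vocab_size = 150, n_gene_groups = 2,
        genes_per_group = 5, n_background_genes = 12, docs_per_gene = 5,
        doc_length_mean = 30, purity = p, seed = 1000 + s))
      run <- suppressWarnings(genetopics(
        fx$genes, fx$index, topic_grid = 3,
        lda_control = fast_lda(3), seed = 2000 + s))
      rec <- evaluate_recovery(run$report, fx$truth)
      if (is.na(rec$gene_recall)) 0 else rec$gene_recall
    }, numeric(1))
    mean(recalls)
  }, numeric(1))
  expect_gte(stats::cor(purities, mean_recall, method = "spearman"), 0)
})
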