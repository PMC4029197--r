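# In-code fixtures shared across test files. Everything is generated at
# test time; nothing is read from disk except files the tests write
# themselves.

# A tiny hand-written index: 3 genes, 5 documents, known years/relevancies.
tiny_index <- function() {
  links <- data.frame(
    gene = c("AKT1", "AKT1", "AKT1", "TP53", "TP53", "BRCA1"),
    doc_id = c("d1", "d2", "d3", "d3", "d4", "d5"),
    relevancy = c(0.9, 0.5, 0.7, 1.0, 0.2, 0.6)
  )
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3", "d4", "d5"),
    year = c(1990L, 1999L, 2005L, 2010L, 2001L),
    title = paste("title", 1:5),
    abstract = paste("abstract text of document", 1:5)
  )
  gene_doc_index(links, docs)
}

# Random index with controlled sizes, for counting oracles.
random_index <- function(n_genes = 10, n_docs = 40, links_per_gene = 8,
                         seed = 1) {
  set.seed(seed)
  docs <- data.frame(
    doc_id = sprintf("p%03d", seq_len(n_docs)),
    year = sample(1985:2015, n_docs, replace = TRUE),
    title = replicate(n_docs, paste(sample(letters, 4), collapse = "")),
    abstract = replicate(n_docs, paste(
      sample(c("alpha", "beta", "gamma", "delta", "kinase", "tumor"),
             8, replace = TRUE), collapse = " "))
  )
  links <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    data.frame(gene = sprintf("G%02d", g),
               doc_id = sample(docs$doc_id, links_per_gene),
               relevancy = round(stats::runif(links_per_gene), 3))
  }))
  gene_doc_index(links, docs)
}

# A corpus built directly from raw text strings (bypasses the index).
text_corpus <- function(texts, doc_ids = sprintf("doc%d", seq_along(texts)),
                        genes = rep("G1", length(texts))) {
  doc_genes <- as.list(genes)
  names(doc_genes) <- doc_ids
  gene_docs <- split(doc_ids, genes)
  structure(list(doc_ids = doc_ids, text = texts, doc_genes = doc_genes,
                 gene_docs = gene_docs, preprocessed = FALSE),
            class = "gene_corpus")
}

# A gene-topic matrix built by hand for enrichment tests.
make_gtm <- function(input_scores, random_scores) {
  scores <- rbind(input_scores, random_scores)
  rownames(scores) <- c(sprintf("IN%02d", seq_len(nrow(input_scores))),
                        sprintf("RN%02d", seq_len(nrow(random_scores))))
  structure(list(scores = scores, genes = rownames(scores),
                 group = rep(c("input", "random"),
                             c(nrow(input_scores), nrow(random_scores))),
                 excluded = character(0)),
            class = "gene_topic_matrix")
}

# Small planted fixture used by several end-to-end tests.
small_planted_fixture <- function(seed = 42) {
  generate_fixture(fixture_spec(
    n_topics_true = 4, vocab_size = 300, n_gene_groups = 2,
    genes_per_group = 8, n_background_genes = 20, docs_per_gene = 8,
    doc_length_mean = 40, purity = 0.85, seed = seed))
}

fast_lda <- function(k, seed = 1, ...) {
  lda_config(k = k, iterations = 200L, burn_in = 100L, seed = seed, ...)
}
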