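## End-to-end orchestration: index -> filter -> working set -> corpus ->
## preprocessing -> topic-number search -> enrichment -> report.

#' Annotate a gene set with literature topics
#'
#' The top-level fitting function. Takes an input gene list and a
#' gene-document index, embeds an equal-sized random background gene set,
#' assembles and preprocesses the literature corpus, scans the topic-number
#' grid with one collapsed-Gibbs LDA fit per candidate k, tests every topic
#' for specificity to the input genes with a one-tailed binomial test
#' against the random genes (Bonferroni-corrected), and reports the
#' significant topics of the selected model with their top terms, member
#' genes and supporting document ids.
#'
#' @param genes character vector of gene identifiers, or the path of a
#'   plain-text gene list (one per line, `#` comments allowed).
#' @param index a [gene_doc_index()], or a length-2 character vector
#'   `c(links_path, docs_path)` loaded via [load_index()].
#' @param background optional character vector (or file path) restricting
#'   the background gene pool; default: all genes in the index.
#' @param docs_per_gene documents sampled per gene; default 50.
#' @param min_year,min_relevancy link filter, see [filter_index()];
#'   defaults 1996 and 0.
#' @param stopwords stopword vector; default [default_stopwords()].
#' @param topic_grid increasing vector of candidate topic numbers; default
#'   `c(5, 10, 15, 20, 25, 30, 40, 50, 75, 100)`. A single value
#'   reproduces a plain fixed-k run.
#' @param threshold gene-score discretization threshold; default 0.5.
#' @param alpha_level significance level on corrected p-values; default
#'   0.05.
#' @param stop_rule,null_smoothing,test see [search_topic_number()] and
#'   [enrichment_test()].
#' @param top_n_terms display terms per reported topic; default 20.
#' @param lda_control an [lda_config()] template for the per-k fits (its
#'   `k` and `seed` are overridden during the search).
#' @param sample_mode document selection mode, see [sample_documents()].
#' @param seed integer master seed; drives the random-gene draw and, via a
#'   deterministic per-k derivation, every LDA fit. Identical inputs and
#'   seed give a byte-identical report.
#' @return an object of class `genetopics`: list with `manifest`, `ws`,
#'   `corpus`, `search` (the [search_topic_number()] trace), `fit`, `gtm`,
#'   `enrichment` (all at the selected k) and `report`.
#' @seealso [write_report()], [generate_fixture()]
#' @export
genetopics <- function(genes, index, background = NULL,
                       docs_per_gene = 50L, min_year = 1996L,
                       min_relevancy = 0, stopwords = default_stopwords(),
                       topic_grid = default_topic_grid(), threshold = 0.5,
                       alpha_level = 0.05,
                       stop_rule = c("no-increase", "strict-decline"),
                       null_smoothing = c("laplace", "raw"),
                       test = c("binomial", "ks", "wilcoxon"),
                       top_n_terms = 20L,
                       lda_control = lda_config(k = 5),
                       sample_mode = "top", seed = 1L) {
  stop_rule <- match.arg(stop_rule)
  null_smoothing <- match.arg(null_smoothing)
  test <- match.arg(test)

  if (is.character(genes) && length(genes) == 1L && file.exists(genes))
    genes <- read_gene_list(genes)
  if (is.character(index)) {
    stopifnot(length(index) == 2L)
    index <- load_index(index[1], index[2])
  }
  stopifnot(inherits(index, "gene_doc_index"))
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- read_gene_list(background)

  index_f <- filter_index(index, min_year = min_year,
                          min_relevancy = min_relevancy)
  ws <- build_working_set(genes, index_f, background = background,
                          seed = seed)
  corpus <- assemble_corpus(ws, index_f, n_docs = docs_per_gene)
  corpus <- preprocess_corpus(corpus, stopwords = stopwords)

  search <- search_topic_number(corpus, ws, grid = topic_grid,
                                base_config = lda_control,
                                threshold = threshold,
                                alpha_level = alpha_level,
                                null_smoothing = null_smoothing,
                                test = test, stop_rule = stop_rule)
  sel <- search$evaluated[[search$selected]]

  manifest <- list(
    package = "genetopics",
    version = as.character(utils::packageVersion("genetopics")),
    seed = as.integer(seed),
    n_input_genes = length(ws$input_genes),
    n_random_genes = length(ws$random_genes),
    excluded_genes = as.list(ws$excluded_genes),
    docs_per_gene = as.integer(docs_per_gene),
    min_year = as.integer(min_year),
    min_relevancy = min_relevancy,
    n_documents = length(corpus$doc_ids),
    vocabulary_size = length(corpus$vocab),
    topic_grid = as.list(as.integer(topic_grid)),
    evaluated_k = as.list(vapply(search$evaluated, `[[`, 0L, "k")),
    n_significant = as.list(search$n_significant),
    selected_k = search$selected_k,
    stop_reason = search$stop_reason,
    stop_rule = stop_rule,
    threshold = threshold,
    alpha_level = alpha_level,
    test = test,
    null_smoothing = null_smoothing,
    lda = list(alpha = if (is.null(lda_control)) NA else "50/k",
               eta = lda_control$eta,
               iterations = lda_control$iterations,
               burn_in = lda_control$burn_in,
               assignment_mode = lda_control$assignment_mode)
  )

  report <- build_report(sel$fit, sel$gtm, sel$enrichment, corpus,
                         manifest = manifest, top_n_terms = top_n_terms)

  structure(
    list(manifest = manifest, ws = ws, corpus = corpus, search = search,
         fit = sel$fit, gtm = sel$gtm, enrichment = sel$enrichment,
         report = report),
    class = "genetopics"
  )
}

#' @export
print.genetopics <- function(x, ...) {
  cat("GeneTopics run\n")
  cat("  input genes:", x$manifest$n_input_genes,
      " random genes:", x$manifest$n_random_genes, "\n")
  if (length(x$manifest$excluded_genes))
    cat("  excluded (no documents):",
        paste(unlist(x$manifest$excluded_genes), collapse = ", "), "\n")
  cat("  corpus:", x$manifest$n_documents, "documents,",
      x$manifest$vocabulary_size, "stems\n")
  cat("  selected k:", x$manifest$selected_k,
      paste0("(", x$manifest$stop_reason, ")"), "\n")
  cat("  significant topics:", length(x$report$topics), "\n")
  invisible(x)
}

#' @export
summary.genetopics <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$enrichment)
  invisible(object)
}

#' Plot score distributions for a topic
#'
#' Base-graphics density overlay of the input-gene and random-gene score
#' distributions the enrichment test compares, with the discretization
#' threshold marked.
#'
#' @param x a `genetopics` object.
#' @param topic topic index of the selected fit; default: the best
#'   reported topic, or topic 1 if none is significant.
#' @param ... passed to [plot()].
#' @return invisibly, the [score_distributions()] list.
#' @export
plot.genetopics <- function(x, topic = NULL, ...) {
  if (is.null(topic))
    topic <- if (length(x$report$topics)) x$report$topics[[1]]$topic else 1L
  sd <- score_distributions(x$gtm, topic)
  di <- stats::density(sd$input, from = 0, to = 1)
  dr <- stats::density(sd$random, from = 0, to = 1)
  plot(di, col = "firebrick", lwd = 2, xlab = "gene-topic score",
       main = paste0("Topic ", topic, ": input vs random gene scores"),
       ylim = range(0, di$y, dr$y), ...)
  graphics::lines(dr, col = "steelblue", lwd = 2)
  graphics::abline(v = attr(x$enrichment, "threshold"), lty = 2)
  graphics::legend("topright", legend = c("input", "random"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(sd)
}
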