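## Latent Dirichlet allocation by collapsed Gibbs sampling, and the two
## derived matrices the downstream gene scoring relies on:
##
##   word count matrix     (documents x topics)  tokens of d assigned to j
##   topic proportion matrix (documents x topics) word counts normalized
##                                                PER DOCUMENT, rows sum 1
##
## A document with 100 tokens of which 40 are assigned to topic 1 and 60
## to topic 2 therefore has proportions (0.4, 0.6, 0, ...).

#' LDA sampler configuration
#'
#' Hyperparameters and run-length settings for [fit_lda()]. The defaults
#' follow common Gibbs-LDA practice: a document-topic concentration of
#' `50 / k`, a topic-word concentration of `0.1`, 1000 sweeps with the
#' first 500 discarded as burn-in (burn-in only affects
#' `assignment_mode = "argmax"`).
#'
#' @param k number of topics (>= 2).
#' @param alpha document-topic Dirichlet concentration (> 0).
#' @param eta topic-word Dirichlet concentration (> 0).
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging (argmax mode).
#' @param seed integer RNG seed; fixed seed makes fits reproducible.
#' @param assignment_mode `"final"` takes token-topic assignments from the
#'   last sweep (a posterior sample); `"argmax"` averages post-burn-in
#'   assignment counts per token and takes the per-token argmax (ties go
#'   to the smaller topic index).
#' @return a list of class `lda_config`.
#' @export
lda_config <- function(k, alpha = 50 / k, eta = 0.1, iterations = 1000L,
                       burn_in = 500L, seed = 1L,
                       assignment_mode = c("final", "argmax")) {
  assignment_mode <- match.arg(assignment_mode)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be finite and > 0")
  if (!is.finite(eta) || eta <= 0) stop("eta must be finite and > 0")
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (!(iterations > burn_in && burn_in >= 0L))
    stop("need iterations > burn_in >= 0")
  structure(list(k = k, alpha = alpha, eta = eta, iterations = iterations,
                 burn_in = burn_in, seed = as.integer(seed),
                 assignment_mode = assignment_mode),
            class = "lda_config")
}

## Build the derived matrices of a fit from per-document assignments.
## assignments: named list (doc_id -> integer topic vector, 1-based, one
## per token); words: parallel list of vocab indices (may be NULL when only
## the document-side matrices are needed, e.g. in tests).
lda_fit_from_assignments <- function(assignments, k, vocab = NULL,
                                     words = NULL, config = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L, length(assignments) > 0L)
  nd <- length(assignments)
  wcm <- matrix(0L, nd, k,
                dimnames = list(names(assignments), paste0("topic", 1:k)))
  for (d in seq_len(nd)) {
    a <- assignments[[d]]
    if (length(a) == 0L) stop("document ", d, " has zero tokens")
    if (any(a < 1L | a > k)) stop("assignment outside 1..k")
    wcm[d, ] <- tabulate(a, nbins = k)
  }
  tpm <- wcm / rowSums(wcm)
  twc <- NULL
  if (!is.null(words)) {
    stopifnot(!is.null(vocab))
    twc <- matrix(0L, k, length(vocab),
                  dimnames = list(paste0("topic", 1:k), vocab))
    aw <- unlist(assignments, use.names = FALSE)
    ww <- unlist(words, use.names = FALSE)
    tt <- table(factor(aw, levels = 1:k), factor(ww, levels = seq_along(vocab)))
    twc[] <- as.integer(tt)
  }
  structure(list(config = config, k = k, assignments = assignments,
                 words = words, vocab = vocab,
                 topic_word_counts = twc,
                 word_count_matrix = wcm,
                 topic_proportion_matrix = tpm),
            class = "lda_fit")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Runs a collapsed Gibbs sampler over per-token topic assignments and
#' derives the word count matrix (documents x topics), the per-document
#' topic proportion matrix and the topic-word count matrix. With a fixed
#' seed the fit is fully reproducible.
#'
#' @param tdm term-document matrix (terms x documents), as returned by
#'   [term_document_matrix()]; any matrix coercible to sparse counts works.
#' @param config an [lda_config()].
#' @return an object of class `lda_fit` with elements `config`, `k`,
#'   `assignments` (per-document 1-based topic vectors),
#'   `topic_word_counts` (k x vocab), `word_count_matrix` (documents x k)
#'   and `topic_proportion_matrix` (documents x k, rows sum to 1).
#' @export
fit_lda <- function(tdm, config) {
  stopifnot(inherits(config, "lda_config"))
  if (!methods::is(tdm, "CsparseMatrix"))
    tdm <- if (methods::is(tdm, "Matrix"))
      methods::as(tdm, "CsparseMatrix")
    else
      Matrix::Matrix(as.matrix(tdm), sparse = TRUE, doDiag = FALSE)
  if (nrow(tdm) == 0L || ncol(tdm) == 0L) stop("empty term-document matrix")
  counts <- Matrix::colSums(tdm)
  if (any(counts == 0))
    stop("zero-token document(s) in term-document matrix: ",
         paste(utils::head(colnames(tdm)[counts == 0], 5), collapse = ", "))
  total <- sum(counts)
  if (config$k >= total)
    warning("k (", config$k, ") is not smaller than the total token ",
            "count (", total, "); the fit is degenerate")
  if (nrow(tdm) < config$k)
    warning("vocabulary (", nrow(tdm), ") smaller than k (", config$k, ")")

  ## expand to token streams; within a document, tokens are laid out in
  ## ascending vocabulary order (bag of words, so any fixed order is valid)
  m <- Matrix::summary(tdm)
  ord <- order(m$j, m$i, method = "radix")
  reps <- as.integer(m$x[ord])
  word <- rep.int(m$i[ord], reps)
  doc <- rep.int(m$j[ord], reps)

  set.seed(config$seed)
  z <- gibbs_lda_cpp(word - 1L, doc - 1L, ncol(tdm), nrow(tdm), config$k,
                     config$alpha, config$eta, config$iterations,
                     config$burn_in,
                     identical(config$assignment_mode, "argmax")) + 1L

  assignments <- split(z, factor(doc, levels = seq_len(ncol(tdm))))
  names(assignments) <- colnames(tdm)
  words <- split(word, factor(doc, levels = seq_len(ncol(tdm))))
  names(words) <- colnames(tdm)

  fit <- lda_fit_from_assignments(assignments, config$k,
                                  vocab = rownames(tdm), words = words,
                                  config = config)
  fit
}

#' Word count matrix of a fit
#'
#' Entry (d, j) is the number of tokens of document d assigned to topic j;
#' row sums equal per-document token counts.
#'
#' @param fit an `lda_fit`.
#' @return integer matrix (documents x topics).
#' @export
word_count_matrix <- function(fit) {
  stopifnot(inherits(fit, "lda_fit"))
  fit$word_count_matrix
}

#' Topic proportion matrix of a fit
#'
#' Each document's row of the word count matrix divided by its token
#' count; rows sum to 1.
#'
#' @param fit an `lda_fit`.
#' @return numeric matrix (documents x topics).
#' @export
topic_proportions <- function(fit) {
  stopifnot(inherits(fit, "lda_fit"))
  fit$topic_proportion_matrix
}

#' Top terms of a topic
#'
#' Stems ranked by the topic's assigned-token counts, descending, with
#' ties broken by ascending stem; only stems with a positive count are
#' returned, so the list may be shorter than `n`. If a stem-to-surface map
#' is supplied, display forms are returned instead of stems.
#'
#' @param fit an `lda_fit` carrying topic-word counts.
#' @param topic topic index in `1..k`.
#' @param n maximum number of terms; default 20.
#' @param stem_to_surface optional named character vector (stem -> display
#'   word), e.g. `corpus$stem_to_surface`.
#' @return character vector of terms.
#' @export
top_terms <- function(fit, topic, n = 20L, stem_to_surface = NULL) {
  stopifnot(inherits(fit, "lda_fit"), topic >= 1L, topic <= fit$k, n >= 1L)
  if (is.null(fit$topic_word_counts))
    stop("fit carries no topic-word counts")
  cnt <- fit$topic_word_counts[topic, ]
  stems <- colnames(fit$topic_word_counts)
  keep <- cnt > 0
  cnt <- cnt[keep]; stems <- stems[keep]
  ord <- order(-cnt, stems, method = "radix")
  out <- stems[ord][seq_len(min(n, length(stems)))]
  if (!is.null(stem_to_surface)) {
    mapped <- unname(stem_to_surface[out])
    out <- ifelse(is.na(mapped), out, mapped)
  }
  out
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("LDA fit (collapsed Gibbs)\n")
  cat("  topics:   ", x$k, "\n")
  cat("  documents:", nrow(x$word_count_matrix), "\n")
  cat("  tokens:   ", sum(x$word_count_matrix), "\n")
  if (!is.null(x$config))
    cat("  config:    alpha=", signif(x$config$alpha, 3),
        " eta=", x$config$eta, " iterations=", x$config$iterations,
        " seed=", x$config$seed, "\n", sep = "")
  invisible(x)
}
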