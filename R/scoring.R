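## Gene-topic scoring and topic enrichment against the embedded random
## background.
##
## A gene's score for a topic is the MAXIMUM topic proportion over the
## gene's documents: the max emphasizes the multi-functional role of genes,
## and single publications usually focus on one biological aspect. The
## enrichment test discretizes scores at a threshold (default 0.5, strict
## ">") and asks, one-tailed, whether more input genes clear it than the
## random-gene proportion predicts.

#' Gene topic matrix
#'
#' For every gene of the working set, the rows of the topic proportion
#' matrix belonging to the gene's documents are max-reduced column-wise.
#' Genes whose documents were all dropped during preprocessing are moved
#' to the excluded set with a warning rather than silently zero-scored.
#'
#' @param fit an [fit_lda()] result over `corpus`.
#' @param corpus the preprocessed [gene_corpus][preprocess_corpus()] the
#'   fit was computed on.
#' @param ws the [working_gene_set][build_working_set()].
#' @return an object of class `gene_topic_matrix`: list with `scores`
#'   (genes x k matrix, input genes first), `genes`, `group`
#'   (`"input"`/`"random"`) and `excluded` (genes without surviving
#'   documents).
#' @export
gene_topic_matrix <- function(fit, corpus, ws) {
  stopifnot(inherits(fit, "lda_fit"), inherits(corpus, "gene_corpus"),
            inherits(ws, "working_gene_set"))
  tpm <- topic_proportions(fit)
  genes <- c(ws$input_genes, ws$random_genes)
  group <- rep(c("input", "random"),
               c(length(ws$input_genes), length(ws$random_genes)))
  rows <- lapply(genes, function(g) {
    d <- corpus$gene_docs[[g]]
    d <- d[d %in% rownames(tpm)]
    if (length(d) == 0L) return(NULL)
    apply(tpm[d, , drop = FALSE], 2, max)
  })
  dead <- vapply(rows, is.null, logical(1))
  if (any(dead))
    warning("gene(s) with no surviving documents excluded from scoring: ",
            paste(genes[dead], collapse = ", "))
  if (all(dead)) stop("no gene has surviving documents")
  scores <- do.call(rbind, rows[!dead])
  rownames(scores) <- genes[!dead]
  structure(list(scores = scores, genes = genes[!dead],
                 group = group[!dead], excluded = genes[dead]),
            class = "gene_topic_matrix")
}

#' Topic enrichment test against the random background
#'
#' Per topic, counts the input genes with score strictly above `threshold`
#' and tests that count, one-tailed, against a binomial null whose success
#' probability comes from the random genes' proportion above the same
#' threshold. By default the null proportion is smoothed with a
#' Laplace-style pseudocount, `p0 = (n_random_high + 1) / (n_random + 2)`,
#' which keeps the null bounded away from 0 (a raw proportion of exactly 0
#' would make any input success infinitely significant);
#' `null_smoothing = "raw"` uses the unsmoothed proportion. Raw p-values
#' are Bonferroni-corrected by the number of topics of the current fit.
#'
#' @param gtm a [gene_topic_matrix()].
#' @param threshold score discretization threshold in (0, 1); default 0.5.
#' @param alpha_level significance level on corrected p-values; default
#'   0.05.
#' @param null_smoothing `"laplace"` (default) or `"raw"`.
#' @param test `"binomial"` (default; the method's test), or `"ks"` /
#'   `"wilcoxon"` comparing the two score distributions directly (kept for
#'   comparison; both tend to flag topics whose scores are higher than
#'   random yet uniformly low, which is why the discretized binomial test
#'   is the default).
#' @return data.frame of class `topic_enrichment`, one row per topic:
#'   `topic`, `n_input_high`, `n_input`, `n_random_high`, `n_random`,
#'   `prop_random` (raw), `p0` (null proportion used), `p_raw`,
#'   `p_bonferroni`, `significant`, plus a list column `member_genes`
#'   (input genes with score above threshold).
#' @export
enrichment_test <- function(gtm, threshold = 0.5, alpha_level = 0.05,
                            null_smoothing = c("laplace", "raw"),
                            test = c("binomial", "ks", "wilcoxon")) {
  stopifnot(inherits(gtm, "gene_topic_matrix"))
  null_smoothing <- match.arg(null_smoothing)
  test <- match.arg(test)
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie strictly inside (0, 1)")
  k <- ncol(gtm$scores)
  inp <- gtm$scores[gtm$group == "input", , drop = FALSE]
  rnd <- gtm$scores[gtm$group == "random", , drop = FALSE]
  n_input <- nrow(inp)
  n_random <- nrow(rnd)
  if (n_input == 0L) stop("no input genes with scores")
  if (n_random < 1L) stop("need at least one random background gene")

  res <- lapply(seq_len(k), function(j) {
    x <- sum(inp[, j] > threshold)
    r <- sum(rnd[, j] > threshold)
    prop_random <- r / n_random
    if (test == "binomial") {
      p0 <- if (null_smoothing == "laplace") (r + 1) / (n_random + 2)
            else prop_random
      ## one-tailed: P(X >= x) under X ~ Binomial(n_input, p0)
      p_raw <- if (p0 >= 1) 1
               else stats::pbinom(x - 1L, n_input, p0, lower.tail = FALSE)
    } else if (test == "ks") {
      p_raw <- suppressWarnings(
        stats::ks.test(inp[, j], rnd[, j], alternative = "less")$p.value)
      p0 <- NA_real_
    } else {
      p_raw <- suppressWarnings(
        stats::wilcox.test(inp[, j], rnd[, j],
                           alternative = "greater")$p.value)
      p0 <- NA_real_
    }
    members <- rownames(inp)[inp[, j] > threshold]
    data.frame(topic = j, n_input_high = x, n_input = n_input,
               n_random_high = r, n_random = n_random,
               prop_random = prop_random, p0 = p0, p_raw = p_raw,
               p_bonferroni = min(1, p_raw * k),
               member_genes = I(list(members)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_bonferroni < alpha_level
  attr(out, "threshold") <- threshold
  attr(out, "alpha_level") <- alpha_level
  attr(out, "test") <- test
  attr(out, "null_smoothing") <- null_smoothing
  class(out) <- c("topic_enrichment", "data.frame")
  out
}

#' Input and random score vectors for one topic
#'
#' Diagnostic export of the two score distributions the enrichment test
#' compares (useful for plotting the separation between input and random
#' genes on a topic).
#'
#' @param gtm a [gene_topic_matrix()].
#' @param topic topic index in `1..k`.
#' @return list with numeric vectors `input` and `random`, named by gene.
#' @export
score_distributions <- function(gtm, topic) {
  stopifnot(inherits(gtm, "gene_topic_matrix"),
            topic >= 1L, topic <= ncol(gtm$scores))
  list(input = gtm$scores[gtm$group == "input", topic],
       random = gtm$scores[gtm$group == "random", topic])
}

#' @export
print.topic_enrichment <- function(x, ...) {
  df <- as.data.frame(x)
  df$member_genes <- vapply(df$member_genes, length, integer(1))
  names(df)[names(df) == "member_genes"] <- "n_members"
  cat("Topic enrichment (", attr(x, "test"), " test, threshold ",
      attr(x, "threshold"), ", alpha ", attr(x, "alpha_level"), ")\n",
      sep = "")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export enrichment results as TSV
#'
#' One row per topic: topic, p_raw, p_bonferroni, significant,
#' n_input_high, prop_random, genes (comma-separated members).
#'
#' @param enrichment a [enrichment_test()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  stopifnot(inherits(enrichment, "topic_enrichment"))
  df <- data.frame(
    topic = enrichment$topic,
    p_raw = enrichment$p_raw,
    p_bonferroni = enrichment$p_bonferroni,
    significant = enrichment$significant,
    n_input_high = enrichment$n_input_high,
    prop_random = enrichment$prop_random,
    genes = vapply(enrichment$member_genes, paste, character(1),
                   collapse = ",")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
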