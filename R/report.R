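## Result report: per significant topic, its p-values, top display terms,
## member genes with scores, and the supporting document ids. Everything
## in the report is re-derivable from (corpus, fit, gene topic matrix,
## enrichment results); the report holds no numbers of its own.

#' Build the result report
#'
#' Includes only the significant topics, sorted by ascending corrected
#' p-value. Per topic, members are the input genes with score strictly
#' above the enrichment threshold; each member's supporting documents are
#' its corpus documents whose topic proportion for that topic exceeds the
#' threshold, always including the maximizing document (whose proportion
#' equals the gene's score). No significant topic yields a valid report
#' with an empty topic list, mirroring the behavior on random gene sets.
#'
#' @param fit the selected `lda_fit`.
#' @param gtm the [gene_topic_matrix()] of that fit.
#' @param enrichment the [enrichment_test()] result of that fit.
#' @param corpus the preprocessed corpus (supplies gene-document links and
#'   the stem-to-surface map).
#' @param manifest named list of run parameters/seeds recorded verbatim.
#' @param top_n_terms number of display terms per topic; default 20.
#' @return an object of class `genetopics_report`: list with
#'   `run_manifest`, `selected_k` and `topics` (each with `topic`,
#'   `p_raw`, `p_bonferroni`, `n_input_high`, `n_input`, `prop_random`,
#'   `top_terms`, `members`).
#' @export
build_report <- function(fit, gtm, enrichment, corpus,
                         manifest = list(), top_n_terms = 20L) {
  stopifnot(inherits(fit, "lda_fit"), inherits(gtm, "gene_topic_matrix"),
            inherits(enrichment, "topic_enrichment"),
            inherits(corpus, "gene_corpus"))
  threshold <- attr(enrichment, "threshold")
  tpm <- topic_proportions(fit)
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  sig <- sig[order(sig$p_bonferroni, sig$topic), , drop = FALSE]

  topics <- lapply(seq_len(nrow(sig)), function(r) {
    j <- sig$topic[r]
    members <- lapply(sig$member_genes[[r]], function(g) {
      d <- corpus$gene_docs[[g]]
      d <- d[d %in% rownames(tpm)]
      prop <- tpm[d, j]
      score <- max(prop)
      keep <- prop > threshold
      keep[which.max(prop)] <- TRUE  # always list the maximizing document
      docs <- d[keep][order(-prop[keep], d[keep], method = "radix")]
      list(gene = g, score = score, supporting_doc_ids = as.list(docs))
    })
    list(topic = j,
         p_raw = sig$p_raw[r],
         p_bonferroni = sig$p_bonferroni[r],
         n_input_high = sig$n_input_high[r],
         n_input = sig$n_input[r],
         prop_random = sig$prop_random[r],
         top_terms = as.list(top_terms(fit, j, n = top_n_terms,
                                       stem_to_surface =
                                         corpus$stem_to_surface)),
         members = members)
  })

  structure(list(run_manifest = manifest, selected_k = fit$k,
                 topics = topics),
            class = "genetopics_report")
}

#' Write a report to disk
#'
#' Writes `report.json` (the full structure), `topics.tsv` (one row per
#' topic), `members.tsv` (one row per topic-gene pair with comma-separated
#' doc ids) and `manifest.json` into `out_dir`, with stable field order
#' and UTF-8 encoding. Identical reports produce byte-identical files.
#'
#' @param report a [build_report()] result.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "genetopics_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("report.json", "topics.tsv",
                                "members.tsv", "manifest.json"))

  jsonlite::write_json(unclass(report), paths[1], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  topics_df <- data.frame(
    topic = vapply(report$topics, `[[`, 0L, "topic"),
    p_raw = vapply(report$topics, `[[`, 0, "p_raw"),
    p_bonferroni = vapply(report$topics, `[[`, 0, "p_bonferroni"),
    n_input_high = vapply(report$topics, `[[`, 0L, "n_input_high"),
    n_input = vapply(report$topics, `[[`, 0L, "n_input"),
    prop_random = vapply(report$topics, `[[`, 0, "prop_random"),
    top_terms = vapply(report$topics, function(t)
      paste(unlist(t$top_terms), collapse = ","), character(1))
  )
  utils::write.table(topics_df, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  rows <- list()
  for (t in report$topics)
    for (m in t$members)
      rows[[length(rows) + 1L]] <- data.frame(
        topic = t$topic, gene = m$gene, score = m$score,
        doc_ids = paste(unlist(m$supporting_doc_ids), collapse = ","))
  members_df <- if (length(rows)) do.call(rbind, rows)
                else data.frame(topic = integer(0), gene = character(0),
                                score = numeric(0), doc_ids = character(0))
  utils::write.table(members_df, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  jsonlite::write_json(report$run_manifest, paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}

#' Read a report back from report.json
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return a `genetopics_report` (lists as written; numeric types follow
#'   JSON parsing).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path)
  class(x) <- "genetopics_report"
  x
}

#' @export
print.genetopics_report <- function(x, ...) {
  cat("GeneTopics report: ", length(x$topics), " significant topic(s), k = ",
      x$selected_k, "\n", sep = "")
  for (t in x$topics) {
    cat(sprintf("  topic %d  p_adj=%.3g  members=%d/%d\n", t$topic,
                t$p_bonferroni, t$n_input_high, t$n_input))
    cat("    ", paste(utils::head(unlist(t$top_terms), 10),
                      collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
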