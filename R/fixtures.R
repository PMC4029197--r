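## Synthetic gene-linked corpora with known topic structure.
##
## The generator emulates the statistical structure the pipeline assumes:
## topics are word distributions, documents are token draws from topic
## mixtures, planted gene groups concentrate their documents' mixtures on
## a home topic, and background genes draw from uniform mixtures. Tokens
## are pronounceable pseudo-words chosen to be fixed points of the Porter
## stemmer, so end-to-end tests isolate topic-model behavior from
## stemming behavior.

#' Fixture specification
#'
#' @param n_topics_true number of true topics.
#' @param vocab_size vocabulary size.
#' @param topic_concentration symmetric Dirichlet concentration of the
#'   topic-word distributions; small values give well-separated topics.
#' @param n_gene_groups number of planted gene groups (0 = pure null
#'   fixture); at most `n_topics_true`.
#' @param genes_per_group genes per planted group.
#' @param n_background_genes genes with uniform (diffuse) topic mixtures.
#' @param docs_per_gene documents generated per gene.
#' @param doc_length_mean mean token count per document (Poisson).
#' @param purity weight of a planted gene's home topic in its documents'
#'   topic mixtures, in (0, 1]; the remainder is spread uniformly over the
#'   other topics. Values at or below `1/n_topics_true` carry no planted
#'   signal.
#' @param seed integer seed; fixed seed gives byte-identical fixtures.
#' @return a validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_topics_true = 5L, vocab_size = 500L,
                         topic_concentration = 0.1, n_gene_groups = 3L,
                         genes_per_group = 20L, n_background_genes = 30L,
                         docs_per_gene = 20L, doc_length_mean = 60L,
                         purity = 0.8, seed = 1L) {
  bad <- character(0)
  if (n_topics_true < 2L) bad <- c(bad, "n_topics_true >= 2")
  if (vocab_size < 10L) bad <- c(bad, "vocab_size >= 10")
  if (!is.finite(topic_concentration) || topic_concentration <= 0)
    bad <- c(bad, "topic_concentration > 0")
  if (n_gene_groups < 0L) bad <- c(bad, "n_gene_groups >= 0")
  if (n_gene_groups > n_topics_true)
    bad <- c(bad, "n_gene_groups <= n_topics_true")
  if (n_gene_groups > 0L && genes_per_group < 1L)
    bad <- c(bad, "genes_per_group >= 1")
  if (n_background_genes < 1L) bad <- c(bad, "n_background_genes >= 1")
  if (docs_per_gene < 1L) bad <- c(bad, "docs_per_gene >= 1")
  if (doc_length_mean < 1L) bad <- c(bad, "doc_length_mean >= 1")
  if (!(purity > 0 && purity <= 1)) bad <- c(bad, "purity in (0, 1]")
  if (length(bad))
    stop("invalid fixture spec; need: ", paste(bad, collapse = "; "))
  if (n_gene_groups > 0L && purity <= 1 / n_topics_true)
    warning("purity <= 1/n_topics_true: planted groups carry no signal")
  structure(list(n_topics_true = as.integer(n_topics_true),
                 vocab_size = as.integer(vocab_size),
                 topic_concentration = topic_concentration,
                 n_gene_groups = as.integer(n_gene_groups),
                 genes_per_group = as.integer(genes_per_group),
                 n_background_genes = as.integer(n_background_genes),
                 docs_per_gene = as.integer(docs_per_gene),
                 doc_length_mean = as.integer(doc_length_mean),
                 purity = purity, seed = as.integer(seed)),
            class = "fixture_spec")
}

## Deterministic stem-stable pseudo-word vocabulary: CV syllables (no 'e',
## no suffix-triggering consonants), filtered to Porter fixed points.
pseudo_vocabulary <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  words <- character(0)
  for (ns in 2:3) {
    grid <- do.call(expand.grid,
                    c(rep(list(syll), ns), stringsAsFactors = FALSE))
    cand <- do.call(paste0, grid)
    cand <- cand[order(cand)]
    cand <- cand[porter_stem(cand) == cand & !(cand %in% default_stopwords())]
    words <- c(words, cand)
    if (length(words) >= n) break
  }
  if (length(words) < n)
    stop("cannot build a stem-stable vocabulary of size ", n)
  words[seq_len(n)]
}

rdirichlet1 <- function(n, conc) {
  x <- stats::rgamma(n, shape = conc)
  while (sum(x) == 0) x <- stats::rgamma(n, shape = conc)
  x / sum(x)
}

#' Generate a synthetic gene-linked corpus
#'
#' Draws topic-word distributions from a symmetric Dirichlet, plants gene
#' groups on the first `n_gene_groups` topics, generates per-gene
#' documents whose tokens are drawn from mixture-weighted topic
#' distributions, and (optionally) writes the result in the TSV dialects
#' that [load_index()] reads: `links.tsv`, `docs.tsv`, `genes.txt` and
#' `truth.json`. All years are sampled from 1996 onwards and every
#' relevancy score is 1, so the default index filter keeps everything.
#' By default documents are gene-private; `shared_docs = TRUE` links every
#' document to a second random gene of the same kind to exercise
#' deduplication paths.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional output directory; if `NULL`, nothing is written.
#' @param shared_docs if `TRUE`, each document is additionally linked to a
#'   second gene.
#' @return list with `index` (a `gene_doc_index`), `genes` (the natural
#'   input gene list: the planted genes, or for a null fixture a seeded
#'   random half of the background genes), `truth` (class `fixture_truth`:
#'   `topic_word_dists`, `gene_home_topic`, `doc_mixtures`,
#'   `doc_topic_token_counts`), `spec`, and `paths` when `out_dir` is
#'   given.
#' @export
generate_fixture <- function(spec, out_dir = NULL, shared_docs = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  K <- spec$n_topics_true
  V <- spec$vocab_size
  vocab <- pseudo_vocabulary(V)

  topics <- t(vapply(seq_len(K),
                     function(i) rdirichlet1(V, spec$topic_concentration),
                     numeric(V)))
  colnames(topics) <- vocab

  planted <- character(0)
  home <- integer(0)
  if (spec$n_gene_groups > 0L) {
    for (g in seq_len(spec$n_gene_groups)) {
      nm <- sprintf("T%02dG%03d", g, seq_len(spec$genes_per_group))
      planted <- c(planted, nm)
      home <- c(home, rep(g, spec$genes_per_group))
    }
  }
  background <- sprintf("BG%03d", seq_len(spec$n_background_genes))
  genes_all <- c(planted, background)
  gene_home <- c(as.list(home), rep(list(NA_integer_), length(background)))
  names(gene_home) <- genes_all

  mix_for <- function(g) {
    h <- gene_home[[g]]
    if (is.na(h)) rep(1 / K, K)
    else {
      m <- rep((1 - spec$purity) / max(1, K - 1), K)
      m[h] <- spec$purity
      m
    }
  }

  n_docs_total <- length(genes_all) * spec$docs_per_gene
  doc_ids <- sprintf("%07d", 1000000L + seq_len(n_docs_total))
  titles <- character(n_docs_total)
  abstracts <- character(n_docs_total)
  doc_mixtures <- matrix(0, n_docs_total, K, dimnames = list(doc_ids, NULL))
  doc_topic_tokens <- matrix(0L, n_docs_total, K,
                             dimnames = list(doc_ids, NULL))
  link_gene <- character(n_docs_total)

  i <- 0L
  for (g in genes_all) {
    m <- mix_for(g)
    for (d in seq_len(spec$docs_per_gene)) {
      i <- i + 1L
      len <- max(5L, stats::rpois(1, spec$doc_length_mean))
      zt <- sample.int(K, len, replace = TRUE, prob = m)
      wt <- integer(len)
      for (t in unique(zt)) {
        sel <- zt == t
        wt[sel] <- sample.int(V, sum(sel), replace = TRUE,
                              prob = topics[t, ])
      }
      toks <- vocab[wt]
      nt <- min(5L, len)
      titles[i] <- paste(toks[seq_len(nt)], collapse = " ")
      abstracts[i] <- if (len > nt)
        paste(toks[(nt + 1L):len], collapse = " ") else ""
      doc_mixtures[i, ] <- m
      doc_topic_tokens[i, ] <- tabulate(zt, nbins = K)
      link_gene[i] <- g
    }
  }

  links <- data.frame(gene = link_gene, doc_id = doc_ids, relevancy = 1,
                      stringsAsFactors = FALSE)
  if (shared_docs) {
    extra_gene <- vapply(link_gene, function(g) {
      pool <- setdiff(genes_all, g)
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    links <- rbind(links,
                   data.frame(gene = extra_gene, doc_id = doc_ids,
                              relevancy = 1, stringsAsFactors = FALSE))
    links <- links[!duplicated(paste(links$gene, links$doc_id)), ]
  }
  docs <- data.frame(doc_id = doc_ids,
                     year = sample(1996:2020, n_docs_total, replace = TRUE),
                     title = titles, abstract = abstracts,
                     stringsAsFactors = FALSE)
  index <- gene_doc_index(links, docs)

  input_genes <- if (length(planted)) planted
                 else sample(background, max(1L, length(background) %/% 2L))

  truth <- structure(
    list(topic_word_dists = topics, gene_home_topic = gene_home,
         doc_mixtures = doc_mixtures,
         doc_topic_token_counts = doc_topic_tokens),
    class = "fixture_truth"
  )

  out <- list(index = index, genes = input_genes, truth = truth,
              spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("links.tsv", "docs.tsv", "genes.txt",
                                  "truth.json"))
    write_index(index, paths[1], paths[2])
    writeLines(input_genes, paths[3])
    jsonlite::write_json(
      list(spec = unclass(spec),
           gene_home_topic = gene_home,
           topic_word_dists = topics,
           doc_mixtures = doc_mixtures),
      paths[4], auto_unbox = TRUE, digits = NA, null = "null")
    out$paths <- paths
  }
  out
}

#' Evaluate how well a report recovers planted structure
#'
#' Greedily matches the report's significant topics to the fixture's
#' planted gene groups by member-gene overlap (largest overlap first, one
#' to one), then computes recovery metrics from the matched pairs.
#'
#' @param report a [build_report()] result (or the `report` element of a
#'   [genetopics()] run).
#' @param truth the `truth` element of [generate_fixture()].
#' @return list with `pairs` (data.frame: topic, group, overlap,
#'   precision, recall per matched pair), `topic_match_rate` (matched
#'   groups / planted groups; `NA` for a null fixture),
#'   `gene_precision`, `gene_recall` (aggregated over matched pairs;
#'   recall counts all planted genes in its denominator) and
#'   `false_topic_count` (significant topics left unmatched).
#' @export
evaluate_recovery <- function(report, truth) {
  stopifnot(inherits(report, "genetopics_report"),
            inherits(truth, "fixture_truth"))
  home <- unlist(truth$gene_home_topic)
  groups <- split(names(home)[!is.na(home)], home[!is.na(home)])
  members <- lapply(report$topics, function(t)
    vapply(t$members, `[[`, character(1), "gene"))
  names(members) <- vapply(report$topics, `[[`, 0L, "topic")

  n_topics <- length(members)
  n_groups <- length(groups)
  pairs <- data.frame(topic = integer(0), group = integer(0),
                      overlap = integer(0), precision = numeric(0),
                      recall = numeric(0))
  if (n_topics > 0L && n_groups > 0L) {
    ov <- matrix(0L, n_topics, n_groups)
    for (a in seq_len(n_topics))
      for (b in seq_len(n_groups))
        ov[a, b] <- length(intersect(members[[a]], groups[[b]]))
    free_t <- rep(TRUE, n_topics); free_g <- rep(TRUE, n_groups)
    repeat {
      sub <- ov
      sub[!free_t, ] <- -1L
      sub[, !free_g] <- -1L
      best <- max(sub)
      if (best <= 0L) break
      idx <- which(sub == best, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      a <- idx[1]; b <- idx[2]
      pairs <- rbind(pairs, data.frame(
        topic = as.integer(names(members)[a]),
        group = as.integer(names(groups)[b]),
        overlap = ov[a, b],
        precision = ov[a, b] / length(members[[a]]),
        recall = ov[a, b] / length(groups[[b]])))
      free_t[a] <- FALSE; free_g[b] <- FALSE
    }
  }
  matched_groups <- pairs$group
  list(
    pairs = pairs,
    topic_match_rate = if (n_groups == 0L) NA_real_
                       else nrow(pairs) / n_groups,
    gene_precision = if (nrow(pairs) == 0L) NA_real_
                     else sum(pairs$overlap) /
                          sum(lengths(members[match(
                            as.character(pairs$topic), names(members))])),
    gene_recall = if (n_groups == 0L) NA_real_
                  else sum(pairs$overlap) / sum(lengths(groups)),
    false_topic_count = n_topics - nrow(pairs)
  )
}
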