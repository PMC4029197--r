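## Working gene set and corpus construction.
##
## The working gene set G_w is the union of the usable input genes G_i and
## an equal-sized random background draw G_r; G_r supplies the embedded
## null used later to triage topics that are not specific to the input.

#' Build the working gene set
#'
#' Input genes without any usable document in the (filtered) index are
#' moved to `excluded_genes`. Random genes are drawn uniformly without
#' replacement, seeded, from `background` excluding the input genes, with
#' size equal to the number of usable input genes. If the eligible pool is
#' smaller than that, the whole pool is taken with a warning; the
#' downstream enrichment test handles unequal set sizes.
#'
#' @param input_genes character vector of input gene identifiers.
#' @param index a [gene_doc_index()] (already filtered as desired).
#' @param background optional character vector restricting the background
#'   pool; defaults to all genes in the index. Must be a subset of the
#'   index's genes (case-insensitive).
#' @param seed integer seed for the random draw.
#' @return an object of class `working_gene_set` with elements
#'   `input_genes` (usable, display form), `random_genes` and
#'   `excluded_genes`.
#' @export
build_working_set <- function(input_genes, index, background = NULL,
                              seed = 1L) {
  stopifnot(inherits(index, "gene_doc_index"))
  if (is.null(background)) background <- index$background
  bg_key <- tolower(background)
  idx_key <- tolower(index$background)
  if (!all(bg_key %in% idx_key))
    stop("background contains genes absent from the index: ",
         paste(utils::head(background[!(bg_key %in% idx_key)], 5),
               collapse = ", "))

  in_key <- tolower(input_genes)
  input_genes <- input_genes[!duplicated(in_key)]
  in_key <- in_key[!duplicated(in_key)]

  usable <- in_key %in% idx_key
  excluded <- input_genes[!usable]
  input_use <- index$background[match(in_key[usable], idx_key)]
  if (length(input_use) == 0L)
    stop("no input gene has any document in the index")

  pool <- index$background[match(setdiff(unique(bg_key), in_key), idx_key)]
  if (length(pool) == 0L)
    stop("background pool is empty after removing input genes")
  n_draw <- length(input_use)
  if (length(pool) < n_draw) {
    warning("background pool (", length(pool), ") smaller than input set (",
            n_draw, "); using the whole pool as random genes")
    n_draw <- length(pool)
  }
  set.seed(seed)
  random_genes <- sample(pool, n_draw)

  structure(
    list(input_genes = input_use, random_genes = random_genes,
         excluded_genes = excluded, seed = as.integer(seed)),
    class = "working_gene_set"
  )
}

#' @export
print.working_gene_set <- function(x, ...) {
  cat("Working gene set\n")
  cat("  input genes (usable):", length(x$input_genes), "\n")
  cat("  random genes:        ", length(x$random_genes), "\n")
  cat("  excluded (no docs):  ", length(x$excluded_genes), "\n")
  invisible(x)
}

#' Assemble the document corpus for a working gene set
#'
#' For every gene in the working set, [sample_documents()] selects up to
#' `n_docs` documents; the union is deduplicated, so a document selected by
#' several genes appears once with all selecting genes recorded in
#' `doc_genes`. Document text is title and abstract joined by a space.
#'
#' @param ws a [build_working_set()] result.
#' @param index a `gene_doc_index`.
#' @param n_docs maximum documents per gene; default 50.
#' @return an object of class `gene_corpus` with elements `doc_ids`, `text`
#'   (raw, parallel to `doc_ids`), `doc_genes` (named list doc_id ->
#'   selecting genes) and `gene_docs` (named list gene -> its doc_ids).
#' @export
assemble_corpus <- function(ws, index, n_docs = 50L) {
  stopifnot(inherits(ws, "working_gene_set"),
            inherits(index, "gene_doc_index"))
  genes <- c(ws$input_genes, ws$random_genes)
  gene_docs <- lapply(genes, function(g)
    sample_documents(index, g, n_docs = n_docs))
  names(gene_docs) <- genes
  empty <- lengths(gene_docs) == 0L
  if (any(empty))
    stop("working-set gene(s) without documents: ",
         paste(genes[empty], collapse = ", "))

  doc_ids <- sort(unique(unlist(gene_docs, use.names = FALSE)))
  doc_genes <- vector("list", length(doc_ids))
  names(doc_genes) <- doc_ids
  for (g in genes)
    for (d in gene_docs[[g]])
      doc_genes[[d]] <- c(doc_genes[[d]], g)

  pos <- match(doc_ids, index$docs$doc_id)
  text <- paste(index$docs$title[pos], index$docs$abstract[pos])

  structure(
    list(doc_ids = doc_ids, text = text, doc_genes = doc_genes,
         gene_docs = gene_docs, preprocessed = FALSE),
    class = "gene_corpus"
  )
}

#' Default English stopword list
#'
#' A standard English stopword list shipped with the package, used when no
#' custom list is supplied to [preprocess_corpus()].
#'
#' @return character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "genetopics",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Tokenize, clean and stem a corpus
#'
#' Per document: lowercase, delete punctuation characters (hyphens and
#' slashes included, so hyphenated terms fuse into one token), tokenize on
#' whitespace, drop stopwords and empty tokens, and Porter-stem. Numeric
#' tokens are retained. Documents left without tokens are dropped with a
#' warning. `stem_to_surface` maps every stem to its most frequent
#' pre-stemming surface form (ties broken by the lexicographically smaller
#' form) so reported topic terms stay readable.
#'
#' @param corpus a [assemble_corpus()] result with raw text.
#' @param stopwords character vector; default [default_stopwords()].
#' @return the corpus with added `tokens` (list of stem vectors per
#'   document), `vocab` (sorted stem vector) and `stem_to_surface`.
#' @export
preprocess_corpus <- function(corpus, stopwords = default_stopwords()) {
  stopifnot(inherits(corpus, "gene_corpus"))
  sw <- unique(tolower(stopwords))

  txt <- tolower(corpus$text)
  txt <- gsub("[^a-z0-9 \t\n]", "", txt)
  toks <- strsplit(txt, "[ \t\n]+")
  toks <- lapply(toks, function(x) x[nzchar(x) & !(x %in% sw)])

  surface <- unlist(toks, use.names = FALSE)
  if (length(surface) == 0L) stop("corpus has no tokens after cleaning")
  usurf <- unique(surface)
  ustem <- porter_stem(usurf)
  stems <- lapply(toks, function(x) ustem[match(x, usurf)])

  ## most frequent surface form per stem; ties -> lexicographically smallest
  cnt <- table(surface)
  sdf <- data.frame(stem = ustem, surf = usurf,
                    n = as.integer(cnt[usurf]), stringsAsFactors = FALSE)
  sdf <- sdf[order(sdf$stem, -sdf$n, sdf$surf, method = "radix"), ]
  sdf <- sdf[!duplicated(sdf$stem), ]
  stem_to_surface <- sdf$surf
  names(stem_to_surface) <- sdf$stem

  keep <- lengths(stems) > 0L
  if (!all(keep))
    warning(sum(!keep), " document(s) reduced to zero tokens dropped")
  if (!any(keep)) stop("all documents dropped during preprocessing")

  out <- corpus
  out$doc_ids <- corpus$doc_ids[keep]
  out$text <- corpus$text[keep]
  out$doc_genes <- corpus$doc_genes[keep]
  out$gene_docs <- lapply(corpus$gene_docs,
                          function(d) d[d %in% out$doc_ids])
  out$tokens <- stems[keep]
  names(out$tokens) <- out$doc_ids
  out$vocab <- sort(unique(unlist(stems[keep], use.names = FALSE)))
  out$stem_to_surface <- stem_to_surface
  out$preprocessed <- TRUE
  out
}

#' Term-document matrix of a preprocessed corpus
#'
#' @param corpus a preprocessed `gene_corpus`.
#' @return a sparse `dgCMatrix` (terms x documents) of token counts, with
#'   stem rownames and doc_id colnames.
#' @export
term_document_matrix <- function(corpus) {
  stopifnot(inherits(corpus, "gene_corpus"), isTRUE(corpus$preprocessed))
  vocab <- corpus$vocab
  i <- unlist(lapply(corpus$tokens, function(x) match(x, vocab)),
              use.names = FALSE)
  j <- rep(seq_along(corpus$tokens), lengths(corpus$tokens))
  Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(vocab), length(corpus$doc_ids)),
    dimnames = list(vocab, corpus$doc_ids)
  )
}

#' @export
print.gene_corpus <- function(x, ...) {
  cat("Gene-linked corpus\n")
  cat("  documents:", length(x$doc_ids), "\n")
  cat("  genes:    ", length(x$gene_docs), "\n")
  if (isTRUE(x$preprocessed)) {
    cat("  vocabulary:", length(x$vocab), "stems\n")
    cat("  tokens:    ", sum(lengths(x$tokens)), "\n")
  } else {
    cat("  (raw text; not yet preprocessed)\n")
  }
  invisible(x)
}
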