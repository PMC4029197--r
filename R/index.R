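## Gene-document index: the pluggable association table standing in for a
## proprietary literature index. Links are (gene, doc_id, relevancy) rows;
## documents are (doc_id, year, title, abstract) records. Gene matching is
## case-insensitive throughout; the first-seen surface form is kept for
## display.

#' Construct a gene-document index
#'
#' Validates and assembles an index from a link table and a document store.
#' Links whose `doc_id` does not resolve in the document store are dropped
#' with a warning. The background gene set is defined as every gene that
#' retains at least one link.
#'
#' @param links data.frame with columns `gene`, `doc_id`, `relevancy`
#'   (relevancy in `[0, 1]`).
#' @param docs data.frame with columns `doc_id`, `year`, `title`,
#'   `abstract`; `doc_id` must be unique.
#' @return an object of class `gene_doc_index` with elements `links`,
#'   `docs` and `background` (display forms of all linked genes).
#' @export
gene_doc_index <- function(links, docs) {
  stopifnot(is.data.frame(links), is.data.frame(docs))
  need_l <- c("gene", "doc_id", "relevancy")
  need_d <- c("doc_id", "year", "title", "abstract")
  if (!all(need_l %in% names(links)))
    stop("links must have columns: ", paste(need_l, collapse = ", "))
  if (!all(need_d %in% names(docs)))
    stop("docs must have columns: ", paste(need_d, collapse = ", "))

  docs <- data.frame(
    doc_id = as.character(docs$doc_id),
    year = as.integer(docs$year),
    title = as.character(docs$title),
    abstract = as.character(docs$abstract),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(docs$doc_id))
    stop("duplicate doc_id in document store: ",
         docs$doc_id[duplicated(docs$doc_id)][1])
  if (any(is.na(docs$year) | docs$year <= 0L))
    stop("document years must be positive integers")
  if (any(!nzchar(trimws(paste(docs$title, docs$abstract)))))
    stop("documents must have non-empty title+abstract")

  links <- data.frame(
    gene = as.character(links$gene),
    doc_id = as.character(links$doc_id),
    relevancy = as.numeric(links$relevancy),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(links$gene)) || any(grepl("\\s", links$gene)))
    stop("gene identifiers must be non-empty and whitespace-free")
  if (any(!is.finite(links$relevancy)) ||
      any(links$relevancy < 0 | links$relevancy > 1))
    stop("relevancy scores must be finite and in [0, 1]")

  ## case-insensitive gene key; keep first-seen surface form
  key <- tolower(links$gene)
  first <- !duplicated(key)
  display <- links$gene[first]
  names(display) <- key[first]
  links$gene <- unname(display[key])

  if (anyDuplicated(paste(key, links$doc_id, sep = "\r")))
    stop("duplicate (gene, doc_id) pairs in links")

  known <- links$doc_id %in% docs$doc_id
  if (!all(known)) {
    warning(sum(!known), " link(s) referencing unknown doc_ids dropped")
    links <- links[known, , drop = FALSE]
  }
  if (nrow(links) == 0L)
    stop("gene-document index is empty after validation")

  rownames(links) <- NULL
  structure(
    list(links = links, docs = docs,
         background = unique(links$gene)),
    class = "gene_doc_index"
  )
}

#' Load a gene-document index from TSV files
#'
#' The link table is a TSV with header `gene`, `pmid`, `score`; the document
#' store is a TSV with header `pmid`, `year`, `title`, `abstract` (tab-free
#' fields, UTF-8).
#'
#' @param links_path path to the link TSV.
#' @param docs_path path to the document TSV.
#' @return a [gene_doc_index()] object.
#' @export
load_index <- function(links_path, docs_path) {
  links_raw <- read_tsv_checked(links_path, c("gene", "pmid", "score"))
  docs_raw <- read_tsv_checked(docs_path,
                               c("pmid", "year", "title", "abstract"))
  links <- data.frame(gene = links_raw$gene, doc_id = links_raw$pmid,
                      relevancy = as.numeric(links_raw$score),
                      stringsAsFactors = FALSE)
  docs <- data.frame(doc_id = docs_raw$pmid,
                     year = suppressWarnings(as.integer(docs_raw$year)),
                     title = docs_raw$title, abstract = docs_raw$abstract,
                     stringsAsFactors = FALSE)
  if (any(is.na(docs$year)))
    stop("non-integer year in ", docs_path, " at data line ",
         which(is.na(docs$year))[1])
  gene_doc_index(links, docs)
}

read_tsv_checked <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(x)[seq_along(header)], header))
    stop(path, ": expected header ", paste(header, collapse = "\t"))
  x
}

#' Write a gene-document index to TSV files
#'
#' Inverse of [load_index()]: writes the link table and document store in
#' the TSV dialects that [load_index()] reads.
#'
#' @param index a `gene_doc_index`.
#' @param links_path,docs_path output paths.
#' @return invisibly, the two paths.
#' @export
write_index <- function(index, links_path, docs_path) {
  stopifnot(inherits(index, "gene_doc_index"))
  l <- data.frame(gene = index$links$gene, pmid = index$links$doc_id,
                  score = index$links$relevancy)
  d <- data.frame(pmid = index$docs$doc_id, year = index$docs$year,
                  title = index$docs$title, abstract = index$docs$abstract)
  utils::write.table(l, links_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(d, docs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(links_path, docs_path))
}

#' Read documents from a MEDLINE-format file
#'
#' Maps the `PMID`, `DP` (publication date; the leading four-digit year is
#' used), `TI` and `AB` fields of MEDLINE records into the document-store
#' data.frame accepted by [gene_doc_index()]. Continuation lines (indented)
#' are folded into the preceding field.
#'
#' @param path path to a MEDLINE text file.
#' @return data.frame with columns `doc_id`, `year`, `title`, `abstract`.
#' @export
read_medline_docs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list()
  cur <- list()
  field <- NULL
  flush <- function(cur) {
    if (!length(cur)) return(NULL)
    yr <- NA_integer_
    if (!is.null(cur$DP)) {
      m <- regmatches(cur$DP, regexpr("[0-9]{4}", cur$DP))
      if (length(m)) yr <- as.integer(m)
    }
    data.frame(doc_id = cur$PMID %||% NA_character_, year = yr,
               title = cur$TI %||% "", abstract = cur$AB %||% "",
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list(); field <- NULL
      next
    }
    if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      field <- trimws(sub("-.*", "", ln))
      val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      cur[[field]] <- if (is.null(cur[[field]])) val
                      else paste(cur[[field]], val)
    } else if (grepl("^\\s", ln) && !is.null(field)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    }
  }
  r <- flush(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (!length(recs)) stop("no MEDLINE records found in ", path)
  out <- do.call(rbind, recs)
  out <- out[!is.na(out$doc_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter an index by publication year and relevancy
#'
#' Keeps only links whose document year is at least `min_year` and whose
#' relevancy is at least `min_relevancy`, then recomputes the background
#' gene set. The default year cutoff keeps literature published after 1995.
#'
#' @param index a `gene_doc_index`.
#' @param min_year minimum document year (inclusive); default 1996.
#' @param min_relevancy minimum link relevancy (inclusive) in `[0, 1]`.
#' @return a filtered `gene_doc_index`.
#' @export
filter_index <- function(index, min_year = 1996L, min_relevancy = 0) {
  stopifnot(inherits(index, "gene_doc_index"),
            min_year >= 0, min_relevancy >= 0, min_relevancy <= 1)
  yr <- index$docs$year[match(index$links$doc_id, index$docs$doc_id)]
  keep <- yr >= min_year & index$links$relevancy >= min_relevancy
  if (!any(keep))
    stop("filter (min_year=", min_year, ", min_relevancy=", min_relevancy,
         ") empties the index")
  links <- index$links[keep, , drop = FALSE]
  rownames(links) <- NULL
  structure(
    list(links = links, docs = index$docs,
         background = unique(links$gene)),
    class = "gene_doc_index"
  )
}

#' Select a gene's documents from the index
#'
#' Returns up to `n_docs` document ids linked to `gene`, ranked by
#' descending relevancy with ties broken by ascending `doc_id`, so the
#' selection is deterministic. With `mode = "random"` a seeded uniform
#' sample (without replacement) is drawn instead, for sensitivity checks.
#'
#' @param index a `gene_doc_index`.
#' @param gene gene identifier (matched case-insensitively).
#' @param n_docs maximum number of documents; default 50.
#' @param mode `"top"` (default) or `"random"`.
#' @param seed integer seed used only for `mode = "random"`.
#' @return character vector of doc_ids (empty if the gene has no links).
#' @export
sample_documents <- function(index, gene, n_docs = 50L,
                             mode = c("top", "random"), seed = NULL) {
  stopifnot(inherits(index, "gene_doc_index"), n_docs >= 1L)
  mode <- match.arg(mode)
  sel <- tolower(index$links$gene) == tolower(gene)
  if (!any(sel)) return(character(0))
  l <- index$links[sel, , drop = FALSE]
  if (mode == "top") {
    ord <- order(-l$relevancy, l$doc_id, method = "radix")
    l$doc_id[ord][seq_len(min(n_docs, nrow(l)))]
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample(l$doc_id, min(n_docs, nrow(l)))
  }
}

#' Read an input gene list
#'
#' Plain text, one identifier per line; blank lines and `#` comments are
#' ignored; duplicates (case-insensitive) are dropped, keeping first-seen.
#'
#' @param path path to the gene list file.
#' @return character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*", "", x))
  x <- x[nzchar(x)]
  if (any(grepl("\\s", x)))
    stop("gene identifiers must not contain whitespace: ", path)
  x[!duplicated(tolower(x))]
}

#' @export
print.gene_doc_index <- function(x, ...) {
  cat("Gene-document index\n")
  cat("  links:     ", nrow(x$links), "\n")
  cat("  documents: ", nrow(x$docs), "\n")
  cat("  genes:     ", length(x$background), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
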