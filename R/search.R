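## Selection of the number of topics: scan an increasing grid of k, count
## the significant topics at each k, and stop as soon as that count stops
## increasing (or, optionally, only once it strictly declines). The
## selected k is the earliest evaluated k attaining the maximal count.

derive_seed <- function(base_seed, k) {
  ## deterministic per-k seed; adding grid points never perturbs earlier
  ## fits, and the value stays inside 32-bit integer range
  as.integer((as.numeric(base_seed) %% 2147483629 * 48271 + k * 9973) %%
               2147483629) + 1L
}

## Pure stopping/selection rule on a vector of significant-topic counts.
## Returns the number of evaluated points, the stop reason and the index
## of the selected grid point.
apply_stop_rule <- function(n_sig, rule = c("no-increase", "strict-decline")) {
  rule <- match.arg(rule)
  stopifnot(length(n_sig) >= 1L)
  n_eval <- length(n_sig)
  reason <- "grid_exhausted"
  for (i in seq_along(n_sig)[-1]) {
    stop_now <- if (rule == "no-increase") n_sig[i] <= n_sig[i - 1L]
                else n_sig[i] < n_sig[i - 1L]
    if (stop_now) {
      n_eval <- i
      reason <- if (n_sig[i] < n_sig[i - 1L]) "decline" else "plateau"
      break
    }
  }
  ns <- n_sig[seq_len(n_eval)]
  list(n_evaluated = n_eval, stop_reason = reason,
       selected_index = which.max(ns))  # earliest maximum
}

#' Search for an appropriate number of topics
#'
#' Fits one LDA model per grid point, in order, counting the topics the
#' enrichment test flags as significant, and stops once that count stops
#' increasing (default grid `[5,10,15,20,25,30,40,50,75,100]`). Grid
#' points not smaller than the corpus token count are skipped with a
#' warning. Per-k RNG seeds are derived deterministically from the base
#' seed and k, so appending grid points never changes earlier fits.
#'
#' @param corpus preprocessed [gene_corpus][preprocess_corpus()].
#' @param ws [working_gene_set][build_working_set()].
#' @param grid strictly increasing integer vector of candidate topic
#'   counts.
#' @param base_config an [lda_config()] whose `k` is overridden per grid
#'   point (its `alpha` is re-derived as `50/k` unless `fixed_alpha`).
#' @param threshold,alpha_level,null_smoothing,test passed to
#'   [enrichment_test()].
#' @param stop_rule `"no-increase"` (default: stop when the count fails to
#'   grow) or `"strict-decline"` (stop only on a drop).
#' @param fixed_alpha if `TRUE`, keep `base_config$alpha` for every k
#'   instead of the `50/k` default.
#' @param evaluate_fn optional override, `function(k, seed)` returning a
#'   list with at least `n_significant`; used for unit testing the search
#'   behavior in isolation.
#' @return an object of class `topic_search`: list with `grid`,
#'   `evaluated` (per evaluated k: `k`, `n_significant`, `fit`, `gtm`,
#'   `enrichment`), `n_significant`, `selected_k`, `selected` (index into
#'   `evaluated`) and `stop_reason`
#'   (`"plateau"`/`"decline"`/`"grid_exhausted"`).
#' @export
search_topic_number <- function(corpus, ws, grid = default_topic_grid(),
                                base_config = lda_config(k = 5),
                                threshold = 0.5, alpha_level = 0.05,
                                null_smoothing = "laplace",
                                test = "binomial",
                                stop_rule = c("no-increase",
                                              "strict-decline"),
                                fixed_alpha = FALSE,
                                evaluate_fn = NULL) {
  stop_rule <- match.arg(stop_rule)
  grid <- as.integer(grid)
  if (length(grid) < 1L || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")

  if (is.null(evaluate_fn)) {
    stopifnot(inherits(corpus, "gene_corpus"), isTRUE(corpus$preprocessed))
    tdm <- term_document_matrix(corpus)
    total_tokens <- sum(tdm)
    evaluate_fn <- function(k, seed) {
      cfg <- lda_config(
        k = k,
        alpha = if (fixed_alpha) base_config$alpha else 50 / k,
        eta = base_config$eta,
        iterations = base_config$iterations,
        burn_in = base_config$burn_in,
        seed = seed,
        assignment_mode = base_config$assignment_mode
      )
      fit <- fit_lda(tdm, cfg)
      gtm <- gene_topic_matrix(fit, corpus, ws)
      enr <- enrichment_test(gtm, threshold = threshold,
                             alpha_level = alpha_level,
                             null_smoothing = null_smoothing, test = test)
      list(k = k, n_significant = sum(enr$significant), fit = fit,
           gtm = gtm, enrichment = enr)
    }
    usable <- grid < total_tokens
    if (!all(usable))
      warning("grid point(s) ", paste(grid[!usable], collapse = ", "),
              " not smaller than the token count (", total_tokens,
              "); skipped")
    grid <- grid[usable]
    if (length(grid) == 0L) stop("no usable grid point")
  }

  evaluated <- list()
  n_sig <- integer(0)
  stop_reason <- "grid_exhausted"
  for (i in seq_along(grid)) {
    k <- grid[i]
    ev <- evaluate_fn(k, derive_seed(base_seed(corpus, ws), k))
    ev$k <- k
    evaluated[[length(evaluated) + 1L]] <- ev
    n_sig <- c(n_sig, ev$n_significant)
    dec <- apply_stop_rule(n_sig, stop_rule)
    if (dec$n_evaluated == length(n_sig) &&
        dec$stop_reason != "grid_exhausted") {
      stop_reason <- dec$stop_reason
      break
    }
  }
  sel <- which.max(n_sig)
  structure(
    list(grid = grid, evaluated = evaluated, n_significant = n_sig,
         selected = sel, selected_k = evaluated[[sel]]$k,
         stop_reason = stop_reason),
    class = "topic_search"
  )
}

## base seed for per-k derivation: the working set's seed keeps the whole
## run reproducible from one integer
base_seed <- function(corpus, ws) {
  if (inherits(ws, "working_gene_set") && !is.null(ws$seed)) ws$seed else 1L
}

default_topic_grid <- function() c(5L, 10L, 15L, 20L, 25L, 30L, 40L, 50L,
                                   75L, 100L)

#' @export
print.topic_search <- function(x, ...) {
  cat("Topic-number search\n")
  cat("  evaluated k:", paste(vapply(x$evaluated, `[[`, 0L, "k"),
                              collapse = ", "), "\n")
  cat("  significant:", paste(x$n_significant, collapse = ", "), "\n")
  cat("  selected k: ", x$selected_k, " (", x$stop_reason, ")\n", sep = "")
  invisible(x)
}
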