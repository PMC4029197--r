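---
title: "Literature-driven topic annotation of gene sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Literature-driven topic annotation of gene sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetopics)
```

## The problem

Gene sets produced by omics experiments are usually interpreted by
comparison against curated libraries of labelled gene sets. That fails
when the library is out of date, curated at the wrong granularity, or
simply silent on the biology at hand. The alternative implemented here is
to interpret a gene set directly against the primary literature: assemble
the abstracts attached to the genes, discover the latent themes of that
corpus with a topic model, and keep only the themes that are specific to
the input genes rather than to genes in general.

## The procedure

Given an input gene set $G_i$ and a gene–document index (a many-to-many
table of gene–publication links with relevancy scores):

1. **Embedded random background.** Draw a random gene set $G_r$ of equal
   size, uniformly without replacement from the background gene pool
   excluding $G_i$, and form the working set $G_w = G_i \cup G_r$. The
   random genes act as an *internal negative control*: any topic driven
   by generic gene literature will attract random genes too, and can be
   triaged statistically.
2. **Corpus.** For every gene in $G_w$, take up to `docs_per_gene`
   documents (default 50) — the top-ranked by relevancy, ties broken by
   document id so the selection is deterministic — restricted to
   publications from `min_year` on (default 1996). Documents selected by
   several genes enter the corpus once, linked to all selecting genes.
3. **Preprocessing.** Lowercase, delete punctuation (fusing hyphenated
   terms such as *enoyl-CoA* into single tokens), tokenize on
   whitespace, drop stopwords, keep numeric tokens, and Porter-stem. A
   stem-to-surface map retains, per stem, the most frequent original
   word form for display.
4. **Topic model.** Fit latent Dirichlet allocation with $k$ topics by
   collapsed Gibbs sampling. From the final token–topic assignments
   derive the *word count matrix* ($W_{dj}$ = tokens of document $d$
   assigned to topic $j$) and the *topic proportion matrix*
   $P_{dj} = W_{dj} / \sum_j W_{dj}$. Normalization is per document: a
   100-token document with 40 tokens on one topic and 60 on another has
   proportions 0.4 and 0.6.
5. **Gene scoring.** The gene–topic score is
   $S_{gj} = \max_{d \in D_g} P_{dj}$, the maximum over the gene's
   documents. The max (rather than a mean or sum) respects the
   multi-functional role of genes: single papers typically treat one
   biological aspect, and averaging drags all scores toward an
   uninformative centre.
6. **Enrichment.** Discretize scores at a threshold $t$ (default 0.5,
   strict $>$). With $r$ of $n_r$ random genes above threshold, test the
   input count $x$ of $n_i$ one-tailed against
   $X \sim \mathrm{Binomial}(n_i, p_0)$, $p$-value $P(X \ge x)$,
   Bonferroni-corrected by the $k$ of the current fit; topics with
   corrected $p < 0.05$ are reported.
7. **Number of topics.** Repeat steps 4–6 along the grid
   $[5,10,15,20,25,30,40,50,75,100]$, stopping as soon as the number of
   significant topics fails to increase; select the earliest $k$
   attaining the maximum.
8. **Report.** Per selected topic: the top 20 display terms, the member
   genes (input genes above threshold) with scores, and each member's
   supporting documents — its documents above threshold for that topic,
   always including the maximizing one.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `docs_per_gene` | 50 | caps over-represented, well-studied genes; equal representation across genes |
| `min_year` | 1996 | drops older abstracts, which are short and often outdated |
| `threshold` | 0.5 | gene–topic discretization; raise to focus on stronger associations |
| `alpha_level` | 0.05 | on Bonferroni-corrected p-values |
| `topic_grid` | 5…100 | candidate topic numbers; a single value gives a fixed-k run |
| `alpha` (LDA) | `50/k` | document–topic concentration, the common Gibbs-LDA convention |
| `eta` (LDA) | 0.1 | topic–word concentration |
| `iterations` / `burn_in` | 1000 / 500 | Gibbs sweeps; burn-in only affects the `argmax` assignment mode |

The hyperparameters and sweep counts are this package's choices (standard
Gibbs-LDA conventions); the method itself treats the topic-model fitter
as a black box, and any fitter producing per-token assignments can stand
behind `fit_lda()`'s contract.

## Design decisions in the open corners

* **Null smoothing.** The raw random-gene proportion can be exactly 0,
  which would make any input success infinitely significant. The default
  null is therefore Laplace-smoothed, $p_0 = (r+1)/(n_r+2)$ — bounded and
  conservative. `null_smoothing = "raw"` restores the unsmoothed
  proportion.
* **Random draw excludes the input.** Overlap between $G_r$ and $G_i$
  would contaminate the null, so the draw pool is
  `background \ input`. When that pool is smaller than the input set
  (possible on small benchmark corpora), the whole pool is used with a
  warning; the binomial test handles unequal group sizes natively.
* **Stopping rule.** "Stops to increase" is read as *stop when the
  count fails to grow* (`no-increase`); `strict-decline` is available
  for the reading that only a drop should stop the scan. Ties for the
  maximal count select the smallest k: fewer topics are easier to
  interpret.
* **Assignments.** Token–topic assignments are the final Gibbs state (a
  posterior sample), matching how collapsed-Gibbs implementations expose
  them; `assignment_mode = "argmax"` instead averages post-burn-in
  assignment counts per token and takes the argmax.
* **Degenerate k.** A fit with $k$ at or above the token count is
  allowed with a warning (the degenerate single-token corpus still
  normalizes correctly); the grid search skips such k entirely.
* **Excluded genes.** Input genes with no usable documents are excluded
  from the working set, reported in the manifest, and not counted in the
  enrichment denominator — they carry no literature signal either way.
* **Supporting documents.** The report lists, per member gene, the
  documents exceeding the threshold for the topic (plus the maximizing
  document), since the gene's score is defined by those documents'
  proportions; listing all sampled documents would dilute follow-up
  reading.
* **Surface forms.** The stem-to-surface reversal picks the most
  frequent pre-stemming form (ties: lexicographically smallest). This is
  a display choice only; all modelling happens on stems.
* **Determinism.** One master seed drives the random-gene draw and, via
  a fixed per-k derivation, every LDA fit, so a rerun with the same
  manifest reproduces the report byte for byte, and extending the topic
  grid never perturbs earlier fits.

## The synthetic fixture generator

`generate_fixture()` emulates exactly the statistical structure the
method assumes: topics are word distributions (symmetric Dirichlet,
concentration 0.1 by default, i.e. well-separated), planted gene groups
concentrate a `purity` share (default 0.8) of their documents' topic
mixtures on a home topic, background genes draw from uniform mixtures,
and documents are multinomial token draws (Poisson lengths, mean 60 by
default — roughly a stopword-stripped abstract). Tokens are
pronounceable CV-syllable pseudo-words chosen to be fixed points of the
Porter stemmer, so end-to-end tests isolate topic-model behavior from
stemming behavior. Years are all ≥ 1996 and relevancies 1, so the
default filters keep everything.

What the generator does **not** emulate: real biomedical language
(collocations, gene-symbol ambiguity, section structure), realistic
document-length and citation-count skew, correlated topics, or noisy
relevancy scores. Passing the planted-recovery and calibration tests
therefore demonstrates that the statistical machinery works under its
own model assumptions — not that topics on real PubMed corpora will be
equally clean.

## Validation and problem sizes

The test suite validates, among others:

* the per-document normalization on the exact 40/60 worked example;
* token conservation and row-normalization across 50 random fits;
* oracle equivalence of the max-score reduction (nested loops), the
  binomial tail (direct pmf summation, agreement to 1e-12) and the term
  ranking (full sort);
* planted recovery: fixtures with 5 true topics, 3 planted groups × 20
  genes, 30 background genes, 20 documents per gene, purity 0.8 and a
  2000-stem vocabulary, evaluated at the generative topic number — the
  package recovers ≥ 2 of 3 planted topics at precision and recall
  ≥ 0.7 in at least 8 of 10 seeds (in practice: all of them, perfectly);
* negative-control calibration: null fixtures with no planted structure,
  analyzed with a fixed 10-topic model, report zero significant topics
  in ≥ 90% of 20 seeded runs;
* the stopping rule on synthetic significant-count traces (plateau,
  decline, grid exhaustion);
* byte-identical reports across reruns with the same seed.

Recovery is evaluated at the generative topic number because a larger k
splits a planted group across sub-topics — each still significant, but
fragmenting the one-to-one matching that precision/recall presuppose;
the grid search remains the operational route when no ground truth
exists. Fixture sizes were chosen so the whole suite runs in a few
minutes on one core while keeping every corpus large enough (≈ 100k
tokens for the recovery fixtures) for stable Gibbs estimates.

## Known limitations

* Bag-of-words topics: phrase structure is ignored, so multi-word
  biomedical terms surface as separate stems.
* LDA assumes independent topics; related themes (e.g. a disease and its
  key pathway) may merge or split depending on k.
* The background pool shapes the contrast: against all genes, generic
  "GWAS vocabulary" topics become significant; restricting the pool to
  genes sharing the input's broad theme focuses the method on
  finer-grained distinctions.
* Genes absent from the literature (or from the index) are invisible to
  the method and are reported as excluded rather than scored.

## A minimal run

```{r example, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 1))
run <- genetopics(fx$genes, fx$index, topic_grid = 5, seed = 1)
print(run)
evaluate_recovery(run$report, fx$truth)
write_report(run$report, "genetopics-out")
```
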