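---
title: "Modelling prenatal depression symptoms from sparse app text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling prenatal depression symptoms from sparse app text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pregnant people using a prenatal-care app occasionally write free text
(journal entries, responses to prompts), self-report daily mood on a 1–5
Likert scale, and complete the Edinburgh Postnatal Depression Scale (EPDS,
a 10-item screen scored 0–30, with > 13 conventionally read as moderate to
severe symptoms). perilang turns those sparse longitudinal traces into a
supervised prediction problem: do language features of what someone wrote
predict their *subsequent* depression-screen scores?

The pipeline has four stages:

1. **Temporal pairing.** Per participant, text entries are clustered in
   time and concatenated; each cluster is labelled with the forward average
   of the EPDS screens that follow its last entry within a fixed window
   (30 or 60 days), with averaging cut off by the next cluster's first
   entry. Screens without preceding text and clusters without a following
   screen are discarded; a usability filter keeps only clusters retaining
   at least one meaningful token after stop/common-word removal.
2. **Language features.** Four families per sample: (a) lexicon sentiment —
   average positive score, average negative score and their difference
   ("sentiment fluctuation"), sense-averaged per stem, averaged over
   lexicon-matched stems; (b) theme-dictionary percentages over raw tokens
   (LIWC-style literal and prefix-wildcard patterns, including bespoke
   COVID-19 and pregnancy-health themes); (c) loadings from a latent
   Dirichlet allocation (LDA) topic model, topic count selected by split
   cross-validation; (d) componentwise maximum over word-embedding vectors
   of the sample's tokens; plus a word-and-emoticon count.
3. **Model.** Participant-grouped 70/15/15 train/development/test split;
   features standardized with training+development parameters; LASSO
   regression of the continuous averaged-EPDS label with the penalty chosen
   by five-fold participant-grouped cross validation over 50 log-spaced
   points on [1e-4, 1]; tied penalties resolve to the larger (sparser)
   value.
4. **Evaluation.** AUROC of the continuous predictions against the > 13
   binarized test labels (rank statistic, ties counted one half), plus
   out-of-sample R². Three variants mirror a natural ablation: baseline
   covariates only; baseline + language features; baseline + language +
   windowed mood summaries (mean/min/max) and an any-physical-symptom flag
   (this variant drops samples without an in-window mood report).

## Pairing rules in full

All timing is integer days since the start of pregnancy (day 0); calendar
dates and time zones are deliberately out of scope. Within a participant:

- A new cluster begins at the first entry that arrives strictly after at
  least one EPDS screen has followed the current cluster (screen day ≥ the
  cluster's last entry day). Entries arriving before any screen extend the
  cluster.
- The cluster's anchor is its last entry day. Screens with
  `anchor ≤ day ≤ anchor + window` contribute to the label, but only up to
  (strictly before) the next cluster's first entry, so each screen
  contributes to at most one sample per window.
- A screen on the same day as an entry counts as following it (lag 0); a
  screen on the same day as the *next* cluster's first entry belongs to
  that next cluster.
- Entries more than `window` days before the earliest contributing screen
  are dropped from the sample, so every retained entry precedes a
  contributing screen within the window.
- Mood (and symptom) reports are summarized over the interval from the
  sample's first entry day to `anchor + window`; absent in-window mood
  yields NA summaries (the sample is kept except in the mood variant).

These rules are frozen by an oracle-equivalence test: a literal,
independently coded scan over random timelines must agree exactly with the
implementation on 1,000 timelines at both windows.

## Preprocessing and the stemmer

Normalization lowercases, folds accents to base letters, removes emoticons
and strips punctuation; it is idempotent. Stop and common-word lists are
file inputs (packaged defaults: a standard English function-word list and
{today, yes}); removal precedes sentiment, topic and embedding extraction
but **not** theme counting, which runs on raw tokens so pronouns and other
function words remain countable. Stemming uses the Porter (1980) algorithm,
implemented in the package because no stemmer ships with the supported R
stack; it is applied only in the sentiment pathway, matching how a stemmed
sentiment lexicon is built. The word-count feature counts pre-removal
tokens plus emoticons, so it keeps the magnitude information that the
percentage-valued theme features deliberately discard.

## Topic model

LDA is fit by collapsed Gibbs sampling (Rcpp) with fixed symmetric priors
(document–topic α = 0.3, topic–word η = 0.05 — standard short-document
choices), 200 iterations with the last 100 averaged. The sampler uses its
own xorshift128+ generator seeded explicitly, so a fit is bit-reproducible
for a given corpus and seed on any platform, independent of R's RNG state.
Collapsed Gibbs was chosen over variational inference because exact seed
determinism and implementation transparency matter more here than
per-iteration speed, and the corpora are small. Held-out document loadings
use a deterministic fixed-point fold-in (responsibilities against the
fixed topic–word matrix, tolerance 1e-10), so inference adds no
randomness.

Topic-count selection follows the split-predictiveness scheme: for each
candidate k, five participant-grouped splits of the training samples; fit
topics on the split's fit portion; regress the mean-EPDS label on the
loadings with a LASSO whose penalty is cross-validated *inside the fit
portion*; score once on the held-out portion; select the k with lowest
mean held-out MSE, ties to the smallest k. The nested penalty choice is
essential: selecting the penalty on the held-out rows themselves
systematically favours larger k (more topics, more knobs evaluated
directly on the scoring rows) and inverts the selection.

## The LASSO and its edge cases

glmnet's Gaussian coordinate descent provides the solver (objective
RSS/(2n) + λ‖β‖₁), so the analytic null threshold λ_max = max_j |x_jᵀ(y −
ȳ)|/n holds on standardized columns; tests pin this limit, the near-OLS
limit at λ = 1e-4, and monotone sparsity along the grid. Zero-variance
feature columns standardize to all-zeros with a warning. Sentiment or
embedding blocks with no lexicon/vocabulary hit are NA at assembly and
mean-imputed with training+development means before standardization.
Baseline covariates are penalized like all other features (one model over
all inputs); race/ethnicity is one-hot with White as the dropped
reference. No fitted quantity — imputation mean, standardization constant,
topic model, vocabulary, penalty — ever sees a test row; a perturbation
audit asserts exact invariance of all fitted parameters under arbitrary
changes to test-participant text and scores.

## The synthetic cohort generator

Real data of this kind cannot be redistributed, so the generator is a
first-class module that emulates the *structure* of such a cohort and
plants known effects for recovery testing. Each participant has a latent
severity scalar z ~ N(0, 1) plus a slow within-pregnancy drift; z drives
every channel:

| channel | default | direction |
|---|---|---|
| sentiment flattening | 1.2 | positive/negative word balance narrows with z |
| mental-health theme odds | 1.0 | up with z |
| want theme odds | 0.6 | up with z |
| space theme odds | 0.5 | up with z |
| first-person-plural odds | 1.0 | down with z |
| verbosity | 0.15 | entry length up with z |
| mood shift | 0.8 | 1–5 mood down with z |
| EPDS loading | 5.0 | points per unit z |
| topic coupling | 1.0 | graded tilt of the topic composition |
| symptom odds | 0.5 | physical-symptom reports up with z |

Event structure is calibrated to the motivating cohort: log-normal entry
lengths around a mean of 53 words (SD 115), about 2.5 raw entries and 2.5
EPDS screens per pregnancy, mood check-ins every 5–6 days, and baseline
covariate marginals matching the published demographics (mean age
29.8 ± 5.4, ~79% White, ~60% household income ≥ $50k, ~68% associate
degree or higher, 24%/30% history of depression/anxiety, with the history
flags mildly tilted by z so baseline-only models retain some signal).
Half of the EPDS screens are drawn shortly (≤ 45 days) after a text entry,
emulating prompt-driven completion in the app; without this the pairing
yield per participant falls far below what engagement-driven usage
produces. The EPDS loading and noise (base 6, SD 2.5) reproduce the
screening severity mix reported for such cohorts (roughly 55% none, 35%
mild, 8% moderate, 2% severe among screens).

Text is a bag-of-words mixture: five disjoint topic vocabularies (sleep,
work, baby preparation, food, appointments), sentiment-bearing words whose
positive share is plogis(1.2 − flatten·z), theme word groups with
odds-scaled weights, filler function words. The severity tilt on the topic
composition is graded across topics (weights from +1 to −1), so coarser
topic models genuinely lose severity-relevant information — a single
tilted topic would be representable by any k. Entry text is therefore
bag-of-words-compatible with every extractor but has no grammar; any
feature that would depend on syntax or word order is outside what this
generator can validate.

The **null configuration** (`null_generator_spec()`) zeroes every channel
and re-centres the EPDS distribution (base 12, noise SD 5.6) so that the
> 13 labels are common enough (~1/3) for a test-set AUROC to concentrate;
under the study-calibrated base, null positives are so rare that the AUROC
estimate is undefined or wildly unstable for many seeds. This choice
affects only the null calibration check, which asks whether the pipeline
invents signal, not what the marginal prevalence is.

## What the tests do and do not show

Passing recovery tests show the pipeline extracts planted bag-of-words
effects in the right direction and discriminates high-severity
participants on data *generated by its own assumed mechanism*. They do not
show that real prenatal language behaves this way: real text has syntax,
topic drift, code-switching, typos and far heavier-tailed engagement. The
published real-data results (test AUROC about 0.7 for language models and
about 0.8 with mood) came from a private cohort and are not reproduction
targets; on the synthetic cohort the planted effects are stronger than
real language signal, and the reported AUROCs are accordingly higher.

## Problem sizes and determinism

Recovery checks use 500-participant cohorts (10 strong and 10 null seeds)
at the 60-day window — the window defined by the DSM-5 remission
criterion, which also yields the larger modeling set; topic-number
recovery uses 150-participant, topic-only corpora over candidates
{2, 5, 20} with 20 seeded replicates; the end-to-end determinism audit
runs the default 200-participant configuration twice and compares output
files byte for byte. Every stochastic stage (generation, splitting, fold
assignment, Gibbs initialization) is seeded from the configuration seed,
and `generate_cohort()` restores R's RNG state on exit.

## Known limitations and open choices

- Whether sentiment averaging denominators should be all tokens or only
  lexicon-matched tokens is a genuine ambiguity; matched-token
  denominators were chosen (unmatched stems carry no sentiment evidence),
  leaving absent blocks NA for imputation rather than silently zero.
- Proprietary LIWC-22 category contents are not reimplemented; the
  packaged theme dictionaries cover the reported summary and
  psychological-process themes with open word lists of identical
  mechanics (Tone and Clout are approximations flagged as such).
- The EPDS item level (e.g. the self-harm item) is not modelled; only
  total scores are in scope.
- English-language detection is assumed to have happened upstream.
- The dev-set is pooled into the cross-validation set rather than used
  for separate early model selection; the split is still produced and
  reported so the 70/15/15 structure is preserved.
- Mood summarization uses the window-averaging rule; when "current mood"
  is referenced informally the most-recent-report reading is plausible,
  but the averaging rule is the explicitly stated procedure and is what
  is implemented.
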