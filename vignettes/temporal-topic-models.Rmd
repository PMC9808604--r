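---
title: "Temporal topic models for closed-cohort clinical note corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal topic models for closed-cohort clinical note corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cohorttopics)
```

## The analysis problem

A closed cohort is a fixed panel of patients followed across T consecutive
quarterly strata, every patient contributing at least one clinical note in
every stratum. Pooling each patient's notes within a quarter gives a
patient-quarter document collection, represented as a sparse
document-term matrix **X** (rows = patient-quarter cells, columns = a
curated vocabulary of V words). Topic models compress X into K latent
themes and, because every row carries a quarter index, the per-document
topic proportions can be averaged within quarters to give a T×K
*topical-prevalence series*: how much of the cohort's clinical activity
each theme accounts for, quarter by quarter. Themes with an annual
rhythm — influenza vaccination, winter respiratory disease — show up as
period-4 cycles in their prevalence column.

`cohorttopics` implements this workflow end to end with two deliberately
different estimators behind one contract, so that agreement between them
is itself evidence about the corpus rather than about either algorithm.

## Preprocessing

Tokenization is intentionally minimal and exactly reproducible: split on
whitespace (spaces, tabs, newlines, carriage returns), lower-case, delete
nonalphabetic characters *within* tokens, then drop tokens of length ≤ 1.
Deletion is character-wise rather than token rejection, because the short
residues it creates ("x2" → "x") are handled by the separate length rule.
"Alphabetic" defaults to ASCII `a-z` after lowercasing, with a
Unicode-letter mode for corpora where that matters. The tokenizer is
idempotent on its own output, which the test suite asserts.

Vocabulary curation in a real study involves manual review; that step is
not mechanically reproducible, so it is replaced by a configurable triple:
a stoplist, a minimum corpus count, and an optional maximum size. Ranking
is by decreasing corpus count with **alphabetical tie-breaking**, so the
vocabulary (and everything downstream) is identical across runs and
platforms. Dates map to quarters by the calendar convention (Jan–Mar,
Apr–Jun, Jul–Sep, Oct–Dec), indexed 1..T chronologically.

At the patient-quarter level the row grid is always complete: a cell whose
notes contain only out-of-vocabulary tokens is kept as an all-zero row, and
the models tolerate it (NMF normalization maps zero rows to the uniform
composition; the LDA estimator returns the normalized prior for token-free
documents). This keeps the D = patients × T geometry exact.

## NMF

The least-squares objective ‖X − WH‖²_F is minimized over nonnegative
W (D×K), H (K×V) by Lee–Seung multiplicative updates, chosen for their
simplicity and provable monotone descent; the loss trace is recorded every
iteration and the package asserts nonincrease (tolerance 1e-9) on every
fit. Numerical choices:

* **Initialization**: entries i.i.d. uniform(0,1) scaled by
  `sqrt(mean(X)/K)`, drawn from the run seed, so the initial
  reconstruction W H is on the scale of the data and runs are
  reproducible.
* **Denominator guard**: a constant 1e-12 is added inside the update
  denominators only, avoiding division by zero for empty rows/columns
  without materially moving fixed points.
* **Stopping**: relative loss change below `tol` (default 1e-5) or
  `max_iter` (default 500).
* No regularization; alternating nonnegative least squares is a possible
  extension point but not implemented.

Row-normalizing W and H yields θ and Φ. The normalization is invariant to
the scale indeterminacy of the factorization (rescaling column k of W by
c > 0 and row k of H by 1/c), which is asserted in tests.

## LDA

The admixture model places Dirichlet priors on per-document topic
mixtures (concentration α, default symmetric 1/K) and per-topic word
distributions (concentration β, default 0.01). Inference is **collapsed
Gibbs sampling**: θ and Φ are integrated out analytically and each token's
topic indicator is resampled from counts excluding that token. We chose
Gibbs over variational inference because it is self-contained, exact in
the long-sweep limit, and checkable against enumeration oracles — the
collapsed joint log p(w, z | α, β) has a closed Dirichlet-multinomial
form (sums of log-Gamma terms) that the test suite verifies against
exhaustive enumeration of all topic configurations on a tiny corpus, and
the per-sweep trace of that quantity serves as the convergence
diagnostic. Equivalence with other inference engines is expected only at
the level of recovered topic structure, never parameter by parameter.

Defaults: 400 sweeps, 200 burn-in, posterior-mean estimators
θ̂[d,k] = (n_dk + α_k)/(n_d + Σα) and φ̂[k,v] = (n_kv + β_v)/(n_k + Σβ)
averaged over every retained sweep. One root seed drives a single
deterministic sweep stream (no document parallelism), so runs are
bit-reproducible; the categorical draw uses cumulative-sum inversion in
double precision, where ties have probability zero.

## The temporal series and its displays

The T×K series takes the **unweighted** mean of θ rows within each
quarter: at the patient-quarter level each cell counts once, matching the
design in which the patient-quarter is the analysis unit. A
document-count-weighted mean is available via the `weights` argument for
note-level analyses. A quarter with no documents is an error (there is
nothing to average) — by construction a closed cohort never produces one.

Topic trajectories (columns, each a length-T point) are hierarchically
clustered with the Euclidean metric and Ward agglomeration. Merge heights
are reported as **the square root of the increase in within-cluster sum of
squares**, so two singleton series at Euclidean distance e merge at height
√(½)·e; heights are nondecreasing. (`stats::hclust(method = "ward.D2")`
computes the same tree with heights √2 larger; the package rescales.)
Heatmaps use a single global color scale on the raw prevalence scale —
per-row normalization would visually equate topics of very different
overall prevalence — with rows in dendrogram leaf order.

Uncertainty bands are percentile bootstraps over documents within each
quarter stratum (default 500 resamples, level 0.95), widened if necessary
to contain the point estimate; a single-document stratum degenerates to a
zero-width interval with a warning. The suite includes a 200-replicate
coverage study on simulated strata with known means.

## Model comparison

Each model is summarized by the top-L (default 5) words of each topic,
ties broken by vocabulary order. From the resulting K·L-word bag:

* **Topic diversity** = unique words / total words.
* **Recurring words** = the bag's most frequent members (alphabetical
  within ties).
* **Jaccard concordance** between two models = |A∩B|/|A∪B| over the
  deduplicated bags.
* **Coherence** over the modeled corpus itself (the evaluation is
  internal; no external reference corpus):
  * UMass: mean over ordered pairs (i > j) of
    log((D(w_i,w_j)+ε)/D(w_j)), whole-document counts;
  * UCI: mean over unordered pairs of log((P(w_i,w_j)+ε)/(P(w_i)P(w_j))),
    sliding-window probabilities;
  * NPMI: the UCI ratio normalized by −log(P(w_i,w_j)+ε), lying in
    [−1, 1].

Numerical conventions: natural logarithms throughout; ε = 1e-12; windows
of width 10 stepping one token at a time (a document shorter than the
window contributes one window); a word absent from the corpus counts as
frequency zero with ε guarding the logarithms. One degenerate case needs a
convention: a pair present in *every* window has P = 1, making NPMI 0/0;
such a pair carries no information and is scored 0. The exact NPMI
weighting exponent varies across the literature; we use the plain
normalization above and document it rather than guessing any particular
implementation's variant. All three measures are verified against an
independent brute-force pair-enumeration implementation to 1e-9.

## The synthetic-corpus generator

The generator emulates the study design, not clinical language: a closed
cohort of `n_patients` × `n_quarters` (default T = 20, five years), notes
per patient-quarter 1 + Poisson(1) (guaranteeing the ≥ 1 note minimum),
note lengths Poisson(40) truncated at ≥ 5 tokens — short-note scale with
no empty documents. The corpus distributions of a real cohort are not
published beyond coarse counts, so these two distributions are explicit
configuration with those defaults. Planted topics are symmetric-Dirichlet
draws over a synthetic vocabulary (lowercase alphabetic words, so the
tokenizer is the identity on clean text; a noise option injects numerals,
punctuation and single characters to exercise the normalizer). Prevalence
curves are constant or seasonal,
base·(1 + a·cos(2π((t−1)−phase)/period)) renormalized per quarter, with
period 4 as the annual default; amplitude must stay below 1 or prevalence
would go negative.

**Document mixing.** By default every note generated in quarter t draws
its tokens from the quarter mixture Σ_k prevalence[t,k]·φ_k, which makes
the planted prevalence the exact expected topic mixture at t. For
*recovery* experiments this default is deliberately not enough: if every
document in a stratum shares one mixing vector, tokens are i.i.d. from a
single unigram law and the individual topic-word rows are unidentifiable —
no estimator can separate them, and empirically both models return badly
mixed topics. Identifiability requires document-level admixture variation,
so recovery studies use the generator's Dirichlet jitter with
concentration equal to the quarter's prevalence row (`doc_jitter = 1`):
E[θ_d] still equals the planted curve, so prevalence remains exactly
recoverable in expectation, while unit total concentration gives sparse,
focused documents — the regime short clinical notes live in. This choice
was fixed on that rationale, once, before being adopted across the
validation suite.

What passing recovery tests shows — and does not show: the pipeline can
identify well-separated planted topics (symmetric Dirichlet 0.05 over
V = 200) and their seasonal dynamics from 2,000 patient-quarter documents.
Real clinical text has correlated topics, abbreviation noise, misspellings
and patient-level covariate structure that the generator does not model;
recovery on simulation validates the estimation machinery, not the
linguistic realism.

## Validation problem sizes

The test suite works at deliberately modest scales: recovery at V = 200,
K* = 5, 2,000 patient-quarter documents, three seeds per model; coherence
oracles on corpora of ≤ 5 documents; the collapsed-likelihood enumeration
on a 2-document, 4-token instance (16 configurations); bootstrap coverage
over 200 replicates of 4 strata × 40 documents; pipeline smoke runs at
K = 5 on a 12-patient, 8-quarter cohort. These sizes make every property
cheap to re-verify while staying in the regime where the asymptotic
arguments (law of large numbers for the marginal word law, posterior
concentration for recovery) have begun to bite.

## Known limitations

* Neither sequential/temporal factorization variants nor dynamic or
  correlated topic models are implemented; time enters only through
  post hoc stratification of θ.
* Covariate-aware prevalence modeling (regression structure on θ) is out
  of scope; the bootstrap bands are the package's uncertainty statement.
* No stemming, lemmatization, multiword terms or concept normalization —
  the tokenizer mirrors a minimal whitespace pipeline by design.
* Coherence is evaluated against the modeled corpus itself; scores are
  comparable across models on one corpus, not across corpora.
* α and β are fixed, not optimized; K selection is left to the analyst
  (the per-K report tabulates diversity and coherence but performs no
  automatic choice, since too-small K merges distinct themes and
  too-large K fragments them).
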