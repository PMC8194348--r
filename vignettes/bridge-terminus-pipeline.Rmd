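---
title: "Modeling bridge/terminus pseudoword learning: similarity-controlled design, scoring, simulation, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bridge/terminus pseudoword learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The experimental logic

`bridgelearn` implements the computational machinery of a two-session
paired-associate vocabulary-learning paradigm. Learners study novel
("pseudoword") translations of familiar meanings in two sessions. The
first-session items are **bridge words**, constructed to be either highly
similar (Familiar condition) or highly dissimilar (Unfamiliar condition) to
the learner's native language, as measured by sublexical letter- and
sound-sequence statistics. Every second-session item — a **terminus word** —
is a single-letter substitution neighbor of exactly one bridge word, and all
terminus words are uniformly dissimilar to the native language. The paradigm
therefore separates two sources of transfer: similarity to the native
lexicon (bridge session) and similarity to just-learned novel words
(terminus session, analyzed through each learner's own bridge performance).

The package provides every computational stage as testable code: the
similarity model and thresholds, the constrained stimulus design, response
scoring and knowledge categorization, a synthetic-participant generator, and
the mixed-model inference with a Monte-Carlo power analysis. The
`analysis/` scripts run the stages in order on the bundled synthetic inputs.

# The similarity model

**Positional bigram probabilities.** For a reference lexicon of fixed-length
words with token frequencies $f_w$ (per million), the probability of letter
pair $b$ at position $i$ is

$$P_i(b) = \frac{\sum_{w:\, w[i..i+1] = b} f_w}{\sum_w f_w},$$

the token-weighted (Vitevitch–Luce style) convention. Position-specific
tables are well defined here because the stimuli and the reference set share
one word length. A form's orthographic score is the mean of $P_i$ over its
adjacent letter pairs; pairs never observed at a position contribute zero.

**Biphone probabilities.** The phonological channel uses the same
token-weighted idea but pools over positions, because transcription lengths
vary. Transcriptions are sequences of ASCII phone symbols; the bundled
inputs use a deterministic one-phone-per-letter transcription rule, which
stands in transparently for a grapheme-to-phoneme system while preserving
the two-channel structure of the metric.

**Composite similarity.** Both channel scores are z-transformed against the
moments of the real-word reference set, and the composite is the mean of the
two z-scores. Using the reference set (rather than the candidate set) for
the moments keeps candidate scores commensurable with the real-word ranking
that defines the thresholds.

**Percentile thresholds.** Reference words are rank-ordered from most to
least similar; the threshold at percentile $p$ is the score at rank
$\lceil p/100 \cdot N \rceil$. The *high* threshold (20th percentile) admits
only candidates more English-like than all but the top fifth of real words;
the *low* threshold (99th percentile) admits only candidates less
English-like than virtually all real words. The descending-rank reading is a
deliberate design choice: it is the only direction under which "above the
20th percentile" (Familiar) and "below the 99th percentile" (Unfamiliar) are
both selective, so we adopt it without asserting it as the only possible
convention.

# Stimulus design

Candidates are drawn uniformly from a CVCVC template (18 consonants — the
alphabet minus a, e, i, o, u, q, x, y — and 5 vowels), deduplicated, and
screened against the reference lexicon; the default pool is 10,000
candidates. Selection then proceeds under these constraints:

* **Onset balancing.** Bridge lists are drawn by greedy round-robin over
  onset letters with a hard per-onset cap of $\lceil k/18 \rceil$ (3 for
  $k = 48$). Infeasibility is a loud error, not a silent imbalance.
* **Bridgeability.** Bridge eligibility is restricted to candidates with at
  least one template-preserving non-word substitution neighbor scoring below
  the low threshold. Without this restriction the terminus construction is
  usually infeasible: the most English-like candidates tend to have *no*
  sufficiently dissimilar neighbors, and the required bridge-terminus
  bijection then cannot be completed. The original selection procedure
  leaves this constraint implicit; here it is explicit and tested.
* **Terminus construction.** Neighbor sets exclude real words and any form
  that neighbors two or more bridge words; one neighbor is drawn per bridge
  word, so the terminus-to-bridge map is a bijection by construction.
  Selection is rejection-sampled (seeded) until Welch t-tests on mean bigram
  and mean biphone probabilities show no difference (all p > 0.1) between
  the Familiar and Unfamiliar terminus lists and between the Unfamiliar
  bridge and terminus lists. When the duplicate exclusion strands a selected
  bridge word, the bridge draw itself is resampled with advanced seeds.
* **Meaning lists.** The 96 meanings (half concrete, half abstract) are
  split into matched A/B halves by seeded constrained re-randomization until
  Welch tests on imageability, age of acquisition, familiarity, and zipf
  frequency are all non-significant (p > 0.05). Counterbalancing group 1
  uses list A meanings in the bridge session and list B in the terminus
  session; group 2 reverses this, so every participant sees all 96 meanings
  exactly once. A bigram-overlap count per list quantifies incidental
  novel-word/meaning form overlap (the near-cognate check).

All stages draw their seeds from one master seed via `fan_out_seeds()`, and
identical inputs plus an identical seed give byte-identical stimulus files.

# Scoring and knowledge categorization

Responses are normalized (lower-case, whitespace and non-letters stripped)
and scored positionally: each correct letter in the correct position earns
0.2 points, maximum 1. Responses longer than five letters are scored on
their first five positions — a hard zero would destroy information about
partially correct overlength answers, and the scoring rule as stated is
purely positional. Bridge-knowledge categories classify each terminus item
per participant by the bridge neighbor's letters correct: Known (4–5),
Partly-Known (1–3), Unknown (0). Categories are assigned from each
learner's own realized performance, so category counts are unbalanced by
design.

# The synthetic-participant generator

Latent accuracy for one trial is, on the percent scale,

$$\mu = \text{cell mean} + b_\text{participant} + s_\text{participant}\cdot[\text{terminus}]
  + u_\text{form} + u_\text{meaning} + \mathbf{x}^\top\boldsymbol\beta,$$

clamped to $[0, 100]$; letters correct are drawn $\mathrm{Binomial}(5, \mu/100)$
and realized as response strings (wrong positions draw a different letter
from the slot alphabet), so simulated data flow through the same scorer as
real data. Bridge cell means default to the study conditions (34.03 /
16.16 percent); terminus accuracy is generated *conditionally on the
realized bridge-knowledge category* of each item's neighbor, with
condition-specific category means (Familiar 27.60 / 24.55 / 19.36;
Unfamiliar 30.75 / 12.68 / 16.25 percent). Group sizes default to 17
(Familiar) and 21 (Unfamiliar).

Design notes:

* **Clamping, not a logit link.** The downstream analysis is a linear model
  on percent accuracy, so the generator stays on the same scale; the
  clamped fraction is recorded (`clamp_fraction`) so heavy truncation is
  visible.
* **Variance components are placeholders.** The study reports no
  variance-component estimates; the defaults (participant intercept SD 12,
  other components 5, percent scale) are recorded configuration values, not
  study values, and the power stage treats them as explicit inputs.
* **Generating truth.** `truth_cell_means()` integrates the generative model
  numerically (201-node stratified-normal grids) to give the exact expected
  cell means and category proportions implied by a configuration; the
  parameter-recovery suite compares fitted contrasts against these, not
  against the study's human numbers.
* **What the generator does not emulate.** Human letter knowledge is closer
  to all-or-none than Binomial(5, p): at a 34-percent latent mean, binomial
  noise yields far fewer fully-known (4–5 letter) bridge words than human
  learners produce, so realized Known-category proportions are smaller than
  in human data, and the implied terminus marginals differ accordingly from
  the study's observed marginals. The generator also omits study-time
  allocation, inter-session forgetting, and item-order effects. Passing
  tests therefore certify the pipeline's machinery — scoring,
  categorization, estimation, calibration — on data with the analysis
  model's own structure, not behavioral realism of the letter-noise process.

# Inference

Both study models are linear mixed-effects regressions fit by REML with
Satterthwaite degrees of freedom (`lmerTest`): accuracy on Similarity ×
Session (all trials) and on Similarity × Bridge-Knowledge (terminus trials,
treatment-coded against Known so the coefficients are the Known-vs-Partly
and Known-vs-Unknown contrasts). Covariates (imageability, age of
acquisition, familiarity, zipf of the paired meanings) are centered at their
sample means so interaction estimates match the marginal-means
parameterization. The maximal random structures (participant intercept +
session or knowledge slope; form intercept or knowledge slope; meaning
intercept + session/knowledge and condition slopes) are the defaults; on
non-convergence the structure is reduced along a fixed, logged policy —
meaning-level slopes first, then participant-level slopes, then grouping
factors — and singular fits are accepted with a log entry, following common
practice for maximal models whose smaller variance components collapse to
zero. If no structure converges cleanly (typical only for degenerate
noise-free inputs), the simplest structure that produced estimates is
returned with all warnings on record. Estimated marginal means hold
covariates at their sample means; pairwise contrasts use the Tukey
studentized-range adjustment (single-step multivariate-t where the
studentized range does not apply), with unadjusted p-values reported
alongside. Welch t-tests and the uncorrected Pearson chi-square test back
the matching checks and the category-table test.

For repeated-fit simulation studies (parameter recovery, type-I
calibration) the package's tests use a reduced random structure —
participant intercept + session slope, form and meaning intercepts — since
the generator contains no form/meaning slope variance; this keeps hundreds
of REML fits tractable on one CPU while matching the generative model. The
maximal structure with the reduction policy remains the default for
`run_analyze()`.

# Power analysis

`power_simulation()` estimates power for a between-group similarity effect
(default 10 percent on latent accuracy) across total sample sizes 20–40 in
steps of 5, with 200 Monte-Carlo datasets per size. Each dataset is a
two-group single-session study (baseline = the Unfamiliar bridge mean;
variance components from the simulation configuration) analyzed with
`accuracy ~ group + (1 | participant) + (1 | form)`; power is the rejection
rate of the group effect at alpha = 0.05, reported with its binomial
Monte-Carlo standard error. Because the original pilot variance components
are unknown, the curve characterizes the simulator's recorded defaults and
makes no claim to reproduce the original sample-size figures.

# Bundled inputs and problem sizes

The three files under `inst/extdata/` are synthetic and generated entirely
by package code (`data-raw/make-extdata.R`, seeds recorded there): a
500-word five-letter CVCVC reference lexicon with English-like letter
frequencies and power-law (zipf) token frequencies, its one-phone-per-letter
pronunciation table, and a 96-meaning norm table (48 concrete / 48 abstract,
ratings on a 100–700 scale). At 500 reference words the 99th-percentile
threshold sits in the extreme tail of the score distribution, so some
lexicon draws cannot support a fully onset-balanced bridgeable pool; the
bundled lexicon uses the first generator seed (ascending scan) under which
the complete design is feasible, a feasibility condition on the input rather
than a tuning of any outcome.

The simulation studies in the test suite use 100 replicate datasets for
parameter recovery, 200 replicates for type-I calibration, and 200
Monte-Carlo datasets per sample size for the power curve — sizes chosen to
give Monte-Carlo standard errors small enough for the stated checks (about
1.5 percentage points on a 5-percent rejection rate, 3.5 on a power
estimate) while keeping a full run on one CPU in the tens of minutes.

# Known limitations

* Letter-level binomial noise understates all-or-none word knowledge (see
  above); consequently simulated knowledge-category distributions are not
  calibrated to human ones.
* The biphone channel of the bundled inputs duplicates the orthographic
  channel up to positional pooling, because transcriptions are
  one-phone-per-letter; with a real pronunciation table the two channels
  diverge as intended.
* The terminus matching loop tests only the two comparisons the design
  requires; it does not jointly match any other moments of the lists.
* Percentile thresholds use the sample rank statistic, not an interpolated
  quantile; at small reference sizes the low threshold is noticeably noisy.
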