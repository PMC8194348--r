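# bridgelearn

Computational pipeline for two-session **bridge/terminus pseudoword-learning
experiments** — the paradigm in which learners first study novel words that
are either similar ("Familiar") or dissimilar ("Unfamiliar") to their native
language, and then study a second list in which every new *terminus* word is
a single-letter substitution neighbor of exactly one first-session *bridge*
word. The package is for psycholinguists who need the machinery of such
studies as tested, reproducible code: similarity-controlled stimulus
generation against a reference lexicon, letter-level response scoring and
knowledge categorization, a synthetic-participant simulator, and the
mixed-effects inference and Monte-Carlo power analysis the design calls for.

## The model at the core

Native-language similarity of a wordform *w* is a composite of two
sublexical channels, each token-weighted by lexical frequency over a
reference lexicon of same-length real words:

- positional bigram probability
  `P_i(b) = Σ_{w: w[i..i+1]=b} f_w / Σ_w f_w`, averaged over the
  adjacent-letter positions of *w*;
- position-independent biphone probability over the adjacent phone pairs of
  *w*'s transcription.

Both channel means are z-scored against the real-word reference moments and
averaged: `composite(w) = (z_ortho + z_phono) / 2`. Real words are
rank-ordered by composite score (most similar first); the **high threshold**
is the score at the 20th percentile rank and the **low threshold** at the
99th. Familiar bridge words score above the high threshold, Unfamiliar
bridge words and *all* terminus words below the low one, with onset-balanced
selection, a bijective bridge-terminus neighbor mapping, and Welch-test
matching of the lists' sublexical statistics (all p > 0.1).

Responses are scored 0.2 points per letter in the correct position (max 1).
Terminus items are categorized per participant by the bridge neighbor's
letters correct — Known (4-5), Partly-Known (1-3), Unknown (0) — and
accuracy is analyzed with linear mixed-effects models (REML, Satterthwaite
degrees of freedom, Tukey-corrected marginal-means contrasts):
`accuracy ~ Similarity * Session + covariates + (1 + Session | participant) +
(1 | form) + (1 + Session + Similarity | meaning)`, and analogously
`Similarity * BridgeKnowledge` on the terminus session.

## Worked example

The bundled inputs under `inst/extdata/` are synthetic: a 500-word
five-letter CVCVC reference lexicon with English-like letter statistics, its
pronunciation table, and a 96-meaning norm table. The numbered scripts under
`analysis/` run the full workflow on them:

```sh
Rscript analysis/01_design_stimuli.R
Rscript analysis/02_simulate_participants.R
Rscript analysis/03_fit_models.R
Rscript analysis/04_power_analysis.R
```

Stage 1 prints the fitted similarity thresholds and the design's matching
report — with the bundled inputs and master seed 1:

```
similarity thresholds: high 0.658 low -0.987
terminus matching p-values (all must exceed 0.1):
              term_bigram              term_biphone  unfam_bridge_term_bigram
                    0.207                     0.106                     0.137
unfam_bridge_term_biphone
                    0.674
accepted after 312 rejection-sampling iterations
```

i.e. the Familiar/Unfamiliar terminus lists and the Unfamiliar
bridge/terminus lists do not differ in mean bigram or biphone probability,
as the design requires. Stage 2 simulates 17 + 21 synthetic learners (3,648
trials) at the configured cell means; stage 3 fits both models and prints,
among other output, the estimated marginal means of the Similarity × Session
model:

```
   condition  session    M   SE   df ci_low ci_high
1   Familiar   Bridge 38.0 3.24 40.3   31.4    44.5
2 Unfamiliar   Bridge 18.1 2.94 41.3   12.2    24.0
3   Familiar Terminus 28.3 3.79 39.1   20.6    35.9
4 Unfamiliar Terminus 17.5 3.42 39.8   10.6    24.4
```

— the simulated Familiar advantage is large in the bridge session and
shrinks in the terminus session (interaction estimate 9.08, SE 2.38, on the
treatment-coded scale where a positive value means the Unfamiliar group
loses less across sessions), together with the knowledge-category table and
its chi-square test. Stage 4 estimates power for a 10-percent similarity
effect over total sample sizes 20-40 (power 0.37 → 0.65 with the recorded
default variance components; the curve's Monte-Carlo standard errors are
about 0.035). All tabular outputs are written under `results/`.

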