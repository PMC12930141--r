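# gazespeech

Tools for studying **cross-modal coordination**: do speakers who describe a
visual scene with similar sentences also move their eyes over the scene in
similar ways — and is that coordination carried by the *meaning* of the
sentences, by their *syntax*, or both, in which phase of speaking, and does
it hold across typologically different languages?

The package is built for cued scene-description experiments (a cue word,
then a scene, then a spoken description while gaze is tracked) and for
analysts who have: per-trial fixation tables, utterance timing and
transcripts, Universal Dependencies parses (CoNLL-U) and multilingual
sentence-embedding vectors. It computes three pairwise similarity measures,
assembles every trial-by-trial comparison, and fits one association model:

* **Scan-pattern similarity.** Fixations are binned (25 ms) onto a 6 × 4
  grid of cells over the image and split into *before speaking* (planning)
  and *during speaking* (articulation) sequences. Two sequences are
  compared by longest common subsequence, normalized by the geometric mean
  of their lengths: `lcs(a, b) / sqrt(m * n)` in [0, 1]. A region-of-
  interest encoding (fixations mapped to labelled objects) is available as
  a robustness variant.
* **Semantic similarity.** Dot product (or cosine) between the two trials'
  sentence-embedding vectors.
* **Syntactic similarity.** A normalized, order-dependent Subset Tree
  Kernel over *delexicalized* dependency trees (labels only, children in
  surface order, a `HEAD` marker recording the head's linear slot):
  `Delta(n1, n2) = lambda * prod_i (1 + Delta(c1_i, c2_i))` over matching
  ordered productions, so subject–verb–object and subject–object–verb
  realizations of the same relations are *not* alike. A coarser
  part-of-speech LCS variant and per-language core-dependency word-order
  tables (`nsubj ROOT dobj`, `nsubj dobj ROOT`, ...) come with it.

The pair table (every unordered trial pair, per phase, with same/different
scene and language labels) feeds a linear mixed-effects model

```
scan_sim ~ sem * syn * language * scene * phase +
  (1 | participant_pair) + (1 | item_pair) + (1 | cue_pair)
```

fitted by maximum likelihood (lme4), with Wald intervals on the
coefficients, standardized coefficients from a declared z-score/±0.5
refit, and — because single treatment-coded coefficients are poor
summaries under a five-way interaction — per-phase *average marginal
slopes* with dyadic-robust standard errors (`marginal_effect()`). A
seeded **shuffle control** re-pairs scan patterns with random sentences to
show what a spurious association looks like.

A synthetic-study generator (`generate_study()`) produces complete studies
— fixations, embeddings, CoNLL-U parses, region maps — from a latent
message model with controllable semantic (`g_sem`) and planning-phase
syntactic (`g_syn_before`) coupling, so the entire pipeline is testable
end to end without any external data.

## Worked example

```r
library(gazespeech)

# simulate a 3-language study with strong semantic coupling
study <- generate_study(synth_config(g_sem = 0.8, g_syn_before = 0.5, seed = 1))

# encode, compare, filter, assemble, fit
res <- analyse_study(study)

# which word orders did the three languages produce?
head(res$word_orders, 4)

# are the two sentence-similarity channels confounded?
res$correlations

# the headline question: does semantic similarity predict scan similarity?
marginal_effect(res$fit, "sem")
```

```
 language              sequence count
      eng       nsubj ROOT dobj    33
      eng            nsubj ROOT    23
      eng        nsubjpass ROOT    16
      eng nsubj ROOT dobj nsubj    10

          stratum      rho     n
  within_language  0.00243 12292
 between_language -0.00430 24836

   phase estimate     se  ci_lo  ci_hi
 overall   0.0439 0.0112 0.0220 0.0657
  before   0.0439 0.0118 0.0207 0.0671
  during   0.0438 0.0112 0.0218 0.0659
```

Reading the output: the verb-final language never appears here because its
root is always utterance-final (`nsubj dobj ROOT` and friends — see the
full table); the near-zero correlations say the semantic and syntactic
measures capture distinct constructs; and the marginal effect says a
one-unit increase in sentence semantic similarity comes with a ~0.04
increase in scan-pattern similarity in *both* production phases, with
confidence intervals well clear of zero — the planted coupling, recovered.
On a shuffled study (`shuffle_pairing(study, seed)`) the same interval
covers zero.

The same analysis as a file-based workflow lives in `analysis/`:
`01_simulate_study.R` (writes the study in every interchange format),
`02_similarities.R` (pair table, word orders, correlations),
`03_fit_model.R` (coefficients, marginal effects, binned means),
`04_shuffle_control.R` (the control analysis). Each writes under
`results/`.

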