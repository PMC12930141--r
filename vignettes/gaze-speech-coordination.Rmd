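---
title: "Measuring the coordination of scan patterns and speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the coordination of scan patterns and speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

When speakers describe a visual scene, where they look and what they say
are tightly coordinated. `gazespeech` quantifies that coordination in
cued scene-description experiments: it turns each trial's fixation stream
into a categorical *scan pattern*, measures how semantically and
syntactically similar any two spoken descriptions are, assembles every
pairwise comparison across participants, scenes, languages and production
phases, and asks — in a single mixed-effects model — whether sentences
that are alike in meaning (or in structure) come with alike gaze
sequences. This vignette explains the measures, the model, the synthetic
validation data, and the numerical decisions behind them.

## Scan patterns

Fixations are mapped onto a 6 × 4 grid of equal cells laid over the
scene image (`grid_spec()`); each cell is a categorical label such as
`"aa"`. The grid is defined over each trial's own image extent, so labels
are comparable across display resolutions. The time axis is cut into
consecutive 25 ms bins from scene onset; a bin whose *start instant*
falls inside a fixation inherits that fixation's cell label. Bins covered
by no fixation (saccades, blinks) are dropped rather than forward-filled,
and consecutive identical labels are kept, so longer fixations weigh
more. Bins are split into a *before speaking* (planning) sequence — scene
onset to utterance onset — and a *during speaking* (articulation)
sequence — utterance onset to offset; later bins are discarded.

Three small rules close the gaps a real data set forces on you:
bin membership is decided by the bin-start instant (simple,
order-preserving, no fractional assignment); fixations that stray
slightly outside the image (tracker overshoot) are clamped to the nearest
edge cell, with a count kept in the run log; and a fixation straddling
utterance onset simply contributes bins to both phases.

Two scan patterns are compared with the longest common subsequence (LCS):
the classic dynamic program over the $(m{+}1)\times(n{+}1)$ score matrix,
where matching tokens extend the diagonal, $C[i][j] = C[i{-}1][j{-}1]+1$,
and mismatches take the running maximum. Similarity is the LCS length
divided by the geometric mean $\sqrt{mn}$ of the two lengths, which is 1
exactly when the sequences are identical and 0 when they share no cell.
The scalar entry point (`lcs_length()`) implements the plain dynamic
program; the all-pairs matrix (`scan_similarity_matrix()`) uses a
word-packed formulation of the same recurrence (one bit per sequence
position, so each update costs $O(n/64)$ words), and the test suite holds
the two implementations equal on random inputs.

As a robustness variant, fixations can instead be mapped to labelled
scene regions (`encode_trial_roi` style encoding via a region map), with
overlaps resolved by a priority order and uncovered fixations labelled
`background`. Grid and region encodings of the same synthetic study give
positively correlated pair similarities.

## Semantic similarity

Each description arrives as a fixed-length sentence-embedding vector
(any multilingual encoder; the package consumes the vectors, never runs
the encoder). The default similarity between two trials is the plain dot
product of their vectors; cosine similarity is available and coincides
with it exactly on unit-normalized embeddings. Embeddings are used as
provided — no silent re-normalization.

## Syntactic similarity

Descriptions also arrive as Universal Dependencies parses (CoNLL-U). To
compare structure and only structure, a parse is *delexicalized*: words
and part-of-speech tags are removed, each node keeps its dependency
relation label, the root is labelled `ROOT`, and children are ordered by
the dependent's linear position. One representational decision matters:
the head's own position among its dependents is recorded by inserting a
reserved `HEAD` marker child at the head's linear slot. Without it, a
verb-medial clause (subject–verb–object) and its verb-final counterpart
(subject–object–verb) would delexicalize to identical ordered trees; with
it, they differ, and the kernel below is genuinely order-dependent.

Similarity between two delexicalized trees is a subset tree kernel
(SST): it counts shared tree fragments, where a fragment keeps either all
or none of a node's children and must match in label, structure *and*
child order. The recursion is

$$\Delta(n_1, n_2) = \begin{cases}
0 & \text{productions differ} \\
\lambda & \text{matching leaves} \\
\lambda \prod_i \bigl(1 + \Delta(c_i^1, c_i^2)\bigr) & \text{matching internal productions,}
\end{cases}$$

summed over all node pairs. The decay $\lambda$ down-weights large
fragments; there is no field-standard value, and we default to
$\lambda = 0.4$, squarely in the range used for tree kernels in NLP, with
the value exposed in `kernel_config()` for ablation. Kernels are
normalized, $K(t_1,t_2)/\sqrt{K(t_1,t_1)K(t_2,t_2)}$, so syntactic
similarity lives on $[0,1]$ like the other measures. Because parses
instantiate a limited set of constructions, the all-pairs computation
canonicalizes each tree to a bracket string and computes each distinct
pair of structures once.

Two coarser structural summaries round out the module: the
*core-dependency sequence* walks the tokens in surface order and keeps
only the obligatory relations (nominal/clausal subjects, objects,
clausal complements) plus `ROOT` — a compact signature of word order
whose per-language frequency table makes typological differences visible
(a head-final language is `ROOT`-final in every utterance) — and a
part-of-speech variant that applies the normalized LCS to UPOS sequences.

Modern UD v2 labels are mapped onto the older inventory on input
(`obj` → `dobj`, `nsubj:pass` → `nsubjpass`), then language-specific
subtypes are truncated at the colon; both steps are configurable.

## Pair assembly, filters and the shuffle control

Descriptions shorter than 4 or longer than 77 words are excluded (both
bounds inclusive; a percentile mode recomputes the bounds from the
study's own distribution), as are phase sequences built from fewer than
two fixations — per phase, not per trial. Word counts use whitespace
tokens where the orthography has spaces and parse tokens otherwise
(relevant for Japanese-style transcripts).

Every surviving trial is then compared with every other trial:
$\binom{k}{2}$ unordered pairs, independently for the two phases —
cross-phase pairs are never formed, and each unordered pair is stored
once. Each record carries the three similarities, same/different-scene
and same/different-language flags, and unordered grouping keys
(participant pair, item pair, cue-word pair; self-pairs such as two
trials of one participant are legitimate levels).

The shuffle control re-pairs each scan pattern with a random sentence: a
seeded uniform permutation moves the whole linguistic bundle (transcript,
cue word, language, embedding, parse) onto another trial's gaze record,
leaving fixations and utterance timing in place. Any association that
survives shuffling is an artifact of marginal structure, not of the
gaze-utterance link. Since the gaze side is untouched, the expensive scan
similarity matrices can be reused across shuffle repetitions
(`shuffle_similarities()`).

## The association model

The pair table is analysed with a linear mixed-effects model (lme4,
maximum likelihood):

```
scan_sim ~ sem * syn * language * scene * phase +
  (1 | participant_pair) + (1 | item_pair) + (1 | cue_pair)
```

with treatment coding and reference levels *between*-scene,
*different*-language, *before*-phase, all interactions up to the five-way
term, and random intercepts only. Inference is by asymptotic Wald tests
and intervals. Standardized coefficients are obtained by refitting with
the response and the continuous predictors z-scored and the two-level
factors coded ±0.5 — a declared recipe, chosen rather than inferred.
Random-effect variances estimated at zero are reported with a boundary
flag rather than triggering a refit, and degenerate designs (a factor
with one level, a constant predictor) drop the affected terms and say so.

A full-interaction treatment-coded model makes individual main-effect
rows poor summaries: the `sem` row is the slope in one corner of the
design (between-scene, different-language, before-phase) and is heavily
collinear with its own interactions. The package therefore reports the
*average marginal slope* (`marginal_effect()`): the model-implied change
in scan similarity per unit predictor, averaged over the observed
covariate distribution, overall and within each phase. The model is
linear, so a unit finite difference on the fixed-effects design is
exact. This is the quantity the recovery analyses track.

Pairwise data need one more care. Every trial takes part in hundreds of
pair records, and the model-based covariance — which conditions on the
three random intercepts — does not absorb that dyadic dependence: on
null and shuffled data its z-statistics are overdispersed by a factor of
two or more. `marginal_effect()` therefore defaults to a *dyadic-robust*
standard error: the contrast's per-record influence contributions are
clustered on the two trials of each pair, allowing records that share a
trial to covary freely (the node-clustering estimator used for dyadic
regression). The coefficient table itself keeps the conventional
model-based Wald intervals, so the two conventions are both available
and labelled.

Descriptive summaries mirror the model: `binned_summary()` averages scan
similarity over bins of width 0.1 on the predictor axis, stratified by
scene × language × phase, min-max rescaling the predictor to $[0,1]$
per study when it is unbounded (dot products); the applied range is
recorded in the output's attributes. `binned_model_agreement()` checks
that per-bin model predictions track the raw means.

## The synthetic study generator

Nothing in the analysis can be validated on real data inside this
package, so `generate_study()` builds complete studies with the causal
structure the analysis presumes, at strengths the caller controls.

The generative story: a global inventory of object types, each anchored
to one grid cell and carrying one latent semantic vector, *shared by all
scenes and languages*. The inventory splits into an animate half (the
agents participants are cued to describe) and an inanimate half (the
patients), as in cued-description designs that cross referent animacy;
a scene is a distinct composition of both halves. Each trial draws a
latent *message* — weights over the scene's objects, concentrated on a
cued (animate) agent and an (inanimate) patient, plus a relation type —
and the message drives all three observable channels:

* **Gaze**: each fixation targets, with probability `g_sem`, an object
  anchor sampled by message weight, otherwise a uniform random cell.
  Fixation durations are gamma-distributed around ~180 ms with short
  saccade gaps.
* **Embedding**: the weighted sum of the focal objects' latent vectors
  plus a relation vector and Gaussian noise (`noise_sd`). The same
  message slot in two languages maps to nearby embeddings — the
  generator's "shared semantics" assumption.
* **Parse**: the language's word-order template (verb-medial, verb-final,
  or a verb-initial/medial mix) instantiated with random transitivity,
  modifier complexity and embedded clauses — a *syntactic channel drawn
  independently of the message*, which is what makes the semantic and
  syntactic similarity measures decorrelated by construction. A
  patient-first argument order (`p_scramble`) realizes passives,
  scrambled objects or object-only clauses depending on the template,
  matching the word-order signatures typologically distinct languages
  produce. The verb-final template puts the root token last in every
  utterance.

The planning-phase syntax link has two components, both gated by
`g_syn_before` and both planning-specific. First, a *reordering*: with
probability `g_syn_before` the trial is planned word-orderly, and its
planning-phase object-directed fixations open the phase in the
utterance's argument order — agent-first realizations inspect the
animate referents before the inanimate ones, patient-first realizations
(passives, scrambled objects) the reverse. Because animacy is bound to
object types, and types to cells, two trials that realize the same
argument order share this visit signature even across scenes; the
animacy split is what makes the signature cell-consistent rather than
message-bound. Second, *encoding time*: planning duration grows with
the utterance's structural complexity (token count), so structurally
similar utterances have similar planning-phase lengths; articulation
timing stays language- and speaker-driven. At `g_sem = 0` there are no
object-directed fixations to reorder, so the gaze carries no semantic
trace — the null condition stays null.

Defaults were fixed once, as a package design decision: 3 languages × 8
participants × 12 scenes (288 trials, ~80 000 pair records — large
enough for stable recovery, small enough that the full validation
pipeline runs in minutes on one core); planning-phase durations around
3 s and articulation durations of 3.4/8.1/5.1 s for the three language
profiles, echoing the durations reported for English, Portuguese and
Japanese scene descriptions, which puts planning sequences at roughly
120 tokens; an inventory of 8 object types (4 animate, 4 inanimate)
with 4 objects per scene, so that scenes overlap substantially and
messages vary both within and across scenes — under heavier overlap or
near-disjoint scenes, chance re-alignments under the shuffle control
become lumpy and the shuffled effect distribution overdisperses
relative to its standard error; embedding noise 0.2, which leaves the planted coupling clearly
recoverable while keeping per-pair semantic similarities realistically
spread; a small rate of degenerate trials (two-word fragments, one
fixation in a phase) so the exclusion filters have real work to do.

What the generator does **not** emulate, and what passing tests
therefore cannot show: natural-language lexicons (transcripts are
pseudo-words), visual saliency and center bias, object-extent geometry
(objects are cell-sized), anticipatory eye–voice span dynamics within
the articulation phase, or any participant-level individual differences.
Recovery results on this generator validate the *pipeline*, not any
claim about real speakers.

## Validation summary

The test suite checks every stage against independent oracles (LCS by
exhaustive subsequence enumeration, the kernel by explicit fragment
enumeration, cell assignment by interval search), the worked
micro-examples, the design combinatorics, and the end-to-end recovery
properties: planted semantic coupling is detected in both phases and
scales monotonically with its strength; a zero-coupling study yields a
null; shuffling removes the effect; planning-phase syntactic coupling is
recovered as a before > during contrast; and the two sentence-similarity
channels stay decorrelated. `scripts/acceptance.R` recomputes all of
these from scratch.

## Known limitations

Model-based Wald intervals on pairwise-similarity data are
anticonservative (see above); the dyadic-robust intervals correct the
first-order problem, but the shuffle control remains the package's
empirical benchmark — effect sizes should be judged against the shuffled
distribution, not only against nominal standard errors. The LCS treats cells as unordered symbols, so near-miss fixations in
adjacent cells count as mismatches; the region-based encoding softens
but does not remove this. And the kernel's decay has no privileged
value: conclusions should be checked across a small $\lambda$ grid.
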