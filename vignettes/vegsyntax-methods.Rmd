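---
title: "Learning the syntax of plant assemblages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning the syntax of plant assemblages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

A vegetation plot (relevé) is a list of plant taxa observed at a site with
an estimate of percent cover for each. vegsyntax treats each plot as a
*sentence*: the species, lowercased, listed in descending cover order and
separated by commas. The ordering is not decoration — relative abundance
carries much of a community's identity, and a model that reads the whole
ordered list bidirectionally can pick up statistical dependencies between
species (shared environmental preferences, co-dominance structures,
obligate companions) that pairwise co-occurrence counts cannot represent.

Two tasks are built on this representation:

* **fill-mask** — hide a species (or half of its binomial name) and ask
  the model to recover it from the remaining assemblage. This is the
  self-supervised objective the encoder is trained on, and doubles as a
  tool for suggesting overlooked species in incomplete surveys.
* **habitat classification** — map a whole sentence to a level-3 EUNIS
  habitat code. The EUNIS typology is hierarchical: one letter per broad
  group (`N`, `Q`, `R`, `S`, `T`, `U`, `V`, with the littoral biogenic
  group written `MA2`), one extra alphanumeric character per level. A
  level-3 prediction therefore also yields level-2 (group) and level-1
  (broad) predictions by truncation, and the package reports accuracy at
  all three levels plus top-3 accuracy.

## The encoder

The model is a small bidirectional transformer encoder implemented in
RcppArmadillo (`src/transformer.cpp`): learned token and position
embeddings, post-layer-norm blocks (multi-head self-attention, then a GELU
feed-forward), a masked-token decoder tied to the token embedding, and a
tanh-pooled classification head over the sequence-level `[CLS]` position.
Optimisation is Adam (0.9/0.999) with global gradient-norm clipping at 1.
The backward pass is hand-derived and checked against central finite
differences in the test suite.

Defaults (`lm_config()`): 2 layers, hidden width 128, 4 heads,
feed-forward width `2 * hidden`, dropout 0, batch size 32, learning rate
1e-3 under the standard encoder fine-tuning schedule — linear warmup over
the first 10% of steps, then linear decay to zero (`warmup = NA` gives a
constant rate, appropriate for very short runs where the decay tail would
starve the late epochs). Five epochs is the protocol's training length
for both the fill-mask stage and the classifier stage; the other sizes
are desk-scale choices — the architecture family scales to the
base/large presets by raising `layers`/`hidden`/`heads`, but every
result this package's tests state is computed with small encoders on
synthetic data. Where the tests train motif models, the learning rate
(5e-3) was selected by held-out perplexity on one corpus, mirroring the
protocol's hyperparameter optimisation of learning rate and batch size.

Two tokenizers are available. The *species* scheme maps a whole binomial
to one token, so a mask hides an entire species and the model chooses
among all species. The *term* scheme splits genus and epithet into
separate tokens; a masked epithet is then often recoverable from its genus
alone, which inflates per-token accuracy — for that reason evaluation
always scores the full binomial (both tokens must be right).

### Masking procedure

15% of content tokens are selected per sentence per epoch (commas and the
`[CLS]`/`[SEP]` markers are never selected). A selected token becomes
`[MASK]` 80% of the time, a random content token 10% of the time, and
stays itself 10% of the time. Two details the protocol leaves open were
fixed as follows:

* random replacements are *category matched* under the term scheme (a
  genus slot draws a genus token, an epithet slot an epithet token), so a
  corrupted sentence stays structurally well formed;
* cover-tie permutations and mask selections are redrawn every epoch,
  seeded from `(seed, epoch)`, so repeated epochs see fresh corruptions
  while the whole run stays reproducible.

### Perplexity

`perplexity()` reports `exp(mean cross-entropy)` over masked positions. A
perfect model scores 1; a model that spreads probability uniformly over
the V content tokens scores exactly V — `uniform_lm()` provides that
reference implementation, and the identity is asserted to 1e-3 relative
in the tests.

### Assemblage completion

`complete_assemblage()` appends a `[MASK]` slot after the observed
species and takes the best candidate among species not already listed;
the end-of-list token `[SEP]` competes with the species, and when it wins
the assemblage is considered complete. Already-listed species are excluded
from the argmax (a species cannot be added twice); this exclusion is a
package decision, not part of the original procedure. Completion is
implemented for the species scheme only — under the term scheme an
appended species would need a joint two-token decision, which the
independence approximation used for term-scheme scoring does not support
cleanly.

## Curation chain

`curate()` applies, in fixed order: zero-cover removal → layer merging
(covers summed; sums above 100% are legitimate) → composition snapshot →
name standardisation against a user-supplied synonym table (subspecies
lumped into their parent binomial, genus-level and unmatched names
dropped) → hybrid and rare-species removal → degraded-plot removal →
rare-habitat demotion → labelled/unlabelled split. Boundary semantics are
strict as worded: "fewer than ten" removes a species present in 9 plots
and keeps one in 10; "more than 25%" keeps a plot that lost exactly a
quarter of its taxa.

Decisions on points the protocol does not pin down:

* the rare-species filter is **single-pass**: plot-presence counts are
  frozen before any removal and applied once. Iterating to a fixed point
  removes more (removals can push other species below threshold), but only
  a single count sequence is described; `rare_fixed_point = TRUE` exposes
  the alternative.
* "appeared less than ten times" is read as **plot-level presence**, not
  raw observation rows, since layers are merged beforehand.
* the degraded-plot rule compares **distinct taxon sets**: a snapshot
  taxon is lost only if its standardised form is absent from the plot, so
  two subspecies lumping into one binomial is not a loss. The
  most-abundant taxon is taken by summed cover with a seeded tie-break.
* names that are already accepted binomials pass through standardisation
  unchanged, which makes the chain idempotent on its own output (up to
  the rare-species filter, whose counts can only shrink — both asserted
  in the tests).

## Spatial cross-validation

Plots are binned into 0.1° x 0.1° (6 arcmin) grid cells; every cell is
assigned to exactly one fold, so near-duplicate plots recorded metres
apart can never straddle a train/test boundary. Because plot density is
strongly uneven, folds are balanced by plot count, not by block count:
blocks are sorted by descending count and each goes to the currently
lightest fold (greedy longest-processing-time). The balancing routine of
the original blocking software is not documented, so this deterministic,
dependency-free scheduler is the package's own choice; on the clustered
synthetic data used in the tests it keeps the max/min fold load within
10% at k = 10. A half-ulp guard on the floor division keeps coordinates
that are exact multiples of the cell size in a deterministic cell.

## Baselines

The **naive Bayes** predictor scores every candidate species s for an
observed assemblage O from the plot co-occurrence matrix:

score(s) = log P(s) + Σ_{o ∈ O} log P(o | s),

with P(s) = N_s / Σ_t N_t and P(o | s) = (C[o,s] + α) / (N_s + αV),
α = 1 by default. The matrix records presence–absence only (how many
plots contain both species), covers are ignored. The exact construction
used in the original supplementary material is not reproduced in the main
text; this is the canonical naive Bayes decomposition over a
co-occurrence matrix, validated in the tests against an independent
per-candidate brute-force loop. Scores within 1e-9 are treated as tied
and broken lexicographically so the ranking is stable against float
association noise.

The **masked MLP** baseline is a one-hidden-layer feedforward network on
presence–absence vectors trained by SGD on the log-loss: each epoch every
training plot has one species masked at random, the input is the
indicator of the remaining species, the target is the masked species.
Architecture details beyond "neural network, log-loss, SGD" are not
specified by the protocol, so one ReLU hidden layer (width 64) is the
default and everything is configurable.

Both baselines and the encoder satisfy a common `fill_blank()` contract,
so `rank_masking_eval()` — mask the rank-r species of every plot with
more than ten species, r = 1..10, score top-1 exact matches — runs
unchanged over all three predictors.

## The synthetic community generator

The generator exists so that every claim in this package can be tested
without access to restricted archive data. `make_model()` defines, per
habitat: a species pool with geometric rank-abundance selection weights
(ratio 0.85), a spatial centre with Gaussian scatter (0.4° by default,
so habitats cluster and spatial blocking differs from random splitting),
and a valid level-3 habitat code. A shared generalist pool with Zipf
weights produces the long-tailed species-frequency distribution typical
of large archives. Richness is negative-binomial with mean 20 species
per plot — matching the ~19–22 species per plot of the archives this
pipeline is designed for. Covers decay geometrically with rank and are
snapped to an ordinal-style grid, so tied covers are frequent, exercising
the seeded tie-break. Habitat-pool species carry a boosted abundance
weight (×3), so the top-cover species of a plot tends to be
habitat-diagnostic — consistent with a typology anchored on dominant
species.

`inject_motif()` adds an obligate-companion pattern: species A and C
never occur together without B. The triple defaults to generalists at
frequency ranks 8 (A), 5 (B) and 12 (C) with a ×2 selection boost on A
and C; their ordering weights are set so cover order tends to run
A > B > C. These ranks keep the motif species clearly below the most
frequent generalists, which is precisely what makes the frequency-driven
naive Bayes baseline answer with the commonest species while a trained
encoder ranks B highly for the context "A, [MASK], C".

What the generator does **not** emulate: taxonomic noise (names are
invented, clean binomials), observer effort gradients, regional sampling
bias, vertical layering, and any mechanistic ecology (dispersal,
competition). Passing tests on this generator therefore demonstrate that
the pipeline's machinery behaves as specified under known structure — not
that a small encoder would reach any particular accuracy on real archive
data.

## Problem sizes used by the tests and the acceptance script

All heavier checks train 2-layer, 64-wide, 4-head encoders (feed-forward
128) for 5 epochs — sizes chosen so a full run stays comfortable on a
single CPU core:

* habitat recovery: 4 habitats × 50-species disjoint pools, 20,000
  plots, spatial fold 1 held out. Bayes-optimal accuracy is 1 by
  construction; the fine-tuned encoder is required to exceed 0.95.
* motif recovery: 5,000-plot corpora, 10 seeds (5 in the acceptance
  script's report); the encoder must rank B in its top 3 for
  "A, [MASK], C" in at least 8 of 10 seeds.
* dominant-species ablation: 4 habitats carried by a single dominant
  specialist over a shared 60-generalist matrix, 6,000 plots; removing
  the top-cover species must cost at least five times more accuracy than
  removing the least abundant one.

## Numerical choices

* Layer-norm epsilon 1e-5; embeddings and weights initialised N(0, 0.02²);
  biases and layer-norm offsets zero.
* Sequences longer than `max_len` (128) are truncated from the least
  abundant end, always keeping the terminal `[SEP]`.
* Softmax rows are max-shifted; cross-entropy adds 1e-12 inside the log.
* Training is deterministic given the seed when BLAS runs
  single-threaded; all RNG streams derive from one seed via an FNV-style
  hash of the context (epoch, plot id, purpose tag), so sub-streams are
  independent and stable across platforms.
* The comma separator is rendered ", " and tokenized as a single comma
  token; term-scheme position categories are inferred structurally (first
  content token after `[CLS]` or a comma is a genus, the rest of the
  group are epithets).
* MA2 projections: broad = `MA2` (3 characters), group = 4, type = 5,
  applying "one character per level" to the stated 3-character broad
  code. Plots labelled at level 1 or 2 are rejected at load time; coarser
  accuracies always come from projecting level-3 codes.

## Known limitations

* The obligate-companion probe "A, [MASK], C" is a three-species sentence,
  far shorter than the ~20-species sentences the motif models train on;
  whether a run generalises to that out-of-distribution length varies
  with the corpus and training seed at the 5,000-plot desk scale, so the
  motif recovery rate across seeds is the least stable quantity the test
  suite measures. Larger motif corpora strengthen the association signal
  but fall outside a single-core test budget.

* The encoder is desk-scale; nothing here is sized for archive-scale
  vocabularies (10⁴ species) or corpora (10⁶ plots), although the
  algorithms are the same.
* Term-scheme assemblage completion is unsupported (see above).
* The masked MLP and naive Bayes baselines are faithful to their
  published descriptions only up to the free choices documented here;
  their numeric outputs are validated against in-package oracles, not
  against any external implementation.
* Cover values must arrive as percentages; ordinal scales are the user's
  responsibility to convert before curation.
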