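---
title: "Schema-constrained rewards and strict-match evaluation for drug-repositioning knowledge extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Schema-constrained rewards and strict-match evaluation for drug-repositioning knowledge extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drkex)
```

## The problem

Drug repositioning — finding new indications for existing drugs — leans
heavily on knowledge buried in the literature: which drug treats which
disease, what a drug's molecular targets and side effects are, which
biomarkers and examinations attach to a disease. Large language models
can extract this knowledge as typed triplets, and reinforcement
learning with *verifiable* rewards (rewards computed mechanically from
a gold annotation, not learned) is an effective way to fine-tune them.
drkex implements the desk-scale computational core of such a pipeline:
everything that can be specified, computed, and tested without a GPU or
trained weights.

The package covers five concerns:

1. **Schema.** An 11-entity/18-directed-relation annotation schema with
   validation lints for the annotation principles (no type overlap, no
   nesting, minimal punctuation, one direction per related pair,
   intrasentence priority, relation/type compatibility).
2. **Output parsing.** Chain-of-thought model outputs carry a single
   `<think>` block with nested `<step>` sections followed by a JSON
   payload with two root keys (`Entities`, `Relationships`);
   `check_tag_integrity()`, `extract_reasoning()` and
   `parse_prediction()` decompose such text deterministically.
3. **Dual reward.** `total_reward()` composes an accuracy reward over
   matched entities/triplets/rare items with a structural format reward
   over tag integrity and reasoning length.
4. **GRPO mathematics.** Group-relative advantages, the per-output KL
   estimator, and the clipped-surrogate objective as pure functions.
5. **Evaluation and synthesis.** Strict exact-match P/R/F1, an
   error-taxonomy classifier, a confusion matrix, document-level
   splitting, corpus statistics — plus a synthetic corpus generator
   with controlled error injection that makes every component testable
   end to end.

## The dual-reward model

For a gold annotation $g$ and raw model output $o$, the reward is

$$R = w_{acc} R_{acc} + w_{fmt} R_{fmt}, \qquad
R_{acc} = \alpha S_{entity} + \beta S_{triplet} + \gamma S_{rare}, \qquad
R_{fmt} = \delta S_{tag} + \varepsilon S_{length},$$

with the tuned defaults $\alpha = \beta = 0.45$, $\gamma = 0.1$,
$\delta = 0.7$, $\varepsilon = 0.3$, $w_{acc} = w_{fmt} = 0.5$, under
the constraints $\alpha + \beta + \gamma = 1$,
$\delta + \varepsilon = 1$, $w_{acc} + w_{fmt} = 1$.

Component definitions, and the decisions behind them where the scoring
rules name a behaviour without fixing a number:

- $S_{entity} = (\#exact + c \cdot \#partial) / \max(n_{gold}, n_{pred})$.
  An exact match requires surface and type equality (case-sensitive by
  default: original casing is part of the contract); a partial match
  requires the correct type and token overlap between
  punctuation-stripped surfaces. The partial credit $c$ defaults to 0.5
  — the scoring rules say only that partial overlap earns a partial
  reward. The $\max$ denominator is deliberate: false positives earn no
  score, and a pure-recall normalizer would leave spurious predictions
  free; dividing by the larger of the two counts makes them strictly
  costly while keeping $S_{entity} \in [0,1]$.
- $S_{triplet}$ is analogous with full credit only, on canonical
  quintuples (inverse-direction statements are rewritten by
  `canonicalize_triplets()` before comparison). Dependency errors —
  plausible relation, wrong entity or entity type — earn nothing.
- $S_{rare}$ is the fraction of *rare* gold items (entity mentions
  whose type, and triplets whose canonical relation, fall below a 5%
  reference frequency) recovered exactly. Rarity is judged against a
  fixed reference statistics table rather than the current batch, for
  determinism; the shipped reference mirrors the DrugReC corpus
  counts, under which `side_effect` (2.59%), `gene` (3.88%) and
  `increases_expression_of` (0.39%) are rare.
- **Vacuous categories renormalize.** A document without gold triplets
  (and no invented ones), or without rare gold items, drops that term
  and renormalizes the remaining weights. Otherwise no real document
  without rare content could ever reach $R_{acc} = 1$. If the
  prediction invents triplets against an empty gold set, the triplet
  term stays active at 0, so inventions still cost reward.
- $S_{tag} \in \{0, 1\}$: one think block, at least one step directly
  inside it, balanced counts, correct nesting and closure order —
  missing or redundant tags and closure disorder all zero it.
- $S_{length} \in \{0, 1\}$: think-content length inside
  `length_bounds`, default 200–8000 characters. Length is counted in
  characters of the think interior with tag tokens removed; characters
  were chosen over tokens for tokenizer independence, and the default
  window is a package choice since only "underlength/overlength" is
  specified. Both choices are configurable through
  `reward_weights()`.

A reward exists for *any* raw text: when no payload parses, $R_{acc}$
is 0 but the format components are still scored (this is why lenient
parsing is the reward default, while evaluation defaults to strict).

```{r reward-example}
gold <- generate_gold_corpus(generator_config(n_docs = 1, seed = 7))[[1]]
ideal <- render_model_output(gold, think_length = 500, seed = 1)
tidy(total_reward(gold, ideal))
```

## GRPO objective

For a group of $G \ge 2$ sampled outputs with raw rewards $r_i$,
advantages standardize within the group,
$A_i = (r_i - \mu_{group})/\sigma_{group}$, with the *population*
standard deviation (divide by $G$): the objective writes
$\sigma_{group}$ without a correction term, and the population form
keeps $|A_i|$ exact at $G = 2$ ($A = \pm 1$). A degenerate group
($\sigma \le$ `std_floor`, default $10^{-8}$) yields zero advantages
rather than an error — uniform-reward groups carry no gradient signal.
The objective averages the clipped pessimistic surrogate
$\min(\rho_i A_i, \mathrm{clip}(\rho_i, 1-\epsilon, 1+\epsilon) A_i)$
over the group and subtracts $\beta_{KL}$ times the mean of the
per-output estimator $x - \log x - 1$ (non-negative, zero only at
$x = 1$). Ratios are sequence-level, matching the per-output notation;
token-level aggregation is the caller's concern. `clip_epsilon` and
`kl_beta` are mandatory in `grpo_config()` because the source work does
not report its values; the symbols $\beta$ and $\varepsilon$ collide
between the objective and the reward weights, so the package uses
distinct field names (`kl_beta`, `clip_epsilon` vs `beta_triplet`,
`epsilon_length`).

```{r grpo}
grpo_objective(
  rewards = c(1, 0), ratios = c(1.5, 1.5), ref_ratios = c(1, 1),
  cfg = grpo_config(clip_epsilon = 0.2, kl_beta = 0)
)
```

## Strict evaluation and the error taxonomy

`evaluate_extraction()` uses exact string matching only — a boundary
overlap that earns partial reward credit is a plain error here. Items
are deduplicated per document to unique (surface, type) pairs or
canonical quintuples because the quintuple output dialect carries no
character offsets. The `ALL` row micro-averages by default (pooled
counts, the common practice in biomedical NLP evaluations; whether the
published overall rows are micro or macro cannot be verified from the
printed per-type values, so macro is available via a flag). Rounding to
two decimals happens only at rendering (`format_metrics()`); internal
values keep full precision.

`classify_errors()` applies a fixed priority per item — exact match,
then same surface with wrong type (*incorrect type*), then same type
with overlapping unequal surface (*boundary error*), then unmatched
prediction (*incorrect extraction*) and unmatched gold (*missing
entity*). The taxonomy names the categories but no tie-break order;
fixing this order makes counts conserve: every gold and predicted item
is accounted for exactly once, a property the tests verify. Triplet
errors are *incorrect entity type* (relation and surfaces match, an
endpoint type does not) and *cross-sentence error* (missed gold triplet
whose endpoints anchor in different sentences).

## Annotation validation choices

Several lints required decisions where the annotation principles are
stated qualitatively:

- Character offsets are 0-based half-open and optional; absent spans
  anchor at the first exact occurrence of the surface.
- The punctuation/conjunction principle is a lint
  (`PUNCTUATION_EDGE`), never an auto-rewrite.
- `NESTED_ENTITY` fires on strict containment of anchored spans.
- `BIDIRECTIONAL_PAIR` fires when one unordered entity pair carries
  more than one triplet with the same canonical relation — this covers
  both a forward/inverse duplicate and a literal duplicate.
- Intrasentence priority: a cross-sentence triplet is flagged
  (`CROSS_SENTENCE_WITH_INTRA_ALTERNATIVE`) only when an intrasentence
  triplet with the same canonical relation shares an endpoint with it;
  sharing an endpoint is the operational reading of "a valid
  intrasentence alternative exists" that stays decidable from the
  annotation alone.
- The full compatibility table is part of the schema's supplementary
  definition that is not reproduced in print; the shipped default is an
  informed reconstruction (e.g. `treat`: drug or treatment against
  disease) and is overridable via one YAML config, which rejects
  unknown keys. Inverse relation labels are likewise not printed; the
  registry uses transparent names (`is_treated_by`, `has_target`, ...),
  and every directed label maps to exactly one canonical relation.

## What the synthetic generator emulates — and what it does not

`generate_gold_corpus()` produces template-sentence documents filled
from a packaged gazetteer (realistic names per type, including the
canonical illustrations Metformin, cetuximab, Docetaxel, BRCA2, p53).
Defaults mirror the DrugReC corpus description: entity and relation
mixtures equal to its published shares (disease 19.10%, drug 15.80%,
`is_examination_for` 18.16%, ...), 6–12 entity mentions and 3–7
triplets per document (the corpus averages 9.3 and 4.9 per abstract),
and a 10% cross-sentence fraction. Document-length and mention-density
distributions of the real corpus are unpublished, so these densities
are order-of-magnitude choices, made once. Entity types are drawn
i.i.d. from the mixture, so empirical shares converge on the configured
ones; triplet relations are drawn from the relation mixture restricted
to relations feasible under the drawn entities, so realized relation
shares track the mixture only approximately. Construction guarantees:
every surface occurs verbatim with recorded spans and sentence bounds,
triplets respect the compatibility table, each entity joins at most one
triplet, and `validate_annotation()` returns zero violations for every
generated document.

`perturb_prediction()` injects the six taxonomy errors independently
per item at configured rates and logs every injection; the log is the
ground truth for recovery tests (the suite checks that
`classify_errors()` recovers injected counts *exactly* at rates 0.1,
0.3, 0.5). Type swaps are confined to the confusable table
(biomarker/gene/target mutually, side effect/complication) reflecting
the observed confusion structure; types without a confusable
alternative are never swapped. `render_model_output()` wraps any
annotation in a three-step think block padded to an exact character
length, and can apply a single tag corruption (drop, duplicate, or
transpose one tag token) — any single edit breaks tag integrity, which
the fragility tests exploit.

What passing tests on this corpus do **not** show: robustness to real
abstract prose (linguistic variety, coreference, hedging), to entity
surfaces unseen in a gazetteer, or to annotation disagreement between
human experts. The generator validates the *machinery* — rewards,
parsers, metrics — not extraction difficulty.

## Numerical and degenerate-input conventions

- Precision/recall/F1 use the 0/0 → 0 convention; `f1_score()` is
  scale-invariant (fractions or percentages).
- $S_{entity}$ on a document with no gold and no predicted entities is
  defined as 1 (nothing to get wrong).
- All reward components are clamped to $[0,1]$; the suite checks
  $R \in [0,1]$ over 1000 randomized perturbed pairs and the exact
  fixed point $R = 1$ for ideal renderings.
- `split_corpus()` takes `round(train_fraction * N)` for the training
  size and preserves input order within partitions; all randomness in
  the package flows through explicit seeds (`withr::with_seed`), and
  identical configurations are byte-identical.
- Payload location uses a recency heuristic: the *last* balanced
  top-level JSON object outside the think block with both root keys —
  models often echo few-shot examples before their answer. JSON
  repair is limited to dropping malformed entries in lenient mode.

## Problem sizes used by the test suite

The shipped suite exercises: 1000 randomized reward pairs for
boundedness and the perfect-sample fixed point; 1000 random tag
sequences against an independent grammar oracle plus per-token
single-edit fragility; 200 perturbed documents against a
set-intersection evaluation oracle; recovery of six single-error
profiles at three rates over 60-document corpora; and a 1000-document
corpus for the 80/20 split and mixture-share checks (±2 percentage
points). These sizes keep the default run to a few minutes while
leaving each check statistically unambiguous.

## Limitations

- The compatibility table and inverse-label names are reconstructions;
  deployments with access to the authoritative schema definition should
  override them via the YAML config.
- Exact numeric credits behind the qualitative scoring rules (partial
  credit, length window) are package defaults, tunable but not
  validated against the original training runs.
- Reward normalization is per document; per-batch normalization, if
  the original used it, would shift absolute reward scales (GRPO's
  group standardization removes much of this difference).
- No model deployment, fine-tuning, or retrieval: the package is the
  verifiable-reward and evaluation layer, designed to slot into an
  external RL trainer via `score_corpus()`/`grpo_objective()` or the
  bundled CLI.
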