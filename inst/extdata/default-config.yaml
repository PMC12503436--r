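# Default drkex configuration.
# All sections are optional; omitted settings fall back to package
# defaults. Unknown keys are rejected.

# Dual-reward coefficients. Constraints: alpha + beta_triplet + gamma = 1,
# delta + epsilon_length = 1, w_acc + w_fmt = 1.
weights:
  alpha: 0.45            # entity accuracy weight
  beta_triplet: 0.45     # triplet accuracy weight
  gamma: 0.1             # rare entity/relation weight
  delta: 0.7             # tag-integrity format weight
  epsilon_length: 0.3    # thinking-length format weight
  w_acc: 0.5             # top-level accuracy reward weight
  w_fmt: 0.5             # top-level format reward weight
  partial_credit: 0.5    # credit for partial entity boundary overlap
  length_bounds: [200, 8000]  # admissible think-content length (characters)
  case_sensitive: true

# Relative-frequency cutoff below which an entity type or canonical
# relation counts as rare (captures side_effect 2.59%, gene 3.88%,
# increases_expression_of 0.39% under the DrugReC reference statistics).
rarity_threshold: 0.05

# Admissible (head type, tail type) pairs per canonical relation. This
# default is an informed reconstruction of the schema's compatibility
# constraints and is meant to be overridden where a deployment's schema
# differs.
compatibility:
  treat:
    - [drug, disease]
    - [treatment, disease]
  is_target_of:
    - [target, drug]
  is_side_effect_of:
    - [side_effect, drug]
  is_biomarker_of:
    - [biomarker, disease]
  is_examination_for:
    - [test, disease]
  complication_of:
    - [complication, disease]
  is_symptom_of:
    - [symptom, disease]
  is_located_in:
    - [disease, anatomy]
    - [complication, anatomy]
    - [biomarker, anatomy]
    - [symptom, anatomy]
  increases_expression_of:
    - [drug, gene]
    - [gene, gene]

# Synthetic corpus generator. Mixture defaults mirror the DrugReC
# entity/relation shares; per-document densities are order-of-magnitude
# choices matching that corpus's 9.3 entities and 4.9 triplets per
# abstract (the real corpus's document-length distribution is
# unpublished).
generator:
  n_docs: 100
  entities_per_doc: [6, 12]
  triplets_per_doc: [3, 7]
  sentences_per_doc: [1, 3]
  cross_sentence_fraction: 0.1
  seed: 1
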