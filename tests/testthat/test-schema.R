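test_that("registries expose 11 entity types and 9 canonical / 18 directed relations", {
  expect_length(entity_types(), 11)
  reg <- relation_types()
  expect_equal(nrow(reg), 18)
  expect_length(canonical_relations(), 9)
  expect_false(any(duplicated(reg$label)))
  # every directed label maps to exactly one (canonical, is_inverse) pair
  expect_equal(nrow(dplyr::distinct(reg, label, canonical, is_inverse)), 18)
  expect_equal(sum(reg$is_inverse), 9)
})

test_that("entity type aliases normalize case-insensitively to canonical names", {
  expect_equal(
    normalize_entity_type(c("Drug", "Side Effect", "anatomical structure",
                            "Clinical Examination", "GENE")),
    c("drug", "side_effect", "anatomy", "test", "gene")
  )
  expect_error(normalize_entity_type("protein"), "Unknown entity type")
  expect_true(is.na(normalize_entity_type("protein", strict = FALSE)))
})

test_that("canonicalize_triplets swaps inverse directions and is idempotent", {
  t_inv <- tibble::tibble(
    head = "colorectal cancer", head_type = "disease",
    relation = "is_treated_by", tail = "cetuximab", tail_type = "drug"
  )
  got <- canonicalize_triplets(t_inv)
  expect_equal(got$relation, "treat")
  expect_equal(got$head, "cetuximab")
  expect_equal(got$tail, "colorectal cancer")

  # already canonical: unchanged (side-effect example stays put)
  t_can <- tibble::tibble(
    head = "infusion reactions", head_type = "side_effect",
    relation = "is_side_effect_of", tail = "cetuximab", tail_type = "drug"
  )
  expect_equal(canonicalize_triplets(t_can), t_can)

  # idempotence over randomized triplets across all 18 labels
  reg <- relation_types()
  gaz <- ke_gazetteer()
  set.seed(11)
  for (k in 1:50) {
    lab <- sample(reg$label, 1)
    tt <- tibble::tibble(
      head = sample(gaz$drug, 1), head_type = "drug", relation = lab,
      tail = sample(gaz$disease, 1), tail_type = "disease"
    )
    once <- canonicalize_triplets(tt)
    expect_identical(canonicalize_triplets(once), once)
    expect_false(any(relation_types()$is_inverse[
      match(once$relation, relation_types()$label)
    ]))
  }
  expect_error(
    canonicalize_triplets(tibble::tibble(
      head = "a", head_type = "drug", relation = "discontinued_due_to",
      tail = "b", tail_type = "disease"
    )),
    "Unregistered"
  )
})

test_that("is_rare compares reference frequency against the threshold", {
  expect_true(is_rare("increases_expression_of", threshold = 0.05))
  expect_false(is_rare("disease", threshold = 0.05))
  expect_true(is_rare("gene", threshold = 0.05))
  expect_true(is_rare("side_effect", threshold = 0.05))
  # uniform stats over 11 types: every type below a near-1 threshold
  uni <- stats_table(
    stats::setNames(rep(1, 11), entity_types()),
    stats::setNames(rep(1, 9), canonical_relations())
  )
  expect_true(all(is_rare(entity_types(), uni, threshold = 1 - 1e-12)))
  expect_error(is_rare("protein"), "Unknown type")
})

test_that("validate_annotation flags type-overlap, bidirectional pairs, and schema incompatibility", {
  # one surface annotated as two types -> exactly one OVERLAP_TYPE_CONFLICT
  doc <- document_annotation(
    "d", "MDM2 overexpression inhibits p53 activity.",
    entities = tibble::tibble(
      surface = c("p53", "p53"), type = c("gene", "target")
    )
  )
  v <- validate_annotation(doc)
  expect_equal(sum(v$code == "OVERLAP_TYPE_CONFLICT"), 1)

  # both directions of one relation between one pair -> one BIDIRECTIONAL_PAIR
  doc2 <- document_annotation(
    "d", "cetuximab is used to treat colorectal cancer.",
    entities = tibble::tibble(
      surface = c("cetuximab", "colorectal cancer"),
      type = c("drug", "disease")
    ),
    triplets = tibble::tibble(
      head = c("cetuximab", "colorectal cancer"),
      head_type = c("drug", "disease"),
      relation = c("treat", "is_treated_by"),
      tail = c("colorectal cancer", "cetuximab"),
      tail_type = c("disease", "drug")
    )
  )
  v2 <- validate_annotation(doc2)
  expect_equal(sum(v2$code == "BIDIRECTIONAL_PAIR"), 1)
  # brute-force pair scan: exactly one unordered pair carries 2 triplets
  ct <- canonicalize_triplets(doc2$triplets)
  keys <- apply(ct, 1, function(r) {
    paste(sort(c(paste(r[["head"]], r[["head_type"]]),
                 paste(r[["tail"]], r[["tail_type"]]))), r[["relation"]],
          collapse = "|")
  })
  expect_equal(sum(table(keys) > 1), 1)

  # schema-incompatible relation (examination between drug and side effect)
  doc3 <- document_annotation(
    "d", "colonoscopy after Metformin exposure.",
    entities = tibble::tibble(
      surface = c("colonoscopy", "Metformin"), type = c("test", "drug")
    ),
    triplets = tibble::tibble(
      head = "colonoscopy", head_type = "test",
      relation = "is_examination_for", tail = "Metformin", tail_type = "drug"
    )
  )
  expect_equal(sum(validate_annotation(doc3)$code == "INCOMPATIBLE_RELATION"), 1)
})

test_that("validate_annotation flags nesting, punctuation edges, unanchored surfaces and cross-sentence alternatives", {
  doc <- document_annotation(
    "d", "The expression of BRCA2 mutations was analyzed, and nausea persisted.",
    entities = tibble::tibble(
      surface = c("BRCA2", "BRCA2 mutations", "and nausea", "absent entity"),
      type = c("gene", "gene", "symptom", "drug")
    )
  )
  v <- validate_annotation(doc)
  expect_equal(sum(v$code == "NESTED_ENTITY"), 1)
  expect_equal(sum(v$code == "PUNCTUATION_EDGE"), 1)
  expect_equal(sum(v$code == "UNANCHORED_SURFACE"), 1)

  # cross-sentence triplet with an intrasentence alternative of the same
  # relation sharing an endpoint
  doc2 <- document_annotation(
    "d",
    paste(
      "Metformin is used to treat type 2 diabetes.",
      "Patients also received cetuximab. This was linked to colorectal cancer."
    ),
    entities = tibble::tibble(
      surface = c("Metformin", "type 2 diabetes", "cetuximab", "colorectal cancer"),
      type = c("drug", "disease", "drug", "disease")
    ),
    triplets = tibble::tibble(
      head = c("Metformin", "Metformin"),
      head_type = "drug", relation = "treat",
      tail = c("type 2 diabetes", "colorectal cancer"),
      tail_type = "disease"
    )
  )
  v2 <- validate_annotation(doc2)
  expect_equal(sum(v2$code == "CROSS_SENTENCE_WITH_INTRA_ALTERNATIVE"), 1)
})

test_that("a schema-conformant annotation yields zero violations", {
  expect_equal(nrow(validate_annotation(tiny_doc())), 0)
})

test_that("structural errors are caught before validation", {
  expect_error(
    document_annotation("d", "text", entities = tibble::tibble(
      surface = "  ", type = "drug"
    )),
    "empty"
  )
  expect_error(
    document_annotation(
      "d", "cetuximab here",
      entities = tibble::tibble(surface = "cetuximab", type = "drug",
                                start = 0L, end = 4L)
    ),
    "span"
  )
  expect_error(
    document_annotation(
      "d", "a treats b",
      triplets = tibble::tibble(
        head = "a", head_type = "drug", relation = "treat",
        tail = "b", tail_type = "disease"
      )
    ),
    "endpoint"
  )
})
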