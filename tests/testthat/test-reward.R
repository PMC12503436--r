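mk_doc <- function(entities, triplets = empty_triplets(), doc_id = "d",
                   text = NULL) {
  if (is.null(text)) {
    text <- paste0(paste(entities$surface, collapse = " and "), ".")
  }
  document_annotation(doc_id, text, entities = entities, triplets = triplets,
                      check = FALSE)
}

test_that("entity matching separates exact, partial, FP and FN", {
  gold <- mk_doc(tibble::tibble(surface = "BRCA2", type = "gene"))
  pred <- mk_doc(tibble::tibble(surface = "BRCA2 mutations", type = "gene"))
  em <- match_entities(gold, pred)
  expect_equal(nrow(em$exact), 0)
  expect_equal(nrow(em$partial), 1)
  expect_equal(nrow(em$false_positives), 0)
  expect_equal(nrow(em$false_negatives), 0)

  # identity
  d <- tiny_doc()
  em2 <- match_entities(d, d)
  expect_equal(nrow(em2$exact), 2)
  expect_equal(nrow(em2$partial) + nrow(em2$false_positives) +
                 nrow(em2$false_negatives), 0)

  # spurious phrase and omission
  gold3 <- mk_doc(tibble::tibble(
    surface = c("Metformin", "Diabetes"), type = c("drug", "disease")
  ))
  pred3 <- mk_doc(tibble::tibble(
    surface = c("Metformin", "severe side effects"),
    type = c("drug", "side_effect")
  ))
  em3 <- match_entities(gold3, pred3)
  expect_equal(nrow(em3$exact), 1)
  expect_equal(nrow(em3$false_positives), 1)
  expect_equal(nrow(em3$false_negatives), 1)
  # brute force: no assignment with more exact matches exists
  n_exact_possible <- sum(outer(
    paste(gold3$entities$surface, gold3$entities$type),
    paste(pred3$entities$surface, pred3$entities$type), "=="
  ))
  expect_equal(nrow(em3$exact), n_exact_possible)

  # surface comparison is case-sensitive by default, optional otherwise
  goldc <- mk_doc(tibble::tibble(surface = "Metformin", type = "drug"))
  predc <- mk_doc(tibble::tibble(surface = "metformin", type = "drug"))
  expect_equal(nrow(match_entities(goldc, predc)$exact), 0)
  expect_equal(nrow(match_entities(goldc, predc, case_sensitive = FALSE)$exact), 1)

  expect_error(match_entities(tiny_doc("a"), tiny_doc("b")), "different documents")
})

test_that("triplet matching intersects canonical quintuples and spots dependency errors", {
  d <- tiny_doc()
  tm <- match_triplets(d, d)
  expect_equal(nrow(tm$correct), 1)
  expect_equal(nrow(tm$missed) + nrow(tm$spurious) + nrow(tm$dependency_errors), 0)

  # inverse-direction statement of the same fact still matches
  pred_inv <- mk_doc(
    d$entities,
    tibble::tibble(
      head = "colorectal cancer", head_type = "disease",
      relation = "is_treated_by", tail = "cetuximab", tail_type = "drug"
    ),
    doc_id = d$doc_id, text = d$text
  )
  expect_equal(nrow(match_triplets(d, pred_inv)$correct), 1)

  # wrong endpoint type with matching relation+surfaces: dependency error
  pred_dep <- mk_doc(
    d$entities,
    tibble::tibble(
      head = "cetuximab", head_type = "drug", relation = "treat",
      tail = "colorectal cancer", tail_type = "complication"
    ),
    doc_id = d$doc_id, text = d$text
  )
  tm2 <- match_triplets(d, pred_dep)
  expect_equal(nrow(tm2$correct), 0)
  expect_equal(nrow(tm2$dependency_errors), 1)
  expect_equal(nrow(tm2$missed), 1)

  # unrelated invented triplet is spurious
  gold_null <- mk_doc(
    tibble::tibble(surface = c("Docetaxel", "gemcitabine"), type = "drug"),
    doc_id = "t", text = "Docetaxel and gemcitabine might result in fewer adverse events."
  )
  pred_spur <- mk_doc(
    tibble::tibble(
      surface = c("adverse events", "Docetaxel"), type = c("side_effect", "drug")
    ),
    tibble::tibble(
      head = "adverse events", head_type = "side_effect",
      relation = "is_side_effect_of", tail = "Docetaxel", tail_type = "drug"
    ),
    doc_id = "t", text = gold_null$text
  )
  tm3 <- match_triplets(gold_null, pred_spur)
  expect_equal(nrow(tm3$correct), 0)
  expect_equal(nrow(tm3$spurious) + nrow(tm3$dependency_errors), 1)
})

test_that("accuracy reward follows the weighted composition with renormalization", {
  w <- reward_weights()
  # perfect prediction, no rare items: renormalized to 1
  d <- tiny_doc()
  em <- match_entities(d, d); tm <- match_triplets(d, d)
  acc <- accuracy_reward(em, tm, list(n_rare = 0L, s_rare = NA_real_), w)
  expect_equal(acc$r_acc, 1)

  # both entities exact, triplet wrong: 0.45 / 0.9 = 0.5
  pred <- mk_doc(
    d$entities,
    tibble::tibble(
      head = "cetuximab", head_type = "drug", relation = "is_symptom_of",
      tail = "colorectal cancer", tail_type = "disease"
    ),
    doc_id = d$doc_id, text = d$text
  )
  acc2 <- accuracy_reward(
    match_entities(d, pred), match_triplets(d, pred),
    list(n_rare = 0L, s_rare = NA_real_), w
  )
  expect_equal(acc2$s_entity, 1)
  expect_equal(acc2$s_triplet, 0)
  expect_equal(acc2$r_acc, 0.5)

  # rare gene recovered only partially: (0.45 * 0.5) / 0.55
  gold_r <- mk_doc(tibble::tibble(surface = "BRCA2", type = "gene"),
                   doc_id = "r", text = "BRCA2 mutations were analyzed.")
  pred_r <- mk_doc(tibble::tibble(surface = "BRCA2 mutations", type = "gene"),
                   doc_id = "r", text = gold_r$text)
  em_r <- match_entities(gold_r, pred_r)
  tm_r <- match_triplets(gold_r, pred_r)
  acc3 <- accuracy_reward(em_r, tm_r, list(n_rare = 1L, s_rare = 0), w)
  expect_equal(acc3$s_entity, 0.5)
  expect_true(is.na(acc3$s_triplet))
  expect_equal(acc3$r_acc, 0.45 * 0.5 / 0.55, tolerance = 1e-12)
})

test_that("format reward weighs tag integrity and think length", {
  w <- reward_weights()
  ok_report <- check_tag_integrity("<think><step>a</step></think>")
  in_range <- structure(list(steps = "a", total_length = 500L),
                        class = "reasoning_trace")
  expect_equal(format_reward(ok_report, in_range, w)$r_fmt, 1)

  disorder <- check_tag_integrity("</think><step>a</step><think>")
  expect_equal(format_reward(disorder, in_range, w)$r_fmt, 0.3)

  empty_trace <- structure(list(steps = character(), total_length = 0L),
                           class = "reasoning_trace")
  expect_equal(format_reward(ok_report, empty_trace, w)$r_fmt, 0.7)
})

test_that("total reward composes the full pipeline", {
  d <- tiny_doc()
  # ideal rendering of gold scores exactly 1
  raw <- render_model_output(d, think_length = 400, seed = 1)
  expect_identical(total_reward(d, raw)$r_total, 1)

  # empty string: nothing to credit
  expect_equal(total_reward(d, "")$r_total, 0)

  # perfect JSON without any think block: r_acc = 1, r_fmt = 0
  b <- total_reward(d, serialize_annotation(d))
  expect_equal(b$r_acc, 1)
  expect_equal(b$r_fmt, 0)
  expect_equal(b$r_total, 0.5)
})

test_that("rewards are bounded, monotone in errors, and attain the perfect fixed point", {
  w <- reward_weights()
  corpus <- generate_gold_corpus(generator_config(n_docs = 60, seed = 31))
  set.seed(31)
  for (i in seq_along(corpus)) {
    prof <- error_profile(
      entity_omission = runif(1, 0, 0.6),
      entity_spurious = runif(1, 0, 0.6),
      entity_type_swap = runif(1, 0, 0.6),
      entity_boundary_shift = runif(1, 0, 0.6),
      triplet_entity_type_error = runif(1, 0, 0.6),
      cross_sentence_drop = runif(1, 0, 0.6)
    )
    pp <- perturb_prediction(corpus[[i]], prof, seed = 1000 + i)
    raw <- render_model_output(
      pp$pred, tag_ok = i %% 3 != 0,
      think_length = if (i %% 4 == 0) 0L else 500L, seed = i
    )
    r <- total_reward(corpus[[i]], raw, w)$r_total
    expect_gte(r, 0); expect_lte(r, 1)
  }

  # demoting an exact match to a partial strictly lowers s_entity by
  # (1 - partial_credit) / max-count, and a spurious entity never raises it
  gold <- tiny_doc()
  exact_pred <- mk_doc(gold$entities, doc_id = gold$doc_id, text = gold$text)
  partial_ents <- gold$entities
  partial_ents$surface[1] <- "cetuximab infusion"
  partial_pred <- mk_doc(partial_ents, doc_id = gold$doc_id, text = gold$text)
  s_exact <- accuracy_reward(match_entities(gold, exact_pred),
                             match_triplets(gold, exact_pred), w = w)$s_entity
  s_partial <- accuracy_reward(match_entities(gold, partial_pred),
                               match_triplets(gold, partial_pred), w = w)$s_entity
  expect_equal(s_exact - s_partial, (1 - w$partial_credit) / 2)

  spur_pred <- mk_doc(
    dplyr::bind_rows(gold$entities,
                     tibble::tibble(surface = "clinical practice", type = "treatment",
                                    start = NA_integer_, end = NA_integer_)),
    doc_id = gold$doc_id, text = gold$text
  )
  s_spur <- accuracy_reward(match_entities(gold, spur_pred),
                            match_triplets(gold, spur_pred), w = w)$s_entity
  expect_lt(s_spur, s_exact)
})

test_that("mean reward decreases in each injected error rate", {
  base_cfg <- function(seed) generator_config(n_docs = 40, seed = seed,
                                              cross_sentence_fraction = 0.3)
  corpus <- generate_gold_corpus(base_cfg(77))
  mean_reward <- function(profile, tag_rate = 0, len_rate = 0) {
    rs <- vapply(seq_along(corpus), function(i) {
      pp <- perturb_prediction(corpus[[i]], profile, seed = 500 + i)
      corrupt <- (i %% 100) / 100 < tag_rate
      len <- if ((i %% 10) / 10 < len_rate) 0L else 500L
      raw <- render_model_output(pp$pred, tag_ok = !corrupt,
                                 think_length = len, seed = i)
      total_reward(corpus[[i]], raw)$r_total
    }, numeric(1))
    mean(rs)
  }
  rates <- c(0.1, 0.3, 0.5)
  for (knob in c("entity_omission", "entity_type_swap", "entity_boundary_shift")) {
    ms <- vapply(rates, function(r) {
      args <- stats::setNames(list(r), knob)
      mean_reward(do.call(error_profile, args))
    }, numeric(1))
    expect_true(all(diff(ms) < 0), info = knob)
  }
  # tag corruption rate
  ms_tag <- vapply(rates, function(r) mean_reward(error_profile(), tag_rate = r),
                   numeric(1))
  expect_true(all(diff(ms_tag) < 0))
})
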