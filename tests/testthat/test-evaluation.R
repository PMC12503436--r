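test_that("precision/recall/F1 follow the harmonic-mean definitions", {
  expect_equal(compute_prf(3, 1, 2),
               tibble::tibble(precision = 0.75, recall = 0.6, f1 = 2/3),
               tolerance = 1e-12)
  expect_equal(compute_prf(0, 0, 0),
               tibble::tibble(precision = 0, recall = 0, f1 = 0))
  # scale-invariance of the harmonic mean (percentages in, percentages out)
  expect_equal(f1_score(0.8337, 0.7964) * 100, f1_score(83.37, 79.64),
               tolerance = 1e-9)
  expect_equal(f1_score(0, 0), 0)
})

test_that("strict evaluation counts only exact matches and pools micro counts", {
  gold <- list(
    document_annotation("a", "BRCA2 mutations were analyzed.",
      entities = tibble::tibble(surface = "BRCA2", type = "gene"))
  )
  pred <- list(
    document_annotation("a", "BRCA2 mutations were analyzed.",
      entities = tibble::tibble(surface = "BRCA2 mutations", type = "gene"),
      check = FALSE)
  )
  m <- evaluate_extraction(gold, pred, "entity")
  gene_row <- m[m$type == "gene", ]
  expect_equal(gene_row$tp, 0)
  expect_equal(gene_row$fp, 1)
  expect_equal(gene_row$fn, 1)
  expect_equal(gene_row$f1, 0)

  # identical corpora: perfect scores
  corpus <- generate_gold_corpus(generator_config(n_docs = 10, seed = 3))
  perfect <- evaluate_extraction(corpus, corpus, "entity")
  expect_equal(perfect[perfect$type == "ALL", ]$f1, 1)
  perfect_t <- evaluate_extraction(corpus, corpus, "triplet")
  expect_equal(perfect_t[perfect_t$type == "ALL", ]$f1, 1)

  # pooled counts: tp 3, fp 1, fn 2 over two documents -> micro P 0.75
  g2 <- list(
    document_annotation("x", "Metformin and cetuximab and Docetaxel and nausea.",
      entities = tibble::tibble(
        surface = c("Metformin", "cetuximab", "Docetaxel", "nausea"),
        type = c("drug", "drug", "drug", "symptom"))),
    document_annotation("y", "fatigue was reported.",
      entities = tibble::tibble(surface = "fatigue", type = "symptom"))
  )
  p2 <- list(
    document_annotation("x", g2[[1]]$text,
      entities = tibble::tibble(
        surface = c("Metformin", "cetuximab", "Docetaxel", "alopecia"),
        type = c("drug", "drug", "drug", "side_effect")),
      check = FALSE),
    document_annotation("y", g2[[2]]$text, check = FALSE)
  )
  m2 <- evaluate_extraction(g2, p2, "entity")
  all_row <- m2[m2$type == "ALL", ]
  expect_equal(all_row$tp, 3)
  expect_equal(all_row$fp, 1)
  expect_equal(all_row$fn, 2)
  expect_equal(all_row$precision, 0.75)
  expect_error(evaluate_extraction(c(g2, g2[1]), p2), "duplicate doc_id")
})

test_that("evaluation agrees with a set-intersection oracle on random corpora", {
  corpus <- generate_gold_corpus(
    generator_config(n_docs = 200, seed = 202, cross_sentence_fraction = 0.2)
  )
  set.seed(202)
  micro_ok <- 0
  for (i in seq_along(corpus)) {
    prof <- error_profile(
      entity_omission = runif(1, 0, 0.5),
      entity_spurious = runif(1, 0, 0.5),
      entity_type_swap = runif(1, 0, 0.5),
      entity_boundary_shift = runif(1, 0, 0.5),
      triplet_entity_type_error = runif(1, 0, 0.5)
    )
    pp <- perturb_prediction(corpus[[i]], prof, seed = 9000 + i)
    for (level in c("entity", "triplet")) {
      keyer <- if (level == "entity") oracle_entity_keys else oracle_triplet_keys
      want <- oracle_prf(keyer(corpus[[i]]), keyer(pp$pred))
      m <- evaluate_extraction(list(corpus[[i]]), list(pp$pred), level)
      got <- m[m$type == "ALL", ]
      expect_equal(got$tp, unname(want["tp"]), info = paste(i, level))
      expect_equal(got$precision, unname(want["precision"]), tolerance = 1e-12)
      expect_equal(got$recall, unname(want["recall"]), tolerance = 1e-12)
      expect_equal(got$f1, unname(want["f1"]), tolerance = 1e-12)
      # micro overall F1 is the harmonic mean of micro overall P and R
      expect_equal(got$f1, f1_score(got$precision, got$recall), tolerance = 1e-12)
    }
    micro_ok <- micro_ok + 1
  }
  expect_equal(micro_ok, 200)
})

test_that("macro averaging averages per-type metrics over supported types", {
  corpus <- generate_gold_corpus(generator_config(n_docs = 15, seed = 5))
  preds <- lapply(corpus, function(d) {
    perturb_prediction(d, error_profile(entity_omission = 0.3), seed = 77)$pred
  })
  m <- evaluate_extraction(corpus, preds, "entity", average = "macro")
  per <- m[m$type != "ALL", ]
  sup <- per$tp + per$fp + per$fn > 0
  expect_equal(m[m$type == "ALL", ]$f1, mean(per$f1[sup]), tolerance = 1e-12)
})

test_that("confusion matrix separates diagonal exact matches from surface-equal type confusions", {
  gold <- list(document_annotation(
    "c", "MDM2 and MDMX inhibit p53 activity and EGFR signalling.",
    entities = tibble::tibble(surface = c("p53", "EGFR"), type = c("gene", "target"))
  ))
  pred <- list(document_annotation(
    "c", gold[[1]]$text,
    entities = tibble::tibble(surface = c("p53", "EGFR"), type = c("target", "target")),
    check = FALSE
  ))
  cm <- as.matrix(entity_confusion(gold, pred))
  expect_equal(cm["gene", "target"], 1)
  expect_equal(cm["target", "target"], 1)
  expect_equal(sum(cm), 2)

  # identical corpora: purely diagonal
  corpus <- generate_gold_corpus(generator_config(n_docs = 10, seed = 9))
  cmd <- as.matrix(entity_confusion(corpus, corpus))
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  expect_equal(sum(diag(cmd)),
               sum(vapply(corpus, function(d) {
                 nrow(dplyr::distinct(d$entities, surface, type))
               }, numeric(1))))

  # type swaps confined to the confusable block show up only there
  swapped <- lapply(corpus, function(d) {
    perturb_prediction(d, error_profile(entity_type_swap = 1), seed = 4)$pred
  })
  cms <- as.matrix(entity_confusion(corpus, swapped))
  block <- c("biomarker", "gene", "target")
  off <- cms; diag(off) <- 0
  confusable_rows <- c(block, "side_effect", "complication")
  expect_equal(sum(off[setdiff(rownames(off), confusable_rows), ]), 0)
  expect_equal(sum(off[block, setdiff(colnames(off), block)]), 0)
})

test_that("error taxonomy classification matches its canonical examples and conserves items", {
  # spurious phrase: gold NULL, pred [severe side effects]
  gold <- document_annotation("e1", "Available therapies are effective, associated with severe side effects.")
  pred <- document_annotation("e1", gold$text,
    entities = tibble::tibble(surface = "severe side effects", type = "side_effect"),
    check = FALSE)
  ec <- classify_errors(gold, pred)
  expect_equal(ec$n[ec$error == "incorrect_extraction"], 1)

  # missing entity
  gold2 <- document_annotation("e2", "Other lung findings were atelectasis or extensive hemorrhage.",
    entities = tibble::tibble(surface = "extensive hemorrhage", type = "complication"))
  pred2 <- document_annotation("e2", gold2$text, check = FALSE)
  ec2 <- classify_errors(gold2, pred2)
  expect_equal(ec2$n[ec2$error == "missing_entity"], 1)

  # cross-sentence miss of a symptom relation
  text3 <- paste(
    "62% of subjects exhibited recurrent gastrointestinal distress and nausea.",
    "Serological testing confirmed antibodies, a hallmark of celiac disease."
  )
  gold3 <- document_annotation("e3", text3,
    entities = tibble::tibble(
      surface = c("nausea", "celiac disease"), type = c("symptom", "disease")),
    triplets = tibble::tibble(
      head = "nausea", head_type = "symptom", relation = "is_symptom_of",
      tail = "celiac disease", tail_type = "disease"))
  pred3 <- document_annotation("e3", text3, entities = gold3$entities, check = FALSE)
  ec3 <- classify_errors(gold3, pred3)
  expect_equal(ec3$n[ec3$error == "cross_sentence_error"], 1)

  # conservation over randomized perturbed pairs:
  # n_gold + n_pred = 2*(exact + type + boundary) + spurious + missing
  corpus <- generate_gold_corpus(generator_config(n_docs = 30, seed = 17))
  set.seed(17)
  for (d in corpus) {
    prof <- error_profile(
      entity_omission = runif(1, 0, 0.5), entity_spurious = runif(1, 0, 0.5),
      entity_type_swap = runif(1, 0, 0.5), entity_boundary_shift = runif(1, 0, 0.5)
    )
    pp <- perturb_prediction(d, prof, seed = 31 + nrow(d$entities))
    ec <- classify_errors(d, pp$pred)
    n <- function(e) ec$n[ec$error == e]
    n_gold <- nrow(dplyr::distinct(d$entities, surface, type))
    n_pred <- nrow(dplyr::distinct(pp$pred$entities, surface, type))
    expect_equal(
      n_gold + n_pred,
      2 * (n("exact_match") + n("incorrect_type") + n("boundary_error")) +
        n("incorrect_extraction") + n("missing_entity")
    )
  }
})

test_that("document-level splitting is deterministic, exhaustive and disjoint", {
  corpus <- generate_gold_corpus(generator_config(n_docs = 10, seed = 1))
  ids <- function(x) vapply(x, function(d) d$doc_id, character(1))
  sp <- split_corpus(corpus, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(corpus))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  # deterministic given seed; membership varies across seeds
  sp2 <- split_corpus(corpus, 0.8, seed = 4)
  expect_identical(ids(sp$train), ids(sp2$train))
  memberships <- vapply(1:100, function(s) {
    paste(ids(split_corpus(corpus, 0.8, seed = s)$train), collapse = ",")
  }, character(1))
  expect_gt(length(unique(memberships)), 1)
  # edge fractions
  expect_length(split_corpus(corpus, 1, seed = 1)$test, 0)
  expect_length(split_corpus(corpus, 0, seed = 1)$train, 0)
  # order within partitions preserved from input
  expect_identical(ids(sp$train), ids(corpus)[ids(corpus) %in% ids(sp$train)])
})

test_that("corpus statistics count mentions and canonical relations with unit-sum frequencies", {
  st <- corpus_statistics(list(tiny_doc("a"), tiny_doc("b")))
  expect_equal(st$count[st$kind == "entity" & st$type == "drug"], 2)
  expect_equal(st$count[st$kind == "relation" & st$type == "treat"], 2)
  expect_equal(sum(st$freq[st$kind == "entity"]), 1, tolerance = 1e-9)
  expect_equal(sum(st$freq[st$kind == "relation"]), 1, tolerance = 1e-9)

  empty <- corpus_statistics(list())
  expect_true(all(empty$count == 0))
  expect_true(all(empty$freq == 0))

  corpus <- generate_gold_corpus(generator_config(n_docs = 50, seed = 8))
  st2 <- corpus_statistics(corpus)
  expect_equal(sum(st2$count[st2$kind == "entity"]),
               sum(vapply(corpus, function(d) nrow(d$entities), numeric(1))))
  expect_equal(sum(st2$freq[st2$kind == "entity"]), 1, tolerance = 1e-9)
  expect_equal(sum(st2$freq[st2$kind == "relation"]), 1, tolerance = 1e-9)
})
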