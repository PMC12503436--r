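#' Precision, recall and F1 from counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F1 = 2PR / (P + R)`,
#' with the 0/0 convention that an undefined ratio is 0. Vectorized.
#' Values are fractions; rounding to two decimals happens only at
#' report rendering.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @export
#' @examples
#' compute_prf(3, 1, 2)
compute_prf <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tibble::tibble(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Harmonic mean of precision and recall
#'
#' Scale-invariant: works identically on fractions and percentages.
#'
#' @param precision,recall Numeric vectors on a common scale.
#' @return `2PR / (P + R)`, 0 where `P + R = 0`.
#' @export
#' @examples
#' f1_score(83.37, 79.64)
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
    2 * precision * recall / (precision + recall), 0
  )
}

.align_corpora <- function(gold_corpus, pred_corpus) {
  gid <- vapply(gold_corpus, function(d) d$doc_id, character(1))
  pid <- vapply(pred_corpus, function(d) d$doc_id, character(1))
  if (anyDuplicated(gid)) stop("duplicate doc_id in gold corpus", call. = FALSE)
  if (anyDuplicated(pid)) stop("duplicate doc_id in predicted corpus", call. = FALSE)
  purrr::map(gid, function(id) {
    j <- match(id, pid)
    list(
      gold = gold_corpus[[match(id, gid)]],
      pred = if (is.na(j)) NULL else pred_corpus[[j]]
    )
  })
}

.unique_entity_keys <- function(doc) {
  if (is.null(doc) || nrow(doc$entities) == 0) {
    return(tibble::tibble(type = character(), key = character()))
  }
  doc$entities |>
    dplyr::distinct(.data$surface, .data$type) |>
    dplyr::transmute(
      type = .data$type,
      key = paste(.data$surface, .data$type, sep = "\r")
    )
}

.unique_triplet_keys <- function(doc) {
  if (is.null(doc) || nrow(doc$triplets) == 0) {
    return(tibble::tibble(type = character(), key = character()))
  }
  ct <- canonicalize_triplets(doc$triplets)
  tibble::tibble(type = ct$relation, key = .quint_key(ct)) |>
    dplyr::distinct()
}

#' Strict-match extraction metrics
#'
#' Exact string matching: a predicted item counts as a true positive
#' only when it equals a gold item completely — surface and type for
#' entities; relation and both typed endpoints (after canonicalization)
#' for triplets. Partial boundary overlaps are errors here, unlike in
#' the reward. Items are deduplicated per document to unique (surface,
#' type) pairs or canonical quintuples, because the quintuple output
#' dialect carries no offsets.
#'
#' @param gold_corpus,pred_corpus Lists of [document_annotation()]
#'   objects; corpora are aligned by `doc_id` and missing predictions
#'   are treated as empty.
#' @param level `"entity"` or `"triplet"`.
#' @param average `"micro"` (pool counts; the default, matching common
#'   BioNLP practice) or `"macro"` (average per-type metrics over types
#'   with support) for the `ALL` row.
#' @return A `ke_metrics` tibble: one row per type plus an `ALL` row,
#'   with columns `type`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (fractions).
#' @export
evaluate_extraction <- function(gold_corpus, pred_corpus,
                                level = c("entity", "triplet"),
                                average = c("micro", "macro")) {
  level <- match.arg(level)
  average <- match.arg(average)
  pairs <- .align_corpora(gold_corpus, pred_corpus)
  keyer <- if (level == "entity") .unique_entity_keys else .unique_triplet_keys
  all_types <- if (level == "entity") entity_types() else canonical_relations()
  counts <- stats::setNames(
    data.frame(tp = numeric(length(all_types)), fp = 0, fn = 0,
               row.names = all_types),
    c("tp", "fp", "fn")
  )
  for (pr in pairs) {
    g <- keyer(pr$gold); p <- keyer(pr$pred)
    for (ty in all_types) {
      gk <- g$key[g$type == ty]; pk <- p$key[p$type == ty]
      counts[ty, "tp"] <- counts[ty, "tp"] + sum(pk %in% gk)
      counts[ty, "fp"] <- counts[ty, "fp"] + sum(!pk %in% gk)
      counts[ty, "fn"] <- counts[ty, "fn"] + sum(!gk %in% pk)
    }
  }
  per_type <- tibble::tibble(
    type = all_types, tp = counts$tp, fp = counts$fp, fn = counts$fn
  ) |>
    dplyr::bind_cols(compute_prf(counts$tp, counts$fp, counts$fn))
  overall <- if (average == "micro") {
    tibble::tibble(
      type = "ALL", tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn)
    ) |>
      dplyr::bind_cols(compute_prf(sum(counts$tp), sum(counts$fp), sum(counts$fn)))
  } else {
    sup <- per_type$tp + per_type$fp + per_type$fn > 0
    tibble::tibble(
      type = "ALL", tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn),
      precision = mean(per_type$precision[sup]),
      recall = mean(per_type$recall[sup]),
      f1 = mean(per_type$f1[sup])
    )
  }
  out <- dplyr::bind_rows(overall, per_type)
  attr(out, "level") <- level
  attr(out, "average") <- average
  class(out) <- c("ke_metrics", class(out))
  out
}

#' Render a metrics table with percentages
#'
#' @param metrics A `ke_metrics` tibble.
#' @param digits Decimal places, default 2.
#' @return The tibble with `precision`, `recall`, `f1` as rounded
#'   percentages.
#' @export
format_metrics <- function(metrics, digits = 2) {
  metrics |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("precision", "recall", "f1")),
      ~ round(100 * .x, digits)
    ))
}

#' Entity-type confusion counts
#'
#' Per document, exact (surface, type) matches populate the diagonal;
#' among the residue, predictions whose surface exactly matches a gold
#' surface but whose type differs populate the off-diagonal cell
#' (gold type, predicted type). Predictions and gold items without a
#' surface counterpart are excluded from the matrix.
#'
#' @inheritParams evaluate_extraction
#' @return A `ke_confusion` tibble with columns `gold_type`,
#'   `pred_type`, `n` covering all 11 x 11 type pairs; see
#'   [as.matrix.ke_confusion()].
#' @export
entity_confusion <- function(gold_corpus, pred_corpus) {
  pairs <- .align_corpora(gold_corpus, pred_corpus)
  types <- entity_types()
  mat <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  for (pr in pairs) {
    g <- .unique_entity_keys(pr$gold)
    p <- .unique_entity_keys(pr$pred)
    exact <- intersect(g$key, p$key)
    for (k in exact) {
      ty <- g$type[g$key == k][1]
      mat[ty, ty] <- mat[ty, ty] + 1L
    }
    g_res <- g[!g$key %in% exact, , drop = FALSE]
    p_res <- p[!p$key %in% exact, , drop = FALSE]
    g_surf <- sub("\r.*$", "", g_res$key)
    p_surf <- sub("\r.*$", "", p_res$key)
    p_used <- rep(FALSE, nrow(p_res))
    for (i in seq_len(nrow(g_res))) {
      j <- which(!p_used & p_surf == g_surf[i] & p_res$type != g_res$type[i])
      if (length(j) > 0) {
        mat[g_res$type[i], p_res$type[j[1]]] <-
          mat[g_res$type[i], p_res$type[j[1]]] + 1L
        p_used[j[1]] <- TRUE
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame.table(mat, stringsAsFactors = FALSE)) |>
    stats::setNames(c("gold_type", "pred_type", "n"))
  class(out) <- c("ke_confusion", class(out))
  out
}

#' @rdname entity_confusion
#' @param x A `ke_confusion` tibble.
#' @param ... Unused.
#' @export
as.matrix.ke_confusion <- function(x, ...) {
  types <- entity_types()
  mat <- matrix(0L, length(types), length(types), dimnames = list(types, types))
  for (i in seq_len(nrow(x))) mat[x$gold_type[i], x$pred_type[i]] <- x$n[i]
  mat
}

#' Classify extraction errors for one document
#'
#' Entity errors follow a fixed priority per item: exact match (no
#' error) > same surface with wrong type (`incorrect_type`) > same type
#' with overlapping unequal surface (`boundary_error`) > unmatched
#' prediction (`incorrect_extraction`) > unmatched gold
#' (`missing_entity`). Triplet errors: a predicted triplet whose
#' relation and endpoint surfaces match gold but with a wrong endpoint
#' type is an `incorrect_entity_type`; a missed gold triplet whose
#' endpoints lie in different sentences is a `cross_sentence_error`.
#' An `exact_match` (entity) and `correct` (triplet) row are included
#' so counts conserve: every gold and predicted item is accounted for
#' exactly once.
#'
#' @param gold,pred [document_annotation()] objects for the same
#'   document; `gold` must carry `sentence_bounds` (required for the
#'   cross-sentence rule).
#' @return A `ke_errors` tibble with columns `scope`, `error`, `n`.
#' @export
classify_errors <- function(gold, pred) {
  stopifnot(
    inherits(gold, "document_annotation"),
    inherits(pred, "document_annotation")
  )
  if (nrow(gold$sentence_bounds) == 0 && nchar(gold$text) > 0) {
    stop("classify_errors requires sentence_bounds on the gold annotation",
      call. = FALSE
    )
  }
  g <- gold$entities |> dplyr::distinct(.data$surface, .data$type)
  p <- pred$entities |> dplyr::distinct(.data$surface, .data$type)
  g_used <- rep(FALSE, nrow(g)); p_used <- rep(FALSE, nrow(p))
  n_exact <- 0L; n_type <- 0L; n_boundary <- 0L
  # stage 1: exact
  for (i in seq_len(nrow(g))) {
    j <- which(!p_used & p$surface == g$surface[i] & p$type == g$type[i])
    if (length(j) > 0) {
      n_exact <- n_exact + 1L; g_used[i] <- TRUE; p_used[j[1]] <- TRUE
    }
  }
  # stage 2: same surface, wrong type
  for (i in which(!g_used)) {
    j <- which(!p_used & p$surface == g$surface[i] & p$type != g$type[i])
    if (length(j) > 0) {
      n_type <- n_type + 1L; g_used[i] <- TRUE; p_used[j[1]] <- TRUE
    }
  }
  # stage 3: same type, overlapping unequal surface
  for (i in which(!g_used)) {
    for (j in which(!p_used)) {
      if (p$type[j] == g$type[i] && p$surface[j] != g$surface[i] &&
          .token_overlap(g$surface[i], p$surface[j])) {
        n_boundary <- n_boundary + 1L; g_used[i] <- TRUE; p_used[j] <- TRUE
        break
      }
    }
  }
  n_spurious <- sum(!p_used)
  n_missing <- sum(!g_used)

  # triplets
  gt <- canonicalize_triplets(gold$triplets)
  pt <- canonicalize_triplets(pred$triplets)
  gt <- gt[!duplicated(.quint_key(gt)), , drop = FALSE]
  pt <- pt[!duplicated(.quint_key(pt)), , drop = FALSE]
  gk <- .quint_key(gt); pk <- .quint_key(pt)
  correct <- sum(pk %in% gk)
  gt_open <- !gk %in% pk
  n_ietype <- 0L
  for (j in which(!pk %in% gk)) {
    i <- which(gt_open & gt$relation == pt$relation[j] &
                 gt$head == pt$head[j] & gt$tail == pt$tail[j] &
                 (gt$head_type != pt$head_type[j] | gt$tail_type != pt$tail_type[j]))
    if (length(i) > 0) {
      n_ietype <- n_ietype + 1L
      gt_open[i[1]] <- FALSE
    }
  }
  # cross-sentence errors among remaining missed gold triplets
  e <- .anchor_entities(gold)
  akey <- paste(e$surface, e$type, sep = "\r")
  sent_of <- function(s, ty) {
    i <- match(paste(s, ty, sep = "\r"), akey)
    if (is.na(i)) return(NA_integer_)
    .sentence_of(e$anchor_start[i], gold$sentence_bounds)
  }
  n_cross <- 0L
  for (i in which(gt_open)) {
    hs <- sent_of(gt$head[i], gt$head_type[i])
    ts <- sent_of(gt$tail[i], gt$tail_type[i])
    if (!is.na(hs) && !is.na(ts) && hs != ts) n_cross <- n_cross + 1L
  }

  out <- tibble::tribble(
    ~scope,    ~error,                 ~n,
    "entity",  "exact_match",          n_exact,
    "entity",  "incorrect_extraction", n_spurious,
    "entity",  "incorrect_type",       n_type,
    "entity",  "boundary_error",       n_boundary,
    "entity",  "missing_entity",       n_missing,
    "triplet", "correct",              correct,
    "triplet", "incorrect_entity_type", n_ietype,
    "triplet", "cross_sentence_error", n_cross
  )
  class(out) <- c("ke_errors", class(out))
  out
}

#' Pool error counts over an aligned corpus pair
#'
#' @inheritParams evaluate_extraction
#' @return A `ke_errors` tibble of summed counts.
#' @export
count_errors <- function(gold_corpus, pred_corpus) {
  pairs <- .align_corpora(gold_corpus, pred_corpus)
  tallies <- purrr::map_dfr(pairs, function(pr) {
    pred <- pr$pred
    if (is.null(pred)) {
      pred <- document_annotation(pr$gold$doc_id, pr$gold$text, check = FALSE)
    }
    classify_errors(pr$gold, pred)
  })
  out <- tallies |>
    dplyr::group_by(.data$scope, .data$error) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(match(.data$scope, c("entity", "triplet")))
  class(out) <- c("ke_errors", class(out))
  out
}

#' Document-level train/test split
#'
#' Deterministic given `seed`; the training partition holds
#' `round(train_fraction * N)` documents; the partition is disjoint and
#' exhaustive and document order within each partition follows the
#' input.
#'
#' @param corpus List of [document_annotation()] objects.
#' @param train_fraction Fraction of documents for training, default
#'   0.8 (the corpus's published 80/20 document-level split).
#' @param seed Integer seed (mandatory; the split is random).
#' @return List with elements `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.8, seed) {
  stopifnot(train_fraction >= 0, train_fraction <= 1, !missing(seed))
  n <- length(corpus)
  n_train <- round(train_fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  idx <- sort(idx)
  list(train = corpus[idx], test = corpus[setdiff(seq_len(n), idx)])
}

#' Corpus statistics
#'
#' Counts entity mentions per type and canonical triplets per relation,
#' with relative frequencies against the within-kind totals.
#'
#' @param corpus List of [document_annotation()] objects.
#' @return A `ke_stats` tibble (`kind`, `type`, `count`, `freq`).
#' @export
corpus_statistics <- function(corpus) {
  e_counts <- stats::setNames(numeric(length(entity_types())), entity_types())
  r_counts <- stats::setNames(numeric(length(canonical_relations())), canonical_relations())
  for (doc in corpus) {
    te <- table(doc$entities$type)
    e_counts[names(te)] <- e_counts[names(te)] + as.numeric(te)
    if (nrow(doc$triplets) > 0) {
      tr <- table(canonicalize_triplets(doc$triplets)$relation)
      r_counts[names(tr)] <- r_counts[names(tr)] + as.numeric(tr)
    }
  }
  stats_table(e_counts, r_counts)
}

#' Published benchmark metrics on the DrugReC test set
#'
#' Per-type precision/recall/F1 percentages reported for the reference
#' extraction model on the DrugReC test set, plus its ablation variants.
#' These are shipped printed values (inputs for arithmetic-consistency
#' checks such as harmonic-mean identities and ablation deltas), not
#' quantities this package computes.
#'
#' @return Tibbles of percentages: `reference_entity_metrics()` and
#'   `reference_triplet_metrics()` with columns `type`, `precision`,
#'   `recall`, `f1`; `reference_ablation()` with columns `model`,
#'   `entity_f1`, `triplet_f1`.
#' @export
reference_entity_metrics <- function() {
  tibble::tribble(
    ~type,          ~precision, ~recall, ~f1,
    "ALL",          83.37,      79.64,   81.46,
    "drug",         95.44,      96.23,   95.83,
    "disease",      90.88,      90.16,   90.52,
    "anatomy",      84.23,      80.60,   82.38,
    "test",         82.98,      81.25,   82.11,
    "side_effect",  76.79,      84.31,   80.37,
    "gene",         64.58,      88.57,   74.70,
    "complication", 87.16,      64.19,   73.93,
    "biomarker",    75.74,      68.67,   72.03,
    "symptom",      66.19,      76.67,   71.04,
    "treatment",    70.94,      63.85,   67.21,
    "target",       81.67,      52.69,   64.05
  )
}

#' @rdname reference_entity_metrics
#' @export
reference_triplet_metrics <- function() {
  tibble::tribble(
    ~type,                     ~precision, ~recall, ~f1,
    "ALL",                     73.94,      67.17,   70.39,
    "treat",                   87.74,      81.44,   84.47,
    "is_target_of",            82.93,      68.00,   74.73,
    "is_located_in",           77.10,      70.63,   73.72,
    "is_symptom_of",           64.84,      73.45,   68.88,
    "is_examination_for",      70.47,      65.63,   67.96,
    "is_side_effect_of",       67.80,      66.67,   67.23,
    "complication_of",         80.95,      55.56,   65.89,
    "is_biomarker_of",         60.98,      54.74,   57.69,
    "increases_expression_of", 66.67,      40.00,   50.00
  )
}

#' @rdname reference_entity_metrics
#' @export
reference_ablation <- function() {
  tibble::tribble(
    ~model,         ~entity_f1, ~triplet_f1,
    "full",         81.46,      69.04,
    "without_grpo", 75.37,      54.95,
    "without_sft",  72.85,      48.34
  )
}
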