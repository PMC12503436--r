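#' Reward weight configuration
#'
#' The dual reward is `R = w_acc * R_acc + w_fmt * R_fmt` with
#' `R_acc = alpha * S_entity + beta * S_triplet + gamma * S_rare` and
#' `R_fmt = delta * S_tag + epsilon * S_length`. The tuned default
#' coefficients are `alpha = beta = 0.45`, `gamma = 0.1`, `delta = 0.7`,
#' `epsilon = 0.3`, and equal top-level weights `w_acc = w_fmt = 0.5`.
#' The constraints `alpha + beta + gamma = 1`, `delta + epsilon = 1`,
#' and `w_acc + w_fmt = 1` are enforced.
#'
#' @param alpha Entity accuracy weight.
#' @param beta_triplet Triplet accuracy weight (named to avoid collision
#'   with the KL coefficient of [grpo_config()]).
#' @param gamma Rare-item accuracy weight.
#' @param delta Tag-integrity format weight.
#' @param epsilon_length Thinking-length format weight (named to avoid
#'   collision with the clip half-width of [grpo_config()]).
#' @param w_acc,w_fmt Top-level accuracy/format weights.
#' @param partial_credit Credit for a partial entity overlap (correct
#'   type, overlapping but unequal boundary), in `[0, 1]`.
#' @param length_bounds Two-element numeric `[min_chars, max_chars]`
#'   acceptance window for think-content length.
#' @param case_sensitive Compare surfaces case-sensitively (default;
#'   original casing is part of an exact match).
#' @return A `reward_weights` list.
#' @export
reward_weights <- function(alpha = 0.45, beta_triplet = 0.45, gamma = 0.1,
                           delta = 0.7, epsilon_length = 0.3,
                           w_acc = 0.5, w_fmt = 0.5,
                           partial_credit = 0.5,
                           length_bounds = c(200, 8000),
                           case_sensitive = TRUE) {
  tol <- 1e-8
  stopifnot(
    abs(alpha + beta_triplet + gamma - 1) < tol,
    abs(delta + epsilon_length - 1) < tol,
    abs(w_acc + w_fmt - 1) < tol,
    partial_credit >= 0, partial_credit <= 1,
    length(length_bounds) == 2,
    length_bounds[1] >= 0, length_bounds[1] < length_bounds[2]
  )
  structure(
    list(
      alpha = alpha, beta_triplet = beta_triplet, gamma = gamma,
      delta = delta, epsilon_length = epsilon_length,
      w_acc = w_acc, w_fmt = w_fmt, partial_credit = partial_credit,
      length_bounds = length_bounds, case_sensitive = case_sensitive
    ),
    class = "reward_weights"
  )
}

.surface_eq <- function(a, b, case_sensitive) {
  if (case_sensitive) a == b else tolower(a) == tolower(b)
}

.strip_punct_tokens <- function(x) {
  toks <- stringr::str_split(tolower(x), "[^[:alnum:]]+")[[1]]
  toks[toks != ""]
}

.token_overlap <- function(a, b) {
  length(intersect(.strip_punct_tokens(a), .strip_punct_tokens(b))) > 0
}

#' Align predicted entities to gold
#'
#' Greedy one-to-one assignment: exact matches first (surface and type
#' fully consistent), then partial overlaps (same type, token overlap
#' between punctuation-stripped surfaces, boundary unequal), in
#' deterministic order (gold order, then prediction order). Residual
#' predictions are false positives, residual gold items false negatives.
#'
#' @param gold,pred [document_annotation()] objects for the same
#'   document.
#' @param case_sensitive Compare surfaces case-sensitively.
#' @return An `entity_match` list: tibbles `exact` and `partial`
#'   (columns `gold_idx`, `pred_idx`, `surface`, `pred_surface`,
#'   `type`), `false_positives`, `false_negatives`, and counts `n_gold`,
#'   `n_pred`.
#' @export
match_entities <- function(gold, pred, case_sensitive = TRUE) {
  stopifnot(
    inherits(gold, "document_annotation"),
    inherits(pred, "document_annotation")
  )
  if (gold$doc_id != pred$doc_id) {
    stop("gold and prediction refer to different documents", call. = FALSE)
  }
  g <- gold$entities; p <- pred$entities
  g_used <- rep(FALSE, nrow(g)); p_used <- rep(FALSE, nrow(p))
  ex_g <- integer(); ex_p <- integer(); pa_g <- integer(); pa_p <- integer()
  for (i in seq_len(nrow(g))) {
    for (j in seq_len(nrow(p))) {
      if (p_used[j]) next
      if (g$type[i] == p$type[j] &&
          .surface_eq(g$surface[i], p$surface[j], case_sensitive)) {
        ex_g <- c(ex_g, i); ex_p <- c(ex_p, j)
        g_used[i] <- TRUE; p_used[j] <- TRUE
        break
      }
    }
  }
  for (i in seq_len(nrow(g))) {
    if (g_used[i]) next
    for (j in seq_len(nrow(p))) {
      if (p_used[j]) next
      if (g$type[i] == p$type[j] &&
          !.surface_eq(g$surface[i], p$surface[j], case_sensitive) &&
          .token_overlap(g$surface[i], p$surface[j])) {
        pa_g <- c(pa_g, i); pa_p <- c(pa_p, j)
        g_used[i] <- TRUE; p_used[j] <- TRUE
        break
      }
    }
  }
  pairs_tbl <- function(gi, pi) {
    tibble::tibble(
      gold_idx = gi, pred_idx = pi, surface = g$surface[gi],
      pred_surface = p$surface[pi], type = g$type[gi]
    )
  }
  structure(
    list(
      exact = pairs_tbl(ex_g, ex_p),
      partial = pairs_tbl(pa_g, pa_p),
      false_positives = p[!p_used, , drop = FALSE],
      false_negatives = g[!g_used, , drop = FALSE],
      n_gold = nrow(g), n_pred = nrow(p)
    ),
    class = "entity_match"
  )
}

.quint_key <- function(ct, case_sensitive = TRUE) {
  s <- function(x) if (case_sensitive) x else tolower(x)
  paste(s(ct$head), ct$head_type, ct$relation, s(ct$tail), ct$tail_type,
    sep = "\r"
  )
}

#' Align predicted triplets to gold
#'
#' Quintuples are compared after [canonicalize_triplets()]: a correct
#' triplet requires surface and type equality on both endpoints plus
#' relation equality. Among the remaining predictions, dependency errors
#' are those whose relation matches a gold relation between overlapping
#' entities but with a wrong entity or entity type; the rest are
#' spurious. Unmatched gold triplets are missed.
#'
#' @inheritParams match_entities
#' @return A `triplet_match` list: tibbles `correct`,
#'   `dependency_errors`, `spurious` (canonical predicted quintuples)
#'   and `missed` (canonical gold quintuples), plus `n_gold`, `n_pred`.
#' @export
match_triplets <- function(gold, pred, case_sensitive = TRUE) {
  stopifnot(
    inherits(gold, "document_annotation"),
    inherits(pred, "document_annotation")
  )
  if (gold$doc_id != pred$doc_id) {
    stop("gold and prediction refer to different documents", call. = FALSE)
  }
  g <- canonicalize_triplets(gold$triplets)
  p <- canonicalize_triplets(pred$triplets)
  gk <- .quint_key(g, case_sensitive); pk <- .quint_key(p, case_sensitive)
  g_used <- rep(FALSE, nrow(g)); p_used <- rep(FALSE, nrow(p))
  for (j in seq_len(nrow(p))) {
    i <- which(!g_used & gk == pk[j])
    if (length(i) > 0) { g_used[i[1]] <- TRUE; p_used[j] <- TRUE }
  }
  correct <- p[p_used, , drop = FALSE]
  rest <- which(!p_used)
  dep <- rep(FALSE, length(rest))
  seq_g_open <- which(!g_used)
  for (k in seq_along(rest)) {
    j <- rest[k]
    for (i in seq_g_open) {
      if (g$relation[i] != p$relation[j]) next
      head_surf_eq <- .surface_eq(g$head[i], p$head[j], case_sensitive)
      tail_surf_eq <- .surface_eq(g$tail[i], p$tail[j], case_sensitive)
      head_eq <- head_surf_eq && g$head_type[i] == p$head_type[j]
      tail_eq <- tail_surf_eq && g$tail_type[i] == p$tail_type[j]
      overlapping <- head_surf_eq || tail_surf_eq ||
        .token_overlap(g$head[i], p$head[j]) ||
        .token_overlap(g$tail[i], p$tail[j])
      if (overlapping && !(head_eq && tail_eq)) { dep[k] <- TRUE; break }
    }
  }
  structure(
    list(
      correct = correct,
      dependency_errors = p[rest[dep], , drop = FALSE],
      spurious = p[rest[!dep], , drop = FALSE],
      missed = g[!g_used, , drop = FALSE],
      n_gold = nrow(g), n_pred = nrow(p)
    ),
    class = "triplet_match"
  )
}

# Rare-item recovery: rare gold entities (by type) recovered exactly and
# rare gold canonical relations recovered as correct triplets.
.rare_recovery <- function(gold, em, tm, ref_stats, threshold) {
  g_ent <- gold$entities
  g_tri <- canonicalize_triplets(gold$triplets)
  rare_e <- if (nrow(g_ent)) is_rare(g_ent$type, ref_stats, threshold) else logical()
  rare_r <- if (nrow(g_tri)) is_rare(g_tri$relation, ref_stats, threshold) else logical()
  n_rare <- sum(rare_e) + sum(rare_r)
  if (n_rare == 0) return(list(n_rare = 0L, s_rare = NA_real_))
  rec_e <- sum(which(rare_e) %in% em$exact$gold_idx)
  gk <- .quint_key(g_tri)
  ck <- .quint_key(tm$correct)
  rec_r <- sum(gk[rare_r] %in% ck)
  list(n_rare = n_rare, s_rare = (rec_e + rec_r) / n_rare)
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

#' Accuracy reward from match results
#'
#' Component scores: `S_entity = (exact + partial_credit * partial) /
#' max(n_gold, n_pred)` (defined as 1 when both counts are 0);
#' `S_triplet = correct / max(n_gold, n_pred)` with no partial credit;
#' `S_rare` is the fraction of rare gold items (entities by type plus
#' canonical relations) recovered exactly. A vacuous category — no
#' triplets on either side, or no rare gold items — is dropped and the
#' remaining weights renormalized, so documents without rare content are
#' not capped below 1. The max-count denominator makes spurious output
#' strictly costly while keeping scores in `[0, 1]`.
#'
#' @param em An `entity_match` from [match_entities()].
#' @param tm A `triplet_match` from [match_triplets()].
#' @param rare List with `n_rare` and `s_rare` (internal contract; built
#'   by [total_reward()] from the reference statistics).
#' @param w A [reward_weights()] object.
#' @return List with `s_entity`, `s_triplet`, `s_rare` (NA when
#'   vacuous), and `r_acc`.
#' @export
accuracy_reward <- function(em, tm, rare = list(n_rare = 0L, s_rare = NA_real_),
                            w = reward_weights()) {
  denom_e <- max(em$n_gold, em$n_pred)
  s_entity <- if (denom_e == 0) {
    1
  } else {
    .clamp01((nrow(em$exact) + w$partial_credit * nrow(em$partial)) / denom_e)
  }
  denom_t <- max(tm$n_gold, tm$n_pred)
  triplet_vacuous <- denom_t == 0
  s_triplet <- if (triplet_vacuous) NA_real_ else .clamp01(nrow(tm$correct) / denom_t)
  rare_vacuous <- rare$n_rare == 0
  s_rare <- if (rare_vacuous) NA_real_ else .clamp01(rare$s_rare)

  weights <- c(w$alpha, w$beta_triplet, w$gamma)
  scores <- c(s_entity, s_triplet, s_rare)
  active <- !is.na(scores)
  r_acc <- .clamp01(sum(weights[active] * scores[active]) / sum(weights[active]))
  list(s_entity = s_entity, s_triplet = s_triplet, s_rare = s_rare, r_acc = r_acc)
}

#' Structural format reward
#'
#' `S_tag` is 1 iff the tag-integrity verdict holds (missing or
#' redundant tags and closure disorder all zero it); `S_length` is 1 iff
#' the think-content character count lies within `length_bounds`
#' (under- or over-length content scores 0). `R_fmt = delta * S_tag +
#' epsilon * S_length`.
#'
#' @param tag_report A `tag_report` from [check_tag_integrity()].
#' @param trace A `reasoning_trace` from [extract_reasoning()].
#' @param w A [reward_weights()] object.
#' @return List with `s_tag`, `s_length`, `r_fmt`.
#' @export
format_reward <- function(tag_report, trace, w = reward_weights()) {
  s_tag <- as.numeric(isTRUE(tag_report$tag_integrity_ok))
  s_length <- as.numeric(
    trace$total_length >= w$length_bounds[1] &&
      trace$total_length <= w$length_bounds[2]
  )
  list(
    s_tag = s_tag, s_length = s_length,
    r_fmt = w$delta * s_tag + w$epsilon_length * s_length
  )
}

#' Total dual reward for one raw model output
#'
#' Full pipeline: lenient payload parsing, entity/triplet matching and
#' the accuracy reward; tag check, reasoning trace and the format
#' reward; then `R = w_acc * R_acc + w_fmt * R_fmt`. A reward exists for
#' any raw text: an unparseable payload yields `R_acc = 0` while format
#' components are still scored.
#'
#' @param gold The gold [document_annotation()].
#' @param raw_output Raw model output text.
#' @param w A [reward_weights()] object.
#' @param ref_stats Reference statistics for rarity, default
#'   [reference_corpus_stats()].
#' @param rare_threshold Rarity cutoff, default 0.05.
#' @return A `reward_breakdown` object (one-row list of component and
#'   composed scores); see [tidy.reward_breakdown()].
#' @export
#' @examples
#' gold <- document_annotation(
#'   "d1", "cetuximab treats colorectal cancer.",
#'   entities = tibble::tibble(
#'     surface = c("cetuximab", "colorectal cancer"),
#'     type = c("drug", "disease")
#'   ),
#'   triplets = tibble::tibble(
#'     head = "cetuximab", head_type = "drug", relation = "treat",
#'     tail = "colorectal cancer", tail_type = "disease"
#'   )
#' )
#' raw <- render_model_output(gold, think_length = 400, seed = 1)
#' total_reward(gold, raw)$r_total
total_reward <- function(gold, raw_output, w = reward_weights(),
                         ref_stats = reference_corpus_stats(),
                         rare_threshold = 0.05) {
  stopifnot(inherits(gold, "document_annotation"))
  parsed <- parse_prediction(raw_output, mode = "lenient",
                             doc_id = gold$doc_id, text = gold$text)
  if (is.null(parsed$annotation)) {
    acc <- list(
      s_entity = NA_real_, s_triplet = NA_real_, s_rare = NA_real_,
      r_acc = 0
    )
  } else {
    em <- match_entities(gold, parsed$annotation, w$case_sensitive)
    tm <- match_triplets(gold, parsed$annotation, w$case_sensitive)
    rare <- .rare_recovery(gold, em, tm, ref_stats, rare_threshold)
    acc <- accuracy_reward(em, tm, rare, w)
  }
  fmt <- format_reward(parsed$tag_report, parsed$trace, w)
  structure(
    list(
      doc_id = gold$doc_id,
      s_entity = acc$s_entity, s_triplet = acc$s_triplet,
      s_rare = acc$s_rare, s_tag = fmt$s_tag, s_length = fmt$s_length,
      r_acc = acc$r_acc, r_fmt = fmt$r_fmt,
      r_total = w$w_acc * acc$r_acc + w$w_fmt * fmt$r_fmt,
      parse_ok = !is.null(parsed$annotation)
    ),
    class = "reward_breakdown"
  )
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat(sprintf(
    "<reward_breakdown %s> r_total = %.4f (r_acc = %.4f, r_fmt = %.4f)\n",
    x$doc_id, x$r_total, x$r_acc, x$r_fmt
  ))
  invisible(x)
}

#' Score a corpus of raw model outputs against gold
#'
#' @param gold_corpus List of gold [document_annotation()] objects.
#' @param outputs Tibble with columns `doc_id`, `output_text`; documents
#'   without an output row receive the reward of an empty string.
#' @inheritParams total_reward
#' @return A tibble with one row per gold document carrying the reward
#'   breakdown columns.
#' @export
score_corpus <- function(gold_corpus, outputs, w = reward_weights(),
                         ref_stats = reference_corpus_stats(),
                         rare_threshold = 0.05) {
  purrr::map_dfr(gold_corpus, function(doc) {
    i <- match(doc$doc_id, outputs$doc_id)
    raw <- if (is.na(i)) "" else outputs$output_text[i]
    b <- total_reward(doc, raw, w, ref_stats, rare_threshold)
    tibble::as_tibble(b[c(
      "doc_id", "s_entity", "s_triplet", "s_rare", "s_tag", "s_length",
      "r_acc", "r_fmt", "r_total", "parse_ok"
    )])
  })
}
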