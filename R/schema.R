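#' Canonical entity types of the drug-repositioning schema
#'
#' The schema distinguishes 11 entity categories relevant to drug
#' repositioning: three core types (`drug`, `disease`, `target`) plus
#' extended dimensions (`side_effect`, `gene`, `biomarker`, `symptom`,
#' `complication`, `anatomy`, `test`, `treatment`). `anatomy` covers
#' anatomical structures and `test` covers clinical examinations.
#'
#' @return A character vector of the 11 canonical type names, in
#'   lowercase snake case.
#' @export
#' @examples
#' entity_types()
entity_types <- function() {
  c(
    "drug", "disease", "target", "side_effect", "gene", "biomarker",
    "symptom", "complication", "anatomy", "test", "treatment"
  )
}

# extra spellings accepted on input, mapped to canonical names after
# snake-casing; canonical names always map to themselves
.entity_aliases <- c(
  anatomical_structure = "anatomy",
  anatomical_site      = "anatomy",
  clinical_examination = "test",
  examination          = "test",
  side_effects         = "side_effect",
  adverse_effect       = "side_effect",
  genes                = "gene",
  drugs                = "drug",
  diseases             = "disease"
)

.snake <- function(x) {
  x <- stringr::str_trim(tolower(x))
  x <- stringr::str_replace_all(x, "[\\s\\-]+", "_")
  x
}

#' Normalize entity type labels to canonical schema names
#'
#' Type labels are case-insensitive aliases of the 11 canonical names:
#' `"Side Effect"` becomes `side_effect`, `"anatomical structure"`
#' becomes `anatomy`, `"clinical examination"` becomes `test`.
#'
#' @param x Character vector of type labels.
#' @param strict Error on unknown labels (`TRUE`, default) or return
#'   `NA` for them (`FALSE`).
#' @return Character vector of canonical type names.
#' @export
#' @examples
#' normalize_entity_type(c("Drug", "Side Effect", "anatomical structure"))
normalize_entity_type <- function(x, strict = TRUE) {
  s <- .snake(x)
  hit <- ifelse(s %in% entity_types(), s, unname(.entity_aliases[s]))
  if (strict && anyNA(hit[!is.na(x)])) {
    bad <- unique(x[is.na(hit) & !is.na(x)])
    stop("Unknown entity type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  hit
}

#' Directed relation registry
#'
#' Nine canonical relation labels describe drug-repositioning semantics
#' (e.g. a drug `treat`s a disease, a `side_effect` `is_side_effect_of`
#' a drug). Every relation is bidirectional between head and tail, so
#' the registry exposes 18 directed labels: each canonical label plus a
#' named inverse reading the arrow the other way.
#'
#' @return A tibble with one row per directed label and columns
#'   `label`, `canonical`, and `is_inverse`.
#' @export
#' @examples
#' relation_types()
#' canonical_relations()
relation_types <- function() {
  can <- c(
    treat                   = "is_treated_by",
    is_target_of            = "has_target",
    is_side_effect_of       = "has_side_effect",
    is_biomarker_of         = "has_biomarker",
    is_examination_for      = "has_examination",
    complication_of         = "has_complication",
    is_located_in           = "location_of",
    is_symptom_of           = "has_symptom",
    increases_expression_of = "expression_increased_by"
  )
  tibble::tibble(
    label      = c(names(can), unname(can)),
    canonical  = c(names(can), names(can)),
    is_inverse = rep(c(FALSE, TRUE), each = length(can))
  )
}

#' @rdname relation_types
#' @export
canonical_relations <- function() {
  reg <- relation_types()
  reg$label[!reg$is_inverse]
}

.relation_aliases <- c(
  treats = "treat", is_treatment_for = "treat",
  is_complication_of = "complication_of"
)

#' Normalize relation labels to registered directed labels
#'
#' @param x Character vector of relation labels (canonical or inverse
#'   direction, any casing, spaces or hyphens allowed).
#' @param strict Error on unregistered labels (default) or return `NA`.
#' @return Character vector of registered directed labels.
#' @export
normalize_relation <- function(x, strict = TRUE) {
  s <- .snake(x)
  reg <- relation_types()$label
  hit <- ifelse(s %in% reg, s, unname(.relation_aliases[s]))
  if (strict && anyNA(hit[!is.na(x)])) {
    bad <- unique(x[is.na(hit) & !is.na(x)])
    stop("Unregistered relation label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  hit
}

#' Rewrite triplets in canonical relation direction
#'
#' Each relation has a canonical direction (e.g. drug `treat` disease);
#' a triplet stated with the inverse label is rewritten by swapping head
#' and tail and substituting the canonical label. Already-canonical
#' triplets pass through unchanged, so the operation is idempotent.
#'
#' @param triplets A triplet tibble with columns `head`, `head_type`,
#'   `relation`, `tail`, `tail_type` (as stored in a
#'   [document_annotation()]).
#' @return The triplet tibble with all relations canonical.
#' @export
#' @examples
#' t <- tibble::tibble(
#'   head = "colorectal cancer", head_type = "disease",
#'   relation = "is_treated_by", tail = "cetuximab", tail_type = "drug"
#' )
#' canonicalize_triplets(t)
canonicalize_triplets <- function(triplets) {
  if (nrow(triplets) == 0) return(triplets)
  reg <- relation_types()
  i <- match(normalize_relation(triplets$relation), reg$label)
  if (anyNA(i)) stop("Unregistered relation label", call. = FALSE)
  inv <- reg$is_inverse[i]
  out <- triplets
  out$relation <- reg$canonical[i]
  if (any(inv)) {
    out[inv, c("head", "head_type", "tail", "tail_type")] <-
      triplets[inv, c("tail", "tail_type", "head", "head_type")]
  }
  out
}

#' Default relation/type compatibility table
#'
#' Admissible (head type, tail type) pairs for each canonical relation.
#' The full authoritative table is part of the schema's supplementary
#' definition and not reproduced verbatim here; this default is an
#' informed reconstruction and is user-overridable through the YAML
#' schema config (see [read_ke_config()]).
#'
#' @return A tibble with columns `relation`, `head_type`, `tail_type`.
#' @export
default_compatibility <- function() {
  tibble::tribble(
    ~relation,                 ~head_type,     ~tail_type,
    "treat",                   "drug",         "disease",
    "treat",                   "treatment",    "disease",
    "is_target_of",            "target",       "drug",
    "is_side_effect_of",       "side_effect",  "drug",
    "is_biomarker_of",         "biomarker",    "disease",
    "is_examination_for",      "test",         "disease",
    "complication_of",         "complication", "disease",
    "is_symptom_of",           "symptom",      "disease",
    "is_located_in",           "disease",      "anatomy",
    "is_located_in",           "complication", "anatomy",
    "is_located_in",           "biomarker",    "anatomy",
    "is_located_in",           "symptom",      "anatomy",
    "increases_expression_of", "drug",         "gene",
    "increases_expression_of", "gene",         "gene"
  )
}

#' Reference corpus statistics (DrugReC)
#'
#' Entity-mention and canonical-relation counts of the publicly released
#' DrugReC drug-repositioning corpus (1000 expert-validated PubMed
#' abstracts; 9329 entity mentions, 4879 triplets). These counts are the
#' default reference frequencies for rarity judgements and the default
#' type mixtures of the synthetic generator.
#'
#' @return A `ke_stats` tibble with columns `kind` (`"entity"` or
#'   `"relation"`), `type`, `count`, `freq`.
#' @seealso [stats_table()], [is_rare()], [corpus_statistics()]
#' @export
reference_corpus_stats <- function() {
  stats_table(
    entity_counts = c(
      disease = 1782, drug = 1474, anatomy = 1271, test = 963,
      biomarker = 957, complication = 644, target = 583, treatment = 561,
      symptom = 490, gene = 362, side_effect = 242
    ),
    relation_counts = c(
      is_examination_for = 886, treat = 839, is_biomarker_of = 837,
      complication_of = 618, is_located_in = 579, is_symptom_of = 449,
      is_target_of = 349, is_side_effect_of = 303,
      increases_expression_of = 19
    )
  )
}

#' Build a corpus statistics table from counts
#'
#' @param entity_counts Named numeric vector of entity-mention counts
#'   per canonical entity type.
#' @param relation_counts Named numeric vector of triplet counts per
#'   canonical relation.
#' @return A `ke_stats` tibble (`kind`, `type`, `count`, `freq`);
#'   frequencies are relative to the within-kind total, 0 when the
#'   total is 0.
#' @export
stats_table <- function(entity_counts, relation_counts) {
  mk <- function(kind, counts) {
    tot <- sum(counts)
    tibble::tibble(
      kind = kind, type = names(counts), count = as.numeric(counts),
      freq = if (tot > 0) as.numeric(counts) / tot else 0
    )
  }
  out <- dplyr::bind_rows(
    mk("entity", entity_counts),
    mk("relation", relation_counts)
  )
  class(out) <- c("ke_stats", class(out))
  out
}

#' Is an entity type or canonical relation rare?
#'
#' An item is rare when its relative frequency in the reference
#' statistics falls below `threshold`. Rare items attract a dedicated
#' reward component so the extractor is not starved of signal on
#' low-frequency categories (e.g. `increases_expression_of` at ~0.4% of
#' DrugReC triplets).
#'
#' @param item_type Character vector of entity types and/or canonical
#'   relation labels.
#' @param ref_stats A `ke_stats` table, default [reference_corpus_stats()].
#' @param threshold Rarity cutoff on relative frequency, default 0.05.
#' @return Logical vector.
#' @export
#' @examples
#' is_rare(c("increases_expression_of", "disease", "gene"))
is_rare <- function(item_type, ref_stats = reference_corpus_stats(),
                    threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  i <- match(item_type, ref_stats$type)
  if (anyNA(i)) {
    stop("Unknown type(s) in rarity lookup: ",
      paste(unique(item_type[is.na(i)]), collapse = ", "),
      call. = FALSE
    )
  }
  ref_stats$freq[i] < threshold
}
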