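#' Synthetic gazetteer of entity surfaces
#'
#' Realistic-looking names per entity type used by the generator,
#' including a handful of widely used real examples (Metformin,
#' cetuximab, Docetaxel, BRCA2, p53) for continuity with the error
#' taxonomy's canonical illustrations. Names are chosen so that no
#' surface is a substring of another, which guarantees nesting-free
#' anchoring by construction.
#'
#' @return Named list of character vectors, one per entity type.
#' @export
ke_gazetteer <- function() {
  list(
    drug = c(
      "Metformin", "cetuximab", "Docetaxel", "imatinib", "rapamycin",
      "atorvastatin", "gemcitabine", "thalidomide", "propranolol",
      "sildenafil", "dexamethasone", "valproate", "minocycline", "losartan"
    ),
    disease = c(
      "colorectal cancer", "celiac disease", "type 2 diabetes",
      "rheumatoid arthritis", "glioblastoma", "pulmonary fibrosis",
      "ulcerative colitis", "Parkinson disease", "multiple myeloma",
      "atopic dermatitis", "hepatocellular carcinoma", "chronic kidney disease"
    ),
    target = c(
      "EGFR", "mTOR", "HDAC6", "PD-L1", "ROCK2", "BTK", "CDK4", "TLR4",
      "JAK2", "PARP1"
    ),
    side_effect = c(
      "infusion reactions", "hepatotoxicity", "neutropenia",
      "QT prolongation", "peripheral neuropathy", "skin rash",
      "myelosuppression", "alopecia", "stomatitis", "photosensitivity"
    ),
    gene = c(
      "BRCA2", "p53", "KRAS", "MTHFR", "APOE", "FOXP3", "SOD1", "PTEN",
      "NOD2", "FMR1"
    ),
    biomarker = c(
      "anti-tTG antibodies", "C-reactive protein", "troponin I", "HbA1c",
      "serum ferritin", "CA-125", "procalcitonin", "D-dimer", "NT-proBNP",
      "fecal calprotectin"
    ),
    symptom = c(
      "nausea", "fatigue", "dizziness", "chronic cough", "night sweats",
      "joint stiffness", "abdominal pain", "blurred vision", "dysphagia",
      "paresthesia"
    ),
    complication = c(
      "extensive hemorrhage", "septic shock", "renal failure",
      "deep vein thrombosis", "bowel perforation", "cardiac tamponade",
      "secondary infection", "diabetic ketoacidosis", "pleural effusion",
      "osteonecrosis"
    ),
    anatomy = c(
      "left ventricle", "hippocampus", "renal cortex", "bone marrow",
      "small intestine", "hepatic portal vein", "synovial membrane",
      "alveolar epithelium", "basal ganglia", "thyroid gland"
    ),
    test = c(
      "colonoscopy", "echocardiography", "serological testing",
      "lumbar puncture", "spirometry", "bone densitometry",
      "polysomnography", "fundoscopic examination", "electromyography",
      "capsule endoscopy"
    ),
    treatment = c(
      "radiotherapy", "hemodialysis", "cognitive behavioral therapy",
      "bariatric surgery", "plasma exchange", "deep brain stimulation",
      "photodynamic therapy", "joint replacement", "stem cell transplantation",
      "prone positioning"
    )
  )
}

.relation_templates <- function() {
  c(
    treat                   = "%s is used to treat %s in clinical practice.",
    is_target_of            = "%s is the molecular target of %s.",
    is_side_effect_of       = "%s was reported as a side effect of %s.",
    is_biomarker_of         = "%s serves as a circulating biomarker of %s.",
    is_examination_for      = "%s is the examination of choice for %s.",
    complication_of         = "%s developed as a complication of %s.",
    is_located_in           = "%s was localized to the %s.",
    is_symptom_of           = "%s is a frequent symptom of %s.",
    increases_expression_of = "%s increases the expression of %s."
  )
}

.cross_templates <- function() {
  c(
    first = "The investigators first characterized %s in the cohort.",
    second = "Subsequent analyses linked this observation to %s."
  )
}

#' Synthetic generator configuration
#'
#' Defaults mirror the DrugReC corpus description: type mixtures equal
#' to the published entity and relation shares, about nine entity
#' mentions and five triplets per abstract (9329 entities and 4879
#' triplets over 1000 abstracts), and a modest fraction of triplets
#' whose endpoints sit in different sentences. Mixtures must sum to 1.
#'
#' @param n_docs Number of documents.
#' @param entity_mixture Named frequency vector over the 11 entity
#'   types.
#' @param relation_mixture Named frequency vector over the 9 canonical
#'   relations.
#' @param entities_per_doc,triplets_per_doc Two-element integer ranges.
#' @param sentences_per_doc Two-element range bounding the number of
#'   filler sentences used to host entities not taking part in a
#'   triplet.
#' @param cross_sentence_fraction Fraction of triplets realized with
#'   head and tail in different sentences.
#' @param seed Integer seed; generation is deterministic given the
#'   config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_docs = 100,
                             entity_mixture = NULL,
                             relation_mixture = NULL,
                             entities_per_doc = c(6L, 12L),
                             triplets_per_doc = c(3L, 7L),
                             sentences_per_doc = c(1L, 3L),
                             cross_sentence_fraction = 0.1,
                             seed = 1L) {
  ref <- reference_corpus_stats()
  if (is.null(entity_mixture)) {
    e <- ref[ref$kind == "entity", ]
    entity_mixture <- stats::setNames(e$freq, e$type)
  }
  if (is.null(relation_mixture)) {
    r <- ref[ref$kind == "relation", ]
    relation_mixture <- stats::setNames(r$freq, r$type)
  }
  stopifnot(
    n_docs >= 0,
    abs(sum(entity_mixture) - 1) < 1e-9,
    abs(sum(relation_mixture) - 1) < 1e-9,
    all(names(entity_mixture) %in% entity_types()),
    all(names(relation_mixture) %in% canonical_relations()),
    length(entities_per_doc) == 2, entities_per_doc[1] <= entities_per_doc[2],
    length(triplets_per_doc) == 2, triplets_per_doc[1] <= triplets_per_doc[2],
    cross_sentence_fraction >= 0, cross_sentence_fraction <= 1
  )
  structure(
    list(
      n_docs = n_docs, entity_mixture = entity_mixture,
      relation_mixture = relation_mixture,
      entities_per_doc = as.integer(entities_per_doc),
      triplets_per_doc = as.integer(triplets_per_doc),
      sentences_per_doc = as.integer(sentences_per_doc),
      cross_sentence_fraction = cross_sentence_fraction,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

.sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
}

#' Generate a gold-annotated synthetic corpus
#'
#' Documents are template sentences filled from the packaged gazetteer.
#' Entity types are drawn i.i.d. from the entity mixture (so empirical
#' shares converge on the configured mixture); triplet relations are
#' drawn from the relation mixture restricted to relations feasible
#' given the drawn entities and the default compatibility table; each
#' entity participates in at most one triplet, which keeps the
#' unidirectional and intrasentence-priority lints satisfied. Every
#' annotated surface occurs verbatim in the text, spans and sentence
#' bounds are recorded by construction, and [validate_annotation()]
#' returns zero violations for every generated document.
#'
#' @param cfg A [generator_config()].
#' @param compat Compatibility table, default [default_compatibility()].
#' @return List of [document_annotation()] objects.
#' @export
generate_gold_corpus <- function(cfg, compat = default_compatibility()) {
  stopifnot(inherits(cfg, "generator_config"))
  # feasibility: at least one positive-probability relation must admit a
  # head/tail pair with positive entity-mixture probability
  pos_types <- names(cfg$entity_mixture)[cfg$entity_mixture > 0]
  pos_rel <- names(cfg$relation_mixture)[cfg$relation_mixture > 0]
  feas <- vapply(pos_rel, function(rel) {
    rows <- compat[compat$relation == rel, ]
    any(rows$head_type %in% pos_types & rows$tail_type %in% pos_types)
  }, logical(1))
  if (length(pos_rel) > 0 && !any(feas) && cfg$triplets_per_doc[2] > 0) {
    stop(
      "Infeasible generator config: no relation in the mixture admits a ",
      "compatible (head, tail) type pair under the entity mixture",
      call. = FALSE
    )
  }
  withr::with_seed(cfg$seed, {
    purrr::map(seq_len(cfg$n_docs), function(i) {
      .generate_doc(sprintf("synth-%04d", i), cfg, compat)
    })
  })
}

.generate_doc <- function(doc_id, cfg, compat) {
  gaz <- ke_gazetteer()
  n_ent <- .sample_range(cfg$entities_per_doc)
  types <- character(0)
  surfaces <- character(0)
  pool <- gaz
  guard <- 0L
  while (length(types) < n_ent && guard < 1000L) {
    guard <- guard + 1L
    ty <- sample(names(cfg$entity_mixture), 1, prob = cfg$entity_mixture)
    if (length(pool[[ty]]) == 0) next # gazetteer for this type exhausted
    s <- sample(pool[[ty]], 1)
    pool[[ty]] <- setdiff(pool[[ty]], s)
    types <- c(types, ty); surfaces <- c(surfaces, s)
  }
  n_ent <- length(types)

  n_tri <- min(.sample_range(cfg$triplets_per_doc), floor(n_ent / 2))
  unused <- rep(TRUE, n_ent)
  trips <- list()
  cross_flags <- logical(0)
  for (k in seq_len(n_tri)) {
    feas_rel <- vapply(names(cfg$relation_mixture), function(rel) {
      if (cfg$relation_mixture[[rel]] <= 0) return(FALSE)
      rows <- compat[compat$relation == rel, ]
      any(vapply(seq_len(nrow(rows)), function(r) {
        hs <- which(unused & types == rows$head_type[r])
        ts <- which(unused & types == rows$tail_type[r])
        length(hs) > 0 && length(ts) > 0 &&
          !(length(hs) == 1 && length(ts) == 1 && hs == ts)
      }, logical(1)))
    }, logical(1))
    if (!any(feas_rel)) break
    rel <- sample(
      names(cfg$relation_mixture)[feas_rel], 1,
      prob = cfg$relation_mixture[feas_rel]
    )
    rows <- compat[compat$relation == rel, ]
    ok_pairs <- list()
    for (r in seq_len(nrow(rows))) {
      hs <- which(unused & types == rows$head_type[r])
      ts <- which(unused & types == rows$tail_type[r])
      for (h in hs) for (t in ts) {
        if (h != t) ok_pairs[[length(ok_pairs) + 1]] <- c(h, t)
      }
    }
    pick <- ok_pairs[[sample.int(length(ok_pairs), 1)]]
    unused[pick] <- FALSE
    trips[[k]] <- tibble::tibble(
      head = surfaces[pick[1]], head_type = types[pick[1]], relation = rel,
      tail = surfaces[pick[2]], tail_type = types[pick[2]]
    )
    cross_flags <- c(
      cross_flags, stats::runif(1) < cfg$cross_sentence_fraction
    )
  }
  triplets <- if (length(trips)) dplyr::bind_rows(trips) else empty_triplets()

  # realize sentences
  tmpl <- .relation_templates()
  xt <- .cross_templates()
  sentences <- character(0)
  for (k in seq_len(nrow(triplets))) {
    if (cross_flags[k]) {
      sentences <- c(
        sentences,
        sprintf(xt[["first"]], triplets$head[k]),
        sprintf(xt[["second"]], triplets$tail[k])
      )
    } else {
      sentences <- c(
        sentences,
        sprintf(tmpl[[triplets$relation[k]]], triplets$head[k], triplets$tail[k])
      )
    }
  }
  standalone <- which(unused)
  if (length(standalone) > 0) {
    n_fill <- max(
      1L,
      min(.sample_range(cfg$sentences_per_doc), length(standalone))
    )
    groups <- split(standalone, sort(rep_len(seq_len(n_fill), length(standalone))))
    for (gidx in groups) {
      listing <- paste(surfaces[gidx], collapse = ", ")
      sentences <- c(
        sentences,
        sprintf("The report additionally documented %s during follow-up.", listing)
      )
    }
  }
  if (length(sentences) == 0) {
    sentences <- "No extractable findings were reported."
  }

  text <- paste(sentences, collapse = " ")
  lens <- nchar(sentences)
  starts <- cumsum(c(0L, utils::head(lens + 1L, -1)))
  sentence_bounds <- tibble::tibble(start = starts, end = starts + lens)

  ents <- tibble::tibble(surface = surfaces, type = types)
  if (nrow(ents) > 0) {
    loc <- stringr::str_locate(text, stringr::fixed(ents$surface))
    ents$start <- as.integer(loc[, 1] - 1L)
    ents$end <- as.integer(loc[, 2])
  }
  document_annotation(
    doc_id, text,
    entities = ents, triplets = triplets,
    sentence_bounds = sentence_bounds, check = TRUE
  )
}

#' Error-injection profile
#'
#' Per-item injection rates implementing the error taxonomy observed in
#' extraction outputs: entity omission, spurious extraction of
#' non-entity phrases, type swaps among confusable categories, boundary
#' shifts by an adjacent token, triplet endpoint retyping, and dropped
#' cross-sentence triplets; plus rates for tag corruption and think
#' length violations applied at rendering time.
#'
#' @param entity_omission,entity_spurious,entity_type_swap,entity_boundary_shift
#'   Per-entity rates in `[0, 1]`.
#' @param triplet_entity_type_error Per-triplet endpoint retyping rate.
#' @param cross_sentence_drop Drop rate for cross-sentence gold
#'   triplets.
#' @param tag_corruption_rate,length_violation_rate Per-document rates
#'   used by [simulate_extraction()] when rendering raw outputs.
#' @return An `error_profile` list.
#' @export
error_profile <- function(entity_omission = 0, entity_spurious = 0,
                          entity_type_swap = 0, entity_boundary_shift = 0,
                          triplet_entity_type_error = 0,
                          cross_sentence_drop = 0,
                          tag_corruption_rate = 0,
                          length_violation_rate = 0) {
  rates <- c(
    entity_omission, entity_spurious, entity_type_swap,
    entity_boundary_shift, triplet_entity_type_error, cross_sentence_drop,
    tag_corruption_rate, length_violation_rate
  )
  stopifnot(all(rates >= 0), all(rates <= 1))
  structure(
    list(
      entity_omission = entity_omission, entity_spurious = entity_spurious,
      entity_type_swap = entity_type_swap,
      entity_boundary_shift = entity_boundary_shift,
      triplet_entity_type_error = triplet_entity_type_error,
      cross_sentence_drop = cross_sentence_drop,
      tag_corruption_rate = tag_corruption_rate,
      length_violation_rate = length_violation_rate
    ),
    class = "error_profile"
  )
}

#' Default confusable-type swap table
#'
#' Mirrors the confusions observed in entity-classification confusion
#' matrices: biomarker, gene and target are mutually confusable, and
#' side effect and complication swap with each other.
#'
#' @return Named list mapping a type to its confusable alternatives.
#' @export
confusable_types <- function() {
  list(
    biomarker = c("gene", "target"),
    gene = c("biomarker", "target"),
    target = c("biomarker", "gene"),
    side_effect = "complication",
    complication = "side_effect"
  )
}

# types absent from the swap table are never swapped: the taxonomy's
# observed confusions are confined to semantically close categories
.swap_type <- function(type, swap_table) {
  alts <- swap_table[[type]]
  if (is.null(alts)) return(NA_character_)
  if (length(alts) == 1) alts else sample(alts, 1)
}

# tokens of the document not overlapping any gold entity anchor
.spurious_candidates <- function(gold) {
  e <- .anchor_entities(gold)
  occupied <- cbind(e$anchor_start, e$anchor_end)
  toks <- stringr::str_locate_all(gold$text, "[A-Za-z][A-Za-z-]{3,}")[[1]]
  keep <- apply(toks, 1, function(t) {
    s <- t[1] - 1; en <- t[2]
    !any(!is.na(occupied[, 1]) & occupied[, 1] < en & s < occupied[, 2])
  })
  toks <- toks[keep, , drop = FALSE]
  if (nrow(toks) == 0) return(character(0))
  unique(stringr::str_sub(gold$text, toks[, 1], toks[, 2]))
}

#' Perturb a gold annotation into a candidate prediction
#'
#' Applies each perturbation per item at its configured rate (an entity
#' receives at most one of omission, type swap, boundary shift, in that
#' priority): omission removes the entity and its dependent triplets;
#' spurious adds a non-gold phrase from the document under a random
#' type; type swap replaces the type with a confusable type (also in
#' triplets referencing the entity; types without a confusable
#' alternative in the swap table are left untouched, mirroring the
#' observed confusion structure); boundary shift extends or truncates
#' the surface by an adjacent token of the text; triplet endpoint
#' retyping alters the type inside the triplet only; cross-sentence drop
#' removes gold triplets whose endpoints sit in different sentences.
#' The injection log records every applied perturbation and is the
#' ground truth for recovery tests.
#'
#' @param gold A gold [document_annotation()].
#' @param profile An [error_profile()].
#' @param seed Integer seed.
#' @param swap_table Confusable-type table, default [confusable_types()].
#' @return List with `pred` (a `document_annotation`, `check = FALSE`)
#'   and `log` (tibble `doc_id`, `kind`, `target`, `replacement`).
#' @export
perturb_prediction <- function(gold, profile, seed,
                               swap_table = confusable_types()) {
  stopifnot(inherits(gold, "document_annotation"), inherits(profile, "error_profile"))
  withr::with_seed(seed, .perturb_impl(gold, profile, swap_table))
}

.perturb_impl <- function(gold, profile, swap_table) {
  log <- list()
  note <- function(kind, target, replacement = NA_character_) {
    log[[length(log) + 1]] <<- tibble::tibble(
      doc_id = gold$doc_id, kind = kind, target = target,
      replacement = replacement
    )
  }
  ents <- gold$entities
  trips <- gold$triplets
  drop_ent <- rep(FALSE, nrow(ents))

  rename_in_triplets <- function(trips, old_s, old_t, new_s, new_t) {
    hi <- trips$head == old_s & trips$head_type == old_t
    trips$head[hi] <- new_s; trips$head_type[hi] <- new_t
    ti <- trips$tail == old_s & trips$tail_type == old_t
    trips$tail[ti] <- new_s; trips$tail_type[ti] <- new_t
    trips
  }

  for (i in seq_len(nrow(ents))) {
    s <- ents$surface[i]; ty <- ents$type[i]
    if (stats::runif(1) < profile$entity_omission) {
      drop_ent[i] <- TRUE
      dep <- (trips$head == s & trips$head_type == ty) |
        (trips$tail == s & trips$tail_type == ty)
      trips <- trips[!dep, , drop = FALSE]
      note("entity_omission", s)
      next
    }
    if (stats::runif(1) < profile$entity_type_swap) {
      new_ty <- .swap_type(ty, swap_table)
      if (!is.na(new_ty)) {
        trips <- rename_in_triplets(trips, s, ty, s, new_ty)
        ents$type[i] <- new_ty
        note("entity_type_swap", paste0(s, "/", ty), new_ty)
        next
      }
    }
    if (stats::runif(1) < profile$entity_boundary_shift) {
      new_s <- .shift_boundary(gold$text, s)
      if (!is.na(new_s)) {
        trips <- rename_in_triplets(trips, s, ty, new_s, ty)
        ents$surface[i] <- new_s
        ents$start[i] <- NA_integer_; ents$end[i] <- NA_integer_
        note("entity_boundary_shift", s, new_s)
      }
    }
  }
  ents <- ents[!drop_ent, , drop = FALSE]

  # spurious additions: expected count = rate * n_gold_entities
  cands <- NULL
  for (k in seq_len(nrow(gold$entities))) {
    if (stats::runif(1) < profile$entity_spurious) {
      if (is.null(cands)) cands <- .spurious_candidates(gold)
      cands <- setdiff(cands, ents$surface)
      if (length(cands) == 0) next
      s <- if (length(cands) == 1) cands else sample(cands, 1)
      ty <- sample(entity_types(), 1)
      ents <- dplyr::bind_rows(ents, tibble::tibble(
        surface = s, type = ty, start = NA_integer_, end = NA_integer_
      ))
      note("entity_spurious", s, ty)
    }
  }

  # triplet endpoint retyping, confined to confusable endpoint types
  if (nrow(trips) > 0) {
    for (k in seq_len(nrow(trips))) {
      if (stats::runif(1) < profile$triplet_entity_type_error) {
        eligible <- c("head", "tail")[c(
          trips$head_type[k] %in% names(swap_table),
          trips$tail_type[k] %in% names(swap_table)
        )]
        if (length(eligible) == 0) next
        end <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        tycol <- paste0(end, "_type")
        old <- trips[[tycol]][k]
        trips[[tycol]][k] <- .swap_type(old, swap_table)
        note(
          "triplet_entity_type_error",
          paste0("(", trips$head[k], ", ", trips$relation[k], ", ", trips$tail[k], ")"),
          paste0(end, ": ", old, " -> ", trips[[tycol]][k])
        )
      }
    }
  }

  # cross-sentence drops
  if (nrow(trips) > 0) {
    e <- .anchor_entities(gold)
    akey <- paste(e$surface, e$type, sep = "\r")
    sent_of <- function(s, ty) {
      i <- match(paste(s, ty, sep = "\r"), akey)
      if (is.na(i)) return(NA_integer_)
      .sentence_of(e$anchor_start[i], gold$sentence_bounds)
    }
    keep <- rep(TRUE, nrow(trips))
    for (k in seq_len(nrow(trips))) {
      hs <- sent_of(trips$head[k], trips$head_type[k])
      ts <- sent_of(trips$tail[k], trips$tail_type[k])
      if (!is.na(hs) && !is.na(ts) && hs != ts &&
          stats::runif(1) < profile$cross_sentence_drop) {
        keep[k] <- FALSE
        note(
          "cross_sentence_drop",
          paste0("(", trips$head[k], ", ", trips$relation[k], ", ", trips$tail[k], ")")
        )
      }
    }
    trips <- trips[keep, , drop = FALSE]
  }

  pred <- document_annotation(
    gold$doc_id, gold$text,
    entities = ents, triplets = trips,
    sentence_bounds = gold$sentence_bounds, check = FALSE
  )
  log_tbl <- if (length(log)) {
    dplyr::bind_rows(log)
  } else {
    tibble::tibble(
      doc_id = character(), kind = character(), target = character(),
      replacement = character()
    )
  }
  list(pred = pred, log = log_tbl)
}

# extend the surface by the following token of the text, else truncate
# the last token of a multiword surface, else prepend the previous token
.shift_boundary <- function(text, surface) {
  loc <- stringr::str_locate(text, stringr::fixed(surface))
  if (is.na(loc[1, 1])) return(NA_character_)
  after <- stringr::str_sub(text, loc[1, 2] + 1)
  m <- stringr::str_match(after, "^ ([A-Za-z-]+)")
  if (!is.na(m[1, 2])) return(paste(surface, m[1, 2]))
  words <- strsplit(surface, " ", fixed = TRUE)[[1]]
  if (length(words) > 1) {
    return(paste(utils::head(words, -1), collapse = " "))
  }
  before <- stringr::str_sub(text, 1, loc[1, 1] - 1)
  m <- stringr::str_match(before, "([A-Za-z-]+) $")
  if (!is.na(m[1, 2])) return(paste(m[1, 2], surface))
  NA_character_
}

#' Render a chain-of-thought model output for an annotation
#'
#' Produces the canonical output layout: one `<think>` block holding at
#' least three `<step>` sections of templated reasoning padded (or
#' truncated) so the think-content character count equals
#' `think_length`, followed by the two-root-key JSON payload. With
#' `tag_ok = FALSE` a single random tag corruption (drop, duplicate, or
#' transpose of one tag token) is applied, which is guaranteed to break
#' tag integrity. [parse_prediction()] recovers the annotation whenever
#' `tag_ok = TRUE`.
#'
#' @param pred A [document_annotation()] (possibly empty).
#' @param tag_ok Emit intact tags (default) or corrupt one.
#' @param think_length Target think-content length in characters.
#' @param seed Integer seed (used for the corruption choice).
#' @return The raw output text.
#' @export
render_model_output <- function(pred, tag_ok = TRUE, think_length = 600L,
                                seed = 1L) {
  stopifnot(inherits(pred, "document_annotation"), think_length >= 0)
  n_e <- nrow(pred$entities); n_t <- nrow(pred$triplets)
  steps <- c(
    "Task framing: extracting schema-conformant drug-repositioning knowledge from the passage.",
    sprintf(
      "Entity identification: %d candidate mention(s) typed against the 11-type schema%s.",
      n_e,
      if (n_e > 0) {
        paste0(
          ", e.g. '", pred$entities$surface[1], "' as ", pred$entities$type[1]
        )
      } else ""
    ),
    sprintf(
      "Relation reasoning: %d candidate triplet(s) checked against type-compatibility constraints.",
      n_t
    ),
    "Formatting: emitting JSON with two root keys and original casing preserved."
  )
  body <- paste(steps, collapse = "")
  if (think_length == 0) {
    steps <- c("", "", "")
  } else if (nchar(body) >= think_length) {
    body <- stringr::str_sub(body, 1, think_length)
    cut <- max(1, floor(think_length / 3))
    steps <- c(
      stringr::str_sub(body, 1, cut),
      stringr::str_sub(body, cut + 1, 2 * cut),
      stringr::str_sub(body, 2 * cut + 1)
    )
  } else {
    filler <- strrep("Further consideration of the contextual evidence. ", 200)
    pad <- stringr::str_sub(filler, 1, think_length - nchar(body))
    steps[length(steps)] <- paste0(steps[length(steps)], pad)
  }
  think <- paste0(
    "<think>",
    paste0("<step>", steps, "</step>", collapse = ""),
    "</think>"
  )
  raw <- paste0(think, "\n", serialize_annotation(pred))
  if (!tag_ok) raw <- withr::with_seed(seed, .corrupt_one_tag(raw))
  raw
}

.corrupt_one_tag <- function(raw) {
  locs <- stringr::str_locate_all(raw, "</?(think|step)>")[[1]]
  n <- nrow(locs)
  mode <- sample(c("drop", "duplicate", "transpose"), 1)
  if (mode == "transpose" && n < 2) mode <- "drop"
  if (mode == "drop") {
    i <- sample.int(n, 1)
    return(paste0(
      stringr::str_sub(raw, 1, locs[i, 1] - 1),
      stringr::str_sub(raw, locs[i, 2] + 1)
    ))
  }
  if (mode == "duplicate") {
    i <- sample.int(n, 1)
    tok <- stringr::str_sub(raw, locs[i, 1], locs[i, 2])
    return(paste0(
      stringr::str_sub(raw, 1, locs[i, 2]), tok,
      stringr::str_sub(raw, locs[i, 2] + 1)
    ))
  }
  i <- sample.int(n - 1, 1)
  tok1 <- stringr::str_sub(raw, locs[i, 1], locs[i, 2])
  tok2 <- stringr::str_sub(raw, locs[i + 1, 1], locs[i + 1, 2])
  paste0(
    stringr::str_sub(raw, 1, locs[i, 1] - 1),
    tok2,
    stringr::str_sub(raw, locs[i, 2] + 1, locs[i + 1, 1] - 1),
    tok1,
    stringr::str_sub(raw, locs[i + 1, 2] + 1)
  )
}

#' Simulate an end-to-end extraction run
#'
#' Generates a gold corpus, perturbs each document into a candidate
#' prediction per the error profile, and renders raw chain-of-thought
#' outputs (corrupting tags or violating the length window at the
#' profile's document-level rates). The injection log is returned as
#' ground truth.
#'
#' @param cfg A [generator_config()].
#' @param profile An [error_profile()].
#' @param w [reward_weights()] supplying the length window for
#'   violation rendering.
#' @param think_length In-range think length used for clean renderings.
#' @return List with `gold`, `pred` (lists of annotations), `outputs`
#'   (tibble `doc_id`, `output_text`), and `log`.
#' @export
simulate_extraction <- function(cfg, profile = error_profile(),
                                w = reward_weights(), think_length = 600L) {
  gold <- generate_gold_corpus(cfg)
  seeds <- withr::with_seed(
    cfg$seed, sample.int(.Machine$integer.max - 1L, max(1L, length(gold)) * 2L)
  )
  pred <- vector("list", length(gold))
  outputs <- vector("list", length(gold))
  logs <- vector("list", length(gold))
  for (i in seq_along(gold)) {
    pp <- perturb_prediction(gold[[i]], profile, seed = seeds[2 * i - 1])
    pred[[i]] <- pp$pred
    extra <- withr::with_seed(seeds[2 * i], stats::runif(2))
    corrupt <- extra[1] < profile$tag_corruption_rate
    len <- if (extra[2] < profile$length_violation_rate) 0L else think_length
    outputs[[i]] <- tibble::tibble(
      doc_id = gold[[i]]$doc_id,
      output_text = render_model_output(
        pp$pred, tag_ok = !corrupt, think_length = len, seed = seeds[2 * i]
      )
    )
    logs[[i]] <- pp$log
  }
  list(
    gold = gold, pred = pred,
    outputs = dplyr::bind_rows(outputs),
    log = dplyr::bind_rows(logs)
  )
}
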