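.SCHEMA_VERSION <- "1.0"

#' Read and write annotation corpora as JSONL
#'
#' One JSON object per line with fields `schema_version`, `doc_id`,
#' `text`, `sentence_bounds` (list of `[start, end]` pairs), `entities`
#' (`surface`, `type`, optional `start`/`end`) and `triplets` (`head`,
#' `head_type`, `relation`, `tail`, `tail_type`). The round trip is
#' lossless; reading validates each record's structure and reports the
#' offending line number on failure. Duplicate `doc_id`s are an error.
#'
#' @param path File path.
#' @param corpus List of [document_annotation()] objects.
#' @return `read_corpus()` returns the list of annotations;
#'   `write_corpus()` returns `path` invisibly.
#' @export
read_corpus <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[stringr::str_trim(lines) != ""]
  docs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (is.null(rec)) stop("Malformed JSON on line ", i, call. = FALSE)
    for (f in c("doc_id", "text")) {
      if (is.null(rec[[f]])) {
        stop("Record on line ", i, " missing required field '", f, "'",
          call. = FALSE
        )
      }
    }
    ents <- purrr::map_dfr(rec$entities, function(e) {
      if (is.null(e$surface) || is.null(e$type)) {
        stop("Entity missing surface/type on line ", i, call. = FALSE)
      }
      tibble::tibble(
        surface = e$surface, type = e$type,
        start = if (is.null(e$start)) NA_integer_ else as.integer(e$start),
        end = if (is.null(e$end)) NA_integer_ else as.integer(e$end)
      )
    })
    trips <- purrr::map_dfr(rec$triplets, function(t) {
      need <- c("head", "head_type", "relation", "tail", "tail_type")
      if (any(vapply(need, function(f) is.null(t[[f]]), logical(1)))) {
        stop("Triplet missing fields on line ", i, call. = FALSE)
      }
      tibble::as_tibble(t[need])
    })
    sb <- if (length(rec$sentence_bounds)) {
      tibble::tibble(
        start = vapply(rec$sentence_bounds, function(b) as.integer(b[[1]]), integer(1)),
        end = vapply(rec$sentence_bounds, function(b) as.integer(b[[2]]), integer(1))
      )
    } else {
      NULL
    }
    docs[[i]] <- tryCatch(
      document_annotation(
        rec$doc_id, rec$text,
        entities = if (nrow(ents)) ents else empty_entities(),
        triplets = if (nrow(trips)) trips else empty_triplets(),
        sentence_bounds = sb, check = FALSE
      ),
      error = function(e) {
        stop("Invalid record on line ", i, ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    ids[i] <- rec$doc_id
  }
  if (anyDuplicated(ids)) {
    stop(
      "Duplicate doc_id in corpus file: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  docs
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    ents <- purrr::pmap(doc$entities, function(surface, type, start, end) {
      e <- list(surface = surface, type = type)
      if (!is.na(start)) e$start <- start
      if (!is.na(end)) e$end <- end
      e
    })
    trips <- purrr::pmap(doc$triplets, function(head, head_type, relation, tail, tail_type) {
      list(
        head = head, head_type = head_type, relation = relation,
        tail = tail, tail_type = tail_type
      )
    })
    sb <- purrr::pmap(doc$sentence_bounds, function(start, end) c(start, end))
    as.character(jsonlite::toJSON(
      list(
        schema_version = .SCHEMA_VERSION, doc_id = doc$doc_id,
        text = doc$text, sentence_bounds = sb,
        entities = ents, triplets = trips
      ),
      auto_unbox = TRUE
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write raw model outputs as JSONL
#'
#' Records are `{doc_id, output_text}`.
#'
#' @param path File path.
#' @param outputs Tibble with columns `doc_id`, `output_text`.
#' @return `read_raw_outputs()` returns the tibble;
#'   `write_raw_outputs()` returns `path` invisibly.
#' @export
read_raw_outputs <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[stringr::str_trim(lines) != ""]
  purrr::map_dfr(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (is.null(rec) || is.null(rec$doc_id) || is.null(rec$output_text)) {
      stop("Malformed raw-output record on line ", i, call. = FALSE)
    }
    tibble::tibble(doc_id = rec$doc_id, output_text = rec$output_text)
  })
}

#' @rdname read_raw_outputs
#' @export
write_raw_outputs <- function(outputs, path) {
  lines <- vapply(seq_len(nrow(outputs)), function(i) {
    as.character(jsonlite::toJSON(
      list(doc_id = outputs$doc_id[i], output_text = outputs$output_text[i]),
      auto_unbox = TRUE
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.KNOWN_CONFIG_KEYS <- c("weights", "compatibility", "rarity_threshold", "generator")
.KNOWN_WEIGHT_KEYS <- c(
  "alpha", "beta_triplet", "gamma", "delta", "epsilon_length",
  "w_acc", "w_fmt", "partial_credit", "length_bounds", "case_sensitive"
)
.KNOWN_GENERATOR_KEYS <- c(
  "n_docs", "entity_mixture", "relation_mixture", "entities_per_doc",
  "triplets_per_doc", "sentences_per_doc", "cross_sentence_fraction", "seed"
)

#' Read the YAML configuration
#'
#' One YAML file carries the schema compatibility table, the rarity
#' threshold, the reward weights, and generator settings; unknown keys
#' are rejected rather than silently ignored. All sections are
#' optional; omitted settings fall back to package defaults. A
#' documented default file ships at
#' `system.file("extdata", "default-config.yaml", package = "drkex")`.
#'
#' @param path Path to a YAML file.
#' @return List with elements `weights` ([reward_weights()]),
#'   `compat` (compatibility tibble), `rarity_threshold`, and
#'   `generator` ([generator_config()] or `NULL`).
#' @export
read_ke_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .reject_unknown(cfg, .KNOWN_CONFIG_KEYS, "top level")
  weights <- if (!is.null(cfg$weights)) {
    .reject_unknown(cfg$weights, .KNOWN_WEIGHT_KEYS, "weights")
    do.call(reward_weights, cfg$weights)
  } else {
    reward_weights()
  }
  compat <- if (!is.null(cfg$compatibility)) {
    purrr::imap_dfr(cfg$compatibility, function(pairs, rel) {
      rel <- normalize_relation(rel)
      purrr::map_dfr(pairs, function(p) {
        if (length(p) != 2) {
          stop("compatibility entries must be [head_type, tail_type] pairs",
            call. = FALSE
          )
        }
        tibble::tibble(
          relation = rel,
          head_type = normalize_entity_type(p[[1]]),
          tail_type = normalize_entity_type(p[[2]])
        )
      })
    })
  } else {
    default_compatibility()
  }
  miss <- setdiff(unique(compat$relation), canonical_relations())
  if (length(miss)) {
    stop("Non-canonical relation in compatibility table: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  generator <- if (!is.null(cfg$generator)) {
    .reject_unknown(cfg$generator, .KNOWN_GENERATOR_KEYS, "generator")
    g <- cfg$generator
    for (f in c("entity_mixture", "relation_mixture")) {
      if (!is.null(g[[f]])) g[[f]] <- unlist(g[[f]])
    }
    for (f in c("entities_per_doc", "triplets_per_doc", "sentences_per_doc")) {
      if (!is.null(g[[f]])) g[[f]] <- as.integer(unlist(g[[f]]))
    }
    do.call(generator_config, g)
  } else {
    NULL
  }
  list(
    weights = weights, compat = compat,
    rarity_threshold = cfg$rarity_threshold %||% 0.05,
    generator = generator
  )
}

.reject_unknown <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop(
      "Unknown config key(s) at ", where, ": ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}
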