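#' Construct a document annotation
#'
#' The unit of scoring and evaluation: a document's text together with
#' its (gold or predicted) entity mentions and relation triplets.
#' Surfaces keep the original casing of the text. Character offsets,
#' where present, are 0-based half-open intervals into `text`; the
#' quintuple output dialect carries no offsets, so they are optional and
#' absent surfaces are anchored by first exact substring occurrence.
#'
#' @param doc_id Document identifier.
#' @param text Document text.
#' @param entities Data frame with columns `surface`, `type` and
#'   optionally `start`, `end` (0-based half-open).
#' @param triplets Data frame with columns `head`, `head_type`,
#'   `relation`, `tail`, `tail_type`.
#' @param sentence_bounds Data frame with columns `start`, `end`
#'   (0-based half-open intervals partitioning `text`), or `NULL` to
#'   derive them with [sentence_bounds_from_text()].
#' @param check Enforce structural invariants (non-empty surfaces, span
#'   agreement, ordered sentence bounds, triplet endpoints present among
#'   entities, distinct head/tail). Predicted annotations produced by a
#'   model may legitimately break the endpoint-coverage invariant, so
#'   parsers and perturbers construct with `check = FALSE`.
#' @return An object of class `document_annotation`.
#' @export
#' @examples
#' document_annotation(
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
document_annotation <- function(doc_id, text, entities = empty_entities(),
                                triplets = empty_triplets(),
                                sentence_bounds = NULL, check = TRUE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  entities <- tibble::as_tibble(entities)
  triplets <- tibble::as_tibble(triplets)
  if (nrow(entities) > 0) {
    entities$surface <- as.character(entities$surface)
    entities$type <- normalize_entity_type(entities$type, strict = check)
  } else {
    entities <- empty_entities()
  }
  if (!"start" %in% names(entities)) entities$start <- NA_integer_
  if (!"end" %in% names(entities)) entities$end <- NA_integer_
  if (nrow(triplets) > 0) {
    triplets$relation <- normalize_relation(triplets$relation, strict = check)
    triplets$head_type <- normalize_entity_type(triplets$head_type, strict = check)
    triplets$tail_type <- normalize_entity_type(triplets$tail_type, strict = check)
  } else {
    triplets <- empty_triplets()
  }
  if (is.null(sentence_bounds)) {
    sentence_bounds <- sentence_bounds_from_text(text)
  } else {
    sentence_bounds <- tibble::as_tibble(sentence_bounds)
  }

  doc <- structure(
    list(
      doc_id = doc_id, text = text, sentence_bounds = sentence_bounds,
      entities = entities, triplets = triplets
    ),
    class = "document_annotation"
  )
  if (check) .check_structure(doc)
  doc
}

#' @rdname document_annotation
#' @export
empty_entities <- function() {
  tibble::tibble(
    surface = character(), type = character(),
    start = integer(), end = integer()
  )
}

#' @rdname document_annotation
#' @export
empty_triplets <- function() {
  tibble::tibble(
    head = character(), head_type = character(), relation = character(),
    tail = character(), tail_type = character()
  )
}

.check_structure <- function(doc) {
  e <- doc$entities
  if (any(stringr::str_trim(e$surface) == "")) {
    stop("Entity surface empty after whitespace trim", call. = FALSE)
  }
  has_span <- !is.na(e$start) & !is.na(e$end)
  if (any(has_span)) {
    got <- stringr::str_sub(doc$text, e$start[has_span] + 1, e$end[has_span])
    if (any(got != e$surface[has_span])) {
      stop("Entity span does not match surface text", call. = FALSE)
    }
  }
  sb <- doc$sentence_bounds
  if (nrow(sb) > 0) {
    if (any(sb$start < 0) || any(sb$end > nchar(doc$text)) ||
        any(sb$end <= sb$start)) {
      stop("sentence_bounds outside text or empty", call. = FALSE)
    }
    if (is.unsorted(sb$start) || any(utils::head(sb$end, -1) > sb$start[-1])) {
      stop("sentence_bounds overlapping or unordered", call. = FALSE)
    }
  }
  t <- doc$triplets
  if (nrow(t) > 0) {
    key <- paste(e$surface, e$type, sep = "\r")
    miss <- !(paste(t$head, t$head_type, sep = "\r") %in% key) |
      !(paste(t$tail, t$tail_type, sep = "\r") %in% key)
    if (any(miss)) {
      stop("Triplet endpoint not present among entities", call. = FALSE)
    }
    if (any(t$head == t$tail & t$head_type == t$tail_type)) {
      stop("Triplet head and tail must be distinct (surface, type) pairs",
        call. = FALSE
      )
    }
  }
  invisible(doc)
}

#' @export
print.document_annotation <- function(x, ...) {
  cat(
    sprintf(
      "<document_annotation> %s: %d chars, %d sentences, %d entities, %d triplets\n",
      x$doc_id, nchar(x$text), nrow(x$sentence_bounds),
      nrow(x$entities), nrow(x$triplets)
    )
  )
  invisible(x)
}

#' @export
format.document_annotation <- function(x, ...) {
  sprintf("<document_annotation %s>", x$doc_id)
}

#' Fallback sentence segmentation
#'
#' Splits on `.`, `?`, `!` followed by whitespace or end of text.
#' Generator-produced documents carry exact bounds by construction; this
#' splitter is only the fallback for external text.
#'
#' @param text Document text.
#' @return Tibble with 0-based half-open `start`, `end` columns.
#' @export
sentence_bounds_from_text <- function(text) {
  if (nchar(text) == 0) return(tibble::tibble(start = integer(), end = integer()))
  ends <- stringr::str_locate_all(text, "[.?!](\\s+|$)")[[1]]
  stops <- if (nrow(ends) > 0) ends[, "start"] else integer()
  if (length(stops) == 0 || max(stops) < nchar(text)) {
    stops <- c(stops, nchar(text))
  }
  starts <- c(0L, utils::head(stops, -1))
  # trim leading whitespace of each sentence
  for (i in seq_along(starts)) {
    while (starts[i] < stops[i] &&
           stringr::str_sub(text, starts[i] + 1, starts[i] + 1) %in% c(" ", "\n", "\t")) {
      starts[i] <- starts[i] + 1L
    }
  }
  keep <- stops > starts
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(stops[keep]))
}

# Anchor each entity to a character interval: declared span when present,
# else first exact occurrence of the surface. Returns entities with
# anchor_start/anchor_end (NA when unanchorable).
.anchor_entities <- function(doc) {
  e <- doc$entities
  n <- nrow(e)
  a_start <- rep(NA_integer_, n)
  a_end <- rep(NA_integer_, n)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (!is.na(e$start[i]) && !is.na(e$end[i])) {
        a_start[i] <- e$start[i]; a_end[i] <- e$end[i]
      } else {
        hit <- stringr::str_locate(doc$text, stringr::fixed(e$surface[i]))
        if (!is.na(hit[1, 1])) {
          a_start[i] <- hit[1, 1] - 1L
          a_end[i] <- hit[1, 2]
        }
      }
    }
  }
  e$anchor_start <- a_start
  e$anchor_end <- a_end
  e
}

.sentence_of <- function(pos, bounds) {
  # sentence index containing 0-based position, NA if none
  if (is.na(pos) || nrow(bounds) == 0) return(NA_integer_)
  i <- which(bounds$start <= pos & pos < bounds$end)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Validate an annotation against the schema's annotation principles
#'
#' Applies the annotation lints: no surface typed twice
#' (`OVERLAP_TYPE_CONFLICT`), no entity span strictly nested in another
#' (`NESTED_ENTITY`), minimal punctuation/conjunction at surface edges
#' (`PUNCTUATION_EDGE`), only one direction retained per related pair
#' (`BIDIRECTIONAL_PAIR`), intrasentence priority
#' (`CROSS_SENTENCE_WITH_INTRA_ALTERNATIVE`), relation/type
#' compatibility (`INCOMPATIBLE_RELATION`), and surfaces anchored in the
#' text (`UNANCHORED_SURFACE`). Violations are data, not errors: an
#' empty result means the annotation is valid.
#'
#' @param doc A [document_annotation()].
#' @param compat Compatibility table, default [default_compatibility()].
#' @return A tibble with columns `code`, `item`, `detail` (zero rows
#'   when valid).
#' @export
validate_annotation <- function(doc, compat = default_compatibility()) {
  stopifnot(inherits(doc, "document_annotation"))
  v <- list()
  add <- function(code, item, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(code = code, item = item, detail = detail)
  }
  e <- .anchor_entities(doc)

  # OVERLAP_TYPE_CONFLICT: one surface string, multiple entity types
  if (nrow(e) > 0) {
    conf <- e |>
      dplyr::distinct(.data$surface, .data$type) |>
      dplyr::count(.data$surface) |>
      dplyr::filter(.data$n > 1)
    for (s in conf$surface) {
      types <- sort(unique(e$type[e$surface == s]))
      add("OVERLAP_TYPE_CONFLICT", s, paste("types:", paste(types, collapse = ", ")))
    }
  }

  # UNANCHORED_SURFACE
  un <- which(is.na(e$anchor_start))
  for (i in un) add("UNANCHORED_SURFACE", e$surface[i], "surface not found in text")

  # NESTED_ENTITY: strict containment of anchored spans
  anch <- e[!is.na(e$anchor_start), , drop = FALSE]
  if (nrow(anch) > 1) {
    for (i in seq_len(nrow(anch))) {
      for (j in seq_len(nrow(anch))) {
        if (i == j) next
        outer_longer <- (anch$anchor_end[i] - anch$anchor_start[i]) >
          (anch$anchor_end[j] - anch$anchor_start[j])
        if (outer_longer &&
            anch$anchor_start[i] <= anch$anchor_start[j] &&
            anch$anchor_end[j] <= anch$anchor_end[i]) {
          add(
            "NESTED_ENTITY", anch$surface[j],
            paste("nested inside", anch$surface[i])
          )
        }
      }
    }
  }

  # PUNCTUATION_EDGE: leading/trailing punctuation or framing conjunction
  if (nrow(e) > 0) {
    bad <- stringr::str_detect(e$surface, "^[[:punct:]]|[[:punct:]]$") |
      stringr::str_detect(tolower(e$surface), "^(and|or)\\s|\\s(and|or)$")
    for (i in which(bad)) {
      add("PUNCTUATION_EDGE", e$surface[i], "punctuation or conjunction at surface edge")
    }
  }

  t <- doc$triplets
  if (nrow(t) > 0) {
    ct <- canonicalize_triplets(t)

    # BIDIRECTIONAL_PAIR: >1 triplet with the same canonical relation
    # between the same unordered entity pair
    ep <- function(s, ty) paste(s, ty, sep = "\r")
    a <- ep(ct$head, ct$head_type); b <- ep(ct$tail, ct$tail_type)
    lo <- pmin(a, b); hi <- pmax(a, b)
    pair_key <- paste(ct$relation, lo, hi, sep = "\n")
    dup <- names(which(table(pair_key) > 1))
    for (k in dup) {
      i <- which(pair_key == k)[1]
      add(
        "BIDIRECTIONAL_PAIR",
        paste0("(", ct$head[i], ", ", ct$relation[i], ", ", ct$tail[i], ")"),
        "both directions (or duplicates) present for one entity pair"
      )
    }

    # INCOMPATIBLE_RELATION against the compatibility table
    ck <- paste(compat$relation, compat$head_type, compat$tail_type)
    bad <- !(paste(ct$relation, ct$head_type, ct$tail_type) %in% ck)
    for (i in which(bad)) {
      add(
        "INCOMPATIBLE_RELATION",
        paste0("(", ct$head[i], "/", ct$head_type[i], ", ", ct$relation[i],
               ", ", ct$tail[i], "/", ct$tail_type[i], ")"),
        "head/tail types not admissible for this relation"
      )
    }

    # CROSS_SENTENCE_WITH_INTRA_ALTERNATIVE: intrasentence priority.
    # A cross-sentence triplet is flagged when some intrasentence triplet
    # with the same canonical relation shares an endpoint with it.
    akey <- ep(e$surface, e$type)
    sent_of_ep <- function(s, ty) {
      i <- match(ep(s, ty), akey)
      if (is.na(i)) return(NA_integer_)
      .sentence_of(e$anchor_start[i], doc$sentence_bounds)
    }
    hs <- mapply(sent_of_ep, ct$head, ct$head_type)
    ts <- mapply(sent_of_ep, ct$tail, ct$tail_type)
    cross <- !is.na(hs) & !is.na(ts) & hs != ts
    intra <- !is.na(hs) & !is.na(ts) & hs == ts
    for (i in which(cross)) {
      shares <- intra & ct$relation == ct$relation[i] &
        (a == a[i] | b == b[i] | a == b[i] | b == a[i])
      shares[i] <- FALSE
      if (any(shares)) {
        add(
          "CROSS_SENTENCE_WITH_INTRA_ALTERNATIVE",
          paste0("(", ct$head[i], ", ", ct$relation[i], ", ", ct$tail[i], ")"),
          "an intrasentence triplet with the same relation exists"
        )
      }
    }
  }

  if (length(v) == 0) {
    tibble::tibble(code = character(), item = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}
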