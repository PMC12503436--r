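#' Check think/step tag integrity of raw model output
#'
#' Model outputs are required to wrap their complete reasoning in a
#' single `<think>...</think>` block containing one or more nested
#' `<step>...</step>` sections. This check scans the four tag tokens
#' with a stack and reports: balanced counts, well-nestedness (closing
#' tags match the innermost open tag; `<step>` only directly inside
#' `<think>`; no nested `<think>` or nested `<step>`), closure order (no
#' closing tag before its opening tag), and the overall verdict
#' `tag_integrity_ok` which additionally requires exactly one think
#' block with at least one step inside it. All non-tag text is ignored.
#'
#' @param raw Arbitrary text.
#' @return A `tag_report`: a one-row tibble with columns
#'   `think_open_count`, `think_close_count`, `step_open_count`,
#'   `step_close_count`, `well_nested`, `closure_ordered`,
#'   `tag_integrity_ok`.
#' @export
#' @examples
#' check_tag_integrity("<think><step>a</step></think>{}")
#' check_tag_integrity("</think><step>a</step><think>")
check_tag_integrity <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  toks <- .tag_tokens(raw)
  report <- .scan_tags(toks)
  class(report) <- c("tag_report", class(report))
  report
}

.tag_tokens <- function(raw) {
  m <- stringr::str_extract_all(raw, "</?(think|step)>")[[1]]
  m
}

.scan_tags <- function(toks) {
  n_to <- sum(toks == "<think>"); n_tc <- sum(toks == "</think>")
  n_so <- sum(toks == "<step>"); n_sc <- sum(toks == "</step>")
  stack <- character()
  well_nested <- TRUE
  closure_ordered <- TRUE
  steps_in_think <- 0L
  open_think <- 0L; open_step <- 0L
  for (tok in toks) {
    if (tok == "<think>") {
      if (length(stack) > 0) well_nested <- FALSE # think must be top-level
      stack <- c(stack, "think"); open_think <- open_think + 1L
    } else if (tok == "<step>") {
      if (length(stack) == 0 || stack[length(stack)] != "think") {
        well_nested <- FALSE # step only directly inside think
      }
      if (length(stack) > 0 && stack[length(stack)] == "think") {
        steps_in_think <- steps_in_think + 1L
      }
      stack <- c(stack, "step"); open_step <- open_step + 1L
    } else if (tok == "</think>") {
      if (open_think == 0L) closure_ordered <- FALSE
      if (length(stack) == 0 || stack[length(stack)] != "think") {
        well_nested <- FALSE
      } else {
        stack <- stack[-length(stack)]; open_think <- open_think - 1L
      }
    } else if (tok == "</step>") {
      if (open_step == 0L) closure_ordered <- FALSE
      if (length(stack) == 0 || stack[length(stack)] != "step") {
        well_nested <- FALSE
      } else {
        stack <- stack[-length(stack)]; open_step <- open_step - 1L
      }
    }
  }
  if (length(stack) > 0) well_nested <- FALSE
  balanced <- (n_to == n_tc) && (n_so == n_sc)
  ok <- balanced && well_nested && closure_ordered &&
    n_to == 1L && steps_in_think >= 1L
  tibble::tibble(
    think_open_count = n_to, think_close_count = n_tc,
    step_open_count = n_so, step_close_count = n_sc,
    well_nested = well_nested, closure_ordered = closure_ordered,
    tag_integrity_ok = ok
  )
}

#' Extract the reasoning trace from raw model output
#'
#' Returns the `<step>` contents in document order plus the total think
#' length. Length is counted in characters of the think-block interior
#' with all four tag tokens removed (characters chosen over tokens for
#' tokenizer independence), so whitespace between tags counts but the
#' tags themselves do not. When no well-formed think block exists the
#' trace is empty with length 0.
#'
#' @param raw Arbitrary text.
#' @return A `reasoning_trace`: list with `steps` (character vector) and
#'   `total_length` (integer).
#' @export
#' @examples
#' extract_reasoning("<think><step>xy</step></think>")
extract_reasoning <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  empty <- structure(
    list(steps = character(), total_length = 0L),
    class = "reasoning_trace"
  )
  interior <- .think_interior(raw)
  if (is.null(interior)) return(empty)
  steps <- stringr::str_match_all(interior, "(?s)<step>(.*?)</step>")[[1]]
  steps <- if (nrow(steps) > 0) steps[, 2] else character()
  stripped <- stringr::str_remove_all(interior, "</?step>")
  structure(
    list(steps = steps, total_length = nchar(stripped)),
    class = "reasoning_trace"
  )
}

# interior of the first well-formed think block, or NULL
.think_interior <- function(raw) {
  open <- stringr::str_locate(raw, stringr::fixed("<think>"))
  if (is.na(open[1, 1])) return(NULL)
  rest_from <- open[1, 2] + 1
  close <- stringr::str_locate(stringr::str_sub(raw, rest_from), stringr::fixed("</think>"))
  if (is.na(close[1, 1])) return(NULL)
  stringr::str_sub(raw, rest_from, rest_from + close[1, 1] - 2)
}

#' @export
print.reasoning_trace <- function(x, ...) {
  cat(sprintf(
    "<reasoning_trace> %d steps, %d think characters\n",
    length(x$steps), x$total_length
  ))
  invisible(x)
}

#' Parse a prediction payload from raw model output
#'
#' Locates the JSON payload outside the think block — taken as the last
#' balanced top-level JSON object carrying both root keys `Entities` and
#' `Relationships` (models often echo examples first, so recency wins) —
#' and converts it to a [document_annotation()]. `Entities` entries
#' carry a surface and a type; `Relationships` entries are quintuples
#' `{Entity1; Type1; Relationship; Entity2; Type2}`. Entity-type and
#' relation strings are alias-normalized, so unknown casing is not an
#' error.
#'
#' In `strict` mode any malformed entry, unknown type, or unregistered
#' relation is fatal (no annotation is returned); in `lenient` mode —
#' the default for reward computation, where a reward must exist for any
#' sample — malformed entries are dropped with diagnostics and the rest
#' kept.
#'
#' @param raw Raw model output text.
#' @param mode `"lenient"` or `"strict"`.
#' @param doc_id,text Carried into the resulting annotation.
#' @return A `parsed_output`: list with `tag_report`, `trace`,
#'   `annotation` (a `document_annotation` or `NULL`), and `diagnostics`
#'   (tibble with `severity`, `message`). The annotation is absent iff a
#'   fatal diagnostic exists.
#' @export
parse_prediction <- function(raw, mode = c("lenient", "strict"),
                             doc_id = "doc", text = "") {
  mode <- match.arg(mode)
  stopifnot(is.character(raw), length(raw) == 1L)
  tag_report <- check_tag_integrity(raw)
  trace <- extract_reasoning(raw)
  diags <- list()
  note <- function(severity, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(severity = severity, message = message)
  }

  payload <- .locate_payload(raw)
  ann <- NULL
  if (is.null(payload)) {
    note("fatal", "no JSON object with root keys Entities and Relationships found")
  } else {
    e_surface <- character(); e_type <- character()
    trips <- list(); fatal <- FALSE
    for (i in seq_along(payload$entities)) {
      p <- .coerce_entity(payload$entities[[i]])
      if (is.null(p)) {
        note(
          if (mode == "strict") "fatal" else "warning",
          sprintf("malformed entity entry %d dropped", i)
        )
        if (mode == "strict") fatal <- TRUE
        next
      }
      ty <- normalize_entity_type(p$type, strict = FALSE)
      if (is.na(ty)) {
        note(
          if (mode == "strict") "fatal" else "warning",
          sprintf("unknown entity type '%s' dropped", p$type)
        )
        if (mode == "strict") fatal <- TRUE
        next
      }
      e_surface <- c(e_surface, p$surface); e_type <- c(e_type, ty)
    }
    for (i in seq_along(payload$relationships)) {
      q <- .coerce_quintuple(payload$relationships[[i]])
      ok <- !is.null(q)
      if (ok) {
        rel <- normalize_relation(q$relation, strict = FALSE)
        ht <- normalize_entity_type(q$head_type, strict = FALSE)
        tt <- normalize_entity_type(q$tail_type, strict = FALSE)
        ok <- !is.na(rel) && !is.na(ht) && !is.na(tt)
      }
      if (!ok) {
        note(
          if (mode == "strict") "fatal" else "warning",
          sprintf("malformed or unregistered relationship entry %d dropped", i)
        )
        if (mode == "strict") fatal <- TRUE
        next
      }
      trips[[length(trips) + 1]] <- tibble::tibble(
        head = q$head, head_type = ht, relation = rel,
        tail = q$tail, tail_type = tt
      )
    }
    if (!fatal) {
      ann <- document_annotation(
        doc_id, text,
        entities = if (length(e_surface)) {
          tibble::tibble(surface = e_surface, type = e_type)
        } else {
          empty_entities()
        },
        triplets = if (length(trips)) dplyr::bind_rows(trips) else empty_triplets(),
        check = FALSE
      )
    }
  }

  diagnostics <- if (length(diags)) {
    dplyr::bind_rows(diags)
  } else {
    tibble::tibble(severity = character(), message = character())
  }
  structure(
    list(
      tag_report = tag_report, trace = trace,
      annotation = ann, diagnostics = diagnostics
    ),
    class = "parsed_output"
  )
}

#' @export
print.parsed_output <- function(x, ...) {
  cat(sprintf(
    "<parsed_output> tags ok: %s; %d steps; annotation: %s; %d diagnostics\n",
    x$tag_report$tag_integrity_ok, length(x$trace$steps),
    if (is.null(x$annotation)) "absent" else "present",
    nrow(x$diagnostics)
  ))
  invisible(x)
}

# Find the last balanced top-level JSON object outside think tags that
# parses and has both root keys (case-insensitive). Returns
# list(entities=, relationships=) of unsimplified lists, or NULL.
.locate_payload <- function(raw) {
  # mask the think interior so echoed examples inside reasoning are skipped
  open <- stringr::str_locate(raw, stringr::fixed("<think>"))
  close <- stringr::str_locate(raw, stringr::fixed("</think>"))
  if (!is.na(open[1, 1]) && !is.na(close[1, 1]) && close[1, 1] > open[1, 2]) {
    pad <- strrep(" ", close[1, 1] - open[1, 2] - 1)
    raw <- paste0(
      stringr::str_sub(raw, 1, open[1, 2]), pad,
      stringr::str_sub(raw, close[1, 1])
    )
  }
  spans <- .toplevel_object_spans(raw)
  for (i in rev(seq_len(nrow(spans)))) {
    txt <- stringr::str_sub(raw, spans$start[i], spans$end[i])
    obj <- tryCatch(
      jsonlite::fromJSON(txt, simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (is.null(obj) || !is.list(obj) || is.null(names(obj))) next
    keys <- tolower(names(obj))
    ei <- match("entities", keys); ri <- match("relationships", keys)
    if (is.na(ei) || is.na(ri)) next
    ents <- obj[[ei]]; rels <- obj[[ri]]
    if (!is.list(ents) && !is.null(ents)) next
    if (!is.list(rels) && !is.null(rels)) next
    return(list(
      entities = if (is.null(ents)) list() else ents,
      relationships = if (is.null(rels)) list() else rels
    ))
  }
  NULL
}

# spans (1-based inclusive) of balanced {...} regions at top level,
# respecting JSON strings and escapes; walks only the structurally
# relevant characters
.toplevel_object_spans <- function(raw) {
  # neutralize escape pairs (length-preserving) so quotes need no
  # lookbehind during the scan
  cleaned <- gsub("\\\\[\\s\\S]", "@@", raw, perl = TRUE)
  m <- gregexpr("[\"{}]", cleaned)[[1]]
  if (m[1] == -1) return(tibble::tibble(start = integer(), end = integer()))
  chars <- substring(cleaned, m, m)
  depth <- 0L; in_str <- FALSE
  starts <- integer(); ends <- integer(); cur <- NA_integer_
  for (k in seq_along(m)) {
    ch <- chars[k]
    if (ch == "\"") {
      if (depth > 0L) in_str <- !in_str
      next
    }
    if (in_str) next
    if (ch == "{") {
      if (depth == 0L) cur <- m[k]
      depth <- depth + 1L
    } else {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) { starts <- c(starts, cur); ends <- c(ends, m[k]) }
      }
    }
  }
  tibble::tibble(start = starts, end = ends)
}

.pick_key <- function(x, candidates) {
  keys <- tolower(names(x))
  for (k in candidates) {
    i <- match(k, keys)
    if (!is.na(i)) return(x[[i]])
  }
  NULL
}

.scalar_chr <- function(x) {
  if (is.character(x) && length(x) == 1L && !is.na(x) &&
      stringr::str_trim(x) != "") x else NULL
}

.coerce_entity <- function(entry) {
  if (is.list(entry) && !is.null(names(entry))) {
    s <- .scalar_chr(.pick_key(entry, c("entity", "surface", "text", "name")))
    ty <- .scalar_chr(.pick_key(entry, c("type", "etype", "entity_type")))
    if (!is.null(s) && !is.null(ty)) return(list(surface = s, type = ty))
    return(NULL)
  }
  if ((is.list(entry) || is.character(entry)) && length(entry) == 2L) {
    s <- .scalar_chr(as.character(entry[[1]]))
    ty <- .scalar_chr(as.character(entry[[2]]))
    if (!is.null(s) && !is.null(ty)) return(list(surface = s, type = ty))
  }
  NULL
}

.coerce_quintuple <- function(entry) {
  if (is.list(entry) && !is.null(names(entry))) {
    h <- .scalar_chr(.pick_key(entry, c("entity1", "head")))
    ht <- .scalar_chr(.pick_key(entry, c("type1", "head_type")))
    r <- .scalar_chr(.pick_key(entry, c("relationship", "relation")))
    t <- .scalar_chr(.pick_key(entry, c("entity2", "tail")))
    tt <- .scalar_chr(.pick_key(entry, c("type2", "tail_type")))
    if (!is.null(h) && !is.null(ht) && !is.null(r) && !is.null(t) && !is.null(tt)) {
      return(list(head = h, head_type = ht, relation = r, tail = t, tail_type = tt))
    }
    return(NULL)
  }
  if ((is.list(entry) || is.character(entry)) && length(entry) == 5L) {
    parts <- vapply(entry, function(p) {
      p <- .scalar_chr(as.character(p)); if (is.null(p)) NA_character_ else p
    }, character(1))
    if (!anyNA(parts)) {
      return(list(
        head = parts[1], head_type = parts[2], relation = parts[3],
        tail = parts[4], tail_type = parts[5]
      ))
    }
  }
  NULL
}

#' Serialize an annotation to the two-root-key JSON dialect
#'
#' Emits `{"Entities": [...], "Relationships": [...]}` with entity
#' entries `{entity, type}` and relationship entries the quintuple
#' `{entity1, type1, relationship, entity2, type2}`. Round-trips through
#' [parse_prediction()] up to span information.
#'
#' @param doc A [document_annotation()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
serialize_annotation <- function(doc, pretty = FALSE) {
  stopifnot(inherits(doc, "document_annotation"))
  ents <- purrr::pmap(
    doc$entities[, c("surface", "type")],
    function(surface, type) list(entity = surface, type = type)
  )
  trips <- purrr::pmap(
    doc$triplets,
    function(head, head_type, relation, tail, tail_type) {
      list(
        entity1 = head, type1 = head_type, relationship = relation,
        entity2 = tail, type2 = tail_type
      )
    }
  )
  jsonlite::toJSON(
    list(Entities = ents, Relationships = trips),
    auto_unbox = TRUE, pretty = pretty
  ) |> as.character()
}
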