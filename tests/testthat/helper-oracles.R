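# Independent oracles and small fixture builders used across the suite.

# Grammar-based tag-integrity oracle, independent of the package's
# stack scanner: a trace is well-formed iff its tag-token sequence is
# exactly  <think> (<step> </step>)+ </think>.
oracle_tag_ok <- function(raw) {
  toks <- regmatches(raw, gregexpr("</?(think|step)>", raw))[[1]]
  if (length(toks) < 4) return(FALSE)
  if (toks[1] != "<think>" || toks[length(toks)] != "</think>") return(FALSE)
  inner <- toks[-c(1, length(toks))]
  if (length(inner) == 0 || length(inner) %% 2 != 0) return(FALSE)
  all(inner[seq(1, length(inner), by = 2)] == "<step>") &&
    all(inner[seq(2, length(inner), by = 2)] == "</step>")
}

# Set-intersection precision/recall oracle on unique item keys.
oracle_prf <- function(gold_keys, pred_keys) {
  tp <- length(intersect(gold_keys, pred_keys))
  fp <- length(setdiff(pred_keys, gold_keys))
  fn <- length(setdiff(gold_keys, pred_keys))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

oracle_entity_keys <- function(doc) {
  unique(paste(doc$entities$surface, doc$entities$type, sep = "\r"))
}

oracle_triplet_keys <- function(doc) {
  ct <- canonicalize_triplets(doc$triplets)
  unique(paste(ct$head, ct$head_type, ct$relation, ct$tail, ct$tail_type,
    sep = "\r"
  ))
}

# two-entity/one-triplet document used in many unit tests
tiny_doc <- function(doc_id = "d1") {
  document_annotation(
    doc_id, "cetuximab is used to treat colorectal cancer in clinical practice.",
    entities = tibble::tibble(
      surface = c("cetuximab", "colorectal cancer"),
      type = c("drug", "disease")
    ),
    triplets = tibble::tibble(
      head = "cetuximab", head_type = "drug", relation = "treat",
      tail = "colorectal cancer", tail_type = "disease"
    )
  )
}

# wrap a JSON payload in a well-formed, in-range think block
wrap_think <- function(json, len = 400L) {
  pad <- strrep("reasoning over schema constraints and context. ", 40)
  third <- max(1L, len %/% 3L)
  content <- substr(strrep(pad, 3), 1, len)
  paste0(
    "<think>",
    "<step>", substr(content, 1, third), "</step>",
    "<step>", substr(content, third + 1, 2 * third), "</step>",
    "<step>", substr(content, 2 * third + 1, len), "</step>",
    "</think>\n", json
  )
}
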