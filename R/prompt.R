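#' Specification of the annotation prompt
#'
#' The chain-of-thought annotation prompt initializes the model as a
#' biomedical annotation specialist and walks it through five steps:
#' role/task with k-shot demonstrations, entity and relation type
#' identification, annotation principles, triplet construction, and the
#' quintuple-JSON output contract.
#'
#' @param role_text Annotator persona text.
#' @param schema_digest Rendered entity/relation definitions; defaults
#'   to a digest of the packaged registries.
#' @param k_examples List of up to 10 demonstration pairs, each a list
#'   with `text` and `annotation` (a [document_annotation()]).
#' @param output_instructions The output-format contract text.
#' @return A `prompt_spec` list.
#' @export
prompt_spec <- function(role_text = NULL, schema_digest = NULL,
                        k_examples = list(), output_instructions = NULL) {
  stopifnot(length(k_examples) <= 10)
  for (ex in k_examples) {
    stopifnot(is.list(ex), !is.null(ex$text),
              inherits(ex$annotation, "document_annotation"))
  }
  structure(
    list(
      role_text = role_text %||% paste(
        "You are a biomedical annotation specialist for drug-repositioning",
        "knowledge extraction. Annotate entities and relation triplets in the",
        "given abstract, strictly following the schema below."
      ),
      schema_digest = schema_digest %||% .schema_digest(),
      k_examples = k_examples,
      output_instructions = output_instructions %||% paste(
        "Output each relationship as {Entity1; Type1; Relationship; Entity2;",
        "Type2} inside a JSON object with exactly two root keys, Entities and",
        "Relationships. Preserve original casing. Emit no explanatory text",
        "outside the JSON."
      )
    ),
    class = "prompt_spec"
  )
}

.schema_digest <- function() {
  reg <- relation_types()
  paste0(
    "Entity types (11): ", paste(entity_types(), collapse = ", "), ".\n",
    "Canonical relations (9, each with a bidirectional inverse; 18 directed labels): ",
    paste(canonical_relations(), collapse = ", "), ".\n",
    "Inverse labels: ",
    paste(reg$label[reg$is_inverse], collapse = ", "), "."
  )
}

#' Render the five-section annotation prompt
#'
#' Deterministic rendering: the five sections in fixed order followed by
#' the serialized k-shot demonstrations (whose JSON blocks are
#' themselves parseable by [parse_prediction()]).
#'
#' @param spec A [prompt_spec()].
#' @return The prompt text.
#' @export
render_annotation_prompt <- function(spec) {
  stopifnot(inherits(spec, "prompt_spec"))
  sections <- c(
    paste0("Step 1 - Role assignment and task description.\n", spec$role_text,
           "\n", spec$schema_digest),
    paste0(
      "Step 2 - Identification of entity and relationship types.\n",
      "Identify candidate entity types and contextual relationship types ",
      "present in the text according to the schema."
    ),
    paste0(
      "Step 3 - Entity and relationship annotation.\n",
      "Entity principles: (1) nonoverlapping - a single string cannot carry ",
      "multiple entity types; (2) nonnesting - an entity must not contain ",
      "another entity within its span; (3) minimal punctuation and ",
      "conjunction at entity boundaries. Relationship principles: (1) ",
      "intrasentence priority - prefer triplets within one sentence, allow ",
      "cross-sentence triplets only when no valid intrasentence relation ",
      "exists; (2) unidirectional relations - retain only one direction ",
      "between any two related entities."
    ),
    paste0(
      "Step 4 - Triplet construction.\n",
      "Combine the annotated entities and their contextual associations ",
      "into semantically coherent triplets."
    ),
    paste0("Step 5 - Output format standardization.\n", spec$output_instructions)
  )
  demos <- purrr::imap_chr(spec$k_examples, function(ex, i) {
    paste0(
      "Demonstration ", i, "\nInput: ", ex$text, "\nOutput: ",
      serialize_annotation(ex$annotation)
    )
  })
  paste(c(sections, demos), collapse = "\n\n")
}
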