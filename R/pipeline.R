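# End-to-end convenience: raw documents -> annotated, scored,
# featurized corpus.

#' Annotate, score and featurize a corpus in one pass
#'
#' Runs [annotate_document()] (metaphor labels), [score_document()]
#' (sentence sentiment) and [feature_vector()] over a list of parsed
#' documents.
#'
#' @param docs list of `msm_document`s.
#' @param store an `msm_embeddings`.
#' @param ontology an `msm_ontology`.
#' @param strength an `msm_strength_lexicon`.
#' @param sentic an `msm_sentic_lexicon`.
#' @param threshold metaphoricity threshold (default 0.5).
#' @param ... further arguments to [annotate_document()].
#' @return list `docs` (annotated + scored) and `features` (data frame,
#'   `doc_id` + 15 feature columns).
#' @export
process_corpus <- function(docs, store, ontology, strength, sentic,
                           threshold = 0.5, ...) {
  docs <- lapply(docs, function(d) {
    d <- annotate_document(d, store, ontology, threshold = threshold, ...)
    score_document(d, strength)
  })
  list(docs = docs, features = featurize_corpus(docs, sentic))
}
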