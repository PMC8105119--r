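# Token-level metaphor identification by best-fit-sense selection.
#
# For each content word ("detected word") in a sentence:
#   1. build the candidate sense set (the word itself, its synonyms and
#      direct hypernyms from the ontology, and their inflections);
#   2. pick the best-fit word w* = argmax_k cos(input(k), v_context),
#      where v_context is the mean input vector of the other
#      in-vocabulary tokens of the sentence;
#   3. score the sense difference as cos(output(detected), output(w*));
#   4. label the word metaphorical when that similarity is strictly below
#      the threshold (default 0.5).
# A word used literally selects a best fit close to its own sense (often
# itself, giving similarity 1); a metaphorically used word's context
# pulls the best fit toward a different sense, lowering the output-space
# similarity.

#' Select the best-fit sense for a detected word
#'
#' Argmax of cosine similarity between candidate input vectors and the
#' context vector. Candidates missing from the embedding vocabulary are
#' dropped (the detected word itself resolves through its surface form
#' when its lemma is out of vocabulary). Exact ties break to the
#' lexicographically smallest candidate.
#'
#' @param candidates an `msm_candidates` set.
#' @param vctx context vector from [context_vector()].
#' @param store an `msm_embeddings`.
#' @param self_row optional row index in the store for the detected word
#'   itself (surface-form fallback).
#' @return list `(word, similarity)` or `NULL` when every candidate is
#'   out of vocabulary.
#' @export
best_fit <- function(candidates, vctx, store, self_row = NULL) {
  words <- candidates$candidates
  idx <- match(words, store$vocab)
  if (!is.null(self_row)) idx[words == candidates$detected] <- self_row
  keep <- !is.na(idx)
  if (!any(keep)) return(NULL)
  words <- words[keep]; idx <- idx[keep]
  ord <- order(words)                      # lexicographic tie-break
  words <- words[ord]; idx <- idx[ord]
  m <- store$input[idx, , drop = FALSE]
  norms <- sqrt(rowSums(m * m))
  nv <- sqrt(sum(vctx * vctx))
  if (nv == 0 || any(norms == 0))
    stop("cosine undefined for a zero vector", call. = FALSE)
  sims <- as.numeric(m %*% vctx) / (norms * nv)
  k <- which.max(sims)                     # first max = smallest word on ties
  list(word = words[k], similarity = sims[k], row = idx[k])
}

#' Decide metaphorical vs literal for one detected word
#'
#' Runs the full best-fit-sense procedure for a single content token and
#' returns the decision record. Out-of-vocabulary detected words, words
#' with no in-vocabulary context, and words whose whole candidate set is
#' out of vocabulary are labelled `"skipped"` with a reason; downstream
#' feature extraction counts skipped words as literal.
#'
#' @param sentence a sentence element of an `msm_document`.
#' @param detected_index 0-based index of the detected token.
#' @param store an `msm_embeddings`.
#' @param ontology an `msm_ontology`.
#' @param threshold metaphoricity threshold on the output-vector cosine
#'   (default 0.5); comparison is strict (`<`).
#' @param window context window passed to [context_vector()].
#' @param cands optional precomputed `msm_candidates` for the detected
#'   word (candidate sets depend only on lemma and POS, so callers that
#'   sweep a corpus cache them).
#' @return list of class `msm_decision`: `detected`, `best_fit`,
#'   `sim_best_fit_context`, `sim_detected_bestfit`, `threshold`,
#'   `label` (`"metaphorical" | "literal" | "skipped"`), `skip_reason`.
#' @export
decide <- function(sentence, detected_index, store, ontology,
                   threshold = 0.5, window = 0, cands = NULL) {
  tok <- sentence$tokens
  row <- match(detected_index, tok$index)
  stopifnot(!is.na(row), tok$is_content[row])
  out <- list(detected = tolower(tok$lemma[row]), best_fit = NA_character_,
              sim_best_fit_context = NA_real_,
              sim_detected_bestfit = NA_real_,
              threshold = threshold, label = "skipped", skip_reason = NULL)
  class(out) <- "msm_decision"
  self_row <- store_index(store, tok$surface[row], tok$lemma[row])
  if (is.na(self_row)) {
    out$skip_reason <- "detected word out of vocabulary"
    return(out)
  }
  vctx <- context_vector(sentence, detected_index, store, window = window)
  if (is.null(vctx)) {
    out$skip_reason <- "no in-vocabulary context token"
    return(out)
  }
  if (is.null(cands))
    cands <- candidate_set(tok$lemma[row], ontology, pos = tok$pos[row])
  bf <- best_fit(cands, vctx, store, self_row = self_row)
  if (is.null(bf)) {
    out$skip_reason <- "all candidates out of vocabulary"
    return(out)
  }
  sim <- cosine(store$output[self_row, ], store$output[bf$row, ])
  out$best_fit <- bf$word
  out$sim_best_fit_context <- bf$similarity
  out$sim_detected_bestfit <- sim
  out$label <- if (sim < threshold) "metaphorical" else "literal"
  out$skip_reason <- NULL
  out
}

#' Annotate every content word of a document
#'
#' Applies [decide()] to each detected word and stores the outcome in new
#' token columns `met_label`, `met_best_fit`, `met_sim` (the
#' output-vector similarity) and `met_skip` (skip reason). Non-content
#' tokens get `NA` labels. Auxiliary/copular verbs and modals are skipped
#' by default to limit spurious flags; an optional stop list of fixed
#' collocations (lemmas) can also be excluded, but is off by default —
#' the method as designed does misflag some fixed collocations (for
#' example "own" in "on my own").
#'
#' @param doc an `msm_document`.
#' @param store an `msm_embeddings`.
#' @param ontology an `msm_ontology`.
#' @param threshold metaphoricity threshold (default 0.5).
#' @param window context window (0 = whole sentence).
#' @param exclude_auxiliaries skip be/have/do forms and modals
#'   (default `TRUE`).
#' @param stop_lemmas optional character vector of lemmas never to flag.
#' @return the document with annotated token tables; idempotent.
#' @export
annotate_document <- function(doc, store, ontology, threshold = 0.5,
                              window = 0, exclude_auxiliaries = TRUE,
                              stop_lemmas = NULL) {
  stopifnot(inherits(doc, "msm_document"))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(doc$sentences)) {
    tok <- doc$sentences[[i]]$tokens
    tok$met_label <- NA_character_
    tok$met_best_fit <- NA_character_
    tok$met_sim <- NA_real_
    tok$met_skip <- NA_character_
    for (r in seq_len(nrow(tok))) {
      if (!tok$is_content[r]) next
      if (exclude_auxiliaries &&
          tolower(tok$surface[r]) %in% .msm_auxiliaries) {
        tok$met_label[r] <- "skipped"
        tok$met_skip[r] <- "auxiliary"
        next
      }
      if (!is.null(stop_lemmas) && tok$lemma[r] %in% stop_lemmas) {
        tok$met_label[r] <- "skipped"
        tok$met_skip[r] <- "stop list"
        next
      }
      key <- paste0(tok$lemma[r], "/", tok$pos[r])
      if (is.null(cache[[key]]))
        cache[[key]] <- candidate_set(tok$lemma[r], ontology,
                                      pos = tok$pos[r])
      d <- decide(doc$sentences[[i]], tok$index[r], store, ontology,
                  threshold = threshold, window = window,
                  cands = cache[[key]])
      tok$met_label[r] <- d$label
      tok$met_best_fit[r] <- d$best_fit
      tok$met_sim[r] <- d$sim_detected_bestfit
      if (!is.null(d$skip_reason)) tok$met_skip[r] <- d$skip_reason
    }
    doc$sentences[[i]]$tokens <- tok
  }
  doc
}

#' Score predicted metaphor labels against gold annotations
#'
#' Token-level precision, recall and F1 with `metaphorical` as the
#' positive class. Skipped predictions count as literal. Gold rows that
#' do not resolve to a token of the supplied documents are an error.
#'
#' @param gold data frame `doc_id, sentence_index, token_index, label`
#'   (0-based indices; label `metaphorical` or `literal`).
#' @param docs list of annotated `msm_document`s.
#' @return list of class `msm_eval` with `precision`, `recall`, `f1` and
#'   a `counts` vector (tp, fp, fn, tn).
#' @export
evaluate_identification <- function(gold, docs) {
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  pred <- character(nrow(gold))
  unmatched <- character(0)
  for (i in seq_len(nrow(gold))) {
    d <- docs[[as.character(gold$doc_id[i])]]
    si <- gold$sentence_index[i] + 1L
    ok <- !is.null(d) && si >= 1L && si <= length(d$sentences)
    if (ok) {
      tok <- d$sentences[[si]]$tokens
      r <- match(gold$token_index[i], tok$index)
      ok <- !is.na(r)
    }
    if (!ok) {
      unmatched <- c(unmatched, paste0(gold$doc_id[i], ":",
                                       gold$sentence_index[i], ":",
                                       gold$token_index[i]))
      next
    }
    lab <- tok$met_label[r]
    pred[i] <- if (!is.na(lab) && lab == "metaphorical") "metaphorical"
               else "literal"
  }
  if (length(unmatched))
    stop("gold rows with no matching token: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  g <- gold$label == "metaphorical"
  p <- pred == "metaphorical"
  counts <- c(tp = sum(g & p), fp = sum(!g & p),
              fn = sum(g & !p), tn = sum(!g & !p))
  precision <- if (counts["tp"] + counts["fp"] > 0)
    unname(counts["tp"] / (counts["tp"] + counts["fp"])) else 0
  recall <- if (counts["tp"] + counts["fn"] > 0)
    unname(counts["tp"] / (counts["tp"] + counts["fn"])) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 counts = counts), class = "msm_eval")
}

#' @export
print.msm_eval <- function(x, ...) {
  cat(sprintf("<msm_eval> P = %.3f  R = %.3f  F1 = %.3f  (tp %d fp %d fn %d tn %d)\n",
              x$precision, x$recall, x$f1,
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  invisible(x)
}
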