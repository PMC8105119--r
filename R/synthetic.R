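# Synthetic inputs for the whole pipeline: embeddings with planted
# metaphor geometry, internally consistent toy lexicons and an ontology
# fixture, and two-class document cohorts with controlled metaphor-rate
# and sentiment effect sizes. Everything is deterministic under a seed.
#
# Geometry of the planted embedding space (dim >= 6):
#   - axis 1 is the "context" direction: context and sentiment words get
#     input vectors close to it;
#   - detected words (metaphor-source and literal) get input vectors
#     nearly orthogonal to it, their ontology synonym sits close to it,
#     and their hypernym in between, so the best-fit search always picks
#     the synonym;
#   - in output space each detected/synonym pair spans a plane where the
#     pair cosine is planted below 0.5 - margin (metaphor words) or
#     above 0.5 + margin (literal words).
# Context/sentiment words have no ontology entry, so their candidate set
# is the singleton self, their best fit is themselves (output cosine 1)
# and they always come out literal.

.msm_with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# pronounceable unique CV-syllable words; never collide with function
# words and never end in the suffixes the lemmatizer strips
synth_words <- function(n, syllables = 3) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(paste0(sample(cons, syllables, TRUE),
                       sample(vow, syllables, TRUE)), collapse = "")
    if (!w %in% out && !w %in% .msm_function_words) out <- c(out, w)
  }
  out
}

#' Specification of a planted embedding space
#'
#' @param n_metaphor,n_literal number of planted metaphor-source and
#'   literal detected words.
#' @param n_context number of context filler words.
#' @param dim embedding dimension (>= 6).
#' @param margin half-width of the forbidden cosine band around the 0.5
#'   decision threshold, in (0, 0.5); planted pairs land at
#'   0.5 - margin - 0.05 (metaphorical) and 0.5 + margin + 0.05
#'   (literal), clamped to [0, 1].
#' @param seed RNG seed; also determines the generated vocabulary.
#' @return list of class `msm_embedding_spec` with the word lists
#'   (`metaphor_words`, `literal_words`, `context_words`,
#'   `pos_strength_words`, `neg_strength_words`, `synonyms`,
#'   `hypernyms`).
#' @export
planted_embedding_spec <- function(n_metaphor = 8, n_literal = 8,
                                   n_context = 6, dim = 8, margin = 0.3,
                                   seed = 1) {
  if (margin <= 0 || margin >= 0.5)
    stop("margin must lie in (0, 0.5)", call. = FALSE)
  if (dim < 6)
    stop("infeasible geometry: planted construction needs dim >= 6",
         call. = FALSE)
  .msm_with_seed(seed, {
    n_det <- n_metaphor + n_literal
    words <- synth_words(n_det * 3 + n_context + 8)
    det <- words[seq_len(n_det)]
    syn <- words[n_det + seq_len(n_det)]
    hyp <- words[2 * n_det + seq_len(n_det)]
    ctx <- words[3 * n_det + seq_len(n_context)]
    strength <- words[3 * n_det + n_context + seq_len(8)]
    structure(list(
      metaphor_words = det[seq_len(n_metaphor)],
      literal_words = det[n_metaphor + seq_len(n_literal)],
      synonyms = stats::setNames(syn, det),
      hypernyms = stats::setNames(hyp, det),
      context_words = ctx,
      pos_strength_words = stats::setNames(strength[1:4], 2:5),
      neg_strength_words = stats::setNames(strength[5:8], 2:5),
      dim = dim, margin = margin, seed = seed),
      class = "msm_embedding_spec")
  })
}

unit <- function(v) v / sqrt(sum(v * v))

#' Generate planted input/output embedding matrices
#'
#' Builds the geometry described in [planted_embedding_spec()], verifies
#' every planted output cosine by direct computation (outside the band
#' `(0.5 - margin, 0.5 + margin)`) and that the input-space best fit of
#' each detected word is its synonym, then optionally writes both
#' matrices as word2vec text files.
#'
#' @param spec an `msm_embedding_spec`.
#' @param dir optional directory; when given, `input.vec` and
#'   `output.vec` are written there.
#' @return list with `input` and `output` matrices (words as rownames),
#'   `truth` (named character vector over detected words:
#'   `"metaphorical"` or `"literal"`), `spec`, and `input_path` /
#'   `output_path` when written.
#' @export
make_embeddings <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "msm_embedding_spec"))
  d <- spec$dim
  det <- c(spec$metaphor_words, spec$literal_words)
  vocab <- c(det, unname(spec$synonyms), unname(spec$hypernyms),
             spec$context_words, unname(spec$pos_strength_words),
             unname(spec$neg_strength_words))
  met_cos <- max(0, 0.5 - spec$margin - 0.05)
  lit_cos <- min(1, 0.5 + spec$margin + 0.05)
  .msm_with_seed(spec$seed + 1L, {
    input <- matrix(0, length(vocab), d, dimnames = list(vocab, NULL))
    output <- matrix(0, length(vocab), d, dimnames = list(vocab, NULL))
    ax <- function(i) { v <- numeric(d); v[i] <- 1; v }
    near_context <- function() {
      a <- stats::runif(1, 0.05, 0.2)     # small angle off the context axis
      unit(cos(a) * ax(1) + sin(a) * ax(3))
    }
    for (w in c(spec$context_words, spec$pos_strength_words,
                spec$neg_strength_words)) {
      input[w, ] <- near_context()
      output[w, ] <- unit(ax(6) + 0.1 * stats::runif(d))
    }
    for (k in seq_along(det)) {
      w <- det[k]; s <- spec$synonyms[[w]]; h <- spec$hypernyms[[w]]
      jit <- stats::runif(1, -0.1, 0.1)
      input[w, ] <- unit(0.1 * ax(1) + ax(2) + jit * ax(3))
      input[s, ] <- unit(0.9 * ax(1) + sqrt(1 - 0.81) * ax(3))
      input[h, ] <- unit(0.3 * ax(1) + ax(2) + ax(3))
      theta <- stats::runif(1, 0, 2 * pi)
      u <- cos(theta) * ax(4) + sin(theta) * ax(5)
      u_perp <- -sin(theta) * ax(4) + cos(theta) * ax(5)
      output[s, ] <- u
      output[h, ] <- u
      target <- if (w %in% spec$metaphor_words) met_cos else lit_cos
      output[w, ] <- target * u + sqrt(1 - target^2) * u_perp
    }
    truth <- stats::setNames(
      ifelse(det %in% spec$metaphor_words, "metaphorical", "literal"), det)
    # generation-time self-check by direct cosine computation
    for (w in det) {
      pc <- cosine(output[w, ], output[spec$synonyms[[w]], ])
      if (pc > 0.5 - spec$margin && pc < 0.5 + spec$margin)
        stop("infeasible geometry: planted cosine ", signif(pc, 4),
             " falls inside the margin band", call. = FALSE)
      c_self <- cosine(input[w, ], ax(1))
      c_syn <- cosine(input[spec$synonyms[[w]], ], ax(1))
      c_hyp <- cosine(input[spec$hypernyms[[w]], ], ax(1))
      if (!(c_syn > c_hyp && c_syn > c_self))
        stop("infeasible geometry: synonym of '", w,
             "' is not the input-space best fit", call. = FALSE)
    }
    out <- list(input = input, output = output, truth = truth, spec = spec)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$input_path <- file.path(dir, "input.vec")
      out$output_path <- file.path(dir, "output.vec")
      write_w2v(input, out$input_path)
      write_w2v(output, out$output_path)
    }
    out
  })
}

#' Generate the toy lexicons and ontology matching an embedding spec
#'
#' The strength lexicon covers the planted sentiment words (positive
#' strength words at (k, -1), negative at (1, -k), k = 2..5); the sentic
#' lexicon covers the whole planted vocabulary with values in [-1, 1]
#' whose pleasantness/polarity track the strength words' sign; the
#' ontology wires every detected word (as a noun) to its planted synonym
#' and hypernym. A POS lexicon mapping every planted word to its coarse
#' tag is included so tagging is exact on synthetic text.
#'
#' @param spec an `msm_embedding_spec`.
#' @param dir optional directory to write `strength.csv`, `sentic.csv`,
#'   `ontology.json`.
#' @return list `strength` (`msm_strength_lexicon`), `sentic`
#'   (`msm_sentic_lexicon`), `ontology` (`msm_ontology`), `pos_lexicon`
#'   (named character), plus file paths when written.
#' @export
make_lexicons <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "msm_embedding_spec"))
  det <- c(spec$metaphor_words, spec$literal_words)
  .msm_with_seed(spec$seed + 2L, {
    strength <- data.frame(
      word = c(unname(spec$pos_strength_words),
               unname(spec$neg_strength_words)),
      pos_strength = c(2:5, rep(1L, 4)),
      neg_strength = c(rep(-1L, 4), -(2:5)),
      stringsAsFactors = FALSE)
    vocab <- c(det, unname(spec$synonyms), unname(spec$hypernyms),
               spec$context_words, strength$word)
    pol <- stats::runif(length(vocab), -0.2, 0.2)
    names(pol) <- vocab
    pol[spec$pos_strength_words] <- (2:5) / 5
    pol[spec$neg_strength_words] <- -(2:5) / 5
    sentic <- data.frame(
      word = vocab,
      pleasantness = unname(pol),
      attention = round(stats::runif(length(vocab), -0.5, 0.5), 3),
      sensitivity = round(stats::runif(length(vocab), -0.5, 0.5), 3),
      aptitude = round(stats::runif(length(vocab), -0.5, 0.5), 3),
      polarity = unname(pol),
      stringsAsFactors = FALSE)
    ontology <- lapply(stats::setNames(det, det), function(w) {
      list(noun = list(synonyms = list(spec$synonyms[[w]]),
                       hypernyms = list(spec$hypernyms[[w]])))
    })
    pos_lexicon <- c(stats::setNames(rep("noun", length(det)), det),
                     stats::setNames(rep("noun", length(spec$context_words)),
                                     spec$context_words),
                     stats::setNames(rep("adjective", nrow(strength)),
                                     strength$word))
    out <- list(pos_lexicon = pos_lexicon)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$strength_path <- file.path(dir, "strength.csv")
      out$sentic_path <- file.path(dir, "sentic.csv")
      out$ontology_path <- file.path(dir, "ontology.json")
      utils::write.csv(strength, out$strength_path, row.names = FALSE)
      utils::write.csv(sentic, out$sentic_path, row.names = FALSE)
      writeLines(jsonlite::toJSON(ontology, auto_unbox = TRUE),
                 out$ontology_path)
      out$strength <- load_strength_lexicon(out$strength_path)
      out$sentic <- load_sentic_lexicon(out$sentic_path)
      out$ontology <- load_ontology(out$ontology_path)
    } else {
      out$strength <- structure(data.frame(
        word = strength$word, pos_strength = strength$pos_strength,
        neg_strength = strength$neg_strength, stringsAsFactors = FALSE),
        class = c("msm_strength_lexicon", "data.frame"))
      out$sentic <- structure(sentic,
                              class = c("msm_sentic_lexicon", "data.frame"))
      out$ontology <- structure(ontology, class = "msm_ontology")
    }
    out
  })
}

#' Specification of a synthetic two-class cohort
#'
#' Default sizes mirror a 156-author cohort with a 29/127 sick/healthy
#' split (the least prevalent condition of the motivating study design);
#' the default effect sizes are a 0.10 vs 0.02 per-slot metaphor rate
#' and a -1 vs +1 mean sentence sentiment.
#'
#' @param n_sick,n_healthy cohort sizes.
#' @param metaphor_rate_sick,metaphor_rate_healthy per-detected-slot
#'   probability of drawing a metaphor-source word.
#' @param mean_sentiment_sick,mean_sentiment_healthy class means of the
#'   per-sentence target sentiment score (clamped to [-4, 4]).
#' @param sentences_per_doc integer vector to sample document lengths
#'   from.
#' @param detected_per_sentence,context_per_sentence slots per sentence.
#' @param condition which condition the label table records.
#' @param seed RNG seed.
#' @return list of class `msm_cohort_spec`.
#' @export
cohort_spec <- function(n_sick = 29, n_healthy = 127,
                        metaphor_rate_sick = 0.10,
                        metaphor_rate_healthy = 0.02,
                        mean_sentiment_sick = -1,
                        mean_sentiment_healthy = 1,
                        sentences_per_doc = 8:12,
                        detected_per_sentence = 2,
                        context_per_sentence = 3,
                        condition = "inferiority", seed = 1) {
  stopifnot(n_sick >= 1, n_healthy >= 1,
            metaphor_rate_sick >= 0, metaphor_rate_sick <= 1,
            metaphor_rate_healthy >= 0, metaphor_rate_healthy <= 1,
            condition %in% .msm_conditions)
  structure(as.list(environment()), class = "msm_cohort_spec")
}

#' Generate a labelled synthetic cohort
#'
#' Assembles template sentences from the planted vocabulary: each
#' sentence holds context words, `detected_per_sentence` detected-word
#' slots (each metaphorical with the class rate) and, when the sentence's
#' target sentiment score is nonzero, one strength word realizing that
#' score exactly. Documents are parsed with the generator's POS lexicon.
#'
#' @param cspec an `msm_cohort_spec`.
#' @param espec an `msm_embedding_spec` (vocabulary source).
#' @param lex the matching [make_lexicons()] bundle.
#' @return list `docs` (list of `msm_document`s), `labels`
#'   (`msm_labels`), `truth` (data frame with per-document realized
#'   metaphor rates and class), `gold` (token-level gold annotation
#'   data frame over all content tokens).
#' @export
make_cohort <- function(cspec, espec, lex) {
  stopifnot(inherits(cspec, "msm_cohort_spec"),
            inherits(espec, "msm_embedding_spec"))
  .msm_with_seed(cspec$seed, {
    pos_words <- spec_strength_words(espec, positive = TRUE)
    neg_words <- spec_strength_words(espec, positive = FALSE)
    classes <- c(rep(TRUE, cspec$n_sick), rep(FALSE, cspec$n_healthy))
    doc_ids <- sprintf("%s%03d", ifelse(classes, "s", "h"),
                       stats::ave(seq_along(classes), classes,
                                  FUN = seq_along))
    docs <- vector("list", length(classes))
    truth <- data.frame(doc_id = doc_ids, sick = classes,
                        n_slots = 0L, n_metaphor = 0L,
                        mean_target_score = NA_real_,
                        stringsAsFactors = FALSE)
    for (i in seq_along(classes)) {
      rate <- if (classes[i]) cspec$metaphor_rate_sick
              else cspec$metaphor_rate_healthy
      mu <- if (classes[i]) cspec$mean_sentiment_sick
            else cspec$mean_sentiment_healthy
      ns <- if (length(cspec$sentences_per_doc) == 1L)
        cspec$sentences_per_doc else sample(cspec$sentences_per_doc, 1)
      sent_txt <- character(ns)
      scores <- numeric(ns)
      for (s in seq_len(ns)) {
        is_met <- stats::runif(cspec$detected_per_sentence) < rate
        det <- ifelse(is_met,
                      sample(espec$metaphor_words,
                             cspec$detected_per_sentence, TRUE),
                      sample(espec$literal_words,
                             cspec$detected_per_sentence, TRUE))
        ctx <- sample(espec$context_words, cspec$context_per_sentence,
                      replace = cspec$context_per_sentence >
                        length(espec$context_words))
        target <- max(-4, min(4, round(stats::rnorm(1, mu, 1.2))))
        sw <- if (target > 0) pos_words[[as.character(target + 1)]]
              else if (target < 0) neg_words[[as.character(-target + 1)]]
              else NULL
        words <- c("the", ctx[1], det[1],
                   if (length(ctx) > 1) ctx[2], sw,
                   if (length(det) > 1) det[-1],
                   if (length(ctx) > 2) ctx[-(1:2)])
        sent_txt[s] <- paste0(paste(words, collapse = " "), ".")
        scores[s] <- target
        truth$n_slots[i] <- truth$n_slots[i] + cspec$detected_per_sentence
        truth$n_metaphor[i] <- truth$n_metaphor[i] + sum(is_met)
      }
      truth$mean_target_score[i] <- mean(scores)
      docs[[i]] <- parse_document(paste(sent_txt, collapse = " "),
                                  doc_id = doc_ids[i],
                                  pos_lexicon = lex$pos_lexicon)
    }
    truth$realized_rate <- truth$n_metaphor / truth$n_slots
    labels <- data.frame(doc_id = doc_ids, condition = cspec$condition,
                         sick = classes, stringsAsFactors = FALSE)
    class(labels) <- c("msm_labels", "data.frame")
    list(docs = docs, labels = labels, truth = truth,
         gold = cohort_gold(docs, espec))
  })
}

spec_strength_words <- function(espec, positive) {
  w <- if (positive) espec$pos_strength_words else espec$neg_strength_words
  as.list(w)
}

#' Token-level gold labels for a synthetic corpus
#'
#' Every content token of every document, labelled metaphorical iff its
#' surface form is one of the planted metaphor-source words.
#'
#' @param docs list of `msm_document`s built from the planted vocabulary.
#' @param espec the `msm_embedding_spec`.
#' @return data frame `doc_id, sentence_index, token_index, label`.
#' @export
cohort_gold <- function(docs, espec) {
  rows <- lapply(docs, function(d) {
    do.call(rbind, lapply(seq_along(d$sentences), function(si) {
      tok <- d$sentences[[si]]$tokens
      keep <- tok$is_content
      if (!any(keep)) return(NULL)
      data.frame(doc_id = d$doc_id, sentence_index = si - 1L,
                 token_index = tok$index[keep],
                 label = ifelse(tolower(tok$surface[keep]) %in%
                                  espec$metaphor_words,
                                "metaphorical", "literal"),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
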