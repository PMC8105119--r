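# Lexical resources: sentence-level sentiment-strength scoring, the
# five-dimension sentic lexicon, and the ontology that supplies candidate
# senses (synonyms + direct hypernyms + rule-based inflections) for the
# metaphor identifier.

#' Load a sentiment-strength lexicon
#'
#' Expects a delimited file (comma or tab, header row) with columns
#' `word`, `pos_strength` (integer 1..5) and `neg_strength` (integer
#' -5..-1). Out-of-range or malformed rows abort with the row number;
#' duplicated words resolve last-wins with a warning.
#'
#' @param path file path.
#' @return data frame of class `msm_strength_lexicon`, one row per word.
#' @export
load_strength_lexicon <- function(path) {
  df <- read_delimited(path, c("word", "pos_strength", "neg_strength"))
  ps <- suppressWarnings(as.integer(df$pos_strength))
  ns <- suppressWarnings(as.integer(df$neg_strength))
  bad <- which(is.na(ps) | is.na(ns) | ps < 1L | ps > 5L | ns < -5L | ns > -1L)
  if (length(bad))
    stop("strength lexicon ", path, ": row ", bad[1] + 1L,
         " out of range (pos_strength in [1,5], neg_strength in [-5,-1])",
         call. = FALSE)
  w <- tolower(df$word)
  if (anyDuplicated(w)) {
    warning("strength lexicon: duplicated word(s) ",
            paste(unique(w[duplicated(w)]), collapse = ", "),
            "; keeping the last occurrence")
    keep <- !duplicated(w, fromLast = TRUE)
    w <- w[keep]; ps <- ps[keep]; ns <- ns[keep]
  }
  structure(data.frame(word = w, pos_strength = ps, neg_strength = ns,
                       stringsAsFactors = FALSE),
            class = c("msm_strength_lexicon", "data.frame"))
}

#' Load a five-dimension sentic lexicon
#'
#' Columns `word`, `pleasantness`, `attention`, `sensitivity`, `aptitude`,
#' `polarity`, all real values in `[-1, 1]`.
#'
#' @param path file path.
#' @return data frame of class `msm_sentic_lexicon`.
#' @export
load_sentic_lexicon <- function(path) {
  dims <- c("pleasantness", "attention", "sensitivity", "aptitude", "polarity")
  df <- read_delimited(path, c("word", dims))
  for (d in dims) {
    v <- suppressWarnings(as.numeric(df[[d]]))
    bad <- which(is.na(v) | v < -1 | v > 1)
    if (length(bad))
      stop("sentic lexicon ", path, ": row ", bad[1] + 1L, " column ", d,
           " outside [-1, 1]", call. = FALSE)
    df[[d]] <- v
  }
  w <- tolower(df$word)
  if (anyDuplicated(w)) {
    warning("sentic lexicon: duplicated word(s); keeping the last occurrence")
    keep <- !duplicated(w, fromLast = TRUE)
    df <- df[keep, , drop = FALSE]
    w <- w[keep]
  }
  df$word <- w
  rownames(df) <- NULL
  structure(df, class = c("msm_sentic_lexicon", "data.frame"))
}

read_delimited <- function(path, need) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(need %in% names(df)))
    stop(path, ": expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[, need, drop = FALSE]
}

# negators for the optional negation flag
.msm_negators <- c("not", "no", "never", "n't", "cannot", "nothing", "hardly")

#' Score one sentence's sentiment strength
#'
#' Looks each token up in the strength lexicon (lowercase surface, then
#' lemma) and aggregates by maximum magnitude: the positive score is the
#' largest matched positive strength (floor 1), the negative score the
#' most negative matched strength (ceiling -1). The overall score is
#' their sum, in `[-4, 4]`; 0 is neutral. A sentence with no lexicon hit
#' scores (1, -1), overall 0.
#'
#' With `negation = TRUE` a strength word preceded within two tokens by a
#' negator has its contribution mirrored: positive strength p feeds the
#' negative side as -p and negative strength n feeds the positive side as
#' -n.
#'
#' @param sentence a sentence element of an `msm_document`.
#' @param lexicon an `msm_strength_lexicon`.
#' @param negation flip contributions after a nearby negator
#'   (default `FALSE`).
#' @return list with integer `positive`, `negative`, `overall`.
#' @export
sentence_sentiment <- function(sentence, lexicon, negation = FALSE) {
  tok <- sentence$tokens
  stopifnot(nrow(tok) >= 1L)
  surf <- tolower(tok$surface)
  idx <- match(surf, lexicon$word)
  miss <- is.na(idx)
  idx[miss] <- match(tok$lemma[miss], lexicon$word)
  hit <- which(!is.na(idx))
  pos_c <- integer(0)
  neg_c <- integer(0)
  for (i in hit) {
    p <- lexicon$pos_strength[idx[i]]
    n <- lexicon$neg_strength[idx[i]]
    negated <- negation && i > 1L &&
      any(surf[max(1L, i - 2L):(i - 1L)] %in% .msm_negators)
    if (negated) {
      pos_c <- c(pos_c, -n)   # -n is positive
      neg_c <- c(neg_c, -p)
    } else {
      pos_c <- c(pos_c, p)
      neg_c <- c(neg_c, n)
    }
  }
  positive <- max(1L, if (length(pos_c)) max(pos_c) else 1L)
  negative <- min(-1L, if (length(neg_c)) min(neg_c) else -1L)
  list(positive = as.integer(positive), negative = as.integer(negative),
       overall = as.integer(positive + negative))
}

#' Attach sentiment scores to every sentence of a document
#'
#' Either scores with [sentence_sentiment()] against a strength lexicon,
#' or copies precomputed per-sentence scores (e.g. produced by an external
#' sentiment-strength tool) from a score table.
#'
#' @param doc an `msm_document`.
#' @param lexicon an `msm_strength_lexicon` (ignored when `scores` given).
#' @param scores optional data frame `doc_id, sentence_index, pos, neg`
#'   (0-based sentence index) as read by [read_sentence_scores()].
#' @param negation passed to [sentence_sentiment()].
#' @return the document with each sentence's `sentiment` slot filled.
#' @export
score_document <- function(doc, lexicon = NULL, scores = NULL,
                           negation = FALSE) {
  stopifnot(inherits(doc, "msm_document"))
  if (!is.null(scores)) {
    sc <- scores[scores$doc_id == doc$doc_id, , drop = FALSE]
    for (i in seq_along(doc$sentences)) {
      row <- sc[sc$sentence_index == i - 1L, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("no precomputed score for document '", doc$doc_id,
             "' sentence ", i - 1L, call. = FALSE)
      p <- as.integer(row$pos); n <- as.integer(row$neg)
      doc$sentences[[i]]$sentiment <-
        list(positive = p, negative = n, overall = p + n)
    }
    return(doc)
  }
  stopifnot(inherits(lexicon, "msm_strength_lexicon"))
  for (i in seq_along(doc$sentences))
    doc$sentences[[i]]$sentiment <-
      sentence_sentiment(doc$sentences[[i]], lexicon, negation = negation)
  doc
}

#' Read a precomputed per-sentence score file
#'
#' CSV with header `doc_id,sentence_index,pos,neg`; the backend for
#' fidelity runs where sentence scores come from an external tool.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_sentence_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("doc_id", "sentence_index", "pos", "neg")
  if (!all(need %in% names(df)))
    stop(path, ": expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  df
}

#' Load an ontology fixture
#'
#' JSON of the form `{word: {pos: {synonyms: [...], hypernyms: [...]}}}`
#' where `pos` is a coarse tag. This is the package's ontology surface: a
#' full lexical database exported to this form plugs in identically.
#'
#' @param path JSON file path.
#' @return list of class `msm_ontology`.
#' @export
load_ontology <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  names(x) <- tolower(names(x))
  structure(x, class = "msm_ontology")
}

#' Rule-based inflections of a word
#'
#' Generates plural/3rd-person `-s`/`-es`, past `-ed`, progressive `-ing`
#' and comparative/superlative `-er`/`-est` forms with final-e drop,
#' consonant doubling and `y -> i` rules. Used to expand candidate sets;
#' no morphology database is consulted.
#'
#' @param word lowercase base form.
#' @param pos coarse tag guiding which inflections apply; `"all"`
#'   generates every form.
#' @return character vector of inflected forms (excluding `word` itself).
#' @export
inflections <- function(word, pos = "all") {
  w <- tolower(word)
  n <- nchar(w)
  if (n < 2L || grepl("[^a-z]", w)) return(character(0))
  last <- substr(w, n, n)
  penult <- if (n >= 2) substr(w, n - 1, n - 1) else ""
  vowels <- c("a", "e", "i", "o", "u")
  # stem variants for suffixes beginning with a vowel
  e_drop <- if (last == "e" && penult != "e") substr(w, 1, n - 1) else w
  doubled <- if (last %in% c("b","d","f","g","l","m","n","p","r","t") &&
                 penult %in% vowels &&
                 (n < 3 || !substr(w, n - 2, n - 2) %in% vowels))
    paste0(w, last) else NULL
  y_to_i <- if (last == "y" && !penult %in% vowels) substr(w, 1, n - 1) else NULL
  s_form <- if (grepl("(s|x|z|ch|sh)$", w)) paste0(w, "es")
            else if (!is.null(y_to_i)) paste0(y_to_i, "ies")
            else paste0(w, "s")
  out <- character(0)
  if (pos %in% c("noun", "verb", "all")) out <- c(out, s_form)
  if (pos %in% c("verb", "all")) {
    ed <- if (!is.null(y_to_i)) paste0(y_to_i, "ied") else paste0(e_drop, "ed")
    ing <- paste0(if (last == "e") e_drop else w, "ing")
    out <- c(out, ed, ing)
    if (!is.null(doubled)) out <- c(out, paste0(doubled, "ed"),
                                    paste0(doubled, "ing"))
  }
  if (pos %in% c("adjective", "adverb", "all")) {
    er <- if (!is.null(y_to_i)) paste0(y_to_i, "ier") else paste0(e_drop, "er")
    est <- if (!is.null(y_to_i)) paste0(y_to_i, "iest") else paste0(e_drop, "est")
    out <- c(out, er, est)
    if (!is.null(doubled)) out <- c(out, paste0(doubled, "er"),
                                    paste0(doubled, "est"))
  }
  setdiff(unique(out), w)
}

#' Build the candidate sense set for a detected word
#'
#' The candidate set contains the detected word's lemma itself, the
#' synonyms and direct hypernyms listed in the ontology for that lemma
#' under the matching coarse POS, and rule-based inflections of all of
#' them. Multiword entries are dropped (the identifier substitutes single
#' tokens); everything is lowercased and deduplicated. A word absent from
#' the ontology yields the degenerate singleton set, flagged.
#'
#' @param detected a token row (needs `lemma`, `pos`) or a character
#'   lemma (then `pos` must be supplied).
#' @param ontology an `msm_ontology`.
#' @param pos coarse POS when `detected` is a bare word.
#' @param inflect expand with [inflections()] (default `TRUE`).
#' @return list of class `msm_candidates` with `detected`, `candidates`
#'   (character), `provenance` (character, parallel to `candidates`) and
#'   `in_ontology` flag.
#' @export
candidate_set <- function(detected, ontology, pos = NULL, inflect = TRUE) {
  if (is.character(detected)) {
    lemma <- tolower(detected)
    stopifnot(!is.null(pos))
  } else {
    lemma <- tolower(detected$lemma)
    pos <- detected$pos
  }
  single <- function(x) x[!grepl("[ _]", x)]
  syn <- hyp <- character(0)
  entry <- ontology[[lemma]]
  in_ont <- FALSE
  if (!is.null(entry) && !is.null(entry[[pos]])) {
    in_ont <- TRUE
    syn <- single(tolower(unlist(entry[[pos]]$synonyms)))
    hyp <- single(tolower(unlist(entry[[pos]]$hypernyms)))
  }
  words <- c(lemma, syn, hyp)
  prov <- c("self", rep("synonym", length(syn)), rep("hypernym", length(hyp)))
  if (inflect) {
    for (k in seq_along(words[-1]) + 1L) {
      infl <- inflections(words[k], pos)
      words <- c(words, infl)
      prov <- c(prov, rep(paste0("inflection-of-", prov[k]), length(infl)))
    }
    self_infl <- inflections(lemma, pos)
    words <- c(words, self_infl)
    prov <- c(prov, rep("inflection-of-self", length(self_infl)))
  }
  keep <- !duplicated(words)
  structure(list(detected = lemma, candidates = words[keep],
                 provenance = prov[keep], in_ontology = in_ont),
            class = "msm_candidates")
}
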