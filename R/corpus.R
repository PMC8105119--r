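# Document model and plain-text ingestion: rule-based sentence splitting,
# tokenization, coarse POS tagging and lemmatization, chronological merging
# of per-user writing records, and the condition label table.

.msm_conditions <- c("anxiety", "depression", "inferiority",
                     "sensitivity", "social_phobia", "obsession")

# closed-class function words -> coarse tag "other"
.msm_function_words <- c(
  "the", "a", "an", "this", "that", "these", "those", "some", "any", "no",
  "each", "every", "either", "neither", "both", "all", "such", "another",
  "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
  "them", "my", "your", "his", "its", "our", "their", "mine", "yours",
  "hers", "ours", "theirs", "myself", "yourself", "himself", "herself",
  "itself", "ourselves", "themselves", "who", "whom", "whose", "which",
  "what", "where", "when", "why", "how", "there", "here",
  "in", "on", "at", "by", "for", "with", "about", "against", "between",
  "into", "through", "during", "before", "after", "above", "below", "to",
  "from", "up", "down", "of", "off", "over", "under", "again", "further",
  "then", "once", "and", "but", "or", "nor", "so", "yet", "if", "because",
  "as", "until", "while", "although", "though", "since", "unless",
  "whether", "than", "not", "only", "just", "also", "too", "very",
  "can", "could", "may", "might", "must", "shall", "should", "will",
  "would", "ought")

# be/have/do forms and modals: tagged verb (hence content words by the POS
# rule) but skipped by the metaphor identifier's auxiliary filter.
.msm_auxiliaries <- c(
  "be", "am", "is", "are", "was", "were", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing",
  "can", "could", "may", "might", "must", "shall", "should",
  "will", "would")

.msm_abbrev <- c("mr", "mrs", "ms", "dr", "prof", "sr", "jr", "st",
                 "etc", "e.g", "i.e", "vs", "no", "fig", "al")

#' Split raw text into sentences
#'
#' Deterministic rule-based splitter: breaks after `.`, `!` or `?` followed
#' by whitespace, except after a short list of common abbreviations.
#'
#' @param text character scalar.
#' @return character vector of sentences (trimmed, non-empty).
#' @keywords internal
split_sentences <- function(text) {
  text <- gsub("[\r\n]+", " ", text)
  pieces <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) <= 1L) return(pieces)
  # re-join fragments that end in a known abbreviation ("Dr." etc.)
  out <- character(0)
  buf <- ""
  for (p in pieces) {
    buf <- if (nzchar(buf)) paste(buf, p) else p
    last <- tolower(sub("\\.$", "", regmatches(
      buf, regexpr("[A-Za-z.]+\\.$", buf))))
    if (length(last) == 1L && last %in% .msm_abbrev) next
    out <- c(out, buf)
    buf <- ""
  }
  if (nzchar(buf)) out <- c(out, buf)
  out
}

#' Tokenize one sentence
#'
#' Words are maximal runs of letters/digits with internal apostrophes or
#' hyphens; every other non-space character is its own token.
#'
#' @param sentence character scalar.
#' @return character vector of surface tokens.
#' @keywords internal
tokenize <- function(sentence) {
  m <- gregexpr("[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*|[^\\sA-Za-z0-9]",
                sentence, perl = TRUE)
  regmatches(sentence, m)[[1]]
}

#' Coarse part-of-speech tag for a single token
#'
#' Closed-class lookup first, then suffix heuristics; an optional POS
#' lexicon (named character vector, word -> tag) takes precedence over
#' both. Tags are one of `"noun"`, `"verb"`, `"adjective"`, `"adverb"`,
#' `"other"`.
#'
#' @param word surface form.
#' @param pos_lexicon optional named character vector of overrides.
#' @return character scalar tag.
#' @keywords internal
tag_pos <- function(word, pos_lexicon = NULL) {
  w <- tolower(word)
  if (!is.null(pos_lexicon) && w %in% names(pos_lexicon))
    return(unname(pos_lexicon[[w]]))
  if (!grepl("^[a-z]", w)) return("other")   # punctuation, numerals
  if (w %in% .msm_auxiliaries) return("verb")
  if (w %in% .msm_function_words) return("other")
  n <- nchar(w)
  if (n > 3 && endsWith(w, "ly")) return("adverb")
  adj_suf <- c("ous", "ful", "ive", "able", "ible", "ish", "less", "ic", "al")
  for (s in adj_suf) if (n > nchar(s) + 2 && endsWith(w, s)) return("adjective")
  if (n > 4 && (endsWith(w, "ize") || endsWith(w, "ise"))) return("verb")
  if (n > 4 && (endsWith(w, "ing") || endsWith(w, "ed"))) return("verb")
  noun_suf <- c("tion", "sion", "ness", "ment", "ity", "ship", "ance", "ence")
  for (s in noun_suf) if (n > nchar(s) + 2 && endsWith(w, s)) return("noun")
  "noun"
}

#' Rule-based lemma keyed on a coarse POS tag
#'
#' @param word surface form (any case).
#' @param pos coarse tag from [tag_pos()].
#' @return lowercase lemma.
#' @keywords internal
lemmatize <- function(word, pos) {
  w <- tolower(word)
  n <- nchar(w)
  undouble <- function(x) {
    k <- nchar(x)
    if (k >= 3 && substr(x, k, k) == substr(x, k - 1, k - 1) &&
        grepl("[bdfglmnprt]$", x))
      substr(x, 1, k - 1) else x
  }
  if (pos == "noun") {
    if (n > 3 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 3 && grepl("(s|x|z|ch|sh)es$", w)) return(substr(w, 1, n - 2))
    if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss"))
      return(substr(w, 1, n - 1))
    return(w)
  }
  if (pos == "verb") {
    if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && endsWith(w, "ing")) return(undouble(substr(w, 1, n - 3)))
    if (n > 3 && endsWith(w, "ed")) return(undouble(substr(w, 1, n - 2)))
    if (n > 3 && grepl("(s|x|z|ch|sh)es$", w)) return(substr(w, 1, n - 2))
    if (n > 2 && endsWith(w, "s") && !endsWith(w, "ss"))
      return(substr(w, 1, n - 1))
    return(w)
  }
  if (pos %in% c("adjective", "adverb")) {
    if (n > 4 && endsWith(w, "iest")) return(paste0(substr(w, 1, n - 4), "y"))
    if (n > 3 && endsWith(w, "ier")) return(paste0(substr(w, 1, n - 3), "y"))
    if (n > 4 && endsWith(w, "est")) return(undouble(substr(w, 1, n - 3)))
    if (n > 3 && endsWith(w, "er")) return(undouble(substr(w, 1, n - 2)))
    return(w)
  }
  w
}

.make_sentence <- function(surfaces, pos_lexicon = NULL) {
  pos <- vapply(surfaces, tag_pos, character(1), pos_lexicon = pos_lexicon,
                USE.NAMES = FALSE)
  lemma <- mapply(lemmatize, surfaces, pos, USE.NAMES = FALSE)
  tokens <- data.frame(
    surface = surfaces,
    lemma = lemma,
    pos = pos,
    is_content = pos %in% c("noun", "verb", "adjective", "adverb"),
    index = seq_along(surfaces) - 1L,
    stringsAsFactors = FALSE)
  list(tokens = tokens, sentiment = NULL)
}

#' Parse raw text into the internal document model
#'
#' Splits `raw` into sentences, tokenizes each, and attaches a coarse POS
#' tag, a rule-based lemma and a content-word flag to every token. Content
#' words are nouns, verbs, adjectives and adverbs; everything else
#' (function words, punctuation, numerals) is tagged `"other"`. Parsing is
#' deterministic: byte-identical input yields an identical token stream.
#'
#' @param raw character scalar, the document text.
#' @param doc_id document identifier.
#' @param pos_lexicon optional named character vector (lowercase word ->
#'   coarse tag) overriding the built-in tagging rules; the synthetic
#'   cohort generator emits one so tagging is exact on synthetic corpora.
#' @return an object of class `msm_document`: a list with `doc_id`,
#'   `sentences` (each a list with a `tokens` data frame and a `sentiment`
#'   slot), `n_sentences` and `n_tokens`.
#' @examples
#' d <- parse_document("My dream was broken. I moved on.", "ex1")
#' d$n_sentences
#' d$sentences[[1]]$tokens
#' @export
parse_document <- function(raw, doc_id, pos_lexicon = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw)))
    stop("empty document: '", doc_id, "' contains no text", call. = FALSE)
  sents <- split_sentences(raw)
  sentences <- lapply(sents, function(s) {
    toks <- tokenize(s)
    if (length(toks) == 0L) return(NULL)
    .make_sentence(toks, pos_lexicon)
  })
  sentences <- Filter(Negate(is.null), sentences)
  if (length(sentences) == 0L)
    stop("empty document: '", doc_id, "' contains no tokens", call. = FALSE)
  structure(list(
    doc_id = doc_id,
    sentences = sentences,
    n_sentences = length(sentences),
    n_tokens = sum(vapply(sentences, function(s) nrow(s$tokens), integer(1)))),
    class = "msm_document")
}

#' @export
print.msm_document <- function(x, ...) {
  cat("<msm_document> ", x$doc_id, ": ", x$n_sentences, " sentence(s), ",
      x$n_tokens, " token(s)\n", sep = "")
  invisible(x)
}

#' Merge one user's writing records chronologically into a document
#'
#' Emulates per-user social-media writing histories: each record has a
#' user id, a timestamp, an optional title and a body. Records are sorted
#' by ascending timestamp and concatenated (title first when present, each
#' part terminated with a period so sentence splitting is preserved), then
#' parsed with [parse_document()]. The result is invariant to the input
#' order of the records.
#'
#' @param records data frame with columns `user_id`, `timestamp`
#'   (ISO-8601 text or POSIXct), `title`, `body`.
#' @param pos_lexicon passed to [parse_document()].
#' @return an `msm_document` whose `doc_id` is the user id.
#' @export
merge_user_records <- function(records, pos_lexicon = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("user_id", "timestamp", "body") %in% names(records)))
  uid <- unique(records$user_id)
  if (length(uid) != 1L)
    stop("records mix user_ids: ", paste(uid, collapse = ", "), call. = FALSE)
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) {
    fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")
    parse_one <- function(x) {
      for (f in fmts) {
        p <- as.POSIXct(x, tz = "UTC", format = f)
        if (!is.na(p)) return(p)
      }
      as.POSIXct(NA)
    }
    parsed <- do.call(c, lapply(as.character(ts), parse_one))
    bad <- which(is.na(parsed))
    if (length(bad))
      stop("unparseable timestamp in record ", bad[1], " of user '", uid,
           "': '", ts[bad[1]], "'", call. = FALSE)
    ts <- parsed
  }
  ord <- order(ts)
  terminate <- function(x) {
    x <- trimws(x)
    ifelse(!nzchar(x), x, ifelse(grepl("[.!?]$", x), x, paste0(x, ".")))
  }
  title <- if ("title" %in% names(records)) records$title else ""
  title[is.na(title)] <- ""
  parts <- paste(terminate(title[ord]), terminate(records$body[ord]))
  parse_document(paste(trimws(parts), collapse = " "), doc_id = uid,
                 pos_lexicon = pos_lexicon)
}

#' Read a condition label table
#'
#' Reads a CSV with header columns `doc_id`, `condition`, `sick`.
#' Conditions must come from the closed six-condition vocabulary
#' (anxiety, depression, inferiority, sensitivity, social_phobia,
#' obsession); `(doc_id, condition)` pairs must be unique.
#'
#' @param path CSV file path.
#' @return data frame of class `msm_labels` with logical `sick`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("doc_id", "condition", "sick")
  if (!all(need %in% names(df)))
    stop("label table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$condition), .msm_conditions)
  if (length(bad))
    stop("unknown condition(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid conditions are: ", paste(.msm_conditions, collapse = ", "),
         call. = FALSE)
  key <- paste(df$doc_id, df$condition)
  if (anyDuplicated(key))
    stop("duplicate (doc_id, condition) pair: ",
         key[duplicated(key)][1], call. = FALSE)
  sick <- df$sick
  if (!is.logical(sick)) {
    sick <- tolower(as.character(sick)) %in% c("true", "1", "yes", "sick")
  }
  out <- data.frame(doc_id = as.character(df$doc_id),
                    condition = df$condition,
                    sick = sick, stringsAsFactors = FALSE)
  class(out) <- c("msm_labels", "data.frame")
  out
}

#' Serialize a document to the internal JSON form
#'
#' Stable field order: `doc_id`, then per sentence the token table
#' (surface, lemma, pos, is_content, index) and, when present, the
#' sentence sentiment triple. [document_from_json()] reproduces the
#' document exactly.
#'
#' @param doc an `msm_document`.
#' @return character scalar of JSON.
#' @export
document_to_json <- function(doc) {
  stopifnot(inherits(doc, "msm_document"))
  sent <- lapply(doc$sentences, function(s) {
    out <- list(tokens = s$tokens)
    if (!is.null(s$sentiment)) out$sentiment <- s$sentiment
    out
  })
  jsonlite::toJSON(list(doc_id = doc$doc_id, sentences = sent),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname document_to_json
#' @param json JSON text produced by [document_to_json()].
#' @export
document_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                          simplifyVector = TRUE)
  sentences <- lapply(seq_len(nrow_or_len(x$sentences)), function(i) {
    s <- extract_row(x$sentences, i)
    tok <- as.data.frame(s$tokens, stringsAsFactors = FALSE)
    tok$index <- as.integer(tok$index)
    sen <- s$sentiment
    if (!is.null(sen)) {
      sen <- as.list(sen)   # jsonlite may simplify to a named vector
      sen <- list(positive = as.integer(sen$positive),
                  negative = as.integer(sen$negative),
                  overall = as.integer(sen$overall))
    }
    list(tokens = tok, sentiment = sen)
  })
  structure(list(
    doc_id = x$doc_id,
    sentences = sentences,
    n_sentences = length(sentences),
    n_tokens = sum(vapply(sentences, function(s) nrow(s$tokens), integer(1)))),
    class = "msm_document")
}

# jsonlite may return the sentence list as a list (heterogeneous) or a
# data frame (homogeneous); normalize access.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_row <- function(x, i) {
  if (is.data.frame(x)) {
    lapply(x, function(col) {
      if (is.data.frame(col)) as.list(col[i, , drop = FALSE])
      else if (is.list(col)) col[[i]]
      else col[i]
    })
  } else x[[i]]
}
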