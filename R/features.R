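# Document-level feature extraction: the 5-feature metaphor set, the
# 10-feature sentiment set, the labelled design matrix, and the
# group-level comparisons (per-condition means, Welch t tests,
# frequent-metaphor tabulation).

.msm_feature_names <- c(
  "pct_metaphor_tokens", "prob_sentence_with_metaphor",
  "n_pos_metaphor", "n_neg_metaphor", "avg_metaphor_sentiment",
  "mean_pleasantness", "mean_attention", "mean_sensitivity",
  "mean_aptitude", "mean_polarity",
  "frac_pos_sentences", "frac_neg_sentences", "frac_neutral_sentences",
  "avg_sentence_sentiment", "fluctuation")

#' Canonical feature order
#'
#' The fixed 15-name order of the combined feature vector: the 5 metaphor
#' features, then the 5 sentic means, then the 5 sentence-sentiment
#' features.
#'
#' @param set `"all"` (default), `"meta"` (first 5) or `"sent"` (last 10).
#' @return character vector of feature names.
#' @export
feature_names <- function(set = c("all", "meta", "sent")) {
  set <- match.arg(set)
  switch(set,
         all = .msm_feature_names,
         meta = .msm_feature_names[1:5],
         sent = .msm_feature_names[6:15])
}

#' Metaphor-based document features
#'
#' From a document whose tokens carry metaphor labels and whose sentences
#' carry sentiment scores, computes: the fraction of tokens labelled
#' metaphorical; the fraction of sentences containing at least one
#' metaphor; the number of metaphor tokens in positive-sentiment
#' sentences; the number in negative-sentiment sentences (each metaphor
#' token inherits its sentence's overall score; neutral sentences feed
#' neither count); and the mean inherited score over all metaphor tokens
#' (0 when the document has none). Skipped tokens count as literal.
#'
#' @param doc an annotated, scored `msm_document`.
#' @return named numeric vector of the 5 metaphor features.
#' @export
metaphor_features <- function(doc) {
  stopifnot(inherits(doc, "msm_document"))
  n_met <- 0L; n_sent_met <- 0L
  n_pos <- 0L; n_neg <- 0L
  inherited <- numeric(0)
  for (s in doc$sentences) {
    if (is.null(s$tokens$met_label))
      stop("document '", doc$doc_id, "' is not annotated", call. = FALSE)
    if (is.null(s$sentiment))
      stop("document '", doc$doc_id, "' is not sentiment-scored",
           call. = FALSE)
    m <- sum(s$tokens$met_label == "metaphorical", na.rm = TRUE)
    n_met <- n_met + m
    if (m > 0L) {
      n_sent_met <- n_sent_met + 1L
      ov <- s$sentiment$overall
      if (ov > 0) n_pos <- n_pos + m
      if (ov < 0) n_neg <- n_neg + m
      inherited <- c(inherited, rep(ov, m))
    }
  }
  c(pct_metaphor_tokens = n_met / doc$n_tokens,
    prob_sentence_with_metaphor = n_sent_met / doc$n_sentences,
    n_pos_metaphor = n_pos,
    n_neg_metaphor = n_neg,
    avg_metaphor_sentiment = if (length(inherited)) mean(inherited) else 0)
}

#' Sentiment-based document features
#'
#' From the per-sentence overall scores S_1..S_n: the mean score
#' E = sum(S_i)/n; the emotional fluctuation
#' F = sum_{i=2..n} |S_i - S_{i-1}| / (n - 1), defined as 0 for
#' single-sentence documents; the fractions of positive, negative and
#' neutral sentences (by sign of the overall score, summing to 1); and
#' the five sentic means (pleasantness, attention, sensitivity, aptitude,
#' polarity) averaged over the tokens found in the sentic lexicon
#' (lowercase surface, then lemma). A document with no sentic hit gets 0
#' for all five means.
#'
#' @param doc a sentiment-scored `msm_document`.
#' @param sentic an `msm_sentic_lexicon`.
#' @return named numeric vector of the 10 sentiment features.
#' @export
sentiment_features <- function(doc, sentic) {
  stopifnot(inherits(doc, "msm_document"))
  scores <- vapply(doc$sentences, function(s) {
    if (is.null(s$sentiment))
      stop("document '", doc$doc_id, "' is not sentiment-scored",
           call. = FALSE)
    as.numeric(s$sentiment$overall)
  }, numeric(1))
  n <- length(scores)
  E <- mean(scores)
  F_ <- if (n > 1) sum(abs(diff(scores))) / (n - 1) else 0
  dims <- c("pleasantness", "attention", "sensitivity", "aptitude", "polarity")
  hits <- matrix(numeric(0), ncol = 5)
  for (s in doc$sentences) {
    idx <- match(tolower(s$tokens$surface), sentic$word)
    miss <- is.na(idx)
    idx[miss] <- match(s$tokens$lemma[miss], sentic$word)
    idx <- idx[!is.na(idx)]
    if (length(idx))
      hits <- rbind(hits, as.matrix(sentic[idx, dims, drop = FALSE]))
  }
  sentic_means <- if (nrow(hits)) colMeans(hits) else stats::setNames(
    rep(0, 5), dims)
  c(mean_pleasantness = unname(sentic_means[1]),
    mean_attention = unname(sentic_means[2]),
    mean_sensitivity = unname(sentic_means[3]),
    mean_aptitude = unname(sentic_means[4]),
    mean_polarity = unname(sentic_means[5]),
    frac_pos_sentences = mean(scores > 0),
    frac_neg_sentences = mean(scores < 0),
    frac_neutral_sentences = mean(scores == 0),
    avg_sentence_sentiment = E,
    fluctuation = F_)
}

#' Full 15-feature vector for one document
#'
#' @param doc an annotated, scored `msm_document`.
#' @param sentic an `msm_sentic_lexicon`.
#' @return named numeric vector in the [feature_names()] order.
#' @export
feature_vector <- function(doc, sentic) {
  v <- c(metaphor_features(doc), sentiment_features(doc, sentic))
  stopifnot(identical(names(v), .msm_feature_names), all(is.finite(v)))
  v
}

#' Feature table for a corpus
#'
#' @param docs list of annotated, scored `msm_document`s.
#' @param sentic an `msm_sentic_lexicon`.
#' @return data frame: `doc_id` plus the 15 feature columns.
#' @export
featurize_corpus <- function(docs, sentic) {
  rows <- lapply(docs, function(d) {
    data.frame(doc_id = d$doc_id, t(feature_vector(d, sentic)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a labelled dataset for one condition
#'
#' Row-aligns the feature table with the label table for one condition
#' and optionally subsets columns to the metaphor-only or sentiment-only
#' feature set.
#'
#' @param features data frame from [featurize_corpus()].
#' @param labels an `msm_labels` table.
#' @param condition one of the six condition names.
#' @param set `"all"`, `"meta"` or `"sent"`.
#' @return list of class `msm_dataset`: `X` (numeric matrix), `y`
#'   (logical, `TRUE` = sick), `doc_ids`, `condition`, `set`.
#' @export
build_matrix <- function(features, labels, condition,
                         set = c("all", "meta", "sent")) {
  set <- match.arg(set)
  stopifnot(condition %in% .msm_conditions)
  lab <- labels[labels$condition == condition, , drop = FALSE]
  idx <- match(features$doc_id, lab$doc_id)
  if (anyNA(idx))
    stop("no '", condition, "' label for document(s): ",
         paste(features$doc_id[is.na(idx)], collapse = ", "), call. = FALSE)
  cols <- feature_names(set)
  X <- as.matrix(features[, cols, drop = FALSE])
  rownames(X) <- features$doc_id
  structure(list(X = X, y = lab$sick[idx], doc_ids = features$doc_id,
                 condition = condition, set = set),
            class = "msm_dataset")
}

#' @export
print.msm_dataset <- function(x, ...) {
  cat("<msm_dataset> ", x$condition, " [", x$set, "]: ",
      nrow(x$X), " documents x ", ncol(x$X), " features; ",
      sum(x$y), " sick / ", sum(!x$y), " not sick\n", sep = "")
  invisible(x)
}

#' Per-feature sick vs not-sick comparison
#'
#' Welch (unequal-variance) two-sample t test per feature; the t
#' statistic is positive when the sick group's mean is larger.
#'
#' @param dataset an `msm_dataset`; both groups need at least 2 members.
#' @return data frame `feature, mean_sick, mean_not_sick, t, p`; features
#'   degenerate in both groups (zero variance) carry `NA` for t and p.
#' @export
group_compare <- function(dataset) {
  stopifnot(inherits(dataset, "msm_dataset"))
  Xs <- dataset$X[dataset$y, , drop = FALSE]
  Xh <- dataset$X[!dataset$y, , drop = FALSE]
  if (nrow(Xs) < 2 || nrow(Xh) < 2)
    stop("both groups need at least 2 members", call. = FALSE)
  out <- lapply(colnames(dataset$X), function(f) {
    a <- Xs[, f]; b <- Xh[, f]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    data.frame(feature = f, mean_sick = mean(a), mean_not_sick = mean(b),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frequent metaphorically-used lemmas per group
#'
#' Counts metaphor-labelled lemmas within each group of annotated
#' documents, removes the `global_exclude_k` lemmas most frequent across
#' all groups pooled (words metaphorical everywhere carry no group
#' signal), and returns the top `top_k` per group. Ties rank
#' alphabetically for determinism.
#'
#' @param groups named list; each element a list of annotated
#'   `msm_document`s.
#' @param top_k ranked list length per group.
#' @param global_exclude_k how many globally most-frequent metaphor
#'   lemmas to drop (default 0).
#' @return named list of data frames `lemma, count`.
#' @export
frequent_metaphors <- function(groups, top_k = 10, global_exclude_k = 0) {
  count_group <- function(docs) {
    lemmas <- unlist(lapply(docs, function(d) {
      unlist(lapply(d$sentences, function(s) {
        lab <- s$tokens$met_label
        s$tokens$lemma[!is.na(lab) & lab == "metaphorical"]
      }))
    }))
    if (is.null(lemmas)) lemmas <- character(0)
    table(lemmas)
  }
  tabs <- lapply(groups, count_group)
  if (global_exclude_k > 0) {
    lemma <- unlist(lapply(tabs, names), use.names = FALSE)
    cnt <- unlist(lapply(tabs, as.integer), use.names = FALSE)
    pooled <- tapply(cnt, lemma, sum)
    ord <- order(-pooled, names(pooled))   # count desc, lemma asc on ties
    excl <- utils::head(names(pooled)[ord], global_exclude_k)
  } else excl <- character(0)
  lapply(tabs, function(tb) {
    tb <- tb[!names(tb) %in% excl]
    if (length(tb) == 0L)
      return(data.frame(lemma = character(0), count = integer(0)))
    df <- data.frame(lemma = names(tb), count = as.integer(tb),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$lemma), , drop = FALSE]
    rownames(df) <- NULL
    utils::head(df, top_k)
  })
}

#' Write the feature table to CSV in the canonical column order
#'
#' @param features data frame from [featurize_corpus()].
#' @param path destination CSV.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features[, c("doc_id", .msm_feature_names)], path,
                   row.names = FALSE)
}
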