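# Shared fixtures: hand-built documents, a tiny deterministic embedding
# store, random problem instances, and an independent brute-force oracle
# for the best-fit-sense decision (naive loops over every candidate and
# every cosine; shares only the inflection primitive with the package).

# a sentence object from bare words, everything tagged noun/content
hand_sentence <- function(words, pos = rep("noun", length(words)),
                          sentiment = NULL) {
  list(tokens = data.frame(
    surface = words, lemma = tolower(words), pos = pos,
    is_content = pos %in% c("noun", "verb", "adjective", "adverb"),
    index = seq_along(words) - 1L, stringsAsFactors = FALSE),
    sentiment = sentiment)
}

hand_document <- function(sentences, doc_id = "doc") {
  structure(list(doc_id = doc_id, sentences = sentences,
                 n_sentences = length(sentences),
                 n_tokens = sum(vapply(sentences,
                                       function(s) nrow(s$tokens),
                                       integer(1)))),
            class = "msm_document")
}

# attach metaphor labels / sentence scores by hand
set_labels <- function(doc, labels_per_sentence) {
  for (i in seq_along(doc$sentences)) {
    tok <- doc$sentences[[i]]$tokens
    tok$met_label <- labels_per_sentence[[i]]
    doc$sentences[[i]]$tokens <- tok
  }
  doc
}
set_scores <- function(doc, overall) {
  for (i in seq_along(doc$sentences)) {
    ov <- overall[i]
    pos <- if (ov > 0) ov + 1L else 1L
    neg <- if (ov < 0) ov - 1L else -1L
    doc$sentences[[i]]$sentiment <-
      list(positive = as.integer(pos), negative = as.integer(neg),
           overall = as.integer(ov))
  }
  doc
}

# deterministic little store over an explicit vector list
hand_store <- function(vectors_in, vectors_out = vectors_in) {
  words <- names(vectors_in)
  input <- do.call(rbind, vectors_in)
  output <- do.call(rbind, vectors_out)
  rownames(input) <- rownames(output) <- words
  embedding_store(input, output)
}

naive_cosine <- function(u, v) {
  num <- 0; a <- 0; b <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]; a <- a + u[i]^2; b <- b + v[i]^2
  }
  num / (sqrt(a) * sqrt(b))
}

# brute-force re-derivation of one decision: enumerate candidates from the
# ontology entry by hand, average the context vectors with a loop, compute
# every cosine naively, take the lexicographically-smallest argmax, and
# threshold the output-space cosine.
brute_decide <- function(sentence, detected_index, store, ontology,
                         threshold) {
  tok <- sentence$tokens
  r <- which(tok$index == detected_index)
  lemma <- tolower(tok$lemma[r])
  self_in_vocab <- tolower(tok$surface[r]) %in% store$vocab ||
    lemma %in% store$vocab
  if (!self_in_vocab) return(list(label = "skipped"))
  self_word <- if (tolower(tok$surface[r]) %in% store$vocab)
    tolower(tok$surface[r]) else lemma
  ctx <- NULL; n_ctx <- 0
  for (j in seq_len(nrow(tok))) {
    if (j == r) next
    w <- tolower(tok$surface[j])
    if (!w %in% store$vocab) w <- tolower(tok$lemma[j])
    if (!w %in% store$vocab) next
    v <- store$input[w, ]
    ctx <- if (is.null(ctx)) v else ctx + v
    n_ctx <- n_ctx + 1
  }
  if (n_ctx == 0) return(list(label = "skipped"))
  ctx <- ctx / n_ctx
  entry <- ontology[[lemma]]
  cand <- lemma
  if (!is.null(entry) && !is.null(entry[[tok$pos[r]]])) {
    syns <- unlist(entry[[tok$pos[r]]]$synonyms)
    hyps <- unlist(entry[[tok$pos[r]]]$hypernyms)
    base <- tolower(c(syns, hyps))
    base <- base[!grepl("[ _]", base)]
    cand <- c(cand, base)
    for (b in base) cand <- c(cand, inflections(b, tok$pos[r]))
  }
  cand <- c(cand, inflections(lemma, tok$pos[r]))
  cand <- unique(cand)
  best <- NULL; best_sim <- -Inf
  for (k in sort(cand)) {
    kk <- if (k == lemma) self_word else k
    if (!kk %in% store$vocab) next
    s <- naive_cosine(store$input[kk, ], ctx)
    if (s > best_sim + 1e-15) { best_sim <- s; best <- kk; best_name <- k }
  }
  if (is.null(best)) return(list(label = "skipped"))
  sim_out <- naive_cosine(store$output[self_word, ], store$output[best, ])
  list(label = if (sim_out < threshold) "metaphorical" else "literal",
       best_fit = best_name, sim_out = sim_out, sim_ctx = best_sim)
}

# one random problem instance: random store, ontology and sentence
random_instance <- function() {
  dim <- sample(3:6, 1)
  n_words <- sample(8:14, 1)
  vocab <- paste0("w", sample(100:999, n_words))
  input <- matrix(rnorm(n_words * dim), n_words, dim,
                  dimnames = list(vocab, NULL))
  output <- matrix(rnorm(n_words * dim), n_words, dim,
                   dimnames = list(vocab, NULL))
  store <- embedding_store(input, output)
  ont <- list()
  for (w in vocab) {
    if (runif(1) < 0.6) {
      ont[[w]] <- list(noun = list(
        synonyms = as.list(sample(vocab, sample(0:3, 1))),
        hypernyms = as.list(sample(vocab, sample(0:2, 1)))))
    }
  }
  ontology <- structure(ont, class = "msm_ontology")
  n_tok <- sample(3:8, 1)
  words <- c(sample(vocab, n_tok - 1, replace = TRUE), "zzoov")[sample(n_tok)]
  sentence <- hand_sentence(words)
  det <- sample(which(sentence$tokens$is_content &
                        sentence$tokens$surface != "zzoov"), 1)
  list(store = store, ontology = ontology, sentence = sentence,
       detected_index = sentence$tokens$index[det],
       threshold = runif(1))
}

# planted world shared by heavier tests
planted_world <- function(seed = 42, margin = 0.3) {
  espec <- planted_embedding_spec(seed = seed, margin = margin)
  emb <- make_embeddings(espec)
  lex <- make_lexicons(espec)
  list(espec = espec,
       store = embedding_store(emb$input, emb$output),
       truth = emb$truth, lex = lex)
}

run_cohort_cv <- function(world, cspec, set = "all", seed = 1,
                          classifier = "net") {
  coh <- make_cohort(cspec, world$espec, world$lex)
  res <- process_corpus(coh$docs, world$store, world$lex$ontology,
                        world$lex$strength, world$lex$sentic)
  ds <- build_matrix(res$features, coh$labels, cspec$condition, set = set)
  cross_validate(ds, net_spec(seed = seed), smote_config(seed = seed),
                 seed = seed, classifier = classifier)
}

# brute-force membership check: is p on the segment (or ray) defined by
# some pair of minority points?
on_segment <- function(p, A, tol = 1e-9, extrapolated = FALSE) {
  for (i in seq_len(nrow(A))) {
    x <- A[i, ]
    d0 <- p - x
    if (sqrt(sum(d0^2)) <= tol) return(TRUE)
    for (j in seq_len(nrow(A))) {
      if (i == j) next
      dir <- if (extrapolated) A[i, ] - A[j, ] else A[j, ] - A[i, ]
      nd <- sqrt(sum(dir^2))
      if (nd == 0) next
      r <- sum(d0 * dir) / nd^2
      if (r < -tol || r > 1 + tol) next
      if (sqrt(sum((x + r * dir - p)^2)) <= tol) return(TRUE)
    }
  }
  FALSE
}

minority_fixture <- function(n_min = 12, n_maj = 40, seed = 31) {
  set.seed(seed)
  X <- rbind(matrix(runif(n_min * 2), ncol = 2),
             matrix(runif(n_maj * 2, 2, 3), ncol = 2))
  list(X = X, y = rep(c(TRUE, FALSE), c(n_min, n_maj)))
}
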