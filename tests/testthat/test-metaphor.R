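# geometry such that "night" used with prison-like context words selects
# the synonym "cell" whose output vector is near-orthogonal to "night"
planted_pair_store <- function() {
  hand_store(
    vectors_in = list(night = c(0, 1, 0), cell = c(1, 0, 0),
                      wall = c(0.9, 0.1, 0), bars = c(0.95, 0, 0.05),
                      dark = c(0, 0.9, 0.1)),
    vectors_out = list(night = c(0, 1, 0), cell = c(1, 0, 0),
                       wall = c(1, 1, 0), bars = c(1, 0, 1),
                       dark = c(0, 1, 1)))
}
pair_ontology <- function() {
  structure(list(night = list(noun = list(synonyms = list("cell"),
                                          hypernyms = list()))),
            class = "msm_ontology")
}

test_that("singleton candidate sets always come out literal", {
  store <- planted_pair_store()
  ont <- structure(list(), class = "msm_ontology")
  s <- hand_sentence(c("night", "wall"))
  for (thr in c(0.1, 0.5, 1)) {
    d <- decide(s, 0L, store, ont, threshold = thr)
    expect_equal(d$label, "literal")
    expect_equal(d$best_fit, "night")
    expect_equal(d$sim_detected_bestfit, 1)
  }
})

test_that("an impossible threshold makes every word literal", {
  store <- planted_pair_store()
  s <- hand_sentence(c("night", "wall", "bars"))
  d <- decide(s, 0L, store, pair_ontology(), threshold = -1)
  expect_equal(d$label, "literal")
})

test_that("a planted orthogonal best fit is flagged metaphorical", {
  store <- planted_pair_store()
  s <- hand_sentence(c("night", "wall", "bars"))
  d <- decide(s, 0L, store, pair_ontology(), threshold = 0.5)
  expect_equal(d$best_fit, "cell")   # input cosine pulls to the context
  expect_equal(d$sim_detected_bestfit, 0)  # output vectors orthogonal
  expect_equal(d$label, "metaphorical")
  # same word in a night-like context stays literal
  s2 <- hand_sentence(c("night", "dark"))
  d2 <- decide(s2, 0L, store, pair_ontology(), threshold = 0.5)
  expect_equal(d2$best_fit, "night")
  expect_equal(d2$label, "literal")
})

test_that("out-of-vocabulary and no-context words are skipped", {
  store <- planted_pair_store()
  ont <- pair_ontology()
  s_oov <- hand_sentence(c("qqqq", "wall"))
  d <- decide(s_oov, 0L, store, ont)
  expect_equal(d$label, "skipped")
  expect_match(d$skip_reason, "out of vocabulary")
  s_noctx <- hand_sentence(c("night", "qqqq"))
  d2 <- decide(s_noctx, 0L, store, ont)
  expect_equal(d2$label, "skipped")
  expect_match(d2$skip_reason, "context")
})

test_that("exact argmax ties break lexicographically", {
  store <- hand_store(list(bb = c(1, 0), aa = c(1, 0), ctx = c(1, 1),
                           det = c(0, 1)))
  ont <- structure(list(det = list(noun = list(
    synonyms = list("bb", "aa"), hypernyms = list()))),
    class = "msm_ontology")
  cands <- candidate_set("det", ont, pos = "noun", inflect = FALSE)
  bf <- best_fit(cands, vctx = c(1, 1), store,
                 self_row = match("det", store$vocab))
  expect_equal(bf$word, "aa")
})

test_that("decisions agree exactly with the brute-force oracle", {
  set.seed(2024)
  n_agree <- 0L
  for (i in 1:120) {
    inst <- random_instance()
    got <- decide(inst$sentence, inst$detected_index, inst$store,
                  inst$ontology, threshold = inst$threshold)
    want <- brute_decide(inst$sentence, inst$detected_index, inst$store,
                         inst$ontology, inst$threshold)
    expect_equal(got$label, want$label)
    if (want$label != "skipped") {
      expect_equal(got$best_fit, want$best_fit)
      expect_equal(got$sim_detected_bestfit, want$sim_out,
                   tolerance = 1e-12)
    }
    n_agree <- n_agree + 1L
  }
  expect_gte(n_agree, 100L)
})

test_that("metaphor sets nest as the threshold grows", {
  world <- planted_world(seed = 9)
  coh <- make_cohort(cohort_spec(n_sick = 4, n_healthy = 4, seed = 2),
                     world$espec, world$lex)
  grid <- seq(0.05, 0.95, length.out = 10)
  flagged <- lapply(grid, function(thr) {
    ann <- lapply(coh$docs, annotate_document, store = world$store,
                  ontology = world$lex$ontology, threshold = thr)
    unlist(lapply(ann, function(d) {
      lapply(seq_along(d$sentences), function(si) {
        tok <- d$sentences[[si]]$tokens
        met <- !is.na(tok$met_label) & tok$met_label == "metaphorical"
        if (any(met)) paste(d$doc_id, si, tok$index[met]) else character(0)
      })
    }))
  })
  for (k in seq_along(grid)[-1])
    expect_true(all(flagged[[k - 1]] %in% flagged[[k]]))
})

test_that("annotation is idempotent, total, and skips auxiliaries", {
  world <- planted_world(seed = 4)
  coh <- make_cohort(cohort_spec(n_sick = 3, n_healthy = 3, seed = 3),
                     world$espec, world$lex)
  a1 <- annotate_document(coh$docs[[1]], world$store, world$lex$ontology)
  a2 <- annotate_document(a1, world$store, world$lex$ontology)
  lab1 <- lapply(a1$sentences, function(s) s$tokens$met_label)
  lab2 <- lapply(a2$sentences, function(s) s$tokens$met_label)
  expect_identical(lab1, lab2)
  for (s in a1$sentences) {
    expect_true(all(!is.na(s$tokens$met_label[s$tokens$is_content])))
    expect_true(all(is.na(s$tokens$met_label[!s$tokens$is_content])))
  }
  d <- parse_document("He was here.", "aux")
  ann <- annotate_document(d, world$store, world$lex$ontology)
  tok <- ann$sentences[[1]]$tokens
  expect_equal(tok$met_skip[tok$surface == "was"], "auxiliary")
})

test_that("a document without content words yields no decisions", {
  d <- parse_document("It was of the in and!", "none")
  d$sentences[[1]]$tokens$is_content <- FALSE   # force the degenerate case
  world <- planted_world(seed = 4)
  ann <- annotate_document(d, world$store, world$lex$ontology)
  expect_true(all(is.na(ann$sentences[[1]]$tokens$met_label)))
})

test_that("identification scoring matches hand-counted confusions", {
  labels <- c("metaphorical", "literal", "metaphorical", "literal",
              "literal", "metaphorical", "literal", "literal",
              "literal", "literal")
  doc <- hand_document(list(hand_sentence(paste0("t", 1:10))), "g1")
  # predictions: 2 TP, 1 FP, 1 FN over the 10 tokens
  pred <- c("metaphorical", "metaphorical", "metaphorical", "literal",
            "literal", "literal", "literal", "literal",
            "literal", "literal")
  doc <- set_labels(doc, list(pred))
  gold <- data.frame(doc_id = "g1", sentence_index = 0L,
                     token_index = 0:9, label = labels,
                     stringsAsFactors = FALSE)
  ev <- evaluate_identification(gold, list(doc))
  expect_equal(unname(ev$counts), c(2L, 1L, 1L, 6L))
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$f1, 2 / 3)

  # perfect predictions
  doc_perfect <- set_labels(doc, list(labels))
  evp <- evaluate_identification(gold, list(doc_perfect))
  expect_equal(c(evp$precision, evp$recall, evp$f1), c(1, 1, 1))

  # all-literal predictions have zero recall and F1
  doc_lit <- set_labels(doc, list(rep("literal", 10)))
  evl <- evaluate_identification(gold, list(doc_lit))
  expect_equal(evl$recall, 0)
  expect_equal(evl$f1, 0)

  bad_gold <- data.frame(doc_id = "g1", sentence_index = 0L,
                         token_index = 99L, label = "literal")
  expect_error(evaluate_identification(bad_gold, list(doc)), "g1:0:99")
})
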