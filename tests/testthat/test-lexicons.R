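strength_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("word,pos_strength,neg_strength", lines), path)
  path
}

test_that("strength lexicon loads, range-checks and deduplicates", {
  lex <- load_strength_lexicon(strength_file(c("glad,3,-1", "grim,1,-4")))
  expect_equal(nrow(lex), 2L)
  expect_error(load_strength_lexicon(strength_file("odd,7,-1")),
               "out of range")
  expect_warning(
    lex2 <- load_strength_lexicon(strength_file(c("glad,2,-1",
                                                  "glad,5,-1"))),
    "last")
  expect_equal(lex2$pos_strength, 5L)
})

test_that("sentic lexicon enforces the [-1, 1] range", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("word,pleasantness,attention,sensitivity,aptitude,polarity",
               "calm,0.7,-0.2,0.1,0.4,0.6"), path)
  lex <- load_sentic_lexicon(path)
  expect_equal(lex$pleasantness, 0.7)
  writeLines(c("word,pleasantness,attention,sensitivity,aptitude,polarity",
               "calm,1.7,0,0,0,0"), path)
  expect_error(load_sentic_lexicon(path), "outside")
})

test_that("sentence scores aggregate by maximum magnitude", {
  lex <- load_strength_lexicon(strength_file(c("glad,3,-1", "grim,1,-4",
                                               "proud,5,-1")))
  s_none <- hand_sentence(c("nothing", "matches", "here"))
  expect_equal(sentence_sentiment(s_none, lex),
               list(positive = 1L, negative = -1L, overall = 0L))

  s_two <- hand_sentence(c("glad", "but", "grim"))
  sc <- sentence_sentiment(s_two, lex)
  expect_equal(sc$positive, 3L)
  expect_equal(sc$negative, -4L)
  expect_equal(sc$overall, -1L)

  expect_equal(sentence_sentiment(hand_sentence("proud"), lex)$overall, 4L)
})

test_that("overall scores stay in [-4, 4] and neutral iff pos = -neg", {
  lex <- load_strength_lexicon(strength_file(
    sprintf("w%d%d,%d,%d", rep(1:5, 5), rep(1:5, each = 5),
            rep(1:5, 5), -rep(1:5, each = 5))))
  set.seed(7)
  for (i in 1:50) {
    words <- sample(c(lex$word, "oov1", "oov2"), sample(1:6, 1),
                    replace = TRUE)
    sc <- sentence_sentiment(hand_sentence(words), lex)
    expect_gte(sc$overall, -4L)
    expect_lte(sc$overall, 4L)
    expect_equal(sc$overall == 0L, sc$positive == -sc$negative)
  }
})

test_that("negation flag mirrors a strength word's contribution", {
  lex <- load_strength_lexicon(strength_file("glad,4,-1"))
  s <- hand_sentence(c("not", "glad"),
                     pos = c("other", "adjective"))
  expect_equal(sentence_sentiment(s, lex)$overall, 3L)
  expect_equal(sentence_sentiment(s, lex, negation = TRUE)$overall, -3L)
})

fixture_ontology <- function() {
  structure(list(
    broken = list(adjective = list(synonyms = list("damaged"),
                                   hypernyms = list("changed"))),
    meet = list(verb = list(synonyms = list("encounter", "hand over"),
                            hypernyms = list()))),
    class = "msm_ontology")
}

test_that("candidate sets enumerate self, synonyms, hypernyms, inflections", {
  cs <- candidate_set("broken", fixture_ontology(), pos = "adjective")
  expect_true(all(c("broken", "damaged", "changed") %in% cs$candidates))
  # adjective inflections of the synonym
  expect_true("damageder" %in% cs$candidates ||
                "damager" %in% cs$candidates)
  expect_equal(cs$provenance[cs$candidates == "damaged"], "synonym")
  expect_equal(cs$provenance[cs$candidates == "changed"], "hypernym")
  expect_true(cs$in_ontology)
  expect_equal(cs$candidates[1], "broken")
  expect_false(anyDuplicated(cs$candidates) > 0)
})

test_that("multiword candidates are dropped and unknown words degrade", {
  cs <- candidate_set("meet", fixture_ontology(), pos = "verb")
  expect_false(any(grepl(" ", cs$candidates)))
  expect_true("encounter" %in% cs$candidates)

  cs2 <- candidate_set("unseen", fixture_ontology(), pos = "noun",
                       inflect = FALSE)
  expect_equal(cs2$candidates, "unseen")
  expect_false(cs2$in_ontology)
})

test_that("growing the ontology never removes candidates", {
  ont <- fixture_ontology()
  before <- candidate_set("broken", ont, pos = "adjective")$candidates
  ont$broken$adjective$synonyms <- c(ont$broken$adjective$synonyms, "torn")
  after <- candidate_set("broken", ont, pos = "adjective")$candidates
  expect_true(all(before %in% after))
  expect_true("torn" %in% after)
})

test_that("rule-based inflections apply doubling, e-drop and y rules", {
  expect_setequal(inflections("stop", "verb"),
                  c("stops", "stoped", "stoping", "stopped", "stopping"))
  expect_true(all(c("moved", "moving", "moves") %in%
                    inflections("move", "verb")))
  expect_true(all(c("carries", "carried") %in% inflections("carry", "verb")))
  expect_setequal(inflections("happy", "adjective"),
                  c("happier", "happiest"))
  expect_true("boxes" %in% inflections("box", "noun"))
})

test_that("precomputed sentence scores can replace the lexicon backend", {
  d <- parse_document("It began well. It ended badly.", "p1")
  sc <- data.frame(doc_id = "p1", sentence_index = 0:1,
                   pos = c(3L, 1L), neg = c(-1L, -4L))
  d2 <- score_document(d, scores = sc)
  expect_equal(d2$sentences[[1]]$sentiment$overall, 2L)
  expect_equal(d2$sentences[[2]]$sentiment$overall, -3L)
  expect_error(score_document(d, scores = sc[1, , drop = FALSE]),
               "sentence 1")
})
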