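sentic_fixture <- function() {
  structure(data.frame(
    word = c("sea", "storm", "calm", "grief", "hope", "stone"),
    pleasantness = c(0.2, -0.6, 0.8, -0.9, 0.7, 0.0),
    attention = c(0.1, 0.9, -0.3, 0.2, 0.4, -0.1),
    sensitivity = c(0.0, 0.5, -0.2, 0.6, -0.1, 0.1),
    aptitude = c(0.3, -0.4, 0.6, -0.7, 0.5, 0.2),
    polarity = c(0.2, -0.5, 0.7, -0.8, 0.6, 0.0),
    stringsAsFactors = FALSE),
    class = c("msm_sentic_lexicon", "data.frame"))
}

# 3 sentences, 4 + 3 + 3 = 10 tokens; metaphors: 2 in sentence 1
# (overall +2), 1 in sentence 2 (overall -1), none in sentence 3
ten_token_doc <- function() {
  doc <- hand_document(list(
    hand_sentence(c("sea", "storm", "calm", "stone")),
    hand_sentence(c("grief", "hope", "sea")),
    hand_sentence(c("stone", "calm", "hope"))), "f1")
  doc <- set_labels(doc, list(
    c("metaphorical", "metaphorical", "literal", "literal"),
    c("literal", "metaphorical", "literal"),
    c("literal", "literal", "literal")))
  set_scores(doc, c(2L, -1L, 0L))
}

test_that("metaphor features match the hand-counted fixture", {
  mf <- metaphor_features(ten_token_doc())
  expect_equal(unname(mf["pct_metaphor_tokens"]), 0.3)
  expect_equal(unname(mf["prob_sentence_with_metaphor"]), 2 / 3)
  expect_equal(unname(mf["n_pos_metaphor"]), 2)
  expect_equal(unname(mf["n_neg_metaphor"]), 1)
  expect_equal(unname(mf["avg_metaphor_sentiment"]), (2 + 2 - 1) / 3)
})

test_that("documents without metaphors or with neutral sentences degrade", {
  doc <- ten_token_doc()
  doc <- set_labels(doc, list(rep("literal", 4), rep("literal", 3),
                              rep("literal", 3)))
  expect_equal(unname(metaphor_features(doc)),
               c(0, 0, 0, 0, 0))
  # all-neutral sentences: metaphors belong to neither polarity count
  doc2 <- ten_token_doc()
  doc2 <- set_scores(doc2, c(0L, 0L, 0L))
  mf <- metaphor_features(doc2)
  expect_equal(unname(mf["n_pos_metaphor"]), 0)
  expect_equal(unname(mf["n_neg_metaphor"]), 0)
  expect_equal(unname(mf["avg_metaphor_sentiment"]), 0)
  expect_error(metaphor_features(hand_document(list(hand_sentence("a")))),
               "not annotated")
})

test_that("E and F follow their defining sums", {
  doc <- ten_token_doc()
  doc <- set_scores(doc, c(2L, -3L, 1L))
  sf <- sentiment_features(doc, sentic_fixture())
  expect_equal(unname(sf["avg_sentence_sentiment"]), 0)
  expect_equal(unname(sf["fluctuation"]), (5 + 4) / 2)

  doc_const <- set_scores(doc, c(1L, 1L, 1L))
  sfc <- sentiment_features(doc_const, sentic_fixture())
  expect_equal(unname(sfc["fluctuation"]), 0)
  expect_equal(unname(sfc["frac_pos_sentences"]), 1)

  one <- hand_document(list(hand_sentence(c("sea", "storm"))), "one")
  one <- set_scores(one, 3L)
  expect_equal(unname(sentiment_features(one,
                                         sentic_fixture())["fluctuation"]),
               0)
})

test_that("sentic means average over matched tokens only", {
  # tokens: sea, storm, calm, stone, grief, hope, sea, stone, calm, hope
  doc <- set_scores(ten_token_doc(), c(1L, -1L, 0L))
  sf <- sentiment_features(doc, sentic_fixture())
  lx <- sentic_fixture()
  words <- c("sea", "storm", "calm", "stone", "grief", "hope",
             "sea", "stone", "calm", "hope")
  for (d in c("pleasantness", "attention", "sensitivity", "aptitude",
              "polarity")) {
    hand <- mean(lx[[d]][match(words, lx$word)])
    expect_equal(unname(sf[paste0("mean_", d)]), hand)
  }
  # no lexicon hits -> all five means are 0
  doc_oov <- hand_document(list(hand_sentence(c("qq", "zz"))), "oov")
  doc_oov <- set_scores(doc_oov, 0L)
  sf_oov <- sentiment_features(doc_oov, sentic_fixture())
  expect_equal(unname(sf_oov[1:5]), rep(0, 5))
})

test_that("sentence fractions always sum to one", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    doc <- hand_document(rep(list(hand_sentence(c("sea", "calm"))), n))
    doc <- set_scores(doc, sample(-4:4, n, replace = TRUE))
    sf <- sentiment_features(doc, sentic_fixture())
    expect_equal(unname(sum(sf[c("frac_pos_sentences", "frac_neg_sentences",
                                 "frac_neutral_sentences")])), 1,
                 tolerance = 1e-9)
  }
})

test_that("E shifts with translation while F is unchanged", {
  doc <- ten_token_doc()
  base <- set_scores(doc, c(2L, -3L, 1L))
  shift <- set_scores(doc, c(2L, -3L, 1L) + 1L)
  sf0 <- sentiment_features(base, sentic_fixture())
  sf1 <- sentiment_features(shift, sentic_fixture())
  expect_equal(unname(sf1["avg_sentence_sentiment"]),
               unname(sf0["avg_sentence_sentiment"]) + 1)
  expect_equal(unname(sf1["fluctuation"]), unname(sf0["fluctuation"]))
})

test_that("sentence order moves F but not the metaphor rates", {
  doc <- ten_token_doc()
  doc <- set_scores(doc, c(2L, -3L, 1L))
  reordered <- hand_document(doc$sentences[c(2, 1, 3)], "f1")
  expect_equal(metaphor_features(reordered)[c(1, 2)],
               metaphor_features(doc)[c(1, 2)])
  f_orig <- sentiment_features(doc, sentic_fixture())["fluctuation"]
  f_re <- sentiment_features(reordered, sentic_fixture())["fluctuation"]
  expect_false(isTRUE(all.equal(unname(f_orig), unname(f_re))))
})

test_that("avg metaphor sentiment is bracketed by metaphor-sentence scores", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    scores <- sample(-4:4, n, replace = TRUE)
    labs <- lapply(seq_len(n), function(j)
      sample(c("metaphorical", "literal"), 2, replace = TRUE))
    doc <- hand_document(lapply(seq_len(n), function(j)
      hand_sentence(c("sea", "calm"))))
    doc <- set_labels(doc, labs)
    doc <- set_scores(doc, scores)
    has_met <- vapply(labs, function(l) any(l == "metaphorical"),
                      logical(1))
    if (!any(has_met)) next
    mf <- metaphor_features(doc)
    expect_lte(unname(mf["avg_metaphor_sentiment"]),
               max(scores[has_met]))
    expect_gte(unname(mf["avg_metaphor_sentiment"]),
               min(scores[has_met]))
  }
})

test_that("design matrices align labels and subset feature sets", {
  world <- planted_world(seed = 21)
  coh <- make_cohort(cohort_spec(n_sick = 4, n_healthy = 6, seed = 5),
                     world$espec, world$lex)
  res <- process_corpus(coh$docs, world$store, world$lex$ontology,
                        world$lex$strength, world$lex$sentic)
  ds <- build_matrix(res$features, coh$labels, "inferiority")
  expect_equal(dim(ds$X), c(10L, 15L))
  expect_equal(colnames(ds$X), feature_names("all"))
  expect_equal(sum(ds$y), 4L)
  ds_m <- build_matrix(res$features, coh$labels, "inferiority", set = "meta")
  expect_equal(ncol(ds_m$X), 5L)
  ds_s <- build_matrix(res$features, coh$labels, "inferiority", set = "sent")
  expect_equal(ncol(ds_s$X), 10L)

  short <- coh$labels[-1, , drop = FALSE]
  expect_error(build_matrix(res$features, short, "inferiority"),
               coh$labels$doc_id[1])

  # deterministic serialization
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_features(res$features, p1)
  write_features(res$features, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("group comparisons use the Welch t and its sign convention", {
  mkds <- function(X, y) structure(list(X = X, y = y, set = "all",
                                        condition = "depression"),
                                   class = "msm_dataset")
  X <- matrix(rnorm(40), 20, 2,
              dimnames = list(NULL, c("f1", "f2")))
  same <- rbind(X, X)
  gs <- group_compare(mkds(same, rep(c(TRUE, FALSE), each = 20)))
  expect_equal(gs$t, c(0, 0))

  set.seed(99)
  Xs <- cbind(a = rnorm(200, 1), b = rnorm(200))
  Xh <- cbind(a = rnorm(200, 0), b = rnorm(200))
  gs2 <- group_compare(mkds(rbind(Xs, Xh),
                            rep(c(TRUE, FALSE), each = 200)))
  diff <- gs2$mean_sick[1] - gs2$mean_not_sick[1]
  se <- sqrt(1 / 200 + 1 / 200)
  expect_lt(abs(diff - 1), 3 * se)
  expect_gt(gs2$t[1], 0)   # sick mean larger -> positive t
  # agrees with stats::t.test directly
  tt <- t.test(Xs[, "a"], Xh[, "a"])
  expect_equal(gs2$t[1], unname(tt$statistic))
  expect_equal(gs2$p[1], tt$p.value)
})

test_that("frequent metaphor rankings count and exclude correctly", {
  mk_doc <- function(words, labels, id) {
    d <- hand_document(list(hand_sentence(words)), id)
    set_labels(d, list(labels))
  }
  g1 <- list(mk_doc(c("fire", "fire", "rain", "stone"),
                    c("metaphorical", "metaphorical", "metaphorical",
                      "literal"), "a"))
  g2 <- list(mk_doc(c("fire", "wind", "wind", "wind"),
                    c("metaphorical", "metaphorical", "metaphorical",
                      "metaphorical"), "b"))
  plain <- frequent_metaphors(list(g1 = g1), top_k = 5)
  expect_equal(plain$g1$lemma, c("fire", "rain"))
  expect_equal(plain$g1$count, c(2L, 1L))

  both <- frequent_metaphors(list(g1 = g1, g2 = g2), top_k = 5,
                             global_exclude_k = 1)
  # "fire" (3 pooled) is the global top -> absent everywhere
  expect_false("fire" %in% both$g1$lemma)
  expect_false("fire" %in% both$g2$lemma)
  expect_equal(both$g2$lemma[1], "wind")

  empty <- frequent_metaphors(list(e = list()), top_k = 3)
  expect_equal(nrow(empty$e), 0L)
})
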