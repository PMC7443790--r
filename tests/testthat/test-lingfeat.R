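# linguistic feature extraction: segmentation, LSA coherence, tagging,
# assembly and the degenerate-feature filter

test_that("sentence segmentation splits on terminal punctuation with guards", {
  t1 <- segment_sentences("I went home. It was late.")
  expect_length(t1$sentences, 2)
  expect_equal(tolower(t1$sentences[[1]]), c("i", "went", "home"))
  expect_equal(tolower(t1$sentences[[2]]), c("it", "was", "late"))

  # ellipsis collapses to a single boundary
  t2 <- segment_sentences("Wait... what?")
  expect_length(t2$sentences, 2)
  expect_equal(tolower(unlist(t2$sentences)), c("wait", "what"))

  # abbreviation and decimal guards
  t3 <- segment_sentences("I saw Dr. Smith at 3.5 pm. He waved.")
  expect_length(t3$sentences, 2)

  expect_error(segment_sentences(""), class = "empty_transcript")
  expect_error(segment_sentences("... !!"), class = "empty_transcript")
})

test_that("speaker-prefix filter keeps only the requested speaker", {
  raw <- "I: How are you?\nP: I am fine today.\nP: It was a long day."
  t <- segment_sentences(raw, keep_speaker = "P")
  expect_length(t$sentences, 2)
  expect_false(any(grepl("how", tolower(unlist(t$sentences)))))
})

test_that("sentence length statistics use the sample sd convention", {
  t <- make_transcript(list(letters[1:5]))
  expect_equal(unname(sentence_length_stats(t)), c(5, 5, 5, 0))

  t <- make_transcript(list(letters[1:3], letters[1:5], letters[1:7]))
  expect_equal(unname(sentence_length_stats(t)), c(3, 7, 5, 2))

  t <- make_transcript(rep(list(letters[1:4]), 4))
  expect_equal(unname(sentence_length_stats(t)), c(4, 4, 4, 0))
})

test_that("stat quadruples agree with brute-force recomputation", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      x <- if (i %% 2) sample.int(30, sample(1:12, 1), replace = TRUE)
           else stats::runif(sample(1:12, 1), -1, 1)
      got <- coherence_stats(x)
      expect_equal(unname(got),
                   c(min(x), max(x), mean(x),
                     if (length(x) > 1) stats::sd(x) else 0))
    }
  })
})

test_that("semantic space separates disjoint vocabularies", {
  ta <- make_transcript(list(c("apple", "banana", "apple")), "a")
  tb <- make_transcript(list(c("table", "chair", "chair")), "b")
  sp <- build_semantic_space(list(ta, tb), k = 2, weighting = "tf")
  va <- sentence_vector("apple", sp)
  vb <- sentence_vector("table", sp)
  expect_lt(abs(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))), 1e-9)
})

test_that("tokens in identical contexts get near-identical directions", {
  # two tokens always co-occurring in the same passages: duplicate rows of
  # the term-passage matrix, hence equal left singular vector rows
  sents <- list(c("red", "blue", "sky"), c("red", "blue", "sea"),
                c("red", "blue", "sun"), c("cloud", "rain", "storm"),
                c("cloud", "wind", "storm"))
  sp <- build_semantic_space(make_transcript(sents), k = 3, weighting = "tf")
  v1 <- sp$vectors["red", ]; v2 <- sp$vectors["blue", ]
  expect_gte(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), 0.99)
})

test_that("rank-deficient corpora reduce k with a warning", {
  t <- make_transcript(list(c("a", "b"), c("a", "b")))
  expect_warning(sp <- build_semantic_space(t, k = 2, weighting = "tf"),
                 class = "rank_deficient")
  expect_lt(sp$k, 2)
  expect_error(build_semantic_space(t, k = 10), class = "vocabulary_too_small")
})

test_that("sentence vectors average in-vocabulary tokens and flag OOV", {
  sp <- make_space(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(sentence_vector("a", sp), c(1, 0))
  expect_equal(sentence_vector(c("a", "b"), sp), c(0.5, 0.5))
  v <- sentence_vector(c("zz", "qq"), sp)
  expect_equal(as.numeric(v), c(0, 0))
  expect_true(isTRUE(attr(v, "oov")))
})

test_that("coherence series matches closed-form cosines and skips OOV pairs", {
  sp <- make_space(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1)))
  t <- make_transcript(list("a", "a"))
  expect_equal(as.numeric(coherence_series(t, sp)), 1.0)
  t <- make_transcript(list("a", "b"))
  expect_equal(as.numeric(coherence_series(t, sp)), 0.0)
  t <- make_transcript(list("a", "c"))
  expect_equal(as.numeric(coherence_series(t, sp)), 0.70710678, tolerance = 1e-7)
  # OOV middle sentence: both adjacent pairs skipped
  t <- make_transcript(list("a", "zz", "b"))
  expect_error(coherence_series(t, sp), class = "all_pairs_skipped")
  t <- make_transcript(list("a", "zz", "b", "c"))
  s <- coherence_series(t, sp)
  expect_length(s, 1)
  expect_equal(attr(s, "n_skipped"), 2)
  expect_error(coherence_series(make_transcript(list("a")), sp),
               class = "empty_transcript")
})

test_that("coherence values stay in [-1, 1] and are reversal-symmetric", {
  g <- generate_transcripts(4, list(n_sentences = 12), seed = 3)
  sp <- build_semantic_space(g$transcripts, k = 10)
  for (t in g$transcripts) {
    s <- coherence_series(t, sp)
    expect_true(all(s >= -1 - 1e-9 & s <= 1 + 1e-9))
    trev <- make_transcript(rev(t$sentences), t$subject_id)
    expect_equal(as.numeric(coherence_series(trev, sp)),
                 rev(as.numeric(s)))
  }
})

test_that("coherence stats follow the sample-sd convention", {
  expect_equal(unname(coherence_stats(1.0)), c(1, 1, 1, 0))
  expect_equal(unname(coherence_stats(c(0.2, 0.4, 0.6))),
               c(0.2, 0.6, 0.4, 0.2))
  expect_equal(unname(coherence_stats(c(0, 0))), c(0, 0, 0, 0))
})

test_that("POS tag frequencies are normalized over the configured tagset", {
  t <- make_transcript(list(c("the", "cat", "sat")))
  f <- pos_tag_frequencies(t)
  expect_equal(unname(f[c("DT", "NN", "VBD")]), rep(1 / 3, 3))
  expect_equal(sum(f), 1)
  expect_equal(sum(f[setdiff(names(f), c("DT", "NN", "VBD"))]), 0)

  t1 <- make_transcript(list("slowly"))
  f1 <- pos_tag_frequencies(t1)
  expect_equal(unname(f1["RB"]), 1)
  expect_equal(sum(f1), 1)
})

test_that("tag frequencies sum to one on random synthetic transcripts", {
  g <- generate_transcripts(6, list(n_sentences = 8), seed = 5)
  for (t in g$transcripts) {
    f <- pos_tag_frequencies(t)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
  }
  # reduced tagset pools the remainder into "other"
  f <- pos_tag_frequencies(g$transcripts[[1]], tagset = c("NN", "DT"))
  expect_named(f, c("NN", "DT", "other"))
  expect_equal(sum(f), 1)
  expect_gt(f[["other"]], 0)
})

test_that("feature matrix assembly enforces its contracts", {
  g <- generate_transcripts(3, list(n_sentences = 10), seed = 9)
  sp <- build_semantic_space(g$transcripts, k = 10)
  vecs <- lapply(g$transcripts, linguistic_features, space = sp)
  m <- assemble_linguistic_matrix(vecs)
  expect_equal(dim(m), c(3, 8 + 37))
  expect_equal(rownames(m), names(g$transcripts))
  expect_equal(attr(m, "provenance"), "language")
  expect_true(all(c("sentlen_mean", "coh_sd", "pos_CC", "pos_other") %in%
                    colnames(m)))
  # invariants of each vector
  for (v in vecs) {
    expect_lte(v[["sentlen_min"]], v[["sentlen_mean"]])
    expect_lte(v[["sentlen_mean"]], v[["sentlen_max"]])
    expect_lte(v[["coh_min"]], v[["coh_mean"]])
  }

  expect_error(assemble_linguistic_matrix(vecs[1]),
               class = "insufficient_subjects")
  dup <- vecs; attr(dup[[2]], "subject_id") <- attr(dup[[1]], "subject_id")
  expect_error(assemble_linguistic_matrix(dup), class = "duplicate_subject")
  odd <- vecs; names(odd[[3]])[1] <- "renamed"
  expect_error(assemble_linguistic_matrix(odd),
               class = "inconsistent_feature_sets")
})

test_that("subject order permutation permutes rows and nothing else", {
  g <- generate_transcripts(5, list(n_sentences = 10), seed = 13)
  sp <- build_semantic_space(g$transcripts, k = 10)
  vecs <- lapply(g$transcripts, linguistic_features, space = sp)
  m1 <- assemble_linguistic_matrix(vecs)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- assemble_linguistic_matrix(vecs[perm])
  expect_equal(m2, m1[perm, ], ignore_attr = TRUE)
  expect_equal(colnames(m2), colnames(m1))
})

test_that("degenerate-feature filter applies the strict majority rule", {
  m <- cbind(a = c(1, 1, 1, 2), b = c(1, 2, 1, 2), c = c(3, 3, 3, 3),
             d = stats::rnorm(4))
  out <- drop_degenerate_features(m, threshold = 0.5)
  expect_setequal(out$dropped, c("a", "c"))       # 0.75 > 0.5; constant
  expect_equal(colnames(out$matrix), c("b", "d")) # 0.5 not > 0.5: retained
  # idempotence
  out2 <- drop_degenerate_features(out$matrix, threshold = 0.5)
  expect_equal(out2$matrix, out$matrix, ignore_attr = TRUE)
  expect_length(out2$dropped, 0)
  expect_error(drop_degenerate_features(cbind(k = rep(1, 5))),
               class = "all_features_dropped")
})

test_that("feature matrices round-trip through TSV", {
  m <- matrix(stats::rnorm(12), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, path)
  m2 <- read_feature_matrix(path)
  expect_equal(m2, m, ignore_attr = TRUE, tolerance = 1e-12)
})
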