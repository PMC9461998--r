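test_that("cluster count aggregation equals brute-force summation", {
  wc <- make_word_counts(n_words = 50, seed = 21)
  labels <- rep_len(1:4, 50)
  cm <- make_cluster_model(wc$words, labels, k = 4)
  cc <- aggregate_cluster_counts(wc$unigrams, wc$bigrams, cm)

  # oracle: explicit nested loop over all word pairs
  uni_oracle <- numeric(4)
  for (i in seq_len(nrow(wc$unigrams))) {
    cl <- labels[match(wc$unigrams$word[i], wc$words)]
    uni_oracle[cl] <- uni_oracle[cl] + wc$unigrams$count[i]
  }
  big_oracle <- matrix(0, 4, 4)
  for (i in seq_len(nrow(wc$bigrams))) {
    c1 <- labels[match(wc$bigrams$word1[i], wc$words)]
    c2 <- labels[match(wc$bigrams$word2[i], wc$words)]
    big_oracle[c1, c2] <- big_oracle[c1, c2] + wc$bigrams$count[i]
  }
  expect_equal(cc$unigram, uni_oracle)
  expect_equal(cc$bigram, big_oracle)
  expect_equal(cc$total_tokens, sum(wc$unigrams$count))
})

test_that("aggregation handles simple and out-of-vocabulary cases", {
  cm <- make_cluster_model(c("red", "big", "tall"), c(3, 1, 2), k = 3)
  cc <- aggregate_cluster_counts(
    data.frame(word = "red", count = 10), NULL, cm)
  expect_equal(cc$unigram, c(0, 0, 10))
  expect_equal(sum(cc$bigram), 0)

  # two clusters, additivity of bigrams into the same cell
  cm2 <- make_cluster_model(c("a", "b", "c"), c(1, 2, 2), k = 2)
  cc2 <- aggregate_cluster_counts(
    data.frame(word = c("a", "b", "c"), count = c(1, 1, 1)),
    data.frame(word1 = c("a", "a"), word2 = c("b", "c"), count = c(4, 6)),
    cm2)
  expect_equal(cc2$bigram[1, 2], 10)

  expect_error(aggregate_cluster_counts(
    data.frame(word = "unknown", count = 1), NULL, cm), "missing")
  cc3 <- aggregate_cluster_counts(
    data.frame(word = c("red", "unknown"), count = c(5, 7)), NULL, cm,
    oov = "drop")
  expect_equal(cc3$unigram[3], 5)
  expect_error(aggregate_cluster_counts(
    data.frame(word = "red", count = -1), NULL, cm), "negative")
})

test_that("cluster surprisal reproduces the raw-count formula and smoothing", {
  big <- matrix(0, 6, 6); big[1, 2] <- 25
  cc <- cluster_counts(c(100, rep(1, 5)), big)
  # -ln(25/100), raw-count formula
  expect_equal(cluster_surprisal(1, 2, cc, alpha = 0), -log(0.25),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cluster_surprisal(1, 2, cc, base = 2, alpha = 0), 2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # probability-one context
  big1 <- matrix(0, 6, 6); big1[3, 3] <- 40
  cc1 <- cluster_counts(c(1, 1, 40, 1, 1, 1), big1)
  expect_equal(cluster_surprisal(3, 3, cc1, alpha = 0), 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  # empty counts with smoothing: uniform 1/k
  cc0 <- cluster_counts(rep(0, 6), matrix(0, 6, 6))
  expect_equal(cluster_surprisal(2, 5, cc0, alpha = 0.5), log(6),
               tolerance = 1e-12, ignore_attr = TRUE)
  # zero bigram with alpha = 0: flagged infinity, not an error
  s_inf <- cluster_surprisal(1, 3, cc, alpha = 0)
  expect_true(is.infinite(s_inf))
  expect_equal(attr(s_inf, "n_infinite"), 1L)
  # zero unigram with alpha = 0: undefined context
  cc_zero <- cluster_counts(c(100, 0, rep(1, 4)), matrix(0, 6, 6))
  expect_error(cluster_surprisal(2, 1, cc_zero, alpha = 0),
               "undefined context")
  expect_error(cluster_surprisal(0, 1, cc), "1..k")
})

test_that("smoothed next-cluster probabilities sum to one on accumulated counts", {
  set.seed(5)
  k <- 4
  trials <- data.frame(speaker = "S1",
                       c1 = sample.int(k, 40, TRUE),
                       c2 = sample.int(k, 40, TRUE))
  # accumulate counts the way the trajectory does
  uni <- numeric(k); big <- matrix(0, k, k)
  for (t in seq_len(nrow(trials))) {
    uni[trials$c1[t]] <- uni[trials$c1[t]] + 1
    big[trials$c1[t], trials$c2[t]] <- big[trials$c1[t], trials$c2[t]] + 1
  }
  cc <- cluster_counts(uni, big)
  for (c1 in 1:k) {
    p <- exp(-cluster_surprisal(rep(c1, k), 1:k, cc, alpha = 0.5))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    s <- cluster_surprisal(rep(c1, k), 1:k, cc, alpha = 0.5)
    expect_true(all(s >= 0))
  }
})

test_that("incremental speaker surprisal matches from-scratch recounting", {
  # stated examples
  tr <- data.frame(speaker = c("S1", "S1"), c1 = c(1, 1), c2 = c(2, 2))
  out <- speaker_surprisal_trajectory(tr, k = 6, alpha = 0.5)
  expect_equal(out[1], log(6), tolerance = 1e-12)
  expect_equal(out[2], -log((1 + 0.5) / (1 + 0.5 * 6)), tolerance = 1e-12)

  # property: every position equals an independent recount of prior trials
  set.seed(17)
  k <- 6
  trials <- data.frame(speaker = sample(c("S1", "S2"), 120, TRUE),
                       c1 = sample.int(k, 120, TRUE),
                       c2 = sample.int(k, 120, TRUE))
  inc <- speaker_surprisal_trajectory(trials, k = k, alpha = 0.5)
  scratch <- vapply(seq_len(nrow(trials)), function(t)
    recount_surprisal(trials, t, k = k, alpha = 0.5), numeric(1))
  expect_equal(inc, scratch, tolerance = 1e-12)

  # speaker independence: each speaker's subsequence run alone is identical
  for (s in c("S1", "S2")) {
    sub <- trials[trials$speaker == s, ]
    expect_equal(inc[trials$speaker == s],
                 speaker_surprisal_trajectory(sub, k = k, alpha = 0.5),
                 tolerance = 1e-12)
  }
  expect_identical(speaker_surprisal_trajectory(trials[0, ], k = k),
                   numeric(0))
})

test_that("include-current toggle counts the current NP before scoring", {
  tr <- data.frame(speaker = "S1", c1 = 1, c2 = 2)
  with_cur <- speaker_surprisal_trajectory(tr, k = 6, alpha = 0.5,
                                           include_current = TRUE)
  expect_equal(with_cur, -log((1 + 0.5) / (1 + 3)), tolerance = 1e-12)
})

test_that("running mean surprisal converges to the generator entropy", {
  # i.i.d. uniform transitions: entropy rate ln(k); long-run mean approaches it
  set.seed(23)
  k <- 4
  n <- 4000
  trials <- data.frame(speaker = "S1",
                       c1 = sample.int(k, n, TRUE),
                       c2 = sample.int(k, n, TRUE))
  out <- speaker_surprisal_trajectory(trials, k = k, alpha = 0.5)
  tail_mean <- mean(out[(n / 2):n])
  expect_lt(abs(tail_mean - log(k)), 0.05)
})

test_that("log unigram frequency applies the natural log and Laplace rule", {
  tab <- data.frame(word = c("red", "big", "rare"), count = c(751, 1, 0))
  expect_equal(word_log_frequency("red", tab), log(751), tolerance = 1e-12)
  expect_equal(word_log_frequency("big", tab), 0)
  expect_equal(word_log_frequency("rare", tab), 0)  # laplace: ln(0 + 1)
  expect_error(word_log_frequency("rare", tab, zero = "error"), "zero")
  expect_error(word_log_frequency("absent", tab), "missing")
  expect_equal(word_log_frequency("absent", tab, strict = FALSE), 0)
})

test_that("count tables round-trip through TSV", {
  wc <- make_word_counts(10, seed = 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(wc$unigrams, p1, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(wc$bigrams, p2, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  expect_equal(read_unigrams(p1)$count, wc$unigrams$count)
  expect_equal(read_bigrams(p2)$word2, wc$bigrams$word2)
})

test_that("add_surprisal joins global, speaker and frequency columns", {
  nps <- make_scaled_session(n_passages = 10, seed = 3)
  expect_true(all(c("surprisal_global", "surprisal_speaker") %in% names(nps)))
  expect_equal(nps$epoch_index, seq_len(nrow(nps)))
  # global surprisal of uniform counts: -ln((100 + .5)/(1000 + 3)) for all rows
  expect_equal(unique(round(nps$surprisal_global, 10)),
               round(-log(100.5 / 1003), 10))
  expect_true(all(is.finite(nps$surprisal_speaker)))
})
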