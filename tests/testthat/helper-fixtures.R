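# shared in-code fixtures; everything is generated, nothing read from disk

# cluster model built directly from known labels (bypasses k-means)
make_cluster_model <- function(words, labels, k = max(labels)) {
  structure(list(
    k = as.integer(k),
    assignment = stats::setNames(as.integer(labels), words),
    centroids = matrix(0, k, 2),
    wss = NA_real_,
    seed = 0L
  ), class = "cluster_model")
}

# random word-level count tables over a fixed vocabulary
make_word_counts <- function(n_words = 50, seed = 1) {
  set.seed(seed)
  words <- sprintf("w%03d", seq_len(n_words))
  uni <- data.frame(word = words,
                    count = rpois(n_words, 20))
  pairs <- expand.grid(word1 = words, word2 = words,
                       stringsAsFactors = FALSE)
  n_big <- min(200, nrow(pairs))
  keep <- sample(nrow(pairs), n_big)
  big <- data.frame(pairs[keep, ], count = rpois(n_big, 5))
  list(unigrams = uni, bigrams = big, words = words)
}

# scaled-down session: n_passages passages of the 90-passage design with
# cluster pairs, pseudo-randomized order and surprisal columns attached
make_scaled_session <- function(n_passages = 30, seed = 1,
                                global_counts = cluster_counts(
                                  rep(1000, 6), matrix(100, 6, 6))) {
  d <- build_design_exp1(1)
  d <- assign_cluster_pairs(d, k = 6, seed = seed + 1L)
  d <- pseudo_randomize(d, seed = seed)
  keep <- unique(d$nps$passage_id[order(d$nps$epoch_index)])[seq_len(n_passages)]
  nps <- d$nps[d$nps$passage_id %in% keep, ]
  nps <- nps[order(nps$epoch_index), ]
  nps$epoch_index <- seq_len(nrow(nps))
  add_surprisal(nps, global_counts)
}

# independent from-scratch recount of trial t's speaker-based surprisal
recount_surprisal <- function(trials, t, k, alpha = 0.5) {
  prior <- trials[seq_len(t - 1L), , drop = FALSE]
  prior <- prior[prior$speaker == trials$speaker[t], , drop = FALSE]
  uni <- sum(prior$c1 == trials$c1[t])
  big <- sum(prior$c1 == trials$c1[t] & prior$c2 == trials$c2[t])
  -log((big + alpha) / (uni + alpha * k))
}
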