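#' Read word-level count tables
#'
#' `read_unigrams` parses TSV `word<TAB>count`; `read_bigrams` parses
#' `word1<TAB>word2<TAB>count`.
#'
#' @param path Path to a TSV file (no header).
#' @return A data.frame (`word, count`) or (`word1, word2, count`).
#' @export
read_unigrams <- function(path) {
  x <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                         col.names = c("word", "count"),
                         colClasses = c("character", "numeric"))
  x$word <- tolower(x$word)
  x
}

#' @rdname read_unigrams
#' @export
read_bigrams <- function(path) {
  x <- utils::read.table(path, sep = "\t", quote = "", header = FALSE,
                         col.names = c("word1", "word2", "count"),
                         colClasses = c("character", "character", "numeric"))
  x$word1 <- tolower(x$word1)
  x$word2 <- tolower(x$word2)
  x
}

#' Aggregate word-level counts to cluster-level counts
#'
#' Cluster unigram counts are sums of the word counts of the cluster's
#' members; cluster bigram counts sum word-bigram counts whose first word
#' falls in the row cluster and second word in the column cluster.
#'
#' @param word_unigrams data.frame `word, count` (counts >= 0).
#' @param word_bigrams data.frame `word1, word2, count`, or `NULL` for none.
#' @param cm A `cluster_model` assigning every counted word to a cluster.
#' @param oov How to treat words absent from `cm`: `"error"` (strict,
#'   default), `"drop"` (ignore those rows), or `"nearest"` (assign by
#'   nearest centroid; requires `red`).
#' @param red `reduced_embeddings` used for `oov = "nearest"`.
#' @return A `cluster_counts` object: `unigram` (length-k vector), `bigram`
#'   (k x k matrix), `k`, `total_tokens` (sum of unigram counts).
#' @export
aggregate_cluster_counts <- function(word_unigrams, word_bigrams, cm,
                                     oov = c("error", "drop", "nearest"),
                                     red = NULL) {
  stopifnot(inherits(cm, "cluster_model"))
  oov <- match.arg(oov)
  if (any(word_unigrams$count < 0) ||
      (!is.null(word_bigrams) && any(word_bigrams$count < 0))) {
    stop("negative counts are not allowed")
  }
  k <- cm$k
  lookup <- function(words) {
    cl <- unname(cm$assignment[words])
    miss <- is.na(cl)
    if (any(miss)) {
      if (oov == "error") {
        stop("words missing from cluster model: ",
             paste(utils::head(unique(words[miss]), 5L), collapse = ", "))
      }
      if (oov == "nearest") {
        if (is.null(red)) stop("oov = \"nearest\" requires `red`")
        for (w in unique(words[miss])) {
          if (!w %in% rownames(red$components)) {
            stop("no embedding available for out-of-vocabulary word: ", w)
          }
          d2 <- colSums((t(cm$centroids) - red$components[w, ])^2)
          cl[words == w] <- which.min(d2)
        }
        miss <- is.na(cl)
      }
    }
    cl
  }
  uni <- numeric(k)
  cl_u <- lookup(word_unigrams$word)
  keep <- !is.na(cl_u)
  sums <- tapply(word_unigrams$count[keep], cl_u[keep], sum)
  uni[as.integer(names(sums))] <- as.numeric(sums)

  big <- matrix(0, k, k)
  if (!is.null(word_bigrams) && nrow(word_bigrams) > 0L) {
    c1 <- lookup(word_bigrams$word1)
    c2 <- lookup(word_bigrams$word2)
    keep <- !is.na(c1) & !is.na(c2)
    if (any(keep)) {
      idx <- cbind(c1[keep], c2[keep])
      for (i in seq_len(sum(keep))) {
        big[idx[i, 1L], idx[i, 2L]] <- big[idx[i, 1L], idx[i, 2L]] +
          word_bigrams$count[keep][i]
      }
    }
  }
  cluster_counts(uni, big)
}

#' Construct a cluster-level count table
#'
#' @param unigram Length-k numeric vector of nonnegative cluster counts.
#' @param bigram k x k numeric matrix of nonnegative cluster-pair counts
#'   (row = cluster of the first item).
#' @return A `cluster_counts` object.
#' @export
cluster_counts <- function(unigram, bigram) {
  unigram <- as.numeric(unigram)
  bigram <- as.matrix(bigram)
  k <- length(unigram)
  stopifnot(nrow(bigram) == k, ncol(bigram) == k,
            all(unigram >= 0), all(bigram >= 0))
  structure(list(unigram = unigram, bigram = bigram, k = k,
                 total_tokens = sum(unigram)),
            class = "cluster_counts")
}

#' @export
print.cluster_counts <- function(x, ...) {
  cat("Cluster counts: k =", x$k, ", total tokens =", x$total_tokens, "\n")
  invisible(x)
}

#' Cluster-based bigram surprisal
#'
#' Surprisal of a second-position cluster given a first-position cluster:
#' `-log((bigram[c1, c2] + alpha) / (unigram[c1] + alpha * k))`.
#' With `alpha = 0` this is the literal ratio of raw counts,
#' `-log(ClusterBigramFrequency / ClusterUnigramFrequency)`, which is `+Inf`
#' when the bigram count is zero; infinite values are returned (flagged via
#' the `"n_infinite"` attribute), not raised as errors. A zero unigram count
#' with `alpha = 0` has no defined context probability and errors.
#'
#' @param c1,c2 Integer cluster ids (vectors recycle as usual).
#' @param counts A `cluster_counts` object.
#' @param base Logarithm base: `exp(1)` (default) or `2`.
#' @param alpha Add-alpha smoothing constant (default 0.5; `alpha = 0`
#'   reproduces the raw-count formula).
#' @return Numeric vector of surprisal values (log units in `base`).
#' @export
cluster_surprisal <- function(c1, c2, counts, base = exp(1), alpha = 0.5) {
  stopifnot(inherits(counts, "cluster_counts"), alpha >= 0)
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  if (any(c(c1, c2) < 1L) || any(c(c1, c2) > counts$k)) {
    stop("cluster ids must lie in 1..k")
  }
  uni <- counts$unigram[c1]
  big <- counts$bigram[cbind(c1, c2)]
  if (alpha == 0 && any(uni == 0)) {
    stop("undefined context: unigram count 0 for cluster ",
         paste(unique(c1[uni == 0]), collapse = ", "), " with alpha = 0")
  }
  p <- (big + alpha) / (uni + alpha * counts$k)
  s <- -log(p, base = base)
  n_inf <- sum(is.infinite(s))
  if (n_inf > 0L) attr(s, "n_infinite") <- n_inf
  s
}

#' Incremental per-speaker surprisal over a trial sequence
#'
#' Walks the trials in presentation order keeping separate running cluster
#' unigram/bigram counts for each speaker. Trial t's surprisal is computed
#' from the counts accumulated over that speaker's trials strictly before t
#' (the listener's prior exposure); only then are trial t's counts added
#' (`include_current = TRUE` adds them first, for sensitivity analyses).
#' Trajectories of different speakers are independent.
#'
#' @param trials data.frame with columns `speaker`, `c1`, `c2`, ordered by
#'   presentation.
#' @param k Number of clusters.
#' @param base,alpha As in [cluster_surprisal()]. `alpha` must be positive
#'   here so first exposures are finite (`-log` of the uniform `1/k`).
#' @param include_current Count the current NP before computing its own
#'   surprisal? Default `FALSE`.
#' @return Numeric vector, one surprisal value per trial row.
#' @export
speaker_surprisal_trajectory <- function(trials, k, base = exp(1),
                                         alpha = 0.5,
                                         include_current = FALSE) {
  if (nrow(trials) == 0L) return(numeric(0L))
  stopifnot(all(c("speaker", "c1", "c2") %in% names(trials)), alpha > 0)
  c1 <- as.integer(trials$c1); c2 <- as.integer(trials$c2)
  if (any(c(c1, c2) < 1L) || any(c(c1, c2) > k)) stop("cluster ids outside 1..k")
  spk <- as.character(trials$speaker)
  uni <- list(); big <- list()
  out <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    s <- spk[t]
    if (is.null(uni[[s]])) {
      uni[[s]] <- numeric(k)
      big[[s]] <- matrix(0, k, k)
    }
    if (include_current) {
      uni[[s]][c1[t]] <- uni[[s]][c1[t]] + 1
      big[[s]][c1[t], c2[t]] <- big[[s]][c1[t], c2[t]] + 1
    }
    p <- (big[[s]][c1[t], c2[t]] + alpha) / (uni[[s]][c1[t]] + alpha * k)
    out[t] <- -log(p, base = base)
    if (!include_current) {
      uni[[s]][c1[t]] <- uni[[s]][c1[t]] + 1
      big[[s]][c1[t], c2[t]] <- big[[s]][c1[t], c2[t]] + 1
    }
  }
  out
}

#' Log-transformed corpus unigram frequency
#'
#' Natural log of the raw word count, the standard frequency control
#' covariate. Zero counts use add-one (Laplace) smoothing by default, giving
#' `log(1) = 0`.
#'
#' @param word Character vector of words.
#' @param word_unigrams data.frame `word, count`.
#' @param zero `"laplace"` (default: `log(count + 1)` for zero counts) or
#'   `"error"`.
#' @param strict Error on words absent from the table? Default `TRUE`;
#'   otherwise absent words are treated as count 0.
#' @return Numeric vector of natural-log frequencies.
#' @export
word_log_frequency <- function(word, word_unigrams,
                               zero = c("laplace", "error"), strict = TRUE) {
  zero <- match.arg(zero)
  counts <- word_unigrams$count[match(tolower(word), word_unigrams$word)]
  if (anyNA(counts)) {
    if (strict) {
      stop("words missing from unigram table: ",
           paste(unique(word[is.na(counts)]), collapse = ", "))
    }
    counts[is.na(counts)] <- 0
  }
  if (any(counts == 0)) {
    if (zero == "error") stop("zero unigram count encountered")
    counts[counts == 0] <- counts[counts == 0] + 1
  }
  log(counts)
}

#' Attach surprisal columns to a trial design
#'
#' Computes, for each critical NP row (in `epoch_index` order), the global
#' (corpus-count) surprisal, the incremental speaker-based surprisal, and —
#' when adjective words and a word unigram table are supplied — the
#' log unigram frequency control covariate for the second adjective.
#'
#' @param nps data.frame of NP rows with columns `speaker`, `c1`, `c2`,
#'   `epoch_index` (and optionally `adj2_word`).
#' @param global_counts A `cluster_counts` object of corpus-level counts.
#' @param word_unigrams Optional data.frame `word, count` for the frequency
#'   covariate.
#' @param base,alpha Passed to the surprisal computations.
#' @return `nps` with columns `surprisal_global`, `surprisal_speaker` and
#'   (if computable) `log_unigram_freq`, ordered by `epoch_index`.
#' @export
add_surprisal <- function(nps, global_counts, word_unigrams = NULL,
                          base = exp(1), alpha = 0.5) {
  stopifnot(inherits(global_counts, "cluster_counts"))
  nps <- nps[order(nps$epoch_index), , drop = FALSE]
  nps$surprisal_global <- as.numeric(
    cluster_surprisal(nps$c1, nps$c2, global_counts, base = base, alpha = alpha))
  nps$surprisal_speaker <- speaker_surprisal_trajectory(
    nps, k = global_counts$k, base = base, alpha = alpha)
  if (!is.null(word_unigrams) && "adj2_word" %in% names(nps)) {
    nps$log_unigram_freq <- word_log_frequency(nps$adj2_word, word_unigrams)
  }
  rownames(nps) <- NULL
  nps
}
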