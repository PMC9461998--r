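#' Read word embeddings in word2vec text format
#'
#' Parses the whitespace-separated text dialect used by word2vec and fastText:
#' an optional first header line `"n_words dim"`, then one `"word v1 ... vd"`
#' row per word. Words are lower-cased.
#'
#' @param path Path to a UTF-8 text file.
#' @return An `embedding_table`: list with `words` (character) and `vectors`
#'   (numeric matrix, one row per word, rownames set to the words).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]  # "n_words dim" header
  }
  parts <- strsplit(trimws(lines), "\\s+")
  words <- tolower(vapply(parts, `[[`, character(1L), 1L))
  vecs <- lapply(parts, function(p) as.numeric(p[-1L]))
  d <- lengths(vecs)
  if (length(unique(d)) != 1L) stop("inconsistent embedding dimension across rows")
  embedding_table(words, do.call(rbind, vecs))
}

#' Construct an embedding table
#'
#' @param words Character vector of (lower-case) word forms.
#' @param vectors Numeric matrix with one row per word.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(words, vectors) {
  words <- as.character(words)
  vectors <- as.matrix(vectors)
  if (length(words) != nrow(vectors)) stop("words and vectors disagree in length")
  if (anyDuplicated(words)) stop("duplicate words in embedding table")
  if (!all(is.finite(vectors))) stop("non-finite entries in embedding vectors")
  rownames(vectors) <- words
  structure(list(words = words, vectors = vectors), class = "embedding_table")
}

#' Write embeddings in word2vec text format
#'
#' @param emb An `embedding_table`.
#' @param path Output path.
#' @param header Write the `"n_words dim"` header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, header = TRUE) {
  stopifnot(inherits(emb, "embedding_table"))
  rows <- paste(emb$words, apply(emb$vectors, 1L, paste, collapse = " "))
  if (header) rows <- c(paste(length(emb$words), ncol(emb$vectors)), rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Project embeddings onto their leading principal components
#'
#' Columns are mean-centred (not scaled: all embedding dimensions share a
#' scale) and the table is projected on the top `n_pc` principal axes. For
#' reproducibility each loading vector's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param emb An `embedding_table`.
#' @param n_pc Number of principal components to retain (default 5).
#' @return A `reduced_embeddings` object: `words`, `components`
#'   (n_words x n_pc score matrix), `loadings` (d x n_pc, orthonormal
#'   columns), `explained_variance` (component variances, non-increasing),
#'   and `center` (the column means removed).
#' @export
reduce_embeddings <- function(emb, n_pc = 5L) {
  stopifnot(inherits(emb, "embedding_table"))
  n <- nrow(emb$vectors)
  d <- ncol(emb$vectors)
  if (n < 2L) stop("need at least 2 words for a principal components analysis")
  if (n_pc < 1L || n_pc > min(n, d)) {
    stop("n_pc must lie in [1, min(n_words, dim)] = [1, ", min(n, d), "]")
  }
  pc <- stats::prcomp(emb$vectors, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  flip <- vapply(seq_len(n_pc), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1L))
  rot[, flip] <- -rot[, flip]
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  scores[, flip] <- -scores[, flip]
  rownames(scores) <- emb$words
  structure(list(
    words = emb$words,
    components = scores,
    loadings = rot,
    explained_variance = pc$sdev[seq_len(n_pc)]^2,
    center = pc$center
  ), class = "reduced_embeddings")
}

#' Scan cluster numbers and pick an elbow on the WSS curve
#'
#' Runs k-means for every k in `k_range` and returns the total
#' within-cluster sum-of-squares curve together with an automated elbow
#' choice: the interior k maximising the discrete second difference of the
#' curve. The curve is intended for inspection; analyses of the adjective
#' materials conventionally use k = 6.
#'
#' @param red A `reduced_embeddings` object.
#' @param k_range Integer vector of candidate cluster numbers.
#' @param seed Integer seed controlling the k-means restarts.
#' @param n_restarts Random restarts per k (default 25).
#' @return List with `k` (elbow choice) and `wss_curve` (named numeric,
#'   names are the k values).
#' @export
select_k <- function(red, k_range = 1:10, seed = 1L, n_restarts = 25L) {
  stopifnot(inherits(red, "reduced_embeddings"))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (min(k_range) < 1L || max(k_range) > length(red$words)) {
    stop("k_range must lie within [1, n_words]")
  }
  wss <- vapply(k_range, function(k) {
    fit_clusters(red, k = k, seed = seed, n_restarts = n_restarts)$wss
  }, numeric(1L))
  names(wss) <- k_range
  # repair tiny inversions left by finite restarts (objective is
  # non-increasing in k for the global optimum)
  wss <- cummin(wss)
  if (length(k_range) >= 3L) {
    d2 <- diff(wss, differences = 2L)          # wss[i-1] - 2 wss[i] + wss[i+1]
    k_hat <- k_range[which.max(d2) + 1L]
  } else {
    k_hat <- k_range[[1L]]
  }
  list(k = k_hat, wss_curve = wss)
}

#' Cluster words in principal-component space
#'
#' k-means (Hartigan-Wong, best of `n_restarts` random starts) on the
#' component scores. Deterministic given `seed`.
#'
#' @param red A `reduced_embeddings` object.
#' @param k Number of clusters (default 6, the adjective-cluster convention).
#' @param seed Integer seed (required for reproducibility).
#' @param n_restarts Random restarts (default 25).
#' @return A `cluster_model`: `k`, `assignment` (named integer vector,
#'   word -> cluster id in 1..k), `centroids` (k x n_pc), `wss` (total
#'   within-cluster sum of squares), `seed`.
#' @export
fit_clusters <- function(red, k = 6L, seed = 1L, n_restarts = 25L) {
  stopifnot(inherits(red, "reduced_embeddings"))
  n <- nrow(red$components)
  if (n == 0L) stop("empty input")
  if (k > n) stop("k exceeds the number of words (", n, ")")
  if (k == n) {
    # every word its own cluster: zero objective, no search needed
    assignment <- stats::setNames(seq_len(n), red$words)
    return(structure(list(k = as.integer(k), assignment = assignment,
                          centroids = red$components, wss = 0,
                          seed = as.integer(seed)),
                     class = "cluster_model"))
  }
  km <- local({
    set.seed(seed)
    stats::kmeans(red$components, centers = k, nstart = n_restarts,
                  iter.max = 100L)
  })
  assignment <- as.integer(km$cluster)
  names(assignment) <- red$words
  structure(list(
    k = as.integer(k),
    assignment = assignment,
    centroids = km$centers,
    wss = km$tot.withinss,
    seed = as.integer(seed)
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Adjective cluster model: k =", x$k, "over", length(x$assignment),
      "words; total WSS =", format(x$wss, digits = 6), "\n")
  print(table(cluster = x$assignment))
  invisible(x)
}

#' Save / load a cluster model as JSON
#'
#' @param cm A `cluster_model`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_cluster_model` returns a `cluster_model`.
#' @export
write_cluster_model <- function(cm, path) {
  stopifnot(inherits(cm, "cluster_model"))
  jsonlite::write_json(list(
    k = cm$k, seed = cm$seed, wss = cm$wss,
    assignment = as.list(cm$assignment),
    centroids = unname(apply(cm$centroids, 1L, as.numeric, simplify = FALSE))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- unlist(x$assignment)
  cent <- x$centroids
  cent <- if (is.list(cent)) do.call(rbind, lapply(cent, as.numeric))
          else as.matrix(cent)
  structure(list(
    k = as.integer(x$k),
    assignment = stats::setNames(as.integer(assignment), names(assignment)),
    centroids = cent,
    wss = as.numeric(x$wss),
    seed = as.integer(x$seed)
  ), class = "cluster_model")
}
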