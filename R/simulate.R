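#' Simulation configuration for single-trial N400 generation
#'
#' Collects the ground-truth parameters of the generative model
#' `amplitude = X beta + b_subject + b_item + b_channel
#'             + prestim_coupling * prestim + eps`.
#' `beta_true` is a named vector over the design columns: `intercept`,
#' `surprisal` (z-scored speaker-based surprisal), `epoch` (z-scored
#' presentation index), `surprisal_epoch` (their product), `canonicity`
#' (sum-coded, canonical = +1), and optionally moderation terms named
#' `<covariate>_surprisal_epoch` for covariates in the participant table
#' (`slope`, `iaf`, `id`). The surprisal coefficient is negative by default:
#' larger prediction error means a more negative centro-parietal amplitude.
#'
#' @param seed Integer seed (mandatory; every generator is a pure function
#'   of its parameters and the seed).
#' @param n_subjects,n_items,n_channels Sample sizes. `n_items` is the
#'   number of critical NPs per session.
#' @param beta_true Named numeric vector of fixed effects (microvolts per
#'   unit predictor).
#' @param re_sd Named vector of random-intercept standard deviations
#'   (microvolts) for `subject`, `item`, `channel`.
#' @param resid_sd Residual standard deviation (microvolts).
#' @param prestim_coupling Coefficient linking the prestimulus window mean
#'   to the N400 window mean.
#' @param prestim_sd Standard deviation of the prestimulus amplitudes.
#' @param covariate_dists Per-covariate `c(mean, sd)`: `iaf` (Hz),
#'   `slope` (1/f exponent), `id` (idea density, ideas/word).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_subjects = 45L, n_items = 180L, n_channels = 15L,
                       beta_true = c(intercept = 1, surprisal = -1.5,
                                     epoch = 0.5, surprisal_epoch = -0.5,
                                     canonicity = 0.5),
                       re_sd = c(subject = 2, item = 0.5, channel = 0.5),
                       resid_sd = 5,
                       prestim_coupling = 0.3,
                       prestim_sd = 2,
                       covariate_dists = list(iaf = c(10, 1),
                                              slope = c(1.3, 0.3),
                                              id = c(0.5, 0.05))) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(re_sd >= 0), resid_sd >= 0, prestim_sd >= 0)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 n_items = as.integer(n_items),
                 n_channels = as.integer(n_channels),
                 beta_true = beta_true, re_sd = re_sd, resid_sd = resid_sd,
                 prestim_coupling = prestim_coupling, prestim_sd = prestim_sd,
                 covariate_dists = covariate_dists),
            class = "sim_config")
}

#' Generate clustered synthetic word embeddings
#'
#' k isotropic Gaussian blobs in `dim`-dimensional space with pairwise
#' centroid spacing governed by `separation`. The generating labels are
#' attached as the `"labels"` attribute (the synthetic ground truth).
#'
#' @param n_words Number of words (>= k).
#' @param k Number of latent clusters (default 6).
#' @param dim Embedding dimensionality (default 300).
#' @param separation Distance scale between blob centroids; 0 gives fully
#'   unstructured embeddings.
#' @param within_sd Within-blob standard deviation per coordinate.
#' @param seed Integer seed.
#' @return An `embedding_table` with attribute `labels` (integer vector).
#' @export
gen_embeddings <- function(n_words, k = 6L, dim = 300L, separation = 10,
                           within_sd = 1, seed = 1L) {
  if (n_words < k) stop("n_words must be >= k")
  if (separation < 0) stop("separation must be nonnegative")
  set.seed(seed)
  # centroids on random directions at the given spacing
  cent <- matrix(stats::rnorm(k * dim), k, dim)
  cent <- cent / sqrt(rowSums(cent^2)) * separation
  labels <- rep_len(seq_len(k), n_words)
  vecs <- cent[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_words * dim, sd = within_sd), n_words, dim)
  words <- sprintf("w%03d", seq_len(n_words))
  emb <- embedding_table(words, vecs)
  attr(emb, "labels") <- labels
  emb
}

#' Generate cluster-consistent corpus count tables
#'
#' Draws `total_tokens` bigram tokens from a cluster-level transition model:
#' first cluster uniform, second cluster from the corresponding row of
#' `bigram_probs`; words within a cluster are drawn uniformly. Word unigram
#' counts are the marginal first-position counts, so cluster-aggregated
#' unigram counts equal bigram row sums (a proper conditional model).
#'
#' @param labels Integer cluster label per word (names or order matching the
#'   word list `words`).
#' @param words Character vector of words (defaults to `names(labels)` or
#'   `w001...`).
#' @param bigram_probs k x k row-stochastic matrix of cluster transition
#'   probabilities.
#' @param total_tokens Number of bigram tokens to draw.
#' @param seed Integer seed.
#' @return List with `unigrams` (data.frame `word, count`) and `bigrams`
#'   (data.frame `word1, word2, count`).
#' @export
gen_corpus_counts <- function(labels, words = NULL, bigram_probs,
                              total_tokens = 1e5, seed = 1L) {
  k <- nrow(bigram_probs)
  if (ncol(bigram_probs) != k) stop("bigram_probs must be square")
  if (any(bigram_probs < 0) || any(abs(rowSums(bigram_probs) - 1) > 1e-8)) {
    stop("bigram_probs rows must be nonnegative and sum to 1")
  }
  if (is.null(words)) {
    words <- names(labels)
    if (is.null(words)) words <- sprintf("w%03d", seq_along(labels))
  }
  set.seed(seed)
  members <- split(seq_along(labels), labels)
  if (length(members) != k) stop("labels must cover all k clusters")
  c1 <- sample.int(k, total_tokens, replace = TRUE)
  u <- stats::runif(total_tokens)
  cum <- t(apply(bigram_probs, 1L, cumsum))
  c2 <- integer(total_tokens)
  for (cl in seq_len(k)) {
    idx <- which(c1 == cl)
    c2[idx] <- findInterval(u[idx], cum[cl, ], left.open = TRUE) + 1L
  }
  draw_words <- function(cl_idx) {
    w <- integer(length(cl_idx))
    for (cl in seq_len(k)) {
      idx <- which(cl_idx == cl)
      m <- members[[cl]]
      w[idx] <- m[sample.int(length(m), length(idx), replace = TRUE)]
    }
    w
  }
  w1 <- draw_words(c1)
  w2 <- draw_words(c2)
  big <- stats::aggregate(count ~ word1 + word2,
                          data = data.frame(word1 = words[w1],
                                            word2 = words[w2],
                                            count = 1), FUN = sum)
  uni <- stats::aggregate(count ~ word,
                          data = data.frame(word = words[w1], count = 1),
                          FUN = sum)
  list(unigrams = uni, bigrams = big)
}

#' Generate a resting-state EEG-like signal with known spectral truth
#'
#' Aperiodic component: Gaussian noise spectrally shaped in the frequency
#' domain to an exact `1/f^beta` power law (unit variance). Oscillatory
#' component: narrowband noise — white noise shaped by a Gaussian spectral
#' envelope of `alpha_bw_hz` full width at half maximum centred at
#' `alpha_freq_hz` (not a pure sinusoid, so peak and centre-of-gravity
#' alpha measures can differ) — scaled to `alpha_amp` times unit sd.
#'
#' @param duration_s Duration in seconds (default 120, a 2-minute block).
#' @param fs_hz Sampling rate (default 500).
#' @param beta_true True power-law exponent (power ~ 1/f^beta).
#' @param alpha_freq_hz Centre frequency of the alpha component (Hz).
#' @param alpha_amp Alpha sd relative to the aperiodic sd; 0 disables it.
#'   Values around 0.2-0.4 give peak elevations of roughly 1-1.5 log10
#'   units over the aperiodic background, the range seen in eyes-closed
#'   recordings.
#' @param alpha_bw_hz Full width at half maximum of the alpha peak
#'   (default 2 Hz).
#' @param seed Integer seed.
#' @return Numeric vector of length `duration_s * fs_hz` with attributes
#'   `fs` and `truth` (list of the generating parameters).
#' @export
gen_resting_signal <- function(duration_s = 120, fs_hz = 500, beta_true = 1,
                               alpha_freq_hz = 10, alpha_amp = 0,
                               alpha_bw_hz = 2, seed = 1L) {
  n <- round(duration_s * fs_hz)
  if (n < 2 * fs_hz) stop("signal must be at least 2 s long")
  if (alpha_amp > 0 && (alpha_freq_hz <= 0 || alpha_freq_hz >= fs_hz / 2)) {
    stop("alpha_freq_hz must lie in (0, fs/2)")
  }
  set.seed(seed)
  white <- stats::rnorm(n)
  x <- Re(stats::fft(shape_spectrum(stats::fft(white), n, fs_hz, beta_true),
                     inverse = TRUE)) / n
  x <- x / stats::sd(x)
  if (alpha_amp > 0) {
    f <- seq(0, fs_hz, length.out = n + 1L)[seq_len(n)]
    f <- pmin(f, fs_hz - f)
    sd_env <- alpha_bw_hz / 2.355            # Gaussian FWHM = alpha_bw_hz
    env <- exp(-(f - alpha_freq_hz)^2 / (2 * sd_env^2))
    a <- Re(stats::fft(stats::fft(stats::rnorm(n)) * env, inverse = TRUE)) / n
    x <- x + alpha_amp * a / stats::sd(a)
  }
  attr(x, "fs") <- fs_hz
  attr(x, "truth") <- list(beta = beta_true, alpha_freq = alpha_freq_hz,
                           alpha_amp = alpha_amp)
  x
}

# multiply FFT coefficients by f^(-beta/2); DC removed
shape_spectrum <- function(X, n, fs, beta) {
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  g <- numeric(n)
  pos <- f > 0
  g[pos] <- f[pos]^(-beta / 2)
  X * g
}

#' Generate a participant covariate table
#'
#' Draws per-subject individual alpha frequency (Hz), aperiodic 1/f slope
#' (exponent) and idea density (ideas/word) from independent normals.
#'
#' @param n Number of participants (the young-adult sample size, 45, is the
#'   default used throughout).
#' @param covariate_dists List of `c(mean, sd)` per covariate, as in
#'   [sim_config()].
#' @param seed Integer seed.
#' @return data.frame `subject, iaf, slope, id`.
#' @export
gen_participants <- function(n = 45L,
                             covariate_dists = list(iaf = c(10, 1),
                                                    slope = c(1.3, 0.3),
                                                    id = c(0.5, 0.05)),
                             seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  draw <- function(d) stats::rnorm(n, d[[1L]], d[[2L]])
  data.frame(subject = sprintf("S%02d", seq_len(n)),
             iaf = draw(covariate_dists$iaf),
             slope = draw(covariate_dists$slope),
             id = draw(covariate_dists$id))
}

#' Assign latent cluster pairs to design NPs
#'
#' Each passage NP receives an underlying (unordered) adjective-cluster pair;
#' the canonical order presents it as (a, b) and the non-canonical order as
#' (b, a). Pairs are drawn uniformly over distinct cluster pairs.
#'
#' @param design A `session_design`.
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @return The design with `c1`, `c2` columns added to `$nps`.
#' @export
assign_cluster_pairs <- function(design, k = 6L, seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  nps <- design$nps
  set.seed(seed)
  a <- sample.int(k, nrow(nps), replace = TRUE)
  b <- ((a - 1L + sample.int(k - 1L, nrow(nps), replace = TRUE)) %% k) + 1L
  canonical <- nps$canonicity == "C"
  nps$c1 <- ifelse(canonical, a, b)
  nps$c2 <- ifelse(canonical, b, a)
  design$nps <- nps
  design
}

#' Simulate single-trial N400 amplitudes from a surprisal-annotated design
#'
#' Expands the NP table over subjects and channels and draws amplitudes from
#' the linear generative model in [sim_config()]: fixed effects on z-scored
#' speaker-based surprisal, z-scored epoch, their interaction, sum-coded
#' canonicity, optional participant-covariate moderations of the
#' surprisal x epoch interaction, crossed Gaussian random intercepts for
#' subject, item and channel, a prestimulus-amplitude coupling, and
#' Gaussian residual noise. All latent draws are recorded in the `"truth"`
#' attribute for parameter-recovery studies.
#'
#' @param nps NP data.frame with `surprisal_speaker`, `epoch_index`,
#'   `canonicity` columns (see [add_surprisal()]).
#' @param participants data.frame from [gen_participants()]; the first
#'   `cfg$n_subjects` rows are used.
#' @param cfg A `sim_config`.
#' @return data.frame (the trial table): one row per subject x NP x channel
#'   with columns `subject, item, channel, epoch_index, canonicity,
#'   surprisal, epoch_z, prestim, amplitude` plus the participant
#'   covariates; attribute `truth` holds `beta_true` and the RE draws.
#' @export
simulate_trial_amplitudes <- function(nps, participants, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("surprisal_speaker", "epoch_index", "canonicity")
  if (!all(need %in% names(nps))) {
    stop("missing columns: ", paste(setdiff(need, names(nps)), collapse = ", "))
  }
  if (nrow(participants) < cfg$n_subjects) stop("not enough participants")
  participants <- participants[seq_len(cfg$n_subjects), , drop = FALSE]
  nps <- nps[order(nps$epoch_index), , drop = FALSE]
  nps <- nps[seq_len(min(nrow(nps), cfg$n_items)), , drop = FALSE]
  set.seed(cfg$seed)
  n_s <- cfg$n_subjects; n_i <- nrow(nps); n_c <- cfg$n_channels
  b_subj <- stats::rnorm(n_s, 0, cfg$re_sd[["subject"]])
  b_item <- stats::rnorm(n_i, 0, cfg$re_sd[["item"]])
  b_chan <- stats::rnorm(n_c, 0, cfg$re_sd[["channel"]])
  grid <- expand.grid(channel = seq_len(n_c), item_row = seq_len(n_i),
                      subject_row = seq_len(n_s))
  d <- data.frame(
    subject = participants$subject[grid$subject_row],
    item = paste0("P", nps$passage_id[grid$item_row], "_",
                  nps$np_slot[grid$item_row]),
    channel = sprintf("ch%02d", grid$channel),
    epoch_index = nps$epoch_index[grid$item_row],
    canonicity = nps$canonicity[grid$item_row],
    stringsAsFactors = FALSE
  )
  z <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  surp_z <- z(nps$surprisal_speaker)[grid$item_row]
  epoch_z <- z(nps$epoch_index)[grid$item_row]
  canon <- ifelse(d$canonicity == "C", 1, -1)
  d$surprisal <- surp_z
  d$epoch_z <- epoch_z
  d$prestim <- stats::rnorm(nrow(d), 0, cfg$prestim_sd)
  for (cv in names(cfg$covariate_dists)) {
    d[[cv]] <- participants[[cv]][grid$subject_row]
  }
  beta <- cfg$beta_true
  mu <- rep(0, nrow(d))
  add <- function(mu, name, col) {
    if (name %in% names(beta)) mu + beta[[name]] * col else mu
  }
  mu <- add(mu, "intercept", 1)
  mu <- add(mu, "surprisal", surp_z)
  mu <- add(mu, "epoch", epoch_z)
  mu <- add(mu, "surprisal_epoch", surp_z * epoch_z)
  mu <- add(mu, "canonicity", canon)
  for (cv in names(cfg$covariate_dists)) {
    nm <- paste0(cv, "_surprisal_epoch")
    if (nm %in% names(beta)) {
      cvz <- z(participants[[cv]])[grid$subject_row]
      mu <- mu + beta[[nm]] * cvz * surp_z * epoch_z
    }
  }
  d$amplitude <- mu +
    b_subj[grid$subject_row] + b_item[grid$item_row] + b_chan[grid$channel] +
    cfg$prestim_coupling * d$prestim +
    stats::rnorm(nrow(d), 0, cfg$resid_sd)
  attr(d, "truth") <- list(beta_true = beta, b_subject = b_subj,
                           b_item = b_item, b_channel = b_chan,
                           re_sd = cfg$re_sd, resid_sd = cfg$resid_sd,
                           prestim_coupling = cfg$prestim_coupling)
  d
}
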