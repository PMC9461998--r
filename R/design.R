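#' Counterbalanced two-speaker listening designs
#'
#' `build_design_exp1()` constructs the 90-critical-passage design: two
#' speakers, one producing mostly canonical adjective orders (C:N 69%:31%)
#' and one mostly non-canonical (31%:69%), with the within-passage order
#' patterns counterbalanced across two material versions:
#'
#' | Version | Speaker       | Passages | Orders within passage |
#' |---------|---------------|----------|------------------------|
#' | 1 | canonical     | 1-45  | 1-7: NC, 8-14: CN, 15-21: NN, 22-45: CC |
#' | 1 | non-canonical | 46-90 | 46-52: CN, 53-59: NC, 60-66: CC, 67-90: NN |
#' | 2 | canonical     | 46-90 | 46-52: NC, 53-59: CN, 60-66: NN, 67-90: CC |
#' | 2 | non-canonical | 1-45  | 1-7: CN, 8-14: NC, 15-21: CC, 22-45: NN |
#'
#' Each critical passage contributes two critical noun phrases (NPs); 60
#' filler passages (no critical NPs) bring the session to 150 passages.
#'
#' @param version Material version, 1 or 2.
#' @return A `session_design`: list with `experiment`, `version`, `nps`
#'   (data.frame: `passage_id`, `np_slot`, `canonicity` ("C"/"N"),
#'   `speaker`, `block`, `epoch_index`), `filler_count`,
#'   `block_boundaries`.
#' @export
build_design_exp1 <- function(version = 1L) {
  version <- as.integer(version)
  if (!version %in% c(1L, 2L)) stop("version must be 1 or 2")
  pat <- character(90L)
  assign_pat <- function(range, p) pat[range] <<- p
  if (version == 1L) {
    assign_pat(1:7, "NC"); assign_pat(8:14, "CN")
    assign_pat(15:21, "NN"); assign_pat(22:45, "CC")
    assign_pat(46:52, "CN"); assign_pat(53:59, "NC")
    assign_pat(60:66, "CC"); assign_pat(67:90, "NN")
    speaker <- ifelse(1:90 <= 45L, "canonical_speaker", "noncanonical_speaker")
  } else {
    assign_pat(46:52, "NC"); assign_pat(53:59, "CN")
    assign_pat(60:66, "NN"); assign_pat(67:90, "CC")
    assign_pat(1:7, "CN"); assign_pat(8:14, "NC")
    assign_pat(15:21, "CC"); assign_pat(22:45, "NN")
    speaker <- ifelse(1:90 <= 45L, "noncanonical_speaker", "canonical_speaker")
  }
  nps <- data.frame(
    passage_id = rep(1:90, each = 2L),
    np_slot = rep(c(1L, 2L), times = 90L),
    speaker = rep(speaker, each = 2L),
    block = 1L,
    stringsAsFactors = FALSE
  )
  # canonicity of slot s in passage p is character s of its order pattern
  nps$canonicity <- substr(rep(pat, each = 2L), nps$np_slot, nps$np_slot)
  nps$epoch_index <- seq_len(nrow(nps))
  structure(list(
    experiment = 1L, version = version, nps = nps,
    filler_count = 60L, block_boundaries = integer(0L)
  ), class = "session_design")
}

#' Build the blocked 150-passage design
#'
#' All 150 passages carry two critical NPs, presented in 5 blocks of 30
#' passages alternating speakers in the order canonical, non-canonical,
#' non-canonical, canonical, canonical. The canonical speaker's 180 NP
#' tokens are 70% canonical (126 C : 54 N); the non-canonical speaker's 120
#' tokens are 30% canonical (36 C : 84 N) — the "approximately 70%:30%"
#' manipulation realised as exact integer token counts.
#'
#' @param canonical_ratio Proportion of canonical tokens for the canonical
#'   speaker (the non-canonical speaker uses `1 - canonical_ratio`).
#'   Default 0.7.
#' @return A `session_design` with 300 NP rows and
#'   `block_boundaries = c(60, 120, 180, 240, 300)` (last NP of each block).
#' @export
build_design_exp2 <- function(canonical_ratio = 0.7) {
  stopifnot(canonical_ratio > 0.5, canonical_ratio < 1)
  block_speaker <- c("canonical_speaker", "noncanonical_speaker",
                     "noncanonical_speaker", "canonical_speaker",
                     "canonical_speaker")
  # per-block within-passage pattern counts chosen so token ratios are exact;
  # patterns interleaved so no block is a solid run of one pattern
  pattern_mix <- function(n_passages, prop_c) {
    n_tok <- 2L * n_passages
    n_c <- round(prop_c * n_tok)
    b <- min(n_passages %/% 6L, n_c %/% 2L)        # mixed-order share
    a <- (n_c - 2L * b) %/% 2L
    rem <- n_c - 2L * a - 2L * b                   # odd remainder -> one CN
    d <- n_passages - a - 2L * b
    stopifnot(a >= 0L, d - rem >= 0L)
    pats <- c(rep("CC", a), rep("CN", b + rem), rep("NC", b),
              rep("NN", d - rem))
    # round-robin interleave of the pattern types
    pats[order(stats::ave(seq_along(pats), pats, FUN = seq_along))]
  }
  passages_per_block <- 30L
  pat <- character(150L)
  spk <- character(150L)
  for (blk in 1:5) {
    idx <- (blk - 1L) * passages_per_block + seq_len(passages_per_block)
    canonical <- block_speaker[blk] == "canonical_speaker"
    pat[idx] <- pattern_mix(passages_per_block,
                            if (canonical) canonical_ratio
                            else 1 - canonical_ratio)
    spk[idx] <- block_speaker[blk]
  }
  nps <- data.frame(
    passage_id = rep(1:150, each = 2L),
    np_slot = rep(c(1L, 2L), times = 150L),
    canonicity = substr(rep(pat, each = 2L), rep(c(1L, 2L), 150L),
                        rep(c(1L, 2L), 150L)),
    speaker = rep(spk, each = 2L),
    block = rep(rep(1:5, each = passages_per_block), each = 2L),
    stringsAsFactors = FALSE
  )
  nps$epoch_index <- seq_len(nrow(nps))
  structure(list(
    experiment = 2L, version = 1L, nps = nps,
    filler_count = 0L, block_boundaries = seq(60L, 300L, by = 60L)
  ), class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design: experiment", x$experiment, "version", x$version, "-",
      length(unique(x$nps$passage_id)), "critical passages,",
      nrow(x$nps), "critical NPs,", x$filler_count, "fillers\n")
  print(with(x$nps, table(speaker, canonicity)))
  invisible(x)
}

#' Validate a session design's counterbalancing invariants
#'
#' Checks that every passage contributes exactly two NPs, epoch indices form
#' a contiguous 1..n sequence, and the speaker/canonicity token counts match
#' the design scheme (62 C of 90 tokens for the canonical speaker in the
#' 90-passage design; block order C,N,N,C,C in the blocked design).
#'
#' @param design A `session_design`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "session_design"))
  nps <- design$nps
  per_passage <- table(nps$passage_id)
  if (any(per_passage != 2L)) stop("a passage must contribute exactly 2 NPs")
  if (!identical(sort(nps$epoch_index), seq_len(nrow(nps)))) {
    stop("epoch_index must be a contiguous 1..n sequence")
  }
  tab <- table(nps$speaker, nps$canonicity)
  if (design$experiment == 1L) {
    if (nrow(nps) != 180L) stop("90-passage design must have 180 critical NPs")
    if (length(unique(nps$passage_id)) + design$filler_count != 150L) {
      stop("critical + filler passages must total 150")
    }
    if (tab["canonical_speaker", "C"] != 62L ||
        tab["noncanonical_speaker", "N"] != 62L) {
      stop("speaker canonicity token counts do not match the 69%:31% scheme")
    }
  } else {
    if (nrow(nps) != 300L) stop("blocked design must have 300 critical NPs")
    ord <- nps[order(nps$epoch_index), ]
    blk_spk <- vapply(split(ord$speaker, ord$block), function(s)
      unique(s)[1], character(1L))
    if (any(vapply(split(ord$speaker, ord$block),
                   function(s) length(unique(s)), integer(1L)) != 1L)) {
      stop("each block must contain a single speaker")
    }
    expected <- c("canonical_speaker", "noncanonical_speaker",
                  "noncanonical_speaker", "canonical_speaker",
                  "canonical_speaker")
    if (!identical(unname(blk_spk[as.character(1:5)]), expected)) {
      stop("block speaker order must be C, N, N, C, C")
    }
  }
  invisible(TRUE)
}

#' Pseudo-randomize passage order under a run-length constraint
#'
#' Permutes the session's passages — critical passages together with
#' interspersed filler placeholders, within speaker blocks for blocked
#' designs — such that no more than `max_run` consecutive passages share a
#' uniform canonicity (a passage counts as "C" if both its NPs are
#' canonical, "N" if both are non-canonical; mixed-order passages and
#' fillers break runs). `epoch_index` is then reassigned to critical NPs in
#' the new presentation order. Deterministic given `seed`; rejection
#' sampling with bounded retries.
#'
#' @param design A `session_design`.
#' @param seed Integer seed.
#' @param max_run Maximum run of same-canonicity passages (default 3).
#' @param max_tries Retries before giving up (default 2000).
#' @return A `session_design` with permuted NP order, fresh epoch indices,
#'   and a `passage_order` element giving the full presentation sequence
#'   (filler placeholders labelled `"F01"...`).
#' @export
pseudo_randomize <- function(design, seed, max_run = 3L, max_tries = 2000L) {
  stopifnot(inherits(design, "session_design"))
  nps <- design$nps[order(design$nps$epoch_index), ]
  pat <- vapply(split(nps$canonicity, nps$passage_id), paste, character(1L),
                collapse = "")
  passages <- data.frame(
    id = names(pat),
    label = ifelse(pat == "CC", "C", ifelse(pat == "NN", "N", "M")),
    block = vapply(split(nps$block, nps$passage_id), `[[`, integer(1L), 1L),
    stringsAsFactors = FALSE
  )
  if (design$filler_count > 0L) {
    passages <- rbind(passages, data.frame(
      id = sprintf("F%02d", seq_len(design$filler_count)),
      label = "F", block = 1L))
  }
  runs_ok <- function(lab) {
    r <- rle(lab)
    all(r$lengths[r$values %in% c("C", "N")] <= max_run)
  }
  set.seed(as.integer(seed))
  # rejection-sample each block separately (cheap), then check the
  # assembled sequence for runs spanning block boundaries
  shuffle_block <- function(p) {
    for (i in seq_len(max_tries)) {
      cand <- p[sample.int(nrow(p)), ]
      if (runs_ok(cand$label)) return(cand)
    }
    stop("run-length constraint unsatisfiable within a block after ",
         max_tries, " tries")
  }
  for (i in seq_len(50L)) {
    perm <- do.call(rbind, lapply(split(passages, passages$block),
                                  shuffle_block))
    if (runs_ok(perm$label)) {
      crit <- perm$id[perm$label != "F"]
      ord <- order(match(as.character(nps$passage_id), crit), nps$np_slot)
      cand <- nps[ord, ]
      cand$epoch_index <- seq_len(nrow(cand))
      rownames(cand) <- NULL
      out <- design
      out$nps <- cand
      out$passage_order <- perm$id
      return(out)
    }
  }
  stop("run-length constraint unsatisfiable after ", max_tries, " tries")
}

#' Write / read a design CSV
#'
#' Columns: `passage_id, np_slot, speaker, canonicity, block, epoch_index`
#' plus any bound word/cluster columns present.
#'
#' @param design A `session_design`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_design_csv` returns the NP data.frame.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design$nps, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
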