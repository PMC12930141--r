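#' Word counts per trial
#'
#' For space-delimited transcripts the count is the number of whitespace
#' tokens; for languages written without spaces the number of syntactic
#' tokens in the parse is used instead (falling back to the parse whenever
#' the transcript contains no spaces).
#'
#' @param study a study bundle.
#' @return Named integer vector (names = trial ids).
#' @export
word_counts <- function(study) {
  tr <- study$trials
  n <- vapply(strsplit(trimws(tr$transcript), "\\s+"), length, 0L)
  no_space <- !grepl("\\s", trimws(tr$transcript)) & tr$trial_id %in% names(study$trees)
  n[no_space] <- vapply(study$trees[tr$trial_id[no_space]], nrow, 0L)
  setNames(n, tr$trial_id)
}

#' Exclude sentences by length
#'
#' Removes trials whose descriptions are shorter than `min_words` or longer
#' than `max_words` words (both bounds inclusive). In percentile mode the
#' bounds are instead recomputed from the study's own word-count
#' distribution.
#'
#' @param study a study bundle.
#' @param min_words,max_words absolute bounds (defaults 4 and 77).
#' @param percentile if `TRUE`, derive bounds as the `p_low` and `p_high`
#'   quantiles of the observed counts.
#' @param p_low,p_high quantile probabilities for percentile mode.
#' @return List: `kept` (trial ids), `log` (data frame of exclusions with
#'   reasons), `bounds` (the bounds applied).
#' @export
filter_sentences <- function(study, min_words = 4, max_words = 77,
                             percentile = FALSE, p_low = 0.02, p_high = 0.99) {
  wc <- word_counts(study)
  if (percentile) {
    q <- quantile(wc, c(p_low, p_high), names = FALSE, type = 1)
    min_words <- q[1]
    max_words <- q[2]
  }
  ok <- wc >= min_words & wc <= max_words
  log <- data.frame(trial_id = names(wc)[!ok],
                    phase = rep_len("both", sum(!ok)),
                    reason = sprintf("word count %d outside [%d, %d]",
                                     wc[!ok], as.integer(min_words),
                                     as.integer(max_words)),
                    stringsAsFactors = FALSE)
  list(kept = names(wc)[ok], log = log,
       bounds = c(min_words = min_words, max_words = max_words))
}

#' Exclude scan patterns with too few fixations
#'
#' A phase sequence built from fewer than `min_fixations` fixations
#' indicates poor-quality data and is removed for that phase only; the
#' trial's other phase is retained if it qualifies.
#'
#' @param encodings output of [encode_study()].
#' @param min_fixations minimum fixations per phase (default 2).
#' @return List: `keep` (logical matrix, trials x phases), `log` (data
#'   frame of excluded trial-phases).
#' @export
filter_scanpatterns <- function(encodings, min_fixations = 2) {
  ids <- names(encodings)
  keep <- cbind(
    before = vapply(encodings, function(e)
      e$n_fix_before >= min_fixations && length(e$before) > 0, TRUE),
    during = vapply(encodings, function(e)
      e$n_fix_during >= min_fixations && length(e$during) > 0, TRUE))
  rownames(keep) <- ids
  drop_idx <- which(!keep, arr.ind = TRUE)
  log <- data.frame(
    trial_id = ids[drop_idx[, 1]],
    phase = colnames(keep)[drop_idx[, 2]],
    reason = rep_len(sprintf("fewer than %d fixations in phase", min_fixations),
                     nrow(drop_idx)),
    stringsAsFactors = FALSE)
  list(keep = keep, log = log)
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Enumerate all unordered trial pairs with condition labels
#'
#' Every trial is compared with every other trial: C(n, 2) unordered pairs.
#' Labels compare the two trials' scene and language; grouping keys are
#' unordered pairs of participants, scenes (items) and cue words.
#' Self-pairs of a grouping key (e.g. two trials of the same participant)
#' are legitimate and retained.
#'
#' @param trials trial metadata data frame (`trial_id`, `participant_id`,
#'   `scene_id`, `language_code`, `cue_word`).
#' @return Data frame with one row per unordered pair: indices `i`, `j`,
#'   both trial ids, `same_scene`, `same_language`, and the three grouping
#'   keys.
#' @export
trial_pairs <- function(trials) {
  n <- nrow(trials)
  if (n < 2) {
    stop("trial_pairs: need at least two trials", call. = FALSE)
  }
  idx <- combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  data.frame(
    i = i, j = j,
    trial_id_1 = trials$trial_id[i],
    trial_id_2 = trials$trial_id[j],
    same_scene = trials$scene_id[i] == trials$scene_id[j],
    same_language = trials$language_code[i] == trials$language_code[j],
    participant_pair = unordered_key(trials$participant_id[i],
                                     trials$participant_id[j]),
    item_pair = unordered_key(trials$scene_id[i], trials$scene_id[j]),
    cue_pair = unordered_key(trials$cue_word[i], trials$cue_word[j]),
    stringsAsFactors = FALSE)
}

#' Assemble the long pair table
#'
#' Combines scan, semantic and syntactic similarity matrices with the pair
#' labels, independently for the two production phases (cross-phase pairs
#' are never formed). Each unordered trial pair appears at most once per
#' phase; semantic and syntactic similarities are identical across the two
#' phase records of a pair, while scan similarity is phase-specific. Pairs
#' involving an excluded sentence, an excluded phase sequence, or an
#' undefined scan similarity are dropped.
#'
#' @param study a study bundle.
#' @param encodings output of [encode_study()].
#' @param sem_mat,syn_mat similarity matrices (trial ids as dimnames).
#' @param scan_before,scan_during phase-specific scan similarity matrices.
#' @param sentence_keep trial ids surviving [filter_sentences()]; `NULL`
#'   keeps all.
#' @param phase_keep logical keep matrix from [filter_scanpatterns()];
#'   `NULL` keeps all.
#' @return Data frame in the pair-table schema (see [write_pair_table()]).
#' @export
build_pair_table <- function(study, encodings, sem_mat, syn_mat,
                             scan_before, scan_during,
                             sentence_keep = NULL, phase_keep = NULL) {
  tr <- study$trials
  ord <- match(tr$trial_id, rownames(sem_mat))
  stopifnot(!anyNA(ord))
  pairs <- trial_pairs(tr)
  sem <- sem_mat[cbind(ord[pairs$i], ord[pairs$j])]
  syn <- syn_mat[cbind(match(tr$trial_id, rownames(syn_mat))[pairs$i],
                       match(tr$trial_id, rownames(syn_mat))[pairs$j])]
  keep_sent <- if (is.null(sentence_keep)) rep(TRUE, nrow(tr)) else
    tr$trial_id %in% sentence_keep
  pair_sent_ok <- keep_sent[pairs$i] & keep_sent[pairs$j]
  one_phase <- function(phase, scan_mat) {
    ordm <- match(tr$trial_id, rownames(scan_mat))
    scan <- scan_mat[cbind(ordm[pairs$i], ordm[pairs$j])]
    ph_ok <- if (is.null(phase_keep)) rep(TRUE, nrow(tr)) else
      phase_keep[match(tr$trial_id, rownames(phase_keep)), phase]
    ok <- pair_sent_ok & ph_ok[pairs$i] & ph_ok[pairs$j] & !is.na(scan)
    data.frame(
      trial_id_1 = pairs$trial_id_1[ok], trial_id_2 = pairs$trial_id_2[ok],
      phase = phase,
      scan_sim = scan[ok], sem_sim = sem[ok], syn_sim = syn[ok],
      same_scene = pairs$same_scene[ok],
      same_language = pairs$same_language[ok],
      participant_pair = pairs$participant_pair[ok],
      item_pair = pairs$item_pair[ok],
      cue_pair = pairs$cue_pair[ok],
      stringsAsFactors = FALSE)
  }
  out <- rbind(one_phase("before", scan_before),
               one_phase("during", scan_during))
  rownames(out) <- NULL
  out
}

#' Shuffle the gaze-sentence correspondence
#'
#' The control analysis randomly re-pairs each scan pattern with a sentence:
#' a uniform seeded permutation maps every trial's linguistic bundle
#' (transcript, cue word, language, embedding vector, dependency parse)
#' onto another trial's eye-movement record. Fixations, utterance timing,
#' participant and scene stay in place, so the phase segmentation of the
#' gaze stream is untouched. With a single trial the shuffle is the
#' identity.
#'
#' @param study a study bundle.
#' @param seed integer seed for the permutation.
#' @return A study bundle with re-paired linguistic data.
#' @export
shuffle_pairing <- function(study, seed) {
  n <- nrow(study$trials)
  if (n < 2) return(study)
  set.seed(seed)
  perm <- sample.int(n)
  ids <- study$trials$trial_id
  out <- study
  for (col in c("language_code", "cue_word", "transcript")) {
    out$trials[[col]] <- study$trials[[col]][perm]
  }
  emb <- study$embeddings[match(ids, rownames(study$embeddings)), , drop = FALSE]
  emb <- emb[perm, , drop = FALSE]
  rownames(emb) <- ids
  out$embeddings <- emb
  trees <- study$trees[match(ids, names(study$trees))]
  trees <- trees[perm]
  names(trees) <- ids
  out$trees <- trees
  out$shuffle_perm <- perm
  out
}
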