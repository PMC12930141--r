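make_meta <- function(n_part, n_scene) {
  g <- expand.grid(p = sprintf("p%02d", seq_len(n_part)),
                   s = sprintf("s%02d", seq_len(n_scene)),
                   stringsAsFactors = FALSE)
  data.frame(trial_id = paste(g$p, g$s, sep = ":"),
             participant_id = g$p, scene_id = g$s,
             language_code = "eng", cue_word = g$s,
             stringsAsFactors = FALSE)
}

test_that("sentence-length filtering is inclusive at both bounds", {
  st <- generate_study(tiny_config())
  wc <- word_counts(st)
  # construct a study view with known counts via direct transcripts
  st$trials$transcript <- vapply(seq_len(nrow(st$trials)), function(i)
    paste(rep("w", c(3, 4, 77, 78, 10)[(i - 1) %% 5 + 1]), collapse = " "), "")
  res <- filter_sentences(st)
  wc2 <- word_counts(st)
  expect_true(all(wc2[res$kept] >= 4 & wc2[res$kept] <= 77))
  expect_true(all(wc2[res$log$trial_id] %in% c(3, 78)))
  expect_equal(length(res$kept) + nrow(res$log), nrow(st$trials))
})

test_that("percentile mode reproduces coinciding absolute thresholds", {
  st <- generate_study(tiny_config())
  counts <- c(3, 4, rep(10, 90), rep(20, 6), 77, 80)
  st2 <- st
  st2$trials <- st$trials[rep(1, length(counts)), ]
  st2$trials$trial_id <- sprintf("t%03d", seq_along(counts))
  st2$trials$transcript <- vapply(counts, function(k)
    paste(rep("w", k), collapse = " "), "")
  abs_res <- filter_sentences(st2, min_words = 4, max_words = 77)
  pct_res <- filter_sentences(st2, percentile = TRUE)
  expect_setequal(abs_res$kept, pct_res$kept)
})

test_that("scan-pattern filtering is per phase and conserves counts", {
  enc <- list(
    t1 = list(before = c("aa"), during = c("ab", "ab"),
              n_fix_before = 1L, n_fix_during = 3L),
    t2 = list(before = c("aa", "ab"), during = c("ab"),
              n_fix_before = 2L, n_fix_during = 2L),
    t3 = list(before = character(0), during = c("aa"),
              n_fix_before = 0L, n_fix_during = 1L))
  res <- filter_scanpatterns(enc)
  expect_false(res$keep["t1", "before"])
  expect_true(res$keep["t1", "during"])
  expect_true(res$keep["t2", "before"])
  expect_true(res$keep["t2", "during"])  # exactly two fixations kept
  expect_false(res$keep["t3", "during"])
  expect_equal(sum(!res$keep), nrow(res$log))
})

test_that("pair enumeration yields C(n,2) labeled unordered pairs", {
  meta <- make_meta(3, 1)
  p <- trial_pairs(meta)
  expect_equal(nrow(p), 3)
  expect_true(all(p$trial_id_1 != p$trial_id_2))
  # grouping keys are order-invariant
  expect_equal(unordered_key <- p$participant_pair,
               with(meta, {
                 idx <- combn(3, 2)
                 paste(pmin(participant_id[idx[1, ]], participant_id[idx[2, ]]),
                       pmax(participant_id[idx[1, ]], participant_id[idx[2, ]]),
                       sep = "|")
               }))
})

test_that("pair labels and keys behave on a mixed design", {
  meta <- make_meta(2, 2)
  meta$language_code <- c("eng", "jpn", "eng", "jpn")
  p <- trial_pairs(meta)
  expect_equal(nrow(p), 6)
  same_scene <- meta$scene_id[match(p$trial_id_1, meta$trial_id)] ==
    meta$scene_id[match(p$trial_id_2, meta$trial_id)]
  expect_equal(p$same_scene, same_scene)
  # self-pairs of a participant arise and are retained
  expect_true(any(sub("\\|.*", "", p$participant_pair) ==
                  sub(".*\\|", "", p$participant_pair)))
})

test_that("the assembled pair table satisfies its invariants", {
  st <- generate_study(tiny_config())
  sims <- study_similarities(st)
  pairs <- build_pair_table(st, sims$encodings, sims$sem, sims$syn,
                            sims$scan_before, sims$scan_during)
  n <- nrow(st$trials)
  expect_lte(nrow(pairs), 2 * n * (n - 1) / 2)
  # sentence similarities identical across the two phase records of a pair
  key <- paste(pairs$trial_id_1, pairs$trial_id_2)
  both <- split(pairs, key)
  both <- both[vapply(both, nrow, 0L) == 2]
  for (b in both[seq_len(min(20, length(both)))]) {
    expect_equal(b$sem_sim[1], b$sem_sim[2])
    expect_equal(b$syn_sim[1], b$syn_sim[2])
  }
  expect_true(all(pairs$scan_sim >= 0 & pairs$scan_sim <= 1))
  expect_true(all(pairs$syn_sim >= 0 & pairs$syn_sim <= 1 + 1e-12))
  expect_true(all(pairs$phase %in% c("before", "during")))
})

test_that("shuffling is seeded, uniform and structure-preserving", {
  st <- generate_study(tiny_config())
  s1 <- shuffle_pairing(st, 5)
  s2 <- shuffle_pairing(st, 5)
  s3 <- shuffle_pairing(st, 6)
  expect_identical(s1$trials$transcript, s2$trials$transcript)
  expect_false(identical(s1$trials$transcript, s3$trials$transcript))
  # gaze side untouched
  expect_identical(s1$fixations, st$fixations)
  expect_identical(s1$trials$utt_onset, st$trials$utt_onset)
  # linguistic bundle moves coherently
  perm <- s1$shuffle_perm
  expect_identical(s1$trials$transcript, st$trials$transcript[perm])
  expect_equal(unname(s1$embeddings[st$trials$trial_id[1], ]),
               unname(st$embeddings[st$trials$trial_id[perm[1]], ]))
  # single-trial study: identity
  one <- st
  one$trials <- st$trials[1, ]
  expect_identical(shuffle_pairing(one, 3)$trials$transcript,
                   one$trials$transcript)
})

test_that("shuffled similarity matrices equal direct recomputation", {
  st <- generate_study(tiny_config())
  sims <- study_similarities(st)
  sh <- shuffle_pairing(st, 12)
  fast <- shuffle_similarities(sims, sh)
  direct_sem <- semantic_similarity_matrix(sh$embeddings)
  ids <- rownames(fast$sem)
  expect_equal(fast$sem, direct_sem[ids, ids], tolerance = 1e-12)
  direct_syn <- syntactic_similarity_matrix(sh$trees)
  expect_equal(fast$syn, direct_syn[ids, ids], tolerance = 1e-12)
})
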