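write_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("fixation tables are read, grouped and sorted; errors are located", {
  f <- write_lines(c(
    "participant\tscene\tx\ty\tt_start\tt_end\timage_width\timage_height",
    "p1\ts1\t500\t300\t120\t300\t1024\t768",
    "p1\ts1\t100\t200\t0\t100\t1024\t768"))
  fx <- read_fixation_table(f)
  expect_equal(nrow(fx$trials), 1)
  expect_equal(nrow(fx$fixations), 2)
  expect_equal(fx$fixations$t_start, c(0, 120))  # sorted by onset

  bad <- write_lines(c(
    "participant\tscene\tx\ty\tt_start\tt_end\timage_width\timage_height",
    "p1\ts1\t100\t200\t0\t100\t1024\t768",
    "p1\ts1\t100\t200\t300\t250\t1024\t768"))
  expect_error(read_fixation_table(bad), "line 3")

  nocol <- write_lines(c("participant\tscene\tx\ty\tt_start",
                         "p1\ts1\t1\t2\t3"))
  expect_error(read_fixation_table(nocol), "t_end")
})

test_that("trial tables validate utterance timing and trial uniqueness", {
  f <- write_lines(c(
    "participant\tscene\tlanguage\tcue_word\tutt_onset\tutt_offset\ttranscript",
    "p1\ts1\ten\tman\t2000\t5000\tthe man reads",
    "p1\ts2\ten\tcup\t1500\t4000\ta cup sits"))
  tr <- read_trial_table(f)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$trial_id, c("p1:s1", "p1:s2"))

  dup <- write_lines(c(
    "participant\tscene\tlanguage\tcue_word\tutt_onset\tutt_offset\ttranscript",
    "p1\ts1\ten\tman\t2000\t5000\ta",
    "p1\ts1\ten\tman\t2100\t5100\tb"))
  expect_error(read_trial_table(dup), "duplicate")

  badt <- write_lines(c(
    "participant\tscene\tlanguage\tcue_word\tutt_onset\tutt_offset\ttranscript",
    "p1\ts1\ten\tman\t5000\t2000\ta"))
  expect_error(read_trial_table(badt), "utt_offset > utt_onset")
})

test_that("CoNLL-U parses into validated trees with normalized labels", {
  f <- write_lines(c(
    "# trial_id = t1",
    "1\tPeter\t_\tNOUN\t_\t_\t2\tnsubj\t_\t_",
    "2\tlikes\t_\tVERB\t_\t_\t0\troot\t_\t_",
    "3\tdogs\t_\tNOUN\t_\t_\t2\tobj:dobj\t_\t_",
    ""))
  trees <- read_conllu(f)
  expect_named(trees, "t1")
  tr <- trees$t1
  expect_equal(tr$head, c(2L, 0L, 2L))
  # children of the root in index order, subtype truncated
  expect_equal(tr$deprel[tr$head == 2], c("nsubj", "obj"))

  # alias map applied on the full label before truncation
  f2 <- write_lines(c(
    "1\tx\t_\tNOUN\t_\t_\t2\tobj\t_\t_",
    "2\ty\t_\tVERB\t_\t_\t0\troot\t_\t_",
    "3\tz\t_\tNOUN\t_\t_\t2\tnsubj:pass\t_\t_",
    ""))
  t2 <- read_conllu(f2)[[1]]
  expect_equal(t2$deprel, c("dobj", "root", "nsubjpass"))

  cyc <- write_lines(c(
    "1\ta\t_\tX\t_\t_\t2\tdep\t_\t_",
    "2\tb\t_\tX\t_\t_\t1\tdep\t_\t_",
    "3\tc\t_\tX\t_\t_\t0\troot\t_\t_",
    ""))
  expect_error(read_conllu(cyc), "cyclic")

  two <- write_lines(c(
    "1\ta\t_\tX\t_\t_\t0\troot\t_\t_",
    "2\tb\t_\tX\t_\t_\t0\troot\t_\t_",
    ""))
  expect_error(read_conllu(two), "exactly one root")
})

test_that("a generated forest round-trips through CoNLL-U unchanged", {
  set.seed(31)
  trees <- lapply(sample(2:9, 50, replace = TRUE), random_dep_tree)
  names(trees) <- sprintf("t%02d", seq_along(trees))
  f <- tempfile(fileext = ".conllu")
  write_conllu(trees, f)
  back <- read_conllu(f)
  expect_identical(names(back), names(trees))
  for (id in names(trees)) {
    expect_identical(back[[id]], trees[[id]], label = id)
  }
})

test_that("embedding tables enforce constant dimension and full precision", {
  f <- write_lines(c("trial_id\te1\te2\te3\te4",
                     "t1\t0.5\t-1\t2\t3.25",
                     "t2\t1\t2\t3\t4"))
  m <- read_embeddings(f)
  expect_equal(dim(m), c(2, 4))
  expect_equal(m["t1", ], c(e1 = 0.5, e2 = -1, e3 = 2, e4 = 3.25))

  ragged <- write_lines(c("trial_id\te1\te2\te3\te4",
                          "t1\t1\t2\t3\t4",
                          "t2\t1\t2\t3"))
  expect_error(read_embeddings(ragged), "dimension")

  set.seed(5)
  mm <- matrix(rnorm(12), 3, dimnames = list(c("a", "b", "c"), NULL))
  f2 <- tempfile()
  write_embeddings(mm, f2)
  back <- read_embeddings(f2)
  expect_equal(unname(back), unname(mm), tolerance = 1e-15)
})

test_that("pair tables round-trip and report row counts", {
  empty <- data.frame(trial_id_1 = character(0), trial_id_2 = character(0),
                      phase = character(0), scan_sim = numeric(0),
                      sem_sim = numeric(0), syn_sim = numeric(0),
                      same_scene = logical(0), same_language = logical(0),
                      participant_pair = character(0),
                      item_pair = character(0), cue_pair = character(0))
  f <- tempfile()
  expect_equal(write_pair_table(empty, f), 0)
  expect_equal(length(readLines(f)), 1)  # header only

  recs <- data.frame(trial_id_1 = c("a", "a", "b"), trial_id_2 = c("b", "c", "c"),
                     phase = "before", scan_sim = c(0.1, 0.25, 1 / 3),
                     sem_sim = c(-0.5, 0.7, 0.9), syn_sim = c(0, 0.5, 1),
                     same_scene = c(TRUE, FALSE, TRUE),
                     same_language = TRUE,
                     participant_pair = "p|q", item_pair = "s|s",
                     cue_pair = "c|d", stringsAsFactors = FALSE)
  expect_equal(write_pair_table(recs, f), 3)
  back <- read_pair_table(f)
  expect_equal(back$scan_sim, recs$scan_sim)
  expect_equal(back$sem_sim, recs$sem_sim)
  expect_equal(back$syn_sim, recs$syn_sim)
})

test_that("a synthetic study round-trips through every format", {
  st <- generate_study(tiny_config())
  dir <- file.path(tempdir(), "study_rt")
  write_study(st, dir)
  back <- read_study(dir)
  expect_equal(back$trials$trial_id, sort(st$trials$trial_id))
  m <- match(back$trials$trial_id, st$trials$trial_id)
  for (col in c("participant_id", "scene_id", "language_code", "cue_word",
                "utt_onset", "utt_offset", "transcript")) {
    expect_equal(back$trials[[col]], st$trials[[col]][m], label = col)
  }
  # no rows silently dropped
  expect_equal(nrow(back$fixations), nrow(st$fixations))
  ids <- st$trials$trial_id
  for (id in ids[c(1, length(ids))]) {
    a <- back$fixations[back$fixations$trial_id == id, ]
    b <- st$fixations[st$fixations$trial_id == id, ]
    expect_equal(a$x, b$x, tolerance = 1e-6)
    expect_equal(a$t_start, b$t_start)
  }
  expect_equal(back$embeddings[ids, ], st$embeddings[ids, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$trees[[ids[1]]][, c("id", "head", "deprel")],
                   st$trees[[ids[1]]][, c("id", "head", "deprel")])
})

test_that("study configs resolve and validate input paths", {
  dir <- file.path(tempdir(), "study_cfg")
  st <- generate_study(tiny_config())
  write_study(st, dir)
  cfg_file <- file.path(dir, "config.yaml")
  writeLines(c("fixations: fixations.tsv", "trials: trials.tsv",
               "conllu: parses.conllu", "embeddings: embeddings.tsv"),
             cfg_file)
  cfg <- read_study_config(cfg_file)
  expect_true(file.exists(cfg$embeddings))
  writeLines(c("fixations: fixations.tsv", "trials: trials.tsv",
               "conllu: parses.conllu", "embeddings: nowhere.tsv"),
             cfg_file)
  expect_error(read_study_config(cfg_file), "nowhere.tsv")
})
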