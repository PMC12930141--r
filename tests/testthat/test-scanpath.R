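test_that("grid cells are labeled row-major with closed far edges", {
  g <- grid_spec(1024, 768)
  expect_equal(as.character(assign_cell(0, 0, g)), "aa")
  expect_equal(as.character(assign_cell(1023.9, 767.9, g)), "df")
  expect_equal(as.character(assign_cell(1024, 768, g)), "df")  # edge closure
  # out-of-image fixations clamp to the nearest edge cell and are counted
  lab <- assign_cell(c(-5, 2000), c(10, 10), g)
  expect_equal(as.character(lab), c("aa", "af"))
  expect_equal(attr(lab, "n_clamped"), 2)
})

test_that("cell assignment matches a brute-force interval search", {
  g <- grid_spec(1024, 768)
  set.seed(12)
  x <- runif(1000, 0, 1024)
  y <- runif(1000, 0, 768)
  got <- as.character(assign_cell(x, y, g))
  xb <- seq(0, 1024, length.out = 7)
  yb <- seq(0, 768, length.out = 5)
  expected <- vapply(seq_along(x), function(i) {
    col <- max(which(x[i] >= xb[-7]))
    row <- max(which(y[i] >= yb[-5]))
    paste0(letters[row], letters[col])
  }, "")
  expect_equal(got, expected)
})

test_that("grid labels are invariant to display resolution", {
  # the same relative fixation positions on two display setups
  rel <- cbind(runif(50), runif(50))
  g1 <- grid_spec(1024, 768)
  g2 <- grid_spec(1920, 1080)
  expect_equal(as.character(assign_cell(rel[, 1] * 1024, rel[, 2] * 768, g1)),
               as.character(assign_cell(rel[, 1] * 1920, rel[, 2] * 1080, g2)))
})

test_that("trial encoding follows the bin-start rule and phase split", {
  g <- grid_spec(1024, 768)
  fx <- data.frame(x = 5, y = 5, t_start = 0, t_end = 100)
  enc <- encode_trial(fx, utt_onset = 50, utt_offset = 100, g)
  expect_equal(enc$before, c("aa", "aa"))  # bins starting at 0, 25
  expect_equal(enc$during, c("aa", "aa"))  # bins starting at 50, 75

  # a fixation entirely after utterance offset contributes nothing
  fx2 <- data.frame(x = c(5, 900), y = c(5, 700),
                    t_start = c(0, 120), t_end = c(100, 400))
  enc2 <- encode_trial(fx2, utt_onset = 50, utt_offset = 100, g)
  expect_equal(enc2$during, c("aa", "aa"))

  # saccade gaps drop bins rather than forward-filling
  fx3 <- data.frame(x = c(5, 5), y = c(5, 5),
                    t_start = c(0, 60), t_end = c(30, 100))
  enc3 <- encode_trial(fx3, utt_onset = 200, utt_offset = 300, g)
  expect_equal(length(enc3$before), 3)  # bins 0, 75 covered; bins 25, 50? -> 0,60-100
})

test_that("token counts respect the bin budget and phases are exclusive", {
  g <- grid_spec(1024, 768)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    ts <- sort(runif(n, 0, 4000))
    fx <- data.frame(x = runif(n, 0, 1024), y = runif(n, 0, 768),
                     t_start = ts, t_end = ts + runif(n, 30, 400))
    fx$t_end <- pmin(fx$t_end, c(fx$t_start[-1], Inf))  # no overlap
    onset <- runif(1, 500, 2000)
    offset <- onset + runif(1, 500, 2000)
    enc <- encode_trial(fx, onset, offset, g)
    expect_lte(length(enc$before) + length(enc$during), floor(offset / 25) + 1)
    expect_lte(length(enc$before), ceiling(onset / 25))
  }
})

test_that("no fixations yields empty flagged sequences", {
  g <- grid_spec(1024, 768)
  enc <- encode_trial(data.frame(x = numeric(0), y = numeric(0),
                                 t_start = numeric(0), t_end = numeric(0)),
                      1000, 2000, g)
  expect_length(enc$before, 0)
  expect_length(enc$during, 0)
  expect_equal(enc$n_fix_before, 0)
})

test_that("region encoding honours containment, priority and coverage", {
  regions <- data.frame(
    scene_id = "s1", label = c("man", "table"),
    x0 = c(100, 150), y0 = c(100, 150), x1 = c(300, 500), y1 = c(300, 500),
    priority = c(1, 2), stringsAsFactors = FALSE)
  expect_equal(assign_region(200, 200, "s1", regions), "man")   # overlap: priority 1
  expect_equal(assign_region(400, 400, "s1", regions), "table")
  expect_equal(assign_region(50, 50, "s1", regions), "background")
  expect_error(assign_region(1, 1, "s2", regions), "s2")
})

test_that("grid and region encodings give correlated pairwise similarities", {
  st <- generate_study(tiny_config())
  g <- study_similarities(st)
  r <- study_similarities(st, use_regions = TRUE)
  lower <- lower.tri(g$scan_before)
  ok <- !is.na(g$scan_before[lower]) & !is.na(r$scan_before[lower])
  expect_gt(cor(g$scan_before[lower][ok], r$scan_before[lower][ok]), 0.3)
})

test_that("LCS length follows the dynamic program on the worked pair", {
  a <- strsplit("ABCBDAB", "")[[1]]
  b <- strsplit("BDCABC", "")[[1]]
  expect_equal(lcs_length(a, b), 4)
  expect_true(is_subseq(strsplit("BCAB", "")[[1]], a))
  expect_true(is_subseq(strsplit("BCAB", "")[[1]], b))
  expect_equal(lcs_length(a, a), length(a))
  expect_equal(lcs_length(character(0), b), 0)
})

test_that("LCS equals exhaustive subsequence enumeration on random pairs", {
  set.seed(8)
  for (i in 1:150) {
    a <- sample(c("A", "B", "C"), sample(0:8, 1), replace = TRUE)
    b <- sample(c("A", "B", "C"), sample(1:8, 1), replace = TRUE)
    expect_equal(lcs_length(a, b), brute_lcs(a, b),
                 label = paste(c(a, "/", b), collapse = ""))
  }
})

test_that("appending a shared token never decreases the LCS", {
  set.seed(9)
  for (i in 1:60) {
    a <- sample(letters[1:4], sample(1:10, 1), replace = TRUE)
    b <- sample(letters[1:4], sample(1:10, 1), replace = TRUE)
    tok <- sample(letters[1:4], 1)
    expect_gte(lcs_length(c(a, tok), c(b, tok)), lcs_length(a, b))
  }
})

test_that("LCS similarity is the geometric-mean-normalized length", {
  a <- strsplit("ABCBDAB", "")[[1]]
  b <- strsplit("BDCABC", "")[[1]]
  expect_equal(lcs_similarity(a, b), 4 / sqrt(42))
  expect_equal(lcs_similarity(a, a), 1)
  expect_equal(lcs_similarity(c("A", "A"), c("B", "C")), 0)
  expect_error(lcs_similarity(character(0), b), "empty")
  # symmetry, range, and 1 iff identical
  set.seed(10)
  for (i in 1:40) {
    a <- sample(c("x", "y", "z"), sample(1:7, 1), replace = TRUE)
    b <- sample(c("x", "y", "z"), sample(1:7, 1), replace = TRUE)
    s <- lcs_similarity(a, b)
    expect_equal(s, lcs_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    if (s == 1) expect_identical(a, b)
  }
})
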