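fixture <- generate_worked_fixture()

test_that("delexicalization keeps only ordered relation structure", {
  s <- delexicalize(fixture$svo_tree)
  expect_equal(s$label, "ROOT")
  expect_equal(vapply(s$children, `[[`, "", "label"),
               c("nsubj", "HEAD", "dobj"))
  # verb-final parse: dependents precede the head marker
  s2 <- delexicalize(fixture$sov_tree)
  expect_equal(vapply(s2$children, `[[`, "", "label"),
               c("nsubj", "dobj", "HEAD"))
  # single-word utterance
  one <- data.frame(id = 1L, form = "scene", upos = "NOUN",
                    head = 0L, deprel = "ROOT")
  expect_equal(delexicalize(one),
               list(label = "ROOT", children = list()))
})

test_that("bracket serialization round-trips structural trees", {
  set.seed(41)
  for (i in 1:30) {
    t <- random_struct_tree(sample(1:8, 1))
    expect_equal(parse_bracket(format_bracket(t)), t)
  }
  expect_equal(format_bracket(parse_bracket("(ROOT (nsubj) (HEAD) (dobj))")),
               "(ROOT (nsubj) (HEAD) (dobj))")
})

test_that("the kernel matches the worked single-production example", {
  t1 <- parse_bracket("(ROOT (nsubj) (dobj))")
  cfg1 <- kernel_config(lambda = 1)
  expect_equal(sst_kernel(t1, t1, cfg1), 6)  # 4 at the root + two leaf matches
  # order-swapped children: no root-level fragment, only leaf matches
  t2 <- parse_bracket("(ROOT (dobj) (nsubj))")
  expect_equal(sst_kernel(t1, t2, cfg1), 2)
  expect_lt(normalized_sst(t1, t2, cfg1), 1)
  expect_equal(normalized_sst(t1, t1, cfg1), 1)
  # disjoint label sets share nothing
  t3 <- parse_bracket("(X (y) (z))")
  expect_equal(sst_kernel(t1, t3, cfg1), 0)
})

test_that("the kernel equals brute-force fragment enumeration", {
  set.seed(42)
  for (i in 1:200) {
    lam <- sample(c(0.4, 1), 1)
    t1 <- random_struct_tree(sample(2:6, 1))
    t2 <- random_struct_tree(sample(2:6, 1))
    expect_equal(sst_kernel(t1, t2, kernel_config(lambda = lam)),
                 brute_sst(t1, t2, lam),
                 tolerance = 1e-10,
                 label = paste(format_bracket(t1), format_bracket(t2), lam))
  }
})

test_that("kernel Gram matrices are positive semidefinite", {
  set.seed(43)
  for (rep in 1:3) {
    trees <- lapply(1:10, function(i) random_struct_tree(sample(2:7, 1)))
    K <- outer(seq_along(trees), seq_along(trees),
               Vectorize(function(i, j) sst_kernel(trees[[i]], trees[[j]])))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("the kernel is symmetric and nondecreasing in the decay", {
  set.seed(44)
  for (i in 1:20) {
    t1 <- random_struct_tree(sample(2:6, 1))
    t2 <- random_struct_tree(sample(2:6, 1))
    expect_equal(sst_kernel(t1, t2), sst_kernel(t2, t1))
    ks <- vapply(c(0.2, 0.5, 0.8, 1), function(l)
      sst_kernel(t1, t2, kernel_config(lambda = l)), 0)
    expect_true(all(diff(ks) >= -1e-12))
  }
})

test_that("order sensitivity separates argument orders", {
  svo <- delexicalize(fixture$svo_tree)
  sov <- delexicalize(fixture$sov_tree)
  expect_lt(normalized_sst(svo, sov), 1)
  expect_equal(normalized_sst(svo, svo), 1)
  expect_lt(normalized_sst(svo, sov), normalized_sst(svo, svo))
})

test_that("core-dependency sequences follow surface order", {
  expect_equal(core_dep_sequence(fixture$svo_tree),
               c("nsubj", "ROOT", "dobj"))
  expect_equal(core_dep_sequence(fixture$sov_tree),
               c("nsubj", "dobj", "ROOT"))
  mods <- data.frame(id = 1:3, form = c("the", "red", "box"),
                     upos = c("DET", "ADJ", "NOUN"),
                     head = c(3L, 3L, 0L),
                     deprel = c("det", "amod", "root"))
  expect_equal(core_dep_sequence(mods), "ROOT")
})

test_that("every tree emits exactly one ROOT in its core sequence", {
  set.seed(45)
  for (i in 1:40) {
    tr <- random_dep_tree(sample(2:10, 1))
    expect_equal(sum(core_dep_sequence(tr) == "ROOT"), 1)
  }
})

test_that("word-order tabulation counts and sorts sequences per language", {
  svo <- fixture$svo_tree
  tab <- tabulate_word_orders(list(a = svo, b = svo, c = svo),
                              rep("eng", 3))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 3)
  expect_equal(tab$sequence, "nsubj ROOT dobj")
  # empty input produces an empty table
  expect_equal(nrow(tabulate_word_orders(list(), character(0))), 0)
})

test_that("POS-sequence similarity reuses the LCS core", {
  expect_equal(pos_lcs_similarity(c("NOUN", "VERB"), c("NOUN", "VERB")), 1)
  expect_equal(pos_lcs_similarity(c("NOUN", "VERB", "NOUN"),
                                  c("NOUN", "NOUN", "VERB")), 2 / 3)
  expect_error(pos_lcs_similarity(character(0), "NOUN"), "empty")
  set.seed(46)
  for (i in 1:30) {
    a <- sample(c("NOUN", "VERB", "ADJ"), sample(1:8, 1), replace = TRUE)
    b <- sample(c("NOUN", "VERB", "ADJ"), sample(1:8, 1), replace = TRUE)
    expect_equal(pos_lcs_similarity(a, b),
                 brute_lcs(a, b) / sqrt(length(a) * length(b)))
  }
})

test_that("pairwise syntactic similarities match per-pair computation", {
  set.seed(47)
  trees <- lapply(1:8, function(i) random_dep_tree(sample(2:7, 1)))
  names(trees) <- sprintf("t%d", 1:8)
  M <- syntactic_similarity_matrix(trees)
  for (i in c(1, 3)) for (j in c(5, 8)) {
    expect_equal(M[i, j],
                 normalized_sst(delexicalize(trees[[i]]),
                                delexicalize(trees[[j]])))
  }
  expect_equal(diag(M), setNames(rep(1, 8), names(trees)))
})
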