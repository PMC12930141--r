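# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: LCS by exhaustive subsequence enumeration, the
# tree kernel by explicit fragment enumeration.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_subseq <- function(s, t) {
  # is s a subsequence of t?
  j <- 1L
  for (x in t) {
    if (j <= length(s) && identical(s[j], x)) j <- j + 1L
  }
  j > length(s)
}

brute_lcs <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a)
  best <- 0L
  if (n == 0) return(0L)
  for (mask in 0:(2^n - 1)) {
    sub <- a[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sub) > best && is_subseq(sub, b)) best <- length(sub)
  }
  best
}

# Enumerate the subset-tree fragment derivations rooted at a node. A
# fragment keeps either all or none of a node's children; each kept child
# is either stopped (written "[label]") or expanded recursively (written
# "(label ...)"). A derivation's weight is lambda^(number of expanded
# nodes). The kernel equals, over all node pairs, the summed weight of
# derivations present at both nodes — i.e. sum over derivation strings of
# count1 * count2 * weight.
enumerate_derivs <- function(node, lambda) {
  if (length(node$children) == 0) {
    return(setNames(lambda, paste0("(", node$label, ")")))
  }
  per_child <- lapply(node$children, function(ch) {
    c(setNames(1, paste0("[", ch$label, "]")),
      enumerate_derivs(ch, lambda))
  })
  combos <- per_child[[1]]
  for (ch in per_child[-1]) {
    combos <- setNames(
      as.vector(outer(combos, ch)),
      as.vector(outer(names(combos), names(ch), paste)))
  }
  setNames(lambda * combos,
           paste0("(", node$label, " ", names(combos), ")"))
}

all_node_derivs <- function(tree, lambda) {
  res <- list(enumerate_derivs(tree, lambda))
  for (ch in tree$children) {
    res <- c(res, list(all_node_derivs(ch, lambda)))
  }
  unlist(res)
}

brute_sst <- function(t1, t2, lambda) {
  f1 <- all_node_derivs(t1, lambda)  # names repeat across nodes
  f2 <- all_node_derivs(t2, lambda)
  c1 <- table(names(f1))
  c2 <- table(names(f2))
  common <- intersect(names(c1), names(c2))
  if (length(common) == 0) return(0)
  w <- f1[match(common, names(f1))]  # weight is a function of the string
  sum(as.numeric(c1[common]) * as.numeric(c2[common]) * w)
}

# random structural tree with n nodes over a label set
random_struct_tree <- function(n, labels = c("ROOT", "nsubj", "dobj", "amod",
                                             "det", "HEAD")) {
  parents <- integer(n)
  for (i in seq_len(n)[-1]) parents[i] <- sample.int(i - 1, 1)
  labs <- sample(labels, n, replace = TRUE)
  build <- function(i) {
    kids <- lapply(which(parents == i), build)
    list(label = labs[i], children = kids)
  }
  build(1)
}

# random valid dependency tree (data frame) with n tokens
random_dep_tree <- function(n, deprels = c("nsubj", "dobj", "amod", "det",
                                           "obl", "advcl", "ccomp")) {
  head <- integer(n)
  root <- sample.int(n, 1)
  placed <- root
  for (i in setdiff(sample.int(n), root)) {
    head[i] <- if (length(placed) == 1) placed else sample(placed, 1)
    placed <- c(placed, i)
  }
  head[root] <- 0L
  data.frame(id = seq_len(n),
             form = sprintf("w%d", seq_len(n)),
             upos = sample(c("NOUN", "VERB", "ADJ", "DET"), n, replace = TRUE),
             head = head,
             deprel = ifelse(head == 0, "root", sample(deprels, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

# small synthetic study shared by several tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_participants = 2, n_scenes = 4, seed = 99),
                            list(...))
  do.call(synth_config, args)
}
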