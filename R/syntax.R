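#' Kernel configuration for syntactic similarity
#'
#' @param lambda decay applied per tree fragment level; in (0, 1]. Larger
#'   fragments are down-weighted geometrically.
#' @param normalize divide by the geometric mean of the self-kernels so
#'   that identical trees score 1.
#' @return A `gs_kernel` config.
#' @export
kernel_config <- function(lambda = 0.4, normalize = TRUE) {
  stopifnot(lambda > 0, lambda <= 1)
  structure(list(lambda = lambda, normalize = normalize),
            class = "gs_kernel")
}

# A structural tree is a recursive list: list(label, children = list(...)).
struct_node <- function(label, children = list()) {
  list(label = label, children = children)
}

#' Delexicalize a dependency tree
#'
#' Strips words and part-of-speech tags, keeping only dependency-relation
#' labels (the root token is labeled `"ROOT"`). Children of each node are
#' ordered by the linear position of the dependent token, and a reserved
#' `"HEAD"` marker child is inserted at the head token's own linear slot
#' among its dependents. The marker makes head position part of the ordered
#' production, so a verb-medial and a verb-final realization of the same
#' head-dependent relations yield different structures — the kernel is
#' order-dependent.
#'
#' @param tree a dependency tree data frame (`id`, `head`, `deprel`).
#' @return A structural tree (nested list with `label` and `children`).
#' @export
delexicalize <- function(tree) {
  build <- function(i) {
    lab <- if (tree$head[i] == 0) "ROOT" else tree$deprel[i]
    deps <- tree$id[tree$head == tree$id[i]]
    if (length(deps) == 0) return(struct_node(lab))
    slots <- sort(c(deps, tree$id[i]))
    children <- lapply(slots, function(j) {
      if (j == tree$id[i]) struct_node("HEAD") else build(which(tree$id == j))
    })
    struct_node(lab, children)
  }
  build(which(tree$head == 0))
}

#' Bracketed serialization of structural trees
#'
#' `format_bracket` writes a tree as e.g. `(ROOT (nsubj) (HEAD) (dobj))`;
#' `parse_bracket` is its inverse. Used for fixtures and for canonical
#' de-duplication of repeated structures.
#'
#' @param tree a structural tree.
#' @return A single string.
#' @export
format_bracket <- function(tree) {
  if (length(tree$children) == 0) return(paste0("(", tree$label, ")"))
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, format_bracket, ""), collapse = " "),
         ")")
}

#' @rdname format_bracket
#' @param s a bracketed string.
#' @export
parse_bracket <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  parse_node <- function() {
    if (toks[pos] != "(") stop("parse_bracket: expected '('", call. = FALSE)
    pos <<- pos + 1L
    lab <- toks[pos]
    pos <<- pos + 1L
    children <- list()
    while (toks[pos] == "(") children[[length(children) + 1L]] <- parse_node()
    if (toks[pos] != ")") stop("parse_bracket: expected ')'", call. = FALSE)
    pos <<- pos + 1L
    struct_node(lab, children)
  }
  node <- parse_node()
  if (pos != length(toks) + 1L) {
    stop("parse_bracket: trailing input", call. = FALSE)
  }
  node
}

# Flatten a structural tree into parallel vectors: label, production string
# (label plus the ordered child-label list), and child indices.
flatten_struct <- function(tree) {
  labels <- character(0); prods <- character(0); children <- list()
  walk <- function(node) {
    idx <- length(labels) + 1L
    labels[idx] <<- node$label
    prods[idx] <<- ""
    children[[idx]] <<- integer(0)
    kid_idx <- vapply(node$children, walk, 0L)
    children[[idx]] <<- kid_idx
    kid_labs <- vapply(node$children, `[[`, "", "label")
    prods[idx] <<- paste(c(node$label, kid_labs), collapse = "\t")
    idx
  }
  walk(tree)
  list(labels = labels, prods = prods, children = children)
}

#' Subset tree kernel over structural trees
#'
#' Counts the tree fragments shared by two trees, where a fragment keeps
#' either all or none of a node's children (subset-tree semantics) and must
#' match in label, structure and child order. The recursive contribution of
#' a matching node pair is `lambda` for matching leaf productions and
#' `lambda * prod(1 + Delta(child_i, child_j))` for matching internal
#' productions; pairs with differing productions contribute 0.
#'
#' @param t1,t2 structural trees (from [delexicalize()] or
#'   [parse_bracket()]).
#' @param cfg a [kernel_config()].
#' @return `sst_kernel`: the raw kernel value (>= 0). `normalized_sst`:
#'   `K(t1,t2) / sqrt(K(t1,t1) K(t2,t2))`, in \[0, 1\].
#' @export
sst_kernel <- function(t1, t2, cfg = kernel_config()) {
  f1 <- flatten_struct(t1)
  f2 <- flatten_struct(t2)
  sst_kernel_flat(f1, f2, cfg$lambda)
}

sst_kernel_flat <- function(f1, f2, lambda) {
  n1 <- length(f1$labels); n2 <- length(f2$labels)
  memo <- matrix(NA_real_, n1, n2)
  delta <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- 0
    if (f1$prods[i] == f2$prods[j]) {
      kids1 <- f1$children[[i]]
      if (length(kids1) == 0) {
        val <- lambda
      } else {
        kids2 <- f2$children[[j]]
        val <- lambda
        for (k in seq_along(kids1)) {
          val <- val * (1 + delta(kids1[k], kids2[k]))
        }
      }
    }
    memo[i, j] <<- val
    val
  }
  total <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (f1$prods[i] == f2$prods[j]) total <- total + delta(i, j)
  }
  total
}

#' @rdname sst_kernel
#' @export
normalized_sst <- function(t1, t2, cfg = kernel_config()) {
  k11 <- sst_kernel(t1, t1, cfg)
  k22 <- sst_kernel(t2, t2, cfg)
  if (k11 <= 0 || k22 <= 0) {
    stop("normalized_sst: undefined (zero self-kernel)", call. = FALSE)
  }
  sst_kernel(t1, t2, cfg) / sqrt(k11 * k22)
}

#' All pairwise syntactic similarities
#'
#' Delexicalizes every tree and computes the normalized subset tree kernel
#' for every unordered pair. Template-generated and natural parses repeat
#' structures heavily, so kernels are computed once per unique canonical
#' bracket string and broadcast.
#'
#' @param trees named list of dependency trees.
#' @param cfg a [kernel_config()].
#' @return Symmetric similarity matrix with trial-id dimnames.
#' @export
syntactic_similarity_matrix <- function(trees, cfg = kernel_config()) {
  struct <- lapply(trees, delexicalize)
  keys <- vapply(struct, format_bracket, "")
  uniq <- !duplicated(keys)
  ukeys <- keys[uniq]
  uflat <- lapply(struct[uniq], flatten_struct)
  m <- length(ukeys)
  self_k <- vapply(uflat, function(f) sst_kernel_flat(f, f, cfg$lambda), 0)
  if (any(self_k <= 0)) {
    stop("normalized_sst: undefined (zero self-kernel)", call. = FALSE)
  }
  usim <- diag(1, m)
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      k <- sst_kernel_flat(uflat[[i]], uflat[[j]], cfg$lambda)
      usim[i, j] <- usim[j, i] <- k / sqrt(self_k[i] * self_k[j])
    }
  }
  idx <- match(keys, ukeys)
  out <- usim[idx, idx, drop = FALSE]
  dimnames(out) <- list(names(trees), names(trees))
  out
}

#' Core dependency labels
#'
#' The obligatory grammatical relations retained by
#' [core_dep_sequence()]: nominal/clausal subjects (active and passive),
#' direct and indirect objects, and clausal complements. Modifiers are
#' excluded.
#'
#' @return Character vector of labels.
#' @export
core_dependency_labels <- function() {
  c("nsubj", "nsubjpass", "dobj", "iobj", "csubj", "csubjpass",
    "ccomp", "xcomp")
}

#' Core-dependency label sequence of a parse
#'
#' Walks the tokens in linear (surface) order and emits `"ROOT"` for the
#' root token and the dependency label for every token bearing a core
#' relation; all other tokens are skipped. The sequence therefore reflects
#' the word order of the obligatory arguments — e.g. a transitive
#' verb-medial clause gives `nsubj ROOT dobj`, its verb-final counterpart
#' `nsubj dobj ROOT`.
#'
#' @param tree a dependency tree data frame.
#' @return Character vector of labels (always exactly one `"ROOT"`).
#' @export
core_dep_sequence <- function(tree) {
  lab <- ifelse(tree$head == 0, "ROOT", tree$deprel)
  lab[lab == "ROOT" | lab %in% core_dependency_labels()]
}

#' Tabulate core-dependency word orders by language
#'
#' @param trees named list of dependency trees.
#' @param language character vector of language codes, parallel to `trees`.
#' @param top_k optionally keep only the `top_k` most frequent sequences
#'   per language.
#' @return Data frame (`language`, `sequence`, `count`), counts descending
#'   within language.
#' @export
tabulate_word_orders <- function(trees, language, top_k = NULL) {
  stopifnot(length(trees) == length(language))
  seqs <- vapply(trees, function(t) paste(core_dep_sequence(t), collapse = " "), "")
  out_rows <- lapply(sort(unique(language)), function(lg) {
    tab <- sort(table(seqs[language == lg]), decreasing = TRUE)
    if (length(tab) == 0) return(NULL)
    if (!is.null(top_k)) tab <- head(tab, top_k)
    data.frame(language = lg, sequence = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out_rows)
  if (is.null(out)) {
    out <- data.frame(language = character(0), sequence = character(0),
                      count = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Part-of-speech sequence similarity
#'
#' A coarser syntactic similarity: the normalized LCS between the
#' part-of-speech (UPOS) sequences of two parses.
#'
#' @param pos1,pos2 nonempty UPOS token vectors.
#' @return Similarity in \[0, 1\].
#' @export
pos_lcs_similarity <- function(pos1, pos2) {
  if (length(pos1) == 0 || length(pos2) == 0) {
    stop("pos_lcs_similarity: undefined for empty sequences", call. = FALSE)
  }
  lcs_similarity(pos1, pos2)
}

#' @rdname pos_lcs_similarity
#' @param trees named list of dependency trees.
#' @return `pos_similarity_matrix`: symmetric similarity matrix.
#' @export
pos_similarity_matrix <- function(trees) {
  seqs <- lapply(trees, `[[`, "upos")
  lev <- unique(unlist(seqs, use.names = FALSE))
  iseqs <- lapply(seqs, function(s) match(s, lev))
  m <- lcs_pairwise_sim(iseqs)
  dimnames(m) <- list(names(trees), names(trees))
  m
}
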