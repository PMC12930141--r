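#' Semantic similarity between sentence embeddings
#'
#' The default semantic similarity is the dot product of the two trials'
#' sentence-embedding vectors; cosine similarity (dot product of the
#' unit-normalized vectors) is available as an alternative and is identical
#' when embeddings are unit length. Embeddings are used as provided — no
#' re-normalization is applied by default.
#'
#' @param u,v numeric vectors of equal dimension.
#' @return A scalar similarity.
#' @export
dot_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop(sprintf("dot_similarity: dimension mismatch (%d vs %d)",
                 length(u), length(v)), call. = FALSE)
  }
  sum(u * v)
}

#' @rdname dot_similarity
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine_similarity: undefined for a zero vector", call. = FALSE)
  }
  dot_similarity(u, v) / (nu * nv)
}

#' All pairwise semantic similarities
#'
#' @param embeddings numeric matrix, one row per trial (rownames = ids).
#' @param method `"dot"` (default) or `"cosine"`.
#' @return Symmetric similarity matrix with trial-id dimnames.
#' @export
semantic_similarity_matrix <- function(embeddings, method = c("dot", "cosine")) {
  method <- match.arg(method)
  if (method == "cosine") {
    nrm <- sqrt(rowSums(embeddings^2))
    if (any(nrm == 0)) {
      stop("cosine_similarity: undefined for a zero vector", call. = FALSE)
    }
    embeddings <- embeddings / nrm
  }
  tcrossprod(embeddings)
}
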