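#' Grid specification for scan pattern encoding
#'
#' A regular grid of equally sized cells laid over the scene image. The
#' default 6 x 4 grid gives 24 cells. Cells are labeled by row letter (top
#' to bottom) followed by column letter (left to right), so the top-left
#' cell is `"aa"` and the bottom-right cell of a 6 x 4 grid is `"df"`.
#' Because the grid is defined over each trial's own image extent, labels
#' are comparable across display resolutions.
#'
#' @param image_width,image_height image size in pixels.
#' @param n_cols,n_rows grid dimensions.
#' @return A `gs_grid` object.
#' @export
grid_spec <- function(image_width, image_height, n_cols = 6, n_rows = 4) {
  stopifnot(n_cols >= 1, n_rows >= 1, image_width > 0, image_height > 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 image_width = image_width, image_height = image_height),
            class = "gs_grid")
}

#' Map fixation coordinates to grid-cell labels
#'
#' Cells are half-open intervals; the right and bottom image edges close
#' into the last column/row. Fixations outside the image (small tracker
#' overshoots) are clamped to the nearest edge cell; the number of clamped
#' fixations is returned as an attribute.
#'
#' @param x,y fixation coordinates in pixels (vectorized).
#' @param grid a [grid_spec()].
#' @return Character vector of cell labels, with attribute `n_clamped`.
#' @export
assign_cell <- function(x, y, grid) {
  clamped <- sum(x < 0 | x > grid$image_width | y < 0 | y > grid$image_height)
  x <- pmin(pmax(x, 0), grid$image_width)
  y <- pmin(pmax(y, 0), grid$image_height)
  col <- pmin(floor(x / (grid$image_width / grid$n_cols)), grid$n_cols - 1)
  row <- pmin(floor(y / (grid$image_height / grid$n_rows)), grid$n_rows - 1)
  structure(paste0(letters[row + 1], letters[col + 1]), n_clamped = clamped)
}

# Assign each bin-start instant to the fixation (if any) covering it.
# Fixations must be sorted by t_start; membership is t_start <= s < t_end.
bin_cover <- function(starts, t_start, t_end) {
  idx <- findInterval(starts, t_start)
  ok <- idx > 0
  ok[ok] <- starts[ok] < t_end[idx[ok]]
  list(idx = idx, covered = ok)
}

#' Encode one trial as phase-segmented categorical scan sequences
#'
#' The time axis is partitioned into consecutive `bin_ms` bins from scene
#' onset (t = 0). A bin whose start instant falls inside a fixation's
#' `[t_start, t_end)` interval receives that fixation's label; bins covered
#' by no fixation (saccades, blinks) are dropped. Bins starting before
#' utterance onset form the "before" (planning) sequence, bins starting in
#' `[utt_onset, utt_offset)` the "during" (articulation) sequence; later
#' bins are discarded. Consecutive identical labels are retained, so longer
#' fixations weigh more.
#'
#' @param fixations data frame (`x`, `y`, `t_start`, `t_end`), sorted by
#'   `t_start`.
#' @param utt_onset,utt_offset utterance onset/offset, ms from scene onset.
#' @param grid a [grid_spec()]; alternatively supply `labels`, one per
#'   fixation (used by the region-of-interest variant).
#' @param bin_ms bin width in milliseconds.
#' @param labels optional precomputed per-fixation labels.
#' @return List: `before` and `during` token vectors, per-phase fixation
#'   counts `n_fix_before` / `n_fix_during`, and `n_clamped`.
#' @export
encode_trial <- function(fixations, utt_onset, utt_offset, grid = NULL,
                         bin_ms = 25, labels = NULL) {
  stopifnot(utt_offset > utt_onset, utt_onset > 0)
  n_clamped <- 0L
  if (is.null(labels)) {
    labels <- assign_cell(fixations$x, fixations$y, grid)
    n_clamped <- attr(labels, "n_clamped")
  }
  starts <- bin_ms * seq(0, ceiling(utt_offset / bin_ms) - 1)
  starts <- starts[starts < utt_offset]
  if (nrow(fixations) == 0) {
    return(list(before = character(0), during = character(0),
                n_fix_before = 0L, n_fix_during = 0L, n_clamped = 0L))
  }
  cov <- bin_cover(starts, fixations$t_start, fixations$t_end)
  tok <- as.character(labels)[cov$idx[cov$covered]]
  s_cov <- starts[cov$covered]
  overlaps <- function(a, b) fixations$t_start < b & fixations$t_end > a
  list(before = tok[s_cov < utt_onset],
       during = tok[s_cov >= utt_onset],
       n_fix_before = sum(overlaps(0, utt_onset)),
       n_fix_during = sum(overlaps(utt_onset, utt_offset)),
       n_clamped = n_clamped)
}

#' Region-of-interest labels for fixations
#'
#' Maps each fixation to the labeled scene region containing it (lowest
#' `priority` value wins among overlapping regions), or `"background"` if
#' no region contains it.
#'
#' @param x,y fixation coordinates.
#' @param scene_id scene whose regions apply.
#' @param regions region data frame (see [read_region_map()]).
#' @return Character vector of region labels.
#' @export
assign_region <- function(x, y, scene_id, regions) {
  reg <- regions[regions$scene_id == scene_id, , drop = FALSE]
  if (nrow(reg) == 0) {
    stop(sprintf("region map: no regions for scene '%s'", scene_id),
         call. = FALSE)
  }
  reg <- reg[order(reg$priority), , drop = FALSE]
  out <- rep("background", length(x))
  for (i in rev(seq_len(nrow(reg)))) {
    hit <- x >= reg$x0[i] & x <= reg$x1[i] & y >= reg$y0[i] & y <= reg$y1[i]
    out[hit] <- reg$label[i]
  }
  out
}

#' Encode every trial of a study
#'
#' @param study a study bundle.
#' @param n_cols,n_rows grid dimensions (the grid is rebuilt per trial from
#'   that trial's image extent).
#' @param bin_ms bin width, ms.
#' @param regions optional region map; when given, fixations are mapped to
#'   scene regions instead of grid cells.
#' @return Named list (by trial id) of [encode_trial()] results, with
#'   attribute `n_clamped` totalling clamped fixations.
#' @export
encode_study <- function(study, n_cols = 6, n_rows = 4, bin_ms = 25,
                         regions = NULL) {
  fx_by_trial <- split(study$fixations, study$fixations$trial_id)
  out <- vector("list", nrow(study$trials))
  names(out) <- study$trials$trial_id
  total_clamped <- 0L
  for (i in seq_len(nrow(study$trials))) {
    tr <- study$trials[i, ]
    fx <- fx_by_trial[[tr$trial_id]]
    if (is.null(fx)) fx <- data.frame(x = numeric(0), y = numeric(0),
                                      t_start = numeric(0), t_end = numeric(0))
    if (is.null(regions)) {
      grid <- grid_spec(tr$image_width, tr$image_height, n_cols, n_rows)
      enc <- encode_trial(fx, tr$utt_onset, tr$utt_offset, grid, bin_ms)
    } else {
      labs <- assign_region(fx$x, fx$y, tr$scene_id, regions)
      enc <- encode_trial(fx, tr$utt_onset, tr$utt_offset, bin_ms = bin_ms,
                          labels = labs)
    }
    total_clamped <- total_clamped + enc$n_clamped
    out[[tr$trial_id]] <- enc
  }
  attr(out, "n_clamped") <- total_clamped
  out
}

#' Longest common subsequence length
#'
#' Dynamic program over the (m+1) x (n+1) score matrix: equal tokens extend
#' the diagonal by one, otherwise the cell takes the maximum of its left
#' and upper neighbours.
#'
#' @param a,b token vectors (character or anything coercible).
#' @return Integer LCS length.
#' @export
lcs_length <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  lev <- unique(c(a, b))
  lcs_length_int(match(a, lev), match(b, lev))
}

#' Normalized LCS similarity
#'
#' LCS length divided by the geometric mean of the two sequence lengths;
#' 1 exactly iff the sequences are identical, 0 iff they share no token.
#'
#' @param a,b nonempty token vectors.
#' @return Similarity in \[0, 1\].
#' @export
lcs_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("lcs_similarity: undefined for empty sequences", call. = FALSE)
  }
  lcs_length(a, b) / sqrt(length(a) * length(b))
}

#' All pairwise scan similarities for one phase
#'
#' @param encodings output of [encode_study()].
#' @param phase `"before"` or `"during"`.
#' @return Symmetric similarity matrix (NA where a sequence is empty),
#'   dimnames = trial ids.
#' @export
scan_similarity_matrix <- function(encodings, phase = c("before", "during")) {
  phase <- match.arg(phase)
  seqs <- lapply(encodings, `[[`, phase)
  lev <- unique(unlist(seqs, use.names = FALSE))
  iseqs <- lapply(seqs, function(s) match(s, lev))
  m <- lcs_pairwise_sim(iseqs)
  dimnames(m) <- list(names(encodings), names(encodings))
  m
}

#' Export encoded sequences as a long table
#'
#' @param encodings output of [encode_study()].
#' @return Data frame: `trial_id`, `phase`, `token_index`, `token`.
#' @export
sequences_as_table <- function(encodings) {
  rows <- lapply(names(encodings), function(id) {
    do.call(rbind, lapply(c("before", "during"), function(ph) {
      tok <- encodings[[id]][[ph]]
      if (length(tok) == 0) return(NULL)
      data.frame(trial_id = id, phase = ph,
                 token_index = seq_along(tok), token = tok,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trial_id = character(0), phase = character(0),
                      token_index = integer(0), token = character(0))
  }
  out
}
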