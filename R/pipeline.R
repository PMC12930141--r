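#' Compute all per-study similarity structures
#'
#' Runs the encoding and similarity stages: phase-segmented scan sequences,
#' pairwise scan similarity per phase, semantic similarity over embeddings
#' and syntactic similarity over delexicalized parses.
#'
#' @param study a study bundle.
#' @param n_cols,n_rows,bin_ms scan-pattern encoding parameters.
#' @param sem_method `"dot"` or `"cosine"`.
#' @param kernel a [kernel_config()].
#' @param use_regions encode fixations over the scene region map instead
#'   of the grid (requires `study$regions`).
#' @return List: `encodings`, `scan_before`, `scan_during`, `sem`, `syn`.
#' @export
study_similarities <- function(study, n_cols = 6, n_rows = 4, bin_ms = 25,
                               sem_method = "dot",
                               kernel = kernel_config(),
                               use_regions = FALSE) {
  regions <- if (use_regions) {
    if (is.null(study$regions)) {
      stop("study_similarities: no region map in study", call. = FALSE)
    }
    study$regions
  } else NULL
  encodings <- encode_study(study, n_cols, n_rows, bin_ms, regions)
  list(encodings = encodings,
       scan_before = scan_similarity_matrix(encodings, "before"),
       scan_during = scan_similarity_matrix(encodings, "during"),
       sem = semantic_similarity_matrix(study$embeddings, sem_method),
       syn = syntactic_similarity_matrix(study$trees, kernel))
}

#' Run the full association analysis on a study
#'
#' Applies the exclusion filters, assembles the pairwise comparison table,
#' fits the association model and produces the descriptive summaries
#' (binned means, word-order tabulation, semantic/syntactic correlation).
#'
#' @param study a study bundle.
#' @param sims optional precomputed [study_similarities()] result (reused,
#'   e.g., across shuffle repetitions).
#' @param min_words,max_words,min_fixations exclusion thresholds.
#' @param fit_model fit the mixed model (set `FALSE` for table-only runs).
#' @param standardize compute standardized coefficients.
#' @inheritParams study_similarities
#' @return A `gs_analysis` list: `pairs`, `fit`, `binned_sem`,
#'   `binned_syn`, `word_orders`, `correlations`, `exclusions`, `log`.
#' @export
analyse_study <- function(study, sims = NULL,
                          n_cols = 6, n_rows = 4, bin_ms = 25,
                          sem_method = "dot", kernel = kernel_config(),
                          use_regions = FALSE,
                          min_words = 4, max_words = 77, min_fixations = 2,
                          fit_model = TRUE, standardize = TRUE) {
  if (is.null(sims)) {
    sims <- study_similarities(study, n_cols, n_rows, bin_ms, sem_method,
                               kernel, use_regions)
  }
  sent <- filter_sentences(study, min_words, max_words)
  scanf <- filter_scanpatterns(sims$encodings, min_fixations)
  pairs <- build_pair_table(study, sims$encodings, sims$sem, sims$syn,
                            sims$scan_before, sims$scan_during,
                            sentence_keep = sent$kept,
                            phase_keep = scanf$keep)
  fit <- if (fit_model) fit_association_model(pairs, standardize) else NULL
  ord <- match(study$trials$trial_id, names(study$trees))
  res <- list(
    pairs = pairs,
    fit = fit,
    binned_sem = binned_summary(pairs, "sem_sim"),
    binned_syn = binned_summary(pairs, "syn_sim"),
    word_orders = tabulate_word_orders(study$trees[ord],
                                       study$trials$language_code),
    correlations = similarity_correlation(pairs),
    exclusions = rbind(sent$log, scanf$log),
    log = list(n_trials = nrow(study$trials),
               n_pairs = nrow(pairs),
               n_excluded_sentences = nrow(sent$log),
               n_excluded_scanpatterns = nrow(scanf$log),
               n_clamped_fixations = attr(sims$encodings, "n_clamped"),
               word_bounds = sent$bounds))
  class(res) <- "gs_analysis"
  res
}

#' Run the end-to-end pipeline from a configuration
#'
#' The single-entry orchestration: load (or synthesize) a study, optionally
#' shuffle the gaze-sentence correspondence, run the analysis, and return
#' everything with a run log. Deterministic given the configuration,
#' including its seed.
#'
#' Config fields: either `synthetic` (a list of [synth_config()] arguments)
#' or the input paths `fixations`, `trials`, `conllu`, `embeddings`
#' (optionally `regions`); plus optional `shuffle` (logical),
#' `seed` (governs both simulation and shuffle), `sem_method`, `lambda`,
#' `n_cols`, `n_rows`, `bin_ms`, `min_words`, `max_words`,
#' `min_fixations`, `use_regions`.
#'
#' @param config a named list, or a path to a YAML/JSON config file.
#' @return A `gs_analysis` (see [analyse_study()]) with the `study` bundle
#'   attached.
#' @export
run_study_pipeline <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  seed <- config$seed %||% 1L
  study <- if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- seed
    generate_study(do.call(synth_config, args))
  } else {
    read_study(config)
  }
  if (isTRUE(config$shuffle)) {
    study <- shuffle_pairing(study, seed)
  }
  kernel <- kernel_config(lambda = config$lambda %||% 0.4)
  res <- analyse_study(
    study,
    n_cols = config$n_cols %||% 6, n_rows = config$n_rows %||% 4,
    bin_ms = config$bin_ms %||% 25,
    sem_method = config$sem_method %||% "dot", kernel = kernel,
    use_regions = isTRUE(config$use_regions),
    min_words = config$min_words %||% 4,
    max_words = config$max_words %||% 77,
    min_fixations = config$min_fixations %||% 2,
    standardize = !isFALSE(config$standardize))
  res$study <- study
  res$log$seed <- seed
  res$log$shuffled <- isTRUE(config$shuffle)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity structures after a shuffle
#'
#' [shuffle_pairing()] leaves the gaze stream (and hence the scan
#' similarity matrices) untouched and only permutes the linguistic bundle,
#' so the shuffled study's semantic and syntactic similarity matrices are
#' row/column permutations of the originals. This helper applies that
#' permutation, avoiding recomputation across shuffle repetitions.
#'
#' @param sims a [study_similarities()] result for the unshuffled study.
#' @param shuffled the study returned by [shuffle_pairing()] (carries the
#'   permutation).
#' @return A similarity list for the shuffled study.
#' @export
shuffle_similarities <- function(sims, shuffled) {
  perm <- shuffled$shuffle_perm
  if (is.null(perm)) return(sims)
  out <- sims
  ids <- shuffled$trials$trial_id  # the permutation indexes trial order
  for (nmat in c("sem", "syn")) {
    m <- sims[[nmat]][ids, ids, drop = FALSE][perm, perm, drop = FALSE]
    dimnames(m) <- list(ids, ids)
    out[[nmat]] <- m
  }
  out
}

#' Write analysis outputs to a directory
#'
#' Emits the long pair table, the coefficient table, binned summaries,
#' word-order frequencies, the exclusion log and a JSON run log.
#'
#' @param res a `gs_analysis`.
#' @param dir output directory.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) write.table(x, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  write_pair_table(res$pairs, file.path(dir, "pair_table.tsv"))
  if (!is.null(res$fit)) tsv(coefficient_table(res$fit), "coefficients.tsv")
  tsv(res$binned_sem, "binned_semantic.tsv")
  tsv(res$binned_syn, "binned_syntactic.tsv")
  tsv(res$word_orders, "word_orders.tsv")
  tsv(res$correlations, "correlations.tsv")
  tsv(res$exclusions, "exclusions.tsv")
  jsonlite::write_json(res$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
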