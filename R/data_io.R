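#' @useDynLib gazespeech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate as.formula coef cor median qnorm quantile rbinom
#'   rgamma rnorm runif sd setNames vcov complete.cases
#' @importFrom utils combn read.delim write.table head
NULL

# Trial identity is the (participant, scene) pair throughout.
make_trial_id <- function(participant_id, scene_id) {
  paste(participant_id, scene_id, sep = ":")
}

#' Column schema for a delimited fixation table
#'
#' Maps the column names found in an input file onto the fields the package
#' needs. Coordinates are pixels with origin at the top-left corner of the
#' image, y increasing downward (the usual eye-tracker report convention);
#' times are milliseconds from scene onset.
#'
#' @param participant,scene,x,y,t_start,t_end,image_width,image_height
#'   column names in the input file.
#' @return A named list of column names (class `gs_schema`).
#' @export
fixation_schema <- function(participant = "participant", scene = "scene",
                            x = "x", y = "y",
                            t_start = "t_start", t_end = "t_end",
                            image_width = "image_width",
                            image_height = "image_height") {
  structure(list(participant = participant, scene = scene, x = x, y = y,
                 t_start = t_start, t_end = t_end,
                 image_width = image_width, image_height = image_height),
            class = "gs_schema")
}

read_delim_checked <- function(file, required, what) {
  tab <- read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab
}

#' Read a fixation table
#'
#' Reads a tab-delimited fixation report (one row per fixation) and returns
#' per-trial fixation data grouped by participant and scene, sorted by onset
#' within trial. Each fixation must satisfy `t_end > t_start >= 0` and have
#' finite coordinates; violations are reported with the offending data line.
#'
#' @param file path to a tab-delimited file with a header row.
#' @param schema a [fixation_schema()] mapping file columns to fields.
#' @return A list with `trials` (data frame: trial_id, participant_id,
#'   scene_id, image_width, image_height) and `fixations` (data frame:
#'   trial_id, x, y, t_start, t_end, ordered by t_start within trial).
#' @export
read_fixation_table <- function(file, schema = fixation_schema()) {
  tab <- read_delim_checked(file, unlist(schema), "fixation table")
  fx <- data.frame(
    participant_id = as.character(tab[[schema$participant]]),
    scene_id = as.character(tab[[schema$scene]]),
    x = tab[[schema$x]], y = tab[[schema$y]],
    t_start = tab[[schema$t_start]], t_end = tab[[schema$t_end]],
    image_width = tab[[schema$image_width]],
    image_height = tab[[schema$image_height]],
    stringsAsFactors = FALSE)
  for (col in c("x", "y", "t_start", "t_end", "image_width", "image_height")) {
    v <- fx[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("fixation table: non-numeric value in column '%s' at line %d",
                   col, bad + 1L), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      stop(sprintf("fixation table: non-finite value in column '%s' at line %d",
                   col, bad + 1L), call. = FALSE)
    }
  }
  bad <- which(!(fx$t_end > fx$t_start & fx$t_start >= 0))
  if (length(bad) > 0) {
    stop(sprintf("fixation table: invalid fixation interval (need t_end > t_start >= 0) at line %d",
                 bad[1] + 1L), call. = FALSE)
  }
  fx$trial_id <- make_trial_id(fx$participant_id, fx$scene_id)
  fx <- fx[order(fx$trial_id, fx$t_start), , drop = FALSE]
  trials <- unique(fx[, c("trial_id", "participant_id", "scene_id",
                          "image_width", "image_height")])
  if (anyDuplicated(trials$trial_id)) {
    stop("fixation table: inconsistent image geometry within a trial",
         call. = FALSE)
  }
  rownames(trials) <- rownames(fx) <- NULL
  list(trials = trials,
       fixations = fx[, c("trial_id", "x", "y", "t_start", "t_end")])
}

#' Read a trial (utterance metadata) table
#'
#' One row per trial: participant, scene, language code, cue word, utterance
#' onset/offset (ms from scene onset) and the transcript. A duplicate
#' (participant, scene) pair is an error: the design has one description per
#' scene per participant.
#'
#' @param file path to a tab-delimited file with a header.
#' @return Data frame with a `trial_id` column prepended.
#' @export
read_trial_table <- function(file) {
  req <- c("participant", "scene", "language", "cue_word",
           "utt_onset", "utt_offset", "transcript")
  tab <- read_delim_checked(file, req, "trial table")
  out <- data.frame(
    trial_id = make_trial_id(as.character(tab$participant),
                             as.character(tab$scene)),
    participant_id = as.character(tab$participant),
    scene_id = as.character(tab$scene),
    language_code = as.character(tab$language),
    cue_word = as.character(tab$cue_word),
    utt_onset = as.numeric(tab$utt_onset),
    utt_offset = as.numeric(tab$utt_offset),
    transcript = as.character(tab$transcript),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$trial_id)) {
    dup <- out$trial_id[duplicated(out$trial_id)][1]
    stop(sprintf("trial table: duplicate (participant, scene) pair: %s", dup),
         call. = FALSE)
  }
  bad <- which(!(out$utt_offset > out$utt_onset & out$utt_onset > 0))
  if (length(bad) > 0) {
    stop(sprintf("trial table: need utt_offset > utt_onset > 0 at line %d",
                 bad[1] + 1L), call. = FALSE)
  }
  out
}

#' Read dependency parses in CoNLL-U format
#'
#' Parses CoNLL-U sentences into one tree per sentence. Multiword-token
#' ranges (`1-2`) and empty nodes (`1.1`) are ignored. A comment line of the
#' form `# trial_id = ...` (or, failing that, `# sent_id = ...`) names the
#' sentence. Each sentence must contain exactly one root (HEAD = 0) and an
#' acyclic head structure.
#'
#' Language-specific dependency subtypes are reduced to the universal label
#' (`obj:dobj` -> `obj`) after applying `aliases`, an exact-match renaming
#' applied to the full label first (by default mapping modern UD v2 labels
#' onto the older inventory: `obj` -> `dobj`, `nsubj:pass` -> `nsubjpass`,
#' `csubj:pass` -> `csubjpass`).
#'
#' @param file path to a CoNLL-U file.
#' @param aliases named character vector: `aliases[label]` replaces `label`.
#' @return Named list of trees; each tree is a data frame with columns
#'   `id`, `form`, `upos`, `head`, `deprel`.
#' @export
read_conllu <- function(file, aliases = default_label_aliases()) {
  lines <- readLines(file, warn = FALSE)
  trees <- list()
  cur <- list()
  cur_id <- NA_character_
  n_sent <- 0L
  flush <- function() {
    if (length(cur) == 0) return(invisible())
    n_sent <<- n_sent + 1L
    sid <- if (is.na(cur_id)) sprintf("sent%d", n_sent) else cur_id
    tree <- do.call(rbind, cur)
    tree <- validate_dep_tree(tree, sid)
    tree$deprel <- normalize_deprel(tree$deprel, aliases)
    trees[[sid]] <<- tree
    cur <<- list(); cur_id <<- NA_character_
  }
  for (ln in lines) {
    if (ln == "") { flush(); next }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*(trial_id|sent_id)\\s*=\\s*(.+)\\s*$", ln))[[1]]
      if (length(m) == 3 && (is.na(cur_id) || m[2] == "trial_id")) cur_id <- m[3]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) {
      stop(sprintf("conllu: malformed line (fewer than 8 fields): %s", ln),
           call. = FALSE)
    }
    if (grepl("[-.]", f[1])) next  # multiword token or empty node
    cur[[length(cur) + 1L]] <- data.frame(
      id = as.integer(f[1]), form = f[2], upos = f[4],
      head = as.integer(f[7]), deprel = f[8], stringsAsFactors = FALSE)
  }
  flush()
  trees
}

#' @rdname read_conllu
#' @export
default_label_aliases <- function() {
  c("obj" = "dobj", "nsubj:pass" = "nsubjpass", "csubj:pass" = "csubjpass")
}

normalize_deprel <- function(deprel, aliases) {
  hit <- deprel %in% names(aliases)
  deprel[hit] <- aliases[deprel[hit]]
  sub(":.*$", "", deprel)
}

validate_dep_tree <- function(tree, sid) {
  rownames(tree) <- NULL
  n <- nrow(tree)
  if (!identical(tree$id, seq_len(n))) {
    stop(sprintf("conllu: sentence '%s': token ids are not 1..n", sid),
         call. = FALSE)
  }
  if (any(tree$head < 0 | tree$head > n)) {
    stop(sprintf("conllu: sentence '%s': head index out of range", sid),
         call. = FALSE)
  }
  if (sum(tree$head == 0) != 1) {
    stop(sprintf("conllu: sentence '%s': expected exactly one root, found %d",
                 sid, sum(tree$head == 0)), call. = FALSE)
  }
  # walk each token to the root; revisiting a token means a cycle
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (j != 0) {
      if (seen[j]) {
        stop(sprintf("conllu: sentence '%s': cyclic head structure at token %d",
                     sid, i), call. = FALSE)
      }
      seen[j] <- TRUE
      j <- tree$head[j]
    }
  }
  tree
}

#' Write dependency trees to CoNLL-U
#'
#' Inverse of [read_conllu()]; each tree is preceded by a
#' `# trial_id = <name>` comment. Unused CoNLL-U columns are written as `_`.
#'
#' @param trees named list of tree data frames (`id`, `form`, `upos`,
#'   `head`, `deprel`).
#' @param file output path.
#' @export
write_conllu <- function(trees, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (sid in names(trees)) {
    tree <- trees[[sid]]
    writeLines(sprintf("# trial_id = %s", sid), con)
    writeLines(sprintf("%d\t%s\t_\t%s\t_\t_\t%d\t%s\t_\t_",
                       tree$id, tree$form, tree$upos, tree$head, tree$deprel),
               con)
    writeLines("", con)
  }
  invisible(length(trees))
}

#' Read sentence-embedding vectors
#'
#' Tab-delimited table: a `trial_id` column followed by `d` numeric columns.
#' Every row must have the same dimension.
#'
#' @param file path to the table.
#' @return Numeric matrix, one row per trial, rownames = trial ids.
#' @export
read_embeddings <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 1) stop("embeddings: empty file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("embeddings: dimension error: line %d has %d fields, expected %d",
                 bad, widths[bad], widths[1]), call. = FALSE)
  }
  header <- fields[[1]]
  if (header[1] != "trial_id") {
    stop("embeddings: first column must be 'trial_id'", call. = FALSE)
  }
  body <- fields[-1]
  ids <- vapply(body, `[[`, "", 1)
  vals <- vapply(body, function(f) as.numeric(f[-1]), numeric(length(header) - 1))
  mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(header) - 1)
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("embeddings: non-finite value", call. = FALSE)
  }
  rownames(mat) <- ids
  colnames(mat) <- header[-1]
  mat
}

#' @rdname read_embeddings
#' @param mat numeric matrix with trial ids as rownames.
#' @param file output path.
#' @export
write_embeddings <- function(mat, file) {
  d <- ncol(mat)
  header <- paste(c("trial_id", sprintf("e%d", seq_len(d))), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 17)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), file)
  invisible(nrow(mat))
}

pair_table_columns <- function() {
  c("trial_id_1", "trial_id_2", "phase", "scan_sim", "sem_sim", "syn_sim",
    "same_scene", "same_language", "participant_pair", "item_pair",
    "cue_pair")
}

#' Write / read the long pair table
#'
#' The assembled pairwise-comparison table (one row per unordered trial pair
#' per production phase) in tab-delimited long format.
#'
#' @param records data frame of pair records (see [build_pair_table()]).
#' @param file path.
#' @return `write_pair_table` returns the number of data rows written.
#' @export
write_pair_table <- function(records, file) {
  cols <- pair_table_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("pair table: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  write.table(records[, cols], file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(nrow(records))
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(file) {
  read_delim_checked(file, pair_table_columns(), "pair table")
}

#' Read / write a scene region map
#'
#' Labeled rectangles per scene for object-based (region of interest) scan
#' pattern encoding: `scene_id, label, x0, y0, x1, y1, priority`, pixel
#' coordinates, lower `priority` value wins where regions overlap.
#'
#' @param file path to a tab-delimited region table.
#' @return Data frame of regions.
#' @export
read_region_map <- function(file) {
  read_delim_checked(file, c("scene_id", "label", "x0", "y0", "x1", "y1",
                             "priority"), "region map")
}

#' @rdname read_region_map
#' @param regions data frame of regions.
#' @export
write_region_map <- function(regions, file) {
  write.table(regions, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(regions))
}

#' Read a study configuration (YAML or JSON)
#'
#' A study config names the input files (`fixations`, `trials`, `conllu`,
#' `embeddings`, optionally `regions`) and analysis parameters. Paths are
#' resolved relative to the config file's directory.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  for (key in c("fixations", "trials", "conllu", "embeddings", "regions")) {
    if (!is.null(cfg[[key]])) {
      p <- cfg[[key]]
      if (!file.exists(p)) p <- file.path(base, cfg[[key]])
      if (!file.exists(p)) {
        stop(sprintf("study config: input '%s' not found: %s", key, cfg[[key]]),
             call. = FALSE)
      }
      cfg[[key]] <- p
    }
  }
  cfg
}

#' Load a complete study from its files
#'
#' @param cfg a config list from [read_study_config()], or a directory
#'   written by [write_study()].
#' @return A study bundle: list with `trials`, `fixations`, `trees`,
#'   `embeddings`, and optionally `regions`.
#' @export
read_study <- function(cfg) {
  if (is.character(cfg)) {
    dir <- cfg
    cfg <- list(fixations = file.path(dir, "fixations.tsv"),
                trials = file.path(dir, "trials.tsv"),
                conllu = file.path(dir, "parses.conllu"),
                embeddings = file.path(dir, "embeddings.tsv"))
    reg <- file.path(dir, "regions.tsv")
    if (file.exists(reg)) cfg$regions <- reg
  }
  fx <- read_fixation_table(cfg$fixations)
  meta <- read_trial_table(cfg$trials)
  trials <- merge(meta, fx$trials[, c("trial_id", "image_width", "image_height")],
                  by = "trial_id", all.x = TRUE, sort = FALSE)
  trials <- trials[order(trials$trial_id), , drop = FALSE]
  rownames(trials) <- NULL
  study <- list(trials = trials,
                fixations = fx$fixations,
                trees = read_conllu(cfg$conllu),
                embeddings = read_embeddings(cfg$embeddings))
  if (!is.null(cfg$regions)) study$regions <- read_region_map(cfg$regions)
  class(study) <- "gs_study"
  study
}

#' Write a study bundle to a directory
#'
#' Emits every input format the pipeline consumes: `fixations.tsv`,
#' `trials.tsv`, `parses.conllu`, `embeddings.tsv`, `regions.tsv` (if
#' present) and a `manifest.json` recording the generator configuration.
#'
#' @param study a study bundle (see [read_study()], [generate_study()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- study$trials
  fx <- merge(study$fixations,
              tr[, c("trial_id", "participant_id", "scene_id",
                     "image_width", "image_height")],
              by = "trial_id", sort = FALSE)
  fx <- fx[order(fx$trial_id, fx$t_start), , drop = FALSE]
  out_fx <- data.frame(participant = fx$participant_id, scene = fx$scene_id,
                       x = fx$x, y = fx$y,
                       t_start = fx$t_start, t_end = fx$t_end,
                       image_width = fx$image_width,
                       image_height = fx$image_height)
  write.table(out_fx, file.path(dir, "fixations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out_tr <- data.frame(participant = tr$participant_id, scene = tr$scene_id,
                       language = tr$language_code, cue_word = tr$cue_word,
                       utt_onset = tr$utt_onset, utt_offset = tr$utt_offset,
                       transcript = tr$transcript)
  write.table(out_tr, file.path(dir, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_conllu(study$trees, file.path(dir, "parses.conllu"))
  write_embeddings(study$embeddings, file.path(dir, "embeddings.tsv"))
  if (!is.null(study$regions)) {
    write_region_map(study$regions, file.path(dir, "regions.tsv"))
  }
  if (!is.null(study$config)) {
    jsonlite::write_json(study$config, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
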