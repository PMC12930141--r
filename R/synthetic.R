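#' Configuration for a synthetic scene-description study
#'
#' The generator emulates a multi-language production study: participants
#' view scenes composed of objects and describe a cued object while their
#' gaze is tracked. A latent per-trial *message* (weights over the scene's
#' objects plus a relation type) jointly drives the scan sequence, the
#' sentence embedding and, through a per-language word-order template, the
#' dependency parse — so the statistical structure the analysis assumes is
#' planted with controllable strength and can be recovered.
#'
#' Object types live in a global inventory shared by all scenes and
#' languages: each type has one grid anchor cell and one latent semantic
#' vector, used identically in every language. Languages differ only in
#' their linearization templates (`SVO`, `SOV`, or a verb-initial/SVO mix)
#' — the generator's "language of vision" assumption.
#'
#' @param n_languages number of languages (templates recycle over
#'   SVO, Vmix, SOV).
#' @param n_participants participants per language.
#' @param n_scenes number of scenes (shared across languages).
#' @param objects_per_scene objects placed in each scene.
#' @param n_object_types size of the global object inventory (each type is
#'   anchored to a distinct grid cell; must fit in the grid).
#' @param embedding_dim sentence-embedding dimension.
#' @param g_sem semantic coupling in \[0, 1\]: probability that a fixation
#'   targets a message-weighted object anchor rather than a random cell.
#' @param g_syn_before early-phase syntactic coupling in \[0, 1\]:
#'   probability that a trial's planning phase opens with an ordered sweep
#'   of the argument anchors in the language template's constituent order.
#' @param noise_sd embedding noise standard deviation.
#' @param before_mean_s mean planning-phase duration, seconds.
#' @param during_mean_s per-language mean articulation duration, seconds
#'   (defaults 3.4, 8.1, 5.1, echoing typical English/Portuguese/Japanese
#'   utterance lengths).
#' @param image_width,image_height display size in pixels.
#' @param n_cols,n_rows scan-pattern grid.
#' @param bin_ms scan-pattern bin width, ms.
#' @param p_fragment probability of a degenerate two-word utterance (below
#'   the sentence-length exclusion threshold).
#' @param p_fixloss probability that the planning phase has a single
#'   fixation (below the fixation-count exclusion threshold).
#' @param p_embed probability of an embedded (subordinate) clause.
#' @param p_scramble probability that a transitive utterance realizes the
#'   patient argument first (passive voice in verb-medial templates,
#'   object scrambling in the verb-final template, object-only clause in
#'   verb-initial ones); part of the syntactic channel, independent of the
#'   message.
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the config.
#' @return A `gs_synth_config` list.
#' @export
synth_config <- function(n_languages = 3, n_participants = 8, n_scenes = 12,
                         objects_per_scene = 4, n_object_types = 8,
                         embedding_dim = 32, g_sem = 0.8,
                         g_syn_before = 0.5, noise_sd = 0.2,
                         before_mean_s = 3.0,
                         during_mean_s = c(3.4, 8.1, 5.1),
                         image_width = 1024, image_height = 768,
                         n_cols = 6, n_rows = 4, bin_ms = 25,
                         p_fragment = 0.02, p_fixloss = 0.02,
                         p_embed = 0.2, p_scramble = 0.4, seed = 1) {
  stopifnot(n_languages >= 1, n_participants >= 1, n_scenes >= 1,
            objects_per_scene >= 2, g_sem >= 0, g_sem <= 1,
            g_syn_before >= 0, g_syn_before <= 1)
  n_cells <- n_cols * n_rows
  if (objects_per_scene > n_cells || n_object_types > n_cells) {
    stop(sprintf(
      "synth_config: infeasible geometry: %d objects cannot anchor to %d grid cells",
      max(objects_per_scene, n_object_types), n_cells), call. = FALSE)
  }
  if (n_object_types < objects_per_scene) {
    stop("synth_config: object inventory smaller than objects per scene",
         call. = FALSE)
  }
  # the inventory splits into animate (agent/cue) and inanimate (patient)
  # halves; each scene needs both
  n_anim <- ceiling(n_object_types / 2)
  k_anim <- ceiling(objects_per_scene / 2)
  if (n_anim < k_anim || (n_object_types - n_anim) < (objects_per_scene - k_anim)) {
    stop("synth_config: inventory halves too small for the scene composition",
         call. = FALSE)
  }
  codes <- c("eng", "por", "jpn")
  templates <- c("SVO", "Vmix", "SOV")
  idx <- ((seq_len(n_languages) - 1) %% 3) + 1
  langs <- data.frame(
    code = if (n_languages <= 3) codes[idx] else sprintf("l%02d", seq_len(n_languages)),
    template = templates[idx],
    during_mean_s = rep_len(during_mean_s, n_languages),
    stringsAsFactors = FALSE)
  structure(list(languages = langs, n_participants = n_participants,
                 n_scenes = n_scenes, objects_per_scene = objects_per_scene,
                 n_object_types = n_object_types,
                 embedding_dim = embedding_dim,
                 g_sem = g_sem, g_syn_before = g_syn_before,
                 noise_sd = noise_sd, before_mean_s = before_mean_s,
                 image_width = image_width, image_height = image_height,
                 n_cols = n_cols, n_rows = n_rows, bin_ms = bin_ms,
                 p_fragment = p_fragment, p_fixloss = p_fixloss,
                 p_embed = p_embed, p_scramble = p_scramble, seed = seed),
            class = "gs_synth_config")
}

# deterministic pseudo-word for inventory item i
pseudo_word <- function(i, tag = "") {
  syl <- c("ba", "do", "ki", "mu", "ra", "te", "no", "pi", "su", "la",
           "ve", "go")
  paste0(tag, syl[(i - 1) %% 12 + 1], syl[(i * 5) %% 12 + 1],
         syl[(i * 7) %% 12 + 1])
}

# token helper for template trees: head_key refers to another token's key
tk <- function(key, form, upos, deprel, head_key) {
  list(key = key, form = form, upos = upos, deprel = deprel,
       head_key = head_key)
}

tokens_to_tree <- function(tokens) {
  keys <- vapply(tokens, `[[`, "", "key")
  data.frame(
    id = seq_along(tokens),
    form = vapply(tokens, `[[`, "", "form"),
    upos = vapply(tokens, `[[`, "", "upos"),
    head = vapply(tokens, function(t)
      if (is.null(t$head_key)) 0L else match(t$head_key, keys), 0L),
    deprel = vapply(tokens, `[[`, "", "deprel"),
    stringsAsFactors = FALSE)
}

# Instantiate a dependency tree from a word-order template.
# variant: "SVO", "SOV", or "V1" (verb-initial); SOV output is head-final
# (the root token is always last). arg_first encodes the trial's argument
# order: "patient"-first realizations are the passive (SVO: nsubjpass),
# object-only verb-initial clause (V1: ROOT dobj) or scrambled object
# (SOV: dobj nsubj ROOT).
make_template_tree <- function(variant, transitive, complexity, embed,
                               words, arg_first = "agent") {
  w <- words
  toks <- list()
  add <- function(...) toks[[length(toks) + 1L]] <<- tk(...)
  emb_toks <- function() {
    add("s2", w$subj2, "NOUN", "nsubj", "verb2")
    add("verb2", w$verb2, "VERB", "advcl", "verb")
  }
  if (!transitive) arg_first <- "agent"
  np <- function(key, noun, deprel, with_adj = FALSE) {
    add(paste0("d_", key), w$det, "DET", "det", key)
    if (with_adj) add(paste0("a_", key), w$adj, "ADJ", "amod", key)
    add(key, noun, "NOUN", deprel, "verb")
  }
  obj_np <- function() {
    if (transitive) np("patient", w$patient, "dobj", complexity >= 2)
    else np("loc", w$loc, "obl", complexity >= 2)
  }
  if (variant == "SOV") {
    if (embed) emb_toks()
    if (arg_first == "patient") {
      np("patient", w$patient, "dobj", complexity >= 2)
      np("agent", w$agent, "nsubj")
    } else {
      np("agent", w$agent, "nsubj")
      obj_np()
    }
    add("verb", w$verb, "VERB", "ROOT", NULL)
  } else if (variant == "V1") {
    add("verb", w$verb, "VERB", "ROOT", NULL)
    if (arg_first == "patient") {
      np("patient", w$patient, "dobj", complexity >= 2)
      np("loc", w$loc, "obl")
    } else {
      np("agent", w$agent, "nsubj")
      obj_np()
    }
    if (embed) emb_toks()
  } else {  # SVO
    if (arg_first == "patient") {
      np("patient", w$patient, "nsubjpass", complexity >= 2)
      add("verb", w$verb, "VERB", "ROOT", NULL)
      np("agent", w$agent, "obl")
    } else {
      np("agent", w$agent, "nsubj")
      add("verb", w$verb, "VERB", "ROOT", NULL)
      obj_np()
    }
    if (embed) emb_toks()
  }
  tokens_to_tree(toks)
}

make_fragment_tree <- function(words) {
  tokens_to_tree(list(tk("d1", words$det, "DET", "det", "n"),
                      tk("n", words$agent, "NOUN", "ROOT", NULL)))
}

cell_centers <- function(cfg) {
  col <- (seq_len(cfg$n_cols * cfg$n_rows) - 1) %% cfg$n_cols
  row <- (seq_len(cfg$n_cols * cfg$n_rows) - 1) %/% cfg$n_cols
  cbind(x = (col + 0.5) * cfg$image_width / cfg$n_cols,
        y = (row + 0.5) * cfg$image_height / cfg$n_rows)
}

point_to_cell <- function(x, y, cfg) {
  col <- pmin(floor(x / (cfg$image_width / cfg$n_cols)), cfg$n_cols - 1)
  row <- pmin(floor(y / (cfg$image_height / cfg$n_rows)), cfg$n_rows - 1)
  row * cfg$n_cols + col + 1
}

#' Generate a complete synthetic study
#'
#' Produces trials, fixations, sentence embeddings, dependency parses and a
#' scene region map, all driven by a per-trial latent message. See
#' [synth_config()] for the generative model. The same (scene, participant
#' index) slot carries the same message in every language, so cross-language
#' semantic alignment is planted by construction; syntactic structure is an
#' independent channel (random transitivity, complexity and embedding-clause
#' draws) linearized by the language template.
#'
#' @param cfg a [synth_config()].
#' @return A study bundle (as [read_study()] returns) with additional
#'   `regions`, `config` and `latent` elements.
#' @export
generate_study <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  n_cells <- cfg$n_cols * cfg$n_rows
  centers <- cell_centers(cfg)
  cw <- cfg$image_width / cfg$n_cols
  ch <- cfg$image_height / cfg$n_rows

  # global inventory: anchor cell + latent semantic vector per object type
  anchors <- sample.int(n_cells, cfg$n_object_types)
  type_vec <- matrix(rnorm(cfg$n_object_types * cfg$embedding_dim),
                     cfg$n_object_types)
  type_vec <- type_vec / sqrt(rowSums(type_vec^2))
  rel_vec <- matrix(rnorm(3 * cfg$embedding_dim), 3)
  rel_vec <- rel_vec / sqrt(rowSums(rel_vec^2))
  type_names <- vapply(seq_len(cfg$n_object_types), pseudo_word, "")

  # the inventory splits into animate types (agents/cues: 1..n_anim) and
  # inanimate types (patients); each scene combines both, and scenes are
  # distinct compositions whenever the inventory allows it
  n_anim <- ceiling(cfg$n_object_types / 2)
  k_anim <- ceiling(cfg$objects_per_scene / 2)
  k_inan <- cfg$objects_per_scene - k_anim
  anim_sub <- combn(seq_len(n_anim), k_anim)
  inan_sub <- combn(seq(n_anim + 1, cfg$n_object_types), k_inan)
  combos <- expand.grid(a = seq_len(ncol(anim_sub)),
                        i = seq_len(ncol(inan_sub)))
  pick <- if (nrow(combos) >= cfg$n_scenes) {
    sample.int(nrow(combos), cfg$n_scenes)
  } else {
    sample.int(nrow(combos), cfg$n_scenes, replace = TRUE)
  }
  scene_objects <- lapply(pick, function(ci)
    c(anim_sub[, combos$a[ci]], inan_sub[, combos$i[ci]]))
  scene_ids <- sprintf("sc%02d", seq_len(cfg$n_scenes))

  regions <- do.call(rbind, lapply(seq_len(cfg$n_scenes), function(s) {
    obj <- scene_objects[[s]]
    cc <- centers[anchors[obj], , drop = FALSE]
    data.frame(scene_id = scene_ids[s], label = type_names[obj],
               x0 = cc[, "x"] - cw / 2, y0 = cc[, "y"] - ch / 2,
               x1 = cc[, "x"] + cw / 2, y1 = cc[, "y"] + ch / 2,
               priority = seq_along(obj), stringsAsFactors = FALSE)
  }))

  langs <- cfg$languages
  trials <- list(); fixrows <- list(); trees <- list(); latent <- list()
  n_trials <- nrow(langs) * cfg$n_participants * cfg$n_scenes
  emb <- matrix(NA_real_, n_trials, cfg$embedding_dim)
  emb_ids <- character(nrow(emb))
  row_i <- 0L

  for (li in seq_len(nrow(langs))) {
    lang <- langs$code[li]
    template <- langs$template[li]
    for (pi in seq_len(cfg$n_participants)) {
      participant <- sprintf("%s_p%02d", lang, pi)
      for (si in seq_len(cfg$n_scenes)) {
        scene <- scene_ids[si]
        trial_id <- make_trial_id(participant, scene)
        obj <- scene_objects[[si]]
        k <- length(obj)

        # --- message: shared across languages for a (scene, participant
        # index) slot; stochastic jitter is trial-specific. The cued
        # agent is an animate object, the patient an inanimate one; the
        # focal pair walks through all animate x inanimate combinations
        # so messages vary within a scene.
        midx <- (pi - 1 + 5 * (si - 1)) %% (k_anim * k_inan)
        cue_idx <- 1 + midx %% k_anim
        pat_idx <- k_anim + 1 + (midx %/% k_anim) %% k_inan
        relation <- 1 + (pi + si) %% 3
        w <- rep(0.2 / max(1, k - 2), k)
        w[cue_idx] <- 0.5
        w[pat_idx] <- 0.3
        w <- w * exp(rnorm(k, 0, 0.6))
        w <- w / sum(w)
        e <- drop(w %*% type_vec[obj, , drop = FALSE]) +
          0.15 * rel_vec[relation, ] +
          rnorm(cfg$embedding_dim, 0, cfg$noise_sd)

        # --- syntactic channel: independent of the message
        transitive <- runif(1) < 0.75
        complexity <- sample(1:2, 1)
        embedded <- runif(1) < cfg$p_embed
        fragment <- runif(1) < cfg$p_fragment
        variant <- if (template == "Vmix") {
          if (runif(1) < 0.5) "V1" else "SVO"
        } else template
        # argument order: patient-first realizations (passive, scrambling)
        arg_first <- if (transitive && runif(1) < cfg$p_scramble) "patient"
          else "agent"

        words <- list(det = pseudo_word(li, "d"),
                      agent = type_names[obj[cue_idx]],
                      patient = type_names[obj[pat_idx]],
                      adj = pseudo_word(complexity + li, "a"),
                      verb = pseudo_word(relation + 3 * li, "v"),
                      verb2 = pseudo_word(relation + 3 * li + 1, "v"),
                      subj2 = type_names[obj[1 + (pat_idx %% k)]],
                      loc = pseudo_word(si, "n"))
        tree <- if (fragment) make_fragment_tree(words) else
          make_template_tree(variant, transitive, complexity, embedded,
                             words, arg_first)
        sep <- if (template == "SOV") "" else " "  # head-final language written without spaces
        transcript <- paste(tree$form, collapse = sep)

        # --- timing: grammatical encoding time grows with structural
        # complexity (gated by g_syn_before), so structurally similar
        # utterances have similar planning-phase lengths; articulation
        # time is language- and speaker-driven, not structure-driven
        plan_s <- rnorm(1, cfg$before_mean_s, 0.8) +
          cfg$g_syn_before * 0.35 * (nrow(tree) - 6)
        utt_onset <- round(1000 * max(1.5, plan_s))
        dur_s <- max(1.5, rnorm(1, langs$during_mean_s[li],
                                0.25 * langs$during_mean_s[li]))
        utt_offset <- utt_onset + round(1000 * dur_s)

        # --- fixation stream
        t <- round(runif(1, 0, 60))
        f_start <- numeric(0); f_end <- numeric(0)
        while (t < utt_offset - 60) {
          d <- 60 + rgamma(1, shape = 4, scale = 30)
          f_start <- c(f_start, t)
          f_end <- c(f_end, min(t + d, utt_offset))
          t <- t + d + 25
        }
        nf <- length(f_start)

        # targets: each fixation is message-driven with probability g_sem
        # (an object anchor sampled by message weight), else uniform noise.
        # The syntactic channel only REORDERS planning-phase object visits
        # (below), so at g_sem = 0 syntax leaves no trace in the gaze.
        agent_cell <- anchors[obj[cue_idx]]
        patient_cell <- anchors[obj[pat_idx]]
        prefix_on <- runif(1) < cfg$g_syn_before
        cells <- integer(nf)
        is_obj <- logical(nf)
        for (fi in seq_len(nf)) {
          if (runif(1) < cfg$g_sem) {
            cells[fi] <- anchors[obj[sample.int(k, 1, prob = w)]]
            is_obj[fi] <- TRUE
          } else {
            cells[fi] <- sample.int(n_cells, 1)
          }
        }
        # planning linearization: object visits open the planning phase
        # in the utterance's argument order — agent-first realizations
        # inspect the animate referents before the inanimate ones,
        # patient-first realizations the reverse — mirroring the tree;
        # stray noise fixations are pushed after them
        if (prefix_on) {
          bidx <- which(f_start < utt_onset)
          bi <- bidx[is_obj[bidx]]
          if (length(bi) > 1) {
            is_anim_cell <- cells[bi] %in% anchors[seq_len(n_anim)]
            role_rank <- if (arg_first == "patient") {
              ifelse(is_anim_cell, 2, 1)
            } else {
              ifelse(is_anim_cell, 1, 2)
            }
            cells[bidx] <- c(cells[bi][order(role_rank)],
                             cells[setdiff(bidx, bi)])
          }
        }
        fx <- data.frame(
          trial_id = trial_id,
          x = centers[cells, "x"] + runif(nf, -0.35, 0.35) * cw,
          y = centers[cells, "y"] + runif(nf, -0.35, 0.35) * ch,
          t_start = f_start, t_end = f_end, stringsAsFactors = FALSE)
        if (runif(1) < cfg$p_fixloss) {
          # track loss: planning phase collapses to one long fixation
          before_idx <- which(fx$t_start < utt_onset)
          if (length(before_idx) >= 2) {
            first <- fx[before_idx[1], ]
            first$t_end <- max(fx$t_end[before_idx])
            fx <- rbind(first, fx[-before_idx, , drop = FALSE])
          }
        }

        row_i <- row_i + 1L
        emb[row_i, ] <- e
        emb_ids[row_i] <- trial_id
        trees[[trial_id]] <- tree
        fixrows[[trial_id]] <- fx
        trials[[trial_id]] <- data.frame(
          trial_id = trial_id, participant_id = participant,
          scene_id = scene, language_code = lang,
          cue_word = type_names[obj[cue_idx]],
          utt_onset = utt_onset, utt_offset = utt_offset,
          transcript = transcript,
          image_width = cfg$image_width, image_height = cfg$image_height,
          stringsAsFactors = FALSE)
        latent[[trial_id]] <- data.frame(
          trial_id = trial_id, message = sprintf("s%02d_m%02d", si, pi),
          relation = relation, transitive = transitive,
          complexity = complexity, variant = variant,
          arg_first = arg_first, prefix_on = prefix_on, fragment = fragment,
          stringsAsFactors = FALSE)
      }
    }
  }
  rownames(emb) <- emb_ids
  study <- list(trials = do.call(rbind, trials),
                fixations = do.call(rbind, fixrows),
                trees = trees,
                embeddings = emb,
                regions = regions,
                latent = do.call(rbind, latent),
                config = unclass(cfg))
  rownames(study$trials) <- rownames(study$fixations) <-
    rownames(study$latent) <- NULL
  class(study) <- "gs_study"
  study
}

#' Worked micro-fixtures
#'
#' The printable examples used throughout the documentation and tests: the
#' sequence pair whose longest common subsequence is "BCAB", a transitive
#' verb-medial parse whose core-dependency sequence is
#' `nsubj ROOT dobj`, and its verb-final counterpart giving
#' `nsubj dobj ROOT`.
#'
#' @return List with `seq_a`, `seq_b`, `svo_tree`, `sov_tree`.
#' @export
generate_worked_fixture <- function() {
  svo <- tokens_to_tree(list(
    tk("s", "peter", "NOUN", "nsubj", "v"),
    tk("v", "likes", "VERB", "ROOT", NULL),
    tk("o", "dogs", "NOUN", "dobj", "v")))
  sov <- tokens_to_tree(list(
    tk("s", "peter", "NOUN", "nsubj", "v"),
    tk("o", "dogs", "NOUN", "dobj", "v"),
    tk("v", "likes", "VERB", "ROOT", NULL)))
  list(seq_a = strsplit("ABCBDAB", "")[[1]],
       seq_b = strsplit("BDCABC", "")[[1]],
       svo_tree = svo, sov_tree = sov)
}
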