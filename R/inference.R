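#' Fit the scan-pattern association model
#'
#' Linear mixed-effects model predicting scan-pattern similarity from the
#' semantic and syntactic similarity of the paired sentences, whether the
#' pair comes from the same scene (reference: between scenes), the same
#' language (reference: different languages) and which production phase it
#' belongs to (reference: before speaking), with all interactions up to the
#' five-way term, and random intercepts for participant pair, item pair and
#' cue-word pair. The model is fitted by maximum likelihood; confidence
#' intervals are asymptotic Wald intervals.
#'
#' Standardized coefficients come from refitting the same model with the
#' response and the continuous predictors z-scored and the two-level
#' factors coded -0.5 / +0.5.
#'
#' @param pairs a pair table (see [build_pair_table()]).
#' @param standardize also compute standardized coefficients (doubles the
#'   fitting cost).
#' @return A `gs_fit` object: `coefficients` (term, beta, std_beta, se,
#'   ci_lo, ci_hi, t), `varcomp`, `converged`, `boundary` (any random
#'   effect variance estimated at zero), `dropped` (terms removed for
#'   degenerate designs), and `model` (the underlying fit).
#' @export
fit_association_model <- function(pairs, standardize = TRUE) {
  dat <- data.frame(
    scan_sim = pairs$scan_sim,
    sem = pairs$sem_sim,
    syn = pairs$syn_sim,
    scene = factor(ifelse(pairs$same_scene, "within", "between"),
                   levels = c("between", "within")),
    language = factor(ifelse(pairs$same_language, "same", "different"),
                      levels = c("different", "same")),
    phase = factor(pairs$phase, levels = c("before", "during")),
    participant_pair = pairs$participant_pair,
    item_pair = pairs$item_pair,
    cue_pair = pairs$cue_pair,
    stringsAsFactors = FALSE)
  fixed <- c("sem", "syn", "language", "scene", "phase")
  dropped <- character(0)
  for (f in c("scene", "language", "phase")) {
    if (length(unique(dat[[f]])) < 2) {
      fixed <- setdiff(fixed, f)
      dropped <- c(dropped, f)
    }
  }
  for (f in c("sem", "syn")) {
    if (sd(dat[[f]]) == 0) {
      fixed <- setdiff(fixed, f)
      dropped <- c(dropped, f)
    }
  }
  if (length(fixed) == 0) {
    stop("fit_association_model: no usable fixed effects", call. = FALSE)
  }
  if (sd(dat$scan_sim) == 0) {
    # degenerate design: constant response fits exactly, slopes all zero
    coefs <- data.frame(term = "(Intercept)", beta = dat$scan_sim[1],
                        se = 0, ci_lo = dat$scan_sim[1],
                        ci_hi = dat$scan_sim[1], t = NA_real_,
                        std_beta = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(coefficients = coefs,
                          varcomp = NULL, converged = TRUE, boundary = TRUE,
                          dropped = dropped, constant_response = TRUE,
                          formula = NULL, model = NULL), class = "gs_fit"))
  }
  form <- as.formula(paste(
    "scan_sim ~", paste(fixed, collapse = " * "),
    "+ (1 | participant_pair) + (1 | item_pair) + (1 | cue_pair)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(form, data = dat, REML = FALSE, control = ctrl)
  coefs <- wald_table(fit)
  std_beta <- rep(NA_real_, nrow(coefs))
  if (standardize) {
    zdat <- dat
    zdat$scan_sim <- as.numeric(scale(dat$scan_sim))
    for (f in intersect(c("sem", "syn"), fixed)) {
      zdat[[f]] <- as.numeric(scale(dat[[f]]))
    }
    contr <- list()
    for (f in intersect(c("scene", "language", "phase"), fixed)) {
      contr[[f]] <- matrix(c(-0.5, 0.5), 2,
                           dimnames = list(levels(dat[[f]]), ""))
    }
    sfit <- lme4::lmer(form, data = zdat, REML = FALSE, control = ctrl,
                       contrasts = contr)
    sb <- lme4::fixef(sfit)
    # align on term order; factor contrast renaming keeps positions stable
    std_beta <- as.numeric(sb)[seq_len(nrow(coefs))]
  }
  coefs$std_beta <- std_beta
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(coefficients = coefs,
                 varcomp = vc[, c("grp", "sdcor")],
                 converged = conv,
                 boundary = any(vc$sdcor[vc$grp != "Residual"] < 1e-8),
                 dropped = dropped,
                 formula = form,
                 pair_ids = pairs[, c("trial_id_1", "trial_id_2")],
                 model = fit),
            class = "gs_fit")
}

wald_table <- function(fit) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- qnorm(0.975)
  data.frame(term = names(beta), beta = as.numeric(beta), se = se,
             ci_lo = beta - z * se, ci_hi = beta + z * se,
             t = as.numeric(beta) / se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("Scan-pattern association model (ML, random intercepts)\n")
  cat(deparse(x$formula), sep = "\n")
  cat(sprintf("converged: %s%s\n", x$converged,
              if (x$boundary) " (variance at boundary)" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Marginal effect of a similarity predictor
#'
#' The average marginal slope of `sem` or `syn` on scan similarity: the
#' change in the model's prediction for a unit increase of the predictor,
#' averaged over the observed covariate distribution (so every interaction
#' involving the predictor contributes at the observed values of its
#' partners). Under a treatment-coded full-interaction structure the
#' reference-level main effect alone is a poor summary — it is the slope in
#' one corner of the design and is heavily collinear with its interactions
#' — whereas the average marginal slope is well identified. The model is
#' linear, so a unit finite difference on the fixed-effects design is
#' exact.
#'
#' By default the standard error is *dyadic-robust*: every trial enters
#' hundreds of pairwise records, and the model-based (Wald) covariance,
#' which conditions on the random-intercept structure, understates the
#' resulting dependence. The robust variance clusters the contrast's
#' influence contributions on the two trials of each pair (pairs sharing a
#' trial are allowed to covary freely), which calibrates the intervals on
#' null and shuffled data. Set `robust = FALSE` for the model-based
#' covariance.
#'
#' @param fit a `gs_fit`.
#' @param term `"sem"` or `"syn"`.
#' @param by_phase also report the effect within each production phase
#'   (averaging over that phase's rows only).
#' @param robust dyadic-robust standard errors (default) or model-based.
#' @return Data frame: phase (`"overall"`, `"before"`, `"during"`),
#'   estimate, se, ci_lo, ci_hi.
#' @export
marginal_effect <- function(fit, term = c("sem", "syn"), by_phase = TRUE,
                            robust = TRUE) {
  term <- match.arg(term)
  m <- fit$model
  beta <- lme4::fixef(m)
  V <- as.matrix(vcov(m))
  fr <- m@frame
  tt <- stats::delete.response(stats::terms(m, fixed.only = TRUE))
  d2 <- fr
  d2[[term]] <- d2[[term]] + 1
  dX <- stats::model.matrix(tt, d2) - stats::model.matrix(tt, fr)
  robust <- robust && !is.null(fit$pair_ids)
  if (robust) {
    X <- lme4::getME(m, "X")
    resid_marg <- m@resp$y - as.numeric(X %*% beta)
    A <- solve(crossprod(X))
    node_ids <- c(fit$pair_ids$trial_id_1, fit$pair_ids$trial_id_2)
  }
  groups <- list(overall = rep(TRUE, nrow(fr)))
  if (by_phase && "phase" %in% names(fr)) {
    for (ph in levels(fr$phase)) groups[[ph]] <- fr$phase == ph
  }
  rows <- lapply(names(groups), function(g) {
    w <- colMeans(dX[groups[[g]], , drop = FALSE])
    est <- sum(w * beta)
    if (robust) {
      # influence of each record on the contrast, clustered by trial:
      # records sharing a trial may covary arbitrarily
      q <- as.numeric(X %*% (A %*% w)) * resid_marg
      S <- rowsum(c(q, q), node_ids)
      v <- sum(S^2) - sum(q^2)
      se <- sqrt(max(v, sum(q^2)))
    } else {
      se <- sqrt(drop(t(w) %*% V %*% w))
    }
    data.frame(phase = g, estimate = est, se = se,
               ci_lo = est - qnorm(0.975) * se,
               ci_hi = est + qnorm(0.975) * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname marginal_effect
#' @export
phase_effect <- function(fit, term = c("sem", "syn")) {
  out <- marginal_effect(fit, term, by_phase = TRUE)
  out[out$phase %in% c("before", "during"), , drop = FALSE]
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[1] >= 0 && r[2] <= 1) return(x)
  if (r[2] == r[1]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Binned-mean summary of scan similarity
#'
#' Mean scan-pattern similarity over regularly spaced bins of semantic or
#' syntactic similarity (default width 0.1 on a 0-1 axis), stratified by
#' scene, language and phase condition. Predictors falling outside [0, 1]
#' (e.g. unbounded dot products) are min-max rescaled to [0, 1] per study
#' first; the applied range is recorded in the `rescaled_from` attribute.
#' Empty bins are omitted.
#'
#' @param pairs a pair table.
#' @param predictor `"sem_sim"` or `"syn_sim"`.
#' @param bin_width bin width on the rescaled axis.
#' @param values optional replacement for `pairs$scan_sim` (e.g. model
#'   predictions) summarised over the same bins.
#' @return Data frame: same_scene, same_language, phase, bin (midpoint),
#'   n, mean, se.
#' @export
binned_summary <- function(pairs, predictor = c("sem_sim", "syn_sim"),
                           bin_width = 0.1, values = NULL) {
  predictor <- match.arg(predictor)
  x <- pairs[[predictor]]
  r <- range(x)
  xs <- rescale01(x)
  if (is.null(values)) values <- pairs$scan_sim
  nb <- ceiling(1 / bin_width)
  bin <- pmin(floor(xs / bin_width), nb - 1)
  g <- data.frame(same_scene = pairs$same_scene,
                  same_language = pairs$same_language,
                  phase = pairs$phase,
                  bin = (bin + 0.5) * bin_width)
  agg_n <- aggregate(values, g, length)
  agg_m <- aggregate(values, g, mean)
  agg_s <- aggregate(values, g, sd)
  out <- agg_m
  names(out)[names(out) == "x"] <- "mean"
  out$n <- agg_n$x
  out$se <- agg_s$x / sqrt(agg_n$x)
  out <- out[order(out$same_scene, out$same_language, out$phase, out$bin), ]
  rownames(out) <- NULL
  attr(out, "rescaled_from") <- if (r[1] >= 0 && r[2] <= 1) NULL else r
  out
}

#' Correlation between semantic and syntactic similarity
#'
#' Pearson correlation of the two sentence-similarity measures over all
#' pairs, split by whether the pair is within or between languages. Phases
#' duplicate sentence similarities, so only before-phase records (or all
#' records if a single phase is present) enter each stratum once.
#'
#' @param pairs a pair table.
#' @return Data frame: stratum (`within_language` / `between_language`),
#'   rho, n; rho is NA (flagged) under zero variance.
#' @export
similarity_correlation <- function(pairs) {
  ph <- if ("before" %in% pairs$phase) "before" else pairs$phase[1]
  p <- pairs[pairs$phase == ph, ]
  one <- function(sub, label) {
    if (nrow(sub) < 3 || sd(sub$sem_sim) == 0 || sd(sub$syn_sim) == 0) {
      return(data.frame(stratum = label, rho = NA_real_, n = nrow(sub)))
    }
    data.frame(stratum = label, rho = cor(sub$sem_sim, sub$syn_sim),
               n = nrow(sub))
  }
  out <- rbind(one(p[p$same_language, ], "within_language"),
               one(p[!p$same_language, ], "between_language"))
  rownames(out) <- NULL
  out
}

#' Per-phase raw association between a predictor and scan similarity
#'
#' Pearson correlation of scan similarity with a sentence-similarity
#' predictor, computed separately per phase, optionally restricted to
#' within-language (and within-scene) pairs. Used to compare the strength
#' of the syntactic association across production phases.
#'
#' @param pairs a pair table.
#' @param predictor `"syn_sim"` or `"sem_sim"`.
#' @param within_language,within_scene restrict to matching pairs.
#' @return Named numeric vector with elements `before` and `during`.
#' @export
phase_association <- function(pairs, predictor = c("syn_sim", "sem_sim"),
                              within_language = TRUE, within_scene = FALSE) {
  predictor <- match.arg(predictor)
  p <- pairs
  if (within_language) p <- p[p$same_language, ]
  if (within_scene) p <- p[p$same_scene, ]
  vapply(c(before = "before", during = "during"), function(ph) {
    sub <- p[p$phase == ph, ]
    if (nrow(sub) < 3) return(NA_real_)
    cor(sub[[predictor]], sub$scan_sim)
  }, 0)
}

#' Agreement between model predictions and raw binned means
#'
#' Summarises the model's fitted values over the same predictor bins and
#' strata as the raw data and reports the Spearman rank correlation between
#' per-bin predicted and observed means.
#'
#' @param fit a `gs_fit`.
#' @param pairs the pair table the model was fitted to.
#' @param predictor binning predictor.
#' @return Spearman correlation (scalar).
#' @export
binned_model_agreement <- function(fit, pairs, predictor = "sem_sim") {
  pred <- stats::fitted(fit$model)
  obs <- binned_summary(pairs, predictor)
  mod <- binned_summary(pairs, predictor, values = pred)
  stopifnot(nrow(obs) == nrow(mod))
  cor(obs$mean, mod$mean, method = "spearman")
}

#' Coefficient table in reporting layout
#'
#' @param fit a `gs_fit`.
#' @return Data frame with term, beta, standardized beta, CI bounds and t.
#' @export
coefficient_table <- function(fit) {
  fit$coefficients[, c("term", "beta", "std_beta", "ci_lo", "ci_hi", "t")]
}
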