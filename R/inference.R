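# Mixed-model inference with simple-slope moderation and the
# cluster-based permutation test on epoch time courses.

#' Fit the trait-moderation linear mixed model
#'
#' Fits `response ~ z_aq4 * z_spin * emotion + sex + (1 | participant_id)`
#' by REML, with emotion (and sex) sum-to-zero coded so that Type III
#' tests and emotion-marginal simple slopes are meaningful. Degrees of
#' freedom use the Satterthwaite approximation by default (Kenward-Roger
#' optional).
#'
#' @param data trial-level data with columns `z_aq4`, `z_spin`, `emotion`,
#'   `sex`, `participant_id` and the response.
#' @param response name of the response column.
#' @param df_method `"Satterthwaite"` or `"Kenward-Roger"`.
#' @param include_emotion set FALSE to drop emotion from the fixed part
#'   (used for reduced designs).
#' @return object of class `gaze_lmm`: list with the `lmerTest` fit, the
#'   analysis data, response name, df method and a convergence flag.
#' @export
fit_gaze_lmm <- function(data, response,
                         df_method = c("Satterthwaite", "Kenward-Roger"),
                         include_emotion = TRUE) {
  df_method <- match.arg(df_method)
  if (df_method == "Kenward-Roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    stop("Kenward-Roger degrees of freedom require the pbkrtest package")
  }
  data <- as.data.frame(data)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (length(unique(data$participant_id)) < 2) {
    stop("need at least 2 participants")
  }
  data$emotion <- factor(data$emotion)
  data$sex <- factor(data$sex)
  fixed <- if (include_emotion && nlevels(data$emotion) > 1) {
    "z_aq4 * z_spin * emotion"
  } else {
    "z_aq4 * z_spin"
  }
  covar <- if (nlevels(data$sex) > 1) " + sex" else ""
  form <- stats::as.formula(paste0(response, " ~ ", fixed, covar,
                                   " + (1 | participant_id)"))
  contr <- list()
  if (include_emotion && nlevels(data$emotion) > 1) {
    contr$emotion <- stats::contr.sum(nlevels(data$emotion))
  }
  if (nlevels(data$sex) > 1) contr$sex <- stats::contr.sum(2)
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = data, REML = TRUE,
                   contrasts = if (length(contr)) contr else NULL),
    message = function(m) {
      if (grepl("rank deficient", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    })
  X <- lme4::getME(fit, "X")
  dropped <- attr(X, "col.dropped")
  if (!is.null(dropped) && length(dropped) > 0) {
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(names(dropped), collapse = ", "))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs,
                                           ignore.case = TRUE))
  if (!converged) warning("model fit did not converge; results are flagged")
  structure(list(fit = fit, data = data, response = response,
                 df_method = df_method, converged = converged),
            class = "gaze_lmm")
}

#' @export
print.gaze_lmm <- function(x, ...) {
  cat("Trait-moderation LMM for", x$response,
      sprintf("(%d trials, %d participants%s)\n", nrow(x$data),
              length(unique(x$data$participant_id)),
              if (x$converged) "" else "; NOT CONVERGED"))
  print(lmm_term_tests(x))
  invisible(x)
}

#' Type III tests for a trait-moderation model
#'
#' @param x a `gaze_lmm` object.
#' @return data.frame with `term`, `F`, `df1`, `df2`, `p`.
#' @export
lmm_term_tests <- function(x) {
  stopifnot(inherits(x, "gaze_lmm"))
  a <- stats::anova(x$fit, type = 3, ddf = x$df_method)
  data.frame(term = rownames(a), F = a$`F value`, df1 = a$NumDF,
             df2 = a$DenDF, p = a$`Pr(>F)`, row.names = NULL)
}

# Contrast vector for the z_spin slope at moderator level a (z_aq4 = a),
# marginal over sum-coded emotion (emotion interaction columns contribute
# zero at the factor mean), optionally conditional on one emotion level.
slope_contrast <- function(fit, a, emotion = NULL) {
  cn <- names(lme4::fixef(fit))
  L <- stats::setNames(numeric(length(cn)), cn)
  if (!("z_spin" %in% cn) || !("z_aq4:z_spin" %in% cn)) {
    stop("model must contain z_spin and z_aq4:z_spin terms")
  }
  L["z_spin"] <- 1
  L["z_aq4:z_spin"] <- a
  if (!is.null(emotion)) {
    ef <- factor(emotion, levels = levels(fit@frame$emotion))
    if (is.na(ef)) stop("unknown emotion level: ", emotion)
    C <- stats::contr.sum(nlevels(fit@frame$emotion))
    row <- C[as.integer(ef), ]
    for (k in seq_along(row)) {
      nm1 <- paste0("z_spin:emotion", k)
      nm2 <- paste0("z_aq4:z_spin:emotion", k)
      if (nm1 %in% cn) L[nm1] <- row[k]
      if (nm2 %in% cn) L[nm2] <- a * row[k]
    }
  }
  L
}

#' Simple slopes of social anxiety at fixed autistic-trait levels
#'
#' Computes the conditional slope of `z_spin` at moderator levels of
#' `z_aq4` (default -1, 0, +1 SD, labelled low/medium/high autistic
#' traits), marginal over sum-coded emotion. The unstandardized slope is
#' `B = b_spin + a * b_interaction`; its SE, t and df come from the
#' coefficient covariance with the model's df method; the standardized
#' slope is `beta = B * SD(z_spin) / SD(response)` over the analysis
#' sample.
#'
#' @param x a `gaze_lmm` object.
#' @param levels moderator z-levels.
#' @param emotion optional emotion level to condition on (default:
#'   marginal over emotions).
#' @return data.frame with `level`, `label`, `B`, `SE`, `t`, `df`, `beta`, `p`.
#' @export
simple_slopes <- function(x, levels = c(-1, 0, 1), emotion = NULL) {
  stopifnot(inherits(x, "gaze_lmm"))
  sd_ratio <- stats::sd(x$data$z_spin) / stats::sd(x$data[[x$response]])
  lab <- function(a) {
    if (a == -1) "low" else if (a == 0) "medium" else if (a == 1) "high"
    else sprintf("z_aq4=%g", a)
  }
  rows <- lapply(levels, function(a) {
    L <- slope_contrast(x$fit, a, emotion)
    ct <- lmerTest::contest1D(x$fit, L, ddf = x$df_method)
    data.frame(level = a, label = lab(a), B = ct$Estimate,
               SE = ct$`Std. Error`, t = ct$`t value`, df = ct$df,
               beta = ct$Estimate * sd_ratio, p = ct$`Pr(>|t|)`)
  })
  do.call(rbind, rows)
}

#' Wald tests of slope differences between moderator levels
#'
#' Pairwise tests of whether the social-anxiety slope differs between two
#' autistic-trait levels, optionally within each emotion.
#'
#' @param x a `gaze_lmm` object.
#' @param levels moderator z-levels to compare pairwise.
#' @param by_emotion if TRUE, test within each emotion level.
#' @return data.frame of pairwise differences with t, df and p.
#' @export
slope_differences <- function(x, levels = c(-1, 0, 1), by_emotion = FALSE) {
  stopifnot(inherits(x, "gaze_lmm"))
  emos <- if (by_emotion) levels(x$fit@frame$emotion) else list(NULL)
  out <- list()
  for (e in emos) {
    for (i in seq_along(levels)) {
      for (j in seq_along(levels)) {
        if (j <= i) next
        L <- slope_contrast(x$fit, levels[j], e) -
          slope_contrast(x$fit, levels[i], e)
        ct <- lmerTest::contest1D(x$fit, L, ddf = x$df_method)
        out[[length(out) + 1L]] <- data.frame(
          emotion = if (is.null(e)) "marginal" else e,
          level_1 = levels[i], level_2 = levels[j],
          diff = ct$Estimate, SE = ct$`Std. Error`,
          t = ct$`t value`, df = ct$df, p = ct$`Pr(>|t|)`)
      }
    }
  }
  do.call(rbind, out)
}

# Per-epoch Welch two-sample t statistics with pairwise NA exclusion,
# computed for a batch of group-1 indicator rows at once via matrix
# algebra (sums, sums of squares and counts per relabeling).
welch_t_batch <- function(G1, Xz, X2z, M) {
  G2 <- 1 - G1
  n1 <- G1 %*% M; n2 <- G2 %*% M
  m1 <- (G1 %*% Xz) / n1; m2 <- (G2 %*% Xz) / n2
  v1 <- ((G1 %*% X2z) - n1 * m1^2) / (n1 - 1)
  v2 <- ((G2 %*% X2z) - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0   # numerical guard
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  bad <- n1 < 2 | n2 < 2 | se2 == 0 | !is.finite(t)
  t[bad] <- NA_real_
  df[bad] <- NA_real_
  list(t = t, df = df)
}

welch_t_epochs <- function(curves, is_g1) {
  Xz <- curves; Xz[is.na(Xz)] <- 0
  w <- welch_t_batch(matrix(as.numeric(is_g1), 1), Xz, Xz^2,
                     (!is.na(curves)) * 1)
  list(t = drop(w$t), df = drop(w$df))
}

# Maximal contiguous same-sign supra-threshold runs and their masses.
find_clusters <- function(t, crit) {
  sup <- !is.na(t) & !is.na(crit) & abs(t) > crit
  sgn <- sign(t)
  out <- list()
  i <- 1L; n <- length(t)
  while (i <= n) {
    if (!sup[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && sup[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
    out[[length(out) + 1L]] <- c(start = i, end = j, mass = sum(t[i:j]))
    i <- j + 1L
  }
  out
}

max_cluster_mass <- function(t, crit) {
  cl <- find_clusters(t, crit)
  if (length(cl) == 0) 0 else max(vapply(cl, function(c) abs(c["mass"]), 0))
}

# Row-wise maximum |cluster mass| for a batch of t/crit matrices,
# vectorized by flattening rows with forced breaks at row boundaries.
max_cluster_mass_rows <- function(T, CRIT) {
  m <- nrow(T); ne <- ncol(T)
  tv <- as.vector(t(T))
  cv <- as.vector(t(CRIT))
  sup <- !is.na(tv) & !is.na(cv) & abs(tv) > cv
  out <- numeric(m)
  if (!any(sup)) return(out)
  sg <- sign(tv)
  rowb <- (seq_along(tv) - 1) %% ne == 0
  prev_sup <- c(FALSE, sup[-length(sup)])
  prev_sg <- c(0, sg[-length(sg)])
  start <- sup & (rowb | !prev_sup | sg != prev_sg)
  runid <- cumsum(start)
  mass <- rowsum(tv[sup], runid[sup])
  runrow <- rep(seq_len(m), each = ne)[sup][!duplicated(runid[sup])]
  agg <- tapply(abs(mass[, 1]), runrow, max)
  out[as.integer(names(agg))] <- agg
  out
}

#' Cluster-based permutation test on epoch time courses
#'
#' Compares two groups of participant-level epoch curves. Per epoch, a
#' Welch two-sample t statistic is computed (undefined epoch values
#' excluded pairwise); epochs with |t| above the two-sided critical value
#' at `cluster_alpha` form clusters as maximal contiguous same-sign runs,
#' each scored by its summed t (cluster mass). The null distribution of
#' the maximum absolute cluster mass is built by relabeling participants:
#' exhaustively when the relabeling space is at most `exact_limit`
#' (or `method = "exact"`), otherwise by `n_perm` random relabelings.
#' Monte-Carlo cluster p-values use the add-one convention
#' `p = (1 + #\{perm mass >= observed\}) / (1 + n_perm)`.
#'
#' @param curves matrix of participants x epochs (NAs allowed).
#' @param groups two-level factor/vector of group labels, one per row.
#' @param n_perm number of random relabelings.
#' @param cluster_alpha two-sided cluster-forming alpha.
#' @param seed optional seed for the relabeling draws.
#' @param method `"auto"`, `"exact"` or `"montecarlo"`.
#' @param exact_limit maximum relabeling-space size for automatic
#'   exhaustive enumeration.
#' @return list of class `cluster_perm`: per-epoch `t`, `df`, `crit`,
#'   `clusters` data.frame (`start`, `end`, `mass`, `p`), `null_max`,
#'   `n_perm`, `method`, `cluster_alpha`.
#' @export
cluster_permutation <- function(curves, groups, n_perm = 1000,
                                cluster_alpha = 0.05, seed = NULL,
                                method = c("auto", "exact", "montecarlo"),
                                exact_limit = 1e5) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (any(table(groups) < 2)) stop("each group needs at least 2 members")
  if (nrow(curves) != length(groups)) stop("curves/groups size mismatch")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  n <- nrow(curves)
  n1 <- sum(groups == levels(groups)[1])
  space <- choose(n, n1)
  if (method == "auto") {
    method <- if (space <= exact_limit) "exact" else "montecarlo"
  }

  Xz <- curves; Xz[is.na(Xz)] <- 0
  X2z <- Xz^2
  M <- (!is.na(curves)) * 1
  obs_g1 <- as.numeric(groups == levels(groups)[1])
  obs_w <- welch_t_batch(matrix(obs_g1, 1), Xz, X2z, M)
  obs <- list(t = drop(obs_w$t), df = drop(obs_w$df))
  obs$crit <- stats::qt(1 - cluster_alpha / 2, obs$df)
  clusters <- find_clusters(obs$t, obs$crit)

  if (method == "exact") {
    combos <- utils::combn(n, n1)
    G1 <- matrix(0, ncol(combos), n)
    G1[cbind(rep(seq_len(ncol(combos)), each = n1), as.vector(combos))] <- 1
  } else {
    if (!is.null(seed)) set.seed(seed)
    G1 <- matrix(0, n_perm, n)
    for (k in seq_len(n_perm)) G1[k, sample.int(n, n1)] <- 1
  }
  w <- welch_t_batch(G1, Xz, X2z, M)
  crit <- stats::qt(1 - cluster_alpha / 2, w$df)
  null_max <- max_cluster_mass_rows(w$t, crit)
  # count with a relative tolerance so the observed relabeling always
  # matches its own null entry despite floating-point reordering
  n_ge <- function(mass) sum(null_max >= abs(mass) * (1 - 1e-10))
  if (method == "exact") {
    p_of <- function(mass) n_ge(mass) / nrow(G1)
    n_used <- nrow(G1)
  } else {
    p_of <- function(mass) (1 + n_ge(mass)) / (1 + n_perm)
    n_used <- n_perm
  }

  cl_df <- if (length(clusters) == 0) {
    data.frame(start = integer(0), end = integer(0),
               mass = numeric(0), p = numeric(0))
  } else {
    m <- do.call(rbind, clusters)
    data.frame(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
               mass = m[, "mass"],
               p = vapply(m[, "mass"], p_of, 0))
  }
  structure(list(t = obs$t, df = obs$df, crit = obs$crit, clusters = cl_df,
                 null_max = null_max, n_perm = n_used, method = method,
                 cluster_alpha = cluster_alpha),
            class = "cluster_perm")
}

#' @export
print.cluster_perm <- function(x, ...) {
  cat(sprintf("Cluster-based permutation test (%s, %d relabelings, alpha %.3g)\n",
              x$method, x$n_perm, x$cluster_alpha))
  if (nrow(x$clusters) == 0) {
    cat("no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Run the full set of analyses
#'
#' Reproduces the study's analysis battery on a processed dataset:
#' (1) LMM on overall proportional eye-looking time; (2) LMM on the
#' trial-level first-fixation-on-eyes indicator; (3) LMM on log first
#' fixation duration over eyes-first trials; (4) LMM on log latency to
#' the eyes over eyes-first trials -- each with Type III tests and simple
#' slopes of social anxiety at -1/0/+1 SD of autistic traits; and
#' (5) cluster-based permutation tests of the epoch time courses between
#' high/low autistic-trait groups and high/low social-anxiety groups.
#'
#' @param trials trial-level metrics joined with participant traits
#'   (columns per [fit_gaze_lmm()] plus `valid`).
#' @param participants scored participant table from
#'   [standardize_and_group()].
#' @param curves participant epoch-curve object from
#'   [participant_epoch_curves()].
#' @param config pipeline configuration, see [default_config()].
#' @param seed seed for the permutation draws.
#' @return results bundle (list) with one entry per analysis plus the
#'   exclusion summary.
#' @export
analyze_all <- function(trials, participants, curves,
                        config = default_config(), seed = config$seed) {
  valid <- trials[trials$valid, , drop = FALSE]
  valid$first_fix_eyes_num <- as.numeric(valid$first_fix_eyes)
  levels_z <- config$slopes$levels
  run_lmm <- function(response) {
    fit <- fit_gaze_lmm(valid, response)
    list(terms = lmm_term_tests(fit),
         slopes = simple_slopes(fit, levels_z),
         converged = fit$converged)
  }
  run_cluster <- function(group_col) {
    ids <- rownames(curves$curves)
    g <- participants[[group_col]][match(ids, participants$participant_id)]
    keep <- !is.na(g)
    tab <- table(factor(g[keep]))
    if (length(tab) < 2 || any(tab < 2)) {
      return(list(skipped = TRUE,
                  reason = "group split is degenerate (fewer than 2 participants in a group)",
                  group_sizes = as.list(tab)))
    }
    res <- cluster_permutation(curves$curves[keep, , drop = FALSE], g[keep],
                               n_perm = config$permutation$n_perm,
                               cluster_alpha = config$permutation$cluster_alpha,
                               seed = seed)
    list(t = res$t, clusters = res$clusters, t_mid = curves$t_mid,
         method = res$method, n_perm = res$n_perm)
  }
  list(
    prop_eyes_overall = run_lmm("prop_eyes_overall"),
    first_fix_eyes = run_lmm("first_fix_eyes_num"),
    log_duration = run_lmm("log_duration"),
    log_latency = run_lmm("log_latency"),
    cluster_aq = run_cluster("aq_group"),
    cluster_spin = run_cluster("spin_group"),
    exclusions = exclusion_summary(trials)
  )
}

#' Write a results bundle to JSON
#'
#' @param bundle output of [analyze_all()].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_results_bundle <- function(bundle, path) {
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
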