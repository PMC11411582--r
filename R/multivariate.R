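# Multivariate analyses: PCA feature selection with Kaiser retention and
# Gaussian imputation, L2-penalised logistic decoding (penalty sweep,
# leave-one-trial-out CV), covariance-based feature importance, and
# cross-community predictive classification.

default_penalties <- function() 10^seq(-4, 4, length.out = 8)

# AUC with a fixed orientation: larger score = positive class
auc_score <- function(y, score) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

# ---- PCA feature selection ---------------------------------------------------

# impute missing cells from per-feature Gaussian(mu, sd) of observed rows
impute_gaussian <- function(X, mu = NULL, sdv = NULL) {
  if (is.null(mu)) {
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
    nobs <- colSums(!is.na(X))
    if (any(nobs == 0)) {
      stop("feature(s) with no observed values: ",
           paste(utils::head(which(nobs == 0), 3), collapse = ", "))
    }
    sdv[is.na(sdv) | nobs < 2] <- 0
  }
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) {
    X[na_idx] <- stats::rnorm(nrow(na_idx), mu[na_idx[, 2]], sdv[na_idx[, 2]])
  }
  list(X = X, mu = mu, sd = sdv)
}

#' PCA feature selection with Kaiser retention
#'
#' Imputes missing feature cells from a per-feature Gaussian fitted to the
#' observed epochs, computes a principal component decomposition, and retains
#' components whose eigenvalue exceeds 1 (the Kaiser criterion on standardised
#' features).
#'
#' @param features trials x features matrix of z-scored spectral features
#'   (a `spectral_features` object is also accepted), `NA` cells allowed.
#' @param seed optional seed for the imputation draws.
#' @param feature_index optional data frame describing the columns.
#' @return object of class `pc_space`: list with `loadings` (features x
#'   retained components), `eigenvalues` (all), `retained` (indices),
#'   `scores` (trials x retained), `center`, `impute_mu`, `impute_sd`,
#'   `feature_index`.
#' @export
pca_select <- function(features, seed = NULL, feature_index = NULL) {
  if (inherits(features, "spectral_features")) {
    if (is.null(feature_index)) feature_index <- features$feature_index
    features <- features$z
  }
  stopifnot(nrow(features) >= 2)
  with_seed(seed, {
    imp <- impute_gaussian(features)
    pr <- stats::prcomp(imp$X, center = TRUE, scale. = FALSE)
    ev <- pr$sdev^2
    retained <- which(ev > 1)
    if (length(retained) == 0) retained <- 1L
    # orient each component so its loading sum is non-negative (PC signs are
    # arbitrary; a fixed convention lets loadings be averaged across fits)
    flip <- colSums(pr$rotation[, retained, drop = FALSE]) < 0
    pr$rotation[, retained[flip]] <- -pr$rotation[, retained[flip],
                                                  drop = FALSE]
    pr$x[, retained[flip]] <- -pr$x[, retained[flip], drop = FALSE]
    structure(list(loadings = pr$rotation[, retained, drop = FALSE],
                   eigenvalues = ev, retained = retained,
                   scores = pr$x[, retained, drop = FALSE],
                   center = pr$center, impute_mu = imp$mu, impute_sd = imp$sd,
                   feature_index = feature_index),
              class = "pc_space")
  })
}

#' @export
print.pc_space <- function(x, ...) {
  cat("pc_space: ", length(x$retained), " of ", length(x$eigenvalues),
      " components retained (Kaiser), top eigenvalue ",
      round(max(x$eigenvalues), 2), "\n", sep = "")
  invisible(x)
}

# project new (possibly missing) rows into a fitted PC space
pc_project <- function(pc, newdata, seed = NULL) {
  with_seed(seed, {
    imp <- impute_gaussian(newdata, pc$impute_mu, pc$impute_sd)
    sweep(imp$X, 2, pc$center) %*% pc$loadings
  })
}

#' Topography and spectrum of retained PC loadings across participants
#'
#' For each participant the retained-component loadings are averaged across
#' frequencies (per-electrode score) and across electrodes (per-frequency
#' score). Across participants, each electrode and frequency is tested
#' against zero with one-sample t tests under Benjamini-Hochberg FDR, and the
#' electrode scores aggregated into quadrant ROIs enter a 2x2 (hemisphere x
#' anterior/posterior) repeated-measures ANOVA.
#'
#' @param pc_list list of `pc_space` fits, one per participant, each with a
#'   `feature_index` of `channel` and `freq`.
#' @param montage montage data frame defining the ROIs.
#' @param q FDR level (default 0.05).
#' @param absolute average absolute loadings instead of signed (default
#'   FALSE).
#' @param weights `"eigenvalue"` (default) weights each retained component by
#'   its share of explained variance when averaging loadings, so components
#'   that explain more variance contribute proportionally; `"none"` averages
#'   unweighted.
#' @return list with `electrode` (data frame: channel, mean score, t, p,
#'   p_fdr, significant), `frequency` (analogous per frequency), `roi_anova`
#'   (data frame of F tests for hemisphere, anterior/posterior, interaction),
#'   `roi_scores` (participant x ROI matrix).
#' @export
loading_topography <- function(pc_list, montage, q = 0.05, absolute = FALSE,
                               weights = c("eigenvalue", "none")) {
  weights <- match.arg(weights)
  stopifnot(length(pc_list) >= 2)
  fi <- pc_list[[1]]$feature_index
  stopifnot(!is.null(fi))
  channels <- unique(fi$channel)
  freqs <- unique(fi$freq)
  comp_avg <- function(pc) {
    L <- pc$loadings
    if (absolute) L <- abs(L)
    if (weights == "eigenvalue") {
      wv <- pc$eigenvalues[pc$retained]
      drop(L %*% (wv / sum(wv)))
    } else {
      rowMeans(L)
    }
  }
  per_elec <- t(vapply(pc_list, function(pc) {
    v <- comp_avg(pc)
    vapply(channels, function(ch) mean(v[fi$channel == ch]), numeric(1))
  }, numeric(length(channels))))
  per_freq <- t(vapply(pc_list, function(pc) {
    v <- comp_avg(pc)
    vapply(freqs, function(f) mean(v[fi$freq == f]), numeric(1))
  }, numeric(length(freqs))))
  one_sample <- function(M, ids) {
    t_ <- apply(M, 2, function(v) {
      if (stats::sd(v) == 0) return(c(NA, 1))
      tt <- stats::t.test(v)
      c(unname(tt$statistic), tt$p.value)
    })
    p_fdr <- stats::p.adjust(t_[2, ], method = "BH")
    data.frame(id = ids, mean = colMeans(M), t = t_[1, ], p = t_[2, ],
               p_fdr = p_fdr, significant = p_fdr < q,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  elec <- one_sample(per_elec, channels)
  names(elec)[1] <- "channel"
  freq <- one_sample(per_freq, freqs)
  names(freq)[1] <- "freq"

  rois <- montage_rois(montage)
  roi_names <- c("left_anterior", "left_posterior", "right_anterior",
                 "right_posterior")
  roi_scores <- t(apply(per_elec, 1, function(v) {
    vapply(roi_names, function(r) {
      mean(v[channels %in% names(rois)[!is.na(rois) & rois == r]])
    }, numeric(1))
  }))
  colnames(roi_scores) <- roi_names
  np <- nrow(roi_scores)
  long <- data.frame(
    participant = factor(rep(seq_len(np), 4)),
    hemi = factor(rep(c("left", "left", "right", "right"), each = np)),
    ap = factor(rep(c("anterior", "posterior", "anterior", "posterior"),
                    each = np)),
    value = as.vector(roi_scores))
  fit <- stats::aov(value ~ hemi * ap + Error(participant / (hemi * ap)),
                    data = long)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    data.frame(term = term, F = tab[row, "F value"], df1 = tab[row, "Df"],
               df2 = tab[nrow(tab), "Df"], p = tab[row, "Pr(>F)"])
  }
  roi_anova <- rbind(pull("Error: participant:hemi", "hemi"),
                     pull("Error: participant:ap", "ap"),
                     pull("Error: participant:hemi:ap", "hemi:ap"))
  list(electrode = elec, frequency = freq, roi_anova = roi_anova,
       roi_scores = roi_scores)
}

# ---- penalised logistic machinery -------------------------------------------

# train L2 logistic models over a penalty sweep and score test rows;
# returns a length(penalties)-column matrix of linear scores. The intercept
# is excluded from the score: it is constant within a fold (so irrelevant to
# ranking) and under leave-one-out CV it carries an anti-correlated class
# imbalance artifact that biases pooled AUC.
ridge_logit_scores <- function(Xtr, ytr, Xte, penalties = default_penalties()) {
  ytr <- as.logical(ytr)
  Xte <- matrix(Xte, ncol = ncol(Xtr))
  if (ncol(Xtr) == 1) {
    # glmnet needs >= 2 predictors; 1-D ridge logistic via Newton iterations
    out <- vapply(penalties, function(lam) {
      b <- c(0, 0)  # intercept, slope
      x <- Xtr[, 1]
      for (it in 1:25) {
        eta <- b[1] + b[2] * x
        p <- 1 / (1 + exp(-eta))
        w <- pmax(p * (1 - p), 1e-10)
        g <- c(sum(y01(ytr) - p), sum((y01(ytr) - p) * x) - lam * b[2])
        H <- -rbind(c(sum(w), sum(w * x)),
                    c(sum(w * x), sum(w * x^2) + lam))
        step <- tryCatch(solve(H, g), error = function(e) rep(0, 2))
        b <- b - step
        if (max(abs(step)) < 1e-8) break
      }
      b[2] * Xte[, 1]
    }, numeric(nrow(Xte)))
    return(matrix(out, nrow = nrow(Xte)))
  }
  lam_path <- sort(unique(penalties), decreasing = TRUE)
  fit <- glmnet::glmnet(Xtr, factor(ytr, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = 0, lambda = lam_path,
                        standardize = FALSE)
  beta <- stats::predict(fit, s = penalties, type = "coefficients")
  beta <- as.matrix(beta)[-1, , drop = FALSE]  # drop intercept row
  Xte %*% beta
}

y01 <- function(y) as.numeric(as.logical(y))

#' Classify two trial conditions with penalised logistic regression
#'
#' L2-penalised logistic regression over a sweep of penalty parameters with
#' leave-one-trial-out cross-validation. AUC is computed per penalty from the
#' assembled out-of-fold scores and the reported AUC is the mean over
#' penalties. By default imputation and PCA feature selection are refitted
#' inside every training fold; `fit_once = TRUE` reproduces the simpler
#' fit-once pipeline (impute + PCA on all trials before cross-validation).
#'
#' @param features trials x features matrix (or `spectral_features`); `NA`
#'   cells are imputed.
#' @param labels logical or two-level factor, positive class = `TRUE` /
#'   second level.
#' @param penalties penalty sweep (default 8 log-spaced, 1e-4..1e4).
#' @param pca apply PCA feature selection (default TRUE).
#' @param fit_once fit imputation/PCA once on all trials (default FALSE).
#' @param seed optional seed (imputation draws).
#' @return object of class `decoding_result`: list with `auc` (mean over
#'   penalties), `auc_per_penalty`, `scores` (trials x penalties out-of-fold
#'   scores), `labels`, `penalties`, `scheme`.
#' @export
classify_conditions <- function(features, labels,
                                penalties = default_penalties(), pca = TRUE,
                                fit_once = FALSE, seed = NULL) {
  if (inherits(features, "spectral_features")) features <- features$z
  y <- if (is.factor(labels)) labels == levels(labels)[2] else as.logical(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 5) stop("need at least 5 trials per class")
  n <- nrow(features)
  with_seed(seed, {
    scores <- matrix(NA_real_, n, length(penalties))
    if (fit_once || !pca) {
      X <- if (pca) pca_select(features)$scores else impute_gaussian(features)$X
      for (i in seq_len(n)) {
        scores[i, ] <- ridge_logit_scores(X[-i, , drop = FALSE], y[-i],
                                          X[i, , drop = FALSE], penalties)
      }
    } else {
      for (i in seq_len(n)) {
        pc <- pca_select(features[-i, , drop = FALSE])
        xte <- pc_project(pc, features[i, , drop = FALSE])
        scores[i, ] <- ridge_logit_scores(pc$scores, y[-i], xte, penalties)
      }
    }
    auc_pen <- apply(scores, 2, function(s) auc_score(y, s))
    structure(list(auc = mean(auc_pen), auc_per_penalty = auc_pen,
                   scores = scores, labels = y, penalties = penalties,
                   scheme = if (fit_once) "loo-fit-once" else "loo-foldwise"),
              class = "decoding_result")
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("decoding_result: mean AUC = ", round(x$auc, 3), " over ",
      length(x$penalties), " penalties (", x$scheme, ", n = ",
      length(x$labels), ")\n", sep = "")
  invisible(x)
}

#' Single-feature (Pz amplitude) classifier control
#'
#' Runs the identical penalty-sweep / leave-one-trial-out protocol on a single
#' univariate feature.
#'
#' @param pz_amplitude numeric per-trial amplitude.
#' @param labels as in [classify_conditions()].
#' @param penalties penalty sweep.
#' @return a `decoding_result`.
#' @export
univariate_pz_classifier <- function(pz_amplitude, labels,
                                     penalties = default_penalties()) {
  classify_conditions(matrix(pz_amplitude, ncol = 1), labels,
                      penalties = penalties, pca = FALSE)
}

#' Paired comparison of two per-participant AUC sets
#' @param auc_a,auc_b equal-length participant AUC vectors.
#' @return data frame with t, df, p, Cohen's d (paired).
#' @export
compare_auc <- function(auc_a, auc_b) {
  tt <- stats::t.test(auc_a, auc_b, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, cohens_d = cohens_d_paired(auc_a, auc_b))
}

# ---- feature importance ------------------------------------------------------

#' Covariance-based classifier feature importance
#'
#' Transforms discriminative weights into an interpretable activation pattern:
#' `A = cov(X) w / var(y)` where `X` are the trial features the classifier
#' saw, `w` its weight vector, and `y` the logit-scale classifier outputs.
#'
#' @param X trials x features matrix.
#' @param w feature weight vector (length = ncol(X)).
#' @param y logit outputs per trial (default `X %*% w`).
#' @return object of class `importance_map`: list with `A`, `sigma_x`
#'   (feature covariance), `w`, `var_y`.
#' @export
haufe_importance <- function(X, w, y = NULL) {
  stopifnot(ncol(X) == length(w))
  if (is.null(y)) y <- drop(X %*% w)
  vy <- stats::var(y)
  if (vy == 0) stop("classifier outputs have zero variance")
  sx <- stats::cov(X)
  structure(list(A = drop(sx %*% w) / vy, sigma_x = sx, w = w, var_y = vy),
            class = "importance_map")
}

#' Project PC-space importance back to channel x frequency features
#'
#' @param imp an `importance_map` computed on PC scores.
#' @param pc the `pc_space` whose scores the classifier used.
#' @return data frame `channel`, `freq`, `importance` (loading-weighted
#'   combination of the per-component importances).
#' @export
project_importance <- function(imp, pc) {
  stopifnot(!is.null(pc$feature_index))
  a_feat <- drop(pc$loadings %*% imp$A)
  data.frame(pc$feature_index, importance = a_feat, row.names = NULL)
}

#' Aggregate projected importance into frequency bands and quadrant ROIs
#'
#' @param imp_df data frame from [project_importance()].
#' @param montage montage defining the ROIs.
#' @param bands named list of Hz ranges (defaults: theta 5-7, alpha 9-10,
#'   beta 17-21, gamma 45-80).
#' @return data frame `band`, `roi`, `importance` (mean over the band's
#'   frequencies and the ROI's electrodes).
#' @export
importance_bands <- function(imp_df, montage,
                             bands = list(theta = c(5, 7), alpha = c(9, 10),
                                          beta = c(17, 21),
                                          gamma = c(45, 80))) {
  rois <- montage_rois(montage)
  out <- list()
  for (b in names(bands)) {
    sel_f <- imp_df$freq >= bands[[b]][1] & imp_df$freq <= bands[[b]][2]
    for (r in unique(rois[!is.na(rois)])) {
      chans <- names(rois)[!is.na(rois) & rois == r]
      sel <- sel_f & imp_df$channel %in% chans
      out[[length(out) + 1L]] <- data.frame(band = b, roi = r,
                                            importance = mean(imp_df$importance[sel]))
    }
  }
  do.call(rbind, out)
}

# ---- predictive decoding -----------------------------------------------------

# eligible boundary test trials for one held-out community: learned-boundary
# visits where the same boundary node was not visited within the previous
# `lag` trials of the full sequence
predictive_test_trials <- function(trials, graph, held_out, lag = 2) {
  bn <- boundary_nodes(graph, held_out)
  node_seq <- trials$node
  ok <- logical(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (!node_seq[i] %in% bn) next
    if (isTRUE(trials$swapped[i])) next  # novel (manipulated) boundary visit
    recent <- node_seq[max(1, i - lag):max(1, i - 1)]
    if (i > 1 && node_seq[i] %in% recent) next
    ok[i] <- TRUE
  }
  which(ok)
}

predictive_train_trials <- function(trials, graph, train_communities) {
  idx <- which(graph$community[trials$node] %in% train_communities &
                 graph$role[trials$node] == "inner" &
                 !isTRUE_vec(trials$swapped))
  idx
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Cross-community predictive decoding of boundary-node epochs
#'
#' For each of the three community rotations, classifiers are trained to
#' discriminate inner-node epochs of two communities and applied to the
#' held-out community's learned-boundary-node epochs, labelled by which
#' trained community each boundary node is adjacent to. Test trials are
#' restricted to boundary visits where the same boundary node was not visited
#' within the previous two trials. Classifiers are trained and tested
#' separately per time window (same window for train and test) and on the
#' window-averaged whole epoch; AUCs are averaged over the penalty sweep and
#' across rotations.
#'
#' @param features a `spectral_features` with windowed `z` (trials x features
#'   x windows) whose `metadata` carries the trial table.
#' @param graph the `community_graph`.
#' @param trials full original trial sequence (defaults to the features'
#'   metadata; supply the full table when epochs were dropped).
#' @param penalties penalty sweep.
#' @param lag exclusion lag for repeated boundary visits (default 2).
#' @param test_trial_sets optional named override of test trial indices per
#'   held-out community (used by the preboundary control).
#' @param windows fit per-window classifiers (default TRUE); FALSE computes
#'   only the whole-epoch AUC.
#' @return object of class `decoding_timecourse`: list with `window_auc`
#'   (mean AUC per window), `per_rotation` (rotations x windows),
#'   `whole_epoch` (scalar AUC, window-averaged features),
#'   `window_start_ms`, `n_test` per rotation, `skipped` rotations.
#' @export
predictive_decode <- function(features, graph, trials = NULL,
                              penalties = default_penalties(), lag = 2,
                              test_trial_sets = NULL, windows = TRUE) {
  stopifnot(inherits(features, "spectral_features"),
            length(dim(features$z)) == 3)
  md <- features$metadata
  if (is.null(trials)) trials <- md
  n_win <- dim(features$z)[3]
  per_rot <- matrix(NA_real_, 3, n_win)
  whole <- rep(NA_real_, 3)
  n_test <- integer(3)
  skipped <- integer(0)
  for (held in 1:3) {
    train_cm <- setdiff(1:3, held)
    # map full-sequence trial indices into feature rows
    if (is.null(test_trial_sets)) {
      test_idx_full <- predictive_test_trials(trials, graph, held, lag)
    } else {
      test_idx_full <- test_trial_sets[[held]]
    }
    test_rows <- match(trials$index[test_idx_full], md$index)
    test_rows <- test_rows[!is.na(test_rows)]
    train_rows <- which(graph$community[md$node] %in% train_cm &
                          graph$role[md$node] == "inner" &
                          !(md$swapped %in% TRUE))
    if (length(test_rows) < 2 || length(train_rows) < 4) {
      skipped <- c(skipped, held)
      message("rotation with held-out community ", held,
              " skipped: too few trials")
      next
    }
    # label: adjacent trained community (positive class = higher community id)
    adj_cm <- vapply(md$node[test_rows], function(nd) {
      if (graph$role[[nd]] == "boundary")
        graph$community[[graph$boundary_partner[[nd]]]]
      else  # preboundary inner node: community of the upcoming boundary node
        NA_integer_
    }, integer(1))
    if (anyNA(adj_cm)) {
      adj_cm[is.na(adj_cm)] <- attr(test_trial_sets, "adjacent")[[held]]
    }
    y_te <- adj_cm == max(train_cm)
    y_tr <- graph$community[md$node[train_rows]] == max(train_cm)
    if (length(unique(y_te)) < 2 || length(unique(y_tr)) < 2) {
      skipped <- c(skipped, held)
      message("rotation with held-out community ", held,
              " skipped: single-class labels")
      next
    }
    n_test[held] <- length(test_rows)
    if (windows) {
      for (w in seq_len(n_win)) {
        s <- ridge_logit_scores(features$z[train_rows, , w], y_tr,
                                features$z[test_rows, , w], penalties)
        per_rot[held, w] <- mean(apply(s, 2, function(v) auc_score(y_te, v)))
      }
    }
    z_avg_tr <- apply(features$z[train_rows, , , drop = FALSE], c(1, 2), mean)
    z_avg_te <- apply(features$z[test_rows, , , drop = FALSE], c(1, 2), mean)
    s <- ridge_logit_scores(z_avg_tr, y_tr, z_avg_te, penalties)
    whole[held] <- mean(apply(s, 2, function(v) auc_score(y_te, v)))
  }
  structure(list(window_auc = colMeans(per_rot, na.rm = TRUE),
                 per_rotation = per_rot,
                 whole_epoch = mean(whole, na.rm = TRUE),
                 window_start_ms = features$window_start_ms,
                 n_test = n_test, skipped = skipped),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat("decoding_timecourse: ", length(x$window_auc), " windows, whole-epoch AUC = ",
      round(x$whole_epoch, 3), "\n", sep = "")
  invisible(x)
}

#' Group-level test of a decoding timecourse against chance
#'
#' One-sample t test of the per-participant window AUCs against chance at
#' every time window, with Benjamini-Hochberg FDR correction across windows.
#'
#' @param timecourses list of `decoding_timecourse` objects (one per
#'   participant).
#' @param q FDR level (default 0.05).
#' @param chance chance AUC (default 0.5).
#' @return data frame per window: `window_start_ms`, `mean_auc`, `t`, `p`,
#'   `p_fdr`, `significant`.
#' @export
decode_window_test <- function(timecourses, q = 0.05, chance = 0.5) {
  M <- do.call(rbind, lapply(timecourses, `[[`, "window_auc"))
  starts <- timecourses[[1]]$window_start_ms
  res <- apply(M, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || stats::sd(v) == 0) return(c(NA, NA))
    tt <- stats::t.test(v, mu = chance)
    c(unname(tt$statistic), tt$p.value)
  })
  p_fdr <- stats::p.adjust(res[2, ], method = "BH")
  data.frame(window_start_ms = starts, mean_auc = colMeans(M, na.rm = TRUE),
             t = res[1, ], p = res[2, ], p_fdr = p_fdr,
             significant = !is.na(p_fdr) & p_fdr < q)
}

#' Early/late split of predictive decoding by community run length
#'
#' Splits eligible boundary test trials at the median number of consecutive
#' same-community trials preceding the boundary visit (ties assigned to the
#' early group) and runs the predictive decoder on each group.
#'
#' @inheritParams predictive_decode
#' @param min_trials minimum test trials per group per rotation (default 2).
#' @return list with `early` and `late` (`decoding_timecourse` objects),
#'   `median_run`, `auc_early`, `auc_late` (whole-epoch).
#' @export
early_late_split <- function(features, graph, trials = NULL,
                             penalties = default_penalties(), lag = 2,
                             min_trials = 2, windows = TRUE) {
  md <- features$metadata
  if (is.null(trials)) trials <- md
  run_len <- community_run_lengths(graph, trials$node)
  sets_e <- vector("list", 3)
  sets_l <- vector("list", 3)
  all_runs <- integer(0)
  for (held in 1:3) {
    idx <- predictive_test_trials(trials, graph, held, lag)
    all_runs <- c(all_runs, run_len[idx])
  }
  med <- stats::median(all_runs)
  for (held in 1:3) {
    idx <- predictive_test_trials(trials, graph, held, lag)
    sets_e[[held]] <- idx[run_len[idx] <= med]
    sets_l[[held]] <- idx[run_len[idx] > med]
  }
  early <- predictive_decode(features, graph, trials, penalties, lag,
                             test_trial_sets = sets_e, windows = windows)
  late <- predictive_decode(features, graph, trials, penalties, lag,
                            test_trial_sets = sets_l, windows = windows)
  list(early = early, late = late, median_run = med,
       auc_early = early$whole_epoch, auc_late = late$whole_epoch)
}

#' Preboundary-node control for predictive decoding
#'
#' Applies the same cross-community classifiers to inner nodes of the held-out
#' community visited immediately before a boundary-node visit. The label of a
#' preboundary trial is the community adjacent to the upcoming boundary node.
#'
#' @inheritParams predictive_decode
#' @return a `decoding_timecourse` for the preboundary trials.
#' @export
preboundary_control <- function(features, graph, trials = NULL,
                                penalties = default_penalties(), lag = 2) {
  md <- features$metadata
  if (is.null(trials)) trials <- md
  sets <- vector("list", 3)
  adjacent <- vector("list", 3)
  n <- nrow(trials)
  for (held in 1:3) {
    bn <- boundary_nodes(graph, held)
    pre <- which(seq_len(n) < n &
                   graph$community[trials$node] == held &
                   graph$role[trials$node] == "inner" &
                   c(trials$node[-1] %in% bn, FALSE))
    sets[[held]] <- pre
    adjacent[[held]] <- vapply(pre, function(i) {
      graph$community[[graph$boundary_partner[[trials$node[i + 1L]]]]]
    }, integer(1))
  }
  # attach per-trial adjacent labels through the metadata match inside
  # predictive_decode: rebuild as named lookup keyed by rotation
  adj_by_rot <- lapply(1:3, function(held) {
    a <- adjacent[[held]]
    md_rows <- match(trials$index[sets[[held]]], md$index)
    a[!is.na(md_rows)]
  })
  tset <- sets
  attr(tset, "adjacent") <- adj_by_rot
  predictive_decode(features, graph, trials, penalties, lag,
                    test_trial_sets = tset)
}

#' Permuted-label control for condition decoding
#'
#' Re-runs the classification protocol with training labels permuted within
#' each cross-validation fold's training set, returning the null AUC
#' distribution.
#'
#' @inheritParams classify_conditions
#' @param n_perm number of permuted runs (default 20).
#' @return list with `auc` (null AUCs, one per permutation) and `mean`.
#' @export
permuted_label_control <- function(features, labels,
                                   penalties = default_penalties(),
                                   n_perm = 20, pca = TRUE,
                                   fit_once = FALSE, seed = NULL) {
  if (inherits(features, "spectral_features")) features <- features$z
  y <- if (is.factor(labels)) labels == levels(labels)[2] else as.logical(labels)
  n <- nrow(features)
  with_seed(seed, {
    X <- if (pca) {
      if (fit_once) pca_select(features)$scores else NULL
    } else impute_gaussian(features)$X
    aucs <- vapply(seq_len(n_perm), function(k) {
      scores <- matrix(NA_real_, n, length(penalties))
      for (i in seq_len(n)) {
        if (is.null(X)) {
          pc <- pca_select(features[-i, , drop = FALSE])
          xtr <- pc$scores
          xte <- pc_project(pc, features[i, , drop = FALSE])
        } else {
          xtr <- X[-i, , drop = FALSE]
          xte <- X[i, , drop = FALSE]
        }
        ytr <- sample(y[-i])  # permuted within the training fold
        scores[i, ] <- ridge_logit_scores(xtr, ytr, xte, penalties)
      }
      mean(apply(scores, 2, function(s) auc_score(y, s)))
    }, numeric(1))
    list(auc = aucs, mean = mean(aucs))
  })
}
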