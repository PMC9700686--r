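# Group classification: scaling + PCA + SVM fitted with an inner
# grid-search cross-validation loop and evaluated in a separate outer
# stratified tenfold loop; AUC/ROC/confusion outputs and a bootstrap
# cross-validation comparison between classifiers.

#' Area under the empirical ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2 per pair, which
#' equals the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels class labels: logical, 0/1, or a two-level factor/character.
#' @param positive the positive class; defaults to `TRUE`, `1`, or the last
#'   factor level.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  pos <- positive_mask(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_vrgaze("both classes must be present to compute an AUC",
                class = "vrgaze_validation_error")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

positive_mask <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    return(labels)
  }
  if (is.numeric(labels)) {
    positive <- positive %||% max(labels)
    return(labels == positive)
  }
  f <- as.factor(labels)
  if (nlevels(f) != 2L) {
    stop_vrgaze("labels must have exactly two classes",
                class = "vrgaze_validation_error")
  }
  positive <- positive %||% levels(f)[2]
  f == positive
}

#' Classifier specification
#'
#' The hyperparameter grid searched in the inner loop: candidate PCA
#' component counts, SVM kernels, cost and gamma values (`NA` gamma uses the
#' 1/n_components scale heuristic; gamma applies to the RBF kernel only).
#'
#' @param feature_set label of the feature set (`performance5`,
#'   `epeli_eye39`, `single_task_eye`, or free text).
#' @param pca_components integer candidates (capped at the feature count and
#'   training size at fit time).
#' @param kernels subset of `c("linear", "radial")`.
#' @param cost SVM cost grid.
#' @param gamma RBF gamma grid (`NA` = scale heuristic).
#' @param outer_folds outer (evaluation) folds, stratified by group.
#' @param inner_folds inner (selection) folds.
#' @param seed fold-assignment seed.
#' @return object of class `vrgaze_classifier_spec`.
#' @export
classifier_spec <- function(feature_set = "features",
                            pca_components = c(2L, 5L, 10L, 20L),
                            kernels = c("linear", "radial"),
                            cost = c(0.1, 1, 10, 100),
                            gamma = c(NA, 0.01, 0.001),
                            outer_folds = 10L, inner_folds = 5L, seed = 1L) {
  stopifnot(length(pca_components) >= 1, length(kernels) >= 1,
            length(cost) >= 1, length(gamma) >= 1,
            all(kernels %in% c("linear", "radial")),
            outer_folds >= 2L, inner_folds >= 2L)
  structure(list(feature_set = feature_set,
                 pca_components = as.integer(pca_components),
                 kernels = kernels, cost = cost, gamma = gamma,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "vrgaze_classifier_spec")
}

build_grid <- function(spec) {
  rows <- list()
  for (k in spec$kernels) {
    gmm <- if (k == "linear") NA else spec$gamma
    for (nc in spec$pca_components) for (cc in spec$cost) for (g in gmm) {
      rows[[length(rows) + 1L]] <- data.frame(ncomp = nc, kernel = k,
                                              cost = cc, gamma = g)
    }
  }
  unique(do.call(rbind, rows))
}

# stratified fold assignment; caller controls the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(table(factor(fold, levels = seq_len(k)), y) == 0)) {
    # one re-stratification attempt, then give up
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    if (any(table(factor(fold, levels = seq_len(k)), y) == 0)) {
      stop_vrgaze("cannot stratify %d folds with class counts %s", k,
                  paste(table(y), collapse = "/"),
                  class = "vrgaze_cv_error")
    }
  }
  fold
}

# scaling + PCA fit on training data only, then an SVM on the scores
fit_pca_svm <- function(X, y, ncomp, kernel, cost, gamma) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ncomp <- min(ncomp, ncol(pca$rotation), nrow(X) - 1L)
  ncomp <- max(1L, ncomp)
  Z <- pca$x[, seq_len(ncomp), drop = FALSE]
  g <- if (kernel == "radial") {
    if (is.na(gamma)) 1 / ncomp else gamma
  } else 1 / ncomp
  model <- e1071::svm(x = Z, y = y, kernel = kernel, cost = cost, gamma = g,
                      scale = FALSE)
  # orientation of the libsvm decision value (which class is "positive")
  pos <- levels(y)[2]
  first <- strsplit(colnames(model$decision.values)[1], "/", fixed = TRUE)[[1]][1]
  list(ctr = ctr, scl = scl, rotation = pca$rotation[, seq_len(ncomp), drop = FALSE],
       model = model, flip = if (identical(first, pos)) 1 else -1,
       ncomp = ncomp, kernel = kernel, cost = cost, gamma = g)
}

predict_scores <- function(fit, X) {
  X <- as.matrix(X)
  Z <- scale(X, center = fit$ctr, scale = fit$scl) %*% fit$rotation
  pr <- predict(fit$model, Z, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values")) * fit$flip
}

as_group_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (all(y %in% c("ADHD", "control"))) {
    factor(y, levels = c("control", "ADHD"))
  } else {
    factor(y)
  }
}

#' Nested cross-validated PCA+SVM evaluation
#'
#' Outer stratified k-fold evaluation with, inside every training fold, a
#' grid-search inner cross-validation that selects the PCA component count,
#' kernel, cost and gamma maximizing inner AUC. Scaling and PCA are fit on
#' training data only. Reports per-fold and mean AUC on the held-out folds,
#' an averaged ROC curve, the averaged confusion percentages at the zero
#' decision threshold, and the hyperparameters chosen per fold. Bit-wise
#' reproducible for a fixed seed.
#'
#' @param X feature matrix (participants x features), no missing values.
#' @param y two-class labels (`ADHD`/`control` or any two-level factor; the
#'   second level is the positive class).
#' @param spec a [classifier_spec()].
#' @param seed RNG seed for the fold assignments (default: the spec's).
#' @return list with `per_fold_auc`, `mean_auc`, `roc` (averaged FPR/TPR
#'   curve), `confusion` (percent per true class), `chosen` (per-fold
#'   hyperparameters).
#' @export
nested_cv <- function(X, y, spec = classifier_spec(), seed = spec$seed) {
  X <- as.matrix(X)
  y <- as_group_factor(y)
  if (any(!is.finite(X))) {
    stop_vrgaze("feature matrix contains missing values; impute upstream",
                class = "vrgaze_validation_error")
  }
  if (nrow(X) < 2L * spec$outer_folds) {
    stop_vrgaze("need at least 2 x outer_folds participants",
                class = "vrgaze_validation_error")
  }
  grid <- build_grid(spec)
  fpr_grid <- seq(0, 1, by = 0.02)
  with_seed(seed, {
    fold <- stratified_folds(y, spec$outer_folds)
    per_fold_auc <- numeric(spec$outer_folds)
    tpr_sum <- numeric(length(fpr_grid))
    conf_sum <- matrix(0, 2, 2,
                       dimnames = list(true = levels(y), predicted = levels(y)))
    chosen <- list()
    for (f in seq_len(spec$outer_folds)) {
      tr <- fold != f; te <- fold == f
      Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
      # inner selection loop
      inner_fold <- stratified_folds(ytr, spec$inner_folds)
      inner_auc <- vapply(seq_len(nrow(grid)), function(gi) {
        aucs <- c()
        for (g in seq_len(spec$inner_folds)) {
          itr <- inner_fold != g; ite <- inner_fold == g
          if (length(unique(ytr[ite])) < 2L) next
          fit <- fit_pca_svm(Xtr[itr, , drop = FALSE], droplevels(ytr[itr]),
                             grid$ncomp[gi], grid$kernel[gi],
                             grid$cost[gi], grid$gamma[gi])
          s <- predict_scores(fit, Xtr[ite, , drop = FALSE])
          aucs <- c(aucs, roc_auc(s, ytr[ite] == levels(y)[2]))
        }
        if (length(aucs)) mean(aucs) else NA_real_
      }, numeric(1))
      best <- which.max(inner_auc)  # ties: first in grid order
      fit <- fit_pca_svm(Xtr, ytr, grid$ncomp[best], grid$kernel[best],
                         grid$cost[best], grid$gamma[best])
      s_te <- predict_scores(fit, X[te, , drop = FALSE])
      is_pos <- y[te] == levels(y)[2]
      per_fold_auc[f] <- roc_auc(s_te, is_pos)
      tpr_sum <- tpr_sum + tpr_at_fpr(s_te, is_pos, fpr_grid)
      pred <- factor(ifelse(s_te > 0, levels(y)[2], levels(y)[1]),
                     levels = levels(y))
      cm <- table(true = y[te], predicted = pred)
      conf_sum <- conf_sum + 100 * sweep(cm, 1, pmax(1, rowSums(cm)), "/")
      chosen[[f]] <- data.frame(fold = f, ncomp = fit$ncomp,
                                kernel = fit$kernel, cost = fit$cost,
                                gamma = fit$gamma)
    }
    list(per_fold_auc = per_fold_auc,
         mean_auc = mean(per_fold_auc),
         roc = data.frame(fpr = fpr_grid, tpr = tpr_sum / spec$outer_folds),
         confusion = conf_sum / spec$outer_folds,
         chosen = do.call(rbind, chosen),
         positive = levels(y)[2])
  })
}

# staircase TPR at fixed FPR abscissae for ROC averaging across folds
tpr_at_fpr <- function(scores, is_pos, fpr_grid) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[ord]) / sum(is_pos)
  fp <- cumsum(!is_pos[ord]) / sum(!is_pos)
  tp <- c(0, tp); fp <- c(0, fp)
  vapply(fpr_grid, function(x) max(tp[fp <= x + 1e-12]), numeric(1))
}

#' Bootstrap cross-validation comparison of two classifiers
#'
#' For each of `iterations` bootstrap iterations the participants are
#' resampled with replacement (degenerate single-class resamples are
#' redrawn), both classifier specifications are evaluated with their nested
#' tenfold cross-validation on the resample, and the two sets of mean AUCs
#' are compared by a two-sided two-sample t test with
#' `df = 2 * iterations - 2` (58 for the default 30 iterations).
#'
#' @param spec_a,spec_b [classifier_spec()] objects.
#' @param X_a,X_b feature matrices over the same participants (rows paired).
#' @param y group labels.
#' @param iterations bootstrap iterations (default 30).
#' @param seed RNG seed.
#' @return list with `t`, `df`, `p`, and the per-iteration mean AUCs
#'   `auc_a`, `auc_b`.
#' @export
bootstrap_compare <- function(spec_a, spec_b, X_a, X_b, y, iterations = 30L,
                              seed = 1L) {
  X_a <- as.matrix(X_a); X_b <- as.matrix(X_b)
  y <- as_group_factor(y)
  if (nrow(X_a) != nrow(X_b) || nrow(X_a) != length(y)) {
    stop_vrgaze("X_a, X_b and y must cover the same participants",
                class = "vrgaze_validation_error")
  }
  n <- length(y)
  auc_a <- numeric(iterations); auc_b <- numeric(iterations)
  redraws <- 0L
  for (it in seq_len(iterations)) {
    it_seed <- derive_seed(seed, paste0("boot_", it))
    idx <- with_seed(it_seed, {
      repeat {
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[cand])) == 2L &&
            min(table(y[cand])) >= 4L) break
        redraws <- redraws + 1L
      }
      cand
    })
    cv_seed <- derive_seed(it_seed, "cv")   # shared folds: paired comparison
    auc_a[it] <- nested_cv(X_a[idx, , drop = FALSE], y[idx], spec_a,
                           seed = cv_seed)$mean_auc
    auc_b[it] <- nested_cv(X_b[idx, , drop = FALSE], y[idx], spec_b,
                           seed = cv_seed)$mean_auc
  }
  df <- 2L * iterations - 2L
  sp2 <- (stats::var(auc_a) * (iterations - 1) +
            stats::var(auc_b) * (iterations - 1)) / df
  if (sp2 <= 0) {
    tstat <- 0; p <- 1
  } else {
    tstat <- (mean(auc_a) - mean(auc_b)) / sqrt(sp2 * 2 / iterations)
    p <- 2 * pt(-abs(tstat), df)
  }
  list(t = tstat, df = df, p = p, auc_a = auc_a, auc_b = auc_b,
       redraws = redraws)
}

# --- feature-matrix builders -------------------------------------------------

#' Feature matrices for the three classifiers
#'
#' `eye_feature_matrix()` reshapes the scenario-feature table into one row
#' per participant with 3 features (mean fixation duration, saccade
#' duration, saccade amplitude) per scenario — 39 columns for the standard
#' 13 scenarios. `performance_matrix()` extracts the five task-performance
#' measures. `single_task_matrix()` extracts the three eye features of one
#' scenario. Missing cells are imputed with the column median.
#'
#' @param features scenario-feature table from [feature_table()].
#' @param impute impute missing cells with the column median.
#' @return list with `X` (matrix), `y` (group factor, positive class ADHD),
#'   `participants`.
#' @export
eye_feature_matrix <- function(features, impute = TRUE) {
  parts <- unique(features$participant)
  scens <- sort(unique(features$scenario))
  feats <- c("mean_fix_dur_ms", "mean_sacc_dur_ms", "mean_sacc_amp_deg")
  X <- matrix(NA_real_, length(parts), length(scens) * length(feats),
              dimnames = list(parts, paste0(rep(c("fix", "saccdur", "amp"),
                                                times = length(scens)),
                                            "_s", rep(scens, each = 3))))
  grp <- character(length(parts))
  for (i in seq_along(parts)) {
    fp <- features[features$participant == parts[i], , drop = FALSE]
    grp[i] <- fp$group[1]
    for (j in seq_along(scens)) {
      row <- fp[fp$scenario == scens[j], , drop = FALSE]
      if (nrow(row)) {
        X[i, (j - 1) * 3 + 1:3] <- unlist(row[1, feats])
      }
    }
  }
  if (impute) X <- impute_median(X)
  list(X = X, y = as_group_factor(grp), participants = parts)
}

#' @rdname eye_feature_matrix
#' @param performance per-participant performance table from
#'   [simulate_cohort()] (columns `participant`, `group` and the five
#'   measures).
#' @export
performance_matrix <- function(performance, impute = TRUE) {
  X <- as.matrix(performance[, PERFORMANCE_MEASURES])
  rownames(X) <- performance$participant
  if (impute) X <- impute_median(X)
  list(X = X, y = as_group_factor(performance$group),
       participants = performance$participant)
}

#' @rdname eye_feature_matrix
#' @param scenario which scenario supplies the single-task eye features.
#' @export
single_task_matrix <- function(features, scenario = 1L, impute = TRUE) {
  fs <- features[features$scenario == scenario, , drop = FALSE]
  X <- as.matrix(fs[, c("mean_fix_dur_ms", "mean_sacc_dur_ms",
                        "mean_sacc_amp_deg")])
  rownames(X) <- fs$participant
  if (impute) X <- impute_median(X)
  list(X = X, y = as_group_factor(fs$group), participants = fs$participant)
}

impute_median <- function(X) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- stats::median(X[!bad, j])
  }
  X
}
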