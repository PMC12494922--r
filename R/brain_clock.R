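#' Augment a training feature matrix
#'
#' Adds `factor` perturbed copies of every training row: each synthetic row
#' is an original row plus zero-mean Gaussian noise of the given sd, keeping
#' its source row's age. Original rows come first, unmodified.
#'
#' @param features Numeric matrix, subjects in rows.
#' @param ages Numeric age vector.
#' @param factor Number of synthetic copies per original row (>= 0).
#' @param noise_sd Perturbation sd in feature units; the default,
#'   `0.1 * sd(features)`, is one tenth of the pooled feature sd.
#' @param seed Integer seed.
#' @return List with augmented `features` and `ages`.
#' @export
augment_training_set <- function(features, ages, factor = 1,
                                 noise_sd = 0.1 * stats::sd(features),
                                 seed = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(ages), factor >= 0)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  factor <- as.integer(factor)
  if (factor == 0) return(list(features = features, ages = ages))
  n <- nrow(features)
  with_local_seed(seed, {
    synth <- do.call(rbind, lapply(seq_len(factor), function(k) {
      features + matrix(stats::rnorm(length(features), 0, noise_sd),
                        nrow(features), ncol(features))
    }))
    list(features = rbind(features, synth),
         ages = c(ages, rep(ages, factor)))
  })
}

# fit one linear-kernel SVR; returns weights, intercept and a predict closure
fit_linear_svr <- function(x, y, cost, epsilon) {
  m <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                  epsilon = epsilon, scale = FALSE, type = "eps-regression")
  w <- as.vector(t(m$coefs) %*% m$SV)
  list(model = m, weights = w, intercept = -m$rho)
}

# inner CV over the (cost, epsilon) grid; returns the best pair by MAE
tune_svr <- function(x, y, grid, inner_folds = 3, seed = 1) {
  combos <- expand.grid(cost = grid$cost, epsilon = grid$epsilon)
  if (nrow(combos) == 1) return(combos[1, ])
  n <- nrow(x)
  fold <- with_local_seed(seed, sample(rep_len(seq_len(inner_folds), n)))
  mae <- vapply(seq_len(nrow(combos)), function(i) {
    errs <- vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      fit <- fit_linear_svr(x[tr, , drop = FALSE], y[tr],
                            combos$cost[i], combos$epsilon[i])
      mean(abs(stats::predict(fit$model, x[!tr, , drop = FALSE]) - y[!tr]))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  combos[which.min(mae), ]
}

#' Train a cross-validated linear-SVR brain clock
#'
#' K-fold cross-validation repeated `n_reps` times. Inside every training
#' fold the data may be augmented ([augment_training_set()]) and the SVR
#' hyperparameters tuned by an inner CV; held-out folds are never augmented.
#' Performance (MAE, Pearson r) is computed on each repetition's pooled
#' out-of-fold predictions and averaged over repetitions. Edge importance is
#' the mean absolute linear SVR weight over folds and repetitions. The
#' age-bias line is fitted by OLS of the out-of-fold raw brain-age gap on
#' chronological age.
#'
#' @param features Numeric matrix, subjects in rows (e.g. [vectorize_fc()]
#'   features).
#' @param ages Chronological ages in years.
#' @param n_folds Folds (default 5).
#' @param n_reps Repetitions (default 15, the maximum used).
#' @param grid Hyperparameter grid, a list with `cost` and `epsilon`
#'   (defaults `c(0.1, 1, 10)` and `c(0.1, 1)`).
#' @param augmentation List with `factor`, `noise_sd` (NULL for the pooled
#'   default) controlling in-fold augmentation; `factor = 0` disables it.
#' @param seed Integer seed.
#' @return An object of class `brain_clock`: fold models, bias line,
#'   performance, edge importances, out-of-fold predictions, training spec.
#' @export
train_brain_clock <- function(features, ages, n_folds = 5, n_reps = 15,
                              grid = list(cost = c(0.1, 1, 10),
                                          epsilon = c(0.1, 1)),
                              augmentation = list(factor = 0, noise_sd = NULL),
                              seed = 1) {
  stopifnot(is.matrix(features), nrow(features) == length(ages),
            n_folds >= 2, n_reps >= 1)
  n <- nrow(features)
  if (n < 2 * n_folds) stop("need at least 2 subjects per fold")
  if (stats::sd(ages) == 0) stop("ages must be nonconstant")
  aug_factor <- augmentation$factor %||% 0
  aug_sd <- augmentation$noise_sd %||% (0.1 * stats::sd(features))
  fold_models <- list()
  oof_by_rep <- matrix(NA_real_, n, n_reps)
  mae_reps <- numeric(n_reps)
  r_reps <- numeric(n_reps)
  importance_sum <- numeric(ncol(features))
  n_models <- 0L
  for (rep_i in seq_len(n_reps)) {
    fold <- with_local_seed(child_seed(seed, rep_i),
                            sample(rep_len(seq_len(n_folds), n)))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      x_tr <- features[tr, , drop = FALSE]
      y_tr <- ages[tr]
      if (aug_factor > 0) {
        aug <- augment_training_set(
          x_tr, y_tr, factor = aug_factor, noise_sd = aug_sd,
          seed = floor(child_seed(seed, rep_i * 100 + f)))
        x_tr <- aug$features
        y_tr <- aug$ages
      }
      hp <- tune_svr(x_tr, y_tr, grid,
                     seed = floor(child_seed(seed, rep_i * 1000 + f)))
      fit <- fit_linear_svr(x_tr, y_tr, hp$cost, hp$epsilon)
      n_models <- n_models + 1L
      fold_models[[n_models]] <- fit
      importance_sum <- importance_sum + abs(fit$weights)
      oof_by_rep[fold == f, rep_i] <-
        stats::predict(fit$model, features[fold == f, , drop = FALSE])
    }
    mae_reps[rep_i] <- mean(abs(oof_by_rep[, rep_i] - ages))
    r_reps[rep_i] <- stats::cor(oof_by_rep[, rep_i], ages)
  }
  oof_mean <- rowMeans(oof_by_rep)
  raw_bag <- oof_mean - ages
  bias <- stats::lm.fit(cbind(1, ages), raw_bag)$coefficients
  structure(
    list(
      fold_models = fold_models,
      bias_intercept = unname(bias[1]),
      bias_slope = unname(bias[2]),
      performance = list(mae = mean(mae_reps), pearson_r = mean(r_reps)),
      edge_importance = importance_sum / n_models,
      oof_predictions = oof_mean,
      training_ages = ages,
      training_spec = list(n_folds = n_folds, n_reps = n_reps, grid = grid,
                           augmentation = list(factor = aug_factor,
                                               noise_sd = aug_sd),
                           seed = seed)
    ),
    class = "brain_clock"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict brain age with a trained clock
#'
#' Mean prediction across all fold-by-repetition SVR models.
#'
#' @param model A [train_brain_clock()] result.
#' @param features Numeric matrix with the model's feature dimensionality.
#' @return Predicted ages in years.
#' @export
predict_age <- function(model, features) {
  stopifnot(inherits(model, "brain_clock"), is.matrix(features))
  p <- length(model$edge_importance)
  if (ncol(features) != p) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 p, ncol(features)), call. = FALSE)
  }
  preds <- vapply(model$fold_models,
                  function(fm) stats::predict(fm$model, features),
                  numeric(nrow(features)))
  if (nrow(features) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Brain-age gaps with bias correction and domain centering
#'
#' Raw gap = predicted minus chronological age; the corrected gap removes
#' the training-derived age-bias line (`raw - (intercept + slope * age)`);
#' the centered gap subtracts the mean corrected gap within each domain of
#' the batch. Positive gaps indicate accelerated, negative delayed, brain
#' aging.
#'
#' @param predicted Predicted ages (years).
#' @param chronological Chronological ages (years).
#' @param model A [train_brain_clock()] result supplying the bias line, or
#'   a list with `bias_intercept` and `bias_slope`.
#' @param domains Character vector of domain labels (recycled if length 1).
#' @param subject_id Optional subject identifiers.
#' @param correct If `FALSE`, skip the bias correction (corrected = raw);
#'   used by the bias-correction sensitivity analysis.
#' @return Data frame with columns `subject_id`, `predicted_age`,
#'   `chronological_age`, `raw_bag`, `corrected_bag`, `centered_bag`,
#'   `domain`.
#' @export
compute_bags <- function(predicted, chronological, model, domains = "all",
                         subject_id = NULL, correct = TRUE) {
  stopifnot(length(predicted) == length(chronological))
  n <- length(predicted)
  domains <- rep_len(domains, n)
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(n))
  raw <- predicted - chronological
  corrected <- if (correct) {
    raw - (model$bias_intercept + model$bias_slope * chronological)
  } else raw
  centered <- corrected - stats::ave(corrected, domains)
  data.frame(
    subject_id = subject_id, predicted_age = predicted,
    chronological_age = chronological, raw_bag = raw,
    corrected_bag = corrected, centered_bag = centered, domain = domains,
    stringsAsFactors = FALSE
  )
}

#' Standardize to z-scores
#'
#' Centers and scales with the sample standard deviation, the scale on
#' which gaps and heterogeneous expertise scores are compared.
#'
#' @param values Numeric vector, length >= 2, nonconstant.
#' @return Standardized numeric vector (mean 0, sample sd 1).
#' @export
zscore <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Slope of predicted on chronological age
#'
#' OLS regression slope of predicted versus chronological age, used to
#' compare prediction compression across sub-cohorts.
#'
#' @param predicted Predicted ages.
#' @param chronological Chronological ages (nonconstant, length >= 3).
#' @return Scalar slope.
#' @export
prediction_slope <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) >= 3)
  if (stats::sd(chronological) == 0) stop("ages must be nonconstant")
  unname(stats::lm.fit(cbind(1, chronological), predicted)$coefficients[2])
}
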