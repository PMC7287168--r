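# RBF-kernel SVM training (via libsvm through e1071), probability
# calibration, grid search and stratified n-fold cross-validation.
#
# libsvm's built-in probability machinery draws its internal CV folds from
# an unseeded C rand(), so two identical training calls give different
# sigmoid parameters. For reproducibility we instead fit the SVM without
# it and calibrate a Platt sigmoid ourselves on seeded out-of-fold decision
# values (for a binary problem libsvm's pairwise coupling reduces to this
# single sigmoid anyway).

#' Train a site-classification SVM
#'
#' Standardizes features (training mean/SD, stored in the model), fits an
#' SVM, and calibrates the probability map `p = 1/(1 + exp(A f + B))` on
#' decision values `f` collected out-of-fold from a seeded internal CV, so
#' training is fully deterministic given the seed.
#'
#' @param data A labeled feature frame (see [fuse_features()]).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @param kernel One of `"radial"` (default), `"linear"`, `"polynomial"`,
#'   `"sigmoid"`.
#' @param calibration_folds Folds of the internal CV used for probability
#'   calibration (default 3).
#' @param seed Integer seed for the calibration folds.
#' @return A `site_model` object; [predict()] on it returns per-record
#'   probabilities and calls. Save/restore with [save_model()] /
#'   [load_model()].
#' @export
svm_train <- function(data, cost = 1, gamma = NULL, kernel = "radial",
                      calibration_folds = 3L, seed = 1L) {
  y <- check_labels(data)
  feats <- feature_cols(data)
  X <- as.matrix(data[feats])
  gamma <- gamma %||% (1 / ncol(X))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(Xs, yf, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  # out-of-fold decision values for Platt calibration
  fold_id <- make_folds(y, calibration_folds, seed)
  dv <- numeric(length(y))
  for (k in seq_len(calibration_folds)) {
    tr <- fold_id != k
    sck <- fit_scaler(X[tr, , drop = FALSE])
    fk <- e1071::svm(apply_scaler(X[tr, , drop = FALSE], sck),
                     factor(y[tr], levels = c(0L, 1L)),
                     kernel = kernel, cost = cost, gamma = gamma,
                     scale = FALSE)
    dv[!tr] <- decision_for_positive(fk, apply_scaler(X[!tr, , drop = FALSE],
                                                      sck))
  }
  platt <- platt_fit(dv, y)
  structure(
    list(
      fit = fit, scaler = sc, features = feats,
      kernel = kernel, cost = cost, gamma = gamma,
      platt = platt, calibration_folds = as.integer(calibration_folds),
      seed = as.integer(seed), encoding = NULL, grid = NULL,
      trained_at = format(Sys.time(), tz = "UTC")
    ),
    class = "site_model"
  )
}

#' Grid-search SVM hyperparameters, then refit on all data
#'
#' Exhaustive search over a cost x gamma lattice scored by stratified
#' cross-validated accuracy; ties are broken toward the smallest cost, then
#' the smallest gamma, and the winner is refit on the full data with
#' calibrated probabilities. The default lattice is the classic libsvm-guide
#' grid; a coarser grid (e.g. `costs = 2^seq(-3, 9, 2)`,
#' `gammas = 2^seq(-9, 1, 2)`) is usually indistinguishable and much
#' faster.
#'
#' @inheritParams svm_train
#' @param costs,gammas Numeric vectors defining the search lattice.
#' @param folds Folds of the model-selection CV (default 5).
#' @return A `site_model` whose `grid` component holds the searched lattice
#'   with its CV accuracies.
#' @export
grid_search_train <- function(data, costs = 2^seq(-5, 15, 2),
                              gammas = 2^seq(-15, 3, 2), folds = 5L,
                              kernel = "radial", calibration_folds = 3L,
                              seed = 1L) {
  y <- check_labels(data)
  X <- as.matrix(data[feature_cols(data)])
  fold_id <- make_folds(y, folds, seed)
  grid <- tidyr::expand_grid(cost = sort(costs), gamma = sort(gammas))
  grid$accuracy <- purrr::pmap_dbl(grid, function(cost, gamma) {
    cv_accuracy(X, y, fold_id, cost = cost, gamma = gamma, kernel = kernel)
  })
  # best accuracy; ties -> smallest cost, then smallest gamma
  best <- dplyr::slice(dplyr::arrange(grid, dplyr::desc(.data$accuracy),
                                      .data$cost, .data$gamma), 1)
  model <- svm_train(data, cost = best$cost, gamma = best$gamma,
                     kernel = kernel, calibration_folds = calibration_folds,
                     seed = seed)
  model$grid <- grid
  model
}

#' Predict methylation probability for encoded records
#'
#' @param object A `site_model`.
#' @param newdata A feature frame containing at least the model's feature
#'   columns (extra columns are ignored).
#' @param ... Unused.
#' @return A tibble with columns `id`, `probability` (calibrated
#'   probability of being a 6mA site) and `call` (1 iff probability
#'   strictly exceeds 0.5 — a tie at exactly 0.5 is a negative call).
#' @export
predict.site_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) {
    abort(paste0("newdata lacks model feature(s): ",
                 paste(utils::head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) sprintf(" (and %d more)",
                                               length(miss) - 5) else ""),
          class = "methsite_contract_error")
  }
  X <- as.matrix(newdata[object$features])
  dv <- decision_for_positive(object$fit, apply_scaler(X, object$scaler))
  prob <- platt_prob(dv, object$platt)
  tibble(
    id = if ("id" %in% names(newdata)) newdata$id else
      as.character(seq_len(nrow(newdata))),
    probability = prob,
    call = as.integer(prob > 0.5)
  )
}

#' Predict directly from sequence records
#'
#' Encodes raw windows with the encoder configuration stored in the model
#' (available when the model came from [train_pipeline()] or had
#' `model$encoding` set), restricts to the model's selected features and
#' predicts. Records failing width/alphabet validation are reported in the
#' `error` column and the remaining records are still scored.
#'
#' @param model A `site_model` with an `encoding` configuration.
#' @param records A record tibble (columns `id`, `seq`).
#' @return A tibble `id`, `probability`, `call`, `error` (NA when scored).
#' @export
predict_sites <- function(model, records) {
  stopifnot(inherits(model, "site_model"))
  if (is.null(model$encoding)) {
    abort("model carries no encoder configuration; use predict() on an encoded feature frame",
          class = "methsite_contract_error")
  }
  check_record_frame(records)
  enc <- model$encoding
  ok <- rep(TRUE, nrow(records))
  errs <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    e <- tryCatch({
      validate_windows(records[i, ], enc$width)
      validate_alphabet(records[i, ])
      NULL
    }, error = conditionMessage)
    if (!is.null(e)) {
      ok[i] <- FALSE
      errs[i] <- e
    }
  }
  out <- tibble(id = records$id, probability = NA_real_,
                call = NA_integer_, error = errs)
  if (any(ok)) {
    feats <- encode_windows(records[ok, , drop = FALSE],
                            width = enc$width, kmer_sizes = enc$kmer_sizes,
                            lambda = enc$lambda, w = enc$w,
                            overlap = enc$overlap,
                            properties = enc$properties)
    pred <- predict(model, feats)
    out$probability[ok] <- pred$probability
    out$call[ok] <- pred$call
  }
  out
}

#' Save / load a fitted site model
#'
#' The on-disk representation round-trips exactly: a reloaded model
#' reproduces predictions bit-for-bit.
#'
#' @param model A `site_model`.
#' @param path File path (conventionally `.rds`).
#' @return `path` (save) or the restored `site_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "site_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "site_model")) {
    abort("file does not contain a site_model", class = "methsite_io_error")
  }
  model
}

#' @export
print.site_model <- function(x, ...) {
  cat("site_model:", x$kernel, "kernel SVM,",
      length(x$features), "features\n")
  cat(sprintf("  cost = %g, gamma = %g, %d support vectors\n",
              x$cost, x$gamma, x$fit$tot.nSV))
  if (!is.null(x$grid)) {
    cat(sprintf("  grid-searched over %d (cost, gamma) pairs\n", nrow(x$grid)))
  }
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/(TP+FP+TN+FN)` and Matthews correlation
#' `MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`.
#' Zero-denominator conventions: an undefined Sn or Sp is reported as 0
#' (with a warning); an MCC with any zero factor is 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return A one-row tibble `tp`, `fp`, `tn`, `fn`, `sn`, `sp`, `acc`, `mcc`.
#' @examples
#' compute_metrics(tp = 40, fn = 10, tn = 30, fp = 20)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  tp <- as.double(tp); fp <- as.double(fp)
  tn <- as.double(tn); fn <- as.double(fn)
  n <- tp + fp + tn + fn
  if (n == 0) abort("empty confusion table", class = "methsite_validation_error")
  sn <- if (tp + fn == 0) {
    warn("no positive samples; Sn reported as 0")
    0
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warn("no negative samples; Sp reported as 0")
    0
  } else tn / (tn + fp)
  denom <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sn = sn, sp = sp, acc = (tp + tn) / n, mcc = mcc)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values, from
#' calling everything negative to calling everything positive; tied scores
#' move as one block, which makes the trapezoidal area agree with the
#' Mann-Whitney ties-count-half convention.
#'
#' @param scores Numeric scores (higher = more site-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return A tibble `threshold`, `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1L) || !any(labels == 0L)) {
    abort("ROC needs both classes present", class = "methsite_validation_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores: cumulative counts at the last index of each tie block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / sum(labels == 0L)),
    tpr = c(0, tp / sum(labels == 1L))
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the threshold-sweep ROC; equals the
#' probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @inheritParams roc_points
#' @return The AUC, a scalar in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Stratified n-fold cross-validation of the SVM
#'
#' Splits the data into `folds` stratified subsets from the seed, trains on
#' each complement (feature standardization and probability calibration
#' refit inside each training fold), scores the held-out fold, and reports
#' per-fold and mean Sn, Sp, ACC, MCC and AUC. With `repeats > 1` the whole
#' procedure is repeated with shifted fold seeds and all folds contribute
#' to the means (the "10 times n-fold" protocol).
#'
#' @inheritParams svm_train
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeated CV rounds (default 1).
#' @return A `site_cv` object: `metrics` (per-fold tibble), `summary`
#'   (mean metrics), `confusion` (pooled counts), `scores` (out-of-fold
#'   probabilities), `roc` (pooled ROC points), plus the call parameters.
#'   [tidy()] returns per-fold metrics, [glance()] the means, [autoplot()]
#'   the pooled ROC curve.
#' @export
cross_validate <- function(data, folds = 10L, repeats = 1L, seed = 1L,
                           cost = 1, gamma = NULL, kernel = "radial",
                           calibration_folds = 3L) {
  y <- check_labels(data)
  folds <- as.integer(folds)
  if (folds < 2L) abort("`folds` must be >= 2", class = "methsite_config_error")
  if (folds > min(sum(y == 0L), sum(y == 1L))) {
    abort("more folds than samples in the smaller class",
          class = "methsite_config_error")
  }
  per_fold <- list()
  score_rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- make_folds(y, folds, as.integer(seed) + r - 1L)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      model <- svm_train(data[tr, , drop = FALSE], cost = cost,
                         gamma = gamma, kernel = kernel,
                         calibration_folds = calibration_folds,
                         seed = as.integer(seed) + r - 1L)
      pred <- predict(model, data[!tr, , drop = FALSE])
      yk <- y[!tr]
      cm <- compute_metrics(
        tp = sum(pred$call == 1L & yk == 1L),
        fp = sum(pred$call == 1L & yk == 0L),
        tn = sum(pred$call == 0L & yk == 0L),
        fn = sum(pred$call == 0L & yk == 1L)
      )
      cm$auc <- roc_auc(pred$probability, yk)
      per_fold[[length(per_fold) + 1L]] <-
        dplyr::bind_cols(tibble(repeat_ = r, fold = k), cm)
      score_rows[[length(score_rows) + 1L]] <-
        tibble(repeat_ = r, fold = k, id = pred$id, label = yk,
               probability = pred$probability)
    }
  }
  metrics <- dplyr::bind_rows(per_fold)
  scores <- dplyr::bind_rows(score_rows)
  summary <- dplyr::summarise(metrics, dplyr::across(
    c("sn", "sp", "acc", "mcc", "auc"), mean))
  confusion <- dplyr::summarise(metrics, dplyr::across(
    c("tp", "fp", "tn", "fn"), sum))
  structure(
    list(
      metrics = metrics, summary = summary, confusion = confusion,
      scores = scores,
      roc = roc_points(scores$probability, scores$label),
      folds = folds, repeats = as.integer(repeats), seed = as.integer(seed),
      cost = cost, gamma = gamma, kernel = kernel
    ),
    class = "site_cv"
  )
}

#' Write an evaluation report to disk
#'
#' Writes `report.json` (per-fold and mean metrics, confusion counts,
#' seed), `metrics.tsv` and `roc.tsv`.
#'
#' @param x A `site_cv` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "site_cv"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(metrics = x$metrics, summary = x$summary,
              confusion = x$confusion, folds = x$folds,
              repeats = x$repeats, seed = x$seed)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(x$metrics, file.path(dir, "metrics.tsv"), progress = FALSE)
  readr::write_tsv(x$roc, file.path(dir, "roc.tsv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.site_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d repeat%s, seed %d)\n",
              x$folds, x$repeats, if (x$repeats > 1) "s" else "", x$seed))
  s <- x$summary
  cat(sprintf("  Sn %.4f  Sp %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
              s$sn, s$sp, s$acc, s$mcc, s$auc))
  invisible(x)
}

#' @export
tidy.site_cv <- function(x, ...) x$metrics

#' @export
glance.site_cv <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble(folds = x$folds, repeats = x$repeats,
                          seed = x$seed))
}

#' @export
autoplot.site_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dotted", color = "grey60") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Pooled ROC (mean AUC %.3f)", object$summary$auc)
    ) +
    ggplot2::theme_minimal()
}

# --- internal -----------------------------------------------------------

# stratified fold assignment, deterministic given the seed
make_folds <- function(y, k, seed) {
  k <- as.integer(k)
  fold_id <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold_id
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2) * nrow(X) / max(1, nrow(X) - 1))
  s[s == 0] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
}

# decision value oriented so larger = more likely class "1"
decision_for_positive <- function(fit, Xs) {
  dv <- attr(predict(fit, Xs, decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == "1") as.numeric(dv) else -as.numeric(dv)
}

# train on (Xtr, ytr), return integer class predictions for Xte
svm_fold_predict <- function(Xtr, ytr, Xte, cost = 1, gamma = NULL,
                             kernel = "radial") {
  gamma <- gamma %||% (1 / ncol(Xtr))
  sc <- fit_scaler(Xtr)
  fit <- e1071::svm(apply_scaler(Xtr, sc),
                    factor(ytr, levels = c(0L, 1L)),
                    kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  as.integer(as.character(predict(fit, apply_scaler(Xte, sc))))
}

# pooled CV accuracy with class-prediction SVMs (no calibration needed)
cv_accuracy <- function(X, y, fold_id, cost = 1, gamma = NULL,
                        kernel = "radial") {
  correct <- 0L
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    pred <- svm_fold_predict(X[tr, , drop = FALSE], y[tr],
                             X[!tr, , drop = FALSE],
                             cost = cost, gamma = gamma, kernel = kernel)
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

# Platt sigmoid fit by Newton iteration with backtracking
# (the standard regularized maximum-likelihood procedure for mapping SVM
# decision values to probabilities)
platt_fit <- function(dv, y, max_iter = 100L, min_step = 1e-10,
                      sigma = 1e-12, tol = 1e-5) {
  t1 <- sum(y == 1L)
  t0 <- sum(y == 0L)
  hi <- (t1 + 1) / (t1 + 2)
  lo <- 1 / (t0 + 2)
  t <- ifelse(y == 1L, hi, lo)
  # p(y = 1 | f) = 1 / (1 + exp(A f + B)); with decision values oriented so
  # larger f means "positive", the fitted A comes out negative
  f <- dv
  A <- 0
  B <- log((t0 + 1) / (t1 + 1))
  fval <- platt_obj(f, t, A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    d1 <- t - p          # gradient of the objective wrt fApB, per sample
    d2 <- p * (1 - p)
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < tol && abs(g2) < tol) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- platt_obj(f, t, newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(A = A, B = B)
}

platt_obj <- function(f, t, A, B) {
  fApB <- A * f + B
  sum(ifelse(fApB >= 0,
             t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

platt_prob <- function(dv, platt) {
  fApB <- platt$A * dv + platt$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}
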