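# End-to-end orchestration: encode -> fuse -> select -> train -> evaluate.

#' Encode records with both feature representations and fuse
#'
#' Runs the positional-specificity encoder and the pseudo dinucleotide
#' composition encoder on the same records and fuses the blocks; defaults
#' give the 522-dimensional fused representation (500 NPS + 22 PseDNC).
#'
#' @inheritParams encode_nps
#' @inheritParams encode_psednc
#' @return A fused feature frame.
#' @export
encode_windows <- function(data, width = 41L, kmer_sizes = c(2L, 3L, 4L),
                           lambda = 6L, w = 0.1, overlap = TRUE,
                           properties = dinuc_property_table()) {
  fuse_features(
    encode_nps(data, width = width, kmer_sizes = kmer_sizes),
    encode_psednc(data, width = width, lambda = lambda, w = w,
                  overlap = overlap, properties = properties)
  )
}

#' Train the full prediction pipeline from sequence records
#'
#' Encodes, fuses, optionally runs incremental ANOVA-F feature selection,
#' grid-searches the RBF-SVM hyperparameters on the selected subset, refits
#' on all data, and estimates performance by stratified n-fold
#' cross-validation at the chosen hyperparameters.
#'
#' @param records A labeled record tibble (columns `id`, `seq`, `label`).
#' @param select Run incremental feature selection (default `TRUE`); with
#'   `FALSE` all fused features are kept.
#' @param dims,selection_folds,selection_mode Passed to
#'   [incremental_select()].
#' @param costs,gammas,grid_folds Hyperparameter lattice and folds for
#'   [grid_search_train()].
#' @param cv_folds,cv_repeats Evaluation cross-validation setup (default
#'   10-fold, 1 repeat).
#' @param seed Integer seed governing every fold assignment.
#' @inheritParams encode_windows
#' @inheritParams svm_train
#' @return A `site_pipeline` list: `model` (a `site_model` with the encoder
#'   configuration embedded, ready for [predict_sites()]), `selection`
#'   (a `site_selection` or `NULL`), `report` (a `site_cv` evaluated at the
#'   tuned hyperparameters on the selected features), and `config`.
#' @export
train_pipeline <- function(records, width = 41L, kmer_sizes = c(2L, 3L, 4L),
                           lambda = 6L, w = 0.1, overlap = TRUE,
                           properties = dinuc_property_table(),
                           select = TRUE, dims = NULL,
                           selection_folds = 5L,
                           selection_mode = "paper",
                           costs = 2^seq(-5, 15, 2),
                           gammas = 2^seq(-15, 3, 2), grid_folds = 5L,
                           cv_folds = 10L, cv_repeats = 1L,
                           kernel = "radial", calibration_folds = 3L,
                           seed = 1L) {
  fused <- encode_windows(records, width = width, kmer_sizes = kmer_sizes,
                          lambda = lambda, w = w, overlap = overlap,
                          properties = properties)
  selection <- NULL
  working <- fused
  if (isTRUE(select)) {
    selection <- incremental_select(fused, dims = dims,
                                    folds = selection_folds,
                                    seed = seed, mode = selection_mode,
                                    kernel = kernel)
    working <- select_features(fused, selection)
  }
  model <- grid_search_train(working, costs = costs, gammas = gammas,
                             folds = grid_folds, kernel = kernel,
                             calibration_folds = calibration_folds,
                             seed = seed)
  model$encoding <- list(width = width, kmer_sizes = kmer_sizes,
                         lambda = lambda, w = w, overlap = overlap,
                         properties = properties)
  report <- cross_validate(working, folds = cv_folds, repeats = cv_repeats,
                           seed = seed, cost = model$cost,
                           gamma = model$gamma, kernel = kernel,
                           calibration_folds = calibration_folds)
  structure(
    list(
      model = model, selection = selection, report = report,
      config = list(width = width, kmer_sizes = kmer_sizes, lambda = lambda,
                    w = w, overlap = overlap, select = select,
                    selection_folds = selection_folds,
                    selection_mode = selection_mode,
                    grid_folds = grid_folds, cv_folds = cv_folds,
                    cv_repeats = cv_repeats, kernel = kernel,
                    calibration_folds = calibration_folds,
                    seed = as.integer(seed))
    ),
    class = "site_pipeline"
  )
}

#' @export
print.site_pipeline <- function(x, ...) {
  cat("6mA site prediction pipeline\n")
  if (!is.null(x$selection)) {
    cat(sprintf("  selection: %d of %d features kept\n",
                x$selection$optimal_dim, nrow(x$selection$ranking)))
  } else {
    cat("  selection: none (all features kept)\n")
  }
  cat(sprintf("  SVM: %s kernel, cost = %g, gamma = %g\n",
              x$model$kernel, x$model$cost, x$model$gamma))
  print(x$report)
  invisible(x)
}

#' Write a feature frame as TSV
#'
#' First columns `id` and `label`, then one named column per feature.
#'
#' @param data A feature frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a feature frame written by [write_feature_tsv()]
#'
#' @param path Path to the TSV.
#' @return A feature frame tibble.
#' @export
read_feature_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    label = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    abort("feature TSV must have `id` and `label` columns",
          class = "methsite_validation_error")
  }
  tab
}
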