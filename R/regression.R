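#' Calibration / validation split
#'
#' Seeded uniform random partition without replacement. When a stratum label
#' is supplied (here: maturity class) the calibration count is allocated
#' across strata by largest remainder, so both sets cover every maturity.
#'
#' @param n number of samples.
#' @param n_calibration calibration-set size (< n); default 90 of 120.
#' @param seed integer seed.
#' @param strata optional length-`n` label vector for stratified splitting.
#' @return object of class `split_plan`: list with sorted integer id vectors
#'   `calibration` and `validation` (disjoint, union = `1:n`).
#' @export
split_samples <- function(n, n_calibration = 90L, seed = 1L, strata = NULL) {
  n <- as.integer(n)
  n_calibration <- as.integer(n_calibration)
  if (n_calibration >= n || n_calibration < 1L)
    invalid_parameter("n_calibration must be in [1, n - 1]")
  set.seed(as.integer(seed))
  if (is.null(strata)) {
    cal <- sort(sample.int(n, n_calibration))
  } else {
    if (length(strata) != n) invalid_parameter("strata length must equal n")
    strata <- as.character(strata)
    groups <- split(seq_len(n), strata)
    exact <- vapply(groups, length, 0L) * n_calibration / n
    take <- floor(exact)
    rem <- n_calibration - sum(take)
    if (rem > 0) {
      extra <- order(exact - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1L
    }
    cal <- sort(unlist(Map(function(ids, k) {
      if (k >= length(ids)) ids else sample(ids, k)
    }, groups, take), use.names = FALSE))
  }
  structure(list(calibration = cal,
                 validation = setdiff(seq_len(n), cal),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Random forest SSC regressor
#'
#' Ensemble of CART regression trees on bootstrap resamples with random
#' feature subsets per split; the prediction is the mean over trees. Thin,
#' seeded wrapper around [randomForest::randomForest()] with regression-forest
#' defaults (`mtry = dim / 3`).
#'
#' @param features `samples x dim` numeric matrix.
#' @param ssc SSC targets (degrees Brix) aligned with rows.
#' @param n_trees ensemble size (default 500).
#' @param seed integer seed.
#' @param mtry features tried per split; default `max(1, floor(dim / 3))`.
#' @param nodesize minimum terminal-node size (default 5).
#' @param bootstrap draw bootstrap resamples (default `TRUE`); `FALSE` grows
#'   every tree on the full sample.
#' @return object of class `ssc_rf`.
#' @export
fit_rf <- function(features, ssc, n_trees = 500L, seed = 1L, mtry = NULL,
                   nodesize = 5L, bootstrap = TRUE) {
  features <- as.matrix(features)
  if (nrow(features) != length(ssc))
    invalid_input("feature rows must align with ssc")
  if (anyNA(features) || !all(is.finite(features)))
    invalid_input("features contain NA or non-finite values")
  if (n_trees < 1L) invalid_parameter("n_trees must be >= 1")
  mtry <- mtry %||% max(1L, floor(ncol(features) / 3))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = features, y = as.numeric(ssc), ntree = as.integer(n_trees),
    mtry = mtry, nodesize = nodesize, replace = bootstrap,
    sampsize = if (bootstrap) nrow(features) else nrow(features))
  structure(list(rf = rf, seed = as.integer(seed), n_trees = as.integer(n_trees)),
            class = "ssc_rf")
}

#' @export
predict.ssc_rf <- function(object, newdata, ...) {
  as.vector(stats::predict(object$rf, as.matrix(newdata)))
}

#' Per-tree predictions of a random forest
#'
#' @param model an [fit_rf()] handle.
#' @param newdata feature matrix.
#' @return `samples x trees` matrix of individual tree predictions.
#' @export
predict_trees <- function(model, newdata) {
  stats::predict(model$rf, as.matrix(newdata), predict.all = TRUE)$individual
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. A constant `y` makes the
#' metric undefined and raises an error rather than returning 0.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions, same length.
#' @return scalar `<= 1`.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) invalid_input("y and yhat lengths differ")
  if (length(y) < 2L) invalid_input("need at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) undefined_metric("R-squared undefined for constant y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean squared error
#'
#' @param y observed values (length >= 1).
#' @param yhat predictions, same length.
#' @return scalar `>= 0`, in the units of `y` (degrees Brix here).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) invalid_input("y and yhat lengths differ")
  if (length(y) == 0L) invalid_input("need at least one observation")
  sqrt(mean((y - yhat)^2))
}

#' Default SAE structure sweep
#'
#' The nine structures evaluated by the comparison harness: three per feature
#' kind, each listing input dim and three stacked hidden widths.
#'
#' @return named list of character vectors keyed by feature kind.
#' @export
default_structures <- function() {
  list(spectral = c("453-300-150-40", "453-350-150-50", "453-350-200-60"),
       image = c("784-600-400-40", "784-550-450-70", "784-350-210-90"),
       fusion = c("1237-750-300-40", "1237-600-460-90", "1237-650-310-130"))
}

#' Evaluation configuration
#'
#' @param train a [train_config()] used for every SAE fit.
#' @param n_trees,nodesize random-forest settings (see [fit_rf()]).
#' @param n_calibration calibration-set size (default 90).
#' @param seed seed for the split and the forests.
#' @param features a [feature_config()].
#' @return list of class `eval_config`.
#' @export
eval_config <- function(train = train_config(), n_trees = 500L, nodesize = 5L,
                        n_calibration = 90L, seed = 1L,
                        features = feature_config()) {
  structure(list(train = train, n_trees = as.integer(n_trees),
                 nodesize = as.integer(nodesize),
                 n_calibration = as.integer(n_calibration),
                 seed = as.integer(seed), features = features),
            class = "eval_config")
}

# Fit SAE + RF for one (feature matrix, structure) and score both sets.
evaluate_structure <- function(f_all, ssc, plan, structure, cfg) {
  dims <- parse_structure(structure)
  if (dims[1L] != ncol(f_all))
    invalid_parameter(sprintf(
      "structure '%s' expects input dim %d but features have %d",
      structure_string(dims), dims[1L], ncol(f_all)))
  cal <- plan$calibration
  val <- plan$validation
  norm <- feature_normalize(f_all[cal, , drop = FALSE])
  f_cal <- norm$values
  f_val <- feature_normalize(f_all[val, , drop = FALSE], norm$stats)$values
  sae <- fit_sae(f_cal, dims, targets = ssc[cal], cfg = cfg$train)
  z_cal <- deep_features(sae, f_cal)
  z_val <- deep_features(sae, f_val)
  rf <- fit_rf(z_cal, ssc[cal], n_trees = cfg$n_trees, seed = cfg$seed,
               nodesize = cfg$nodesize)
  p_cal <- predict(rf, z_cal)
  p_val <- predict(rf, z_val)
  list(sae = sae, rf = rf, stats = norm$stats,
       metrics = data.frame(structure = structure_string(dims),
                            r2_cal = r_squared(ssc[cal], p_cal),
                            rmse_cal = rmse(ssc[cal], p_cal),
                            r2_val = r_squared(ssc[val], p_val),
                            rmse_val = rmse(ssc[val], p_val),
                            stringsAsFactors = FALSE))
}

#' Compare feature sets and SAE structures
#'
#' For every (feature kind, structure) pair: extract features, min-max
#' normalize with calibration-set statistics, fit the stacked autoencoder
#' (pretraining + supervised fine-tuning on calibration SSC), extract deep
#' features, fit the random forest on the calibration set, and score both
#' sets — producing one evaluation row per pair.
#'
#' @param dataset list of sample records from [generate_dataset()], or a
#'   precomputed [dataset_features()] list.
#' @param structures named list of structure strings per feature kind (default
#'   [default_structures()]).
#' @param cfg an [eval_config()].
#' @return object of class `evaluation_report`: data.frame with columns
#'   `feature_kind`, `structure`, `r2_cal`, `rmse_cal`, `r2_val`, `rmse_val`.
#' @export
compare_feature_sets <- function(dataset, structures = default_structures(),
                                 cfg = eval_config()) {
  feats <- if (!is.null(dataset$spectral)) dataset
           else dataset_features(dataset, cfg$features)
  n <- length(feats$ssc)
  plan <- split_samples(n, cfg$n_calibration, seed = cfg$seed,
                        strata = feats$maturity)
  rows <- list()
  for (kind in names(structures)) {
    f_all <- feats[[kind]]
    if (is.null(f_all))
      invalid_parameter(sprintf("unknown feature kind '%s'", kind))
    for (structure in structures[[kind]]) {
      res <- evaluate_structure(f_all, feats$ssc, plan, structure, cfg)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(feature_kind = kind, stringsAsFactors = FALSE),
              res$metrics)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("evaluation_report", "data.frame")
  attr(report, "split") <- plan
  report
}

#' Write an evaluation report as CSV
#'
#' @param report an [compare_feature_sets()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  tryCatch(utils::write.csv(as.data.frame(report), path, row.names = FALSE),
           error = function(e) io_error(conditionMessage(e)))
  invisible(path)
}
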