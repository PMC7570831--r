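#' Pipeline configuration
#'
#' One declarative object driving [run_pipeline()]: phantom generation,
#' feature extraction, SAE structures per feature kind, training and forest
#' settings, split sizes and the master seed. Validated up front (structure
#' input dims are checked against the feature dims implied by the phantom and
#' feature configs) so misconfigurations fail before any compute.
#'
#' @param out_dir output directory for all artifacts.
#' @param n number of phantom samples (default 120).
#' @param maturity_counts immature/semi_mature/mature counts (30/50/40).
#' @param ssc_mean,ssc_sd,ssc_range SSC sampling targets (9.29, 2.17,
#'   `c(6, 14.1)` degrees Brix).
#' @param phantom a [phantom_config()].
#' @param roi_size ROI side length (`NULL` = auto from phantom size).
#' @param features a [feature_config()].
#' @param structures named list of structure strings per feature kind.
#' @param train a [train_config()].
#' @param n_trees,nodesize random-forest settings.
#' @param n_calibration calibration-set size (default 90).
#' @param visualize render pixel-wise SSC maps for one sample per maturity.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "peachsae-out", n = 120L,
                            maturity_counts = c(immature = 30L,
                                                semi_mature = 50L,
                                                mature = 40L),
                            ssc_mean = 9.29, ssc_sd = 2.17,
                            ssc_range = c(6, 14.1),
                            phantom = phantom_config(),
                            roi_size = NULL,
                            features = feature_config(),
                            structures = default_structures(),
                            train = train_config(),
                            n_trees = 500L, nodesize = 5L,
                            n_calibration = 90L,
                            visualize = TRUE, seed = 1L) {
  cfg <- structure(list(out_dir = out_dir, n = as.integer(n),
                        maturity_counts = maturity_counts,
                        ssc_mean = ssc_mean, ssc_sd = ssc_sd,
                        ssc_range = ssc_range, phantom = phantom,
                        roi_size = roi_size, features = features,
                        structures = structures, train = train,
                        n_trees = as.integer(n_trees),
                        nodesize = as.integer(nodesize),
                        n_calibration = as.integer(n_calibration),
                        visualize = isTRUE(visualize),
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

expected_feature_dims <- function(phantom, features) {
  spectral <- phantom$n_bands - features$trim_front - features$trim_back
  image <- features$image_side^2
  c(spectral = spectral, image = image, fusion = spectral + image)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n != sum(cfg$maturity_counts))
    invalid_parameter("n must equal sum(maturity_counts)")
  if (cfg$n_calibration >= cfg$n)
    invalid_parameter("n_calibration must be < n")
  dims <- expected_feature_dims(cfg$phantom, cfg$features)
  for (kind in names(cfg$structures)) {
    if (!kind %in% names(dims))
      invalid_parameter(sprintf("unknown feature kind '%s'", kind))
    for (s in cfg$structures[[kind]]) {
      in_dim <- parse_structure(s)[1L]
      if (in_dim != dims[[kind]])
        invalid_parameter(sprintf(
          "structure '%s' input dim %d != %s feature dim %d",
          s, in_dim, kind, dims[[kind]]))
    }
  }
  invisible(cfg)
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[peachsae] %-12s %6.1fs  %s", stage,
                  as.numeric(Sys.time()) - t0, paste0(..., collapse = "")))
}

#' Run the full phantom-to-report pipeline
#'
#' generate -> calibrate -> featurize -> SAE train -> RF evaluate ->
#' visualize. Writes the SSC ground truth, per-kind feature matrices
#' (CSV), the structure-sweep evaluation report (CSV), serialized best
#' spectral SAE/RF models, and pseudo-color SSC maps (PNG, one sample per
#' maturity). Rerunning with an identical config reproduces the report
#' exactly.
#'
#' @param cfg a [pipeline_config()].
#' @return the [compare_feature_sets()] evaluation report, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  dataset <- generate_dataset(cfg$n, cfg$maturity_counts, cfg$ssc_mean,
                              cfg$ssc_sd, cfg$ssc_range, cfg$phantom,
                              seed = cfg$seed, roi_size = cfg$roi_size)
  truth <- dataset_truth(dataset)
  utils::write.csv(truth, file.path(cfg$out_dir, "ssc_ground_truth.csv"),
                   row.names = FALSE)
  stage_log("generate", t0, sprintf("n=%d seed=%d", cfg$n, cfg$seed))

  feats <- dataset_features(dataset, cfg$features)
  for (kind in c("spectral", "image", "fusion")) {
    df <- data.frame(sample_id = feats$sample_id, feats[[kind]])
    utils::write.csv(df, file.path(cfg$out_dir, sprintf("features_%s.csv", kind)),
                     row.names = FALSE)
  }
  stage_log("featurize", t0,
            sprintf("dims=%s", paste(vapply(feats[c("spectral", "image", "fusion")],
                                            ncol, 0L), collapse = "/")))

  ecfg <- eval_config(train = cfg$train, n_trees = cfg$n_trees,
                      nodesize = cfg$nodesize,
                      n_calibration = cfg$n_calibration, seed = cfg$seed,
                      features = cfg$features)
  report <- compare_feature_sets(feats, cfg$structures, ecfg)
  write_report(report, file.path(cfg$out_dir, "evaluation_report.csv"))
  stage_log("evaluate", t0, sprintf("%d rows", nrow(report)))

  if (cfg$visualize && "spectral" %in% names(cfg$structures)) {
    spec_rows <- report[report$feature_kind == "spectral", ]
    best <- spec_rows$structure[which.max(spec_rows$r2_val)]
    plan <- attr(report, "split")
    norm <- feature_normalize(feats$spectral[plan$calibration, , drop = FALSE])
    sae <- fit_sae(norm$values, best, targets = feats$ssc[plan$calibration],
                   cfg = cfg$train)
    rf <- fit_rf(deep_features(sae, norm$values), feats$ssc[plan$calibration],
                 n_trees = cfg$n_trees, seed = cfg$seed,
                 nodesize = cfg$nodesize)
    save_sae(sae, file.path(cfg$out_dir, "sae_spectral.rds"))
    saveRDS(rf, file.path(cfg$out_dir, "rf_spectral.rds"))
    for (mat in unique(truth$maturity)) {
      i <- which(truth$maturity == mat)[1L]
      map <- pixelwise_predict(dataset[[i]]$cube, sae, rf,
                               stats = norm$stats, fc = cfg$features,
                               maturity = mat)
      render_pseudocolor(map, path = file.path(
        cfg$out_dir, sprintf("ssc_map_%s_%s.png", mat, truth$sample_id[i])))
    }
    stage_log("visualize", t0, sprintf("model=%s", best))
  }
  invisible(report)
}

#' Build a pipeline config from a YAML file
#'
#' Reads a flat YAML document whose keys mirror the [pipeline_config()],
#' [phantom_config()], [feature_config()] and [train_config()] arguments
#' (nested under `phantom:`, `features:`, `train:`), fills in defaults for
#' anything omitted, and validates before returning.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's.
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) io_error(sprintf("no such config: '%s'", path))
  y <- yaml::read_yaml(path) %||% list()
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(y)[names(y) %in% c("FALSE", "false")] <- "n"
  build <- function(fn, args) do.call(fn, args[names(args) %in% names(formals(fn))])
  top <- y[setdiff(names(y), c("phantom", "features", "train"))]
  top$phantom <- build(phantom_config, y$phantom %||% list())
  top$features <- build(feature_config, y$features %||% list())
  top$train <- build(train_config, y$train %||% list())
  if (!is.null(top$maturity_counts))
    top$maturity_counts <- unlist(top$maturity_counts)
  if (!is.null(seed)) top$seed <- as.integer(seed)
  build(pipeline_config, top)
}
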