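# End-to-end orchestration: simulate -> window -> features -> PSO-train the
# fuzzy selector -> evaluate, plus the single-index baseline selectors used
# for comparison.

#' Single-index baseline selection and evaluation
#'
#' Ranks features by one filter index computed on the training split,
#' selects the top `k` (or, for `method = "all"`, every feature), then
#' trains and evaluates the same SVM as the fuzzy path on the validation
#' split.
#'
#' @param method One of `"fisher"`, `"ttest"`, `"corr"`, `"mi"`, `"all"`.
#'   The correlation ranks by absolute value.
#' @param k Number of top-ranked features to keep (ignored for `"all"`);
#'   must be in `1..ncol(x)`.
#' @param x Feature matrix (rows = windows).
#' @param y Binary labels (0/1).
#' @param split List with `train`/`val` index vectors, e.g. from
#'   [stratified_split()]; `NULL` makes a seeded 70/30 split.
#' @param svm_cfg Optional classifier settings, see [train_classifier()].
#' @param seed Seed for the default split.
#' @return List with `method`, `selected` (column indices), and `report`
#'   (an `eval_report` on the validation split).
#' @export
run_baseline <- function(method, k = 6L, x, y, split = NULL,
                         svm_cfg = list(), seed = 1L) {
  method <- match.arg(method, c("fisher", "ttest", "corr", "mi", "all"))
  if (is.null(split)) split <- stratified_split(y, 0.7, seed)
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  if (method == "all") {
    cols <- seq_len(ncol(x))
  } else {
    k <- as.integer(k)
    if (k < 1L || k > ncol(x)) {
      stop("k must be between 1 and the number of features", call. = FALSE)
    }
    idx <- switch(method,
                  fisher = apply(x_tr, 2, fisher_index, y = y_tr),
                  ttest = apply(x_tr, 2, ttest_index, y = y_tr),
                  corr = abs(suppressWarnings(
                    apply(x_tr, 2, correlation_index, y = y_tr))),
                  mi = apply(x_tr, 2, mutual_information_index, y = y_tr))
    cols <- order(idx, decreasing = TRUE)[seq_len(k)]
  }
  fit <- do.call(train_classifier,
                 c(list(x = x_tr[, cols, drop = FALSE], y = y_tr), svm_cfg))
  report <- evaluate_classifier(fit, x[split$val, cols, drop = FALSE],
                                y[split$val])
  list(method = method, selected = sort(cols), report = report)
}

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()],
#' with sections `scenario`, `window`, `features`, `fuzzy`, `pso`, `svm`
#' and `eval`. Any entry can be overridden via `...` (named lists are
#' merged one level deep).
#'
#' @param ... Named sections to merge over the defaults.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    scenario = list(duration_s = 300, fs = 60, track_curve_amp = 20,
                    track_curve_period_s = 30, awake_correction_rate = 4,
                    awake_correction_amp = 0.5, drowsy_correction_rate = 0.25,
                    drowsy_correction_amp = 8, drift_rate = 2,
                    noise_sd = 0.1),
    window = list(length_s = 3.0, overlap_frac = 0.5),
    features = list(mi_bins = 10),
    fuzzy = list(threshold = 0.5, s0 = 0.2125),
    pso = list(c1 = 2, c2 = 2, n_particles = 15, inertia = 0.95,
               max_iter = 20, v_clamp_frac = 0.2, penalty_empty = 1.0,
               stall_iter = 10, stall_tol = 1e-6),
    svm = list(cost = 1, kernel = "radial"),
    eval = list(train_frac = 0.7),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Run the full drowsiness-detection pipeline
#'
#' Executes simulate -> window/detrend -> feature extraction -> min-max
#' normalization -> PSO training of the fuzzy selector -> SVM evaluation on
#' the validation split, writing every artifact to `out_dir`: `trace.csv`,
#' `features.csv`, `params.yaml`, `history.csv`, `report.json`, and a
#' `manifest.json` recording the configuration hash, the master seed and
#' stage seeds. One master seed (`config$seed`) fans out to per-stage seeds
#' via fixed offsets, so the whole run — including the report — is
#' bit-identical when repeated.
#'
#' @param config Nested configuration list, see [default_config()]; may also
#'   be the path of a YAML file with the same layout.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the trained `params`, the validation
#'   `report`, the `selection` on the training split, the feature set and
#'   the artifact paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master <- as.integer(config$seed)
  stage_seed <- function(k) (master * 101L + k) %% 2000000000L

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate ------------------------------------------------------------
  trace <- run_stage("simulate", {
    sc <- do.call(scenario_config,
                  c(config$scenario, list(seed = stage_seed(1L))))
    generate_trace(sc)
  })
  trace_path <- file.path(out_dir, "trace.csv")
  write_trace_csv(trace, trace_path)

  # --- preprocess + features ----------------------------------------------
  fset <- run_stage("features", {
    spec <- window_spec_seconds(config$window$length_s,
                                config$window$overlap_frac,
                                fs = config$scenario$fs)
    extract_features(slide_windows(trace, spec), fs = config$scenario$fs)
  })
  feat_path <- file.path(out_dir, "features.csv")
  write_features_csv(fset, feat_path)

  # --- normalize + train ---------------------------------------------------
  # normalization bounds come from the training split only; validation
  # values outside them are clipped by apply_normalizer
  split <- stratified_split(fset$y, config$eval$train_frac,
                            seed = stage_seed(3L))
  norm <- fit_normalizer(fset$x[split$train, , drop = FALSE])
  xn <- apply_normalizer(fset$x, norm)
  trained <- run_stage("train", {
    cfg <- do.call(pso_config, c(config$pso, list(seed = stage_seed(2L))))
    optimize_selector(xn, fset$y, cfg, svm_cfg = config$svm,
                      threshold = config$fuzzy$threshold, split = split)
  })
  params_path <- file.path(out_dir, "params.yaml")
  write_params_yaml(trained$params, params_path)
  hist_path <- file.path(out_dir, "history.csv")
  utils::write.csv(trained$history, hist_path, row.names = FALSE,
                   quote = FALSE)

  # --- evaluate ------------------------------------------------------------
  report <- run_stage("evaluate", {
    cols <- which(trained$selection$selected)
    if (length(cols) == 0) stop("trained selector selected no features")
    fit <- do.call(train_classifier,
                   c(list(x = xn[split$train, cols, drop = FALSE],
                          y = fset$y[split$train]), config$svm))
    evaluate_classifier(fit, xn[split$val, cols, drop = FALSE],
                        fset$y[split$val])
  })
  report_path <- file.path(out_dir, "report.json")
  write_report_json(report, report_path)

  # --- manifest ------------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file, precision = 15)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    master_seed = master,
    stage_seeds = list(simulate = stage_seed(1L), train = stage_seed(2L),
                       split = stage_seed(3L)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("steerwake")),
    artifacts = c("trace.csv", "features.csv", "params.yaml", "history.csv",
                  "report.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(params = trained$params, report = report,
                 selection = trained$selection, features = fset,
                 history = trained$history,
                 paths = list(trace = trace_path, features = feat_path,
                              params = params_path, history = hist_path,
                              report = report_path,
                              manifest = file.path(out_dir, "manifest.json"))))
}
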