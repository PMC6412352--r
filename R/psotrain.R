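# Global-best particle swarm optimization of the fuzzy-selector parameters
# against the validation error of the SVM wrapper.
#
# The search position is the flattened parameter vector of length
# 105 = 12 centres + 12 widths + 81 relaxed consequents. Consequents are
# searched on the continuous unit interval and snapped to {0, 0.5, 1} at
# decode time; centres are re-sorted per input so the L <= M <= H invariant
# always holds.

#' PSO configuration
#'
#' Defaults follow the swarm settings used for training the selector:
#' cognitive and social coefficients 2, population 50, constant inertia
#' 0.95, with velocities clamped to a fraction of each coordinate's box
#' width. Stopping is at `max_iter` iterations or after `stall_iter`
#' iterations whose global-best improvement is below `stall_tol`.
#'
#' @param c1 Cognitive coefficient (default 2).
#' @param c2 Social coefficient (default 2).
#' @param n_particles Swarm size (default 50).
#' @param inertia Constant inertia weight (default 0.95).
#' @param max_iter Iteration budget (default 100).
#' @param v_clamp_frac Velocity clamp as a fraction of the box width per
#'   coordinate (default 0.2).
#' @param seed Integer seed; fixes the whole run.
#' @param penalty_empty Objective value charged when no feature is selected
#'   (default 1.0).
#' @param stall_iter Stall window for early stopping (default 20).
#' @param stall_tol Minimum global-best improvement counted as progress
#'   (default 1e-6).
#' @return A `pso_config` object.
#' @export
pso_config <- function(c1 = 2, c2 = 2, n_particles = 50L, inertia = 0.95,
                       max_iter = 100L, v_clamp_frac = 0.2, seed = 1L,
                       penalty_empty = 1.0, stall_iter = 20L,
                       stall_tol = 1e-6) {
  stopifnot(c1 > 0, c2 > 0, inertia > 0, v_clamp_frac > 0,
            penalty_empty > 0, n_particles >= 2)
  if (max_iter <= 0) stop("max_iter must be positive", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, n_particles = as.integer(n_particles),
                 inertia = inertia, max_iter = as.integer(max_iter),
                 v_clamp_frac = v_clamp_frac, seed = as.integer(seed),
                 penalty_empty = penalty_empty,
                 stall_iter = as.integer(stall_iter), stall_tol = stall_tol),
            class = "pso_config")
}

# Box bounds of the flattened fuzzy parameter vector.
fuzzy_box <- function() {
  list(lower = c(rep(0, 12), rep(0.05, 12), rep(0, 81)),
       upper = rep(1, 105))
}

#' Encode fuzzy parameters as a PSO position
#'
#' Flattens to `c` (12, input-major: the L/M/H triple of input 1 first),
#' then `s` (12), then `alpha` (81).
#'
#' @param params A [fuzzy_params()] object.
#' @return Numeric vector of length 105.
#' @export
encode_params <- function(params) {
  c(as.numeric(t(params$c)), as.numeric(t(params$s)), params$alpha)
}

#' Decode a PSO position into fuzzy parameters
#'
#' Each input's centre triple is sorted ascending to restore the
#' L <= M <= H invariant, and each relaxed consequent is snapped to the
#' nearest of `{0, 0.5, 1}` with ties resolved towards the larger value
#' (0.25 snaps to 0.5, 0.75 to 1).
#'
#' @param position Numeric vector of length 105.
#' @return A [fuzzy_params()] object.
#' @export
decode_params <- function(position) {
  stopifnot(length(position) == 105)
  cmat <- matrix(position[1:12], 4, 3, byrow = TRUE)
  cmat <- t(apply(cmat, 1, sort))
  smat <- matrix(position[13:24], 4, 3, byrow = TRUE)
  smat[smat <= 0] <- 0.05
  a <- position[25:105]
  alpha <- ifelse(a < 0.25, 0, ifelse(a < 0.75, 0.5, 1))
  fuzzy_params(cmat, smat, alpha)
}

#' Wrapper objective: half squared error of the SVM on a validation split
#'
#' Selects features on the training split with the candidate fuzzy
#' parameters, trains the margin classifier on the selected training
#' columns, predicts binary labels on the validation split, and returns the
#' mean of `(yhat - y)^2 / 2` — i.e. half the validation misclassification
#' rate. An empty selection (or classifier failure) costs `penalty_empty`.
#'
#' @param params A [fuzzy_params()] object.
#' @param x_train,y_train Training features/labels.
#' @param x_val,y_val Validation features/labels.
#' @param svm_cfg Optional classifier settings, see [train_classifier()].
#' @param penalty_empty Cost of an empty selection (default 1.0).
#' @param scaled_train Optional precomputed scaled filter indexes of the
#'   training split (they do not depend on the fuzzy parameters).
#' @return Scalar objective value, >= 0.
#' @export
objective <- function(params, x_train, y_train, x_val, y_val,
                      svm_cfg = list(), penalty_empty = 1.0,
                      scaled_train = NULL) {
  sel <- select_features(x_train, y_train, params, scaled = scaled_train)
  cols <- which(sel$selected)
  if (length(cols) == 0) return(penalty_empty)
  fit <- tryCatch(
    do.call(train_classifier,
            c(list(x = x_train[, cols, drop = FALSE], y = y_train), svm_cfg)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("classifier failure in objective; charging penalty_empty")
    return(penalty_empty)
  }
  yhat <- predict_labels(fit, x_val[, cols, drop = FALSE])
  mean(0.5 * (yhat - y_val)^2)
}

#' Minimize a function with global-best PSO
#'
#' Standard global-best PSO with constant inertia:
#' `v <- W v + C1 R1 (pbest - x) + C2 R2 (gbest - x)`, `x <- x + v`, with
#' per-coordinate uniform random factors R1, R2, velocities clamped to
#' `±v_clamp_frac` of the box width and positions clamped to the box.
#' Initial positions are uniform in the box; `init` rows, when given, seed
#' the first particles (warm start). Fully reproducible under `cfg$seed`.
#'
#' @param fn Objective taking a numeric vector, returning a scalar.
#' @param lower,upper Box bounds (equal-length numeric vectors).
#' @param cfg A [pso_config()].
#' @param init Optional matrix of warm-start positions (rows).
#' @return List with `par` (best position), `value` (best cost), and
#'   `history` (data frame `iter`, `gbest_cost`; iteration 0 is the initial
#'   evaluation).
#' @export
pso_minimize <- function(fn, lower, upper, cfg = pso_config(), init = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  np <- cfg$n_particles
  local_seed(cfg$seed)

  box_w <- upper - lower
  vmax <- cfg$v_clamp_frac * box_w
  x <- matrix(stats::runif(np * d), np, d)
  x <- sweep(sweep(x, 2, box_w, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), np)
    x[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  v <- matrix(0, np, d)

  cost <- apply(x, 1, fn)
  pbest <- x
  pbest_cost <- cost
  g <- which.min(pbest_cost)
  gbest <- pbest[g, ]
  gbest_cost <- pbest_cost[g]

  hist_cost <- numeric(cfg$max_iter + 1)
  hist_cost[1] <- gbest_cost
  par_hist <- matrix(NA_real_, cfg$max_iter + 1, d)
  par_hist[1, ] <- gbest
  stall <- 0L
  it_done <- 0L
  for (it in seq_len(cfg$max_iter)) {
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    v <- cfg$inertia * v + cfg$c1 * r1 * (pbest - x) +
      cfg$c2 * r2 * sweep(-x, 2, gbest, "+")
    v <- pmin(pmax(v, rep(-vmax, each = np)), rep(vmax, each = np))
    x <- x + v
    x <- pmin(pmax(x, rep(lower, each = np)), rep(upper, each = np))
    cost <- apply(x, 1, fn)
    better <- cost < pbest_cost
    pbest[better, ] <- x[better, , drop = FALSE]
    pbest_cost[better] <- cost[better]
    g <- which.min(pbest_cost)
    improvement <- gbest_cost - pbest_cost[g]
    if (improvement > 0) {
      gbest <- pbest[g, ]
      gbest_cost <- pbest_cost[g]
    }
    stall <- if (improvement > cfg$stall_tol) 0L else stall + 1L
    hist_cost[it + 1] <- gbest_cost
    par_hist[it + 1, ] <- gbest
    it_done <- it
    if (stall >= cfg$stall_iter) break
  }
  keep <- seq_len(it_done + 1)
  list(par = gbest, value = gbest_cost,
       history = data.frame(iter = 0:it_done, gbest_cost = hist_cost[keep]),
       par_history = par_hist[keep, , drop = FALSE])
}

#' Stratified train/validation split
#'
#' @param y Binary labels.
#' @param train_frac Fraction of each class assigned to training (default
#'   0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(y, train_frac = 0.7, seed = 1L) {
  local_seed(seed)
  idx <- seq_along(y)
  train <- unlist(lapply(unique(y), function(cl) {
    pool <- idx[y == cl]
    sample(pool, max(1L, round(train_frac * length(pool))))
  }))
  train <- sort(train)
  list(train = train, val = setdiff(idx, train))
}

#' Train the fuzzy selector by PSO
#'
#' Splits the data into stratified training and validation parts, then runs
#' global-best PSO over the 105 fuzzy parameters minimizing the wrapper
#' [objective()]. Particle 1 is warm-started at [default_params()], which
#' guarantees the trained objective never exceeds the untrained one. Filter
#' indexes of the training split are precomputed once (they are independent
#' of the fuzzy parameters), and classifier fits are cached per selected
#' feature subset.
#'
#' @param x Numeric feature matrix (rows = windows).
#' @param y Binary labels (0/1).
#' @param cfg A [pso_config()].
#' @param train_frac Training fraction of the stratified split (default
#'   0.7).
#' @param svm_cfg Optional classifier settings, see [train_classifier()].
#' @param threshold Selection threshold on importance degree (default 0.5).
#' @param split Optional list with `train`/`val` index vectors; by default a
#'   stratified split with `train_frac` seeded from `cfg$seed`.
#' @return List with `params` (trained [fuzzy_params()]), `history` (data
#'   frame `iter`, `gbest_cost`, `n_selected`), `split` (the index split),
#'   `value` (best objective), and `selection` (the final
#'   `selection_result` on the training split).
#' @export
optimize_selector <- function(x, y, cfg = pso_config(), train_frac = 0.7,
                              svm_cfg = list(), threshold = 0.5,
                              split = NULL) {
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (is.null(split)) split <- stratified_split(y, train_frac,
                                                seed = cfg$seed + 1L)
  x_tr <- x[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  x_va <- x[split$val, , drop = FALSE]
  y_va <- y[split$val]

  scaled_tr <- filter_indexes(x_tr, y_tr)$scaled
  cache <- new.env(parent = emptyenv())
  fn <- function(pos) {
    params <- decode_params(pos)
    sel <- select_features(params = params, threshold = threshold,
                           scaled = scaled_tr)
    cols <- which(sel$selected)
    if (length(cols) == 0) return(cfg$penalty_empty)
    key <- paste(cols, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- objective_on_cols(cols, x_tr, y_tr, x_va, y_va, svm_cfg,
                             cfg$penalty_empty)
    cache[[key]] <- val
    val
  }

  box <- fuzzy_box()
  res <- pso_minimize(fn, box$lower, box$upper, cfg,
                      init = matrix(encode_params(default_params()), 1))
  params <- decode_params(res$par)
  sel <- select_features(params = params, threshold = threshold,
                         scaled = scaled_tr)
  n_sel <- vapply(seq_len(nrow(res$par_history)), function(i) {
    p <- decode_params(res$par_history[i, ])
    sum(select_features(params = p, threshold = threshold,
                        scaled = scaled_tr)$selected)
  }, integer(1))
  history <- data.frame(iter = res$history$iter,
                        gbest_cost = res$history$gbest_cost,
                        n_selected = n_sel)
  list(params = params, history = history, split = split,
       value = res$value, selection = sel)
}

objective_on_cols <- function(cols, x_tr, y_tr, x_va, y_va, svm_cfg,
                              penalty_empty) {
  fit <- tryCatch(
    do.call(train_classifier,
            c(list(x = x_tr[, cols, drop = FALSE], y = y_tr), svm_cfg)),
    error = function(e) NULL)
  if (is.null(fit)) return(penalty_empty)
  yhat <- predict_labels(fit, x_va[, cols, drop = FALSE])
  mean(0.5 * (yhat - y_va)^2)
}
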