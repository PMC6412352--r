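# Zero-order Takagi-Sugeno fuzzy system fusing the four scaled filter
# indexes of a feature into one importance degree (ID) in [0, 1].
#
# Each of the four inputs (Fisher, correlation, t, MI) carries three Gaussian
# membership functions Low/Medium/High on the unit domain, giving a full
# 3^4 = 81-rule base. Each rule has a singleton consequent alpha in
# {0, 0.5, 1}; with product AND and firing-strength-weighted averaging no
# separate defuzzification step is needed.

FUZZY_INPUTS <- c("fisher", "corr", "ttest", "mi")

#' The 81-rule antecedent table
#'
#' Rules are ordered lexicographically over the antecedent tuple
#' (Fisher, correlation, t, MI) with levels L < M < H, the last input varying
#' fastest: rule 1 is (L,L,L,L), rule 2 (L,L,L,M), ..., rule 81 (H,H,H,H).
#' This ordering is part of the parameter-file contract.
#'
#' @return Integer matrix 81 x 4 with entries 1 (L), 2 (M), 3 (H); columns
#'   named after the four inputs.
#' @export
rule_table <- function() {
  g <- expand.grid(mi = 1:3, ttest = 1:3, corr = 1:3, fisher = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  a <- as.matrix(g[, c("fisher", "corr", "ttest", "mi")])
  storage.mode(a) <- "integer"
  rownames(a) <- NULL
  a
}

#' Construct fuzzy-selector parameters
#'
#' @param c Numeric 4 x 3 matrix of Gaussian membership-function centres
#'   (rows = inputs, columns = L, M, H); each row must be non-decreasing.
#' @param s Numeric 4 x 3 matrix of positive membership widths.
#' @param alpha Numeric vector of 81 singleton consequents, each in
#'   `{0, 0.5, 1}`, in [rule_table()] order.
#' @return A `fuzzy_params` object.
#' @export
fuzzy_params <- function(c, s, alpha) {
  c <- matrix(as.numeric(c), 4, 3)
  s <- matrix(as.numeric(s), 4, 3)
  alpha <- as.numeric(alpha)
  if (any(s <= 0)) stop("invalid fuzzy params: widths s must be positive",
                        call. = FALSE)
  if (length(alpha) != 81 || !all(alpha %in% c(0, 0.5, 1))) {
    stop("invalid fuzzy params: alpha must be 81 values in {0, 0.5, 1}",
         call. = FALSE)
  }
  if (any(c[, 1] > c[, 2] | c[, 2] > c[, 3])) {
    stop("invalid fuzzy params: centres must satisfy c_L <= c_M <= c_H",
         call. = FALSE)
  }
  rownames(c) <- rownames(s) <- FUZZY_INPUTS
  colnames(c) <- colnames(s) <- c("L", "M", "H")
  structure(list(c = c, s = s, alpha = alpha), class = "fuzzy_params")
}

#' Default (untrained) fuzzy-selector parameters
#'
#' Three Gaussians per input centred at 0, 0.5 and 1 with common width
#' 0.2125, so neighbouring functions cross near membership 0.5 on the unit
#' domain. Consequents are initialised by an antecedent-majority heuristic:
#' a rule whose antecedents include at least three High labels gets
#' `alpha = 1`, at least three Low labels `alpha = 0`, anything else 0.5.
#' These are the starting point for PSO training.
#'
#' @param s0 Initial membership width (default 0.2125).
#' @return A [fuzzy_params()] object.
#' @export
default_params <- function(s0 = 0.2125) {
  rules <- rule_table()
  n_h <- rowSums(rules == 3L)
  n_l <- rowSums(rules == 1L)
  alpha <- ifelse(n_h >= 3, 1, ifelse(n_l >= 3, 0, 0.5))
  fuzzy_params(c = matrix(c(0, 0.5, 1), 4, 3, byrow = TRUE),
               s = matrix(s0, 4, 3), alpha = alpha)
}

#' Gaussian membership function
#'
#' `exp(-((h - c) / s)^2 / 2)`, the degree to which input value `h` belongs
#' to the linguistic label with centre `c` and width `s`.
#'
#' @param h Input value(s).
#' @param c Centre.
#' @param s Width, > 0.
#' @return Membership in `(0, 1]`.
#' @export
#' @examples
#' membership(0.5, 0.5, 0.2125)  # 1
#' membership(0.7125, 0.5, 0.2125)  # exp(-0.5)
membership <- function(h, c, s) {
  if (any(s <= 0)) stop("invalid fuzzy params: width s must be positive",
                        call. = FALSE)
  exp(-0.5 * ((h - c) / s)^2)
}

#' Importance degree of one feature
#'
#' Evaluates the 81-rule Takagi-Sugeno system: each rule's firing strength is
#' the product of its four antecedent memberships, and the output is the
#' firing-strength-weighted average of the singleton consequents,
#' `ID = sum(w_l alpha_l) / sum(w_l)`. Gaussian memberships are strictly
#' positive, so the denominator never vanishes and the result lies between
#' the smallest and largest consequent.
#'
#' @param h Numeric vector of 4 scaled filter indexes (Fisher, correlation,
#'   t, MI); values are clipped to `[0, 1]`.
#' @param params A [fuzzy_params()] object.
#' @return Importance degree in `[0, 1]`.
#' @export
importance_degree <- function(h, params) {
  drop(importance_degree_matrix(matrix(h, 1), params))
}

#' Importance degrees for a matrix of scaled indexes
#'
#' Vectorized form of [importance_degree()]: one row per feature.
#'
#' @param H Numeric matrix, features x 4, scaled indexes in `[0, 1]`
#'   (clipped otherwise).
#' @param params A [fuzzy_params()] object.
#' @return Numeric vector of importance degrees, one per row of `H`.
#' @export
importance_degree_matrix <- function(H, params) {
  stopifnot(ncol(H) == 4)
  H <- pmin(pmax(H, 0), 1)
  rules <- rule_table()
  # memberships per input and level: list over inputs of n x 3 matrices
  M <- lapply(1:4, function(j) {
    outer(H[, j], seq_len(3), function(h, k) {
      membership(h, params$c[j, k], params$s[j, k])
    })
  })
  W <- M[[1]][, rules[, 1], drop = FALSE] *
    M[[2]][, rules[, 2], drop = FALSE] *
    M[[3]][, rules[, 3], drop = FALSE] *
    M[[4]][, rules[, 4], drop = FALSE]
  as.numeric((W %*% params$alpha) / rowSums(W))
}

#' Select features by fuzzy importance degree
#'
#' Computes the four filter indexes of every feature against the labels,
#' rescales them to the unit interval, evaluates the fuzzy importance degree,
#' and keeps the features whose ID strictly exceeds the threshold.
#'
#' @param x Numeric feature matrix (rows = windows).
#' @param y Binary labels (0/1).
#' @param params A [fuzzy_params()] object.
#' @param threshold Selection threshold on ID (default 0.5; strict
#'   inequality).
#' @param scaled Optional precomputed scaled-index matrix (features x 4),
#'   e.g. from [filter_indexes()]; when supplied `x` and `y` are not used.
#' @return A `selection_result`: list with `importance` (named numeric),
#'   `threshold`, and logical `selected`.
#' @export
select_features <- function(x = NULL, y = NULL, params = default_params(),
                            threshold = 0.5, scaled = NULL) {
  if (is.null(scaled)) {
    fi <- filter_indexes(x, y)
    scaled <- fi$scaled
  }
  id <- importance_degree_matrix(scaled, params)
  names(id) <- rownames(scaled)
  structure(list(importance = id, threshold = threshold,
                 selected = id > threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Fuzzy feature selection: ", sum(x$selected), " of ",
      length(x$selected), " features with ID > ", x$threshold, "\n",
      sep = "")
  sel <- names(x$importance)[x$selected]
  if (length(sel)) {
    cat("  selected:", paste(sel, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read fuzzy parameters as YAML
#'
#' The file stores `c` and `s` as 4 lists of 3 (input order Fisher,
#' correlation, t, MI; level order L, M, H) and `alpha` as 81 values in
#' [rule_table()] order. This layout is part of the file-format contract.
#'
#' @param params A [fuzzy_params()] object.
#' @param path File path.
#' @return `write_params_yaml` returns `path` invisibly; `read_params_yaml`
#'   returns a [fuzzy_params()] object.
#' @export
write_params_yaml <- function(params, path) {
  obj <- list(c = unname(apply(params$c, 1, as.list, simplify = FALSE)),
              s = unname(apply(params$s, 1, as.list, simplify = FALSE)),
              alpha = as.list(params$alpha))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cmat <- t(vapply(obj$c, function(r) as.numeric(unlist(r)), numeric(3)))
  smat <- t(vapply(obj$s, function(r) as.numeric(unlist(r)), numeric(3)))
  fuzzy_params(cmat, smat, as.numeric(unlist(obj$alpha)))
}
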