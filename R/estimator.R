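# Second-order polynomial anxiety estimator: least-squares identification,
# distribution-matched data splitting, exhaustive feature-subset search, and
# threshold classification with confusion matrices.
#
# The estimator is y = sum_{i<=j} alpha_{ij} x_i x_j + sum_i beta_i x_i + gamma,
# a second-order Taylor approximation of an unknown anxiety-response function
# around x = 0. With P features it has P(P+1)/2 + P + 1 coefficients.

#' Coefficient count of the second-order polynomial model
#'
#' `p (p + 1) / 2` pairwise-product coefficients (i <= j), `p` linear
#' coefficients and one intercept; 171 for `p = 17`.
#'
#' @param p Number of features in the model, `>= 1`.
#' @return Integer coefficient count.
#' @export
n_coefficients <- function(p) {
  p <- as.integer(p)
  if (any(is.na(p)) || any(p < 1L)) stop("`p` must be >= 1", call. = FALSE)
  p * (p + 1L) %/% 2L + p + 1L
}

#' Exact binomial coefficient
#'
#' Number of size-`p` feature subsets from a pool of `n`; `choose(32, 7)` is
#' 3,365,856, the size of the seven-feature exhaustive search.
#'
#' @param n Pool size.
#' @param p Subset size, `0 <= p <= n`.
#' @return Exact integer-valued count.
#' @export
n_combinations <- function(n, p) {
  if (any(p > n) || any(p < 0) || any(n < 0))
    stop("require 0 <= p <= n", call. = FALSE)
  round(choose(n, p))
}

# Term pairs (i, j) with i <= j in lexicographic order for p features.
term_pairs <- function(p) {
  i <- rep(seq_len(p), times = p - seq_len(p) + 1L)
  j <- unlist(lapply(seq_len(p), function(k) k:p))
  cbind(i = i, j = j)
}

#' Build the design (term) matrix of the polynomial model
#'
#' Columns are ordered: products `x_i * x_j` for `i <= j` in lexicographic
#' `(i, j)` order, then the linear terms `x_1 ... x_p`, then the constant 1;
#' `n_coefficients(p)` columns in total. `build_design_row()` is the
#' single-observation version.
#'
#' @param X Numeric matrix (observations x features).
#' @return Matrix with `n_coefficients(ncol(X))` columns.
#' @export
poly_term_matrix <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  tp <- term_pairs(p)
  cbind(X[, tp[, "i"], drop = FALSE] * X[, tp[, "j"], drop = FALSE],
        X, rep(1, nrow(X)))
}

#' @rdname poly_term_matrix
#' @param x Numeric feature vector.
#' @export
build_design_row <- function(x) {
  as.numeric(poly_term_matrix(matrix(x, nrow = 1L)))
}

# Minimum-norm least squares via SVD. For full-rank systems this is the
# ordinary LS solution; rank-deficient systems get the minimum-norm
# minimizer so exhaustive enumeration never aborts.
min_norm_lsq <- function(A, y) {
  s <- La.svd(A)
  tol <- max(s$d) * max(dim(A)) * .Machine$double.eps
  di <- ifelse(s$d > tol, 1 / s$d, 0)
  crossprod(s$vt, di * crossprod(s$u, y)[, 1L])[, 1L]
}

#' Fit the polynomial anxiety model by least squares
#'
#' Minimizes the sum of squared residuals `S = sum((ANX - ANX*)^2)` over the
#' coefficient vector. When the design matrix is rank-deficient the
#' minimum-norm minimizer is returned.
#'
#' @param X Feature matrix (rows = windows, columns = the model's features).
#' @param y Reported anxiety levels (ANX).
#' @param feature_names Names of the columns of `X`.
#' @return Object of class `poly_model`: list with `features`, `coef` (full
#'   term-ordered coefficient vector), `alpha` (named `"i,j"` list), `beta`,
#'   `gamma`, `p`.
#' @export
fit_poly_model <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("empty dataset", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  p <- ncol(X)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  cf <- min_norm_lsq(poly_term_matrix(X), as.numeric(y))
  tp <- term_pairs(p)
  nq <- nrow(tp)
  alpha <- as.list(cf[seq_len(nq)])
  names(alpha) <- paste(tp[, "i"], tp[, "j"], sep = ",")
  beta <- cf[nq + seq_len(p)]
  names(beta) <- feature_names
  structure(list(features = feature_names, coef = cf, alpha = alpha,
                 beta = beta, gamma = cf[nq + p + 1L], p = p),
            class = "poly_model")
}

#' Evaluate the polynomial anxiety estimate
#'
#' Returns the raw (unclamped) estimate; clamping into class intervals is a
#' classification concern handled by [classify_anxiety()].
#'
#' @param object A `poly_model`.
#' @param newdata Feature matrix, data frame or single vector whose columns
#'   match the model's feature subset.
#' @param ... Unused.
#' @return Numeric estimates.
#' @export
predict.poly_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    if (!all(object$features %in% names(newdata)))
      stop("`newdata` lacks the model's features", call. = FALSE)
    newdata <- as.matrix(newdata[object$features])
  } else if (is.null(dim(newdata))) {
    if (length(newdata) != object$p)
      stop("feature vector length does not match the model", call. = FALSE)
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != object$p)
    stop("feature dimension does not match the model", call. = FALSE)
  as.numeric(poly_term_matrix(newdata) %*% object$coef)
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("<poly_model> p = %d features (%s), %d coefficients, gamma = %.4g\n",
              x$p, paste(x$features, collapse = ", "), length(x$coef), x$gamma))
  invisible(x)
}

#' Sum of squared residuals of a model on a dataset
#'
#' @param model A `poly_model`.
#' @param X Feature matrix or data frame containing the model's features.
#' @param y Reported anxiety levels.
#' @return `sum((y - predict(model, X))^2)`.
#' @export
model_ssr <- function(model, X, y) {
  sum((as.numeric(y) - predict(model, X))^2)
}

#' Distribution-matched identification/validation split
#'
#' Splits window indices into an identification set (IS) and validation set
#' (VS) so that the distribution of reported anxiety levels is preserved: at
#' each level `k` with `NTK` occurrences, `NIK = round(train_fraction * NTK)`
#' windows go to the IS (rounding half away from zero) and the remaining
#' `NVK = NTK - NIK` to the VS. With the study's 105 windows and the default
#' 6/7 fraction this yields the 90/15 split. Membership within a level is
#' uniformly random under `seed`.
#'
#' @param ratings Reported anxiety levels, in `[0, 10]` (non-integer ratings
#'   are stratified by their rounded level).
#' @param train_fraction Identification-set fraction (default `6/7`).
#' @param seed Optional integer seed for the within-level draw.
#' @return Object of class `split_plan`: list with `per_level_counts` (data
#'   frame `level`, `n_total`, `n_identification`, `n_validation`),
#'   `identification_indices`, `validation_indices`, `seed`.
#' @export
stratified_split <- function(ratings, train_fraction = 6 / 7, seed = NULL) {
  if (length(ratings) == 0L) stop("empty ratings", call. = FALSE)
  lev <- pmin(10, pmax(0, round_half_away(as.numeric(ratings))))
  levels_present <- sort(unique(lev))
  id_idx <- integer(0)
  counts <- with_seed(seed, {
    rows <- lapply(levels_present, function(k) {
      idx <- which(lev == k)
      nik <- as.integer(round_half_away(train_fraction * length(idx)))
      take <- if (nik >= length(idx)) idx else sample(idx, nik)
      id_idx <<- c(id_idx, take)
      data.frame(level = k, n_total = length(idx),
                 n_identification = nik, n_validation = length(idx) - nik)
    })
    do.call(rbind, rows)
  })
  id_idx <- sort(id_idx)
  structure(list(per_level_counts = counts,
                 identification_indices = id_idx,
                 validation_indices = setdiff(seq_along(ratings), id_idx),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d identification / %d validation windows\n",
              length(x$identification_indices), length(x$validation_indices)))
  print(x$per_level_counts, row.names = FALSE)
  invisible(x)
}

#' Exhaustive feature-subset search for the anxiety estimator
#'
#' Fits the second-order polynomial model to every size-`p` subset of the
#' feature pool on the identification set, selects the subset minimizing the
#' identification-set sum of squared residuals (ties broken in favour of the
#' lexicographically first subset in canonical feature order), and reports
#' the winner's validation-set residuals. Enumeration order is fixed, so the
#' result is identical regardless of execution strategy.
#'
#' @param dataset Feature dataset from [assemble_dataset()] (or any data
#'   frame with an `anx` column and feature columns).
#' @param split A [stratified_split()] of the dataset rows.
#' @param p Subset size, `>= 1`.
#' @param pool Feature names to search over (default: all canonical features
#'   present in the dataset).
#' @param keep_log Keep the per-subset residual log (data frame `subset`,
#'   `ssr`); off by default since the log grows as `choose(length(pool), p)`.
#'
#' @return Object of class `subset_search`: list with `best_subset`,
#'   `best_model`, `ssr_identification`, `ssr_validation`, `ssr_all`,
#'   `evaluated_count`, `p`, and `log` (when requested).
#' @export
exhaustive_search <- function(dataset, split, p, pool = NULL, keep_log = FALSE) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("`p` must be >= 1", call. = FALSE)
  if (is.null(pool)) pool <- intersect(feature_names(), names(dataset))
  if (p > length(pool)) stop("`p` exceeds the feature pool", call. = FALSE)
  X <- as.matrix(dataset[pool])
  y <- as.numeric(dataset$anx)
  is_idx <- split$identification_indices
  vs_idx <- split$validation_indices
  if (n_coefficients(p) > length(is_idx))
    warning("more coefficients than identification points: minimum-norm fits",
            call. = FALSE)
  Xi <- X[is_idx, , drop = FALSE]
  yi <- y[is_idx]
  combs <- utils::combn(length(pool), p)
  n_comb <- ncol(combs)
  best_s <- Inf
  best_j <- 1L
  log_s <- if (keep_log) numeric(n_comb)
  for (j in seq_len(n_comb)) {
    idx <- combs[, j]
    Tj <- poly_term_matrix(Xi[, idx, drop = FALSE])
    cf <- min_norm_lsq(Tj, yi)
    s <- sum((yi - Tj %*% cf)^2)
    if (keep_log) log_s[j] <- s
    if (s < best_s) {
      best_s <- s
      best_j <- j
    }
  }
  subset <- pool[combs[, best_j]]
  model <- fit_poly_model(Xi[, combs[, best_j], drop = FALSE], yi,
                          feature_names = subset)
  res <- list(
    best_subset = subset,
    best_model = model,
    ssr_identification = model_ssr(model, as.data.frame(Xi), yi),
    ssr_validation = if (length(vs_idx) > 0L)
      model_ssr(model, as.data.frame(X[vs_idx, , drop = FALSE]), y[vs_idx]) else NA_real_,
    ssr_all = model_ssr(model, as.data.frame(X), y),
    evaluated_count = n_comb,
    p = p
  )
  if (keep_log)
    res$log <- data.frame(
      subset = apply(combs, 2L, function(ix) paste(pool[ix], collapse = "+")),
      ssr = log_s)
  structure(res, class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> p = %d, %d subsets evaluated\n  best: %s\n  S(IS) = %.4g, S(VS) = %.4g\n",
              x$p, x$evaluated_count, paste(x$best_subset, collapse = ", "),
              x$ssr_identification, x$ssr_validation))
  invisible(x)
}

#' Anxiety class schemes and threshold classification
#'
#' Two-level scheme: `[0, 5]` is "low", `(5, 10]` is "high". Three-level
#' scheme: `[0, 3]` "low", `(3, 7]` "mild", `(7, 10]` "high". Raw regression
#' estimates are not clamped beforehand; the extreme intervals extend to
#' minus/plus infinity so every estimate maps to exactly one class.
#'
#' @param n_levels 2 or 3.
#' @return Object of class `class_scheme`: list with `n_levels`, `breaks`,
#'   `labels`.
#' @export
class_scheme <- function(n_levels = 2) {
  if (!n_levels %in% c(2, 3)) stop("`n_levels` must be 2 or 3", call. = FALSE)
  if (n_levels == 2) {
    structure(list(n_levels = 2L, breaks = c(-Inf, 5, Inf),
                   labels = c("low", "high")), class = "class_scheme")
  } else {
    structure(list(n_levels = 3L, breaks = c(-Inf, 3, 7, Inf),
                   labels = c("low", "mild", "high")), class = "class_scheme")
  }
}

#' @rdname class_scheme
#' @param estimate Numeric anxiety estimates (or true ratings).
#' @param scheme A `class_scheme`.
#' @return `classify_anxiety()`: factor of class labels.
#' @export
classify_anxiety <- function(estimate, scheme = class_scheme(2)) {
  stopifnot(inherits(scheme, "class_scheme"))
  cut(as.numeric(estimate), breaks = scheme$breaks, labels = scheme$labels,
      right = TRUE)
}

#' Confusion matrix and overall classification accuracy
#'
#' Cross-tabulates true against estimated class labels; the normalized matrix
#' is row-normalized (rows are true classes), with `NaN` rows flagged when a
#' true class never occurs. Overall accuracy is the percentage of correctly
#' classified windows.
#'
#' @param truth,predicted Class labels (factors or characters), equal length.
#' @param scheme The `class_scheme` defining the label set.
#' @return Object of class `confusion_report`: list with `counts`, `matrix`
#'   (row-normalized proportions), `overall_accuracy` (percent),
#'   `empty_classes`.
#' @export
confusion_report <- function(truth, predicted, scheme = class_scheme(2)) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  truth <- factor(as.character(truth), levels = scheme$labels)
  predicted <- factor(as.character(predicted), levels = scheme$labels)
  counts <- table(true = truth, estimated = predicted)
  totals <- rowSums(counts)
  prop <- sweep(unclass(counts), 1L, totals, "/")
  structure(list(counts = unclass(counts), matrix = prop,
                 overall_accuracy = 100 * sum(diag(counts)) / length(truth),
                 empty_classes = scheme$labels[totals == 0]),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> row-normalized (true x estimated):\n")
  print(round(x$matrix, 2))
  cat(sprintf("Overall accuracy: %.2f%%\n", x$overall_accuracy))
  if (length(x$empty_classes) > 0L)
    cat("Empty true classes:", paste(x$empty_classes, collapse = ", "), "\n")
  invisible(x)
}
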