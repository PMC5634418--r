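#' Configuration of an extreme learning machine (ELM)
#'
#' An ELM is a single-hidden-layer feed-forward network whose hidden-layer
#' (input) weights and biases are drawn at random and frozen; only the linear
#' readout is fitted, by minimum-norm least squares. The random hidden layer
#' is what makes repeated fits distinct solutions, so the seed is part of the
#' configuration and two fits with the same data and config are bit-identical.
#'
#' @param n_hidden number of hidden units (conventional screen settings:
#'   150 for a 20-feature input, 290 for all features).
#' @param activation hidden-unit nonlinearity, `"tanh"` (default) or
#'   `"sigmoid"`.
#' @param weight_scale weights and biases are uniform on
#'   `(-weight_scale, +weight_scale)`; inputs are standardized before the
#'   projection so the default scale 1 is meaningful across datasets.
#' @param seed integer seed for the hidden-layer draw.
#' @return an object of class `ELMConfig`.
#' @export
elm_config <- function(n_hidden = 150L, activation = c("tanh", "sigmoid"),
                       weight_scale = 1, seed = 1L) {
  fail_if(!is_count(n_hidden), "n_hidden must be a positive integer")
  activation <- match.arg(activation)
  fail_if(!is_number(weight_scale) || weight_scale <= 0,
          "weight_scale must be > 0")
  structure(
    list(n_hidden = as.integer(n_hidden), activation = activation,
         weight_scale = weight_scale, seed = as.integer(seed)),
    class = "ELMConfig"
  )
}

activation_fun <- function(name) {
  switch(name,
         tanh = tanh,
         sigmoid = function(x) 1 / (1 + exp(-x)),
         stop("unknown activation: ", name))
}

# Minimum-norm least-squares solution of A b = y via SVD with a relative
# singular-value tolerance (rank-deficient A is expected, not an error).
min_norm_lsq <- function(A, y, rel_tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > s$d[1L] * rel_tol
  drop(s$v[, keep, drop = FALSE] %*%
         (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep]))
}

#' Fit an ELM binary classifier
#'
#' Training features are standardized to train-set mean 0 / SD 1 (constant
#' features get scale 1), the seeded random hidden layer is applied,
#' `H = act(W x + b)`, and the readout (with intercept) is the minimum-norm
#' least-squares map from hidden activations to the labels encoded as
#' positive = 1, negative = 0. With `n_hidden >=` the number of training
#' samples and generic data, the network interpolates the training labels.
#'
#' @param ds_train an [ExpressionDataset][expression_dataset] containing both
#'   classes.
#' @param config an [elm_config()].
#' @return an object of class `ELMModel` with elements `input_weights`
#'   (`n_hidden x m`, the matrix compared by [weight_difference()]), `biases`,
#'   `readout_weights` (length `n_hidden`), `intercept`, `feature_ids`,
#'   `center`, `scale`, `threshold` (0.5), `config`, `positive_class`,
#'   `classes`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_features = 20, seed = 2))
#' fit <- fit_elm(ds, elm_config(n_hidden = 80, seed = 5))
#' mean(predict(fit, ds) == ds$labels)   # interpolates: 1
#' @export
fit_elm <- function(ds_train, config = elm_config()) {
  stopifnot(inherits(ds_train, "ExpressionDataset"),
            inherits(config, "ELMConfig"))
  classes <- sort(unique(ds_train$labels))
  fail_if(length(classes) < 2L, "training data contains a single class")
  m <- nrow(ds_train$values)
  n <- ncol(ds_train$values)

  center <- rowMeans(ds_train$values)
  scale <- apply(ds_train$values, 1L, stats::sd)
  scale[scale == 0] <- 1
  x <- (ds_train$values - center) / scale

  wb <- with_seed(config$seed, {
    list(W = matrix(stats::runif(config$n_hidden * m, -config$weight_scale,
                                 config$weight_scale),
                    nrow = config$n_hidden, ncol = m),
         b = stats::runif(config$n_hidden, -config$weight_scale,
                          config$weight_scale))
  })
  act <- activation_fun(config$activation)
  H <- act(wb$W %*% x + wb$b)                      # n_hidden x n
  y <- as.numeric(ds_train$labels == ds_train$positive_class)
  beta <- min_norm_lsq(cbind(1, t(H)), y)          # intercept + readout

  colnames(wb$W) <- rownames(ds_train$values)
  structure(
    list(input_weights = wb$W, biases = wb$b,
         readout_weights = beta[-1L], intercept = beta[1L],
         feature_ids = rownames(ds_train$values),
         center = center, scale = scale, threshold = 0.5,
         config = config,
         positive_class = ds_train$positive_class,
         classes = classes),
    class = "ELMModel"
  )
}

#' @export
print.ELMModel <- function(x, ...) {
  cat(sprintf("ELMModel: %d hidden units (%s), %d features, seed %d\n",
              x$config$n_hidden, x$config$activation,
              length(x$feature_ids), x$config$seed))
  invisible(x)
}

#' Predict class labels (or continuous scores) for new samples
#'
#' Features are aligned to the model by id, so column/row order of the new
#' dataset does not matter; features the model was trained on must all be
#' present. A sample is called positive iff its continuous readout score is
#' `>= threshold` (default 0.5 under the 0/1 label encoding).
#'
#' @param object an [fit_elm()] model.
#' @param ds dataset to predict on (labels, if any, are ignored).
#' @param type `"label"` (default) or `"score"`.
#' @param ... unused.
#' @return named vector (by sample id) of labels or scores; empty input gives
#'   an empty vector.
#' @export
predict.ELMModel <- function(object, ds, type = c("label", "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing <- setdiff(object$feature_ids, rownames(ds$values))
  fail_if(length(missing) > 0, "dataset lacks model feature(s): %s",
          paste(missing, collapse = ", "))
  x <- ds$values[object$feature_ids, , drop = FALSE]
  if (ncol(x) == 0L) {
    out <- if (type == "score") numeric(0) else character(0)
    return(out)
  }
  x <- (x - object$center) / object$scale
  act <- activation_fun(object$config$activation)
  H <- act(object$input_weights %*% x + object$biases)
  score <- drop(crossprod(H, object$readout_weights)) + object$intercept
  names(score) <- colnames(ds$values)
  if (type == "score") return(score)
  negative <- setdiff(object$classes, object$positive_class)
  stats::setNames(ifelse(score >= object$threshold,
                         object$positive_class, negative),
                  colnames(ds$values))
}

#' Elementwise absolute difference of two models' hidden-layer weights
#'
#' Two independently trained ELMs with equal test performance can be shown to
#' be genuinely different solutions by the size of the entries of
#' `|W_a - W_b|`; the maximum entry summarizes the comparison and anchors the
#' heatmap color scale.
#'
#' @param a,b [fit_elm()] models sharing `n_hidden` and the same features in
#'   the same order.
#' @return an object of class `DifferenceMatrix`: list with `values`
#'   (non-negative `n_hidden x m` matrix) and `max_difference`.
#' @export
weight_difference <- function(a, b) {
  stopifnot(inherits(a, "ELMModel"), inherits(b, "ELMModel"))
  fail_if(!identical(dim(a$input_weights), dim(b$input_weights)),
          "weight matrices differ in shape: %s vs %s",
          paste(dim(a$input_weights), collapse = "x"),
          paste(dim(b$input_weights), collapse = "x"))
  fail_if(!identical(a$feature_ids, b$feature_ids),
          "models were trained on different feature sets/orders")
  d <- abs(a$input_weights - b$input_weights)
  structure(list(values = d, max_difference = max(d)),
            class = "DifferenceMatrix")
}

#' @export
print.DifferenceMatrix <- function(x, ...) {
  cat(sprintf("DifferenceMatrix: %d x %d, max difference %.4g\n",
              nrow(x$values), ncol(x$values), x$max_difference))
  invisible(x)
}

#' Serialize / restore an ELM model as a flat text archive
#'
#' A JSON header (config, ids, scalars) followed by the numeric arrays,
#' written at full precision; `read_elm()` restores a model whose predictions
#' match the original.
#'
#' @param model an [fit_elm()] model.
#' @param path file path (`.json`).
#' @return `write_elm()`: invisibly `path`; `read_elm()`: the model.
#' @export
write_elm <- function(model, path) {
  stopifnot(inherits(model, "ELMModel"))
  payload <- list(
    config = unclass(model$config),
    feature_ids = model$feature_ids,
    classes = model$classes,
    positive_class = model$positive_class,
    threshold = model$threshold,
    intercept = model$intercept,
    center = unname(model$center), scale = unname(model$scale),
    biases = model$biases,
    readout_weights = model$readout_weights,
    input_weights = model$input_weights
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_elm
#' @export
read_elm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- p$input_weights
  colnames(W) <- p$feature_ids
  structure(
    list(input_weights = W, biases = p$biases,
         readout_weights = p$readout_weights, intercept = p$intercept,
         feature_ids = p$feature_ids,
         center = stats::setNames(p$center, p$feature_ids),
         scale = stats::setNames(p$scale, p$feature_ids),
         threshold = p$threshold,
         config = structure(as.list(p$config), class = "ELMConfig"),
         positive_class = p$positive_class,
         classes = p$classes),
    class = "ELMModel"
  )
}
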