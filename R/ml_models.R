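#' Neural-network training configuration
#'
#' Architecture and stopping rule of the pooled multilayer perceptron: two
#' logistic hidden layers (25 and 10 neurons), linear output, sum-of-squared-
#' errors loss minimised by resilient backpropagation with weight
#' backtracking, 50 random restarts per training event, training stopped when
#' every partial derivative of the loss falls below 0.01 in absolute value.
#' `max_epochs` is a safety cap on top of the gradient criterion.
#'
#' @param hidden_sizes two positive integers.
#' @param n_restarts independent weight initialisations; best by training SSE.
#' @param grad_stop gradient stopping threshold (> 0).
#' @param max_epochs epoch cap per restart.
#' @return An object of class `nn_config`.
#' @export
nn_config <- function(hidden_sizes = c(25L, 10L), n_restarts = 50L,
                      grad_stop = 0.01, max_epochs = 10000L) {
  stopifnot(length(hidden_sizes) == 2L, all(hidden_sizes >= 1L),
            n_restarts >= 1L, grad_stop > 0, max_epochs >= 1L)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 n_restarts = as.integer(n_restarts),
                 grad_stop = grad_stop, max_epochs = as.integer(max_epochs)),
            class = "nn_config")
}

#' Random-forest training configuration
#'
#' 300 regression trees, 2 candidate predictors sampled per split (of the 6
#' inputs), and nodes with fewer than 5 observations never split; splits
#' minimise the sum of squared errors and predictions average the per-tree
#' leaf means.
#'
#' @param n_trees number of trees.
#' @param m_try candidate predictors per split.
#' @param min_node_size below this node size no split is attempted.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 300L, m_try = 2L, min_node_size = 5L) {
  stopifnot(n_trees >= 1L, m_try >= 1L, min_node_size >= 1L)
  structure(list(n_trees = as.integer(n_trees), m_try = as.integer(m_try),
                 min_node_size = as.integer(min_node_size)),
            class = "rf_config")
}

#' Build the scaled input vector for the pooled regressors
#'
#' Continuous predictors are scaled (dbh/100, ht/10, h/10) and the forest
#' type is one-hot coded as three dummies, in the fixed order
#' (dbh, ht, h, d1 cerrado, d2 semi-deciduous, d3 rainforest). A cerrado tree
#' with dbh 53 cm, ht 8.7 m, evaluated at h = 4.3 m yields
#' `c(0.53, 0.87, 0.43, 1, 0, 0)`.
#'
#' @param dbh diameter at breast height, cm (> 0).
#' @param ht total height, m (> 0).
#' @param h evaluation height, m (> 0).
#' @param forest_type one of [forest_types()].
#' @return Named numeric vector of length 6.
#' @export
build_input_vector <- function(dbh, ht, h, forest_type) {
  if (!all(is.finite(c(dbh, ht, h))) || any(c(dbh, ht, h) <= 0))
    stopf("build_input_vector: dbh, ht, h must be positive")
  assert_forest_type(forest_type)
  dummies <- as.numeric(forest_types() == forest_type)
  c(dbh = dbh / 100, ht = ht / 10, h = h / 10,
    d1 = dummies[1], d2 = dummies[2], d3 = dummies[3])
}

# rows: data.frame with dbh, ht, h, forest_type -> n x 6 predictor matrix
build_input_matrix <- function(rows) {
  stopifnot(all(c("dbh", "ht", "h", "forest_type") %in% names(rows)))
  bad <- setdiff(unique(rows$forest_type), forest_types())
  if (length(bad)) stopf("unknown forest_type '%s'", bad[1])
  m <- cbind(dbh = rows$dbh / 100, ht = rows$ht / 10, h = rows$h / 10,
             d1 = as.numeric(rows$forest_type == "cerrado"),
             d2 = as.numeric(rows$forest_type == "semideciduous"),
             d3 = as.numeric(rows$forest_type == "rainforest"))
  storage.mode(m) <- "double"
  m
}

#' Train the pooled neural network
#'
#' Trains one multilayer perceptron for one target (`d` in cm or `vac` in
#' m^3) on rows pooled across all forest types. Targets are used unscaled;
#' only the inputs carry the fixed scaling of [build_input_vector()]. Each
#' restart draws fresh weights from the seeded R generator and trains by
#' Rprop+ until the gradient criterion or the epoch cap; the restart with the
#' lowest training SSE is returned. If no restart reached the gradient
#' criterion the model is still returned, flagged `converged = FALSE`.
#'
#' @param rows data.frame with `dbh`, `ht`, `h`, `forest_type` and the target
#'   column named by `target`.
#' @param target `"d"` or `"vac"`.
#' @param config an [nn_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the training is reproducible.
#' @return An object of class `nn_model`.
#' @export
train_nn <- function(rows, target = c("d", "vac"), config = nn_config(),
                     seed = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(config, "nn_config"), nrow(rows) > 0,
            target %in% names(rows))
  y <- rows[[target]]
  if (any(!is.finite(y))) stopf("train_nn: non-finite targets")
  X <- build_input_matrix(rows)
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_train_nn(X, y, config$hidden_sizes[1], config$hidden_sizes[2],
                      config$n_restarts, config$grad_stop, config$max_epochs)
  structure(list(weights = as.numeric(fit$weights), sse = fit$sse,
                 converged = fit$converged, epochs = fit$epochs,
                 config = config, target = target, p = fit$p),
            class = "nn_model")
}

#' Train the pooled random forest
#'
#' @inheritParams train_nn
#' @param config an [rf_config()].
#' @return An object of class `rf_model`; stores the training-target range
#'   (forest predictions can never leave it).
#' @export
train_rf <- function(rows, target = c("d", "vac"), config = rf_config(),
                     seed = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(config, "rf_config"), nrow(rows) > 0,
            target %in% names(rows))
  y <- rows[[target]]
  if (any(!is.finite(y))) stopf("train_rf: non-finite targets")
  X <- build_input_matrix(rows)
  if (config$m_try > ncol(X)) stopf("train_rf: m_try exceeds predictor count")
  if (!is.null(seed)) set.seed(seed)
  forest <- cpp_train_rf(X, y, config$n_trees, config$m_try,
                         config$min_node_size)
  structure(list(forest = forest, config = config, target = target,
                 y_range = range(y)),
            class = "rf_model")
}

#' @rdname train_nn
#' @param object a trained `nn_model`.
#' @param newdata data.frame with `dbh`, `ht`, `h`, `forest_type` (or a
#'   ready-made 6-column predictor matrix).
#' @param ... ignored.
#' @return `predict()`: numeric predictions, one per row; diameter
#'   predictions are clipped at 0.
#' @export
predict.nn_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else build_input_matrix(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != object$p) stopf("predict: expected %d predictors", object$p)
  out <- as.numeric(cpp_predict_nn(object$weights, object$p,
                                   object$config$hidden_sizes[1],
                                   object$config$hidden_sizes[2], X))
  if (object$target == "d") out <- pmax(out, 0)
  out
}

#' @rdname train_rf
#' @param object a trained `rf_model`.
#' @param newdata data.frame with `dbh`, `ht`, `h`, `forest_type` (or a
#'   ready-made 6-column predictor matrix).
#' @param ... ignored.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else build_input_matrix(newdata)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != 6L) stopf("predict: expected 6 predictors")
  out <- as.numeric(cpp_predict_rf(object$forest, X))
  if (object$target == "d") out <- pmax(out, 0)
  out
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model [%s]: %d-%d hidden, %s, training SSE %.4g>\n",
              x$target, x$config$hidden_sizes[1], x$config$hidden_sizes[2],
              if (x$converged) "converged" else "epoch cap reached", x$sse))
  invisible(x)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model [%s]: %d trees, m_try %d, min node %d>\n",
              x$target, x$config$n_trees, x$config$m_try,
              x$config$min_node_size))
  invisible(x)
}
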