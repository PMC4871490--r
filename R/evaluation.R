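#' Root mean squared error
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`, in the target's units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L)
    stopf("rmse: vectors must have equal non-zero length")
  sqrt(mean((predicted - observed)^2))
}

#' Average bias
#'
#' Mean of (predicted - observed); positive means over-prediction.
#'
#' @inheritParams rmse
#' @return Bias in the target's units.
#' @export
bias <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L)
    stopf("bias: vectors must have equal non-zero length")
  mean(predicted - observed)
}

#' Model efficiency
#'
#' `1 - SSE/SST` with SST about the observed mean of the evaluated set; 1 for
#' a perfect model, 0 for the mean predictor, negative for anything worse.
#'
#' @inheritParams rmse
#' @return Dimensionless efficiency (<= 1).
#' @export
efficiency <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stopf("efficiency: vectors must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stopf("efficiency: observed values are all equal (SST = 0)")
  1 - sum((observed - predicted)^2) / sst
}

metric_row <- function(observed, predicted) {
  c(rmse = rmse(observed, predicted), bias = bias(observed, predicted),
    ef = efficiency(observed, predicted))
}

#' Modelling records from a tree set
#'
#' Flattens trees into one record per measurement height: predictors (tree
#' dbh, ht, evaluation height h, forest type) and both targets — the
#' observed diameter `d` (for multi-stemmed trees the equivalent diameter of
#' the stems measured at that height) and the Smalian accumulated volume
#' `vac` from the stump, summed over stems. The unmeasured tip is not a
#' record; volumes at measurement heights never include the cone tip.
#'
#' @param trees list of [taper_tree()].
#' @return data.frame: `tree_id`, `forest_type`, `dbh`, `ht`, `h`, `d`, `vac`.
#' @export
observation_rows <- function(trees) {
  stopifnot(length(trees) > 0, all(vapply(trees, inherits, TRUE, "taper_tree")))
  out <- lapply(trees, function(tree) {
    hs <- sort(unique(unlist(lapply(tree$stems, `[[`, "h"))))
    d2 <- numeric(length(hs))
    vac <- numeric(length(hs))
    for (stem in tree$stems) {
      m <- match(round(stem$h, 9), round(hs, 9))
      d2[m] <- d2[m] + stem$d^2
      prof <- accumulated_volume_profile(stem, tree$ht)
      # step lookup: a stem that ended below h keeps its last measured vac
      vac <- vac + vapply(hs, function(h) {
        i <- findInterval(h + 1e-9, stem$h)
        if (i < 1L) 0 else prof$vac[i]
      }, 0)
    }
    data.frame(tree_id = tree$tree_id, forest_type = tree$forest_type,
               dbh = tree$dbh, ht = tree$ht, h = hs, d = sqrt(d2), vac = vac)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

# stratified tree-level split: per forest type, round(val_frac * n) trees
# (at least 1) go to validation
split_trees <- function(rows, val_frac) {
  ids <- unique(rows[, c("tree_id", "forest_type")])
  val <- character(0)
  for (ft in unique(ids$forest_type)) {
    ft_ids <- ids$tree_id[ids$forest_type == ft]
    n_val <- max(1L, round(val_frac * length(ft_ids)))
    if (n_val >= length(ft_ids))
      stopf("cross_validate: forest '%s' has too few trees to split", ft)
    val <- c(val, sample(ft_ids, n_val))
  }
  val
}

# TM prediction of both targets on a row set, using per-forest fitted laws
tm_predict_rows <- function(fits_by_forest, rows) {
  d_hat <- rep(NA_real_, nrow(rows))
  v_hat <- rep(NA_real_, nrow(rows))
  for (ft in names(fits_by_forest)) {
    fit <- fits_by_forest[[ft]]
    sel <- which(rows$forest_type == ft)
    if (length(sel) == 0L) next
    sub <- rows[sel, ]
    d_hat[sel] <- predict_diameter(fit$spec, fit$beta, sub$dbh, sub$ht,
                                   pmin(sub$h, sub$ht * (1 - 1e-9)))
    for (id in unique(sub$tree_id)) {
      tr <- sel[sub$tree_id == id]
      v_hat[tr] <- taper_vac_at_heights(fit$spec, fit$beta,
                                        rows$dbh[tr[1]], rows$ht[tr[1]],
                                        rows$h[tr])
    }
  }
  list(d = d_hat, vac = v_hat)
}

#' Repeated tree-level cross-validation of the three modelling techniques
#'
#' The full evaluation protocol: trees are split 75/25 at the tree level
#' (stratified by forest type so every site can support its site-specific
#' taper fit), 500 times by default. Per iteration the selected taper
#' equation is refitted per forest type on the training trees, and the
#' neural network and random forest are trained pooled across forest types;
#' RMSE, bias and efficiency are computed on both partitions for both
#' targets (diameter and accumulated volume, the latter predicted by
#' integrating the fitted taper law or directly by the ML regressors).
#' The taper model form is selected once, on the full data by AICc, before
#' any splitting. Iterations where the taper fit fails to converge are
#' flagged (`tm_ok = FALSE`) and excluded from summaries.
#'
#' @param trees list of [taper_tree()]; every forest type needs >= 8 trees.
#' @param methods subset of `c("tm", "nn", "rf")`.
#' @param targets subset of `c("d", "vac")`.
#' @param n_iter number of split repetitions (study protocol: 500).
#' @param val_frac validation fraction of trees (study protocol: 0.25).
#' @param seed integer seed controlling every random draw.
#' @param nn_control an [nn_config()]; the study protocol (50 restarts) is
#'   the default — pass a lighter configuration to trade fidelity for time.
#' @param rf_control an [rf_config()].
#' @param tm_candidates taper model names entered in the pre-selection
#'   (default: all six).
#' @param keep_predictions retain per-iteration predictions (for metric
#'   audits and residual analyses).
#' @return An object of class `cv_result`: `runs` (one row per iteration x
#'   method x target x partition with rmse/bias/ef and `tm_ok`),
#'   `tm_selected` (per-forest selected model name), `selection_fits`,
#'   `tally`, `tm_failures`, and optionally `predictions`.
#' @export
cross_validate <- function(trees, methods = c("tm", "nn", "rf"),
                           targets = c("d", "vac"), n_iter = 500L,
                           val_frac = 0.25, seed = 1L,
                           nn_control = nn_config(),
                           rf_control = rf_config(),
                           tm_candidates = taper_model_names(),
                           keep_predictions = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  targets <- match.arg(targets, several.ok = TRUE)
  rows <- observation_rows(trees)
  ft_counts <- table(unique(rows[, c("tree_id", "forest_type")])$forest_type)
  if (any(ft_counts < 8))
    stopf("cross_validate: every forest type needs >= 8 trees")
  set.seed(seed)

  # model-form pre-selection on the full data, once, by AICc
  tm_selected <- NULL; selection_fits <- NULL; tally <- NULL
  if ("tm" %in% methods) {
    selection_fits <- list()
    for (ft in names(ft_counts)) {
      sub <- rows[rows$forest_type == ft, ]
      for (nm in tm_candidates)
        selection_fits[[paste(ft, nm, sep = ".")]] <-
          gauss_newton_fit(taper_model_spec(nm), sub, forest_type = ft)
    }
    tally <- select_best_model(selection_fits)
    if (length(tally$skipped_forests))
      stopf("cross_validate: no converged taper fit for forest(s): %s",
            paste(tally$skipped_forests, collapse = ", "))
    tm_selected <- vapply(tally$winners, `[[`, "", 1L)
  }

  runs <- list(); preds <- list(); tm_failures <- 0L
  for (it in seq_len(n_iter)) {
    val_ids <- split_trees(rows, val_frac)
    is_val <- rows$tree_id %in% val_ids
    train <- rows[!is_val, ]; val <- rows[is_val, ]
    part <- list(training = train, validation = val)

    pred <- list()
    tm_ok <- TRUE
    if ("tm" %in% methods) {
      fits <- list()
      for (ft in names(tm_selected)) {
        f <- gauss_newton_fit(taper_model_spec(tm_selected[[ft]]),
                              train[train$forest_type == ft, ],
                              forest_type = ft)
        if (!f$converged) tm_ok <- FALSE
        fits[[ft]] <- f
      }
      if (tm_ok)
        pred$tm <- lapply(part, function(p) tm_predict_rows(fits, p))
      else tm_failures <- tm_failures + 1L
    }
    if ("nn" %in% methods) {
      nets <- lapply(setNames(targets, targets), function(tg)
        train_nn(train, tg, nn_control))
      pred$nn <- lapply(part, function(p)
        lapply(nets, function(m) predict(m, p)))
    }
    if ("rf" %in% methods) {
      forests <- lapply(setNames(targets, targets), function(tg)
        train_rf(train, tg, rf_control))
      pred$rf <- lapply(part, function(p)
        lapply(forests, function(m) predict(m, p)))
    }

    for (me in names(pred)) for (pa in names(part)) for (tg in targets) {
      yhat <- pred[[me]][[pa]][[tg]]
      if (is.null(yhat)) next
      m <- metric_row(part[[pa]][[tg]], yhat)
      runs[[length(runs) + 1L]] <- data.frame(
        iteration = it, method = me, target = tg, partition = pa,
        rmse = m[["rmse"]], bias = m[["bias"]], ef = m[["ef"]],
        tm_ok = if (me == "tm") tm_ok else NA)
    }
    if (keep_predictions)
      preds[[it]] <- list(val_ids = val_ids, pred = pred)
  }
  structure(list(runs = do.call(rbind, c(runs, make.row.names = FALSE)),
                 tm_selected = tm_selected, selection_fits = selection_fits,
                 tally = tally, tm_failures = tm_failures,
                 n_iter = n_iter, val_frac = val_frac, seed = seed,
                 predictions = if (keep_predictions) preds else NULL,
                 rows = rows),
            class = "cv_result")
}

#' Summarise a cross-validation run
#'
#' Arithmetic means of RMSE, bias and efficiency over iterations, per method,
#' target and partition (the study's summary-table layout). Taper-model
#' iterations that failed to converge are excluded; their count is attached
#' as attribute `"tm_failures"`.
#'
#' @param cv a [cross_validate()] result.
#' @return data.frame with columns method, target, partition, rmse, bias,
#'   ef, n_iter.
#' @export
cv_summary <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  r <- cv$runs
  r <- r[is.na(r$tm_ok) | r$tm_ok, ]
  agg <- aggregate(r[, c("rmse", "bias", "ef")],
                   by = r[, c("method", "target", "partition")], mean)
  n <- aggregate(list(n_iter = r$rmse),
                 by = r[, c("method", "target", "partition")], length)
  out <- merge(agg, n)
  out <- out[order(out$method, out$target, out$partition), ]
  rownames(out) <- NULL
  attr(out, "tm_failures") <- cv$tm_failures
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d iterations, val_frac %.2f, seed %d>\n",
              x$n_iter, x$val_frac, x$seed))
  if (!is.null(x$tm_selected)) {
    cat("  selected taper model per forest:\n")
    for (ft in names(x$tm_selected))
      cat(sprintf("    %-14s %s\n", ft, x$tm_selected[[ft]]))
    cat(sprintf("  taper non-convergent iterations: %d\n", x$tm_failures))
  }
  print(cv_summary(x))
  invisible(x)
}

#' Residuals against observed diameter for fitted models
#'
#' Builds the residual-analysis table (residual = predicted - observed)
#' against the observed stem diameter, per forest type, method and target.
#' This is the view in which the random forest's bounded-range mechanism is
#' visible: being an average of leaf means, it can never predict outside the
#' training target range, so it under-predicts the largest diameters and
#' over-predicts the smallest.
#'
#' @param models named list with any of `nn` (an `nn_model` or per-target
#'   list), `rf` (likewise) and `tm` (named list of [gauss_newton_fit()]
#'   results per forest type).
#' @param rows observation rows ([observation_rows()]).
#' @return data.frame: forest_type, method, target, observed_d, observed,
#'   predicted, residual.
#' @export
residual_table <- function(models, rows) {
  stopifnot(is.list(models), nrow(rows) > 0)
  out <- list()
  add <- function(method, target, predicted) {
    obs <- rows[[target]]
    out[[length(out) + 1L]] <<- data.frame(
      forest_type = rows$forest_type, method = method, target = target,
      observed_d = rows$d, observed = obs, predicted = predicted,
      residual = predicted - obs)
  }
  for (me in intersect(c("nn", "rf"), names(models))) {
    mods <- models[[me]]
    if (inherits(mods, c("nn_model", "rf_model"))) mods <- list(mods)
    for (m in mods) add(me, m$target, predict(m, rows))
  }
  if ("tm" %in% names(models)) {
    p <- tm_predict_rows(models$tm, rows)
    add("tm", "d", p$d)
    add("tm", "vac", p$vac)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-height predicted versus measured diameters for one tree
#'
#' The per-tree profile view: measured diameters at every measurement height
#' in `[0.1, ht)` next to each method's prediction.
#'
#' @param tree a [taper_tree()].
#' @param models named list as in [residual_table()] (diameter models only).
#' @return data.frame: h, d_measured, and one `d_<method>` column per model.
#' @export
profile_prediction <- function(tree, models) {
  stopifnot(inherits(tree, "taper_tree"))
  rows <- observation_rows(list(tree))
  rows <- rows[rows$h >= 0.1 & rows$h < tree$ht, ]
  out <- data.frame(h = rows$h, d_measured = rows$d)
  for (me in intersect(c("nn", "rf"), names(models))) {
    m <- models[[me]]
    if (!inherits(m, c("nn_model", "rf_model"))) m <- m[["d"]]
    out[[paste0("d_", me)]] <- predict(m, rows)
  }
  if ("tm" %in% names(models)) {
    fit <- models$tm[[tree$forest_type]]
    out$d_tm <- predict_diameter(fit$spec, fit$beta, rows$dbh, rows$ht, rows$h)
  }
  out
}
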