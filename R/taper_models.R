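# Six literature taper equations. Each functional form is isolated in one
# function of (beta, dbh, ht, h) so a corrected form is a one-line change.
# Shared relative-height terms: q = h/ht, p = 1.3/ht,
# Z = 1 - q^(1/3), X = Z / (1 - p^(1/3)).

taper_form_demaerschalk <- function(beta, dbh, ht, h) {
  # d = dbh * sqrt(10^(2 b0) * dbh^(2 b1 - 2) * ht^(-2 b2) * (ht - h)^(2 b3))
  #   = 10^b0 * dbh^b1 * ht^(-b2) * (ht - h)^b3
  10^beta[1] * dbh^beta[2] * ht^(-beta[3]) * (ht - h)^beta[4]
}

taper_form_biging <- function(beta, dbh, ht, h) {
  # d = dbh * { b0 + b1 * ln[1 - q^(1/3) * (1 - exp(-b0/b1))] }
  q <- h / ht
  dbh * (beta[1] + beta[2] * log(1 - q^(1/3) * (1 - exp(-beta[1] / beta[2]))))
}

taper_form_bi <- function(beta, dbh, ht, h) {
  # variable-exponent trigonometric form on base ln sin(pi q/2)/ln sin(pi p/2)
  q <- h / ht
  p <- 1.3 / ht
  base <- log(sin(pi * q / 2)) / log(sin(pi * p / 2))
  expo <- beta[1] + beta[2] * sin(pi * q / 2) + beta[3] * cos(3 * pi * q / 2) +
    beta[4] * sin(pi * q / 2) / q + beta[5] * dbh +
    beta[6] * q * sqrt(dbh) + beta[7] * q * sqrt(ht)
  dbh * base^expo
}

taper_form_lee <- function(beta, dbh, ht, h) {
  # d = b1 * dbh^b2 * (1 - q)^(b3 q^2 + b4 q + b5)
  q <- h / ht
  beta[1] * dbh^beta[2] * (1 - q)^(beta[3] * q^2 + beta[4] * q + beta[5])
}

taper_form_kozak <- function(beta, dbh, ht, h) {
  # variable-exponent form on base X = (1 - q^(1/3)) / (1 - p^(1/3))
  q <- h / ht
  p <- 1.3 / ht
  Z <- 1 - q^(1/3)
  X <- Z / (1 - p^(1/3))
  expo <- beta[4] * q^4 + beta[5] * exp(-dbh / ht) + beta[6] * X^0.1 +
    beta[7] / dbh + beta[8] * ht^Z + beta[9] * X
  beta[1] * dbh^beta[2] * ht^beta[3] * X^expo
}

taper_form_metcalf <- function(beta, dbh, ht, h) {
  # d = dbh * exp(-b1 * (h - 1.3)); equals dbh exactly at breast height
  dbh * exp(-beta[1] * (h - 1.3))
}

.taper_forms <- list(
  demaerschalk = list(fn = taper_form_demaerschalk, n_params = 4L,
                      inits = c(0, 1, 1, 1)),
  biging       = list(fn = taper_form_biging, n_params = 2L,
                      inits = c(1.04, 0.34)),
  bi           = list(fn = taper_form_bi, n_params = 7L,
                      inits = c(1.0, 0.1, 0.1, 0.1, 0.001, 0.001, 0.001)),
  lee          = list(fn = taper_form_lee, n_params = 5L,
                      inits = c(1.05, 0.98, 0.8, -1.2, 0.7)),
  kozak        = list(fn = taper_form_kozak, n_params = 9L,
                      inits = c(0.9, 1.0, 0.05, 0.4, -0.6, 0.4, 1.4, 0.05, -0.3)),
  metcalf      = list(fn = taper_form_metcalf, n_params = 1L,
                      inits = 0.05)
)

#' Taper model specification
#'
#' Looks up one of the six supported taper equations by name and returns its
#' specification: the functional form, the number of parameters and default
#' starting values (literature-based, overridable in [gauss_newton_fit()]).
#'
#' @param name one of `"demaerschalk"`, `"biging"`, `"bi"`, `"lee"`,
#'   `"kozak"`, `"metcalf"`.
#' @return An object of class `taper_model_spec` with fields `name`,
#'   `n_params`, `default_inits` and the form function `fn(beta, dbh, ht, h)`.
#' @export
taper_model_spec <- function(name) {
  name <- match.arg(name, names(.taper_forms))
  f <- .taper_forms[[name]]
  structure(list(name = name, n_params = f$n_params,
                 default_inits = f$inits, fn = f$fn),
            class = "taper_model_spec")
}

#' Names of the supported taper equations
#' @return Character vector of the six model names.
#' @export
taper_model_names <- function() names(.taper_forms)

#' @export
print.taper_model_spec <- function(x, ...) {
  cat(sprintf("<taper_model_spec %s: %d parameter(s)>\n", x$name, x$n_params))
  invisible(x)
}

#' Predict stem diameter from a taper equation
#'
#' Evaluates the model's diameter d(h) for vectors of observations. Negative
#' computed diameters are clipped to 0 (prediction only; the fitter sees raw
#' values). Rows with non-finite intermediates raise a domain error.
#'
#' @param spec a [taper_model_spec()].
#' @param beta numeric parameter vector of length `spec$n_params`.
#' @param dbh diameter at breast height, cm.
#' @param ht total height, m (> 1.3).
#' @param h evaluation height, m, in `[0, ht)`.
#' @param clip clip negative predictions to zero (default TRUE).
#' @return Predicted diameters, cm.
#' @export
predict_diameter <- function(spec, beta, dbh, ht, h, clip = TRUE) {
  stopifnot(inherits(spec, "taper_model_spec"))
  if (length(beta) != spec$n_params)
    stopf("predict_diameter: %s needs %d parameters, got %d",
          spec$name, spec$n_params, length(beta))
  if (any(ht <= 1.3)) stopf("predict_diameter: ht must exceed 1.3 m")
  if (any(dbh <= 0)) stopf("predict_diameter: dbh must be > 0")
  if (any(h < 0) || any(h >= ht))
    stopf("predict_diameter: h must lie in [0, ht)")
  d <- spec$fn(beta, dbh, ht, h)
  if (any(!is.finite(d)))
    stopf("predict_diameter: non-finite diameter from model %s at %d row(s)",
          spec$name, sum(!is.finite(d)))
  if (clip) d <- pmax(d, 0)
  d
}

# Raw evaluation used inside the fitter: no clipping, non-finite allowed
# (the optimizer must feel the penalty / detect divergence itself).
taper_eval_raw <- function(spec, beta, dbh, ht, h) {
  suppressWarnings(spec$fn(beta, dbh, ht, h))
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' Least-squares AICc: `n*log(sse/n) + 2k + 2k(k+1)/(n-k-1)` with
#' `k = n_params + 1` (the error variance is counted as a parameter). The
#' additive constant `n*log(2*pi) + n`, common to all candidates on the same
#' data, is dropped; ranking is unaffected.
#'
#' @param sse sum of squared residuals (> 0).
#' @param n_obs number of observations.
#' @param n_params number of mean-model parameters.
#' @return AICc score (smaller is better).
#' @export
aicc <- function(sse, n_obs, n_params) {
  k <- n_params + 1
  if (!is.finite(sse) || sse <= 0) stopf("aicc: sse must be > 0")
  if (n_obs <= n_params + 2)
    stopf("aicc: need n_obs > n_params + 2 (got n=%d, p=%d)", n_obs, n_params)
  n_obs * log(sse / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Fit a taper equation by Gauss-Newton least squares
#'
#' Minimises the sum of squared diameter residuals by Gauss-Newton iteration
#' with a central-finite-difference Jacobian and step-halving line search.
#' Non-convergence (singular normal equations, non-finite residuals at the
#' start, or iteration exhaustion) is reported in the result, never raised:
#' complex variable-exponent forms routinely fail to converge on irregular
#' tropical stems and the caller must be able to tally that outcome.
#'
#' @param spec a [taper_model_spec()].
#' @param rows data.frame with columns `dbh`, `ht`, `h`, `d` (one measurement
#'   per row).
#' @param inits starting parameters (default: the spec's literature values).
#' @param tol relative SSE decrease declaring convergence (default 1e-8).
#' @param max_iter maximum Gauss-Newton iterations (default 50).
#' @param forest_type optional label stored on the result.
#' @return An object of class `taper_fit`: `spec`, `forest_type`, `beta`,
#'   `sse`, `n_obs`, `converged`, `n_iter`, `aicc` (NA unless converged),
#'   `message`.
#' @export
gauss_newton_fit <- function(spec, rows, inits = NULL, tol = 1e-8,
                             max_iter = 50L, forest_type = NA_character_) {
  stopifnot(inherits(spec, "taper_model_spec"), is.data.frame(rows))
  need <- c("dbh", "ht", "h", "d")
  if (!all(need %in% names(rows)))
    stopf("gauss_newton_fit: rows must have columns %s", paste(need, collapse = ", "))
  p <- spec$n_params
  n <- nrow(rows)
  if (n <= p) stopf("gauss_newton_fit: fewer rows (%d) than parameters (%d)", n, p)
  beta <- if (is.null(inits)) spec$default_inits else as.numeric(inits)
  if (length(beta) != p) stopf("gauss_newton_fit: inits must have length %d", p)

  fail <- function(msg, beta, sse, it) {
    structure(list(spec = spec, forest_type = forest_type, beta = beta,
                   sse = sse, n_obs = n, converged = FALSE, n_iter = it,
                   aicc = NA_real_, message = msg),
              class = "taper_fit")
  }

  resid_at <- function(b) rows$d - taper_eval_raw(spec, b, rows$dbh, rows$ht, rows$h)

  r <- resid_at(beta)
  if (any(!is.finite(r)))
    return(fail("non-finite residuals at initial parameters", beta, NA_real_, 0L))
  sse <- sum(r^2)
  converged <- FALSE
  msg <- "max_iter reached"
  it <- 0L

  for (it in seq_len(max_iter)) {
    # central finite-difference Jacobian of predictions, relative step 1e-6
    J <- matrix(NA_real_, n, p)
    for (j in seq_len(p)) {
      step <- 1e-6 * max(abs(beta[j]), 1e-4)
      bp <- beta; bp[j] <- bp[j] + step
      bm <- beta; bm[j] <- bm[j] - step
      J[, j] <- (taper_eval_raw(spec, bp, rows$dbh, rows$ht, rows$h) -
                 taper_eval_raw(spec, bm, rows$dbh, rows$ht, rows$h)) / (2 * step)
    }
    if (any(!is.finite(J)))
      return(fail("non-finite Jacobian", beta, sse, it))
    sv <- svd(J)
    if (sv$d[1] <= 0 || sv$d[p] == 0 || sv$d[1] / sv$d[p] > 1e12)
      return(fail("singular normal equations (condition > 1e12)", beta, sse, it))
    delta <- sv$v %*% ((crossprod(sv$u, r)) / sv$d)

    # step-halving line search: accept the first step that decreases SSE
    lambda <- 1
    accepted <- FALSE
    for (half in 0:20) {
      cand <- beta + lambda * as.numeric(delta)
      rc <- resid_at(cand)
      if (all(is.finite(rc))) {
        sse_c <- sum(rc^2)
        if (sse_c < sse) {
          rel <- (sse - sse_c) / sse
          beta <- cand; r <- rc; sse <- sse_c
          accepted <- TRUE
          if (rel < tol) { converged <- TRUE; msg <- "converged" }
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!accepted) {
      # no downhill step found: current point is a (local) minimum
      converged <- TRUE; msg <- "converged (no downhill step)"
      break
    }
    if (converged) break
  }

  structure(list(spec = spec, forest_type = forest_type, beta = beta,
                 sse = sse, n_obs = n, converged = converged, n_iter = it,
                 aicc = if (converged && sse > 0) aicc(sse, n, p) else NA_real_,
                 message = msg),
            class = "taper_fit")
}

#' @export
print.taper_fit <- function(x, ...) {
  cat(sprintf("<taper_fit %s%s: %s, sse=%.4g, n=%d, AICc=%s>\n",
              x$spec$name,
              if (is.na(x$forest_type)) "" else paste0(" [", x$forest_type, "]"),
              if (x$converged) "converged" else "NO CONVERGENCE",
              x$sse, x$n_obs,
              if (is.na(x$aicc)) "NA" else sprintf("%.2f", x$aicc)))
  invisible(x)
}

#' Tally AICc winners across forest types
#'
#' For each forest type, the converged fit with the lowest AICc wins; fits
#' that did not converge are excluded. The overall best model is the one with
#' the most wins. AICc differences below `tie_tol` credit all tied models and
#' flag the tie.
#'
#' @param fits list of [gauss_newton_fit()] results, each with its
#'   `forest_type` set.
#' @param tie_tol AICc difference treated as a tie (default 1e-6).
#' @return An object of class `model_selection_tally`: `winners` (named list
#'   per forest of winning model names), `counts` (wins per model),
#'   `best_model`, `ties` (forests with a flagged tie), `skipped_forests`
#'   (no converged fit).
#' @export
select_best_model <- function(fits, tie_tol = 1e-6) {
  stopifnot(all(vapply(fits, inherits, TRUE, "taper_fit")))
  forests <- unique(vapply(fits, function(f) f$forest_type, ""))
  winners <- list(); ties <- character(); skipped <- character()
  counts <- setNames(numeric(length(taper_model_names())), taper_model_names())
  for (ft in forests) {
    ff <- Filter(function(f) identical(f$forest_type, ft) && f$converged &&
                   is.finite(f$aicc), fits)
    if (length(ff) == 0L) { skipped <- c(skipped, ft); next }
    a <- vapply(ff, function(f) f$aicc, 0)
    best <- min(a)
    win <- vapply(ff[a - best < tie_tol], function(f) f$spec$name, "")
    if (length(win) > 1L) ties <- c(ties, ft)
    winners[[ft]] <- win
    counts[win] <- counts[win] + 1
  }
  if (all(counts == 0))
    stopf("select_best_model: no forest type had a converged fit")
  structure(list(winners = winners, counts = counts,
                 best_model = names(counts)[which.max(counts)],
                 ties = ties, skipped_forests = skipped),
            class = "model_selection_tally")
}

#' @export
print.model_selection_tally <- function(x, ...) {
  cat("<model_selection_tally>\n")
  for (ft in names(x$winners))
    cat(sprintf("  %-14s -> %s\n", ft, paste(x$winners[[ft]], collapse = " & ")))
  cat(sprintf("  overall best: %s (%d win(s))\n", x$best_model,
              max(x$counts)))
  if (length(x$skipped_forests))
    cat("  no converged fit:", paste(x$skipped_forests, collapse = ", "), "\n")
  invisible(x)
}

# Adaptive composite Simpson on f over [a, b] to absolute tolerance tol.
# f must accept a numeric vector.
adaptive_simpson <- function(f, a, b, tol) {
  simp <- function(fa, fm, fb, h) h / 6 * (fa + 4 * fm + fb)
  rec <- function(a, b, fa, fm, fb, whole, tol, depth) {
    m <- (a + b) / 2
    lm <- (a + m) / 2; rm <- (m + b) / 2
    flm <- f(lm); frm <- f(rm)
    left <- simp(fa, flm, fm, m - a)
    right <- simp(fm, frm, fb, b - m)
    if (depth <= 0 || abs(left + right - whole) <= 15 * tol)
      return(left + right + (left + right - whole) / 15)
    rec(a, m, fa, flm, fm, left, tol / 2, depth - 1) +
      rec(m, b, fm, frm, fb, right, tol / 2, depth - 1)
  }
  fa <- f(a); fb <- f(b); fm <- f((a + b) / 2)
  if (any(!is.finite(c(fa, fm, fb))))
    stopf("taper_volume: non-finite integrand")
  rec(a, b, fa, fm, fb, simp(fa, fm, fb, b - a), tol, 40L)
}

#' Accumulated volume by integrating a taper equation
#'
#' Integrates the cross-sectional area implied by the taper law,
#' \eqn{Vac = \int_{h_{lower}}^{h_{upper}} K\, d(h)^2\, dh} with
#' \eqn{K = \pi/40000}, by adaptive composite Simpson quadrature to an
#' absolute tolerance of 1e-9 m^3.
#'
#' @param spec a [taper_model_spec()].
#' @param beta parameter vector.
#' @param dbh,ht tree-level predictors (cm, m).
#' @param h_upper upper integration bound, m (<= ht).
#' @param h_lower lower bound, m (default the 0.1 m stump).
#' @param tol absolute tolerance, m^3.
#' @return Volume in m^3.
#' @export
taper_volume <- function(spec, beta, dbh, ht, h_upper, h_lower = 0.1,
                         tol = 1e-9) {
  stopifnot(inherits(spec, "taper_model_spec"))
  if (!is.finite(h_lower) || !is.finite(h_upper) || h_lower < 0.1 - 1e-12 ||
      h_upper < h_lower || h_upper > ht)
    stopf("taper_volume: bounds must satisfy 0.1 <= h_lower <= h_upper <= ht")
  if (h_upper == h_lower) return(0)
  f <- function(h) {
    d <- taper_eval_raw(spec, beta, dbh, ht, pmin(h, ht * (1 - 1e-12)))
    K_AREA * pmax(d, 0)^2
  }
  adaptive_simpson(f, h_lower, h_upper, tol)
}

# Vectorised accumulated volume at several (sorted or not) heights for one
# tree: cumulative fixed-grid composite Simpson, cheap enough for the CV
# harness where taper_volume's adaptive recursion per row would dominate.
# Grid step ~1 cm keeps the error far below measurement noise; validated
# against taper_volume in the test suite.
taper_vac_at_heights <- function(spec, beta, dbh, ht, heights, step = 0.01) {
  if (length(heights) == 0L) return(numeric(0))
  out <- numeric(length(heights))
  ord <- order(heights)
  hs <- heights[ord]
  f <- function(h) {
    d <- taper_eval_raw(spec, beta, dbh, ht, pmin(h, ht * (1 - 1e-12)))
    K_AREA * pmax(d, 0)^2
  }
  acc <- 0; lo <- 0.1
  for (i in seq_along(hs)) {
    hi <- hs[i]
    if (hi > lo + 1e-12) {
      m <- max(2L, ceiling((hi - lo) / step))
      # composite Simpson needs an even interval count
      if (m %% 2L == 1L) m <- m + 1L
      x <- seq(lo, hi, length.out = m + 1L)
      y <- f(x)
      w <- c(1, rep(c(4, 2), length.out = m - 1L), 1)
      acc <- acc + (hi - lo) / m / 3 * sum(w * y)
      lo <- hi
    }
    out[ord[i]] <- acc
  }
  out
}
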