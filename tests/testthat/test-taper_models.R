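test_that("taper forms evaluate as printed", {
  lee <- taper_model_spec("lee")
  # exponent vanishes -> d = dbh everywhere
  expect_equal(predict_diameter(lee, c(1, 1, 0, 0, 0), 30, 20, c(1, 5, 15)),
               rep(30, 3))
  # d = dbh * (1 - h/ht)
  expect_equal(predict_diameter(lee, c(1, 1, 0, 0, 1), 30, 20, 10), 15)
  # metcalf at breast height is exactly dbh
  met <- taper_model_spec("metcalf")
  expect_equal(predict_diameter(met, 0.07, 44.2, 18, 1.3), 44.2)
  # negative computed diameters are clipped at prediction time (none of the
  # six printed forms can go negative on their domain, so exercise the
  # contract with a synthetic linear form)
  fake <- structure(list(name = "linear", n_params = 1L,
                         fn = function(b, dbh, ht, h) dbh - b[1] * h),
                    class = "taper_model_spec")
  expect_equal(predict_diameter(fake, 2, 10, 20, 10), 0)
  expect_equal(predict_diameter(fake, 2, 10, 20, 10, clip = FALSE), -10)
  # domain checks
  expect_error(predict_diameter(met, 0.05, 30, 20, 20), "\\[0, ht\\)")
  expect_error(predict_diameter(met, 0.05, 30, 1.2, 0.5), "1.3")
  expect_error(predict_diameter(lee, c(1, 1), 30, 20, 10), "parameters")
})

test_that("all six specs expose the advertised parameter counts", {
  counts <- c(demaerschalk = 4L, biging = 2L, bi = 7L, lee = 5L,
              kozak = 9L, metcalf = 1L)
  for (nm in names(counts)) {
    sp <- taper_model_spec(nm)
    expect_identical(sp$n_params, counts[[nm]])
    expect_length(sp$default_inits, counts[[nm]])
    # every form evaluates finitely at interior heights under its inits
    d <- predict_diameter(sp, sp$default_inits, 30, 18, c(0.7, 5, 12))
    expect_true(all(is.finite(d)))
  }
})

test_that("AICc: closed form and monotonicity", {
  # sse = n so the log term vanishes: 2k + 2k(k+1)/(n-k-1), k = 2
  expect_equal(aicc(100, 100, 1), 4 + 12 / 97, tolerance = 1e-12)
  expect_lt(aicc(50, 200, 2), aicc(50, 200, 5))   # penalty monotone in p
  expect_lt(aicc(50, 200, 2), aicc(80, 200, 2))   # monotone in sse
  expect_error(aicc(0, 100, 1), "> 0")
  expect_error(aicc(10, 4, 3), "n_obs")
})

test_that("Gauss-Newton recovers generating parameters from noise-free data", {
  rows <- rows_from_truth("metcalf", 0.05, n = 200, seed = 5)
  f <- gauss_newton_fit(taper_model_spec("metcalf"), rows, inits = 0.2)
  expect_true(f$converged)
  expect_lt(abs(f$beta - 0.05) / 0.05, 1e-6)
  expect_lt(f$sse, 1e-16)

  beta <- c(1.05, 0.98, 0.8, -1.2, 0.7)
  rows <- rows_from_truth("lee", beta, n = 400, seed = 6)
  f <- gauss_newton_fit(taper_model_spec("lee"), rows,
                        inits = c(1.2, 0.9, 0.5, -0.8, 0.5))
  expect_true(f$converged)
  expect_lt(max(abs(f$beta - beta) / abs(beta)), 1e-5)

  # better-conditioned forms recover from their shipped inits
  for (nm in c("demaerschalk", "biging")) {
    sp <- taper_model_spec(nm)
    truth <- sp$default_inits * c(1.05, 0.95)[seq_along(sp$default_inits) %% 2 + 1]
    rows <- rows_from_truth(nm, truth, n = 300, seed = 8)
    f <- gauss_newton_fit(sp, rows)
    expect_true(f$converged)
    expect_lt(max(abs(f$beta - truth) / pmax(abs(truth), 1e-3)), 1e-4)
  }

  # ill-conditioned variable-exponent forms: recovery from inits near truth
  for (nm in c("bi", "kozak")) {
    sp <- taper_model_spec(nm)
    truth <- sp$default_inits
    rows <- rows_from_truth(nm, truth, n = 400, seed = 9)
    f <- gauss_newton_fit(sp, rows, inits = truth * 1.05)
    expect_true(f$converged)
    expect_lt(max(abs(f$beta - truth) / pmax(abs(truth), 1e-3)), 1e-4)
  }
})

test_that("Gauss-Newton SSE matches a general-purpose minimizer", {
  beta <- c(1.1, 0.95, 0.6, -1.0, 0.65)
  rows <- rows_from_truth("lee", beta, n = 300, noise_sd = 0.4, seed = 10)
  inits <- c(1.2, 0.9, 0.5, -0.8, 0.5)
  f <- gauss_newton_fit(taper_model_spec("lee"), rows, inits = inits)
  sp <- taper_model_spec("lee")
  obj <- function(b) sum((rows$d - sp$fn(b, rows$dbh, rows$ht, rows$h))^2)
  om <- optim(inits, obj, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-14))
  expect_true(f$converged)
  # never materially worse than the general-purpose minimizer ...
  expect_lt(f$sse, om$value * (1 + 1e-6))
  # ... and the general-purpose minimizer cannot improve on the GN optimum
  om2 <- optim(f$beta, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(f$sse - om2$value) / om2$value, 1e-6)
})

test_that("non-convergence is reported, never raised", {
  rows <- rows_from_truth("lee", c(1.15, 0.97, 0.9, -1.4, 0.8),
                          n = 250, noise_sd = 0.5, seed = 11)
  f <- expect_no_error(gauss_newton_fit(taper_model_spec("bi"), rows))
  expect_true(is.logical(f$converged))
  if (!f$converged) expect_true(is.na(f$aicc)) else expect_true(is.finite(f$aicc))
  # pathological inits exercise the failure path explicitly
  f2 <- gauss_newton_fit(taper_model_spec("biging"), rows, inits = c(1, 1e-12))
  expect_false(f2$converged)
  expect_true(is.na(f2$aicc))
  expect_error(gauss_newton_fit(taper_model_spec("lee"), rows[1:3, ]), "fewer rows")
})

test_that("select_best_model tallies winners, ties and skipped forests", {
  mk <- function(name, ft, aicc_val, conv = TRUE) {
    sp <- taper_model_spec(name)
    structure(list(spec = sp, forest_type = ft, beta = sp$default_inits,
                   sse = 1, n_obs = 100, converged = conv, n_iter = 1,
                   aicc = if (conv) aicc_val else NA_real_, message = ""),
              class = "taper_fit")
  }
  fits <- list(mk("lee", "cerrado", 100), mk("kozak", "cerrado", 90),
               mk("lee", "semideciduous", 80), mk("kozak", "semideciduous", 85),
               mk("lee", "rainforest", 70), mk("kozak", "rainforest", 75, conv = FALSE))
  tal <- select_best_model(fits)
  expect_equal(tal$best_model, "lee")
  expect_equal(unname(tal$counts["lee"]), 2)
  expect_equal(unname(tal$counts["kozak"]), 1)
  # non-converged fits are excluded even with the lowest score
  fits2 <- c(fits, list(mk("bi", "rainforest", 1, conv = FALSE)))
  expect_equal(select_best_model(fits2)$best_model, "lee")
  # ties within 1e-6 credit both and are flagged
  fits3 <- list(mk("lee", "cerrado", 50), mk("kozak", "cerrado", 50 + 1e-8))
  tal3 <- select_best_model(fits3)
  expect_setequal(tal3$winners$cerrado, c("lee", "kozak"))
  expect_equal(tal3$ties, "cerrado")
  # forest with zero converged fits is reported and excluded
  fits4 <- c(fits, list(mk("lee", "extra", 10, conv = FALSE)))
  fits4[[7]]$forest_type <- "mystery"
  expect_equal(select_best_model(fits4)$skipped_forests, "mystery")
})

test_that("taper_volume: analytic oracle, additivity, degenerate bounds", {
  met <- taper_model_spec("metcalf")
  oracle <- function(b1, dbh, lo, hi)
    pi / 40000 * dbh^2 / (2 * b1) *
      (exp(-2 * b1 * (lo - 1.3)) - exp(-2 * b1 * (hi - 1.3)))
  expect_equal(taper_volume(met, 0.05, 30, 20, 15),
               oracle(0.05, 30, 0.1, 15), tolerance = 1e-8)
  expect_identical(taper_volume(met, 0.05, 30, 20, 4, 4), 0)
  lee <- taper_model_spec("lee")
  beta <- c(1.05, 0.98, 0.8, -1.2, 0.7)
  a <- taper_volume(lee, beta, 30, 12, 5)
  b <- taper_volume(lee, beta, 30, 12, 11, 5)
  whole <- taper_volume(lee, beta, 30, 12, 11)
  expect_equal(a + b, whole, tolerance = 1e-9)
  expect_error(taper_volume(lee, beta, 30, 12, 13), "bounds")
  expect_error(taper_volume(lee, beta, 30, 12, 5, 0.05), "bounds")
})

test_that("batch vac integrator agrees with the adaptive scalar one", {
  lee <- taper_model_spec("lee")
  beta <- c(1.1, 0.96, 0.7, -1.1, 0.72)
  hs <- c(0.1, 0.3, 0.7, 1.3, 2.3, 4.3, 7.3, 9.0)
  batch <- stemtaper:::taper_vac_at_heights(lee, beta, 42, 10, hs)
  scalar <- vapply(hs, function(h) taper_volume(lee, beta, 42, 10, h), 0)
  expect_equal(batch, scalar, tolerance = 1e-7)
  # unsorted heights map back to their positions
  sh <- c(5, 0.5, 9)
  expect_equal(stemtaper:::taper_vac_at_heights(lee, beta, 42, 10, sh),
               vapply(sh, function(h) taper_volume(lee, beta, 42, 10, h), 0),
               tolerance = 1e-7)
})

test_that("fitted taper volume tracks the Smalian ground truth", {
  # finely sampled synthetic stems, residual sd < 0.3 cm -> volume within 2%
  sc <- default_scenarios()$semideciduous
  sc$noise_sd <- 0.005
  set.seed(12)
  trees <- lapply(1:20, function(i) generate_tree(sc, paste0("t", i)))
  rows <- observation_rows(trees)
  f <- gauss_newton_fit(taper_model_spec("lee"), rows)
  expect_true(f$converged)
  expect_lt(sqrt(f$sse / f$n_obs), 0.3)   # residual sd below 0.3 cm
  big <- trees[[which.max(vapply(trees, function(t) t$dbh, 0))]]
  truth <- tree_total_volume(big)
  pred <- taper_volume(f$spec, f$beta, big$dbh, big$ht,
                       big$stems[[1]]$h[length(big$stems[[1]]$h)])
  # compare over the measured span (truth without the cone tip)
  prof <- accumulated_volume_profile(big$stems[[1]], big$ht)
  truth_meas <- prof$vac[nrow(prof) - 1]
  expect_lt(abs(pred - truth_meas) / truth_meas, 0.02)
})
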