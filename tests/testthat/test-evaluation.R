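test_that("metric definitions: trivial cases and symmetries", {
  y <- c(1, 2, 3)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, y + 1), 1)
  expect_equal(rmse(3 * y, 3 * (y + 1)), 3 * rmse(y, y + 1))  # equivariance
  expect_equal(bias(y, y), 0)
  expect_equal(bias(y, y + 2), 2)
  expect_equal(bias(y, y + 2), -bias(y + 2, y))               # antisymmetry
  expect_equal(efficiency(y, y), 1)
  expect_equal(efficiency(y, rep(mean(y), 3)), 0)
  expect_lt(efficiency(y, c(10, -4, 8)), 0)                   # worse than mean
  expect_error(rmse(y, 1:2), "length")
  expect_error(efficiency(c(2, 2), c(1, 3)), "SST")
})

test_that("observation rows: targets, stump reference, multi-stem combination", {
  t1 <- taper_tree("a", "cerrado", 20, 4,
                   stems = stem_profile("s", c(0.1, 1.1, 2.1), c(20, 18, 12)))
  r <- observation_rows(list(t1))
  expect_equal(r$h, c(0.1, 1.1, 2.1))
  expect_equal(r$d, c(20, 18, 12))
  expect_equal(r$vac[1], 0)
  expect_equal(r$vac[2], smalian_section_volume(20, 18, 1))
  expect_equal(r$vac[3], smalian_section_volume(20, 18, 1) +
                         smalian_section_volume(18, 12, 1))
  # no cone-tip row: volumes stop at the last measurement height
  expect_false(any(r$h == t1$ht))

  # multi-stem: d is the equivalent diameter, vac the sum over stems
  t2 <- taper_tree("b", "cerrado", equivalent_diameter(c(12, 9)), 4,
                   stems = list(stem_profile("s1", c(0.1, 1.1), c(12, 10)),
                                stem_profile("s2", c(0.1, 1.1), c(9, 7))))
  r2 <- observation_rows(list(t2))
  expect_equal(r2$d, c(equivalent_diameter(c(12, 9)), equivalent_diameter(c(10, 7))))
  expect_equal(r2$vac[2], smalian_section_volume(12, 10, 1) +
                          smalian_section_volume(9, 7, 1))
})

test_that("cross_validate: structure, split integrity, determinism", {
  inv <- tiny_inventory(seed = 6)
  cv <- cross_validate(inv$trees, n_iter = 3L, seed = 31,
                       nn_control = nn_light(), keep_predictions = TRUE)
  expect_s3_class(cv, "cv_result")
  # 3 methods x 2 targets x 2 partitions x 3 iterations
  expect_equal(nrow(cv$runs), 36)
  expect_setequal(unique(cv$runs$method), c("tm", "nn", "rf"))
  # pre-selected one taper form per forest, fixed across iterations
  expect_length(cv$tm_selected, 3)

  # no tree in both partitions, stratified 25% per forest
  ids <- unique(cv$rows[, c("tree_id", "forest_type")])
  for (it in seq_along(cv$predictions)) {
    val <- cv$predictions[[it]]$val_ids
    per_ft <- table(ids$forest_type[ids$tree_id %in% val])
    expect_true(all(per_ft == round(0.25 * table(ids$forest_type))))
  }

  cv2 <- cross_validate(inv$trees, n_iter = 3L, seed = 31,
                        nn_control = nn_light())
  expect_identical(cv$runs, cv2$runs)

  s <- cv_summary(cv)
  expect_setequal(names(s), c("method", "target", "partition",
                              "rmse", "bias", "ef", "n_iter"))
  expect_true(all(s$rmse >= 0) && all(s$ef <= 1))
})

test_that("stored predictions reproduce every metric to 1e-12", {
  inv <- tiny_inventory(seed = 8)
  cv <- cross_validate(inv$trees, n_iter = 2L, seed = 13,
                       nn_control = nn_light(), keep_predictions = TRUE)
  for (it in seq_along(cv$predictions)) {
    pr <- cv$predictions[[it]]
    is_val <- cv$rows$tree_id %in% pr$val_ids
    parts <- list(training = cv$rows[!is_val, ], validation = cv$rows[is_val, ])
    for (me in names(pr$pred)) for (pa in names(parts)) for (tg in c("d", "vac")) {
      yhat <- pr$pred[[me]][[pa]][[tg]]
      y <- parts[[pa]][[tg]]
      row <- cv$runs[cv$runs$iteration == it & cv$runs$method == me &
                     cv$runs$partition == pa & cv$runs$target == tg, ]
      # brute-force recomputation, independent of the metric functions
      expect_equal(row$rmse, sqrt(sum((yhat - y)^2) / length(y)), tolerance = 1e-12)
      expect_equal(row$bias, sum(yhat - y) / length(y), tolerance = 1e-12)
      expect_equal(row$ef, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                   tolerance = 1e-12)
    }
  }
})

test_that("perfect synthetic world drives validation efficiency toward 1", {
  sc <- default_scenarios()
  sc <- lapply(sc, function(s) { s$n_trees <- 10L; s$noise_sd <- 1e-4
                                 s$multi_stem_prob <- 0; s$butt_swell <- 0; s })
  inv <- generate_inventory(sc, seed = 14)
  cv <- cross_validate(inv$trees, methods = "tm", n_iter = 2L, seed = 15,
                       tm_candidates = "lee")
  s <- cv_summary(cv)
  expect_gt(min(s$ef[s$partition == "validation"]), 0.9999)
})

test_that("residual_table and profile_prediction", {
  inv <- tiny_inventory(seed = 16)
  rows <- observation_rows(inv$trees)
  fits <- lapply(setNames(forest_types(), forest_types()), function(ft)
    gauss_newton_fit(taper_model_spec("lee"), rows[rows$forest_type == ft, ],
                     forest_type = ft))
  nn <- train_nn(rows, "d", nn_light(), seed = 1)
  rt <- residual_table(list(nn = nn, tm = fits), rows)
  expect_setequal(unique(rt$method), c("nn", "tm"))
  expect_equal(rt$residual, rt$predicted - rt$observed)

  # residuals of a perfect model are all zero
  perfect <- rows
  sc <- default_scenarios()$cerrado
  sub <- rows[rows$forest_type == "cerrado", ]
  noise_free <- gauss_newton_fit(taper_model_spec("lee"), {
    s <- sub; s$d <- predict_diameter(taper_model_spec("lee"),
                                      sc$taper_beta, s$dbh, s$ht, s$h); s
  }, inits = sc$taper_beta, forest_type = "cerrado")
  rt0 <- residual_table(list(tm = list(cerrado = noise_free)), {
    s <- sub; s$d <- predict_diameter(taper_model_spec("lee"),
                                      noise_free$beta, s$dbh, s$ht, s$h)
    s$vac <- stemtaper:::tm_predict_rows(list(cerrado = noise_free), s)$vac; s
  })
  expect_lt(max(abs(rt0$residual)), 1e-8)

  tree <- inv$trees[[1]]
  pp <- profile_prediction(tree, list(nn = nn, tm = fits))
  expect_true(all(pp$h >= 0.1 & pp$h < tree$ht))
  expect_setequal(names(pp), c("h", "d_measured", "d_nn", "d_tm"))
  expect_true(all(is.finite(as.matrix(pp))) && all(as.matrix(pp) >= 0))
  # metcalf prediction at breast height is the tree's dbh exactly
  mfit <- gauss_newton_fit(taper_model_spec("metcalf"),
                           rows[rows$forest_type == tree$forest_type, ],
                           forest_type = tree$forest_type)
  pp2 <- profile_prediction(tree, list(tm = setNames(list(mfit), tree$forest_type)))
  if (any(pp2$h == 1.3)) expect_equal(pp2$d_tm[pp2$h == 1.3], tree$dbh)
})
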