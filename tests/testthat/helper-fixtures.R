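# Fixtures are generated in code; nothing is read from disk.

# observation rows drawn exactly (or noisily) from a known taper law,
# the truth source for parameter-recovery tests
rows_from_truth <- function(model = "lee", beta = c(1.05, 0.98, 0.8, -1.2, 0.7),
                            n = 200, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- taper_model_spec(model)
  dbh <- runif(n, 8, 60)
  ht <- 2.5 * dbh^0.45 * exp(rnorm(n, 0, 0.05))
  ht <- pmax(ht, 3)
  h <- runif(n, 0.1, 0.95 * ht)
  d <- predict_diameter(spec, beta, dbh, ht, h) + rnorm(n, 0, noise_sd)
  data.frame(dbh = dbh, ht = ht, h = h, d = d)
}

# a small but CV-capable synthetic inventory (>= 8 trees per forest)
tiny_inventory <- function(seed = 1, n_per_forest = 10L) {
  sc <- default_scenarios()
  for (i in seq_along(sc)) {
    sc[[i]]$n_trees <- as.integer(n_per_forest)
    sc[[i]]$n_census <- 20L
  }
  generate_inventory(sc, seed = seed)
}

# light NN settings for tests: the architecture and gradient rule are the
# study protocol; restarts/epochs are scaled down for the test budget
nn_light <- function(restarts = 2L, epochs = 200L)
  nn_config(n_restarts = restarts, max_epochs = epochs)

# a deliberately simple two-point cylinder tree
cylinder_tree <- function(d = 20, ht = 1.2) {
  taper_tree("cyl", "cerrado", dbh = d, ht = ht,
             stems = stem_profile("s1", c(0.1, 1.1), c(d, d)))
}
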