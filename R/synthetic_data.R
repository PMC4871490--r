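# Synthetic three-site inventory generator. The stated world: three forest
# types with the tree counts and dbh/ht ranges of the study sites, the field
# measurement protocol (0.1, 0.3, 0.7, 1.3 m then 1-m steps up to a 5-cm top
# diameter), cerrado multi-stemming, rainforest butt swell, and profiles
# drawn from a known taper law with multiplicative measurement noise.

#' Forest scenario for the synthetic generator
#'
#' Describes one forest type's tree population: tree count, dbh and height
#' ranges, the height-diameter allometry `ht = a * dbh^b * lognormal noise`,
#' the generating taper law (the ground truth for parameter-recovery tests),
#' the multiplicative diameter measurement noise, the probability of a
#' multi-stemmed tree, and an optional butt-swell multiplier emulating
#' buttressed rainforest stems.
#'
#' @param forest_type one of [forest_types()].
#' @param n_trees number of taper trees.
#' @param dbh_range,ht_range ranges in cm / m; `ht_range[1]` must allow
#'   heights above 1.4 m.
#' @param height_a,height_b,height_sdlog allometry coefficients and lognormal
#'   noise sd (log scale).
#' @param dbh_meanlog,dbh_sdlog truncated-lognormal dbh distribution.
#' @param taper_model,taper_beta generating taper law.
#' @param noise_sd multiplicative diameter noise sd (fraction of the true
#'   diameter; 0.02 emulates optical-dendrometer-scale error).
#' @param multi_stem_prob probability a tree carries 2-3 stems.
#' @param butt_swell basal flare fraction applied below breast height.
#' @param n_census size of the walk-through census (Table-1-style summary).
#' @return An object of class `forest_scenario`.
#' @export
forest_scenario <- function(forest_type, n_trees, dbh_range, ht_range,
                            height_a, height_b, height_sdlog = 0.12,
                            dbh_meanlog = log(15), dbh_sdlog = 0.9,
                            taper_model = "lee", taper_beta,
                            noise_sd = 0.02, multi_stem_prob = 0,
                            butt_swell = 0, n_census = 500L) {
  assert_forest_type(forest_type)
  stopifnot(n_trees >= 1L, length(dbh_range) == 2L, length(ht_range) == 2L,
            dbh_range[1] > 0, diff(dbh_range) > 0, ht_range[1] > 0,
            diff(ht_range) > 0, noise_sd >= 0,
            multi_stem_prob >= 0, multi_stem_prob <= 1, butt_swell >= 0)
  if (ht_range[2] <= 1.4)
    stopf("forest_scenario: ht_range must extend above 1.4 m")
  spec <- taper_model_spec(taper_model)
  if (length(taper_beta) != spec$n_params)
    stopf("forest_scenario: taper_beta must have length %d", spec$n_params)
  structure(list(forest_type = forest_type, n_trees = as.integer(n_trees),
                 dbh_range = dbh_range, ht_range = ht_range,
                 height_a = height_a, height_b = height_b,
                 height_sdlog = height_sdlog, dbh_meanlog = dbh_meanlog,
                 dbh_sdlog = dbh_sdlog, taper_spec = spec,
                 taper_beta = taper_beta, noise_sd = noise_sd,
                 multi_stem_prob = multi_stem_prob, butt_swell = butt_swell,
                 n_census = as.integer(n_census)),
            class = "forest_scenario")
}

#' Default scenarios for the three study sites
#'
#' Tree counts (52/53/55), taper-tree dbh ranges (5.0-52.0, 5.0-135.0,
#' 5.1-157.0 cm), height ranges (1.7-17.0, 2.0-24.0, 1.4-26.0 m) and census
#' sizes (531/446/540) follow the field study the generator emulates. The
#' generating taper law is the lee family with forest-specific coefficients
#' giving neiloid-like bases; cerrado trees are multi-stemmed with
#' probability 0.25 and rainforest stems carry a 15% butt swell.
#'
#' @return Named list of three [forest_scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    cerrado = forest_scenario(
      "cerrado", n_trees = 52L, dbh_range = c(5.0, 52.0),
      ht_range = c(1.7, 17.0), height_a = 2.2, height_b = 0.45,
      dbh_meanlog = log(12), dbh_sdlog = 0.8,
      taper_beta = c(1.15, 0.97, 0.9, -1.4, 0.8),
      multi_stem_prob = 0.25, n_census = 531L),
    semideciduous = forest_scenario(
      "semideciduous", n_trees = 53L, dbh_range = c(5.0, 135.0),
      ht_range = c(2.0, 24.0), height_a = 2.6, height_b = 0.45,
      dbh_meanlog = log(16), dbh_sdlog = 0.95,
      taper_beta = c(1.10, 0.98, 0.8, -1.2, 0.7),
      n_census = 446L),
    rainforest = forest_scenario(
      "rainforest", n_trees = 55L, dbh_range = c(5.1, 157.0),
      ht_range = c(1.4, 26.0), height_a = 2.4, height_b = 0.45,
      dbh_meanlog = log(16), dbh_sdlog = 1.0,
      taper_beta = c(1.05, 0.99, 0.7, -1.1, 0.75),
      butt_swell = 0.15, n_census = 540L))
}

# truncated lognormal draw via inverse CDF
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

# true outside-bark diameter of the generating law, with optional butt swell
scenario_true_diameter <- function(scenario, dbh, ht, h) {
  d <- taper_eval_raw(scenario$taper_spec, scenario$taper_beta, dbh, ht, h)
  if (scenario$butt_swell > 0)
    d <- d * (1 + scenario$butt_swell * pmax(0, (1.3 - h) / 1.3)^2)
  pmax(d, 0)
}

# field protocol: 0.1, 0.3, 0.7, 1.3 m, then 1-m steps while the true
# diameter stays at or above the 5-cm top limit and the height stays < ht
measurement_heights <- function(scenario, dbh, ht, top_d = 5) {
  base <- c(0.1, 0.3, 0.7, 1.3)
  hs <- base[base < ht]
  h <- 1.3 + 1
  while (h < ht && scenario_true_diameter(scenario, dbh, ht, h) >= top_d) {
    hs <- c(hs, h)
    h <- h + 1
  }
  hs
}

#' Generate one synthetic tree
#'
#' Draws dbh from a truncated lognormal, height from the scenario allometry
#' (truncated to the height range and above 1.4 m), lays out the measurement
#' protocol heights, evaluates the generating taper law, applies
#' multiplicative Gaussian measurement noise, and — with the scenario's
#' multi-stem probability — splits basal area across 2-3 stems by fixed
#' fractions so the equivalent diameter reproduces the drawn dbh exactly at
#' every height.
#'
#' @param scenario a [forest_scenario()].
#' @param tree_id identifier.
#' @return A [taper_tree()]; attribute `"stem_dbh"` holds the construction
#'   breast-height diameter of each stem, attribute `"truth"` the generating
#'   taper law.
#' @export
generate_tree <- function(scenario, tree_id = "t1") {
  stopifnot(inherits(scenario, "forest_scenario"))
  dbh <- rlnorm_trunc(1, scenario$dbh_meanlog, scenario$dbh_sdlog,
                      scenario$dbh_range[1], scenario$dbh_range[2])
  ht <- scenario$height_a * dbh^scenario$height_b *
    rlnorm(1, 0, scenario$height_sdlog)
  ht <- min(max(ht, scenario$ht_range[1], 1.45), scenario$ht_range[2])
  hs <- measurement_heights(scenario, dbh, ht)
  d_true <- scenario_true_diameter(scenario, dbh, ht, hs)

  n_stems <- 1L
  if (runif(1) < scenario$multi_stem_prob) n_stems <- sample(2:3, 1L)
  # basal-area split fractions: sum(frac^2) = 1
  w <- runif(n_stems, 0.3, 1)
  frac <- sqrt(w / sum(w))

  stems <- vector("list", n_stems)
  for (s in seq_len(n_stems)) {
    noise <- 1 + rnorm(length(hs), 0, scenario$noise_sd)
    d_meas <- pmax(frac[s] * d_true * noise, 0.05)
    stems[[s]] <- stem_profile(sprintf("%s_s%d", tree_id, s), hs, d_meas)
  }
  tree <- taper_tree(tree_id, scenario$forest_type, dbh, ht, stems,
                     species = sprintf("species_%02d", sample.int(72L, 1L)))
  attr(tree, "stem_dbh") <- frac * dbh
  attr(tree, "truth") <- list(model = scenario$taper_spec$name,
                              beta = scenario$taper_beta)
  tree
}

#' Generate a full synthetic inventory
#'
#' One taper-tree set across the three scenarios (160 trees by default) plus
#' a larger walk-through census table for summary statistics. Deterministic
#' under `seed`.
#'
#' @param scenarios named list of [forest_scenario()] (default
#'   [default_scenarios()]).
#' @param seed integer seed.
#' @return List with `trees` (list of [taper_tree()]) and `census`
#'   (data.frame: forest_type, species, dbh_cm, ht_m).
#' @export
generate_inventory <- function(scenarios = default_scenarios(), seed = 1L) {
  stopifnot(all(vapply(scenarios, inherits, TRUE, "forest_scenario")))
  set.seed(seed)
  trees <- list()
  census <- list()
  for (sc in scenarios) {
    for (i in seq_len(sc$n_trees)) {
      id <- sprintf("%s_%03d", substr(sc$forest_type, 1, 3), i)
      trees[[id]] <- generate_tree(sc, id)
    }
    # census: the full stand walk-through, dbh >= 5 cm
    cd <- rlnorm_trunc(sc$n_census, log(9), 0.45, 5, sc$dbh_range[2])
    ch <- sc$height_a * cd^sc$height_b * rlnorm(sc$n_census, 0, sc$height_sdlog)
    ch <- pmin(pmax(ch, sc$ht_range[1]), sc$ht_range[2])
    census[[sc$forest_type]] <- data.frame(
      forest_type = sc$forest_type,
      species = sprintf("species_%02d", sample.int(72L, sc$n_census, TRUE)),
      dbh_cm = cd, ht_m = ch)
  }
  list(trees = trees, census = do.call(rbind, c(census, make.row.names = FALSE)))
}
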