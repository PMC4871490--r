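#' Equivalent diameter of a multi-stemmed tree
#'
#' Combines the stem diameters of a multi-stemmed tree into the single
#' diameter whose cross-sectional area equals the summed areas of the
#' individual stems: \eqn{D_e = \sqrt{d_1^2 + d_2^2 + \dots + d_n^2}}.
#' Basal area is conserved exactly, so the equivalent diameter can be used
#' as a tree-level predictor in place of the individual stem diameters.
#'
#' @param diameters numeric vector of stem diameters (cm), all positive.
#' @return Equivalent diameter in cm.
#' @examples
#' equivalent_diameter(c(3, 4))  # 5
#' @export
equivalent_diameter <- function(diameters) {
  if (length(diameters) == 0L) stopf("equivalent_diameter: empty diameter set")
  if (!is.numeric(diameters) || any(!is.finite(diameters)) || any(diameters <= 0))
    stopf("equivalent_diameter: all diameters must be finite and > 0")
  sqrt(sum(diameters^2))
}

#' Cross-sectional area of a stem
#'
#' Area of a circular cross-section of diameter `d` cm, in square meters:
#' \eqn{A = K d^2} with \eqn{K = \pi/40000}.
#'
#' @param d diameter outside bark, cm (vectorised).
#' @return Area in m^2.
#' @export
cross_section_area <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stopf("cross_section_area: diameters must be finite and >= 0")
  K_AREA * d^2
}

#' Smalian volume of a stem section
#'
#' Section volume as length times the mean of the end cross-sectional areas.
#' Over-estimates the volume of a true cone frustum (mean of areas instead of
#' area of mean), so short sections are preferred.
#'
#' @param d_lower,d_upper end diameters, cm.
#' @param length section length, m (> 0).
#' @return Volume in m^3.
#' @export
smalian_section_volume <- function(d_lower, d_upper, length) {
  if (any(!is.finite(length)) || any(length <= 0))
    stopf("smalian_section_volume: length must be > 0")
  length * (cross_section_area(d_lower) + cross_section_area(d_upper)) / 2
}

#' Cone volume of the unmeasured stem tip
#'
#' Above the last measurement point the stem is treated as a cone on the
#' last measured diameter.
#'
#' @param d_base diameter at the cone base, cm.
#' @param length cone length, m (>= 0).
#' @return Volume in m^3.
#' @export
cone_tip_volume <- function(d_base, length) {
  if (any(!is.finite(length)) || any(length < 0))
    stopf("cone_tip_volume: length must be >= 0")
  cross_section_area(d_base) * length / 3
}

#' Construct a stem profile
#'
#' One stem's ordered (height, diameter) measurements, heights strictly
#' increasing from the stump (conventionally 0.1 m).
#'
#' @param stem_id identifier.
#' @param h numeric vector of measurement heights, m.
#' @param d numeric vector of outside-bark diameters, cm.
#' @return An object of class `stem_profile` with fields `stem_id`, `h`, `d`.
#' @export
stem_profile <- function(stem_id, h, d) {
  if (length(h) != length(d)) stopf("stem_profile: h and d lengths differ")
  if (length(h) < 2L) stopf("stem_profile: at least 2 measurements required")
  if (any(!is.finite(h)) || any(h < 0)) stopf("stem_profile: heights must be >= 0")
  if (any(!is.finite(d)) || any(d < 0)) stopf("stem_profile: diameters must be >= 0")
  if (any(diff(h) <= 0)) stopf("stem_profile: heights must be strictly increasing")
  structure(list(stem_id = as.character(stem_id), h = as.numeric(h),
                 d = as.numeric(d)),
            class = "stem_profile")
}

#' Construct a tree
#'
#' A tree carries its forest type, breast-height diameter (for multi-stemmed
#' trees: the equivalent diameter of the stems), total height and one or more
#' measured stem profiles.
#'
#' @param tree_id identifier.
#' @param forest_type one of [forest_types()].
#' @param dbh diameter at breast height, cm (> 0).
#' @param ht total height, m; must exceed every stem's last measured height.
#' @param stems list of [stem_profile()] objects (at least one).
#' @param species species label (free text).
#' @return An object of class `taper_tree`.
#' @export
taper_tree <- function(tree_id, forest_type, dbh, ht, stems,
                       species = "unknown") {
  assert_forest_type(forest_type)
  if (!is.finite(dbh) || dbh <= 0) stopf("taper_tree: dbh must be > 0")
  if (inherits(stems, "stem_profile")) stems <- list(stems)
  if (length(stems) == 0L || !all(vapply(stems, inherits, TRUE, "stem_profile")))
    stopf("taper_tree: stems must be a non-empty list of stem_profile")
  top <- max(vapply(stems, function(s) s$h[length(s$h)], 0))
  if (!is.finite(ht) || ht <= top)
    stopf("taper_tree: ht (%.2f) must exceed the last measured height (%.2f)",
          ht, top)
  structure(list(tree_id = as.character(tree_id), forest_type = forest_type,
                 species = as.character(species), dbh = as.numeric(dbh),
                 ht = as.numeric(ht), stems = stems),
            class = "taper_tree")
}

#' @export
print.taper_tree <- function(x, ...) {
  cat(sprintf("<taper_tree %s: %s, dbh %.1f cm, ht %.1f m, %d stem(s)>\n",
              x$tree_id, x$forest_type, x$dbh, x$ht, length(x$stems)))
  invisible(x)
}

#' Accumulated volume along a measured stem
#'
#' Smalian volumes of the successive measured sections, cumulated from the
#' stump upward, plus a final cone tip from the last measured diameter up to
#' the total height. Volume is referenced to the first measurement height
#' (the stump, 0.1 m by convention): `vac` is 0 there.
#'
#' @param stem a [stem_profile()].
#' @param ht total tree height, m; must exceed the last measurement height.
#' @return data.frame with columns `h` (m) and `vac` (m^3), one row per
#'   measurement height plus one row at `ht` for the cone tip.
#' @export
accumulated_volume_profile <- function(stem, ht) {
  stopifnot(inherits(stem, "stem_profile"))
  n <- length(stem$h)
  if (!is.finite(ht) || ht <= stem$h[n])
    stopf("accumulated_volume_profile: ht must exceed the last measured height")
  sect <- smalian_section_volume(stem$d[-n], stem$d[-1], diff(stem$h))
  vac <- c(0, cumsum(sect))
  tip <- cone_tip_volume(stem$d[n], ht - stem$h[n])
  data.frame(h = c(stem$h, ht), vac = c(vac, vac[n] + tip))
}

#' Total outside-bark volume of a tree
#'
#' Sum over stems of the accumulated volume at total height (measured
#' sections by Smalian's formula plus the cone tip).
#'
#' @param tree a [taper_tree()].
#' @return Volume in m^3.
#' @export
tree_total_volume <- function(tree) {
  stopifnot(inherits(tree, "taper_tree"))
  sum(vapply(tree$stems, function(s) {
    p <- accumulated_volume_profile(s, tree$ht)
    p$vac[nrow(p)]
  }, 0))
}
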