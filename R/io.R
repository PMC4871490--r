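# CSV readers/writers for inventories. Canonical schema:
#   tree table:    tree_id, forest_type, species, dbh_cm, ht_m
#   section table: tree_id, stem_id, h_m, d_cm
# Internally all heights are meters and all diameters centimeters.

.unit_factor <- function(unit, kind) {
  tab <- if (kind == "length_m") c(m = 1, dm = 0.1, cm = 0.01, mm = 0.001)
         else c(cm = 1, mm = 0.1, m = 100)
  if (!unit %in% names(tab))
    stopf("unsupported unit '%s' for %s", unit, kind)
  unname(tab[unit])
}

#' Column mapping for inventory CSV files
#'
#' Maps source column names onto the canonical fields and declares the
#' units of the measured columns, so deposited files with arbitrary headers
#' can be ingested without editing.
#'
#' @param tree_cols named character vector mapping canonical tree fields
#'   (`tree_id`, `forest_type`, `species`, `dbh`, `ht`) to source columns.
#' @param section_cols likewise for section fields (`tree_id`, `stem_id`,
#'   `h`, `d`).
#' @param dbh_unit,d_unit diameter units (`"cm"`, `"mm"` or `"m"`).
#' @param ht_unit,h_unit height units (`"m"`, `"dm"`, `"cm"` or `"mm"`).
#' @param forest_levels named character vector recoding source forest-type
#'   labels to [forest_types()]; identity by default.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(tree_cols = c(tree_id = "tree_id",
                                         forest_type = "forest_type",
                                         species = "species",
                                         dbh = "dbh_cm", ht = "ht_m"),
                           section_cols = c(tree_id = "tree_id",
                                            stem_id = "stem_id",
                                            h = "h_m", d = "d_cm"),
                           dbh_unit = "cm", d_unit = "cm",
                           ht_unit = "m", h_unit = "m",
                           forest_levels = NULL) {
  need_t <- c("tree_id", "forest_type", "species", "dbh", "ht")
  need_s <- c("tree_id", "stem_id", "h", "d")
  if (!all(need_t %in% names(tree_cols)))
    stopf("column_mapping: tree_cols must name %s", paste(need_t, collapse = ", "))
  if (!all(need_s %in% names(section_cols)))
    stopf("column_mapping: section_cols must name %s", paste(need_s, collapse = ", "))
  structure(list(tree_cols = tree_cols, section_cols = section_cols,
                 dbh_factor = .unit_factor(dbh_unit, "diameter_cm"),
                 d_factor = .unit_factor(d_unit, "diameter_cm"),
                 ht_factor = .unit_factor(ht_unit, "length_m"),
                 h_factor = .unit_factor(h_unit, "length_m"),
                 forest_levels = forest_levels),
            class = "column_mapping")
}

#' Read an inventory from tree and section CSV files
#'
#' Builds validated trees; section rows that violate the invariants
#' (non-positive diameter, height at or above the tree height, duplicated
#' height within a stem) are rejected with a per-row diagnostic, and trees
#' left without a usable stem are dropped.
#'
#' @param tree_csv,section_csv file paths.
#' @param mapping a [column_mapping()].
#' @return List: `trees` (list of [taper_tree()]), `rejects` (data.frame of
#'   per-row diagnostics), `n_rejected`.
#' @export
read_inventory <- function(tree_csv, section_csv, mapping = column_mapping()) {
  stopifnot(inherits(mapping, "column_mapping"))
  for (f in c(tree_csv, section_csv))
    if (!file.exists(f)) stopf("read_inventory: file not found: %s", f)
  tt <- read.csv(tree_csv, stringsAsFactors = FALSE)
  st <- read.csv(section_csv, stringsAsFactors = FALSE)
  if (nrow(tt) == 0L) stopf("read_inventory: empty tree table")
  if (nrow(st) == 0L) stopf("read_inventory: empty section table")
  for (col in mapping$tree_cols)
    if (!col %in% names(tt)) stopf("read_inventory: tree table lacks column '%s'", col)
  for (col in mapping$section_cols)
    if (!col %in% names(st)) stopf("read_inventory: section table lacks column '%s'", col)

  tc <- mapping$tree_cols; sc <- mapping$section_cols
  tt2 <- data.frame(tree_id = as.character(tt[[tc["tree_id"]]]),
                    forest_type = as.character(tt[[tc["forest_type"]]]),
                    species = as.character(tt[[tc["species"]]]),
                    dbh = tt[[tc["dbh"]]] * mapping$dbh_factor,
                    ht = tt[[tc["ht"]]] * mapping$ht_factor)
  if (!is.null(mapping$forest_levels))
    tt2$forest_type <- unname(mapping$forest_levels[tt2$forest_type])
  st2 <- data.frame(tree_id = as.character(st[[sc["tree_id"]]]),
                    stem_id = as.character(st[[sc["stem_id"]]]),
                    h = st[[sc["h"]]] * mapping$h_factor,
                    d = st[[sc["d"]]] * mapping$d_factor)

  rejects <- list()
  reject <- function(df, reason)
    if (nrow(df)) rejects[[length(rejects) + 1L]] <<-
      data.frame(tree_id = df$tree_id, stem_id = df$stem_id, h = df$h,
                 d = df$d, reason = reason)
  trees <- list()
  for (i in seq_len(nrow(tt2))) {
    tri <- tt2[i, ]
    sec <- st2[st2$tree_id == tri$tree_id, ]
    bad_d <- !is.finite(sec$d) | sec$d <= 0
    reject(sec[bad_d, ], "non-positive diameter")
    sec <- sec[!bad_d, ]
    bad_h <- !is.finite(sec$h) | sec$h < 0 | sec$h >= tri$ht
    reject(sec[bad_h, ], "height outside [0, ht)")
    sec <- sec[!bad_h, ]
    stems <- list()
    for (sid in unique(sec$stem_id)) {
      s <- sec[sec$stem_id == sid, ]
      s <- s[order(s$h), ]
      dup <- duplicated(s$h)
      reject(s[dup, ], "duplicated height within stem")
      s <- s[!dup, ]
      if (nrow(s) < 2L) { reject(s, "fewer than 2 usable measurements"); next }
      stems[[sid]] <- stem_profile(sid, s$h, s$d)
    }
    if (length(stems) == 0L) next
    trees[[tri$tree_id]] <- taper_tree(tri$tree_id, tri$forest_type,
                                       tri$dbh, tri$ht, stems, tri$species)
  }
  if (length(trees) == 0L) stopf("read_inventory: no valid trees")
  rej <- if (length(rejects)) do.call(rbind, c(rejects, make.row.names = FALSE))
         else data.frame(tree_id = character(), stem_id = character(),
                         h = numeric(), d = numeric(), reason = character())
  list(trees = trees, rejects = rej, n_rejected = nrow(rej))
}

#' Write an inventory to tree and section CSV files
#'
#' Inverse of [read_inventory()] under the canonical schema; the round trip
#' reproduces the tree set exactly (up to CSV number formatting, avoided by
#' writing full precision).
#'
#' @param trees list of [taper_tree()].
#' @param tree_csv,section_csv output paths.
#' @return Invisibly, the two paths.
#' @export
write_inventory <- function(trees, tree_csv, section_csv) {
  stopifnot(all(vapply(trees, inherits, TRUE, "taper_tree")))
  tt <- do.call(rbind, lapply(trees, function(tr)
    data.frame(tree_id = tr$tree_id, forest_type = tr$forest_type,
               species = tr$species, dbh_cm = tr$dbh, ht_m = tr$ht)))
  st <- do.call(rbind, lapply(trees, function(tr)
    do.call(rbind, lapply(tr$stems, function(s)
      data.frame(tree_id = tr$tree_id, stem_id = s$stem_id,
                 h_m = s$h, d_cm = s$d)))))
  write.csv(format(tt, digits = 17, trim = TRUE), tree_csv,
            row.names = FALSE, quote = FALSE)
  write.csv(format(st, digits = 17, trim = TRUE), section_csv,
            row.names = FALSE, quote = FALSE)
  invisible(c(tree_csv, section_csv))
}
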