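#' Render the run report
#'
#' Writes deterministic artifacts from a pipeline run into a directory:
#' `taper_fits.csv` (per model x forest: parameters, SSE, n, convergence,
#' AICc — non-converged fits carry the marker `no convergence` instead of a
#' score), `cv_runs.csv` (the raw per-iteration metric stream),
#' `cv_summary.csv` (mean RMSE/bias/EF per method x target x partition) and
#' `report.txt` (human-readable rendering of all three). Every number in
#' the text report is re-derivable from the CSVs.
#'
#' @param cv a [cross_validate()] result.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
run_report <- function(cv, out_dir) {
  stopifnot(inherits(cv, "cv_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  fits_df <- NULL
  if (!is.null(cv$selection_fits)) {
    fits_df <- do.call(rbind, lapply(cv$selection_fits, function(f)
      data.frame(model = f$spec$name, forest_type = f$forest_type,
                 beta = paste(signif(f$beta, 8), collapse = ";"),
                 sse = f$sse, n_obs = f$n_obs, converged = f$converged,
                 aicc = ifelse(f$converged, sprintf("%.4f", f$aicc),
                               "no convergence"))))
    p <- file.path(out_dir, "taper_fits.csv")
    write.csv(fits_df, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "cv_runs.csv")
  write.csv(cv$runs, p, row.names = FALSE)
  paths <- c(paths, p)

  summ <- cv_summary(cv)
  p <- file.path(out_dir, "cv_summary.csv")
  write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)

  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("stem taper modelling run report")
  w("===============================")
  w("iterations: %d  validation fraction: %.2f  seed: %d",
    cv$n_iter, cv$val_frac, cv$seed)
  if (!is.null(fits_df)) {
    w("")
    w("AICc per taper model and forest type")
    for (i in seq_len(nrow(fits_df)))
      w("  %-13s %-14s %s", fits_df$model[i], fits_df$forest_type[i],
        fits_df$aicc[i])
    w("")
    w("AICc wins per model")
    for (nm in names(cv$tally$counts))
      if (cv$tally$counts[nm] > 0) w("  %-13s %d", nm, cv$tally$counts[nm])
    w("overall best taper model: %s", cv$tally$best_model)
    w("taper non-convergent CV iterations: %d", cv$tm_failures)
  }
  w("")
  w("mean metrics over iterations (method / target / partition)")
  for (i in seq_len(nrow(summ)))
    w("  %-3s %-4s %-10s rmse %.4g  bias %+.4g  ef %.4f",
      summ$method[i], summ$target[i], summ$partition[i],
      summ$rmse[i], summ$bias[i], summ$ef[i])
  paths <- c(paths, txt)
  invisible(paths)
}

# Manifest: everything needed to reproduce a CLI run bit-for-bit.
write_manifest <- function(out_dir, config, seed, inputs = character(0)) {
  man <- list(package = "stemtaper",
              version = as.character(packageVersion("stemtaper")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = seed, config = config,
              input_md5 = as.list(tools::md5sum(inputs)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
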