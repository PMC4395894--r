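# File exports for an analysis: CSV matrices, report JSON/CSV, and summary
# PNG panels (visual aid only; no numeric contract on the images).

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write every artifact of an analysis to a directory
#'
#' Writes `report.json`, `report.csv`, `contours.csv` (long format),
#' component maps (`full.csv`, `eyeball.csv`, `cornea.csv`, `cornea_low.csv`,
#' `vibration.csv`, `baseline.csv`), `spectra.csv` with a `spectra_freqs.csv`
#' axis, a `provenance.json` block (configuration, package version) and a
#' `summary.png` panel figure.
#'
#' @param analysis a `corvis_analysis`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "corvis_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- analysis$report
  jsonlite::write_json(unclass(rep), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  utils::write.csv(as.data.frame(rep), file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(analysis$contours),
                   file.path(out_dir, "contours.csv"), row.names = FALSE)
  f <- analysis$field
  write_matrix_csv(f$full, file.path(out_dir, "full.csv"))
  write_matrix_csv(f$eyeball, file.path(out_dir, "eyeball.csv"))
  write_matrix_csv(f$cornea, file.path(out_dir, "cornea.csv"))
  write_matrix_csv(f$cornea_low, file.path(out_dir, "cornea_low.csv"))
  write_matrix_csv(f$vibration, file.path(out_dir, "vibration.csv"))
  write_matrix_csv(matrix(f$baseline, nrow = 1),
                   file.path(out_dir, "baseline.csv"))
  write_matrix_csv(analysis$spectrum$amplitude,
                   file.path(out_dir, "spectra.csv"))
  write_matrix_csv(matrix(analysis$spectrum$freqs, ncol = 1),
                   file.path(out_dir, "spectra_freqs.csv"))
  prov <- list(package = "corvistk",
               version = as.character(utils::packageVersion("corvistk")),
               source_id = analysis$source_id,
               config = analysis$config)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  try(plot_analysis_summary(analysis, file.path(out_dir, "summary.png")),
      silent = TRUE)
  invisible(out_dir)
}

#' Summary panel figure of an analysis
#'
#' Four panels: full deformation map, corneal component map, vibration map,
#' and the apex traces of the decomposition.
#'
#' @param analysis a `corvis_analysis`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_analysis_summary <- function(analysis, path) {
  f <- analysis$field
  grDevices::png(path, width = 1200, height = 900)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  show_map <- function(m, main) {
    graphics::image(x = 0:(nrow(m) - 1), y = 0:(ncol(m) - 1), z = m,
                    xlab = "frame", ylab = "column", main = main,
                    col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE)
  }
  show_map(f$full, "full deformation [px]")
  show_map(f$cornea, "corneal deformation [px]")
  show_map(f$vibration, sprintf("vibration > %g Hz [px]", f$cutoff_hz))
  apex <- apex_column(f)
  graphics::matplot(0:(nrow(f$full) - 1),
                    cbind(f$full[, apex], f$eyeball[, apex], f$cornea[, apex]),
                    type = "l", lty = 1, col = c("black", "blue", "red"),
                    xlab = "frame", ylab = "displacement [px]",
                    main = "apex traces")
  graphics::legend("topright", c("full", "eyeball", "cornea"),
                   col = c("black", "blue", "red"), lty = 1, bty = "n")
  invisible(path)
}
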