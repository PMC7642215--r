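# Ki-67 positivity quantification: the ratio of positive cells to all cells.
# Nucleus pixels are separated from background/stroma by a saturation +
# darkness rule, split into brown-dominant (positive) vs blue-dominant
# (negative) by the R - B margin, and counted as 8-connected components.

#' Thresholds of the colour-rule nucleus counter
#'
#' @param min_saturation minimum HSV saturation of a nucleus pixel.
#' @param max_value maximum HSV value (darkness requirement).
#' @param positive_margin a cell is positive when its mean R minus mean B
#'   exceeds this margin (8-bit scale).
#' @param min_area minimum component area in pixels (calibrated to the
#'   synthetic nucleus radii; scale by (cell_radius)^2 for other
#'   resolutions).
#' @return list of class `quantify_config`.
#' @export
quantify_config <- function(min_saturation = 0.15, max_value = 0.85,
                            positive_margin = 20, min_area = 9L) {
  structure(list(min_saturation = min_saturation, max_value = max_value,
                 positive_margin = positive_margin,
                 min_area = as.integer(min_area)),
            class = "quantify_config")
}

#' Detect nuclei and compute the positivity ratio of a Ki-67-style image
#'
#' @param image `slide_image` or (H, W, 3) array in \[0, 255\].
#' @param config a [quantify_config()].
#' @return object of class `positivity_result`: `n_positive`, `n_total`,
#'   `ratio` (`NA` when no cells are found), and `cells` (data.frame with
#'   0-based centroid `x`, `y`, `area`, `positive`).
#' @export
detect_nuclei <- function(image, config = quantify_config()) {
  px <- as_pixels(image)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  value <- mx / 255
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  nucleus <- sat >= config$min_saturation & value < config$max_value
  lab <- nn_bwlabel8(nucleus)
  nl <- attr(lab, "n_labels")
  if (nl == 0) {
    return(structure(list(n_positive = 0L, n_total = 0L, ratio = NA_real_,
                          cells = data.frame(x = numeric(), y = numeric(),
                                             area = integer(),
                                             positive = logical())),
                     class = "positivity_result"))
  }
  st <- nn_label_stats(lab, nl)
  # mean R - B per component
  idx <- lab > 0
  labs_px <- lab[idx]
  sum_r <- tapply(r[idx], labs_px, sum)
  sum_b <- tapply(b[idx], labs_px, sum)
  comp_ids <- as.integer(names(sum_r))
  area <- st$area[comp_ids]
  keep <- area >= config$min_area
  rb <- (sum_r[keep] - sum_b[keep]) / area[keep]
  positive <- as.vector(rb) > config$positive_margin
  cells <- data.frame(x = st$x[comp_ids][keep], y = st$y[comp_ids][keep],
                      area = area[keep], positive = positive)
  n_total <- nrow(cells)
  structure(list(n_positive = sum(cells$positive), n_total = n_total,
                 ratio = if (n_total > 0) sum(cells$positive) / n_total else NA_real_,
                 cells = cells),
            class = "positivity_result")
}

#' @export
print.positivity_result <- function(x, ...) {
  if (x$n_total == 0) {
    cat("<positivity_result> no cells detected; ratio undefined\n")
  } else {
    cat(sprintf("<positivity_result> %d / %d positive cells, ratio %.4f\n",
                x$n_positive, x$n_total, x$ratio))
  }
  invisible(x)
}

#' Compare positivity ratios of a real and a synthetic Ki-67 image
#'
#' @param real,synthetic `slide_image` or pixel arrays.
#' @param config a [quantify_config()].
#' @return object of class `ratio_comparison`: `ratio_real`,
#'   `ratio_synthetic`, `abs_difference` (`NA` and `flagged = TRUE` when
#'   either ratio is undefined).
#' @export
compare_ratios <- function(real, synthetic, config = quantify_config()) {
  rr <- detect_nuclei(real, config)
  rs <- detect_nuclei(synthetic, config)
  flagged <- is.na(rr$ratio) || is.na(rs$ratio)
  structure(list(ratio_real = rr$ratio, ratio_synthetic = rs$ratio,
                 abs_difference = if (flagged) NA_real_
                   else abs(rr$ratio - rs$ratio),
                 n_cells_real = rr$n_total, n_cells_synthetic = rs$n_total,
                 flagged = flagged),
            class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat("          Real Ki-67   Synthetic Ki-67   |difference|\n")
  cat(sprintf("Ratio     %-12s %-17s %s\n",
              ifelse(is.na(x$ratio_real), "undefined", sprintf("%.4f", x$ratio_real)),
              ifelse(is.na(x$ratio_synthetic), "undefined", sprintf("%.4f", x$ratio_synthetic)),
              ifelse(x$flagged, "flagged", sprintf("%.4f", x$abs_difference))))
  invisible(x)
}

#' Per-slide and aggregate positivity report for a cohort
#'
#' For every slide in the manifest: translates the HE image with the fitted
#' CycleGAN, quantifies the real and the synthetic Ki-67 image, and appends
#' an aggregate row of mean ratios — a machine-readable analogue of a
#' real-vs-synthetic ratio table.
#'
#' @param manifest manifest from [render_cohort()] / [read_manifest()].
#' @param fit a `cyclegan_fit`.
#' @param small_size tile side used for translation.
#' @param config a [quantify_config()].
#' @return data.frame with columns `slide_id`, `ratio_real`,
#'   `ratio_synthetic`, `abs_difference`, `n_cells_real`,
#'   `n_cells_synthetic`; the last row (`slide_id == "mean"`) aggregates.
#' @export
cohort_report <- function(manifest, fit, small_size = 32L,
                          config = quantify_config()) {
  slides <- manifest$slides
  empty <- data.frame(slide_id = character(), ratio_real = numeric(),
                      ratio_synthetic = numeric(), abs_difference = numeric(),
                      n_cells_real = integer(), n_cells_synthetic = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(slides) || nrow(slides) == 0) return(empty)
  rows <- vector("list", nrow(slides))
  for (i in seq_len(nrow(slides))) {
    for (f in c(slides$he[i], slides$ki67[i]))
      if (!file.exists(f)) stop("cohort_report: missing artifact ", f)
    he <- read_slide(slides$he[i], "HE")
    real_ki <- read_slide(slides$ki67[i], "KI67")
    syn_ki <- predict(fit, he, small_size = small_size)
    cmp <- compare_ratios(real_ki, syn_ki, config)
    rows[[i]] <- data.frame(slide_id = slides$slide_id[i],
                            ratio_real = cmp$ratio_real,
                            ratio_synthetic = cmp$ratio_synthetic,
                            abs_difference = cmp$abs_difference,
                            n_cells_real = cmp$n_cells_real,
                            n_cells_synthetic = cmp$n_cells_synthetic,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  agg <- data.frame(slide_id = "mean",
                    ratio_real = mean(out$ratio_real, na.rm = TRUE),
                    ratio_synthetic = mean(out$ratio_synthetic, na.rm = TRUE),
                    abs_difference = mean(out$abs_difference, na.rm = TRUE),
                    n_cells_real = as.integer(round(mean(out$n_cells_real))),
                    n_cells_synthetic = as.integer(round(mean(out$n_cells_synthetic))),
                    stringsAsFactors = FALSE)
  rbind(out, agg)
}

#' Write a cohort report as CSV and JSON
#' @param report data.frame from [cohort_report()].
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(report)
}
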