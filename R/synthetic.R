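# Synthetic two-domain slide generator. Emulates pairs of consecutive-section
# stains: an HE-like rendering (purple nuclei on pink tissue) and a Ki-67-like
# rendering (DAB-brown positive nuclei, blue negative nuclei on a grey-blue
# counterstained field) sharing one cell geometry, with full ground truth.

#' Fixed colour palette of the synthetic stains
#'
#' 8-bit RGB constants used by [render_slide_pair()]. Background is near-white
#' (all channels >= 241). Tissue tones sit at mid luma (~150) so that the Otsu
#' histogram of a rendered slide is dominated by the background/tissue split;
#' nuclei are darker still. Positive (DAB brown) and negative (haematoxylin
#' blue) Ki-67 nuclei are linearly separable on the R - B axis by a wide
#' margin, which is what makes the positivity counter oracle-exact.
#'
#' @return named list of RGB triplets and noise standard deviations.
#' @export
stain_palette <- function() {
  list(
    background        = c(247, 246, 248),
    he_tissue         = c(205, 125, 165),   # eosin pink
    he_nucleus_normal = c(91, 42, 134),     # haematoxylin purple
    he_nucleus_tumor  = c(56, 20, 90),      # denser chromatin, darker purple
    ki_tissue         = c(150, 155, 165),   # counterstained stroma, low saturation
    ki_positive       = c(139, 69, 19),     # DAB brown
    ki_negative       = c(43, 75, 140),     # haematoxylin blue
    background_noise_sd = 1.5,
    tissue_noise_sd     = 4,
    nucleus_noise_sd    = 3
  )
}

#' Specify a synthetic slide
#'
#' @param width,height image size in pixels (>= 64).
#' @param tissue_fraction fraction of the image covered by tissue, in (0, 1].
#' @param n_cells number of nuclei to place (>= 0); if the requested density
#'   is infeasible under the non-overlap constraint, fewer are placed with a
#'   warning.
#' @param tumor_region_fraction fraction of the tissue belonging to the tumor
#'   blob, in \[0, 1\].
#' @param positive_fraction fraction of tumor-region nuclei rendered Ki-67
#'   positive, in \[0, 1\].
#' @param cell_radius_px numeric length-2, min and max nucleus radius in px.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   renderings.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(width = 320L, height = 320L, tissue_fraction = 0.75,
                       n_cells = 150L, tumor_region_fraction = 0.4,
                       positive_fraction = 1.0, cell_radius_px = c(3, 5),
                       seed = 1L) {
  check <- function(ok, field, msg) if (!ok) stop("slide_spec: invalid ", field, ": ", msg, call. = FALSE)
  check(is.numeric(width) && length(width) == 1 && width >= 64, "width", "must be >= 64")
  check(is.numeric(height) && length(height) == 1 && height >= 64, "height", "must be >= 64")
  check(is.numeric(tissue_fraction) && tissue_fraction > 0 && tissue_fraction <= 1,
        "tissue_fraction", "must be in (0, 1]")
  check(is.numeric(n_cells) && n_cells >= 0, "n_cells", "must be >= 0")
  check(is.numeric(tumor_region_fraction) && tumor_region_fraction >= 0 &&
          tumor_region_fraction <= 1, "tumor_region_fraction", "must be in [0, 1]")
  check(is.numeric(positive_fraction) && positive_fraction >= 0 &&
          positive_fraction <= 1, "positive_fraction", "must be in [0, 1]")
  check(length(cell_radius_px) == 2 && all(cell_radius_px > 0) &&
          cell_radius_px[1] <= cell_radius_px[2], "cell_radius_px",
        "must be (min, max) with 0 < min <= max")
  check(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  structure(list(width = as.integer(width), height = as.integer(height),
                 tissue_fraction = tissue_fraction, n_cells = as.integer(n_cells),
                 tumor_region_fraction = tumor_region_fraction,
                 positive_fraction = positive_fraction,
                 cell_radius_px = as.numeric(cell_radius_px),
                 seed = as.integer(seed)),
            class = "slide_spec")
}

new_slide_image <- function(pixels, domain) {
  structure(list(pixels = pixels, domain = domain), class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s, %d x %d px\n", x$domain, d[2], d[1]))
  invisible(x)
}

# Bilinear upsampling of an m x m Gaussian grid: a cheap smooth random field
# whose threshold sets carve blob-shaped regions.
smooth_field <- function(h, w, m) {
  g <- matrix(stats::rnorm(m * m), m, m)
  ys <- seq(1, m, length.out = h); xs <- seq(1, m, length.out = w)
  y0 <- pmin(floor(ys), m - 1); x0 <- pmin(floor(xs), m - 1)
  fy <- ys - y0; fx <- xs - x0
  g[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    g[y0 + 1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    g[y0, x0 + 1, drop = FALSE] * outer(1 - fy, fx) +
    g[y0 + 1, x0 + 1, drop = FALSE] * outer(fy, fx)
}

# Threshold a smooth field so that `fraction` of `within` (logical matrix or
# NULL for everywhere) is selected.
blob_mask <- function(h, w, fraction, m, within = NULL) {
  if (fraction <= 0) return(matrix(FALSE, h, w))
  f <- smooth_field(h, w, m)
  if (is.null(within)) {
    if (fraction >= 1) return(matrix(TRUE, h, w))
    thr <- stats::quantile(f, 1 - fraction, names = FALSE)
    f >= thr
  } else {
    out <- matrix(FALSE, h, w)
    if (fraction >= 1) { out[within] <- TRUE; return(out) }
    vals <- f[within]
    thr <- stats::quantile(vals, 1 - fraction, names = FALSE)
    out[within] <- vals >= thr
    out
  }
}

# Place up to n non-overlapping ellipse centres inside `mask`, keeping
# boundary gaps >= 2 px so every nucleus is its own connected component.
# Separation checks use a bucket grid so placement stays near-linear in n.
place_cells <- function(mask, n, radius_range, tumor_scale, tumor_mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  if (n == 0 || length(idx) == 0) {
    return(data.frame(x = integer(), y = integer(), rx = numeric(),
                      ry = numeric(), angle = numeric(), tumor = logical()))
  }
  max_try <- 40L * n
  xs <- ys <- integer(n); rxs <- rys <- angs <- numeric(n); tum <- logical(n)
  reff <- numeric(n)  # effective (major) radius for separation checks
  # bucket grid sized to the largest possible exclusion distance
  gs <- ceiling(2 * radius_range[2] * max(1, tumor_scale) + 2)
  gb_h <- (h - 1L) %/% gs + 1L; gb_w <- (w - 1L) %/% gs + 1L
  buckets <- vector("list", gb_h * gb_w)
  bucket_of <- function(x, y) (x %/% gs) * gb_h + (y %/% gs) + 1L
  placed <- 0L; tries <- 0L
  while (placed < n && tries < max_try) {
    tries <- tries + 1L
    pick <- idx[sample.int(length(idx), 1L)]
    y <- ((pick - 1L) %% h)            # 0-based row
    x <- ((pick - 1L) %/% h)           # 0-based col
    is_tumor <- tumor_mask[y + 1L, x + 1L]
    r <- stats::runif(1, radius_range[1], radius_range[2]) *
      (if (is_tumor) tumor_scale else 1)
    # keep the whole ellipse inside the image
    if (y - r < 1 || y + r > h - 2 || x - r < 1 || x + r > w - 2) next
    bx <- x %/% gs; by <- y %/% gs
    neigh <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      nbx <- bx + dx; nby <- by + dy
      if (nbx < 0 || nbx >= gb_w || nby < 0 || nby >= gb_h) next
      neigh <- c(neigh, buckets[[nbx * gb_h + nby + 1L]])
    }
    if (length(neigh)) {
      dd <- sqrt((xs[neigh] - x)^2 + (ys[neigh] - y)^2)
      if (any(dd < reff[neigh] + r + 2)) next
    }
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
    rxs[placed] <- r
    rys[placed] <- r * stats::runif(1, 0.75, 1)
    angs[placed] <- stats::runif(1, 0, pi)
    reff[placed] <- r
    tum[placed] <- is_tumor
    bi <- bucket_of(x, y)
    buckets[[bi]] <- c(buckets[[bi]], placed)
  }
  if (placed < n)
    warning(sprintf("placed %d of %d requested cells (density too high)", placed, n))
  keep <- seq_len(placed)
  data.frame(x = xs[keep], y = ys[keep], rx = rxs[keep], ry = rys[keep],
             angle = angs[keep], tumor = tum[keep])
}

# Linear (column-major) pixel indices of one filled ellipse, 0-based centre.
ellipse_indices <- function(x, y, rx, ry, angle, h, w) {
  r <- ceiling(max(rx, ry))
  rows <- max(1, y + 1 - r):min(h, y + 1 + r)
  cols <- max(1, x + 1 - r):min(w, x + 1 + r)
  dy <- rows - 1 - y; dx <- cols - 1 - x
  ca <- cos(angle); sa <- sin(angle)
  u <- outer(dy, dx, function(a, b) (b * ca + a * sa) / rx)
  v <- outer(dy, dx, function(a, b) (-b * sa + a * ca) / ry)
  inside <- (u * u + v * v) <= 1
  (rep(cols, each = length(rows))[inside] - 1L) * h +
    rep(rows, times = length(cols))[inside]
}

render_domain <- function(geom, domain, pal) {
  h <- geom$height; w <- geom$width
  img <- array(0, c(h, w, 3))
  tissue_col <- if (domain == "HE") pal$he_tissue else pal$ki_tissue
  planes <- vector("list", 3)
  # texture is luminance-only (one noise field shared by all channels), so
  # background and tissue never gain saturation and the colour rules of the
  # quantifier stay exact
  bg_noise <- stats::rnorm(h * w, 0, pal$background_noise_sd)
  ti_noise <- stats::rnorm(h * w, 0, pal$tissue_noise_sd)
  for (ch in 1:3) {
    bg <- pmin(pmax(pal$background[ch] + bg_noise, 241), 255)
    ti <- pmin(pmax(tissue_col[ch] + ti_noise, 0), 240)
    plane <- matrix(bg, h, w)
    plane[geom$foreground_mask] <- matrix(ti, h, w)[geom$foreground_mask]
    planes[[ch]] <- plane
  }
  cells <- geom$cells
  if (nrow(cells) > 0) {
    n <- nrow(cells)
    idx_list <- vector("list", n)
    val_list <- list(vector("list", n), vector("list", n), vector("list", n))
    for (i in seq_len(n)) {
      col <- if (domain == "HE") {
        if (cells$tumor[i]) pal$he_nucleus_tumor else pal$he_nucleus_normal
      } else {
        if (geom$positive[i]) pal$ki_positive else pal$ki_negative
      }
      idx <- ellipse_indices(cells$x[i], cells$y[i], cells$rx[i], cells$ry[i],
                             cells$angle[i], h, w)
      idx_list[[i]] <- idx
      npx <- length(idx)
      for (ch in 1:3)
        val_list[[ch]][[i]] <- pmin(pmax(col[ch] + stats::rnorm(npx, 0, pal$nucleus_noise_sd), 0), 255)
    }
    all_idx <- unlist(idx_list)
    for (ch in 1:3) planes[[ch]][all_idx] <- unlist(val_list[[ch]])
  }
  for (ch in 1:3) img[, , ch] <- planes[[ch]]
  round(img)
}

#' Render one synthetic HE / Ki-67 slide pair with ground truth
#'
#' Draws a tissue blob on a near-white background, places non-overlapping
#' elliptical nuclei inside it (tumor nuclei confined to a tumor sub-blob and
#' rendered larger and, in HE, darker), then renders the same geometry twice:
#' HE-style (purple nuclei on pink tissue) and Ki-67-style (brown positive /
#' blue negative nuclei on a desaturated field). Positivity is sampled
#' per tumor-region nucleus with probability `positive_fraction`; normal
#' nuclei are never positive.
#'
#' @param spec a [slide_spec()].
#' @return list with elements `he` and `ki67` (class `slide_image`) and `gt`
#'   (class `ground_truth`: `cell_centers` (n x 2, 0-based x = column,
#'   y = row), `cell_labels`, `cell_positive`, `tumor_mask`,
#'   `foreground_mask`).
#' @export
render_slide_pair <- function(spec) {
  if (!inherits(spec, "slide_spec")) spec <- do.call(slide_spec, spec)
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    fg <- blob_mask(h, w, spec$tissue_fraction, m = 5L)
    tm <- blob_mask(h, w, spec$tumor_region_fraction, m = 4L, within = fg)
    cells <- place_cells(fg, spec$n_cells, spec$cell_radius_px,
                         tumor_scale = 1.5, tumor_mask = tm)
    positive <- cells$tumor & (stats::runif(nrow(cells)) < spec$positive_fraction)
    geom <- list(height = h, width = w, foreground_mask = fg, tumor_mask = tm,
                 cells = cells, positive = positive)
    pal <- stain_palette()
    he <- render_domain(geom, "HE", pal)
    ki <- render_domain(geom, "KI67", pal)
    gt <- structure(list(
      cell_centers = cbind(x = cells$x, y = cells$y),
      cell_labels = ifelse(cells$tumor, "TUMOR", "NORMAL"),
      cell_positive = positive,
      tumor_mask = tm,
      foreground_mask = fg
    ), class = "ground_truth")
    list(he = new_slide_image(he, "HE"), ki67 = new_slide_image(ki, "KI67"), gt = gt)
  })
}

gt_positivity_ratio <- function(gt) {
  n <- length(gt$cell_positive)
  if (n == 0) return(NA_real_)
  sum(gt$cell_positive) / n
}

rle_encode <- function(mask) {
  r <- rle(as.integer(mask))
  list(h = nrow(mask), w = ncol(mask), lengths = r$lengths, values = r$values)
}

rle_decode <- function(enc) {
  v <- inverse.rle(list(lengths = enc$lengths, values = enc$values))
  matrix(as.logical(v), enc$h, enc$w)
}

#' Write ground truth to a JSON sidecar
#' @param gt a `ground_truth` object.
#' @param path output path (conventionally `<stem>.gt.json`).
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(
    cell_centers = unname(gt$cell_centers),
    cell_labels = gt$cell_labels,
    cell_positive = gt$cell_positive,
    tumor_mask = rle_encode(gt$tumor_mask),
    foreground_mask = rle_encode(gt$foreground_mask)
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path path written by [write_ground_truth()].
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- obj$cell_centers
  if (length(cc) == 0) cc <- matrix(integer(), 0, 2)
  colnames(cc) <- c("x", "y")
  structure(list(
    cell_centers = cc,
    cell_labels = as.character(obj$cell_labels),
    cell_positive = as.logical(obj$cell_positive),
    tumor_mask = rle_decode(obj$tumor_mask),
    foreground_mask = rle_decode(obj$foreground_mask)
  ), class = "ground_truth")
}

#' Write a slide image as 8-bit RGB PNG
#' @param image a `slide_image` or (H, W, 3) array of values in \[0, 255\].
#' @param path output path; if `raw()`, returns the PNG payload as raw bytes.
#' @export
write_slide <- function(image, path) {
  px <- if (inherits(image, "slide_image")) image$pixels else image
  png::writePNG(round(px) / 255, path)
}

#' Read a PNG slide image
#' @param path PNG file.
#' @param domain domain tag to attach (`"HE"` or `"KI67"`).
#' @export
read_slide <- function(path, domain = "HE") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]
  new_slide_image(round(px * 255), domain)
}

#' Render a cohort of synthetic slide pairs to disk
#'
#' Writes `n_slides` HE/Ki-67 PNG pairs plus ground-truth sidecars and a
#' `manifest.json` listing paths, the per-slide seed (template seed + i), and
#' the ground-truth positivity ratio of each slide.
#'
#' @param n_slides number of slide pairs (>= 1).
#' @param spec_template a [slide_spec()] whose seed anchors the per-slide seeds.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly a list with `slides` (data.frame) and
#'   `spec_template`.
#' @export
render_cohort <- function(n_slides, spec_template, out_dir) {
  if (!is.numeric(n_slides) || n_slides < 1)
    stop("render_cohort: n_slides must be >= 1")
  n_slides <- as.integer(n_slides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("render_cohort: cannot create out_dir ", out_dir)
  rows <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    sp <- spec_template
    sp$seed <- spec_template$seed + i
    pair <- render_slide_pair(sp)
    stem <- sprintf("slide_%03d", i)
    he_path <- file.path(out_dir, paste0(stem, "_HE.png"))
    ki_path <- file.path(out_dir, paste0(stem, "_KI67.png"))
    gt_path <- file.path(out_dir, paste0(stem, ".gt.json"))
    write_slide(pair$he, he_path)
    write_slide(pair$ki67, ki_path)
    write_ground_truth(pair$gt, gt_path)
    rows[[i]] <- data.frame(slide_id = stem, he = he_path, ki67 = ki_path,
                            gt = gt_path, seed = sp$seed,
                            gt_positivity_ratio = gt_positivity_ratio(pair$gt),
                            stringsAsFactors = FALSE)
  }
  manifest <- list(slides = do.call(rbind, rows),
                   spec_template = unclass(spec_template))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest
}

#' Read a cohort manifest written by [render_cohort()]
#' @param path the `manifest.json` file or its directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
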