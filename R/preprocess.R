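# Foreground extraction and two-scale patch extraction: Otsu thresholding of
# the slide, non-overlapping large-patch bagging for MIL, and small-patch
# tiling for both MIL instances and GAN training pools.

as_pixels <- function(image) {
  if (inherits(image, "slide_image")) image$pixels else image
}

#' Convert an RGB image to 8-bit grayscale using standard luma weights
#' @param image `slide_image` or (H, W, 3) array in \[0, 255\].
#' @return integer matrix of gray levels 0..255.
#' @export
to_grayscale <- function(image) {
  px <- as_pixels(image)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(as.integer(round(g)), nrow(g), ncol(g))
}

# Otsu's threshold on a 256-bin histogram of gray levels 0..255: the level t
# maximising the between-class variance of {g <= t} vs {g > t}; ties break to
# the lowest t. Returns NA for a constant image.
otsu_threshold <- function(gray) {
  counts <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  p <- counts / n
  w0 <- cumsum(p)
  mu_t <- sum(levels * p)
  mu0 <- cumsum(levels * p)
  valid <- w0 > 0 & w0 < 1
  if (!any(valid)) return(NA_integer_)
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  as.integer(which.max(sigma_b) - 1L)
}

#' Otsu foreground extraction
#'
#' Converts the slide to grayscale (luma weights 0.299/0.587/0.114), computes
#' Otsu's between-class-variance-maximising threshold on the 256-bin
#' histogram, and marks as foreground the pixels at or below the threshold
#' (tissue is darker than the near-white slide background).
#'
#' @param image `slide_image` or (H, W, 3) array in \[0, 255\].
#' @return object of class `foreground_mask`: list with `mask` (logical
#'   matrix) and `threshold_used` (gray level, `NA` for a constant image, in
#'   which case the mask is all background and a warning is issued).
#' @export
otsu_foreground <- function(image) {
  gray <- to_grayscale(image)
  thr <- otsu_threshold(gray)
  if (is.na(thr)) {
    warning("otsu_foreground: constant image; returning all-background mask")
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
  } else {
    mask <- gray <= thr
  }
  structure(list(mask = mask, threshold_used = thr), class = "foreground_mask")
}

grid_origins <- function(extent, size) {
  n <- extent %/% size
  if (n < 1) integer() else (seq_len(n) - 1L) * size
}

#' Extract non-overlapping large patches covering enough foreground
#'
#' Tiles the image on a non-overlapping grid from origin (0, 0); partial
#' border tiles are dropped; tiles whose foreground coverage is below
#' `min_fg_fraction` are discarded.
#'
#' @param image `slide_image` or (H, W, 3) array.
#' @param mask a `foreground_mask` (or logical matrix) matching the image.
#' @param large_size tile side in pixels.
#' @param min_fg_fraction minimum fraction of foreground pixels to retain a
#'   tile (default 0.05).
#' @return list of `list(origin = c(row, col), pixels)` with 0-based origins;
#'   empty (with a warning) if the image is smaller than `large_size`.
#' @export
extract_large_patches <- function(image, mask, large_size = 2240L,
                                  min_fg_fraction = 0.05) {
  px <- as_pixels(image)
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  h <- dim(px)[1]; w <- dim(px)[2]
  if (large_size > h || large_size > w) {
    warning("extract_large_patches: image smaller than large_size")
    return(list())
  }
  out <- list()
  for (r in grid_origins(h, large_size)) {
    for (cc in grid_origins(w, large_size)) {
      rows <- (r + 1):(r + large_size); cols <- (cc + 1):(cc + large_size)
      if (mean(m[rows, cols]) >= min_fg_fraction) {
        out[[length(out) + 1L]] <- list(origin = c(r, cc),
                                        pixels = px[rows, cols, , drop = FALSE])
      }
    }
  }
  out
}

#' Tile a region into small patches on a non-overlapping row-major grid
#'
#' Border remainders are dropped, never padded. No foreground filtering is
#' applied: for GAN pools the background tiles are kept deliberately, since
#' the generator must synthesise background too.
#'
#' @param region (H, W, 3) array or `slide_image`.
#' @param small_size tile side in pixels.
#' @param domain domain tag attached to each patch.
#' @param offset 0-based (row, col) of the region inside its source image;
#'   patch origins are reported in source coordinates.
#' @return ordered list of `small_patch` objects: `list(pixels, origin, domain)`.
#' @export
tile_small_patches <- function(region, small_size = 224L, domain = "HE",
                               offset = c(0L, 0L)) {
  px <- as_pixels(region)
  if (inherits(region, "slide_image")) domain <- region$domain
  h <- dim(px)[1]; w <- dim(px)[2]
  if (small_size > h || small_size > w) return(list())
  out <- list()
  for (r in grid_origins(h, small_size)) {        # row-major: rows outer
    for (cc in grid_origins(w, small_size)) {
      out[[length(out) + 1L]] <- structure(
        list(pixels = px[(r + 1):(r + small_size), (cc + 1):(cc + small_size), , drop = FALSE],
             origin = c(offset[1] + r, offset[2] + cc), domain = domain),
        class = "small_patch")
    }
  }
  out
}

#' Stitch small patches back into an image by origin
#'
#' Inverse of [tile_small_patches()]: places each patch at its origin in a
#' canvas of the given size. Uncovered pixels (dropped border remainders) are
#' filled with `fill`.
#'
#' @param patches list of `small_patch` objects (or lists with `pixels` and
#'   `origin`).
#' @param height,width canvas size in pixels.
#' @param fill RGB triplet for uncovered pixels.
#' @return (H, W, 3) array.
#' @export
stitch_patches <- function(patches, height, width,
                           fill = stain_palette()$background) {
  canvas <- array(rep(fill, each = height * width), c(height, width, 3))
  for (p in patches) {
    d <- dim(p$pixels)
    rows <- (p$origin[1] + 1):(p$origin[1] + d[1])
    cols <- (p$origin[2] + 1):(p$origin[2] + d[2])
    canvas[rows, cols, ] <- p$pixels
  }
  canvas
}

#' Build weakly labelled bags from a slide
#'
#' One bag per retained large patch; the bag's weak label is TUMOR if the
#' large patch contains at least one tumor-cell centre (from the ground-truth
#' sidecar) and NORMAL if it contains only normal cells; the bag's instances
#' are the complete non-overlapping grid of small patches.
#'
#' @param image `slide_image` or array.
#' @param ground_truth a `ground_truth` sidecar, or a named character vector
#'   of labels (`"TUMOR"`/`"NORMAL"`) keyed by bag id `"r<row>_c<col>"`.
#' @param large_size,small_size tile sides in pixels (defaults 2240 / 224;
#'   desk-scale tests use 320 / 32, preserving the 10 x 10 instance grid).
#' @param min_fg_fraction retention threshold for large patches.
#' @return list of `bag` objects: `list(bag_id, weak_label, large_patch_origin,
#'   instances)`.
#' @export
build_bags <- function(image, ground_truth, large_size = 2240L,
                       small_size = 224L, min_fg_fraction = 0.05) {
  px <- as_pixels(image)
  domain <- if (inherits(image, "slide_image")) image$domain else "HE"
  fg <- otsu_foreground(px)
  larges <- extract_large_patches(px, fg, large_size, min_fg_fraction)
  bags <- vector("list", length(larges))
  for (i in seq_along(larges)) {
    lp <- larges[[i]]
    bag_id <- sprintf("r%d_c%d", lp$origin[1], lp$origin[2])
    if (inherits(ground_truth, "ground_truth")) {
      cc <- ground_truth$cell_centers
      lab <- ground_truth$cell_labels
      inside <- cc[, "y"] >= lp$origin[1] & cc[, "y"] < lp$origin[1] + large_size &
        cc[, "x"] >= lp$origin[2] & cc[, "x"] < lp$origin[2] + large_size
      weak <- if (any(lab[inside] == "TUMOR")) "TUMOR" else "NORMAL"
    } else {
      if (is.null(ground_truth[bag_id]) || is.na(ground_truth[bag_id]))
        stop("build_bags: missing label for patch ", bag_id)
      weak <- unname(ground_truth[bag_id])
    }
    bags[[i]] <- structure(
      list(bag_id = bag_id, weak_label = weak, large_patch_origin = lp$origin,
           instances = tile_small_patches(lp$pixels, small_size, domain,
                                          offset = lp$origin)),
      class = "bag")
  }
  bags
}

# Stack a list of small patches into an (H, W, 3, N) batch array.
patches_to_batch <- function(patches) {
  stopifnot(length(patches) > 0)
  d <- dim(patches[[1]]$pixels)
  out <- array(0, c(d[1], d[2], 3L, length(patches)))
  for (i in seq_along(patches)) out[, , , i] <- patches[[i]]$pixels
  out
}
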