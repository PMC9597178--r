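# Masked-image container and the colour-map construction: load a PNG whose
# background is masked by transparency, equalize sampling frequency across a
# cohort by downsampling to a common pixel width, bin pixels into a coarse
# sRGB histogram, then agglomeratively merge similar bins in CIE Lab space.

#' Construct a masked image
#'
#' @param rgb Integer array `h x w x 3` of 8-bit sRGB values in `[0, 255]`.
#' @param mask Logical matrix `h x w`; `TRUE` marks plumage (valid) pixels.
#' @return An object of class `masked_image`.
#' @export
masked_image <- function(rgb, mask) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("rgb must be an h x w x 3 array")
  if (!is.matrix(mask) || !identical(dim(mask), dim(rgb)[1:2]))
    stop("mask must be a logical matrix matching the image dimensions")
  if (any(rgb < 0) || any(rgb > 255)) stop("rgb channels must lie in [0, 255]")
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("image has no valid (unmasked) pixels")
  structure(list(rgb = rgb, mask = mask), class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<masked_image> %d x %d px, %d valid (%.1f%%)\n",
              d[2], d[1], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Image dimensions helpers
#' @param img A `masked_image`.
#' @return Width or height in pixels.
#' @export
image_width <- function(img) dim(img$rgb)[2]

#' @rdname image_width
#' @export
image_height <- function(img) dim(img$rgb)[1]

#' Load a masked plumage image from a PNG file
#'
#' The PNG is expected to carry an alpha channel: pixels with 8-bit alpha
#' >= 128 are treated as plumage, the rest as masked background. Images
#' without an alpha channel are refused unless `allow_no_alpha = TRUE`, in
#' which case every pixel is valid.
#'
#' @param path Path to an RGBA (or, with `allow_no_alpha`, RGB/grey) PNG.
#' @param allow_no_alpha Accept PNGs without transparency (mask all-`TRUE`).
#' @return A [masked_image()].
#' @export
load_masked_image <- function(path, allow_no_alpha = FALSE) {
  if (!file.exists(path)) stop("cannot read PNG: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  nc <- dim(arr)[3]
  if (nc >= 4) {
    alpha <- round(arr[, , 4] * 255)
    mask <- alpha >= 128
  } else if (allow_no_alpha) {
    mask <- matrix(TRUE, dim(arr)[1], dim(arr)[2])
  } else {
    stop("PNG has no alpha channel; pass allow_no_alpha = TRUE to treat all ",
         "pixels as valid")
  }
  rgb <- round(arr[, , 1:3, drop = FALSE] * 255)
  storage.mode(rgb) <- "integer"
  masked_image(rgb, mask)
}

#' Write a masked image to an RGBA PNG
#'
#' Masked pixels receive alpha 0; valid pixels alpha 1.
#'
#' @param img A [masked_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masked_image <- function(img, path) {
  d <- dim(img$rgb)
  out <- array(0, c(d[1], d[2], 4))
  out[, , 1:3] <- img$rgb / 255
  out[, , 4] <- ifelse(img$mask, 1, 0)
  png::writePNG(out, path)
  invisible(path)
}

#' Downsample an image to a common pixel width
#'
#' Equalizes the sampling frequency across a cohort: every image is sampled
#' on a grid of `target_width` columns (height scaled to preserve the aspect
#' ratio) by nearest-neighbour lookup, so no new colours are invented and the
#' mask is sampled identically. Upsampling is never performed: a
#' `target_width` above the source width returns the image unchanged with a
#' warning.
#'
#' @param img A [masked_image()].
#' @param target_width Target width in pixels (>= 2).
#' @return A [masked_image()] of width `target_width`.
#' @export
resample_to_common_width <- function(img, target_width) {
  w <- image_width(img); h <- image_height(img)
  if (target_width < 2) stop("target_width must be >= 2")
  if (target_width > w) {
    warning("target_width ", target_width, " exceeds source width ", w,
            "; image returned unchanged (no upsampling)")
    return(img)
  }
  if (target_width == w) return(img)
  w2 <- as.integer(target_width)
  h2 <- max(1L, as.integer(round(h * w2 / w)))
  ci <- pmin(w, pmax(1, ceiling((seq_len(w2) - 0.5) * w / w2)))
  ri <- pmin(h, pmax(1, ceiling((seq_len(h2) - 0.5) * h / h2)))
  masked_image(img$rgb[ri, ci, , drop = FALSE], img$mask[ri, ci, drop = FALSE])
}

#' Coarse sRGB histogram binning
#'
#' Assigns every valid pixel to the bin of its channel-wise triple
#' `floor(bins * value / 256)` (default 3 bins per channel, 27 bins total)
#' and summarises each non-empty bin by the mean sRGB of its member pixels,
#' converted to CIE Lab.
#'
#' @param img A [masked_image()].
#' @param bins_per_channel Number of histogram bins per sRGB channel.
#' @return Data frame with one row per non-empty bin: `bin` (1-based index
#'   into the full bin grid), `count`, mean sRGB (`r`, `g`, `b`) and the Lab
#'   centroid (`L`, `a`, `b_lab`).
#' @export
bin_colors <- function(img, bins_per_channel = 3) {
  k <- as.integer(bins_per_channel)
  if (k < 1) stop("bins_per_channel must be >= 1")
  px <- .valid_pixels(img)
  idx <- floor(k * px[, 1] / 256) * k * k +
    floor(k * px[, 2] / 256) * k +
    floor(k * px[, 3] / 256) + 1
  counts <- tabulate(idx, nbins = k^3)
  keep <- which(counts > 0)
  sums <- rowsum(px + 0, idx)          # rows ordered by sorted unique idx
  stopifnot(identical(as.integer(rownames(sums)), keep))
  mean_rgb <- sums / counts[keep]
  lab <- srgb_to_lab(mean_rgb)
  out <- data.frame(
    bin = keep, count = counts[keep],
    r = mean_rgb[, 1], g = mean_rgb[, 2], b = mean_rgb[, 3],
    L = lab[, 1], a = lab[, 2], b_lab = lab[, 3]
  )
  rownames(out) <- NULL
  out
}

#' Agglomerative merging of colour clusters in CIE Lab space
#'
#' Repeatedly merges the closest pair of clusters whose CIE76 distance falls
#' below `cutoff`, replacing the pair by its pixel-count-weighted Lab
#' centroid, until every remaining pair is at least `cutoff` apart. Ties are
#' broken deterministically in favour of the lowest pair of cluster indices.
#'
#' @param bins Data frame with columns `L`, `a`, `b_lab` and `count`, as
#'   returned by [bin_colors()].
#' @param cutoff CIE Lab (ΔE) merge cutoff; clusters closer than this are
#'   combined. The workflow default is 45.
#' @return Data frame of merged clusters (`L`, `a`, `b_lab`, `count`).
#' @export
recluster <- function(bins, cutoff = 45) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nrow(bins) == 0) stop("at least one colour bin is required")
  lab <- cbind(bins$L, bins$a, bins$b_lab)
  count <- as.numeric(bins$count)
  repeat {
    n <- nrow(lab)
    if (n == 1) break
    d <- delta_e_matrix(lab)
    d[lower.tri(d, diag = TRUE)] <- Inf
    m <- min(d)
    if (m >= cutoff) break
    # lowest (i, j) pair among ties, column-major scan of the upper triangle
    hit <- which(d == m, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    wtot <- count[i] + count[j]
    lab[i, ] <- (count[i] * lab[i, ] + count[j] * lab[j, ]) / wtot
    count[i] <- wtot
    lab <- lab[-j, , drop = FALSE]
    count <- count[-j]
  }
  data.frame(L = lab[, 1], a = lab[, 2], b_lab = lab[, 3], count = count)
}

#' Build a discrete colour map of a masked image
#'
#' The composite segmentation: [bin_colors()] into `bins_per_channel^3` sRGB
#' histogram bins, [recluster()] the bin centroids with the ΔE `cutoff`, then
#' relabel every valid pixel to the nearest merged centroid by CIE76
#' distance.
#'
#' @param img A [masked_image()].
#' @param cutoff ΔE merge cutoff (default 45; 55 reproduces the looser
#'   published-figure setting).
#' @param bins_per_channel Histogram bins per sRGB channel (default 3).
#' @return An object of class `color_map`: `labels` (integer matrix, `NA`
#'   outside the mask), `palette` (Lab matrix, one row per colour class),
#'   `proportions` (fraction of valid pixels per class), and `palette_dist`
#'   (pairwise ΔE matrix of the final palette).
#' @export
make_color_map <- function(img, cutoff = 45, bins_per_channel = 3) {
  bins <- bin_colors(img, bins_per_channel)
  merged <- recluster(bins, cutoff)
  palette <- cbind(L = merged$L, a = merged$a, b = merged$b_lab)
  px <- .valid_pixels(img)
  lab_px <- srgb_to_lab(px)
  lab <- .nearest_palette_label(lab_px, palette)
  labels <- matrix(NA_integer_, image_height(img), image_width(img))
  labels[img$mask] <- lab
  # drop palette entries that attracted no pixels (possible when a merged
  # centroid is dominated by its neighbours)
  used <- sort(unique(lab))
  if (length(used) < nrow(palette)) {
    relab <- match(lab, used)
    labels[img$mask] <- relab
    palette <- palette[used, , drop = FALSE]
    lab <- relab
  }
  prop <- tabulate(lab, nbins = nrow(palette)) / length(lab)
  structure(list(
    labels = labels,
    palette = palette,
    proportions = prop,
    palette_dist = delta_e_matrix(palette),
    cutoff = cutoff
  ), class = "color_map")
}

#' Construct a colour map directly from components
#'
#' Used by generators and tests to build ground-truth maps without going
#' through image segmentation.
#'
#' @param labels Integer matrix of colour-class labels (`NA` = background).
#' @param palette Lab matrix, one row per class.
#' @return A `color_map`.
#' @export
color_map <- function(labels, palette) {
  palette <- .as_lab_matrix(palette)
  lab <- labels[!is.na(labels)]
  if (length(lab) == 0) stop("color map has no valid pixels")
  if (any(lab < 1 | lab > nrow(palette)))
    stop("labels must index palette rows")
  prop <- tabulate(lab, nbins = nrow(palette)) / length(lab)
  structure(list(
    labels = labels, palette = palette, proportions = prop,
    palette_dist = delta_e_matrix(palette), cutoff = NA_real_
  ), class = "color_map")
}

#' @export
print.color_map <- function(x, ...) {
  cat(sprintf("<color_map> %d colour classes over %d valid pixels\n",
              nrow(x$palette), sum(!is.na(x$labels))))
  info <- data.frame(round(x$palette, 2), proportion = round(x$proportions, 4))
  print(info)
  invisible(x)
}

.valid_pixels <- function(img) {
  cbind(
    r = img$rgb[, , 1][img$mask],
    g = img$rgb[, , 2][img$mask],
    b = img$rgb[, , 3][img$mask]
  )
}

# nearest palette row (CIE76) for each Lab pixel; vectorized over pixels
.nearest_palette_label <- function(lab_px, palette) {
  k <- nrow(palette)
  if (k == 1) return(rep(1L, nrow(lab_px)))
  d2 <- outer(rowSums(lab_px^2), rep(1, k)) -
    2 * lab_px %*% t(palette) +
    outer(rep(1, nrow(lab_px)), rowSums(palette^2))
  max.col(-d2, ties.method = "first")
}
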