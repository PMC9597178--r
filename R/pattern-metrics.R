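# Colour-pattern geometry statistics computed from a color_map, plus the
# pairwise image colour distance and the neighbour-joining colour tree.

#' Adjacency transition counts of a colour map
#'
#' Counts every unordered horizontal and vertical neighbour pair of valid
#' pixels by colour-class pair (4-neighbour adjacency, no diagonals). Pairs
#' touching the background are excluded.
#'
#' @param cm A `color_map`.
#' @return Symmetric `k x k` matrix; entry `(i, j)` (and `(j, i)`) is the
#'   number of unordered adjacent pairs with classes `i` and `j`. Each
#'   unordered pair is counted once (read off the upper triangle and
#'   diagonal when summing).
#' @export
transition_counts <- function(cm) {
  lab <- cm$labels
  k <- nrow(cm$palette)
  h <- cbind(as.vector(lab[, -ncol(lab), drop = FALSE]),
             as.vector(lab[, -1, drop = FALSE]))
  v <- cbind(as.vector(lab[-nrow(lab), , drop = FALSE]),
             as.vector(lab[-1, , drop = FALSE]))
  pr <- rbind(h, v)
  pr <- pr[!is.na(pr[, 1]) & !is.na(pr[, 2]), , drop = FALSE]
  lo <- pmin(pr[, 1], pr[, 2])
  hi <- pmax(pr[, 1], pr[, 2])
  counts <- tabulate((lo - 1) * k + hi, nbins = k * k)
  m <- matrix(counts, k, k, byrow = TRUE)  # m[lo, hi] = count of (lo, hi)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Chromatic and achromatic boundary strength
#'
#' Mean colour distance between adjacent colour patches, weighted by how
#' often each class pair meets along patch boundaries: with `t_ij` the
#' off-diagonal transition counts and `w_ij = t_ij / sum t_ij`, the
#' chromatic contrast is `sum w_ij * chromatic_distance(palette_i,
#' palette_j)` and the achromatic contrast is the analogue with `|delta L|`.
#' Maps with a single class (no colour boundaries) score 0 on both.
#'
#' @param cm A `color_map`.
#' @return Named numeric vector `c(chromatic, achromatic)`.
#' @export
boundary_strength <- function(cm) {
  k <- nrow(cm$palette)
  if (k == 1)
    return(c(chromatic = 0, achromatic = 0))
  tc <- transition_counts(cm)
  off <- upper.tri(tc)
  tot <- sum(tc[off])
  if (tot == 0)
    return(c(chromatic = 0, achromatic = 0))
  w <- tc[off] / tot
  dc <- delta_e_matrix(cm$palette, "chromatic")[off]
  da <- delta_e_matrix(cm$palette, "achromatic")[off]
  c(chromatic = sum(w * dc), achromatic = sum(w * da))
}

#' Scaled Simpson colour diversity
#'
#' Inverse Simpson index `D = 1 / sum(p_i^2)` of the colour-class
#' proportions, rescaled to `[0, 1]` as `(D - 1) / (k - 1)`: 1 when every
#' colour patch occupies an equal share, approaching 0 when a single patch
#' dominates. A single-class map scores 0 (maximal dominance). The
#' unscaled alternative `D / k` is available via `scale = "D_over_k"`.
#'
#' @param proportions Non-negative class proportions summing to 1.
#' @param scale Rescaling convention, `"D_minus_1"` (default) or
#'   `"D_over_k"`.
#' @return Diversity in `[0, 1]`.
#' @export
simpson_scaled <- function(proportions, scale = c("D_minus_1", "D_over_k")) {
  scale <- match.arg(scale)
  p <- proportions
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  k <- length(p)
  D <- 1 / sum(p^2)
  if (scale == "D_over_k") return(D / k)
  if (k == 1) 0 else (D - 1) / (k - 1)
}

#' Red patch proportion of a masked image
#'
#' Fraction of valid pixels whose CIE Lab coordinates exceed the
#' carotenoid-red thresholds (all strict inequalities): `L > 55`, `a > 30`,
#' `b > 5` by default. Computed on the raw pixels, not the segmented map.
#'
#' @param img A [masked_image()].
#' @param thresholds Named numeric vector `c(L = 55, a = 30, b = 5)`.
#' @return Fraction in `[0, 1]`.
#' @export
red_proportion <- function(img, thresholds = c(L = 55, a = 30, b = 5)) {
  lab <- srgb_to_lab(.valid_pixels(img))
  mean(lab[, 1] > thresholds[["L"]] &
         lab[, 2] > thresholds[["a"]] &
         lab[, 3] > thresholds[["b"]])
}

#' All four colour-pattern metrics of an image
#'
#' Convenience wrapper: segments the image (unless a pre-built map is
#' supplied) and returns chromatic contrast, achromatic contrast, scaled
#' Simpson colour diversity and red patch proportion.
#'
#' @param img A [masked_image()].
#' @param cutoff,bins_per_channel Passed to [make_color_map()].
#' @param cm Optional pre-computed `color_map` for `img`.
#' @param red_thresholds Passed to [red_proportion()].
#' @return Named numeric vector with elements `chromatic_contrast`,
#'   `achromatic_contrast`, `simpson_scaled`, `red_proportion`.
#' @export
pattern_metrics <- function(img, cutoff = 45, bins_per_channel = 3,
                            cm = NULL,
                            red_thresholds = c(L = 55, a = 30, b = 5)) {
  if (is.null(cm)) cm <- make_color_map(img, cutoff, bins_per_channel)
  bs <- boundary_strength(cm)
  c(chromatic_contrast = unname(bs["chromatic"]),
    achromatic_contrast = unname(bs["achromatic"]),
    simpson_scaled = simpson_scaled(cm$proportions),
    red_proportion = red_proportion(img, red_thresholds))
}

#' Colour distance between two segmented images
#'
#' Minimum-cost transport distance between the two (palette, proportions)
#' signatures with CIE76 ΔE as the ground cost: the cheapest way to move
#' one image's colour mass onto the other's. Zero iff the signatures match;
#' for two single-colour maps it equals the ΔE between the colours.
#'
#' @param a,b `color_map` objects.
#' @return Distance in ΔE units.
#' @export
image_color_distance <- function(a, b) {
  cost <- outer(seq_len(nrow(a$palette)), seq_len(nrow(b$palette)),
                function(i, j) delta_e(a$palette[i, , drop = FALSE],
                                       b$palette[j, , drop = FALSE]))
  emd(a$proportions, b$proportions, cost)
}

#' Pairwise colour distance matrix for a set of colour maps
#'
#' @param maps Named list of `color_map` objects.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
color_distance_matrix <- function(maps) {
  n <- length(maps)
  d <- matrix(0, n, n, dimnames = list(names(maps), names(maps)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- image_color_distance(maps[[i]], maps[[j]])
    }
  }
  d
}

#' Neighbour-joining tree from a colour distance matrix
#'
#' Standard Saitou–Nei neighbour joining on a symmetric, zero-diagonal
#' distance matrix. Negative branch lengths (a known artefact of NJ on
#' non-additive matrices) are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal and non-negative
#'   entries; at least 3 taxa.
#' @param names Optional taxon names (defaults to `rownames(d)`).
#' @return An unrooted `phylo` tree (see \pkg{ape}).
#' @export
neighbour_joining <- function(d, names = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || nrow(d) < 3)
    stop("d must be a square matrix with at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (!is.null(names)) dimnames(d) <- list(names, names)
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
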