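# Generators for synthetic inputs with known ground truth: plumage-like
# masked images built from a few discrete colour patches, pure-birth trees,
# and trait tables evolved on those trees under lambda-scaled Brownian
# covariance with known regression coefficients.

# Discrete patch colours (CIE Lab) used by the cohort generator. All are
# inside the sRGB gamut after quantization and pairwise >= 63 Delta E apart,
# so patch recovery is unambiguous at either merge cutoff (45 or 55).
.plumage_lab_palette <- rbind(
  black  = c(15, 0, 0),
  white  = c(92, 0, 3),
  red    = c(60, 65, 55),   # carotenoid red; passes L>55, a>30, b>5
  yellow = c(85, 5, 80),
  olive  = c(50, -35, 40)
)

#' Specify a synthetic plumage image
#'
#' Describes a head-like masked canvas partitioned into a few discrete
#' colour patches, plus per-pixel Gaussian sRGB noise. The first patch is
#' the base plumage colour filling the mask; later patches are painted over
#' it in order (later wins). `shape = "band"` patches are horizontal bands
#' sized to an exact pixel-area fraction of the mask; `"rect"` and
#' `"ellipse"` patches are centred shapes sized to approximate their
#' fraction.
#'
#' @param width,height Canvas size in pixels.
#' @param patches List of patches, each `list(frac =, lab =, shape =,
#'   center =)`; `lab` is a length-3 CIE Lab colour, `frac` the target area
#'   fraction of the mask, `center` (relative x, y in `[0, 1]`) only used
#'   for `"rect"`/`"ellipse"` shapes.
#' @param noise_sd Gaussian sRGB noise standard deviation (8-bit units).
#' @param mask_shape `"ellipse"` (head outline inscribed in the canvas) or
#'   `"full"`.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `plumage_spec`.
#' @export
plumage_spec <- function(width = 200, height = 240,
                         patches = list(
                           list(frac = 1, lab = c(15, 0, 0), shape = "band"),
                           list(frac = 0.3, lab = c(60, 65, 55), shape = "band")
                         ),
                         noise_sd = 0, mask_shape = c("ellipse", "full"),
                         seed = 1L) {
  mask_shape <- match.arg(mask_shape)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fr <- vapply(patches[-1], function(p) p$frac, numeric(1))
  if (length(fr) && sum(fr) > 1) stop("patch area fractions exceed 1")
  structure(list(width = width, height = height, patches = patches,
                 noise_sd = noise_sd, mask_shape = mask_shape,
                 seed = as.integer(seed)),
            class = "plumage_spec")
}

#' Render a synthetic plumage image with analytic ground truth
#'
#' Paints the patches of a [plumage_spec()] into the head mask, adds
#' clipped Gaussian sRGB noise, and returns both the image and the ground
#' truth computed from the noiseless layout: the true colour map (labels
#' and palette), class proportions, and the four pattern metrics evaluated
#' analytically on that layout. Patch Lab colours are first quantized
#' through 8-bit sRGB so that the recorded truth matches what the image can
#' actually encode.
#'
#' @param spec A [plumage_spec()].
#' @return List with elements `image` (a [masked_image()]), `truth` (a
#'   `color_map` of the noiseless layout) and `metrics` (named vector:
#'   chromatic_contrast, achromatic_contrast, simpson_scaled,
#'   red_proportion).
#' @export
make_plumage_image <- function(spec) {
  stopifnot(inherits(spec, "plumage_spec"))
  w <- spec$width; h <- spec$height
  mask <- if (spec$mask_shape == "ellipse") {
    cx <- (w + 1) / 2; cy <- (h + 1) / 2
    outer(seq_len(h), seq_len(w), function(r, c)
      ((c - cx) / (w / 2))^2 + ((r - cy) / (h / 2))^2 <= 1)
  } else {
    matrix(TRUE, h, w)
  }
  n_valid <- sum(mask)
  labels <- matrix(NA_integer_, h, w)
  labels[mask] <- 1L

  # valid pixels in reading order (row-major) for exact band fractions
  valid_idx <- which(t(mask))                     # position in transposed grid
  rc <- cbind(row = (valid_idx - 1) %/% w + 1, col = (valid_idx - 1) %% w + 1)
  cursor <- 0
  for (i in seq_along(spec$patches)[-1]) {
    p <- spec$patches[[i]]
    shape <- if (is.null(p$shape)) "band" else p$shape
    npix <- round(p$frac * n_valid)
    if (shape == "band") {
      take <- seq_len(npix) + cursor
      take <- take[take <= n_valid]
      labels[rc[take, , drop = FALSE]] <- i
      cursor <- cursor + npix
    } else {
      ctr <- if (is.null(p$center)) c(0.5, 0.5) else p$center
      cx <- ctr[1] * w; cy <- ctr[2] * h
      if (shape == "rect") {
        side <- sqrt(p$frac * n_valid)
        sel <- outer(seq_len(h), seq_len(w), function(r, c)
          abs(c - cx) <= side / 2 & abs(r - cy) <= side / 2)
      } else if (shape == "ellipse") {
        rad <- sqrt(p$frac * n_valid / pi)
        sel <- outer(seq_len(h), seq_len(w), function(r, c)
          (c - cx)^2 + (r - cy)^2 <= rad^2)
      } else stop("unknown patch shape: ", shape)
      labels[sel & mask] <- i
    }
  }

  lab_in <- do.call(rbind, lapply(spec$patches, function(p) p$lab))
  srgb <- lab_to_srgb(lab_in)                 # quantized patch colours
  palette_true <- srgb_to_lab(srgb)

  # keep only classes that actually occupy pixels
  used <- sort(unique(labels[mask]))
  relab <- matrix(NA_integer_, h, w)
  relab[mask] <- match(labels[mask], used)
  truth <- color_map(relab, palette_true[used, , drop = FALSE])
  srgb_used <- srgb[used, , drop = FALSE]

  set.seed(spec$seed)
  rgb <- array(0L, c(h, w, 3))
  lab_vec <- relab[mask]
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    vals <- srgb_used[lab_vec, ch]
    if (spec$noise_sd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
    plane[mask] <- pmin(255, pmax(0, round(vals)))
    rgb[, , ch] <- plane
  }
  storage.mode(rgb) <- "integer"
  img <- masked_image(rgb, mask)

  bs <- boundary_strength(truth)
  passes_red <- truth$palette[, 1] > 55 & truth$palette[, 2] > 30 &
    truth$palette[, 3] > 5
  metrics <- c(
    chromatic_contrast = unname(bs["chromatic"]),
    achromatic_contrast = unname(bs["achromatic"]),
    simpson_scaled = simpson_scaled(truth$proportions),
    red_proportion = sum(truth$proportions[passes_red])
  )
  list(image = img, truth = truth, metrics = metrics)
}

#' Generate a cohort of varied plumage image specs
#'
#' Draws `n` specs with 2–5 patches, colours sampled without replacement
#' from a fixed well-separated Lab palette (black, white, carotenoid red,
#' yellow, olive), patch fractions from a broken-stick draw (each >= 0.08),
#' varying canvas widths and mild pixel noise — the variation a comparative
#' colour study sees across species plates. The default width range
#' (280-360 px) corresponds to head crops from plates scanned at 300 dpi
#' (a head of roughly 2.5-3 cm on the plate).
#'
#' @param n Number of images.
#' @param seed Integer seed.
#' @param noise_sd Pixel noise sd (8-bit sRGB units; default 4).
#' @param width_range Canvas width range in pixels.
#' @return List of [plumage_spec()] objects.
#' @export
plumage_cohort_specs <- function(n, seed = 1L, noise_sd = 4,
                                 width_range = c(280, 360)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(2:5, 1)
    cols <- .plumage_lab_palette[sample(nrow(.plumage_lab_palette), k), ,
                                 drop = FALSE]
    fr <- stats::runif(k, 0.08, 1)
    fr <- fr / sum(fr)
    w <- sample(seq(width_range[1], width_range[2]), 1)
    patches <- c(
      list(list(frac = 1, lab = cols[1, ], shape = "band")),
      lapply(seq_len(k - 1), function(j)
        list(frac = fr[j + 1], lab = cols[j + 1, ], shape = "band"))
    )
    plumage_spec(width = w, height = round(1.2 * w), patches = patches,
                 noise_sd = noise_sd, seed = seed * 10000L + i)
  })
}

#' Simulate a pure-birth phylogeny scaled to unit depth
#'
#' @param n Number of tips (>= 3).
#' @param rate Speciation rate of the pure-birth process.
#' @param seed Integer seed (optional).
#' @return An ultrametric `phylo` tree with unit root-to-tip depth and tip
#'   labels `sp_001`, `sp_002`, ...
#' @export
simulate_tree <- function(n, rate = 1, seed = NULL) {
  if (n < 3) stop("n must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp_%03d", seq_len(n))
  tr
}

#' Specify a trait-evolution simulation
#'
#' Fixes the generative model for a synthetic species table: colour
#' predictors evolve by Brownian motion (on the log10 scale) on the tree,
#' habitat is a thresholded Brownian liability (so it carries phylogenetic
#' signal), and each response is a linear combination of the transformed
#' predictors plus multivariate-normal residuals with covariance
#' `sigma2 * C(lambda)`. Default coefficients and lambda echo the scale of
#' a 132-species comparative analysis of drum displays: a true chromatic
#' effect of 0.1535 on mass-corrected log drum speed at lambda 0.877, and a
#' null-ish model for drum length at lambda 0.715.
#'
#' @param beta_speed Named coefficients (intercept, simpson, chromatic,
#'   achromatic, red, habitat) for log10 mass-corrected drum speed.
#' @param beta_length Same layout for log10 drum length.
#' @param lambda_speed,lambda_length Residual phylogenetic signal in
#'   `[0, 1]` for each response.
#' @param sigma2_speed,sigma2_length Residual variance at unit tree depth
#'   (log10 scale).
#' @param bm_sigma2 Brownian rate of each predictor on the log10 scale.
#' @param predictor_means Named means (root states) of the log10 colour
#'   predictors and log10 body mass.
#' @param habitat_open_frac Expected fraction of species in open habitat
#'   (sets the liability threshold).
#' @param mass_intercept,mass_slope Allometry of log10 drum speed on log10
#'   body mass (negative slope: heavier species drum slower).
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(
    beta_speed = c(intercept = -0.597, simpson = 0.0398, chromatic = 0.1535,
                   achromatic = 0.0051, red = -0.0405, habitat = 0.0021),
    beta_length = c(intercept = 2.7748, simpson = 0.1495, chromatic = 0.0567,
                    achromatic = 0.0150, red = -0.0465, habitat = 0.0102),
    lambda_speed = 0.877, lambda_length = 0.715,
    sigma2_speed = 0.01, sigma2_length = 0.03,
    bm_sigma2 = 0.09,
    predictor_means = c(simpson = -0.3, chromatic = 1.3, achromatic = 1.18,
                        red = -1, mass = 2),
    habitat_open_frac = 0.3,
    mass_intercept = 1.8, mass_slope = -0.3,
    seed = 1L) {
  stopifnot(lambda_speed >= 0, lambda_speed <= 1,
            lambda_length >= 0, lambda_length <= 1,
            sigma2_speed > 0, sigma2_length > 0, bm_sigma2 > 0,
            habitat_open_frac > 0, habitat_open_frac < 1)
  structure(as.list(environment()), class = "simulation_spec")
}

# one multivariate-normal draw with covariance S (upper-Cholesky sampler)
.mvn_draw <- function(S) {
  as.numeric(t(chol(S)) %*% stats::rnorm(nrow(S)))
}

#' Simulate a species trait table on a phylogeny
#'
#' See [simulation_spec()] for the generative model. The returned table is
#' on the natural scale (beats per second, beats, grams, metric units);
#' feeding it through [transform_variables()] recovers the log10 quantities
#' the model was simulated on. The attribute `latent` stores the true
#' log-scale components (including the true mass-corrected speed residual).
#'
#' @param tree An ultrametric `phylo` tree (unit depth recommended).
#' @param spec A [simulation_spec()].
#' @return Data frame with columns `species`, `drum_speed`, `drum_length`,
#'   `body_mass`, `habitat`, `chromatic_contrast`, `achromatic_contrast`,
#'   `simpson_scaled`, `red_proportion`.
#' @export
simulate_traits <- function(tree, spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  C <- ape::vcv.phylo(tree)
  n <- nrow(C)
  pm <- spec$predictor_means
  bm <- function(mean) mean + .mvn_draw(spec$bm_sigma2 * C)
  log_simpson <- bm(pm[["simpson"]])
  log_chrom <- bm(pm[["chromatic"]])
  log_achrom <- bm(pm[["achromatic"]])
  log_red <- bm(pm[["red"]])
  log_mass <- bm(pm[["mass"]])
  liability <- .mvn_draw(spec$bm_sigma2 * C)
  thr <- stats::qnorm(1 - spec$habitat_open_frac, sd = sqrt(spec$bm_sigma2))
  habitat <- ifelse(liability > thr, "open", "closed")
  X <- cbind(intercept = 1, simpson = log_simpson, chromatic = log_chrom,
             achromatic = log_achrom, red = log_red,
             habitat = as.numeric(habitat == "open"))
  y_speed <- as.numeric(X %*% spec$beta_speed) +
    .mvn_draw(spec$sigma2_speed * lambda_transform(C, spec$lambda_speed))
  y_length <- as.numeric(X %*% spec$beta_length) +
    .mvn_draw(spec$sigma2_length * lambda_transform(C, spec$lambda_length))
  log_speed <- spec$mass_intercept + spec$mass_slope * log_mass + y_speed
  out <- data.frame(
    species = rownames(C),
    drum_speed = 10^log_speed,
    drum_length = 10^y_length,
    body_mass = 10^log_mass,
    habitat = habitat,
    chromatic_contrast = 10^log_chrom,
    achromatic_contrast = 10^log_achrom,
    simpson_scaled = 10^log_simpson,
    red_proportion = 10^log_red,
    row.names = NULL
  )
  attr(out, "latent") <- data.frame(
    species = rownames(C), speed_resid_true = y_speed,
    log_length = y_length, log_mass = log_mass
  )
  out
}
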