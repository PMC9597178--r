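test_that("transition_counts matches hand enumeration and symmetry", {
  cm <- map_2x2_AB()
  tc <- transition_counts(cm)
  expect_equal(tc[1, 1], 1)  # A-A
  expect_equal(tc[2, 2], 1)  # B-B
  expect_equal(tc[1, 2], 2)  # A-B (two vertical pairs)
  expect_equal(tc[2, 1], 2)
  # uniform map: only diagonal transitions
  uni <- tiny_map(matrix(1L, 3, 4), rbind(c(50, 0, 0)))
  tcu <- transition_counts(uni)
  expect_equal(dim(tcu), c(1, 1))
  expect_equal(tcu[1, 1], 3 * 3 + 2 * 4)  # horizontal + vertical pairs
  # rotation invariance of the transition multiset
  set.seed(31)
  lab <- matrix(sample(1:3, 30, replace = TRUE), 5, 6)
  pal <- rbind(c(20, 0, 0), c(50, 30, 0), c(80, 0, 30))
  m1 <- transition_counts(tiny_map(lab, pal))
  rot <- t(lab)[, nrow(lab):1]  # 90 degree rotation
  m2 <- transition_counts(tiny_map(rot, pal))
  expect_equal(m1, m2)
  # background-touching pairs excluded
  lab_na <- lab; lab_na[1, ] <- NA
  tc_na <- transition_counts(tiny_map(lab_na, pal))
  expect_equal(sum(tc_na[upper.tri(tc_na, diag = TRUE)]),
               4 * 5 + 3 * 6)  # horizontal pairs in rows 2-5 + vertical pairs
})

test_that("boundary_strength is the transition-weighted mean pair distance", {
  bs <- boundary_strength(map_2x2_AB(A = c(50, 10, 0), B = c(50, 0, 10)))
  expect_equal(unname(bs["chromatic"]), sqrt(200))
  expect_equal(unname(bs["achromatic"]), 0)
  # single-class map scores zero on both
  uni <- tiny_map(matrix(1L, 4, 4), rbind(c(50, 0, 0)))
  expect_equal(unname(boundary_strength(uni)), c(0, 0))
  # three-class hand oracle: weighted mean over off-diagonal transitions
  lab <- matrix(c(1L, 1L, 2L, 3L), 2, 2)  # pairs: (1,2),(1,3),(1,1),(2,3)
  pal <- rbind(c(10, 0, 0), c(50, 40, 0), c(90, 0, 40))
  bs3 <- boundary_strength(tiny_map(lab, pal))
  dc <- function(i, j) sqrt(sum((pal[i, 2:3] - pal[j, 2:3])^2))
  da <- function(i, j) abs(pal[i, 1] - pal[j, 1])
  expect_equal(unname(bs3["chromatic"]),
               (dc(1, 2) + dc(1, 3) + dc(2, 3)) / 3)
  expect_equal(unname(bs3["achromatic"]),
               (da(1, 2) + da(1, 3) + da(2, 3)) / 3)
  # chromatic contrast is 0 iff the palette has one class (two grey classes
  # still give 0 chromatic but nonzero achromatic)
  grey <- tiny_map(matrix(c(1L, 1L, 2L, 2L), 2, 2),
                   rbind(c(20, 0, 0), c(80, 0, 0)))
  bsg <- boundary_strength(grey)
  expect_equal(unname(bsg["chromatic"]), 0)
  expect_equal(unname(bsg["achromatic"]), 60)
})

test_that("boundary strengths are resolution-normalized", {
  out <- make_plumage_image(three_patch_spec(width = 160, noise_sd = 0))
  img <- out$image
  bs_full <- boundary_strength(make_color_map(img))
  bs_half <- boundary_strength(make_color_map(
    resample_to_common_width(img, 80)))
  expect_lt(max(abs(bs_full - bs_half) / bs_full), 0.05)
})

test_that("simpson_scaled matches hand values and is maximal at equality", {
  expect_equal(simpson_scaled(c(0.5, 0.5)), 1)
  expect_equal(simpson_scaled(1), 0)
  expect_equal(simpson_scaled(c(0.9, 0.1)), (1 / 0.82 - 1) / 1,
               tolerance = 1e-9)
  expect_equal(simpson_scaled(c(0.9, 0.1)), 0.2195, tolerance = 1e-4)
  expect_error(simpson_scaled(c(0.5, 0.4)), "sum to 1")
  expect_error(simpson_scaled(c(1.2, -0.2)), "non-negative")
  # maximized at equal proportions for fixed k, over random simplexes
  set.seed(41)
  for (k in 2:5) {
    equal <- simpson_scaled(rep(1 / k, k))
    expect_equal(equal, 1)
    for (r in 1:20) {
      p <- rgamma(k, 1); p <- p / sum(p)
      expect_lte(simpson_scaled(p), equal + 1e-12)
    }
  }
  # alternative convention
  expect_equal(simpson_scaled(c(0.5, 0.5), scale = "D_over_k"), 1)
  expect_equal(simpson_scaled(1, scale = "D_over_k"), 1)
})

test_that("red_proportion applies strict Lab thresholds to raw pixels", {
  # one passing red pixel, one failing (a too low)
  pass <- lab_to_srgb(c(60, 40, 10))
  fail <- lab_to_srgb(c(60, 20, 10))
  rgb <- array(0L, c(1, 2, 3))
  rgb[1, 1, ] <- pass; rgb[1, 2, ] <- fail
  img <- masked_image(rgb, matrix(TRUE, 1, 2))
  expect_equal(red_proportion(img), 0.5)
  # boundary case: L exactly at the threshold is excluded
  expect_equal(red_proportion(img, thresholds = c(L = 60.2, a = 30, b = 5)),
               0)
  # nothing exceeding a = 30 -> exactly 0
  grey <- array(100L, c(4, 4, 3))
  expect_equal(red_proportion(masked_image(grey, matrix(TRUE, 4, 4))), 0)
  # fixture with a 30% red patch
  out <- make_plumage_image(three_patch_spec(noise_sd = 2))
  expect_equal(red_proportion(out$image), 0.30, tolerance = 0.01)
})

test_that("all four metrics are invariant under rotation and mirror", {
  out <- make_plumage_image(three_patch_spec(width = 90, noise_sd = 3))
  img <- out$image
  flip <- function(im, f) masked_image(
    array(c(f(im$rgb[, , 1]), f(im$rgb[, , 2]), f(im$rgb[, , 3])),
          c(dim(f(im$mask)), 3)), f(im$mask))
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  mirror <- function(m) m[, ncol(m):1, drop = FALSE]
  m0 <- pattern_metrics(img)
  expect_all_equal(pattern_metrics(flip(img, rot90)), m0, tol = 1e-9)
  expect_all_equal(pattern_metrics(flip(img, mirror)), m0, tol = 1e-9)
})

test_that("emd transport distance is exact on hand cases", {
  expect_equal(emd(c(0.5, 0.5), c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0)
  # all mass moves distance d between two single-colour signatures
  expect_equal(emd(1, 1, matrix(7.5, 1, 1)), 7.5)
  # classic split: supply (0.6, 0.4), demand (0.5, 0.5)
  cost <- matrix(c(0, 2, 3, 0), 2, byrow = TRUE)
  expect_equal(emd(c(0.6, 0.4), c(0.5, 0.5), cost), 0.1 * 2)
  # brute-force LP oracle on random 3x3 instances via grid search over the
  # two free transport variables
  set.seed(51)
  for (r in 1:5) {
    p <- rgamma(2, 1); p <- p / sum(p)
    q <- rgamma(2, 1); q <- q / sum(q)
    cost <- matrix(runif(4, 0, 10), 2)
    # 2x2 transportation has one free variable x11 in [max(0, p1-q2), min(p1, q1)]
    x11 <- seq(max(0, p[1] - q[2]), min(p[1], q[1]), length.out = 2001)
    tot <- cost[1, 1] * x11 + cost[1, 2] * (p[1] - x11) +
      cost[2, 1] * (q[1] - x11) + cost[2, 2] * (q[2] - p[1] + x11)
    expect_equal(emd(p, q, cost), min(tot), tolerance = 1e-5)
  }
})

test_that("image_color_distance is a symmetric signature distance", {
  a <- tiny_map(matrix(c(1L, 1L, 2L, 2L), 2), rbind(c(10, 0, 0), c(50, 20, 0)))
  expect_equal(image_color_distance(a, a), 0)
  # single-colour maps: distance equals the palette ΔE
  u1 <- tiny_map(matrix(1L, 2, 2), rbind(c(20, 0, 0)))
  u2 <- tiny_map(matrix(1L, 2, 2), rbind(c(60, 30, 0)))
  expect_equal(image_color_distance(u1, u2),
               delta_e(c(20, 0, 0), c(60, 30, 0)))
  # symmetry over random signatures
  set.seed(52)
  for (r in 1:5) {
    ka <- sample(2:4, 1); kb <- sample(2:4, 1)
    pa <- rbind(matrix(c(runif(ka, 0, 100), runif(2 * ka, -60, 60)), ka))
    pb <- rbind(matrix(c(runif(kb, 0, 100), runif(2 * kb, -60, 60)), kb))
    la <- matrix(sample(seq_len(ka), 30, replace = TRUE), 5)
    lb <- matrix(sample(seq_len(kb), 30, replace = TRUE), 5)
    ma <- tiny_map(la, pa); mb <- tiny_map(lb, pb)
    expect_equal(image_color_distance(ma, mb), image_color_distance(mb, ma),
                 tolerance = 1e-9)
  }
})

test_that("neighbour joining recovers additive trees", {
  # 4-taxon additive matrix -> topology ((A,B),(C,D))
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbour_joining(d)
  # A and B (and C and D) are cherries
  tip_parent <- tr$edge[match(seq_len(4), tr$edge[, 2]), 1]
  names(tip_parent) <- tr$tip.label
  expect_equal(tip_parent[["A"]], tip_parent[["B"]])
  expect_equal(tip_parent[["C"]], tip_parent[["D"]])
  # path lengths reproduce the additive input exactly
  path_d <- .tree_path_dist(tr)
  expect_all_equal(path_d[rownames(d), colnames(d)], d, tol = 1e-9)
  # 3 taxa resolved exactly
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- neighbour_joining(d3)
  p3 <- .tree_path_dist(tr3)
  expect_all_equal(p3[rownames(d3), colnames(d3)], d3, tol = 1e-9)
  # validation
  expect_error(neighbour_joining(matrix(1, 2, 2)), "at least 3")
  bad <- d; bad[1, 2] <- 99
  expect_error(neighbour_joining(bad), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbour_joining(neg), "non-negative")
})
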