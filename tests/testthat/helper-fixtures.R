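# Shared fixture builders: everything is generated in code at test time.

# tiny color_map built directly from a label matrix and Lab palette
tiny_map <- function(labels, palette) {
  color_map(labels, palette)
}

# the 2x2 hand-enumerated map [[A, A], [B, B]] (rows of the image)
map_2x2_AB <- function(A = c(50, 10, 0), B = c(50, 0, 10)) {
  tiny_map(matrix(c(1L, 2L, 1L, 2L), 2, 2), rbind(A, B))
}

# three-band zero-noise plumage fixture with known areas 0.5 / 0.3 / 0.2
three_patch_spec <- function(width = 120, noise_sd = 0, seed = 3L) {
  plumage_spec(
    width = width, height = round(1.2 * width),
    patches = list(
      list(frac = 1, lab = c(15, 0, 0), shape = "band"),     # base: black
      list(frac = 0.3, lab = c(60, 65, 55), shape = "band"), # red
      list(frac = 0.2, lab = c(92, 0, 3), shape = "band")    # white
    ),
    noise_sd = noise_sd, seed = seed
  )
}

# small ultrametric hand tree ((A:1,B:1):1,C:2);
hand_tree_abc <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# deterministic design + response for GLS tests
gls_toy <- function(n = 10, seed = 1) {
  set.seed(seed)
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(intercept)", "x1", "x2")
  y <- rnorm(n)
  list(X = X, y = y)
}

# random positive-definite covariance from a random pure-birth tree
random_tree_cov <- function(n = 10, seed = 1) {
  tr <- simulate_tree(n, seed = seed)
  ape::vcv.phylo(tr)
}

expect_all_equal <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) < tol)
}

# simulated tree + traits; retries seeds until both habitat levels occur
# (the phylogenetically correlated liability occasionally yields a
# one-level cohort, which would make the habitat column constant)
make_sim_inputs <- function(n = 40, seed = 1L, ...) {
  for (k in 0:25) {
    tr <- simulate_tree(n, seed = seed + 10000L * k)
    traits <- simulate_traits(tr, simulation_spec(seed = seed + 1L +
                                                    10000L * k, ...))
    if (length(unique(traits$habitat)) == 2)
      return(list(tree = tr, traits = traits))
  }
  stop("no two-level habitat cohort found")
}

# independent path-length oracle on a phylo tree, computed directly from
# the edge matrix (label-propagation shortest paths; trees are acyclic so
# this is exact)
.tree_path_dist <- function(tr) {
  n_tip <- length(tr$tip.label)
  n_node <- max(tr$edge)
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tr$edge))) {
    a <- tr$edge[i, 1]; b <- tr$edge[i, 2]; w <- tr$edge.length[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(NA_real_, n_tip, n_tip,
              dimnames = list(tr$tip.label, tr$tip.label))
  for (s in seq_len(n_tip)) {
    dist <- rep(Inf, n_node); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (dist[v] + w < dist[u] - 1e-15) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    d[s, ] <- dist[seq_len(n_tip)]
  }
  d
}
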