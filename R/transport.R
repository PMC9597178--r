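# Exact minimum-cost transport between two discrete colour signatures.
# Solved as a min-cost flow on the complete bipartite network with
# successive shortest paths (Bellman-Ford on the residual graph). Problem
# sizes here are tiny (palettes of at most 27 colours), so exactness is
# cheap and no external LP solver is needed.

#' Earth-mover (minimum-cost transport) distance between two signatures
#'
#' @param p,q Non-negative mass vectors summing to the same total (they are
#'   normalised internally to sum to 1).
#' @param cost Cost matrix, `length(p)` rows by `length(q)` columns.
#' @return The minimum total cost of transporting mass `p` onto `q`.
#' @export
emd <- function(p, q, cost) {
  if (any(p < 0) || any(q < 0)) stop("masses must be non-negative")
  if (!is.matrix(cost) || nrow(cost) != length(p) || ncol(cost) != length(q))
    stop("cost must be a length(p) x length(q) matrix")
  p <- p / sum(p)
  q <- q / sum(q)
  m <- length(p); n <- length(q)
  if (m == 1) return(sum(q * cost[1, ]))
  if (n == 1) return(sum(p * cost[, 1]))

  # nodes: 1 = source, 1+i supplies, 1+m+j demands, N = sink
  N <- m + n + 2
  src <- 1L; snk <- N
  from <- c(rep(src, m), rep(1L + seq_len(m), each = n), 1L + m + seq_len(n))
  to <- c(1L + seq_len(m), rep(1L + m + seq_len(n), times = m), rep(snk, n))
  cap <- c(p, rep(Inf, m * n), q)
  cst <- c(rep(0, m), as.vector(t(cost)), rep(0, n))
  flow <- numeric(length(cap))
  eps <- 1e-12

  repeat {
    # Bellman-Ford over residual arcs (forward: cap - flow > 0 at cost c;
    # backward: flow > 0 at cost -c)
    dist <- rep(Inf, N); dist[src] <- 0
    prev_edge <- integer(N); prev_dir <- integer(N)
    for (it in seq_len(N)) {
      changed <- FALSE
      res_f <- which(cap - flow > eps & is.finite(dist[from]))
      for (e in res_f) {
        nd <- dist[from[e]] + cst[e]
        if (nd < dist[to[e]] - 1e-15) {
          dist[to[e]] <- nd; prev_edge[to[e]] <- e; prev_dir[to[e]] <- 1L
          changed <- TRUE
        }
      }
      res_b <- which(flow > eps & is.finite(dist[to]))
      for (e in res_b) {
        nd <- dist[to[e]] - cst[e]
        if (nd < dist[from[e]] - 1e-15) {
          dist[from[e]] <- nd; prev_edge[from[e]] <- e; prev_dir[from[e]] <- -1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[snk])) break
    # bottleneck along the path
    v <- snk; bott <- Inf
    while (v != src) {
      e <- prev_edge[v]
      bott <- min(bott, if (prev_dir[v] == 1L) cap[e] - flow[e] else flow[e])
      v <- if (prev_dir[v] == 1L) from[e] else to[e]
    }
    if (!is.finite(bott) || bott <= eps) break
    v <- snk
    while (v != src) {
      e <- prev_edge[v]
      if (prev_dir[v] == 1L) {
        flow[e] <- flow[e] + bott
        v <- from[e]
      } else {
        flow[e] <- flow[e] - bott
        v <- to[e]
      }
    }
    if (sum(flow[seq_len(m)]) >= 1 - 1e-9) break
  }
  sum(flow * cst)
}
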