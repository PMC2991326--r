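# Comparison methods: randomized hill-climbing from a weighted random
# spanning tree, and a uniformly random edge set.

#' Random spanning tree weighted by the connectivity matrix
#'
#' Grows a tree by repeatedly attaching an outside vertex through an edge
#' drawn with probability proportional to its matrix entry, so pairs with
#' high observed connectivity are preferred.
#'
#' @param M a [connectivity_matrix()]
#' @return a `ppi_graph` spanning tree (n - 1 edges, connected)
#' @export
random_spanning_tree <- function(M) {
  ids <- rownames(M$values)
  n <- length(ids)
  if (n < 2) stop("a spanning tree needs at least 2 vertices")
  inside <- sample(ids, 1)
  outside <- setdiff(ids, inside)
  edges <- NULL
  while (length(outside) > 0) {
    w <- M$values[inside, outside, drop = FALSE]
    if (sum(w) <= 0) w[] <- 1
    pick <- sample.int(length(w), 1, prob = as.vector(w))
    i <- (pick - 1) %% length(inside) + 1
    j <- (pick - 1) %/% length(inside) + 1
    edges <- rbind(edges, c(inside[i], outside[j]))
    inside <- c(inside, outside[j])
    outside <- outside[-j]
  }
  ppi_graph(edges, vertices = ids)
}

#' Randomized hill-climbing reconstruction
#'
#' Starts from a [random_spanning_tree()]. Each iteration samples the
#' current candidate's connectivity matrix, draws a vertex pair with
#' probability proportional to the discrepancy `D(u,v) = |M(u,v) - P(u,v)|`,
#' and flips that pair towards the observation: the edge is removed when
#' present but observed connectivity is below the candidate's (rejecting
#' removals that disconnect the graph), and added when absent but observed
#' connectivity is above.
#'
#' @param M a [connectivity_matrix()]
#' @param max_iters iteration budget
#' @param n_samples Monte-Carlo samples per iteration (default 500, matching
#'   the GA fitness sampler)
#' @return the final `ppi_graph` (always connected)
#' @export
hill_climb <- function(M, max_iters = 1000, n_samples = 500) {
  if (max_iters < 0) stop("max_iters must be >= 0")
  g <- random_spanning_tree(M)
  ids <- rownames(M$values)
  delta <- max(M$delta, sampling_half_width(n_samples, 0.95))
  for (it in seq_len(max_iters)) {
    P <- estimate_connectivity(prob_graph(g, p_hat = M$p_hat), n_samples)
    D <- abs(M$values - P$values[ids, ids])
    D[lower.tri(D, diag = TRUE)] <- 0
    if (sum(D) <= 0) break
    pick <- sample.int(length(D), 1, prob = as.vector(D))
    u <- ids[(pick - 1) %% length(ids) + 1]
    v <- ids[(pick - 1) %/% length(ids) + 1]
    key <- edge_keys(cbind(u, v))
    present <- key %in% edge_keys(g$edges)
    if (present && M$values[u, v] < P$values[u, v] - delta) {
      keep <- edge_keys(g$edges) != key
      cand <- ppi_graph(g$edges[keep, , drop = FALSE], vertices = ids)
      comp <- igraph::components(as_igraph(cand))
      if (comp$no == igraph::components(as_igraph(g))$no) g <- cand
    } else if (!present && M$values[u, v] > P$values[u, v] + delta) {
      g <- ppi_graph(rbind(g$edges, c(u, v)), vertices = ids)
    }
  }
  g
}

#' Uniformly random edge baseline
#'
#' @param vertices character vector of vertex ids (or a count)
#' @param m_edges number of distinct edges to draw
#' @return a `ppi_graph` with `m_edges` pairs drawn uniformly without
#'   replacement
#' @export
random_edge_baseline <- function(vertices, m_edges) {
  if (length(vertices) == 1 && is.numeric(vertices)) {
    vertices <- paste0("v", seq_len(vertices))
  }
  n <- length(vertices)
  npairs <- choose(n, 2)
  if (m_edges > npairs) stop("m_edges exceeds the number of vertex pairs")
  if (m_edges == 0) return(ppi_graph(NULL, vertices = vertices))
  pairs <- t(combn(sort(vertices), 2))
  sel <- sample.int(npairs, m_edges)
  ppi_graph(pairs[sel, , drop = FALSE], vertices = vertices)
}
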