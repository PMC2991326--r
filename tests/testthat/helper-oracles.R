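# Independent oracles used to validate the implementation. They enumerate
# edge subsets with igraph component labelling and never touch the package's
# reliability kernels.

# brute-force two-terminal connection probabilities (uniform p or per-edge
# probs, aligned with g$edges rows)
oracle_connectivity <- function(g, p = 0.5, probs = NULL) {
  ids <- g$vertices
  m <- nrow(g$edges)
  if (is.null(probs)) probs <- rep(p, m)
  vals <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ig <- as_igraph(g)
  for (mask in 0:(2^m - 1)) {
    keep <- if (m > 0) bitwAnd(mask, 2^(seq_len(m) - 1)) > 0 else logical(0)
    pr <- prod(ifelse(keep, probs, 1 - probs))
    if (pr == 0) next
    sub <- igraph::subgraph_from_edges(ig, which(keep), delete.vertices = FALSE)
    comp <- igraph::components(sub)$membership[ids]
    vals <- vals + pr * outer(comp, comp, "==")
  }
  diag(vals) <- 1
  vals
}

# closed-form connectivity of a forest: survival^distance along unique paths
tree_matrix_oracle <- function(g, p = 0.5) {
  d <- igraph::distances(as_igraph(g))
  vals <- p^d
  vals[is.infinite(d)] <- 0
  diag(vals) <- 1
  connectivity_matrix(vals[g$vertices, g$vertices], p_hat = p,
                      delta = 0, n_samples = 0)
}

# exact matrix computed by the package (validated against the oracle in the
# reliability tests); delta can be overridden to emulate a tolerance-bearing
# observation
exact_matrix <- function(g, p = 0.5, delta = 0) {
  M <- exact_connectivity(prob_graph(g, p))
  if (delta > 0) {
    M <- connectivity_matrix(M$values, p_hat = p, delta = delta, n_samples = 0)
  }
  M
}

# random connected graph: random recursive tree plus `extra` chords
random_connected_graph <- function(n, extra = 0) {
  tr <- generate_fixture("tree", n = n)
  e <- tr$edges
  if (extra > 0) {
    allp <- t(combn(tr$vertices, 2))
    used <- paste(e[, 1], e[, 2])
    free <- allp[!(paste(allp[, 1], allp[, 2]) %in% used), , drop = FALSE]
    if (nrow(free) > 0) {
      pick <- sample(nrow(free), min(extra, nrow(free)))
      e <- rbind(e, free[pick, , drop = FALSE])
    }
  }
  ppi_graph(e, vertices = tr$vertices)
}

edge_key_set <- function(edges) {
  if (NROW(edges) == 0) return(character(0))
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
}

vertex_degrees <- function(g) {
  table(factor(as.vector(g$edges), levels = g$vertices))
}

adjacency_list <- function(g) {
  split(c(g$edges[, 2], g$edges[, 1]), c(g$edges[, 1], g$edges[, 2]))
}

# fitness of a candidate computed entirely through the igraph oracle
oracle_fitness <- function(idx, inst, tol) {
  sel <- inst$e_maybe[idx, , drop = FALSE]
  ed <- rbind(cbind(inst$e_yes$u, inst$e_yes$v), cbind(sel$u, sel$v))
  pr <- c(inst$e_yes$prob, rep(inst$p_hat, nrow(sel)))
  if (NROW(ed) > 0) {
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    agg <- tapply(pr, key, function(x) 1 - prod(1 - x))
    uk <- !duplicated(key)
    ed <- ed[uk, , drop = FALSE]
    pr <- as.numeric(agg[key[uk]])
    ord <- order(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    g <- ppi_graph(ed, vertices = inst$core)
    vals <- oracle_connectivity(g, probs = pr[ord])
  } else {
    g <- ppi_graph(NULL, vertices = inst$core)
    vals <- oracle_connectivity(g)
  }
  obs <- inst$matrix$values[inst$core, inst$core]
  est <- vals[inst$core, inst$core]
  ut <- upper.tri(obs)
  sum(abs(est[ut] - obs[ut]) <= tol)
}

# hand-built decomposition record (for exercising reduce_instance directly)
manual_decomp <- function(blocks, degree2 = character(0), e2 = NULL,
                          neighbors = list(), cut_edges = NULL) {
  e2m <- if (is.null(e2)) matrix(character(0), ncol = 2) else {
    cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  }
  cm <- if (is.null(cut_edges)) matrix(character(0), ncol = 2) else cut_edges
  structure(list(cut_edges = cm, one_cut = character(0),
                 isolated = character(0), blocks = blocks, tree = NULL,
                 degree2_vertices = degree2, degree2_edges = e2m,
                 degree2_neighbors = neighbors),
            class = "decomp")
}
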