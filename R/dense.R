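# Phase II: dense-region (possible k-clique) detection. Inside a k-clique,
# every vertex pair is connected with probability at least clique_conn(k),
# so thresholding the connectivity matrix at t_k and enumerating maximal
# cliques of the threshold graph finds every true clique of size >= k
# (with some over-reporting tolerated).

#' Threshold graph of a connectivity matrix
#'
#' @param M a [connectivity_matrix()]
#' @param t threshold in `[0,1]`
#' @return a `ppi_graph` with an edge for every pair with `M(u,v) >= t`
#' @export
build_threshold_graph <- function(M, t) {
  if (t < 0 || t > 1) stop("t must lie in [0,1]")
  vals <- M$values
  hits <- which(vals >= t & upper.tri(vals), arr.ind = TRUE)
  edges <- cbind(rownames(vals)[hits[, 1]], colnames(vals)[hits[, 2]])
  ppi_graph(edges, vertices = rownames(vals))
}

#' Detect dense regions (candidate k-cliques)
#'
#' Thresholds the matrix at `t = clique_conn(k, p_hat) - delta` (the slack
#' absorbs sampling noise so the completeness guarantee survives on sampled
#' matrices), then enumerates maximal cliques of size >= k within each
#' connected component of the threshold graph. Components larger than
#' `component_guard` are reported whole as a single region rather than
#' enumerated.
#'
#' @param M a [connectivity_matrix()]
#' @param k minimum clique size (>= 3)
#' @param component_guard abort clique enumeration above this component size
#' @return object of class `dense_regions`: `k`, `threshold`, `regions`
#'   (list of vertex-id vectors, possibly overlapping), `region_edges`
#'   (two-column matrix of all within-region pairs)
#' @export
detect_dense_regions <- function(M, k = 5, component_guard = 60) {
  if (k < 3) stop("k must be >= 3")
  t_k <- clique_conn(k, M$p_hat) - M$delta
  gt <- build_threshold_graph(M, t_k)
  ig <- as_igraph(gt)
  comp <- igraph::components(ig)
  regions <- list()
  for (ci in seq_len(comp$no)) {
    memb <- names(comp$membership)[comp$membership == ci]
    if (length(memb) < k) next
    if (length(memb) > component_guard) {
      regions[[length(regions) + 1]] <- sort(memb)
      next
    }
    sub <- igraph::induced_subgraph(ig, memb)
    cls <- igraph::max_cliques(sub, min = k)
    for (cl in cls) {
      regions[[length(regions) + 1]] <- sort(igraph::V(sub)$name[as.integer(cl)])
    }
  }
  region_edges <- do.call(rbind, lapply(regions, function(r) t(combn(r, 2))))
  structure(list(k = k, threshold = t_k, regions = regions,
                 region_edges = canonical_edges(region_edges)),
            class = "dense_regions")
}

#' @export
print.dense_regions <- function(x, ...) {
  cat(sprintf("<dense_regions> k = %d, threshold = %.4f, %d regions\n",
              x$k, x$threshold, length(x$regions)))
  invisible(x)
}

#' Sweep dense-region detection over several clique sizes
#'
#' Runs [detect_dense_regions()] for each k (largest first); regions found at
#' larger k take precedence, and any region contained in an already accepted
#' one is dropped.
#'
#' @param M a [connectivity_matrix()]
#' @param ks clique sizes, default `c(7, 6, 5)`
#' @param component_guard see [detect_dense_regions()]
#' @return a `dense_regions` object (field `k` holds the smallest swept k)
#' @export
sweep_dense_regions <- function(M, ks = c(7, 6, 5), component_guard = 60) {
  ks <- sort(ks, decreasing = TRUE)
  regions <- list()
  for (k in ks) {
    dr <- detect_dense_regions(M, k = k, component_guard = component_guard)
    for (r in dr$regions) {
      if (!any(vapply(regions, function(q) all(r %in% q), logical(1)))) {
        regions[[length(regions) + 1]] <- r
      }
    }
  }
  region_edges <- do.call(rbind, lapply(regions, function(r) t(combn(r, 2))))
  structure(list(k = min(ks), threshold = clique_conn(min(ks), M$p_hat) - M$delta,
                 regions = regions, region_edges = canonical_edges(region_edges)),
            class = "dense_regions")
}

# merge overlapping regions into disjoint super-regions (union-find); the
# crossover cut contracts each super-region to one weighted block
merge_regions <- function(regions) {
  if (length(regions) == 0) return(list())
  verts <- sort(unique(unlist(regions)))
  par <- setNames(seq_along(verts), verts)
  findp <- function(i) {
    while (par[i] != i) {
      par[i] <<- par[par[i]]
      i <- par[i]
    }
    i
  }
  for (r in regions) {
    i0 <- findp(match(r[1], verts))
    for (x in r[-1]) {
      ix <- findp(match(x, verts))
      if (ix != i0) par[ix] <- i0
    }
  }
  roots <- vapply(seq_along(verts), findp, numeric(1))
  unname(lapply(split(verts, roots), sort))
}

#' Write dense regions as TSV (one region per line: k, threshold, members)
#' @param dr a `dense_regions`
#' @param path output file
#' @export
write_dense_regions <- function(dr, path) {
  lines <- vapply(dr$regions, function(r) {
    paste(c(dr$k, format(dr$threshold, digits = 6), r), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
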