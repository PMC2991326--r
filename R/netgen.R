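# Synthetic ground-truth networks. PPI networks are approximately
# scale-free, so the test networks come from a preferential-attachment
# model (few dense clusters, many weakly connected vertices) and a
# duplication model (clustered, clique-rich). Deterministic fixtures cover
# the canonical small cases.

vertex_ids <- function(n) sprintf("v%04d", seq_len(n))

#' Preferential-attachment network
#'
#' Starts from a single edge; every new vertex attaches 1 or 2 edges
#' (uniformly, an expected attachment factor of 1.5) to existing vertices
#' chosen with probability proportional to their current degree. The
#' construction adds at most two edges per vertex, so the generated graphs
#' contain no clique larger than a triangle.
#'
#' @param n number of vertices (>= 2)
#' @param attach_range inclusive range of edges attached per new vertex
#' @return a connected simple `ppi_graph`
#' @export
generate_pam <- function(n, attach_range = c(1, 2)) {
  if (n < 2) stop("n must be >= 2")
  ids <- vertex_ids(n)
  deg <- setNames(integer(n), ids)
  edges <- matrix(c(ids[1], ids[2]), ncol = 2)
  deg[1:2] <- 1L
  for (i in seq(3, length.out = max(0, n - 2))) {
    k <- min(sample(seq(attach_range[1], attach_range[2]), 1), i - 1)
    existing <- ids[seq_len(i - 1)]
    targets <- sample(existing, k, prob = deg[existing])
    edges <- rbind(edges, cbind(ids[i], targets))
    deg[i] <- k
    deg[targets] <- deg[targets] + 1L
  }
  ppi_graph(edges, vertices = ids)
}

#' Duplication-model network
#'
#' Starts from a triangle; each step picks an existing vertex with
#' probability proportional to its degree, duplicates it, and retains each
#' copied edge independently with probability `retention` (steps retaining
#' no edge are redrawn so the graph stays connected). The duplicate is not
#' linked to its parent.
#'
#' @param n number of vertices (>= 3)
#' @param retention per-edge retention probability in (0, 1]
#' @return a connected simple `ppi_graph`
#' @export
generate_dm <- function(n, retention = 0.5) {
  if (n < 3) stop("n must be >= 3")
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  ids <- vertex_ids(n)
  adj <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  deg <- c(2L, 2L, 2L)
  while (length(deg) < n) {
    v <- sample.int(length(deg), 1, prob = deg)
    keep <- adj[[v]][runif(length(adj[[v]])) < retention]
    if (length(keep) == 0) next
    id <- length(deg) + 1L
    adj[[id]] <- keep
    deg[id] <- length(keep)
    for (u in keep) {
      adj[[u]] <- c(adj[[u]], id)
      deg[u] <- deg[u] + 1L
    }
  }
  edges <- do.call(rbind, lapply(seq_along(adj), function(i) {
    nb <- adj[[i]][adj[[i]] > i]
    if (length(nb) == 0) return(NULL)
    cbind(ids[i], ids[nb])
  }))
  ppi_graph(edges, vertices = ids)
}

#' Deterministic and seeded fixture graphs
#'
#' @param kind one of `"path"`, `"cycle"`, `"clique"`, `"tree"` (random
#'   recursive tree), `"planted_clique"` (random tree backbone plus one
#'   k-clique over randomly chosen backbone vertices, recorded in the
#'   `"clique"` attribute)
#' @param n number of vertices
#' @param k clique size for `"clique"` / `"planted_clique"`
#' @return a `ppi_graph`
#' @export
generate_fixture <- function(kind = c("path", "cycle", "clique", "tree",
                                      "planted_clique"),
                             n = NULL, k = NULL) {
  kind <- match.arg(kind)
  if (kind == "clique") {
    if (is.null(k)) k <- n
    if (is.null(k) || k < 2) stop("clique needs k >= 2")
    ids <- vertex_ids(k)
    return(ppi_graph(t(combn(ids, 2)), vertices = ids))
  }
  if (is.null(n) || n < 2) stop("n must be >= 2")
  ids <- vertex_ids(n)
  if (kind == "path") {
    return(ppi_graph(cbind(ids[-n], ids[-1]), vertices = ids))
  }
  if (kind == "cycle") {
    if (n < 3) stop("a cycle needs n >= 3")
    return(ppi_graph(rbind(cbind(ids[-n], ids[-1]), c(ids[n], ids[1])),
                     vertices = ids))
  }
  # random recursive tree: vertex i attaches to a uniform earlier vertex
  parents <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  edges <- cbind(ids[parents[-1]], ids[-1])
  if (kind == "tree") return(ppi_graph(edges, vertices = ids))
  if (is.null(k) || k < 2 || k > n) stop("planted_clique needs 2 <= k <= n")
  members <- sort(sample(ids, k))
  g <- ppi_graph(rbind(edges, t(combn(members, 2))), vertices = ids)
  attr(g, "clique") <- members
  g
}
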