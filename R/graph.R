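# Graph containers. Vertex ids are opaque character strings; edges are stored
# as a canonical two-column character matrix with pmin/pmax ordering so that
# every unordered pair has a single representation.

canonical_edges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("u", "v"))))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two columns")
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  if (any(a == b)) stop("self-loops are not allowed")
  m <- cbind(u = pmin(a, b), v = pmax(a, b))
  m <- m[!duplicated(paste(m[, 1], m[, 2], sep = "\r")), , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

edge_keys <- function(edges) {
  if (NROW(edges) == 0) return(character(0))
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "\r")
}

#' Create an undirected simple graph
#'
#' @param edges two-column matrix or data frame of vertex-id pairs (character
#'   or coercible); self-loops are rejected, duplicates collapsed.
#' @param vertices optional character vector of vertex ids; defaults to the
#'   ids appearing in `edges`. Isolated vertices can be added here.
#' @return an object of class `ppi_graph` with fields `vertices` (sorted
#'   character vector) and `edges` (canonical two-column character matrix).
#' @examples
#' g <- ppi_graph(rbind(c("a", "b"), c("b", "c")))
#' @export
ppi_graph <- function(edges = NULL, vertices = NULL) {
  e <- canonical_edges(edges)
  v <- sort(unique(c(as.character(vertices), as.vector(e))))
  if (length(v) == 0) stop("a graph needs at least one vertex or edge")
  if (!all(as.vector(e) %in% v)) stop("edge endpoint not in vertex set")
  structure(list(vertices = v, edges = e), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

#' Convert to an igraph object
#' @param g a `ppi_graph`
#' @return an undirected `igraph` graph with vertex names preserved
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(as.data.frame(g$edges),
                                directed = FALSE,
                                vertices = g$vertices)
}

#' Attach edge-survival probabilities to a graph
#'
#' The probabilistic-graph model of AP-MS: each direct interaction survives
#' purification independently with its survival probability (uniform `p_hat`
#' by default, per-edge overrides allowed for meta-edges).
#'
#' @param graph a [ppi_graph()]
#' @param p_hat uniform survival probability in (0, 1]
#' @param survival optional numeric vector, one probability per edge row of
#'   `graph$edges`
#' @return an object of class `prob_graph`
#' @export
prob_graph <- function(graph, p_hat = 0.5, survival = NULL) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!is.numeric(p_hat) || length(p_hat) != 1 || p_hat <= 0 || p_hat > 1) {
    stop("p_hat must be a single probability in (0, 1]")
  }
  if (is.null(survival)) {
    survival <- rep(p_hat, n_edges(graph))
  }
  if (length(survival) != n_edges(graph)) {
    stop("survival must have one entry per edge")
  }
  if (any(survival <= 0 | survival > 1)) {
    stop("edge survival probabilities must lie in (0, 1]")
  }
  structure(list(graph = graph, p_hat = p_hat, survival = as.numeric(survival)),
            class = "prob_graph")
}

#' @export
print.prob_graph <- function(x, ...) {
  cat(sprintf("<prob_graph> %d vertices, %d edges, p_hat = %g\n",
              length(x$graph$vertices), n_edges(x$graph), x$p_hat))
  invisible(x)
}

# 0-based integer edge matrix + vertex index map, for the C++ kernels
graph_index <- function(g) {
  idx <- seq_along(g$vertices) - 1L
  names(idx) <- g$vertices
  e <- g$edges
  list(vertices = g$vertices,
       edges0 = cbind(idx[e[, 1]], idx[e[, 2]]))
}

#' True cut edges (bridges) of a graph
#' @param g a `ppi_graph`
#' @return two-column character matrix of bridge edges
#' @export
true_cut_edges <- function(g) {
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  if (length(br) == 0) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("u", "v"))))
  }
  ends <- igraph::ends(ig, br)
  canonical_edges(ends)
}

#' Vertices all of whose incident edges are cut edges
#' @param g a `ppi_graph`
#' @return character vector of 1-cut vertex ids
#' @export
one_cut_vertices <- function(g) {
  bridges <- edge_keys(true_cut_edges(g))
  all_e <- g$edges
  bad <- unique(as.vector(all_e[!(edge_keys(all_e) %in% bridges), , drop = FALSE]))
  deg <- table(factor(as.vector(all_e), levels = g$vertices))
  setdiff(g$vertices[deg > 0], bad)
}

#' Read / write an edge-list TSV
#'
#' Two id columns, optional third column with a per-edge survival
#' probability. Lines starting with `#` are treated as comments.
#'
#' @param path file path
#' @return `read_edgelist`: a `ppi_graph` (with attribute `survival` if a
#'   third column is present)
#' @export
read_edgelist <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   colClasses = "character")
  g <- ppi_graph(df[, 1:2])
  if (ncol(df) >= 3) attr(g, "survival") <- as.numeric(df[, 3])
  g
}

#' @rdname read_edgelist
#' @param g a `ppi_graph` or `prob_graph`
#' @param comments optional character vector written as `#`-prefixed header
#' @export
write_edgelist <- function(g, path, comments = NULL) {
  pg <- NULL
  if (inherits(g, "prob_graph")) {
    pg <- g
    g <- g$graph
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  df <- as.data.frame(g$edges)
  if (!is.null(pg)) df$p <- format(pg$survival, digits = 10)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare a predicted edge set against a ground-truth edge set
#'
#' Computes true/false positives and negatives over unordered vertex pairs,
#' and the false-discovery and false-negative rates (in percent) used
#' throughout the performance evaluation.
#'
#' @param predicted,truth `ppi_graph` objects over the same vertex universe
#' @return list with `tp`, `fp`, `fn`, `fdr`, `fnr` (rates in percent)
#' @export
evaluate_prediction <- function(predicted, truth) {
  if (!setequal(predicted$vertices, truth$vertices)) {
    stop("predicted and truth graphs must share the same vertex universe")
  }
  pk <- edge_keys(predicted$edges)
  tk <- edge_keys(truth$edges)
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  fdr <- if (tp + fp > 0) 100 * fp / (tp + fp) else 0
  fnr <- if (tp + fn > 0) 100 * fn / (tp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, fdr = fdr, fnr = fnr)
}
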