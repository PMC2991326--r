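# Two-terminal reliability of probabilistic graphs: Monte-Carlo estimation,
# exact enumeration for small instances, series/parallel composition and
# clique-connectivity combinatorics.

#' Construct a connectivity matrix
#'
#' A connectivity matrix holds, for every pair of proteins, the probability
#' that they remain connected after each direct interaction independently
#' survives with probability `p_hat`. Sampled matrices carry the additive
#' sampling tolerance `delta` and the sample count used.
#'
#' @param values symmetric numeric matrix in `[0,1]` with unit diagonal and
#'   vertex ids as dimnames
#' @param p_hat edge survival probability the matrix refers to
#' @param delta additive sampling tolerance; defaults to
#'   [sampling_half_width()] at 95% confidence when `n_samples > 0`, else 0
#' @param n_samples Monte-Carlo sample count (0 for exact/analytic matrices)
#' @return object of class `conn_matrix`
#' @export
connectivity_matrix <- function(values, p_hat, delta = NULL, n_samples = 0) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("v", seq_len(nrow(values)))
  }
  if (nrow(values) != ncol(values)) stop("values must be square")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8))) {
    stop("values must be symmetric")
  }
  if (any(values < -1e-12 | values > 1 + 1e-12)) stop("entries must lie in [0,1]")
  values <- pmin(pmax(values, 0), 1)
  diag(values) <- 1
  values <- (values + t(values)) / 2
  if (is.null(delta)) {
    delta <- if (n_samples > 0) sampling_half_width(n_samples, 0.95) else 0
  }
  structure(list(values = values, vertex_order = rownames(values),
                 p_hat = p_hat, delta = delta, n_samples = as.integer(n_samples)),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d vertices, p_hat = %g, delta = %.4g, n_samples = %d\n",
              nrow(x$values), x$p_hat, x$delta, x$n_samples))
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$values)

# restrict to a vertex subset, keeping metadata
subset_matrix <- function(M, vids) {
  connectivity_matrix(M$values[vids, vids, drop = FALSE], p_hat = M$p_hat,
                      delta = M$delta, n_samples = M$n_samples)
}

#' Sample one realization of a probabilistic graph
#'
#' Each edge is retained independently with its survival probability,
#' emulating one AP-MS purification of the direct-interaction network.
#'
#' @param pg a [prob_graph()]
#' @return a `ppi_graph` on the same vertex set
#' @export
sample_realization <- function(pg) {
  stopifnot(inherits(pg, "prob_graph"))
  keep <- runif(n_edges(pg$graph)) < pg$survival
  ppi_graph(pg$graph$edges[keep, , drop = FALSE], vertices = pg$graph$vertices)
}

#' Monte-Carlo estimate of the connectivity matrix
#'
#' Draws `n_samples` independent edge-survival realizations; entry (u,v) is
#' the fraction of realizations in which u and v fall in the same connected
#' component (one component labelling per realization).
#'
#' @param pg a [prob_graph()]
#' @param n_samples number of realizations (>= 1)
#' @return a [connectivity_matrix()] with `delta` set to the 95% worst-case
#'   sampling half-width
#' @export
estimate_connectivity <- function(pg, n_samples = 20000) {
  stopifnot(inherits(pg, "prob_graph"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  gi <- graph_index(pg$graph)
  counts <- mc_connectivity_counts(length(gi$vertices), gi$edges0,
                                   pg$survival, as.integer(n_samples))
  vals <- counts / n_samples
  dimnames(vals) <- list(gi$vertices, gi$vertices)
  diag(vals) <- 1
  connectivity_matrix(vals, p_hat = pg$p_hat, n_samples = n_samples)
}

# closed form for forests: product of edge survival along the unique path
forest_connectivity <- function(pg) {
  g <- pg$graph
  n <- length(g$vertices)
  vals <- matrix(0, n, n, dimnames = list(g$vertices, g$vertices))
  adj <- vector("list", n)
  names(adj) <- g$vertices
  for (k in seq_len(n_edges(g))) {
    u <- g$edges[k, 1]; v <- g$edges[k, 2]; p <- pg$survival[k]
    adj[[u]] <- rbind(adj[[u]], data.frame(to = v, p = p))
    adj[[v]] <- rbind(adj[[v]], data.frame(to = u, p = p))
  }
  for (s in g$vertices) { # BFS accumulating path products
    prodv <- setNames(rep(NA_real_, n), g$vertices)
    prodv[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (x in frontier) {
        for (row in seq_len(NROW(adj[[x]]))) {
          y <- adj[[x]]$to[row]
          if (is.na(prodv[y])) {
            prodv[y] <- prodv[x] * adj[[x]]$p[row]
            nxt <- c(nxt, y)
          }
        }
      }
      frontier <- nxt
    }
    prodv[is.na(prodv)] <- 0
    vals[s, ] <- prodv
  }
  diag(vals) <- 1
  (vals + t(vals)) / 2
}

is_forest <- function(g) {
  comps <- igraph::components(as_igraph(g))
  n_edges(g) == length(g$vertices) - comps$no
}

#' Exact connectivity matrix by subset enumeration
#'
#' Sums, over all 2^|E| edge subsets, the subset probability times the
#' indicator that two vertices are connected. Forests short-circuit to the
#' closed form (path product of survival probabilities). Exact computation of
#' two-terminal reliability is #P-complete in general, so the enumeration is
#' capped; this routine is the small-instance oracle.
#'
#' @param pg a [prob_graph()]
#' @param max_edges refuse enumeration above this edge count (default 22)
#' @return a [connectivity_matrix()] with `delta = 0`, `n_samples = 0`
#' @export
exact_connectivity <- function(pg, max_edges = 22) {
  stopifnot(inherits(pg, "prob_graph"))
  if (is_forest(pg$graph)) {
    vals <- forest_connectivity(pg)
  } else {
    if (n_edges(pg$graph) > max_edges) {
      stop(sprintf("exact_connectivity: %d edges exceeds the enumeration cap of %d",
                   n_edges(pg$graph), max_edges))
    }
    gi <- graph_index(pg$graph)
    vals <- exact_connectivity_cpp(length(gi$vertices), gi$edges0, pg$survival)
    dimnames(vals) <- list(gi$vertices, gi$vertices)
  }
  connectivity_matrix(vals, p_hat = pg$p_hat, delta = 0, n_samples = 0)
}

#' Series and parallel composition of connection probabilities
#'
#' Two subnetworks joined at a single vertex connect terminals with the
#' product of their reliabilities (series); two subnetworks joined at both
#' terminals connect them with the inclusion-exclusion combination
#' (parallel).
#'
#' @param p1,p2 probabilities in `[0,1]`
#' @return a probability
#' @export
series_prob <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) stop("probabilities must lie in [0,1]")
  p1 * p2
}

#' @rdname series_prob
#' @export
parallel_prob <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) stop("probabilities must lie in [0,1]")
  p1 + p2 - p1 * p2
}

#' Number of connected labelled simple graphs
#'
#' The classical recurrence: gamma_1 = 1 and
#' `gamma_n = 2^C(n,2) - (1/n) * sum_{i<n} i*C(n,i)*2^C(n-i,2)*gamma_i`.
#' Values are exact integers; above n = 10 they exceed the exactly
#' representable double range and the function refuses.
#'
#' @param n number of labelled vertices (1..10)
#' @return gamma_n as a numeric holding an exact integer
#' @export
gamma_connected <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  if (n > 10) stop("gamma_connected is exact only up to n = 10")
  g <- numeric(n)
  g[1] <- 1
  if (n > 1) {
    for (m in 2:n) {
      s <- 0
      for (i in 1:(m - 1)) {
        s <- s + i * choose(m, i) * 2^choose(m - i, 2) * g[i]
      }
      g[m] <- 2^choose(m, 2) - s / m
    }
  }
  g[n]
}

# probability that an Erdos-Renyi G(m, p) graph is connected (exact recurrence)
connectedness_prob <- function(m, p) {
  C <- numeric(m)
  C[1] <- 1
  if (m > 1) {
    for (k in 2:m) {
      s <- 0
      for (i in 1:(k - 1)) {
        s <- s + choose(k - 1, i - 1) * C[i] * (1 - p)^(i * (k - i))
      }
      C[k] <- 1 - s
    }
  }
  C
}

#' Two-terminal reliability of a k-clique
#'
#' The probability that two fixed vertices of K_k remain connected when every
#' edge survives independently with probability `p_hat`. Computed by summing
#' over the size i of the component containing the two terminals:
#' `sum_i C(k-2, i-2) * C_i(p) * (1-p)^{i(k-i)}` where `C_i(p)` is the exact
#' connectedness probability of G(i, p). At `p_hat = 1/2` this reduces to the
#' closed form `sum_i C(k-2, i-2) * gamma_i / 2^{C(k,2) - C(k-i,2)}`.
#'
#' @param k clique size (>= 2)
#' @param p_hat edge survival probability
#' @return the pairwise reliability, used as the dense-region threshold t_k
#' @export
clique_conn <- function(k, p_hat = 0.5) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2")
  }
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0,1]")
  Cp <- connectedness_prob(k, p_hat)
  sum(vapply(2:k, function(i) {
    choose(k - 2, i - 2) * Cp[i] * (1 - p_hat)^(i * (k - i))
  }, numeric(1)))
}

#' Worst-case sampling half-width of a Monte-Carlo connectivity estimate
#'
#' Each matrix entry is a binomial proportion; by the central limit theorem
#' its confidence half-width is largest at p = 0.5, where it equals
#' `z_{1-alpha/2} / (2 sqrt(n))`. This is the additive tolerance delta
#' attached to sampled connectivity matrices.
#'
#' @param n_samples number of Monte-Carlo samples (>= 1)
#' @param confidence confidence level in (0,1), default 0.95
#' @return the half-width delta
#' @examples
#' sampling_half_width(20000) # ~0.007
#' sampling_half_width(500)   # ~0.04
#' @export
sampling_half_width <- function(n_samples, confidence = 0.95) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (confidence <= 0 || confidence >= 1) stop("confidence must lie in (0,1)")
  qnorm(1 - (1 - confidence) / 2) / (2 * sqrt(n_samples))
}

#' Read / write a connectivity matrix TSV
#'
#' First row and first column carry vertex ids; cells are decimals in
#' `[0,1]`, written at 6 decimal places. Metadata (`p_hat`, `delta`,
#' `n_samples`) is stored in `#`-prefixed header comments.
#'
#' @param path file path
#' @return `read_connectivity`: a `conn_matrix`
#' @export
read_connectivity <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con)
  on.exit(NULL)
  meta <- list(p_hat = 0.5, delta = 0, n_samples = 0)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   row.names = 1, check.names = FALSE)
  connectivity_matrix(as.matrix(df), p_hat = meta$p_hat, delta = meta$delta,
                      n_samples = meta$n_samples)
}

#' @rdname read_connectivity
#' @param M a `conn_matrix`
#' @export
write_connectivity <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p_hat: %g", M$p_hat), con)
  writeLines(sprintf("# delta: %g", M$delta), con)
  writeLines(sprintf("# n_samples: %d", M$n_samples), con)
  vals <- round(M$values, 6)
  writeLines(paste(c("", colnames(vals)), collapse = "\t"), con)
  for (i in seq_len(nrow(vals))) {
    writeLines(paste(c(rownames(vals)[i], format(vals[i, ], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
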