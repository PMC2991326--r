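# Phase I: identify weakly connected structure directly from the
# connectivity matrix. A pair (u,v) is a cut edge iff (i) M(u,v) is at the
# survival probability p_hat and (ii) the induced partition
# V_u = {x : M(x,u) >= M(x,v)} satisfies the series factorization
# M(s,t) = M(s,u) * p_hat * M(v,t) across the cut. Degree-2 vertices obey
# three necessary conditions on their matrix row (low connectivity, a
# two-way tied neighborhood maximum, and a triangle inequality).

# Tolerances. delta is a per-entry 95% half-width; the detection conditions
# compare hundreds to millions of entries simultaneously, so the bands are
# widened to family-wise coverage: sigma = 1/(2 sqrt(n)) is the worst-case
# binomial sd of one entry, condition (i) uses 4.5 sigma and the product
# condition 5.5 * sqrt(3) * sigma (three estimated factors). Exact matrices
# (n_samples = 0) get machine-epsilon bands.
cut_tolerances <- function(M) {
  sigma <- if (M$n_samples > 0) 1 / (2 * sqrt(M$n_samples)) else 0
  list(edge = max(M$delta, 4.5 * sigma, 1e-9),
       prod = max(3 * M$delta, 5.5 * sqrt(3) * sigma, 1e-9))
}

#' Test whether a vertex pair forms a cut edge
#'
#' @param M a [connectivity_matrix()]
#' @param u,v distinct vertex ids present in `M`
#' @param edge_tol,prod_tol tolerances for the probe condition
#'   `|M(u,v) - p_hat|` and the cross-partition product condition; default to
#'   family-wise bands derived from `M`'s sampling metadata
#' @return list with `is_cut` (logical) and, when true, the partition
#'   `V_u`, `V_v`
#' @export
check_cut_edge <- function(M, u, v, edge_tol = NULL, prod_tol = NULL) {
  vals <- M$values
  if (!(u %in% rownames(vals)) || !(v %in% rownames(vals))) {
    stop("unknown vertex id")
  }
  if (u == v) stop("u and v must differ")
  tol <- cut_tolerances(M)
  if (is.null(edge_tol)) edge_tol <- tol$edge
  if (is.null(prod_tol)) prod_tol <- tol$prod
  no <- list(is_cut = FALSE, V_u = NULL, V_v = NULL)
  if (abs(vals[u, v] - M$p_hat) > edge_tol) return(no)
  side_u <- vals[, u] >= vals[, v]
  Vu <- rownames(vals)[side_u]
  Vv <- rownames(vals)[!side_u]
  if (length(Vv) == 0) return(no)
  pred <- outer(vals[Vu, u], vals[v, Vv]) * M$p_hat
  if (max(abs(vals[Vu, Vv, drop = FALSE] - pred)) > prod_tol) return(no)
  list(is_cut = TRUE, V_u = Vu, V_v = Vv)
}

# find the first qualifying cut edge within a vertex block; candidates are
# probed strongest-evidence first (|M - p_hat| ascending, ties broken
# lexicographically) so that exact-band bridges win over coincidental
# near-p_hat pairs
find_cut_edge <- function(M, vids, edge_tol, prod_tol) {
  vals <- M$values[vids, vids, drop = FALSE]
  cand <- which(abs(vals - M$p_hat) <= edge_tol & upper.tri(vals), arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  ord <- order(abs(vals[cand] - M$p_hat),
               rownames(vals)[cand[, 1]], colnames(vals)[cand[, 2]])
  Msub <- subset_matrix(M, vids)
  for (k in ord) {
    u <- rownames(vals)[cand[k, 1]]
    v <- colnames(vals)[cand[k, 2]]
    res <- check_cut_edge(Msub, u, v, edge_tol = edge_tol, prod_tol = prod_tol)
    if (res$is_cut) return(list(u = u, v = v, V_u = res$V_u, V_v = res$V_v))
  }
  NULL
}

#' Recursive cut-edge decomposition
#'
#' Repeatedly detects a cut edge, splits the matrix into the two induced
#' submatrices (within-side entries are unchanged by removing a cut edge) and
#' recurses until no pair qualifies. Vertices that end up in singleton blocks
#' have all their incident edges detected as cut edges and are flagged 1-cut.
#' On the exact matrix of a tree this recovers the whole tree.
#'
#' @inheritParams check_cut_edge
#' @return object of class `decomp` with fields `cut_edges` (two-column
#'   matrix), `one_cut` (vertex ids), `blocks` (list of unresolved vertex
#'   sets of size >= 2), `tree` (nested split record), and empty degree-2
#'   fields (filled by [decompose_matrix()])
#' @export
decompose_one_cut <- function(M, edge_tol = NULL, prod_tol = NULL) {
  tol <- cut_tolerances(M)
  if (is.null(edge_tol)) edge_tol <- tol$edge
  if (is.null(prod_tol)) prod_tol <- tol$prod
  cut_edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("u", "v")))
  blocks <- list()
  one_cut <- character(0)
  isolated <- character(0)
  rec <- function(vids) {
    if (length(vids) < 2) {
      if (length(vids) == 1) one_cut <<- c(one_cut, vids)
      return(list(vertices = vids))
    }
    hit <- find_cut_edge(M, vids, edge_tol, prod_tol)
    if (is.null(hit)) {
      blocks[[length(blocks) + 1]] <<- vids
      return(list(vertices = vids))
    }
    cut_edges <<- rbind(cut_edges, canonical_edges(cbind(hit$u, hit$v)))
    list(vertices = vids, cut = c(hit$u, hit$v),
         left = rec(hit$V_u), right = rec(hit$V_v))
  }
  # decompose each connectivity component separately: vertices with zero
  # observed connectivity can share no path, and a cut edge only exists
  # within a component
  ids <- rownames(M$values)
  adjpos <- M$values > 0
  diag(adjpos) <- FALSE
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adjpos, mode = "undirected"))$membership
  tree <- list(vertices = ids, components = list())
  for (ci in sort(unique(comp))) {
    vids <- ids[comp == ci]
    if (length(vids) == 1) {
      isolated <- c(isolated, vids)
      next
    }
    tree$components[[length(tree$components) + 1]] <- rec(vids)
  }
  structure(list(cut_edges = canonical_edges(cut_edges), one_cut = sort(one_cut),
                 isolated = sort(isolated), blocks = blocks, tree = tree,
                 degree2_vertices = character(0),
                 degree2_edges = matrix(character(0), ncol = 2),
                 degree2_neighbors = list()),
            class = "decomp")
}

#' @export
print.decomp <- function(x, ...) {
  cat(sprintf("<decomp> %d cut edges, %d 1-cut vertices, %d degree-2 vertices, %d unresolved blocks\n",
              nrow(x$cut_edges), length(x$one_cut),
              length(x$degree2_vertices), length(x$blocks)))
  invisible(x)
}

#' Predict degree-2 vertices from a connectivity matrix
#'
#' Flags every vertex s whose matrix row satisfies, within tolerance:
#' (i) all entries below `2 p_hat - p_hat^2 + delta`; (ii) exactly two tied
#' largest off-diagonal entries (the predicted neighbors u, v), strictly
#' above all others; (iii) for every other t,
#' `M(s,t) < max(M(u,t), M(v,t))` plus tolerance. These are necessary
#' conditions for true degree-2 vertices, so on exact matrices none is
#' missed; occasional higher-degree vertices may be flagged too.
#'
#' @param M a [connectivity_matrix()]
#' @return list with `v2` (flagged ids), `e2` (two-column matrix of
#'   predicted incident edges), `neighbors` (named list id -> its two
#'   predicted neighbors)
#' @export
detect_degree_two <- function(M) {
  vals <- M$values
  p <- M$p_hat
  delta <- M$delta
  eps <- 1e-9
  tie_tol <- 2 * delta + eps
  tri_tol <- 3 * delta + eps
  ids <- rownames(vals)
  v2 <- character(0)
  neighbors <- list()
  if (length(ids) < 3) {
    return(list(v2 = v2, e2 = matrix(character(0), ncol = 2), neighbors = neighbors))
  }
  for (s in ids) {
    row <- vals[s, ]
    row <- row[names(row) != s]
    if (any(row >= 2 * p - p^2 + delta + eps)) next            # (i)
    m1 <- max(row)
    tied <- names(row)[row >= m1 - tie_tol]
    if (length(tied) < 2) next                                 # (ii): no equal pair
    if (length(tied) > 2) {
      # more than two entries share the maximum: on an exact matrix this is
      # a genuine tie (ambiguous neighborhood; e.g. a star center) and the
      # vertex is rejected; on a sampled matrix near-ties are expected in
      # densely connected regions, so the two largest entries are taken
      if (delta <= 0) next
      tied <- tied[order(-row[tied], tied)][1:2]
    }
    u <- tied[1]; v <- tied[2]
    others <- setdiff(names(row), tied)
    if (length(others) > 0) {                                  # (iii)
      lim <- pmax(vals[u, others], vals[v, others]) + tri_tol
      if (any(row[others] >= lim)) next
    }
    v2 <- c(v2, s)
    neighbors[[s]] <- sort(c(u, v))
  }
  e2 <- do.call(rbind, lapply(v2, function(s) {
    rbind(c(s, neighbors[[s]][1]), c(s, neighbors[[s]][2]))
  }))
  list(v2 = v2, e2 = canonical_edges(e2), neighbors = neighbors)
}

#' Full Phase-I decomposition to fixpoint
#'
#' Runs the recursive cut-edge detection, then degree-2 prediction inside
#' each unresolved block (flagged vertices are marked, not removed, since
#' removing them would alter the remaining matrix entries), and repeats
#' until no new structure is found.
#'
#' @inheritParams check_cut_edge
#' @return a `decomp` object with both the cut-edge and degree-2 fields set
#' @export
decompose_matrix <- function(M, edge_tol = NULL, prod_tol = NULL) {
  dec <- decompose_one_cut(M, edge_tol = edge_tol, prod_tol = prod_tol)
  repeat {
    n_before <- length(dec$degree2_vertices)
    v2 <- character(0); e2 <- NULL; nb <- list()
    for (blk in dec$blocks) {
      d2 <- detect_degree_two(subset_matrix(M, blk))
      v2 <- c(v2, d2$v2)
      e2 <- rbind(e2, d2$e2)
      nb <- c(nb, d2$neighbors)
    }
    dec$degree2_vertices <- sort(unique(v2))
    dec$degree2_edges <- canonical_edges(e2)
    dec$degree2_neighbors <- nb
    if (length(dec$degree2_vertices) == n_before) break
  }
  dec
}

#' Survival probability of contracted parallel paths
#'
#' A bundle of vertex-disjoint forced paths between two hard-core vertices is
#' replaced by one meta-edge surviving with probability
#' `1 - prod_i (1 - p_hat^L_i)` for path lengths `L_i`.
#'
#' @param lengths integer path lengths (>= 1), one per parallel path
#' @param p_hat edge survival probability
#' @return the meta-edge survival probability
#' @export
contract_parallel_paths <- function(lengths, p_hat) {
  if (length(lengths) == 0) stop("at least one path length is required")
  if (any(lengths < 1)) stop("path lengths must be >= 1")
  1 - prod(1 - p_hat^lengths)
}

# Walk the chains of flagged degree-2 vertices through the predicted edge
# set. Returns forced paths between core endpoints plus the set of flagged
# vertices that had to be demoted because their predicted neighborhood is
# inconsistent (degree != 2 in the predicted edge graph).
extract_chains <- function(block, flagged, e2) {
  keys <- edge_keys(e2)
  in_block <- e2[, 1] %in% block & e2[, 2] %in% block
  e2 <- e2[in_block, , drop = FALSE]
  repeat {
    adj <- split(c(e2[, 2], e2[, 1]), c(e2[, 1], e2[, 2]))
    degs <- vapply(flagged, function(f) length(adj[[f]]), integer(1))
    demote <- flagged[degs != 2]
    if (length(demote) == 0) break
    flagged <- setdiff(flagged, demote)
    # drop edges predicted only by demoted vertices? keep edges incident to
    # still-flagged vertices; edges between two demoted vertices are dropped
    keep <- e2[, 1] %in% flagged | e2[, 2] %in% flagged
    e2 <- e2[keep, , drop = FALSE]
  }
  core <- setdiff(block, flagged)
  paths <- list()
  seen <- character(0)
  for (u in core) {
    for (f in adj[[u]]) {
      if (!(f %in% flagged)) next
      path <- c(u, f)
      prev <- u; cur <- f
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1) break
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
        if (!(cur %in% flagged)) break
      }
      endv <- path[length(path)]
      if (endv %in% flagged) next # open or cyclic chain; edges stay forced
      key <- paste(c(min(u, endv), if (u <= endv) path[2:(length(path) - 1)] else rev(path[2:(length(path) - 1)]), max(u, endv)), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      paths[[length(paths) + 1]] <- path
    }
  }
  list(paths = paths, flagged = flagged, e2 = e2)
}

#' Reduce a decomposed problem to its hard core
#'
#' Removes 1-cut vertices, contracts chains of flagged degree-2 vertices
#' between hard-core vertices into meta-edges (parallel forced paths with
#' derived survival probabilities), rules out all remaining pairs incident to
#' flagged vertices (`e_no`), and indexes the unresolved candidate pairs
#' (`e_maybe`) that the genetic algorithm will search over.
#'
#' @param M a [connectivity_matrix()]
#' @param dec a `decomp` produced from `M` by [decompose_matrix()]
#' @return object of class `reduced_instance` with fields `core`
#'   (hard-core vertex ids), `matrix` (M restricted to the core), `e_yes`
#'   (data frame of meta-edges: `u`, `v`, `prob`, plus a list column `paths`),
#'   `e_no` (two-column matrix), `e_maybe` (data frame `idx`, `u`, `v`,
#'   `block`), and `block` (named vector: core vertex -> block id)
#' @export
reduce_instance <- function(M, dec) {
  ids <- rownames(M$values)
  if (!all(c(dec$degree2_vertices, as.vector(dec$degree2_edges)) %in% ids)) {
    stop("decomposition refers to vertices absent from the matrix")
  }
  core <- character(0)
  block_of <- character(0)
  e_yes <- data.frame(u = character(0), v = character(0), prob = numeric(0))
  e_yes_paths <- list()
  e_no <- NULL
  e_maybe <- data.frame(u = character(0), v = character(0), block = character(0))
  for (bi in seq_along(dec$blocks)) {
    blk <- sort(dec$blocks[[bi]])
    flagged0 <- intersect(dec$degree2_vertices, blk)
    ch <- extract_chains(blk, flagged0, dec$degree2_edges)
    flagged <- ch$flagged
    bcore <- setdiff(blk, flagged)
    core <- c(core, bcore)
    block_of <- c(block_of, setNames(rep(as.character(bi), length(bcore)), bcore))
    # meta-edges from parallel chains between distinct core endpoints
    if (length(ch$paths) > 0) {
      ends <- t(vapply(ch$paths, function(p) sort(c(p[1], p[length(p)])), character(2)))
      lens <- vapply(ch$paths, function(p) length(p) - 1L, integer(1))
      grp <- paste(ends[, 1], ends[, 2], sep = "\r")
      for (g in unique(grp[ends[, 1] != ends[, 2]])) {
        sel <- which(grp == g)
        uv <- ends[sel[1], ]
        e_yes <- rbind(e_yes, data.frame(u = uv[1], v = uv[2],
                                         prob = contract_parallel_paths(lens[sel], M$p_hat)))
        e_yes_paths[[length(e_yes_paths) + 1]] <- ch$paths[sel]
      }
    }
    # e_no: non-predicted pairs incident to flagged vertices, within block
    if (length(flagged) > 0) {
      allp <- expand.grid(f = flagged, t = blk, stringsAsFactors = FALSE)
      allp <- allp[allp$f != allp$t, ]
      cand <- canonical_edges(allp)
      pred <- edge_keys(ch$e2)
      e_no <- rbind(e_no, cand[!(edge_keys(cand) %in% pred), , drop = FALSE])
    }
    # e_maybe: unresolved core pairs within the block. Under the survival
    # model a direct edge forces P(u,v) >= p_hat, so pairs observed well
    # below p_hat cannot be direct and are ruled out (e_no); this prunes
    # the genetic algorithm's search space considerably.
    if (length(bcore) >= 2) {
      pr <- t(combn(sort(bcore), 2))
      band <- cut_tolerances(M)$edge
      plausible <- M$values[pr] >= M$p_hat - band
      lows <- pr[!plausible, , drop = FALSE]
      pr <- pr[plausible, , drop = FALSE]
      # keep the block connectable: re-admit the strongest ruled-out pairs
      # while the plausible pairs plus meta-edges leave the block split
      if (length(bcore) >= 2 && nrow(lows) > 0) {
        repeat {
          yes_b <- e_yes[e_yes$u %in% bcore & e_yes$v %in% bcore, , drop = FALSE]
          comp <- uf_components(bcore, rbind(as.matrix(yes_b[, c("u", "v")]), pr))
          if (length(unique(comp)) <= 1 || nrow(lows) == 0) break
          joining <- comp[lows[, 1]] != comp[lows[, 2]]
          if (!any(joining)) break
          cand_rows <- which(joining)
          best <- cand_rows[which.max(M$values[lows[cand_rows, , drop = FALSE]])]
          pr <- rbind(pr, lows[best, ])
          lows <- lows[-best, , drop = FALSE]
        }
      }
      if (nrow(lows) > 0) e_no <- rbind(e_no, lows)
      if (nrow(pr) > 0) {
        e_maybe <- rbind(e_maybe, data.frame(u = pr[, 1], v = pr[, 2],
                                             block = as.character(bi)))
      }
    }
  }
  # cross-block core pairs are separated by detected cut edges: forbidden
  if (length(core) >= 2) {
    pr <- t(combn(sort(core), 2))
    cross <- block_of[pr[, 1]] != block_of[pr[, 2]]
    cutk <- edge_keys(dec$cut_edges)
    crossp <- pr[cross, , drop = FALSE]
    crossp <- crossp[!(edge_keys(crossp) %in% cutk), , drop = FALSE]
    e_no <- rbind(e_no, crossp)
  }
  e_maybe <- e_maybe[order(e_maybe$u, e_maybe$v), , drop = FALSE]
  e_maybe <- data.frame(idx = seq_len(nrow(e_maybe)), e_maybe,
                        row.names = NULL, stringsAsFactors = FALSE)
  core <- sort(core)
  attr(e_yes, "paths") <- e_yes_paths
  structure(list(core = core,
                 core_index = setNames(seq_along(core), core),
                 matrix = if (length(core) > 0) subset_matrix(M, core) else NULL,
                 e_yes = e_yes,
                 e_no = canonical_edges(e_no),
                 e_maybe = e_maybe,
                 block = block_of,
                 p_hat = M$p_hat, delta = M$delta, n_samples = M$n_samples),
            class = "reduced_instance")
}

#' @export
print.reduced_instance <- function(x, ...) {
  cat(sprintf("<reduced_instance> core %d vertices, |e_yes| = %d, |e_no| = %d, |e_maybe| = %d\n",
              length(x$core), nrow(x$e_yes), nrow(x$e_no), nrow(x$e_maybe)))
  invisible(x)
}

#' Serialize Phase-I results to a structured text report
#'
#' Sections: CUT_EDGES, ONE_CUT, DEG2, E_YES (with meta-edge probabilities),
#' E_NO, E_MAYBE (index table).
#'
#' @param dec a `decomp`
#' @param inst a `reduced_instance` (optional)
#' @param path output file
#' @export
write_decomposition_report <- function(dec, inst = NULL, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[CUT_EDGES]", con)
  if (nrow(dec$cut_edges) > 0) {
    writeLines(paste(dec$cut_edges[, 1], dec$cut_edges[, 2], sep = "\t"), con)
  }
  writeLines("[ONE_CUT]", con)
  writeLines(dec$one_cut, con)
  writeLines("[DEG2]", con)
  for (s in dec$degree2_vertices) {
    writeLines(paste(c(s, dec$degree2_neighbors[[s]]), collapse = "\t"), con)
  }
  if (!is.null(inst)) {
    writeLines("[E_YES]", con)
    if (nrow(inst$e_yes) > 0) {
      writeLines(paste(inst$e_yes$u, inst$e_yes$v,
                       format(inst$e_yes$prob, digits = 10), sep = "\t"), con)
    }
    writeLines("[E_NO]", con)
    if (nrow(inst$e_no) > 0) {
      writeLines(paste(inst$e_no[, 1], inst$e_no[, 2], sep = "\t"), con)
    }
    writeLines("[E_MAYBE]", con)
    if (nrow(inst$e_maybe) > 0) {
      writeLines(paste(inst$e_maybe$idx, inst$e_maybe$u, inst$e_maybe$v, sep = "\t"), con)
    }
  }
  invisible(path)
}
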