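# Full inference pipeline: Phase I (cut edges, degree-2 vertices), Phase II
# (dense regions), instance reduction, Phase III (genetic algorithm on the
# hard core), and re-assembly of the predicted direct-interaction network.

#' Inference configuration
#'
#' @param k_sweep clique sizes for the dense-region sweep (default 7, 6, 5)
#' @param ga a [ga_config()]
#' @param use_dense run dense-region detection (default TRUE)
#' @return an `inference_config` list
#' @export
inference_config <- function(k_sweep = c(7, 6, 5), ga = ga_config(),
                             use_dense = TRUE) {
  structure(list(k_sweep = k_sweep, ga = ga, use_dense = use_dense),
            class = "inference_config")
}

#' Infer the direct-interaction network from a connectivity matrix
#'
#' Runs the three inference phases and assembles the final edge set:
#' detected cut edges, predicted degree-2 edges (which include the
#' expansion of every contracted meta-edge back to its constituent chain
#' edges), and the e_maybe pairs selected by the genetic algorithm on the
#' hard core.
#'
#' @param M a [connectivity_matrix()]
#' @param cfg an [inference_config()]
#' @return object of class `ppi_inference` with the predicted `graph` and
#'   all phase artifacts (`decomposition`, `dense`, `instance`, `ga`)
#' @export
run_inference <- function(M, cfg = inference_config()) {
  ids <- rownames(M$values)
  if (length(ids) < 2) {
    return(structure(list(graph = ppi_graph(NULL, vertices = ids),
                          decomposition = NULL, dense = NULL,
                          instance = NULL, ga = NULL, config = cfg),
                     class = "ppi_inference"))
  }
  dec <- decompose_matrix(M)
  dense <- if (cfg$use_dense) sweep_dense_regions(M, ks = cfg$k_sweep) else NULL
  inst <- reduce_instance(M, dec)
  ga <- NULL
  ga_edges <- NULL
  if (nrow(inst$e_maybe) > 0) {
    ga <- run_ga(inst, dense, cfg$ga)
    sel <- inst$e_maybe[ga$best$edge_idx, , drop = FALSE]
    ga_edges <- cbind(sel$u, sel$v)
  }
  edges <- rbind(dec$cut_edges, dec$degree2_edges, ga_edges)
  structure(list(graph = ppi_graph(edges, vertices = ids),
                 decomposition = dec, dense = dense, instance = inst,
                 ga = ga, config = cfg),
            class = "ppi_inference")
}

#' @export
print.ppi_inference <- function(x, ...) {
  cat(sprintf("<ppi_inference> %d predicted direct interactions over %d proteins\n",
              nrow(x$graph$edges), length(x$graph$vertices)))
  if (!is.null(x$decomposition)) {
    cat(sprintf("  phase I: %d cut edges, %d one-cut vertices, %d degree-2 vertices\n",
                nrow(x$decomposition$cut_edges),
                length(x$decomposition$one_cut),
                length(x$decomposition$degree2_vertices)))
  }
  if (!is.null(x$instance)) {
    cat(sprintf("  hard core: %d vertices, %d candidate pairs\n",
                length(x$instance$core), nrow(x$instance$e_maybe)))
  }
  invisible(x)
}

#' Per-phase evaluation of an inference run against the true network
#'
#' @param inf a `ppi_inference`
#' @param truth the true `ppi_graph`
#' @return list with the overall [evaluate_prediction()] report plus
#'   per-phase breakdowns (`phase1` for cut + degree-2 edges, `ga` for the
#'   genetic-algorithm edges on the hard core)
#' @export
evaluate_inference <- function(inf, truth) {
  overall <- evaluate_prediction(inf$graph, truth)
  tk <- edge_keys(truth$edges)
  phase1_edges <- rbind(inf$decomposition$cut_edges, inf$decomposition$degree2_edges)
  p1 <- edge_keys(canonical_edges(phase1_edges))
  phase1 <- list(tp = sum(p1 %in% tk), fp = sum(!(p1 %in% tk)))
  phase1$fdr <- if (length(p1) > 0) 100 * phase1$fp / length(p1) else 0
  ga_rep <- NULL
  if (!is.null(inf$ga) && length(inf$ga$best$edge_idx) > 0) {
    sel <- inf$instance$e_maybe[inf$ga$best$edge_idx, , drop = FALSE]
    gk <- edge_keys(canonical_edges(cbind(sel$u, sel$v)))
    core_tk <- tk[vapply(strsplit(tk, "\r"), function(p) {
      all(p %in% inf$instance$core)
    }, logical(1))]
    ga_rep <- list(tp = sum(gk %in% tk), fp = sum(!(gk %in% tk)),
                   fn = sum(!(core_tk %in% gk)))
    ga_rep$fdr <- if (length(gk) > 0) 100 * ga_rep$fp / length(gk) else 0
    ga_rep$fnr <- if (length(core_tk) > 0) 100 * ga_rep$fn / length(core_tk) else 0
  }
  list(overall = overall, phase1 = phase1, ga = ga_rep)
}
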