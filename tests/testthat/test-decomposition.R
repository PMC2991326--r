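# Phase I: cut-edge detection, recursive decomposition, degree-2
# prediction, meta-edge contraction and instance reduction.

test_that("cut-edge test recognizes bridges and rejects cycle edges", {
  p4 <- generate_fixture("path", n = 4)
  M <- exact_matrix(p4, 0.5)
  ids <- p4$vertices
  res <- check_cut_edge(M, ids[2], ids[3])
  expect_true(res$is_cut)
  expect_setequal(res$V_u, ids[1:2])
  expect_setequal(res$V_v, ids[3:4])
  # the cross product identity: M(a,d) = M(a,b) * p * M(c,d)
  expect_equal(M$values[ids[1], ids[4]], 0.5 * 0.5 * 0.5)

  tri <- generate_fixture("cycle", n = 3)
  Mt <- exact_matrix(tri, 0.5)
  expect_false(check_cut_edge(Mt, tri$vertices[1], tri$vertices[2])$is_cut)
  K4 <- generate_fixture("clique", k = 4)
  Mk <- exact_matrix(K4, 0.5)
  expect_false(check_cut_edge(Mk, K4$vertices[1], K4$vertices[2])$is_cut)
  expect_error(check_cut_edge(M, "nope", ids[1]), "unknown")
  expect_error(check_cut_edge(M, ids[1], ids[1]), "differ")
})

test_that("recursive decomposition resolves paths, cycles and pendants", {
  p4 <- generate_fixture("path", n = 4)
  dec <- decompose_one_cut(exact_matrix(p4, 0.5))
  expect_setequal(edge_key_set(dec$cut_edges), edge_key_set(p4$edges))
  expect_setequal(dec$one_cut, p4$vertices)
  expect_length(dec$blocks, 0)

  tri <- generate_fixture("cycle", n = 3)
  dtri <- decompose_one_cut(exact_matrix(tri, 0.5))
  expect_equal(nrow(dtri$cut_edges), 0)
  expect_length(dtri$one_cut, 0)

  # triangle u,v,w with pendant d attached to u
  g <- ppi_graph(rbind(c("u", "v"), c("v", "w"), c("u", "w"), c("u", "d")))
  dg <- decompose_one_cut(exact_matrix(g, 0.5))
  expect_identical(edge_key_set(dg$cut_edges), "d u")
  expect_identical(dg$one_cut, "d")
  expect_length(dg$blocks, 1)
  expect_setequal(dg$blocks[[1]], c("u", "v", "w"))
})

test_that("removing a detected cut edge leaves within-side entries unchanged", {
  g <- ppi_graph(rbind(c("u", "v"), c("v", "w"), c("u", "w"), c("u", "d"),
                       c("d", "e")))
  M <- exact_matrix(g, 0.5)
  res <- check_cut_edge(M, "u", "d")
  expect_true(res$is_cut)
  gcut <- ppi_graph(g$edges[edge_key_set(g$edges) != "d u", , drop = FALSE],
                    vertices = g$vertices)
  Mcut <- exact_matrix(gcut, 0.5)
  for (side in list(res$V_u, res$V_v)) {
    expect_equal(M$values[side, side], Mcut$values[side, side],
                 tolerance = 1e-12)
  }
})

test_that("exact tree matrices are recovered exactly by the recursion", {
  set.seed(41)
  for (i in 1:10) {
    tr <- generate_fixture("tree", n = sample(20:60, 1))
    dec <- decompose_one_cut(tree_matrix_oracle(tr, 0.5))
    expect_setequal(edge_key_set(dec$cut_edges), edge_key_set(tr$edges))
    expect_setequal(dec$one_cut, tr$vertices) # FDR = FNR = 0
  }
})

test_that("degree-2 prediction flags path interiors and 4-cycles, not stars", {
  p4 <- generate_fixture("path", n = 4)
  ids <- p4$vertices
  d2 <- detect_degree_two(exact_matrix(p4, 0.5))
  expect_true(all(c(ids[2], ids[3]) %in% d2$v2))
  expect_false(ids[1] %in% d2$v2) # row maxima 0.5 vs 0.25 unequal
  expect_false(ids[4] %in% d2$v2)
  expect_setequal(d2$neighbors[[ids[2]]], c(ids[1], ids[3]))

  star <- ppi_graph(rbind(c("s", "l1"), c("s", "l2"), c("s", "l3")))
  ds <- detect_degree_two(exact_matrix(star, 0.5))
  expect_false("s" %in% ds$v2) # three-way tie is ambiguous on an exact matrix

  c4 <- generate_fixture("cycle", n = 4)
  Mc <- exact_matrix(c4, 0.5)
  # adjacent 9/16, opposite 7/16
  expect_equal(Mc$values[c4$vertices[1], c4$vertices[2]], 9 / 16)
  expect_equal(Mc$values[c4$vertices[1], c4$vertices[3]], 7 / 16)
  dc <- detect_degree_two(Mc)
  adj <- adjacency_list(c4)
  expect_setequal(dc$v2, c4$vertices)
  for (s in c4$vertices) expect_setequal(dc$neighbors[[s]], adj[[s]])
})

test_that("every true degree-2 vertex is flagged with its true neighbors", {
  # the flagging conditions are necessary, so exact matrices miss nothing;
  # false positives are tolerated
  set.seed(42)
  n_flagged <- 0
  n_wrong <- 0
  for (i in 1:30) {
    g <- random_connected_graph(sample(5:12, 1), extra = sample(0:3, 1))
    if (nrow(g$edges) > 16) next
    d2 <- detect_degree_two(exact_matrix(g, 0.5))
    deg <- vertex_degrees(g)
    adj <- adjacency_list(g)
    for (s in names(deg)[deg == 2]) {
      expect_true(s %in% d2$v2)
      expect_setequal(d2$neighbors[[s]], adj[[s]])
    }
    n_flagged <- n_flagged + length(d2$v2)
    n_wrong <- n_wrong + sum(deg[d2$v2] != 2)
  }
  expect_lt(n_wrong / max(n_flagged, 1), 0.25) # observed FDR stays low
})

test_that("the phase-I fixpoint is idempotent", {
  g <- ppi_graph(rbind(c("u", "v"), c("v", "w"), c("u", "w"), c("u", "d"),
                       c("v", "x"), c("x", "w")))
  M <- exact_matrix(g, 0.5)
  dec1 <- decompose_matrix(M)
  # re-running degree-2 detection inside each block finds nothing new
  for (blk in dec1$blocks) {
    d2 <- detect_degree_two(connectivity_matrix(
      M$values[blk, blk, drop = FALSE], p_hat = 0.5, delta = 0, n_samples = 0))
    expect_true(all(d2$v2 %in% dec1$degree2_vertices))
  }
  dec2 <- decompose_matrix(M)
  expect_identical(dec1$cut_edges, dec2$cut_edges)
  expect_identical(dec1$degree2_vertices, dec2$degree2_vertices)
})

test_that("parallel path contraction follows the composition law", {
  expect_equal(contract_parallel_paths(1, 0.5), 0.5)
  expect_equal(contract_parallel_paths(c(1, 2), 0.5), 5 / 8)
  expect_equal(contract_parallel_paths(c(2, 2), 0.5), 7 / 16)
  # cross-checks: triangle pair and 4-cycle opposite pair
  tri <- oracle_connectivity(generate_fixture("cycle", n = 3), 0.5)
  expect_equal(contract_parallel_paths(c(1, 2), 0.5), tri[1, 2])
  c4 <- generate_fixture("cycle", n = 4)
  oc4 <- oracle_connectivity(c4, 0.5)
  expect_equal(contract_parallel_paths(c(2, 2), 0.5),
               oc4[c4$vertices[1], c4$vertices[3]])
  expect_error(contract_parallel_paths(numeric(0), 0.5), "at least one")
  expect_error(contract_parallel_paths(0, 0.5), ">= 1")
})

test_that("instance reduction contracts chains into meta-edges", {
  # fully resolved path: nothing remains
  p4 <- generate_fixture("path", n = 4)
  dec <- decompose_matrix(exact_matrix(p4, 0.5))
  inst <- reduce_instance(exact_matrix(p4, 0.5), dec)
  expect_length(inst$core, 0)
  expect_equal(nrow(inst$e_maybe), 0)

  # two hubs joined by two disjoint length-2 chains plus an unresolved
  # direct hub pair: one meta-edge of probability 1-(1-p^2)^2 = 7/16
  ids <- c("H1", "H2", "x", "y")
  vals <- diag(4)
  dimnames(vals) <- list(ids, ids)
  set_val <- function(i, j, v) {
    vals[i, j] <<- v
    vals[j, i] <<- v
  }
  set_val("H1", "H2", 0.6)
  set_val("H1", "x", 0.55); set_val("H2", "x", 0.55)
  set_val("H1", "y", 0.55); set_val("H2", "y", 0.55)
  set_val("x", "y", 0.35)
  Mh <- connectivity_matrix(vals, p_hat = 0.5, delta = 0, n_samples = 0)
  dec <- manual_decomp(
    blocks = list(ids), degree2 = c("x", "y"),
    e2 = rbind(c("x", "H1"), c("x", "H2"), c("y", "H1"), c("y", "H2")),
    neighbors = list(x = c("H1", "H2"), y = c("H1", "H2")))
  inst <- reduce_instance(Mh, dec)
  expect_setequal(inst$core, c("H1", "H2"))
  expect_equal(nrow(inst$e_yes), 1)
  expect_equal(inst$e_yes$prob, 7 / 16)
  expect_identical(paste(inst$e_maybe$u, inst$e_maybe$v), "H1 H2")
  # all non-predicted pairs incident to flagged vertices are forbidden
  expect_true("x y" %in% edge_key_set(inst$e_no))

  # no flags on a dense block: every pair remains a candidate
  tri <- generate_fixture("cycle", n = 3)
  Mt <- exact_matrix(tri, 0.5)
  dtri <- manual_decomp(blocks = list(tri$vertices))
  itri <- reduce_instance(Mt, dtri)
  expect_equal(nrow(itri$e_maybe), 3)
  expect_equal(nrow(itri$e_yes), 0)
  expect_equal(nrow(itri$e_no), 0)
  # e_maybe, e_yes pairs and e_no are disjoint pair sets
  expect_length(intersect(paste(itri$e_maybe$u, itri$e_maybe$v),
                          edge_key_set(itri$e_no)), 0)

  # integrity: decomposition naming unknown vertices is rejected
  bad <- manual_decomp(blocks = list(c("H1", "H2", "zz")), degree2 = "zz",
                       e2 = rbind(c("zz", "H1"), c("zz", "H2")),
                       neighbors = list(zz = c("H1", "H2")))
  expect_error(reduce_instance(Mh, bad), "absent")
})

test_that("decomposition reports serialize with all sections", {
  g <- ppi_graph(rbind(c("u", "v"), c("v", "w"), c("u", "w"), c("u", "d")))
  M <- exact_matrix(g, 0.5)
  dec <- decompose_matrix(M)
  inst <- reduce_instance(M, dec)
  path <- tempfile(fileext = ".txt")
  write_decomposition_report(dec, inst, path)
  txt <- readLines(path)
  for (sec in c("[CUT_EDGES]", "[ONE_CUT]", "[DEG2]", "[E_YES]", "[E_NO]",
                "[E_MAYBE]")) {
    expect_true(sec %in% txt)
  }
})
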