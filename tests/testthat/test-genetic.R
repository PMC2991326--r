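# Phase III: cut-based genetic algorithm on reduced instances.

# small instance helpers -------------------------------------------------

# instance over one block with no phase-I flags, from an explicit matrix
block_instance <- function(M) {
  reduce_instance(M, manual_decomp(blocks = list(rownames(M$values))))
}

test_that("average connectivity is the row mean over |V|", {
  vals <- diag(3)
  dimnames(vals) <- list(c("a", "b", "c"), c("a", "b", "c"))
  vals["a", "b"] <- vals["b", "a"] <- 0.5
  vals["a", "c"] <- vals["c", "a"] <- 0.25
  M <- connectivity_matrix(vals, p_hat = 0.5)
  expect_equal(avg_connectivity(M, "a"), 0.75 / 3)
  expect_equal(avg_connectivity(M, "b"), 0.5 / 3)
  expect_error(avg_connectivity(M, "zz"), "unknown")

  # star center beats every leaf (degree correlation)
  star <- ppi_graph(rbind(c("s", "l1"), c("s", "l2"), c("s", "l3"), c("s", "l4")))
  Ms <- exact_matrix(star, 0.5)
  expect_equal(avg_connectivity(Ms, "s"), 4 * 0.5 / 5)
  for (l in paste0("l", 1:4)) {
    expect_equal(avg_connectivity(Ms, l), (0.5 + 3 * 0.25) / 5)
    expect_lt(avg_connectivity(Ms, l), avg_connectivity(Ms, "s"))
  }
})

test_that("initial population is seeded, connected and dense-aware", {
  # empty search space: identical empty candidates
  p4 <- generate_fixture("path", n = 4)
  dec <- decompose_matrix(exact_matrix(p4, 0.5))
  inst0 <- reduce_instance(exact_matrix(p4, 0.5), dec)
  pop0 <- init_population(inst0, NULL, ga_config(population_size = 5))
  expect_true(all(vapply(pop0, function(c) length(c$edge_idx) == 0, logical(1))))

  # planted K5: dense-region edges enter every candidate
  cl <- sprintf("c%d", 1:5)
  g <- ppi_graph(rbind(t(combn(cl, 2)), c("c5", "p1"), c("p1", "p2")))
  M <- exact_matrix(g, 0.5, delta = 0.04)
  inst <- reduce_instance(M, decompose_matrix(M))
  dense <- detect_dense_regions(M, k = 5)
  cfg <- ga_config(population_size = 10)
  set.seed(61)
  pop <- init_population(inst, dense, cfg)
  clique_idx <- inst$e_maybe$idx[inst$e_maybe$u %in% cl & inst$e_maybe$v %in% cl]
  for (cand in pop) expect_true(all(clique_idx %in% cand$edge_idx))

  # determinism under a fixed seed
  set.seed(62)
  a <- init_population(inst, dense, cfg)
  set.seed(62)
  b <- init_population(inst, dense, cfg)
  expect_identical(a, b)
})

test_that("fitness counts matrix entries matched within tolerance", {
  # all-zero observation, empty candidate: every pair matches
  ids <- c("a", "b", "c", "d")
  vals <- diag(4)
  dimnames(vals) <- list(ids, ids)
  M0 <- connectivity_matrix(vals, p_hat = 0.5, delta = 0.01)
  inst0 <- block_instance(M0)
  cfg <- ga_config(population_size = 5, fitness_samples = 100)
  set.seed(63)
  expect_equal(evaluate_fitness(ga_candidate(), inst0, cfg), choose(4, 2))

  # two vertices with observed connectivity 0.5: the empty graph fails
  v2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  M2 <- connectivity_matrix(v2, p_hat = 0.5, delta = 0.01)
  inst2 <- block_instance(M2)
  set.seed(64)
  expect_equal(evaluate_fitness(ga_candidate(), inst2, cfg), 0)

  # the true generating graph matches all pairs (exact mode)
  g <- generate_fixture("clique", k = 4)
  M <- exact_matrix(g, 0.5, delta = 0.02)
  inst <- block_instance(M)
  truth <- inst$e_maybe$idx # K4: every pair is an edge
  cfge <- ga_config(population_size = 5, fitness_samples = 0)
  expect_equal(evaluate_fitness(ga_candidate(truth), inst, cfge), choose(4, 2))
})

test_that("sparse cuts balance contracted blocks and never split regions", {
  ids <- sprintf("v%02d", 1:10)
  inst <- list(core = ids, block = setNames(rep("1", 10), ids))
  set.seed(65)
  cut <- sample_sparse_cut(inst, NULL)
  expect_equal(length(cut$side1), 5)
  expect_equal(length(cut$side2), 5)

  # two 5-vertex regions plus 2 singletons: regions land on opposite sides
  ids2 <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5), "s1", "s2")
  inst2 <- list(core = ids2, block = setNames(rep("1", 12), ids2))
  dense <- list(regions = list(sprintf("a%d", 1:5), sprintf("b%d", 1:5)))
  set.seed(66)
  for (i in 1:20) {
    cut <- sample_sparse_cut(inst2, dense)
    a_side <- c(all(sprintf("a%d", 1:5) %in% cut$side1),
                all(sprintf("a%d", 1:5) %in% cut$side2))
    b_side <- c(all(sprintf("b%d", 1:5) %in% cut$side1),
                all(sprintf("b%d", 1:5) %in% cut$side2))
    expect_true(any(a_side) && any(b_side)) # never split
    expect_false(identical(a_side, b_side)) # opposite sides
  }

  # a dominating region admits no balanced cut
  ids3 <- c(sprintf("a%d", 1:9), "s1")
  inst3 <- list(core = ids3, block = setNames(rep("1", 10), ids3))
  dense3 <- list(regions = list(sprintf("a%d", 1:9)))
  expect_error(sample_sparse_cut(inst3, dense3), "degenerate")
  inst1 <- list(core = "a1", block = setNames("1", "a1"))
  expect_error(sample_sparse_cut(inst1, NULL), "degenerate")
})

test_that("crossover recombines within-side edges and shared crossing edges", {
  ids <- c("1", "2", "3", "4")
  em <- expand.grid(u = ids, v = ids, stringsAsFactors = FALSE)
  em <- em[em$u < em$v, ]
  em <- em[order(em$u, em$v), ]
  em <- data.frame(idx = seq_len(nrow(em)), em, block = "1")
  inst <- list(core = ids, e_maybe = em, e_yes = data.frame(u = character(0),
               v = character(0), prob = numeric(0)))
  cut <- list(side1 = c("1", "2"), side2 = c("3", "4"))
  pick <- function(...) em$idx[paste(em$u, em$v) %in% c(...)]
  g1 <- ga_candidate(pick("1 2", "3 4", "1 3"))
  g2 <- ga_candidate(pick("1 2", "3 4", "2 4"))
  kids <- crossover(g1, g2, cut, inst)
  expect_identical(kids[[1]]$edge_idx, pick("1 2", "3 4"))
  expect_identical(kids[[2]]$edge_idx, pick("1 2", "3 4"))

  g3 <- ga_candidate(pick("1 2", "3 4", "1 3", "2 4"))
  kids2 <- crossover(g1, g3, cut, inst)
  expect_identical(kids2[[1]]$edge_idx, pick("1 2", "3 4", "1 3"))
  expect_identical(kids2[[2]]$edge_idx, pick("1 2", "3 4", "1 3"))

  same <- crossover(g1, g1, cut, inst)
  expect_identical(same[[1]]$edge_idx, g1$edge_idx)
  expect_identical(same[[2]]$edge_idx, g1$edge_idx)

  # within-side inheritance: side-1 edges of a child come from a parent
  kid_sides <- kids2[[1]]$edge_idx
  in1 <- em$idx[em$u %in% cut$side1 & em$v %in% cut$side1]
  expect_true(all(intersect(kid_sides, in1) %in% union(g1$edge_idx, g3$edge_idx)))
})

test_that("mutation respects the rate and repairs connectivity", {
  K4 <- generate_fixture("clique", k = 4)
  M <- exact_matrix(K4, 0.5, delta = 0.02)
  inst <- block_instance(M)
  cfg0 <- ga_config(population_size = 5, mutation_rate = 0)
  full <- ga_candidate(inst$e_maybe$idx)
  expect_identical(mutate_candidate(full, inst, cfg0)$edge_idx, full$edge_idx)

  # disconnected candidate with a unique usable bridge: repair inserts it
  ids <- K4$vertices
  pick <- function(...) {
    inst$e_maybe$idx[paste(inst$e_maybe$u, inst$e_maybe$v) %in% c(...)]
  }
  split_cand <- ga_candidate(pick(paste(ids[1], ids[2]), paste(ids[3], ids[4])))
  rep_cand <- mutate_candidate(split_cand, inst, cfg0)
  comp_edges <- inst$e_maybe[rep_cand$edge_idx, ]
  g_rep <- ppi_graph(cbind(comp_edges$u, comp_edges$v), vertices = ids)
  expect_equal(igraph::components(as_igraph(g_rep))$no, 1)
  expect_true(all(split_cand$edge_idx %in% rep_cand$edge_idx))

  cfg <- ga_config(population_size = 5, mutation_rate = 0.3)
  set.seed(67)
  a <- mutate_candidate(full, inst, cfg)
  set.seed(67)
  b <- mutate_candidate(full, inst, cfg)
  expect_identical(a, b)
})

test_that("parent selection weights fitness above the worst candidate", {
  mk <- function(f) {
    c <- ga_candidate(1L)
    c$fitness <- f
    c
  }
  set.seed(68)
  # equal fitness: uniform; both candidates appear as first parent
  pop <- list(mk(10), mk(10))
  picks <- replicate(200, select_parents(pop)[1])
  expect_setequal(unique(picks), c(1, 2))
  # the worst candidate has weight zero and is never drawn
  pop2 <- list(mk(5), mk(10))
  picks2 <- replicate(200, select_parents(pop2))
  expect_true(all(picks2 == 2))
  # weights 0 : 0.5 : 1
  pop3 <- list(mk(0), mk(5), mk(10))
  picks3 <- as.vector(replicate(600, select_parents(pop3)))
  expect_false(any(picks3 == 1))
  frac3 <- mean(picks3 == 3)
  expect_gt(frac3, 0.55)
  expect_lt(frac3, 0.78) # ~2/3
  expect_error(select_parents(list()), "empty")
})

test_that("the GA recovers small cores exactly and logs monotone history", {
  # empty search space returns the empty candidate immediately
  p4 <- generate_fixture("path", n = 4)
  dec <- decompose_matrix(exact_matrix(p4, 0.5))
  inst0 <- reduce_instance(exact_matrix(p4, 0.5), dec)
  ga0 <- run_ga(inst0, NULL, ga_config(population_size = 5))
  expect_length(ga0$best$edge_idx, 0)

  cfg <- ga_config(population_size = 30, generations = 30,
                   fitness_samples = 0)
  tol <- 0.04
  cases <- list(
    K4 = generate_fixture("clique", k = 4),
    house = ppi_graph(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                            c("b", "d"), c("c", "e"), c("d", "e"),
                            c("b", "e"))))
  for (nm in names(cases)) {
    M <- exact_matrix(cases[[nm]], 0.5, delta = tol)
    inst <- reduce_instance(M, decompose_matrix(M))
    K <- nrow(inst$e_maybe)
    expect_lte(K, 12)
    set.seed(69)
    ga <- run_ga(inst, NULL, cfg)
    best <- -1 # exhaustive search over all subsets via the igraph oracle
    for (mask in 0:(2^K - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
      best <- max(best, oracle_fitness(idx, inst, tol))
    }
    expect_equal(ga$best_fitness, best, info = nm)
    expect_true(all(diff(ga$history$best_fitness) >= 0))
  }

  # dense-region seeding carries a planted K5 core to the optimum
  cl <- sprintf("c%d", 1:5)
  g <- ppi_graph(rbind(t(combn(cl, 2)), c("c5", "p1"), c("p1", "p2")))
  M <- exact_matrix(g, 0.5, delta = tol)
  inst <- reduce_instance(M, decompose_matrix(M))
  dense <- detect_dense_regions(M, k = 5)
  set.seed(70)
  ga <- run_ga(inst, dense, cfg)
  expect_equal(ga$best_fitness, choose(5, 2))

  # determinism: identical history under identical seeds
  set.seed(71)
  h1 <- run_ga(inst, dense, ga_config(population_size = 10, generations = 5,
                                      fitness_samples = 0))$history
  set.seed(71)
  h2 <- run_ga(inst, dense, ga_config(population_size = 10, generations = 5,
                                      fitness_samples = 0))$history
  expect_equal(h1$best_fitness, h2$best_fitness)
})
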