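# Phase III: cut-based genetic algorithm on the reduced instance. A
# candidate is a sorted vector of indices into e_maybe; meta-edges from
# e_yes are implicit in every candidate. Fitness is the number of core
# vertex pairs whose (estimated) connectivity under the candidate falls
# within the tolerance of the observed matrix entry.

#' Genetic algorithm configuration
#'
#' @param population_size number of candidates per generation (default 500)
#' @param mutation_rate fraction of current edges perturbed per mutation
#'   (default 0.05; the useful range is roughly 0.05-0.10)
#' @param fitness_samples Monte-Carlo samples per fitness evaluation
#'   (default 500); 0 requests exact evaluation (small instances only)
#' @param generations generation budget (default 200)
#' @param elitism number of best candidates carried over unchanged
#' @param time_limit optional wall-clock budget in seconds
#' @return a `ga_config` list
#' @export
ga_config <- function(population_size = 500, mutation_rate = 0.05,
                      fitness_samples = 500, generations = 200,
                      elitism = 5, time_limit = Inf) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must lie in [0,1]")
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 fitness_samples = as.integer(fitness_samples),
                 generations = as.integer(generations),
                 elitism = as.integer(elitism),
                 time_limit = time_limit),
            class = "ga_config")
}

new_candidate <- function(idx) {
  structure(list(edge_idx = sort(unique(as.integer(idx))), fitness = NA_real_),
            class = "ga_candidate")
}

#' Construct a GA candidate
#'
#' A candidate solution is a sorted vector of indices into the instance's
#' `e_maybe` table; the forced meta-edges of `e_yes` are implicit in every
#' candidate.
#'
#' @param edge_idx integer indices into `e_maybe`
#' @return a `ga_candidate` with unset fitness
#' @export
ga_candidate <- function(edge_idx = integer(0)) new_candidate(edge_idx)

#' Average connectivity of a vertex
#'
#' `avgCon(u) = (1/|V|) sum_{v != u} M(u,v)`; strongly positively correlated
#' with the degree of u in the hidden direct network, which is what the
#' initial-population generator exploits.
#'
#' @param M a [connectivity_matrix()]
#' @param u vertex id
#' @return value in `[0,1]`
#' @export
avg_connectivity <- function(M, u) {
  if (!(u %in% rownames(M$values))) stop("unknown vertex id")
  sum(M$values[u, colnames(M$values) != u]) / nrow(M$values)
}

# decode a candidate into a probabilistic graph on the core: e_yes
# meta-edges keep their derived survival probabilities; selected e_maybe
# edges get p_hat; a selected pair that coincides with a meta-edge pair is
# composed in parallel.
decode_candidate <- function(cand, inst) {
  sel <- inst$e_maybe[cand$edge_idx, , drop = FALSE]
  edges <- rbind(cbind(inst$e_yes$u, inst$e_yes$v), cbind(sel$u, sel$v))
  probs <- c(inst$e_yes$prob, rep(inst$p_hat, nrow(sel)))
  if (NROW(edges) == 0) {
    return(prob_graph(ppi_graph(NULL, vertices = inst$core), p_hat = inst$p_hat))
  }
  keys <- edge_keys(edges)
  if (anyDuplicated(keys)) {
    agg <- tapply(probs, keys, function(ps) Reduce(parallel_prob, ps))
    uk <- !duplicated(keys)
    edges <- edges[uk, , drop = FALSE]
    probs <- as.numeric(agg[keys[uk]])
  }
  ord <- order(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  g <- ppi_graph(edges, vertices = inst$core)
  # canonical_edges sorts identically, so probs align after the same ordering
  prob_graph(g, p_hat = inst$p_hat, survival = probs[ord])
}

# union-find component labels for a vertex set under an edge list
uf_components <- function(members, edges) {
  par <- setNames(seq_along(members), members)
  findp <- function(i) {
    while (par[i] != i) {
      par[i] <<- par[par[i]]
      i <- par[i]
    }
    i
  }
  if (NROW(edges) > 0) {
    keep <- edges[, 1] %in% members & edges[, 2] %in% members
    for (k in which(keep)) {
      ra <- findp(match(edges[k, 1], members))
      rb <- findp(match(edges[k, 2], members))
      if (ra != rb) par[rb] <- ra
    }
  }
  setNames(vapply(seq_along(members), findp, numeric(1)), members)
}

# greedy connectivity repair: while a block is disconnected, add the
# e_maybe edge with the highest observed connectivity joining two components
repair_candidate <- function(cand, inst) {
  vals <- if (!is.null(inst$matrix)) inst$matrix$values else NULL
  em_all <- inst$e_maybe
  for (b in unique(inst$block)) {
    members <- names(inst$block)[inst$block == b]
    if (length(members) < 2) next
    em <- em_all[em_all$block == b, , drop = FALSE]
    repeat {
      sel <- em_all[cand$edge_idx, , drop = FALSE]
      edges <- rbind(cbind(inst$e_yes$u, inst$e_yes$v), cbind(sel$u, sel$v))
      comp <- uf_components(members, edges)
      if (length(unique(comp)) <= 1) break
      joining <- em[comp[em$u] != comp[em$v] &
                      !(em$idx %in% cand$edge_idx), , drop = FALSE]
      if (nrow(joining) == 0) {
        stop("infeasible instance: no connected completion exists for block ", b)
      }
      w <- vals[cbind(joining$u, joining$v)]
      best <- joining$idx[which.max(w)]
      cand <- new_candidate(c(cand$edge_idx, best))
    }
  }
  cand
}

#' Generate the initial GA population
#'
#' Each candidate is grown per block by a preferential-attachment process:
#' core vertices enter in a random order weighted by [avg_connectivity()]
#' (which tracks true degree), and each new vertex attaches 1-2 edges to
#' already placed vertices with probability proportional to their current
#' degree. All dense-region within-edges available in `e_maybe` are added to
#' every candidate, and candidates are repaired to be connected per block.
#'
#' @param inst a [reduce_instance()] result
#' @param dense a `dense_regions` object (or NULL)
#' @param cfg a [ga_config()]
#' @return list of `ga_candidate`
#' @export
init_population <- function(inst, dense = NULL, cfg = ga_config()) {
  em <- inst$e_maybe
  key2idx <- setNames(em$idx, paste(em$u, em$v, sep = "\r"))
  dense_idx <- integer(0)
  if (!is.null(dense) && NROW(dense$region_edges) > 0) {
    dense_idx <- key2idx[edge_keys(dense$region_edges)]
    dense_idx <- as.integer(dense_idx[!is.na(dense_idx)])
  }
  avgcon <- if (!is.null(inst$matrix)) {
    setNames(vapply(inst$core, function(u) avg_connectivity(inst$matrix, u),
                    numeric(1)), inst$core)
  } else {
    setNames(numeric(0), character(0))
  }
  lapply(seq_len(cfg$population_size), function(i) {
    idx <- dense_idx
    for (b in unique(inst$block)) {
      members <- names(inst$block)[inst$block == b]
      if (length(members) < 2) next
      w <- avgcon[members] + 1e-9
      ord <- sample(members, length(members), prob = w)
      deg <- setNames(rep(0L, length(members)), members)
      for (j in 2:length(ord)) {
        placed <- ord[seq_len(j - 1)]
        k <- min(sample(1:2, 1), length(placed))
        targets <- if (length(placed) == 1) placed else {
          sample(placed, k, prob = deg[placed] + 1)
        }
        for (tgt in targets) {
          id <- key2idx[paste(min(ord[j], tgt), max(ord[j], tgt), sep = "\r")]
          if (!is.na(id)) idx <- c(idx, id)
        }
        deg[ord[j]] <- deg[ord[j]] + length(targets)
        deg[targets] <- deg[targets] + 1L
      }
    }
    repair_candidate(new_candidate(idx), inst)
  })
}

#' Evaluate candidate fitness
#'
#' Decodes the candidate, estimates its connectivity matrix
#' (`cfg$fitness_samples` Monte-Carlo draws, or exactly when
#' `fitness_samples = 0`), and counts the core vertex pairs whose
#' connectivity matches the observed matrix within
#' `max(delta_M, sampling_half_width(fitness_samples))`.
#'
#' @param cand a `ga_candidate`
#' @param inst a `reduced_instance`
#' @param cfg a [ga_config()]
#' @return integer fitness (number of matched pairs)
#' @export
evaluate_fitness <- function(cand, inst, cfg = ga_config()) {
  if (cfg$fitness_samples == 0) {
    pg <- decode_candidate(cand, inst)
    P <- exact_connectivity(pg)
    tol <- max(inst$delta, 1e-9)
    obs <- inst$matrix$values[inst$core, inst$core]
    est <- P$values[inst$core, inst$core]
    ut <- upper.tri(obs)
    return(sum(abs(est[ut] - obs[ut]) <= tol))
  }
  # fast Monte-Carlo path: integer-indexed edges straight into the kernel
  fc <- fitness_cache(inst)
  sel <- cand$edge_idx
  edges0 <- rbind(fc$yes_edges0, fc$maybe_edges0[sel, , drop = FALSE])
  probs <- c(fc$yes_probs, rep(inst$p_hat, length(sel)))
  dup <- fc$maybe_meta[sel]
  if (any(!is.na(dup))) { # selected pair doubling a meta-edge: parallel-compose
    for (k in which(!is.na(dup))) {
      probs[dup[k]] <- parallel_prob(probs[dup[k]], inst$p_hat)
    }
    keep <- c(rep(TRUE, nrow(fc$yes_edges0)), is.na(dup))
    edges0 <- edges0[keep, , drop = FALSE]
    probs <- probs[keep]
  }
  counts <- mc_connectivity_counts(length(inst$core), edges0, probs,
                                   cfg$fitness_samples)
  tol <- max(inst$delta, sampling_half_width(cfg$fitness_samples, 0.95))
  est <- counts[fc$ut] / cfg$fitness_samples
  sum(abs(est - fc$obs_ut) <= tol)
}

# memoized integer-indexed views of the instance used by the fast fitness path
fitness_cache <- function(inst) {
  cache <- attr(inst, "fitness_cache", exact = TRUE)
  if (!is.null(cache)) return(cache)
  ci <- inst$core_index
  maybe_edges0 <- cbind(ci[inst$e_maybe$u], ci[inst$e_maybe$v]) - 1L
  yes_edges0 <- if (nrow(inst$e_yes) > 0) {
    cbind(ci[inst$e_yes$u], ci[inst$e_yes$v]) - 1L
  } else {
    matrix(integer(0), ncol = 2)
  }
  # for each e_maybe pair, the row of e_yes carrying the same endpoints (NA if none)
  mk <- paste(inst$e_maybe$u, inst$e_maybe$v)
  yk <- if (nrow(inst$e_yes) > 0) paste(inst$e_yes$u, inst$e_yes$v) else character(0)
  obs <- inst$matrix$values[inst$core, inst$core]
  ut <- which(upper.tri(obs))
  cache <- list(maybe_edges0 = maybe_edges0, yes_edges0 = yes_edges0,
                yes_probs = inst$e_yes$prob, maybe_meta = match(mk, yk),
                obs_ut = obs[ut], ut = ut)
  # store in the instance's environmentless list via attribute on the caller's
  # copy is not possible; recompute cost is tiny, but memoize per call chain
  cache
}

#' Sample a sparse balanced cut for crossover
#'
#' Contracts each merged dense super-region to one weighted block (weight =
#' vertex count) and draws a random partition of blocks with both sides as
#' balanced as the block weights allow; no region is ever split. Errors when
#' one block dominates (heaviest block above 60% of the total weight), since
#' no usefully balanced cut exists then.
#'
#' @param inst a `reduced_instance`
#' @param dense a `dense_regions` (or NULL for singleton blocks only)
#' @param max_tries random shuffles attempted to reach 20% balance
#' @return list with `side1`, `side2` (disjoint core vertex sets)
#' @export
sample_sparse_cut <- function(inst, dense = NULL, max_tries = 50) {
  core <- inst$core
  blocks <- list()
  if (!is.null(dense)) {
    for (sr in merge_regions(dense$regions)) {
      sr <- intersect(sr, core)
      if (length(sr) > 0) blocks[[length(blocks) + 1]] <- sr
    }
  }
  covered <- unlist(blocks)
  for (v in setdiff(core, covered)) blocks[[length(blocks) + 1]] <- v
  if (length(blocks) < 2) stop("degenerate cut: fewer than two contracted blocks")
  w <- lengths(blocks)
  total <- sum(w)
  if (max(w) > 0.6 * total) {
    stop("degenerate cut: a single contracted block dominates the core")
  }
  best <- NULL
  best_imb <- Inf
  for (try in seq_len(max_tries)) {
    ord <- sample(seq_along(blocks))
    s1 <- 0; a1 <- logical(length(blocks))
    s2 <- 0
    for (bi in ord) {
      if (s1 <= s2) {
        s1 <- s1 + w[bi]; a1[bi] <- TRUE
      } else {
        s2 <- s2 + w[bi]
      }
    }
    imb <- abs(s1 - s2)
    if (imb < best_imb) {
      best_imb <- imb
      best <- a1
    }
    if (imb <= 0.2 * total) {
      best <- a1
      break
    }
  }
  list(side1 = sort(unlist(blocks[best])), side2 = sort(unlist(blocks[!best])))
}

#' Crossover two candidates at a cut
#'
#' Child 1 inherits parent 1's edges within side 1, parent 2's edges within
#' side 2, and the crossing edges shared by both parents; child 2 takes the
#' complementary combination.
#'
#' @param g1,g2 `ga_candidate` parents
#' @param cut a cut from [sample_sparse_cut()]
#' @param inst a `reduced_instance`
#' @return list of two `ga_candidate` children (unrepaired; repair happens
#'   in [mutate_candidate()])
#' @export
crossover <- function(g1, g2, cut, inst) {
  em <- inst$e_maybe
  in1 <- em$u %in% cut$side1 & em$v %in% cut$side1
  in2 <- em$u %in% cut$side2 & em$v %in% cut$side2
  crossing <- !(in1 | in2)
  e1 <- em$idx %in% g1$edge_idx
  e2 <- em$idx %in% g2$edge_idx
  child1 <- em$idx[(in1 & e1) | (in2 & e2) | (crossing & e1 & e2)]
  child2 <- em$idx[(in2 & e1) | (in1 & e2) | (crossing & e1 & e2)]
  list(new_candidate(child1), new_candidate(child2))
}

#' Mutate a candidate and repair connectivity
#'
#' Each `e_maybe` membership is flipped independently with a probability
#' calibrated so that about `mutation_rate` of the candidate's current edges
#' change, then the decoded graph is greedily repaired to stay connected
#' within every block (adding the unused candidate edge with the highest
#' observed connectivity that joins two components).
#'
#' @param cand a `ga_candidate`
#' @param inst a `reduced_instance`
#' @param cfg a [ga_config()]
#' @return a repaired `ga_candidate`
#' @export
mutate_candidate <- function(cand, inst, cfg = ga_config()) {
  K <- nrow(inst$e_maybe)
  k <- length(cand$edge_idx)
  if (cfg$mutation_rate > 0 && K > 0) {
    # each current edge is deleted with probability mutation_rate; absent
    # pairs are inserted with the matching rate so the expected edge count
    # is preserved and ~mutation_rate of the current edges change
    r <- cfg$mutation_rate
    q_ins <- if (K > k) min(1, r * max(k, 1) / (K - k)) else 0
    u <- runif(K)
    is_edge <- logical(K)
    is_edge[cand$edge_idx] <- TRUE
    flip <- (is_edge & u < r) | (!is_edge & u < q_ins)
    if (any(flip)) {
      sel <- union(setdiff(cand$edge_idx, which(flip)),
                   setdiff(which(flip), cand$edge_idx))
      cand <- new_candidate(sel)
    }
  }
  repair_candidate(cand, inst)
}

#' Select two parents by fitness-above-worst weighting
#'
#' Each parent is drawn independently with probability proportional to
#' `fitness(c) - minFit`, where `minFit` is the worst fitness in the
#' population; when all fitnesses tie, the draw is uniform.
#'
#' @param pop list of evaluated `ga_candidate`
#' @return indices of the two selected parents
#' @export
select_parents <- function(pop) {
  if (length(pop) == 0) stop("empty population")
  fit <- vapply(pop, function(c) c$fitness, numeric(1))
  if (anyNA(fit)) stop("all candidates must be evaluated before selection")
  w <- fit - min(fit)
  if (sum(w) <= 0) w <- rep(1, length(pop))
  c(sample.int(length(pop), 1, prob = w), sample.int(length(pop), 1, prob = w))
}

# Evaluate a population under common random numbers: one seed block, drawn
# when the GA starts, is reused for every candidate of every generation so
# that fitness values are comparable across the whole run (ranking noise is
# correlated and the running best is never an artifact of a lucky draw);
# the ambient RNG stream is preserved.
evaluate_population <- function(pop, inst, cfg, gen_seed = NULL) {
  if (is.null(gen_seed)) gen_seed <- sample.int(.Machine$integer.max, 1)
  state <- get(".Random.seed", envir = globalenv())
  pop <- lapply(pop, function(cand) {
    if (!is.na(cand$fitness)) return(cand)
    set.seed(gen_seed)
    cand$fitness <- evaluate_fitness(cand, inst, cfg)
    cand
  })
  assign(".Random.seed", state, envir = globalenv())
  pop
}

#' Run the cut-based genetic algorithm
#'
#' Generational GA with elitism: parents are selected by
#' [select_parents()], recombined by [crossover()] at a fresh sparse cut,
#' mutated and repaired, and evaluated under common random numbers. The
#' best candidate ever seen is returned together with a per-generation
#' history whose best-fitness column is non-decreasing.
#'
#' @param inst a `reduced_instance`
#' @param dense a `dense_regions` (or NULL)
#' @param cfg a [ga_config()]
#' @return list with `best` (a `ga_candidate`), `best_fitness`, `history`
#'   (data frame: generation, best_fitness, mean_fitness, wall_seconds) and
#'   the final `population`
#' @export
run_ga <- function(inst, dense = NULL, cfg = ga_config()) {
  t0 <- proc.time()[["elapsed"]]
  if (nrow(inst$e_maybe) == 0) {
    cand <- new_candidate(integer(0))
    cand$fitness <- if (length(inst$core) > 1) {
      evaluate_fitness(cand, inst, cfg)
    } else 0
    return(list(best = cand, best_fitness = cand$fitness,
                history = data.frame(generation = integer(0),
                                     best_fitness = numeric(0),
                                     mean_fitness = numeric(0),
                                     wall_seconds = numeric(0)),
                population = list(cand)))
  }
  attr(inst, "fitness_cache") <- fitness_cache(inst)
  crn_seed <- sample.int(.Machine$integer.max, 1)
  pop <- init_population(inst, dense, cfg)
  pop <- evaluate_population(pop, inst, cfg, crn_seed)
  fit <- vapply(pop, function(c) c$fitness, numeric(1))
  sizes <- vapply(pop, function(c) length(c$edge_idx), numeric(1))
  best <- pop[[order(-fit, sizes)[1]]]
  history <- data.frame(generation = 0L, best_fitness = best$fitness,
                        mean_fitness = mean(fit),
                        wall_seconds = proc.time()[["elapsed"]] - t0)
  for (gen in seq_len(cfg$generations)) {
    # elite order and best-ever updates break fitness ties towards fewer
    # edges: among equally well-fitting candidates the sparser explanation
    # is preferred
    ord <- order(-fit, sizes)
    elites <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
    offspring <- list()
    while (length(offspring) < cfg$population_size - length(elites)) {
      pids <- select_parents(pop)
      kids <- tryCatch({
        cut <- sample_sparse_cut(inst, dense)
        crossover(pop[[pids[1]]], pop[[pids[2]]], cut, inst)
      }, error = function(e) {
        if (grepl("infeasible instance", conditionMessage(e))) stop(e)
        list(pop[[pids[1]]], pop[[pids[2]]]) # degenerate cut: clone parents
      })
      for (kid in kids) {
        if (length(offspring) >= cfg$population_size - length(elites)) break
        offspring[[length(offspring) + 1]] <- mutate_candidate(kid, inst, cfg)
      }
    }
    offspring <- evaluate_population(offspring, inst, cfg, crn_seed)
    pop <- c(elites, offspring)
    fit <- vapply(pop, function(c) c$fitness, numeric(1))
    sizes <- vapply(pop, function(c) length(c$edge_idx), numeric(1))
    top <- order(-fit, sizes)[1]
    if (fit[top] > best$fitness ||
        (fit[top] == best$fitness && sizes[top] < length(best$edge_idx))) {
      best <- pop[[top]]
    }
    history <- rbind(history,
                     data.frame(generation = gen, best_fitness = best$fitness,
                                mean_fitness = mean(fit),
                                wall_seconds = proc.time()[["elapsed"]] - t0))
    if (proc.time()[["elapsed"]] - t0 > cfg$time_limit) break
  }
  list(best = best, best_fitness = best$fitness, history = history,
       population = pop)
}

#' Write a GA history log as TSV
#' @param ga result of [run_ga()]
#' @param path output file
#' @export
write_ga_history <- function(ga, path) {
  write.table(ga$history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
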