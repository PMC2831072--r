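test_that("sample_dag respects density, cap, and acyclicity", {
  set.seed(80)
  expect_identical(nrow(dag_edges(sample_dag(6, edge_prob = 0))), 0L)
  full <- sample_dag(3, max_parents = 10L, edge_prob = 1)
  expect_identical(nrow(dag_edges(full)), 3L)
  for (i in 1:200) {
    d <- sample_dag(sample(2:10, 1), max_parents = 3L,
                    edge_prob = runif(1))
    expect_true(bnexpand:::is_acyclic_adj(d$adj))
    expect_true(all(colSums(d$adj) <= 3L))
  }
})

test_that("sampled CPTs are sharpened row-stochastic tables", {
  set.seed(81)
  dag <- sample_dag(5, edge_prob = 0.5)
  for (strength in c(1, 0.9, 1 / 3)) {
    cpts <- sample_cpts(dag, 3L, strength)
    for (nd in dag$nodes) {
      expect_equal(rowSums(cpts[[nd]]), rep(1, nrow(cpts[[nd]])),
                   tolerance = 1e-12)
      expect_true(all(apply(cpts[[nd]], 1, max) >= strength - 1e-12))
      if (strength == 1) {
        expect_true(all(apply(cpts[[nd]], 1, max) == 1))
      }
    }
  }
})

test_that("ancestral sampling follows the model", {
  # deterministic chain: child state is a fixed function of its parent
  chain <- bn_dag(c("a", "b", "c"),
                  data.frame(from = c("a", "b"), to = c("b", "c")))
  perm <- matrix(0, 3, 3); perm[cbind(1:3, c(2, 3, 1))] <- 1  # s -> s+1 mod 3
  cpts <- list(a = matrix(1 / 3, 1, 3), b = perm, c = perm)
  model <- ground_truth_model(chain, 3L, cpts,
                              bnexpand:::default_emissions(c("a", "b", "c"), 3))
  set.seed(82)
  sim <- simulate_expression(model, 200)
  expect_identical(unname(sim$states$states["b", ]),
                   unname((sim$states$states["a", ] + 1L) %% 3L))
  expect_identical(unname(sim$states$states["c", ]),
                   unname((sim$states$states["b", ] + 1L) %% 3L))

  # root frequencies converge to the CPT (3 sigma at m = 1e4)
  set.seed(83)
  root <- bn_dag("r")
  p <- c(0.2, 0.5, 0.3)
  m1 <- ground_truth_model(root, 3L, list(r = matrix(p, 1)),
                           bnexpand:::default_emissions("r", 3))
  big <- simulate_expression(m1, 10000)
  freq <- tabulate(big$states$states["r", ] + 1L, 3) / 10000
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / 10000)))
})

test_that("vanishing emission noise recovers balanced states exactly", {
  # balanced state frequencies, near-zero emission noise: the equal-
  # frequency cuts land exactly between the emission clusters
  set.seed(84)
  em <- list(mean = c(0, 2, 4), sd = rep(1e-9, 3))
  states <- rbind(g1 = sample(rep(0:2, each = 33)),
                  g2 = sample(rep(0:2, each = 33)))
  colnames(states) <- sprintf("s%02d", 1:99)
  vals <- matrix(rnorm(length(states), em$mean[states + 1L],
                       em$sd[states + 1L]),
                 nrow = 2, dimnames = dimnames(states))
  disc <- q3_discretize(vals)
  expect_identical(disc$states, states + 0L)
})

test_that("planted regulators couple targets and leave noise independent", {
  set.seed(85)
  dag <- sample_dag(6, edge_prob = 0.25)
  model <- ground_truth_model(dag, 3L, sample_cpts(dag, 3L, 0.9),
                              bnexpand:::default_emissions(dag$nodes, 3L))
  pl0 <- plant_regulator(model, n_targets = 2L, n_noise_candidates = 0L)
  expect_identical(pl0$candidates, "hreg")
  pl <- plant_regulator(model, n_targets = 2L, n_noise_candidates = 4L)
  expect_length(dag_children(pl$model$dag, "hreg"), 2L)
  expect_identical(pl$core_dag$nodes, dag$nodes)

  # chi-squared independence sanity check at m = 1e4, alpha = 0.01
  sim <- simulate_expression(pl$model, 10000)
  rejections <- 0L; tests <- 0L
  for (nz in grep("^noise", pl$candidates, value = TRUE)) {
    for (cg in dag$nodes) {
      tab <- table(sim$states$states[nz, ], sim$states$states[cg, ])
      if (any(dim(tab) < 2)) next
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      tests <- tests + 1L
      if (p < 0.01) rejections <- rejections + 1L
    }
  }
  expect_lte(rejections, max(3L, ceiling(0.05 * tests)))
})

test_that("planted metadata behaves at both effect extremes", {
  set.seed(86)
  d <- rand_discrete(2, 60, genes = c("A", "B"))
  meta <- make_metadata(d, "A", "B", term = "biofilm",
                        target_bin = c(2L, 2L), hit_rate = 1,
                        background_rate = 0)
  bins <- assign_bins(d, "A", "B")
  has <- grepl("\\bbiofilm\\b", meta$description)
  expect_identical(has, bins$state_a == 2L & bins$state_b == 2L)
  expect_true(all(nzchar(meta$description)))

  # null: equal rates give no planted signal
  ps <- replicate(60, {
    meta0 <- make_metadata(d, "A", "B", term = "biofilm",
                           target_bin = c(2L, 2L), hit_rate = 0.3,
                           background_rate = 0.3)
    idx <- tokenize_metadata(meta0)
    ht <- vapply(idx$per_sample, function(s) "biofilm" %in% s, logical(1))
    inb <- bins$state_a == 2L & bins$state_b == 2L
    fisher_pvalue(sum(inb & ht), sum(inb & !ht),
                  sum(!inb & ht), sum(!inb & !ht))$p_one_sided
  })
  expect_gte(median(ps), 0.1)
})

test_that("generation is fully deterministic under a fixed seed", {
  gen <- function() {
    set.seed(87)
    dag <- sample_dag(7, edge_prob = 0.3)
    model <- ground_truth_model(dag, 3L, sample_cpts(dag, 3L, 0.9),
                                bnexpand:::default_emissions(dag$nodes, 3L))
    pl <- plant_regulator(model, 2L, 5L)
    sim <- simulate_expression(pl$model, 50)
    meta <- make_metadata(sim$states, dag$nodes[1], dag$nodes[2])
    list(sim, meta, pl$candidates)
  }
  expect_identical(gen(), gen())
})

test_that("structure is recoverable end-to-end from simulated data", {
  # 8-node ground truth (strength 0.9, m = 500): mean skeleton F1 of the
  # best searched network over 20 seeds must reach 0.8 at a 2e5 budget
  f1 <- vapply(1:20, function(seed) {
    set.seed(seed)
    dag <- sample_dag(8, edge_prob = 0.25)
    model <- ground_truth_model(dag, 3L, sample_cpts(dag, 3L, 0.9),
                                bnexpand:::default_emissions(dag$nodes, 3L))
    sim <- simulate_expression(model, 500)
    pool <- multi_restart_search(sim$states, config = search_config(
      networks_per_run = 50000, restarts = 4, rng_seed = seed))
    skeleton_f1(pool$networks[[1]]$dag, dag)
  }, numeric(1))
  expect_gte(mean(f1), 0.8)
})
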