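# 4-sample fixture behind the worked closed forms:
#   A = [0,0,1,1], B = [0,0,1,0], arity 2
ab_data <- function() {
  discrete_matrix(matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), sprintf("s%d", 1:4))),
                  arity = 2)
}

test_that("family_counts tallies in mixed-radix parent order", {
  d <- discrete_matrix(matrix(c(0L, 0L, 1L, 2L, 2L, 2L), 1,
                              dimnames = list("g", sprintf("s%d", 1:6))), 3)
  fc <- family_counts(d, "g")
  expect_identical(fc$q_i, 1L)
  expect_identical(unname(fc$n_ijk[1, ]), c(2L, 1L, 3L))
  expect_identical(unname(fc$n_ij), 6L)

  fc2 <- family_counts(ab_data(), "B", "A")
  expect_identical(fc2$q_i, 2L)
  expect_identical(unname(fc2$n_ijk[1, ]), c(2L, 0L))  # A = 0
  expect_identical(unname(fc2$n_ijk[2, ]), c(1L, 1L))  # A = 1
  expect_identical(as.integer(rowSums(fc2$n_ijk)), unname(fc2$n_ij))
  expect_identical(sum(fc2$n_ij), 4L)

  # two parents: configuration index is (first sorted parent) * r + second
  d3 <- discrete_matrix(matrix(c(1L, 0L, 0L, 1L, 1L, 0L), 3,
                               dimnames = list(c("c", "a", "b"),
                                               c("s1", "s2"))), 2)
  fc3 <- family_counts(d3, "c", c("b", "a"))
  expect_identical(fc3$parents, c("a", "b"))
  expect_identical(fc3$q_i, 4L)
  # s1: a=0,b=0 -> config 0, child 1; s2: a=1,b=0 -> config 2, child 1
  expect_identical(unname(fc3$n_ijk[1, ]), c(0L, 1L))
  expect_identical(unname(fc3$n_ijk[3, ]), c(0L, 1L))
  expect_identical(unname(fc3$n_ij), c(1L, 0L, 1L, 0L))

  # zero samples: all counts zero, invariants hold
  d0 <- discrete_matrix(matrix(integer(0), 2, 0,
                               dimnames = list(c("A", "B"), character(0))), 3)
  fc0 <- family_counts(d0, "A", "B")
  expect_true(all(fc0$n_ijk == 0L))
  expect_identical(sum(fc0$n_ij), 0L)

  expect_error(family_counts(d, "nope"), "nope")
  expect_error(family_counts(ab_data(), "A", "A"), "own parent")
})

test_that("worked closed-form scores are reproduced exactly", {
  one_obs <- discrete_matrix(matrix(0L, 1, 1, dimnames = list("g", "s1")), 3)
  expect_equal(log_family_score(family_counts(one_obs, "g")), log(1 / 3),
               tolerance = 1e-9)

  none <- discrete_matrix(matrix(integer(0), 1, 0,
                                 dimnames = list("g", character(0))), 2)
  expect_identical(log_family_score(family_counts(none, "g")), 0)

  d <- ab_data()
  expect_equal(log_family_score(family_counts(d, "A")), log(1 / 30),
               tolerance = 1e-9)
  ab <- bn_dag(c("A", "B"), data.frame(from = "A", to = "B"))
  sn <- log_network_score(ab, d)
  expect_equal(sn$log_score, -log(540), tolerance = 1e-9)
  expect_equal(unname(sn$per_family["B"]), log(1 / 3) + log(1 / 6),
               tolerance = 1e-9)
  expect_equal(log_network_score(bn_dag(c("A", "B")), d)$log_score,
               -log(600), tolerance = 1e-9)

  # zero-sample data scores zero for any dag
  d0 <- discrete_matrix(matrix(integer(0), 2, 0,
                               dimnames = list(c("A", "B"), character(0))), 3)
  expect_identical(log_network_score(ab, d0)$log_score, 0)
})

test_that("log_network_score matches the factorial oracle on random instances", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(1:4, 1); m <- sample(1:8, 1); r <- sample(2:3, 1)
    d <- rand_discrete(n, m, r)
    dags <- all_dags(d$gene_ids)
    adj <- dags[[sample.int(length(dags), 1)]]
    dag <- bn_dag(d$gene_ids,
                  {e <- which(adj, arr.ind = TRUE)
                   if (nrow(e)) data.frame(from = d$gene_ids[e[, 1]],
                                           to = d$gene_ids[e[, 2]]) else NULL})
    expect_equal(log_network_score(dag, d)$log_score,
                 oracle_network_score(adj, d$states, r), tolerance = 1e-9)
  }
})

test_that("score is decomposable and caching is consistent", {
  set.seed(21)
  d <- rand_discrete(5, 30)
  dag <- random_dag(d$gene_ids, 0.4)
  cache <- new.env()
  full <- log_network_score(dag, d, cache = cache)
  expect_true(full$log_score <= 0)
  expect_equal(sum(full$per_family), full$log_score, tolerance = 1e-9)

  # edit one node's parent set: only that family term changes
  nd <- d$gene_ids[5]
  adj2 <- dag$adj; adj2[, nd] <- FALSE
  dag2 <- structure(list(nodes = dag$nodes, adj = adj2), class = "bn_dag")
  full2 <- log_network_score(dag2, d, cache = cache)
  others <- setdiff(d$gene_ids, nd)
  expect_equal(full2$per_family[others], full$per_family[others],
               tolerance = 1e-12)
  # incremental rescoring equals full rescoring
  inc <- full$log_score - full$per_family[nd] + full2$per_family[nd]
  expect_equal(unname(inc), full2$log_score, tolerance = 1e-9)
})

test_that("compiled family scorer agrees with the R scorer", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(5:40, 1)
    d <- rand_discrete(n, m)
    child <- sample(n, 1)
    parents <- sample(setdiff(seq_len(n), child),
                      sample(0:min(3, n - 1), 1))
    r_score <- log_family_score(
      family_counts(d, d$gene_ids[child], d$gene_ids[parents]))
    c_score <- bnexpand:::cpp_family_score(d$states, rep(3L, n),
                                           child - 1L, parents - 1L)
    expect_equal(c_score, r_score, tolerance = 1e-9)
  }
})

test_that("a copied parent outranks an independent random parent", {
  set.seed(23)
  wins <- 0L
  for (i in 1:50) {
    m <- 30
    child <- sample(0:2, m, replace = TRUE)
    st <- rbind(child = child, copy = child,
                rand = sample(0:2, m, replace = TRUE))
    dimnames(st) <- list(c("child", "copy", "rand"), sprintf("s%d", 1:m))
    d <- discrete_matrix(st, 3)
    s_copy <- log_family_score(family_counts(d, "child", "copy"))
    s_rand <- log_family_score(family_counts(d, "child", "rand"))
    if (s_copy >= s_rand) wins <- wins + 1L
  }
  expect_gt(wins, 25L)
})

test_that("structural errors are rejected", {
  expect_error(bn_dag(c("A", "B"),
                      data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
  expect_error(bn_dag(c("A", "B"), data.frame(from = "A", to = "A")),
               "self-loop")
  d <- ab_data()
  expect_error(log_network_score(bn_dag(c("A", "Z")), d), "Z")
})
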