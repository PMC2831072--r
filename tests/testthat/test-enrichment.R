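test_that("tokenization lowercases, splits, and filters", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     title = c("Biofilm, time course T4", "", "biofilm biofilm"),
                     description = c("", "", ""),
                     stringsAsFactors = FALSE)
  idx <- tokenize_metadata(meta)
  expect_setequal(idx$per_sample$s1, c("biofilm", "time", "course", "t4"))
  expect_identical(idx$per_sample$s2, character(0))
  expect_identical(idx$per_sample$s3, "biofilm")  # set semantics
  expect_identical(idx$vocabulary$n_samples[idx$vocabulary$term == "biofilm"],
                   2L)
  # length-1 and purely numeric tokens are dropped
  meta2 <- data.frame(sample_id = "s1", title = "a 123 pH7 42",
                      description = "x", stringsAsFactors = FALSE)
  expect_identical(tokenize_metadata(meta2)$per_sample$s1, "ph7")
})

test_that("bin assignment labels every sample exactly once", {
  set.seed(70)
  d <- rand_discrete(3, 50, genes = c("uspE", "gadX", "other"))
  bins <- assign_bins(d, "uspE", "gadX")
  expect_identical(nrow(bins), 50L)
  expect_identical(bins$state_a, unname(d$states["uspE", ]))
  expect_identical(bins$joint,
                   paste(d$states["uspE", ], d$states["gadX", ], sep = ","))
  expect_identical(sum(table(bins$joint)), 50L)
  expect_error(assign_bins(d, "uspE", "nope"), "nope")
})

test_that("fisher_pvalue reproduces exact fractions and symmetries", {
  # full enumeration over the 7 tables with margins of (5,1,1,5)
  p <- fisher_pvalue(5, 1, 1, 5)
  expect_equal(p$p_one_sided, 37 / 924, tolerance = 1e-12)
  expect_equal(p$p_two_sided, 74 / 924, tolerance = 1e-12)

  # degenerate margin
  expect_equal(fisher_pvalue(0, 0, 3, 5)$p_two_sided, 1)
  # symmetry under simultaneous row and column swap
  for (tb in list(c(3, 1, 2, 6), c(0, 4, 7, 2), c(5, 5, 5, 5))) {
    p1 <- fisher_pvalue(tb[1], tb[2], tb[3], tb[4])
    p2 <- fisher_pvalue(tb[4], tb[3], tb[2], tb[1])
    expect_equal(p1$p_two_sided, p2$p_two_sided, tolerance = 1e-12)
  }
  expect_error(fisher_pvalue(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_pvalue(0, 0, 0, 0), "positive")
})

test_that("fisher_pvalue matches enumeration oracle and stats::fisher.test", {
  set.seed(71)
  for (i in 1:300) {
    tot <- sample(1:60, 1)
    cnt <- as.vector(stats::rmultinom(1, tot, runif(4)))
    mine <- fisher_pvalue(cnt[1], cnt[2], cnt[3], cnt[4])
    orac <- oracle_fisher(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(orac$total, 1, tolerance = 1e-12)  # oracle self-check
    expect_equal(mine$p_two_sided, orac$p_two_sided, tolerance = 1e-12)
    expect_equal(mine$p_one_sided, orac$p_one_sided, tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(cnt, 2, byrow = TRUE))
    expect_equal(mine$p_two_sided, ft$p.value, tolerance = 1e-9)
  }
})

test_that("enrich_gene_pair finds a planted term and handles degenerate terms", {
  # 10 samples in joint cell (2,2) carry the term; 2 of the other 90 do
  sa <- c(rep(2L, 10), rep(0:2, 30))
  sb <- c(rep(2L, 10), rep(c(0L, 1L, 0L, 2L, 1L, 0L), 15))
  sb[-(1:10)][sa[-(1:10)] == 2 & sb[-(1:10)] == 2] <- 1L  # background avoids (2,2)
  st <- rbind(A = sa, B = sb)
  colnames(st) <- sprintf("s%03d", seq_along(sa))
  d <- discrete_matrix(st, 3)
  term_in <- c(rep(TRUE, 10), rep(FALSE, 88), TRUE, TRUE)
  meta <- data.frame(sample_id = colnames(st),
                     title = "chip",
                     description = ifelse(term_in, "biofilm growth", "growth"),
                     stringsAsFactors = FALSE)
  out <- enrich_gene_pair(d, meta, "A", "B", min_term_count = 3)
  expect_identical(out$term[1], "biofilm")
  expect_identical(out$bin[1], "(2,2)")
  a <- out$a[1]; b <- out$b[1]; cc <- out$c[1]; dd <- out$d[1]
  expect_identical(c(a, b), c(10L, 0L))
  expect_lt(out$p_one_sided[1], 1e-8)
  expect_equal(out$p_one_sided[1],
               oracle_fisher(a, b, cc, dd)$p_one_sided, tolerance = 1e-12)

  # a term present in every sample is never enriched anywhere
  expect_true(all(out$p_two_sided[out$term == "growth"] == 1))
  # impossible minimum count -> empty output
  expect_identical(nrow(enrich_gene_pair(d, meta, "A", "B",
                                         min_term_count = 1000L)), 0L)
})

test_that("uncovered samples are excluded with a warning", {
  set.seed(72)
  d <- rand_discrete(2, 10, genes = c("A", "B"))
  meta <- data.frame(sample_id = d$sample_ids[1:8], title = "x growth",
                     description = "medium", stringsAsFactors = FALSE)
  expect_warning(out <- enrich_gene_pair(d, meta, "A", "B", 1), "2 samples")
  expect_true(all(out$a + out$b + out$c + out$d == 8L))
})
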