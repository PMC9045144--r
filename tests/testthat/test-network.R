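test_that("kendall_tau matches hand values, the pair-counting oracle and cor.test", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4))$tau, (5 - 1) / 6,
               tolerance = 1e-12)

  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(3:8, 1)
      x <- sample(1:5, n, replace = TRUE)   # ties likely
      y <- rnorm(n)
      res <- kendall_tau(x, y)
      expect_equal(res$tau, brute_kendall(x, y), tolerance = 1e-12)
    }
  })

  # exact p equals cor.test's exact enumeration when there are no ties
  withr::with_seed(101, {
    for (rep in 1:10) {
      x <- rnorm(8); y <- rnorm(8)
      mine <- kendall_tau(x, y)
      ref <- cor.test(x, y, method = "kendall")
      expect_equal(mine$method, "exact")
      expect_equal(mine$tau, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  })

  # large-n approximation matches cor.test's continuity-corrected z test
  withr::with_seed(103, {
    for (rep in 1:10) {
      x <- sample(1:10, 30, replace = TRUE)
      y <- rnorm(30)
      mine <- kendall_tau(x, y)
      ref <- suppressWarnings(
        cor.test(x, y, method = "kendall", continuity = TRUE))
      expect_equal(mine$tau, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  })

  expect_true(is.na(kendall_tau(rep(1, 5), rnorm(5))$tau))
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("the all-pairs kendall engine agrees with stats::cor and the scalar path", {
  m <- withr::with_seed(7, {
    x <- matrix(rnorm(25 * 6), 25, 6)
    x[, 2] <- round(x[, 2])                  # introduce ties
    x
  })
  res <- cstnet:::kendall_all(m)
  expect_equal(res$tau, cor(m, method = "kendall"),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (j in 1:5) for (k in (j + 1):6) {
    expect_equal(res$p[j, k], kendall_tau(m[, j], m[, k])$p, tolerance = 1e-12)
  }
})

test_that("planted monotone coupling yields a positive edge; nulls yield none", {
  recovered <- vapply(1:10, function(s) {
    tbl <- withr::with_seed(1200 + s, {
      x <- runif(50, 0.1, 1)
      y <- x + rnorm(50, sd = 0.01)
      noise <- matrix(runif(50 * 8), 50)
      m <- cbind(x, y, noise)
      abund_tbl(m / rowSums(m))
    })
    net <- build_network(tbl, min_prevalence = 0.2, alpha = 0.05)
    any(net$edges$taxon_a == "sp01" & net$edges$taxon_b == "sp02" &
          net$edges$sign == "positive")
  }, logical(1))
  expect_true(all(recovered))

  empty <- vapply(1:50, function(s) {
    tbl <- generate_null_cohort(50, 40, seed = 2200 + s)
    nrow(build_network(tbl, alpha = 0.05, correction = "bh")$edges) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("the prevalence filter excludes sparse taxa", {
  m <- withr::with_seed(15, {
    x <- matrix(runif(12 * 4) + 0.1, 12)
    x[1, 4] <- 0                             # one zero in species 4
    x / rowSums(x)
  })
  net <- build_network(abund_tbl(m), min_prevalence = 1.0)
  expect_false("sp04" %in% net$nodes$species)
  expect_equal(nrow(net$nodes), 3)
  expect_error(build_network(abund_tbl(m[1:5, ])), "at least 10")
})

test_that("BH edge sets shrink monotonically as alpha decreases", {
  tbl <- generate_cohort(cohort_config(n_samples = 60, n_species = 40,
                                       seed = 5))$abundance
  nets <- lapply(c(0.1, 0.05, 0.01), function(a) {
    build_network(tbl, alpha = a)$edges
  })
  key <- function(e) paste(e$taxon_a, e$taxon_b)
  expect_true(all(key(nets[[2]]) %in% key(nets[[1]])))
  expect_true(all(key(nets[[3]]) %in% key(nets[[2]])))
})

test_that("network construction is equivariant to sample order", {
  tbl <- generate_cohort(cohort_config(n_samples = 40, n_species = 25,
                                       seed = 9))$abundance
  net1 <- build_network(tbl)
  perm <- withr::with_seed(1, sample(nrow(tbl)))
  net2 <- build_network(tbl[perm, ])
  e1 <- dplyr::arrange(net1$edges, taxon_a, taxon_b)
  e2 <- dplyr::arrange(net2$edges, taxon_a, taxon_b)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("edge signs follow tau and the invariants of a built network hold", {
  sim <- generate_cohort(cohort_config(n_samples = 80, n_species = 30, seed = 3))
  net <- build_network(sim$abundance)
  expect_true(all((net$edges$tau > 0) == (net$edges$sign == "positive")))
  expect_true(all(net$edges$q <= net$alpha))
  expect_false(any(net$edges$taxon_a == net$edges$taxon_b))
  expect_equal(anyDuplicated(paste(net$edges$taxon_a, net$edges$taxon_b)), 0L)
  # degree bookkeeping matches the edge list
  deg <- table(factor(c(net$edges$taxon_a, net$edges$taxon_b),
                      levels = net$nodes$species))
  expect_equal(net$nodes$degree, as.integer(deg))
})

test_that("network summaries count edges and signs", {
  net <- make_network(edge_tbl(c("a", "a", "b"), c("b", "c", "c"),
                               tau = c(0.5, 0.4, -0.3)))
  s <- network_summary(net)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$pct_positive, 100 * 2 / 3, tolerance = 1e-10)

  empty <- make_network(edge_tbl(character(0), character(0), numeric(0)),
                        species = c("a", "b"))
  se <- network_summary(empty, top_n = 2)
  expect_equal(se$n_edges, 0L)
  expect_equal(se$pct_positive, 0)
})

test_that("modularity detection reproduces closed-form and planted partitions", {
  tri2 <- make_network(edge_tbl(
    c("a", "a", "b", "x", "x", "y"),
    c("b", "c", "c", "y", "z", "z"),
    tau = rep(0.5, 6)))
  res <- modularity_clusters(tri2, seed = 1)
  expect_equal(res$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$nodes$module)), 2L)

  cmpl <- t(combn(letters[1:5], 2))
  full <- make_network(edge_tbl(cmpl[, 1], cmpl[, 2], tau = rep(0.4, 10)))
  resf <- modularity_clusters(full)
  expect_equal(length(unique(resf$nodes$module)), 1L)

  lonely <- make_network(edge_tbl(character(0), character(0), numeric(0)),
                         species = c("a", "b", "c"))
  resl <- modularity_clusters(lonely)
  expect_equal(resl$modularity, 0)
  expect_equal(length(unique(resl$nodes$module)), 3L)

  # planted two-block graphs are split correctly across seeds
  for (s in 1:5) {
    edges <- withr::with_seed(3300 + s, {
      nodes <- sprintf("n%02d", 1:20)
      block <- rep(1:2, each = 10)
      pairs <- t(combn(20, 2))
      prob <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], 0.8, 0.05)
      keep <- runif(nrow(pairs)) < prob
      edge_tbl(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]],
               tau = rep(0.5, sum(keep)))
    })
    net <- make_network(edges, species = sprintf("n%02d", 1:20))
    res <- modularity_clusters(net, seed = s)
    expect_equal(adjusted_rand_index(res$nodes$module, rep(1:2, each = 10)), 1)
  }
})

test_that("keystone ranking uses degree then abundance then name", {
  star <- make_network(edge_tbl(rep("hub", 4), c("l1", "l2", "l3", "l4"),
                                tau = rep(0.5, 4)))
  expect_equal(keystone_taxa(star, 1)$species, "hub")

  tied <- make_network(edge_tbl(c("a", "b"), c("c", "d"), tau = c(0.5, 0.5)),
                       species = c("a", "b", "c", "d"),
                       mean_abundance = c(0.2, 0.1, 0.05, 0.05))
  expect_equal(keystone_taxa(tied, 2)$species, c("a", "b"))
  expect_warning(keystone_taxa(tied, 10), "node count")
})
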