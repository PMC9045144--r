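test_that("duplicated profiles cluster exactly, and extreme cuts behave", {
  base <- withr::with_seed(3, { m <- matrix(rgamma(20, 1), 2); m / rowSums(m) })
  m <- base[rep(1:2, each = 4), ]
  # perturb within duplicates is zero; cross-group distance positive
  tbl <- abund_tbl(m)
  cl <- hcl_cluster(tbl, k = 2)
  expect_equal(cl$cluster, rep(1:2, each = 4))

  tbl3 <- three_mode_cohort(n_per = 3)$table
  singletons <- hcl_cluster(tbl3, k = nrow(tbl3))
  expect_equal(sort(singletons$cluster), 1:9)

  expect_error(hcl_cluster(tbl, k = 1), "between 2")
  expect_error(hcl_cluster(tbl, k = 9), "between 2")
})

test_that("planted three-mode structure is recovered perfectly at k = 3", {
  sim <- three_mode_cohort(n_per = 10, seed = 8)
  cl <- hcl_cluster(sim$table, k = 3)
  expect_equal(adjusted_rand_index(cl$cluster, sim$states), 1)
})

test_that("cluster ids are contiguous and ordered by decreasing size", {
  sim <- three_mode_cohort(n_per = 6, seed = 5)
  # merge two modes unevenly by cutting at k = 2
  cl <- hcl_cluster(sim$table, k = 2)
  sizes <- as.vector(table(cl$cluster))
  expect_equal(sort(unique(cl$cluster)), seq_along(sizes))
  expect_true(all(diff(sizes) <= 0))
})

test_that("mean_silhouette matches hand values and the brute-force oracle", {
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 0.1
  dm[3, 4] <- dm[4, 3] <- 0.1
  labels <- c(1, 1, 2, 2)
  expect_equal(mean_silhouette(as.dist(dm), labels), 0.9, tolerance = 1e-12)

  zero <- matrix(0, 4, 4)
  expect_equal(mean_silhouette(as.dist(zero), labels), 0)

  expect_error(mean_silhouette(as.dist(dm), rep(1, 4)), "2 clusters")

  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      dmat <- as.matrix(dist(matrix(rnorm(n * 3), n)))
      labs <- sample(1:3, n, replace = TRUE)
      if (length(unique(labs)) < 2) next
      expect_equal(mean_silhouette(as.dist(dmat), labs),
                   brute_silhouette(dmat, labs), tolerance = 1e-12)
      # cluster::silhouette as an independent packaged reference
      if (all(table(labs) > 1)) {
        ref <- mean(cluster::silhouette(labs, dmatrix = dmat)[, "sil_width"])
        expect_equal(mean_silhouette(as.dist(dmat), labs), ref,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("random labels on structure-free data give near-zero silhouette", {
  sils <- vapply(1:30, function(s) {
    tbl <- generate_null_cohort(20, 40, seed = 300 + s)
    d <- distance_matrix(tbl, "pearson")
    labs <- withr::with_seed(500 + s, sample(1:2, 20, replace = TRUE))
    if (length(unique(labs)) < 2) return(NA_real_)
    mean_silhouette(d, labs)
  }, numeric(1))
  expect_lt(max(abs(sils), na.rm = TRUE), 0.1)
})

test_that("select_k picks the planted mode count and is internally consistent", {
  sim <- three_mode_cohort(n_per = 10, seed = 4)
  res <- select_k(sim$table, k_range = 2:8)
  expect_equal(res$k, 3L)
  expect_equal(adjusted_rand_index(res$labels$cluster, sim$states), 1)

  # silhouette trace must equal the scalar recomputation on the same cuts
  d <- distance_matrix(sim$table, "pearson")
  tree <- hclust(d, method = "average")
  for (i in seq_len(nrow(res$silhouette_by_k))) {
    k <- res$silhouette_by_k$k[i]
    expect_equal(res$silhouette_by_k$mean_silhouette[i],
                 mean_silhouette(d, cutree(tree, k = k)), tolerance = 1e-12)
  }

  base <- withr::with_seed(3, { m <- matrix(rgamma(20, 1), 2); m / rowSums(m) })
  dup <- abund_tbl(base[rep(1:2, each = 10), ])
  expect_equal(select_k(dup, k_range = 2:5)$k, 2L)

  expect_error(select_k(sim$table, k_range = integer(0)), "k_range")
  expect_error(select_k(sim$table, k_range = 1:3), "k_range")
})

test_that("dendrogram cuts are nested partitions", {
  sim <- three_mode_cohort(n_per = 7, seed = 19)
  d <- distance_matrix(sim$table, "pearson")
  tree <- hclust(d, method = "average")
  for (k in 2:6) {
    a <- cutree(tree, k = k)
    b <- cutree(tree, k = k + 1)
    # refinement: samples together at k+1 are together at k
    for (cl in unique(b)) {
      expect_equal(length(unique(a[b == cl])), 1L)
    }
  }
})

test_that("HPC flagging follows the inclusive 15% threshold arithmetic", {
  sizes <- c(70, 55, 40, 20, 12, 10)
  labels <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:207),
    cluster = rep(seq_along(sizes), sizes)
  )
  res <- identify_hpcs(labels, min_prevalence = 0.15)
  expect_equal(sort(res$hpc_ids), 1:3)
  expect_equal(res$collective_coverage, 165 / 207, tolerance = 1e-12)

  single <- tibble::tibble(sample_id = sprintf("s%02d", 1:20), cluster = 1:20)
  expect_length(identify_hpcs(single)$hpc_ids, 0)

  all_one <- tibble::tibble(sample_id = sprintf("s%02d", 1:10), cluster = 1)
  res1 <- identify_hpcs(all_one)
  expect_equal(res1$hpc_ids, 1)
  expect_equal(res1$collective_coverage, 1)

  expect_equal(sum(res$hpc$prevalence), 1, tolerance = 1e-12)
})

test_that("group composition fractions are per-cluster proportions", {
  labels <- tibble::tibble(sample_id = sprintf("s%02d", 1:14),
                           cluster = rep(1:2, c(10, 4)))
  md <- tibble::tibble(
    sample_id = labels$sample_id,
    group = c(rep(c("athlete", "non_athlete"), 5), rep("athlete", 4))
  )
  res <- group_composition(labels, md)
  comp <- res$group_composition
  expect_equal(comp$fraction[comp$cluster == 1 & comp$group == "athlete"], 0.5)
  expect_equal(comp$fraction[comp$cluster == 2 & comp$group == "athlete"], 1)
  sums <- tapply(comp$fraction, comp$cluster, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(group_composition(labels, md[-1, ]), "without metadata")
})

test_that("planted group-state association is recovered within 0.1 at n = 207", {
  sim <- generate_cohort(cohort_config(seed = 99))
  res <- select_k(sim$abundance, k_range = 2:6) |>
    group_composition(sim$metadata)
  # map clusters to planted states by majority vote
  states <- sim$truth$states$state
  comp <- res$group_composition
  cfg <- sim$truth$config
  for (cl in unique(res$labels$cluster)) {
    state <- as.integer(names(which.max(table(states[res$labels$cluster == cl]))))
    ath <- comp$fraction[comp$cluster == cl & comp$group == "athlete"]
    if (length(ath) == 0) ath <- 0
    expect_lt(abs(ath - cfg$group_assoc[state]), 0.1)
  }
})
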