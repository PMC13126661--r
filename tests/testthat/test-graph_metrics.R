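test_that("clustering coefficient matches analytic limits", {
  # equal-weight triangle: CC = 1 everywhere
  tri <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3)
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))

  # 3-node path: no triangles
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(unname(clustering_coefficient(path3)), rep(0, 3))

  expect_warning(cc0 <- clustering_coefficient(matrix(0, 4, 4)), "all-zero")
  expect_equal(unname(cc0), rep(0, 4))
})

test_that("clustering coefficient matches the triangle-enumeration oracle", {
  withr::with_seed(11, {
    for (r in 1:60) {
      W <- random_graph(sample(4:12, 1), density = stats::runif(1, 0.3, 0.9))
      if (max(W) == 0) next
      expect_equal(unname(clustering_coefficient(W)), oracle_cc(W),
                   tolerance = 1e-12)
    }
  })
})

test_that("eigenvector centrality matches symmetry limits and the dense eigensolver", {
  # complete equal-weight graph: all entries 1/sqrt(n)
  n <- 6
  K <- matrix(1, n, n); diag(K) <- 0
  expect_equal(unname(eigenvector_centrality(K)), rep(1 / sqrt(n), n),
               tolerance = 1e-10)

  # 5-node star: centre strictly dominates leaves
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- c(1, 1.2, 0.8, 1.1)
  ec <- eigenvector_centrality(S)
  expect_true(all(ec[1] > ec[2:5]))

  withr::with_seed(12, {
    for (r in 1:60) {
      W <- random_graph_nondeg(sample(5:12, 1), density = stats::runif(1, 0.4, 0.9))
      got <- suppressWarnings(eigenvector_centrality(W))
      expect_equal(unname(got), oracle_ec(W), tolerance = 1e-8)
    }
  })
})

test_that("eigenvector centrality warns on disconnected graphs", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 3
  W[3, 4] <- W[4, 3] <- 1
  W[4, 5] <- W[5, 4] <- 1
  W[5, 6] <- W[6, 5] <- 1
  expect_warning(eigenvector_centrality(W), "disconnected")
})

test_that("local assortativity sums to the global weighted assortativity", {
  withr::with_seed(13, {
    for (r in 1:60) {
      W <- random_graph_nondeg(sample(5:12, 1), density = stats::runif(1, 0.4, 0.9))
      la <- local_assortativity(W)
      expect_equal(unname(la), oracle_la(W), tolerance = 1e-10)
      expect_equal(sum(la), oracle_global_assortativity(W), tolerance = 1e-12)
    }
  })
})

test_that("local assortativity handles its analytic cases", {
  # regular equal-weight ring: all strengths equal, LA undefined
  ring <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_error(local_assortativity(ring), "degenerate")

  # two disjoint dyads with very different weights: perfectly assortative
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 10
  la <- local_assortativity(W)
  expect_true(all(la > 0))
  expect_equal(sum(la), 1, tolerance = 1e-12)  # perfect strength correlation
})

test_that("participation coefficient matches closed forms and the module-sum oracle", {
  # all weight inside own module -> 0
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 3
  expect_equal(unname(participation_coefficient(W, c(1, 1, 2, 2))[1]), 0)

  # equal split over M modules -> 1 - 1/M
  M <- 3
  Wq <- matrix(0, 4, 4); Wq[1, 2:4] <- Wq[2:4, 1] <- 2
  expect_equal(unname(participation_coefficient(Wq, c(4, 1, 2, 3))[1]), 1 - 1 / M)

  withr::with_seed(14, {
    for (r in 1:60) {
      n <- sample(6:12, 1)
      W <- random_graph(n, density = 0.6)
      part <- sample(1:3, n, replace = TRUE)
      expect_equal(unname(participation_coefficient(W, part)),
                   oracle_pc(W, part), tolerance = 1e-12)
    }
  })
})

test_that("metrics are invariant to a global rescaling of the weights", {
  withr::with_seed(15, {
    W <- random_graph_nondeg(10, density = 0.6)
    part <- sample(1:3, 10, replace = TRUE)
    for (k in c(0.01, 5, 1e4)) {
      expect_equal(clustering_coefficient(W * k), clustering_coefficient(W),
                   tolerance = 1e-12)
      expect_equal(suppressWarnings(eigenvector_centrality(W * k)),
                   suppressWarnings(eigenvector_centrality(W)), tolerance = 1e-9)
      expect_equal(local_assortativity(W * k), local_assortativity(W),
                   tolerance = 1e-10)
      expect_equal(participation_coefficient(W * k, part),
                   participation_coefficient(W, part), tolerance = 1e-12)
    }
  })
})

test_that("compute_metrics produces a complete, deterministic long table", {
  h <- test_hierarchy()
  cfg <- sim_config(n_per_group = 5, seed = 21)
  cohort <- generate_cohort(cfg, h)
  ms <- purrr::map(cohort$connectomes, build_multiscale,
                   volumes = cohort$volumes, hierarchy = h)
  fm <- compute_metrics(purrr::map(ms, "fine"), h, "fine76")
  expect_equal(nrow(fm), 10 * 76 * 4)
  expect_setequal(unique(fm$metric), c("CC", "EC", "LA", "PC"))
  expect_equal(attr(fm, "scale"), "fine76")
  expect_true(all(fm$value[fm$metric == "CC"] >= 0 &
                    fm$value[fm$metric == "CC"] <= 1))
  pcv <- fm$value[fm$metric == "PC"]
  expect_true(all(pcv >= 0 & pcv <= 1 - 1 / 24 + 1e-12))
  ecn <- fm |>
    dplyr::filter(metric == "EC") |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(l2 = sum(value^2))
  expect_equal(ecn$l2, rep(1, 10), tolerance = 1e-8)

  fm2 <- compute_metrics(purrr::map(ms, "fine"), h, "fine76")
  expect_identical(fm$value, fm2$value)

  cm <- compute_metrics(purrr::map(ms, "coarse"), h, "coarse24")
  expect_equal(nrow(cm), 10 * 24 * 4)
  expect_true(all(cm$value[cm$metric == "PC"] <= 1 - 1 / 4 + 1e-12))

  expect_error(compute_metrics(purrr::map(ms, "coarse"), h, "fine76"),
               "not at scale")
})

test_that("permuting node order permutes metric values identically", {
  h <- test_hierarchy()
  W <- tiny_wholebrain(seed = 22)
  f <- extract_subnetwork(connectome(W, scale = "wholebrain379"), h)
  part <- coarse_partition(h, "groups24")
  perm <- withr::with_seed(23, sample(76))
  Wp <- unclass(f)[perm, perm]

  expect_equal(unname(clustering_coefficient(Wp)),
               unname(clustering_coefficient(f))[perm], tolerance = 1e-12)
  expect_equal(unname(suppressWarnings(eigenvector_centrality(Wp))),
               unname(suppressWarnings(eigenvector_centrality(f)))[perm],
               tolerance = 1e-9)
  expect_equal(unname(local_assortativity(Wp)),
               unname(local_assortativity(f))[perm], tolerance = 1e-10)
  expect_equal(unname(participation_coefficient(Wp, unname(part)[perm])),
               unname(participation_coefficient(f, part))[perm],
               tolerance = 1e-12)
})
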