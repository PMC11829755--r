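# build a feature tibble from a numeric matrix
as_features <- function(X, ids = sprintf("g%03d", seq_len(nrow(X)))) {
  dplyr::bind_cols(tibble::tibble(gene_id = ids),
                   tibble::as_tibble(X, .name_repair = "minimal"))
}

# two well-separated gaussian clouds in 6 dimensions
two_clouds <- function(n_per = 20, sep = 10, seed = 4) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * 6, 0, 0.3), n_per),
             matrix(stats::rnorm(n_per * 6, sep, 0.3), n_per))
  list(X = X, labels = rep(1:2, each = n_per))
}

test_that("trajectory normalization uses the shared max and is scale invariant", {
  t <- seq(0, 2, by = 1)
  traj <- tibble::tibble(
    gene_id = "g1",
    condition = rep(c("UIC", "MO"), each = 3),
    time = rep(t, 2),
    median = c(10, 5, 2, 8, 6, 4))
  f <- normalize_trajectories(traj)
  vals <- as.numeric(f[1, -1])
  expect_equal(max(vals), 1)
  expect_equal(vals, c(10, 5, 2, 8, 6, 4) / 10)
  scaled <- traj; scaled$median <- scaled$median * 100
  expect_equal(normalize_trajectories(scaled), f, ignore_attr = TRUE)
  const <- traj; const$median <- 1
  expect_equal(as.numeric(normalize_trajectories(const)[1, -1]), rep(1, 6))
  zero <- traj; zero$median <- 0
  expect_error(normalize_trajectories(zero), "all-zero")
})

test_that("seeded k-means recovers planted partitions deterministically", {
  cl <- two_clouds()
  feats <- as_features(cl$X)
  fit <- kmeans_cluster(feats, 2, rng_seed = 1618033)
  expect_equal(length(unique(fit$assignment$cluster[cl$labels == 1])), 1)
  expect_equal(length(unique(fit$assignment$cluster[cl$labels == 2])), 1)
  fit2 <- kmeans_cluster(feats, 2, rng_seed = 1618033)
  expect_identical(fit$assignment, fit2$assignment)
  # objective trace non-increasing (asserted internally too)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # k = n gives singletons with zero WCSS
  small <- as_features(cl$X[1:5, ])
  expect_equal(kmeans_cluster(small, 5)$wcss, 0, tolerance = 1e-20)
})

test_that("k-means matches the stats::kmeans objective on separated data", {
  cl <- two_clouds()
  ours <- kmeans_cluster(as_features(cl$X), 2)
  ref <- stats::kmeans(cl$X, 2, nstart = 10)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("mean silhouette matches cluster::silhouette and is bounded", {
  cl <- two_clouds()
  got <- mean_silhouette(cl$X, cl$labels)
  ref <- mean(cluster::silhouette(cl$labels, stats::dist(cl$X))[, 3])
  expect_equal(got, ref, tolerance = 1e-12)
  expect_gt(got, 0.9)  # distant clouds approach 1
  expect_true(got >= -1 && got <= 1)
  # planted partition beats random relabelings
  set.seed(11)
  for (i in 1:20) {
    expect_gte(got, mean_silhouette(cl$X, sample(cl$labels)))
  }
})

test_that("silhouette selection recovers the planted cluster number", {
  set.seed(6)
  centers <- rbind(c(rep(1, 4), rep(0, 8)),
                   c(rep(0, 4), rep(1, 4), rep(0, 4)),
                   c(rep(0, 8), rep(1, 4)))
  X3 <- centers[rep(1:3, each = 25), ] + matrix(stats::rnorm(75 * 12, 0, 0.08), 75)
  sel3 <- silhouette_select_k(as_features(X3), k_range = 2:6)
  expect_equal(sel3$k, 3)
  cl2 <- two_clouds(n_per = 25)
  sel2 <- silhouette_select_k(as_features(cl2$X), k_range = 2:6)
  expect_equal(sel2$k, 2)
  expect_equal(mode_k(c(3, 3, 2, 3)), 3L)
  expect_error(silhouette_select_k(as_features(matrix(1, 12, 3)), 2:10),
               "identical")
})

test_that("cluster naming orders by divergence onset and never mixes directions", {
  t <- seq(0, 9.5, by = 0.5)
  mk_traj <- function(id, onset, dir) {
    uic <- 100 * exp(-t / 4)
    mo <- if (dir == "increased") pmax(uic, ifelse(t >= onset, 60, 0)) else uic * ifelse(t >= onset, 0.2, 1)
    dplyr::bind_rows(
      tibble::tibble(gene_id = id, condition = "UIC", time = t, median = uic),
      tibble::tibble(gene_id = id, condition = "MO", time = t, median = mo))
  }
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    direction = rep(c("increased", "decreased"), each = 15),
    onset = rep(rep(c(1, 5, 8), each = 5), 2))
  traj <- purrr::pmap_dfr(genes, function(gene_id, direction, onset) {
    d <- mk_traj(gene_id, onset, direction)
    d$median <- d$median * exp(stats::rnorm(nrow(d), 0, 0.01))
    d
  })
  out <- cluster_trajectories(traj, genes[, c("gene_id", "direction")], k = 3,
                              rng_seed = 1618033)
  expect_true(all(grepl("^U", out$cluster[out$direction == "increased"])))
  expect_true(all(grepl("^D", out$cluster[out$direction == "decreased"])))
  # earliest-onset genes get label 1
  up <- dplyr::inner_join(out, genes, by = c("gene_id", "direction"))
  expect_true(all(up$cluster[up$onset == 1 & up$direction == "increased"] == "U1"))
  expect_true(all(up$cluster[up$onset == 8 & up$direction == "increased"] == "U3"))
})
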