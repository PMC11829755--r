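#' Max-normalized trajectory features for clustering
#'
#' For each gene, divides the UIC and MO GP median trajectories by the
#' maximum value attained by either condition, then concatenates the two
#' normalized vectors; every gene's feature vector lies in `[0, 1]` with
#' maximum exactly 1, so clustering sees trajectory shape, not expression
#' level.
#'
#' @param trajectories Long tibble from [gp_trajectories()] (`gene_id`,
#'   `condition`, `time`, `median`).
#' @return Tibble: `gene_id`, then `UIC_<t>` and `MO_<t>` feature columns;
#'   the grid is stored in the `"times"` attribute.
#' @export
normalize_trajectories <- function(trajectories) {
  need <- c("gene_id", "condition", "time", "median")
  if (!all(need %in% names(trajectories))) {
    abort("`trajectories` needs columns gene_id, condition, time, median.")
  }
  wide <- trajectories %>%
    dplyr::mutate(sample = paste0(.data$condition, "_", .data$time)) %>%
    dplyr::select("gene_id", "sample", "median") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "median")
  feat_cols <- setdiff(names(wide), "gene_id")
  mat <- as.matrix(wide[, feat_cols])
  mx <- apply(mat, 1, max)
  if (any(mx <= 0)) {
    abort(sprintf("Gene %s has an all-zero trajectory.",
                  wide$gene_id[which(mx <= 0)[1]]))
  }
  out <- dplyr::bind_cols(wide["gene_id"], as_tibble(mat / mx))
  attr(out, "times") <- sort(unique(trajectories$time))
  out
}

feature_matrix <- function(features) {
  m <- as.matrix(features[, setdiff(names(features), "gene_id")])
  rownames(m) <- features$gene_id
  m
}

# k-means++ seeding from the current RNG stream
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = p), ]
    dn <- rowSums((X - matrix(centers[j + 1, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  centers
}

#' Seeded k-means clustering of trajectory features
#'
#' Lloyd's algorithm with k-means++ seeding drawn from a fixed RNG seed
#' (default 1618033), so assignments are fully reproducible. The
#' within-cluster sum of squares is checked to be non-increasing across
#' iterations; an emptied cluster is re-seeded at the point farthest from
#' its centroid and the event is recorded.
#'
#' @param features Feature tibble from [normalize_trajectories()] (or any
#'   tibble with `gene_id` plus numeric columns).
#' @param k Number of clusters (`>= 2`, `<=` number of genes).
#' @param rng_seed Seed for the k-means++ draws.
#' @param max_iter Lloyd iteration cap.
#' @return A `cluster_assignment` list: `assignment` (tibble `gene_id`,
#'   `cluster`), `centers`, `wcss`, `objective_trace`, `k`, `rng_seed`,
#'   `reseeded`.
#' @export
kmeans_cluster <- function(features, k, rng_seed = 1618033, max_iter = 100) {
  X <- feature_matrix(features)
  n <- nrow(X)
  if (k < 1 || k > n) abort("`k` must be between 1 and the number of genes.")
  with_seed(rng_seed, {
    centers <- if (k == 1) matrix(colMeans(X), 1) else kmeanspp_centers(X, k)
    labels <- integer(n)
    trace <- numeric(0)
    reseeded <- 0L
    for (iter in seq_len(max_iter)) {
      d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      new_labels <- max.col(-d2, ties.method = "first")
      obj <- sum(d2[cbind(seq_len(n), new_labels)])
      if (length(trace) && obj > utils::tail(trace, 1) + 1e-8) {
        abort("k-means objective increased; numerical failure.")
      }
      trace <- c(trace, obj)
      for (j in seq_len(k)) {
        idx <- new_labels == j
        if (!any(idx)) {
          far <- which.max(d2[cbind(seq_len(n), new_labels)])
          new_labels[far] <- j
          idx <- new_labels == j
          reseeded <- reseeded + 1L
        }
        centers[j, ] <- colMeans(X[idx, , drop = FALSE])
      }
      if (identical(new_labels, labels)) { labels <- new_labels; break }
      labels <- new_labels
    }
    wcss <- sum((X - centers[labels, , drop = FALSE])^2)
    structure(list(
      assignment = tibble(gene_id = rownames(X), cluster = labels),
      centers = centers, wcss = wcss, objective_trace = trace,
      k = k, rng_seed = rng_seed, reseeded = reseeded
    ), class = "cluster_assignment")
  })
}

#' Mean silhouette width of a clustering
#'
#' Euclidean silhouette: for each point, `(b - a) / max(a, b)` with `a` the
#' mean distance to its own cluster and `b` the smallest mean distance to
#' another cluster; singleton clusters score 0.
#'
#' @param features Feature tibble (or matrix).
#' @param labels Integer cluster labels.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(features, labels) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(X)
  if (length(unique(labels)) < 2) abort("Silhouette needs at least 2 clusters.")
  D <- as.matrix(stats::dist(X))
  ks <- sort(unique(labels))
  sizes <- table(factor(labels, levels = ks))
  # mean distance from every point to every cluster
  md <- vapply(ks, function(j) {
    rowSums(D[, labels == j, drop = FALSE]) / sum(labels == j)
  }, numeric(n))
  s <- vapply(seq_len(n), function(i) {
    j <- match(labels[i], ks)
    nj <- sizes[j]
    if (nj == 1) return(0)
    a <- md[i, j] * nj / (nj - 1)          # exclude self
    b <- min(md[i, -j])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Select the cluster number by maximal mean silhouette
#'
#' Runs seeded k-means for each candidate `k` and scores the partition by
#' mean Euclidean silhouette; the selected `k` is the argmax. When several
#' related runs are analyzed (two library types times two directions), the
#' pipeline reports the mode of the per-run selections.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster numbers (default `2:10`).
#' @return List: `k` (selected), `scores` (tibble `k`, `silhouette`),
#'   `assignments` (list of `cluster_assignment` keyed by `k`).
#' @export
silhouette_select_k <- function(features, k_range = 2:10,
                                rng_seed = 1618033) {
  X <- feature_matrix(features)
  if (nrow(X) < max(k_range) + 1) {
    abort("Need more genes than the largest candidate k.")
  }
  if (all(stats::dist(X) == 0)) abort("All feature vectors are identical.")
  fits <- purrr::map(k_range, function(k) kmeans_cluster(features, k, rng_seed))
  scores <- vapply(fits, function(f) {
    mean_silhouette(X, f$assignment$cluster)
  }, numeric(1))
  best <- which.max(scores)
  list(k = k_range[best],
       scores = tibble(k = k_range, silhouette = scores),
       assignments = stats::setNames(fits, k_range))
}

#' Statistical mode of selected cluster numbers
#'
#' @param ks Integer vector of per-run selected `k` values.
#' @return The most frequent value (smallest on ties).
#' @export
mode_k <- function(ks) {
  tab <- table(ks)
  as.integer(names(tab)[which.max(tab)])
}

# order cluster indices by divergence onset of the cluster mean: the first
# grid position where |MO - UIC| of the mean feature vector exceeds 10% of
# full (normalized) scale; earliest onset gets label 1
order_by_onset <- function(centers, n_time) {
  onsets <- apply(centers, 1, function(ctr) {
    d <- abs(ctr[seq_len(n_time) + n_time] - ctr[seq_len(n_time)])
    hit <- which(d > 0.1)
    if (length(hit)) hit[1] + max(d) * 1e-6 else Inf
  })
  order(onsets)
}

#' Cluster differential genes by trajectory shape, per direction
#'
#' Applies the full clustering stage: splits genes by direction
#' (increased/decreased), max-normalizes the GP medians, selects `k` by
#' silhouette (or uses a fixed `k`), runs seeded k-means, and names the
#' clusters `U1..Uk` / `D1..Dk` ordered by the divergence-onset time of the
#' cluster mean (U1 earliest).
#'
#' @param trajectories Long tibble from [gp_trajectories()].
#' @param de Tibble from [gp_de()] with `gene_id` and `direction`; only
#'   called genes should be passed.
#' @param k Fixed cluster number, or `NULL` to select by silhouette.
#' @param k_range Candidate `k` values when selecting.
#' @param rng_seed Seed for k-means (default 1618033).
#' @return Tibble `gene_id`, `direction`, `cluster`, with per-direction
#'   silhouette tables in the `"silhouette"` attribute and selected `k`s in
#'   `"k"`.
#' @export
cluster_trajectories <- function(trajectories, de, k = NULL, k_range = 2:10,
                                 rng_seed = 1618033) {
  if (!all(c("gene_id", "direction") %in% names(de))) {
    abort("`de` needs columns gene_id and direction.")
  }
  sil_tables <- list(); chosen <- list()
  out <- purrr::map_dfr(c("increased", "decreased"), function(dir) {
    genes <- de$gene_id[de$direction == dir]
    if (!length(genes)) return(tibble())
    feats <- normalize_trajectories(
      trajectories[trajectories$gene_id %in% genes, ])
    n_time <- length(attr(feats, "times"))
    if (is.null(k)) {
      sel <- silhouette_select_k(feats, k_range, rng_seed)
      fit <- sel$assignments[[as.character(sel$k)]]
      sil_tables[[dir]] <<- sel$scores
      chosen[[dir]] <<- sel$k
    } else {
      fit <- kmeans_cluster(feats, k, rng_seed)
      chosen[[dir]] <<- k
    }
    ord <- order_by_onset(fit$centers, n_time)
    prefix <- if (dir == "increased") "U" else "D"
    relabel <- stats::setNames(seq_along(ord), ord)
    fit$assignment %>%
      dplyr::mutate(direction = dir,
                    cluster = paste0(prefix, relabel[as.character(.data$cluster)]))
  })
  attr(out, "silhouette") <- sil_tables
  attr(out, "k") <- chosen
  out
}
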