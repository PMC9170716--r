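# UMAP and community detection are delegated to uwot and igraph; this
# module owns parameters, seeding, graph construction and the
# principal-curve trajectory contract.

#' Embed PCA scores with UMAP
#'
#' @param scores numeric matrix (organoids x components).
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param n_neighbors UMAP neighbourhood size (default 15).
#' @param seed integer seed; coordinates are reproducible under it
#'   (single-threaded optimization).
#' @return object of class `EmbeddingResult`: list with `coordinates`
#'   (rows x 2), `params`, and `cluster_labels` (NULL until
#'   [cluster_graph()] is run).
#' @export
embed_umap <- function(scores, min_dist = 0.1, n_neighbors = 15, seed = 1) {
  scores <- as.matrix(scores)
  if (nrow(scores) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 rows")
  set.seed(seed)
  coords <- uwot::umap(scores, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_threads = 1,
                       n_sgd_threads = 0, verbose = FALSE)
  colnames(coords) <- c("umap_1", "umap_2")
  structure(list(coordinates = coords,
                 params = list(min_dist = min_dist,
                               n_neighbors = n_neighbors, seed = seed),
                 cluster_labels = NULL),
            class = "EmbeddingResult")
}

snn_graph <- function(x, n_neighbors) {
  n <- nrow(x)
  k <- min(n_neighbors, n - 1)
  nn <- FNN::get.knn(x, k = k)$nn.index
  nbr <- lapply(seq_len(n), function(i) sort(c(i, nn[i, ])))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(n)) {
    for (j in nn[i, ]) {          # kNN is asymmetric; keep every pair
      inter <- length(intersect(nbr[[i]], nbr[[j]]))
      jac <- inter / (2 * (k + 1) - inter)
      from <- c(from, min(i, j)); to <- c(to, max(i, j)); w <- c(w, jac)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Graph-based (leiden) clustering of the phenotype landscape
#'
#' Builds a shared-nearest-neighbour graph (Jaccard edge weights over
#' the union of each point's neighbourhood) and partitions it with the
#' leiden algorithm under the constant Potts model, so a very small
#' resolution merges all but well-separated groups.
#'
#' @param x matrix of embedding coordinates or PC scores.
#' @param resolution leiden resolution parameter (default 1e-7, the
#'   landscape-scale setting).
#' @param n_neighbors neighbourhood size for the graph (default 15).
#' @param seed integer seed.
#' @return integer cluster labels `1..K`, one per row.
#' @export
cluster_graph <- function(x, resolution = 1e-7, n_neighbors = 15, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2) return(rep(1L, nrow(x)))
  if (all(apply(x, 2, stats::sd) == 0)) return(rep(1L, nrow(x)))
  set.seed(seed)
  g <- snn_graph(x, n_neighbors)
  cl <- igraph::cluster_leiden(g, objective_function = "CPM",
                               resolution = resolution,
                               weights = igraph::E(g)$weight,
                               n_iterations = 5)
  labs <- igraph::membership(cl)
  as.integer(factor(labs, levels = unique(labs[order(labs)])))
}

# project points onto a polyline; returns arc-length position and squared
# distance to the curve for each point
project_polyline <- function(pts, curve) {
  nseg <- nrow(curve) - 1
  seg_start <- curve[-nrow(curve), , drop = FALSE]
  seg_vec <- curve[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  arc0 <- c(0, cumsum(seg_len))[seq_len(nseg)]
  lambda <- numeric(nrow(pts)); d2 <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    dp <- sweep(seg_start, 2, pts[i, ], "-")
    tt <- pmin(pmax(-rowSums(dp * seg_vec) / pmax(seg_len2, 1e-12), 0), 1)
    px <- seg_start + seg_vec * tt
    dd <- rowSums(sweep(px, 2, pts[i, ], "-")^2)
    j <- which.min(dd)
    lambda[i] <- arc0[j] + tt[j] * seg_len[j]
    d2[i] <- dd[j]
  }
  list(lambda = lambda, d2 = d2)
}

#' Fit a dose-dependent principal-curve trajectory
#'
#' Fits a principal curve through (optionally downsampled) embedding
#' coordinates of one drug's organoids across doses plus its solvent
#' controls, by alternating projection and per-coordinate smoothing
#' (cubic smoothing splines along arc length). Rows in excluded
#' clusters (e.g. a dead-particle cluster) take no part in fitting and
#' carry no position. Pseudotime is arc length measured from the curve
#' end with the higher density of control (DMSO) observations.
#'
#' @param embedding an `EmbeddingResult`.
#' @param rows integer indices into the embedding for this drug's
#'   organoids (all doses) and its DMSO controls.
#' @param dose numeric dose per row (`0` or `NA` for controls).
#' @param is_control logical per row; used to orient the curve.
#' @param exclude_clusters integer cluster labels to exclude (requires
#'   `embedding$cluster_labels`).
#' @param downsample_frac fraction of points used for curve fitting
#'   (default 0.05, capped at `max_points` and floored at 200).
#' @param max_points cap on fitting points (default 10000).
#' @param max_iter,tol iteration controls; convergence when the mean
#'   point-curve distance changes by less than `tol` times the
#'   embedding diameter.
#' @param seed integer seed for downsampling.
#' @return object of class `DoseTrajectory`: list with `curve` (ordered
#'   polyline), `pseudotime` (per input row; NA for excluded rows),
#'   `objective` (per-iteration mean squared projection distance),
#'   `excluded_clusters`.
#' @export
fit_dose_trajectory <- function(embedding, rows, dose = NULL,
                                is_control = NULL,
                                exclude_clusters = integer(0),
                                downsample_frac = 0.05, max_points = 10000,
                                spline_df = 8, max_iter = 30, tol = 1e-4,
                                seed = 1) {
  coords <- embedding$coordinates[rows, , drop = FALSE]
  keep <- rep(TRUE, nrow(coords))
  if (length(exclude_clusters) > 0) {
    if (is.null(embedding$cluster_labels))
      stop("embedding carries no cluster labels")
    keep <- !(embedding$cluster_labels[rows] %in% exclude_clusters)
  }
  if (!any(keep)) stop("all points excluded from trajectory fitting")
  pts <- coords[keep, , drop = FALSE]
  if (!is.null(dose) && length(unique(dose[keep & !is.na(dose) & dose > 0])) < 2 &&
      is.null(is_control))
    stop("need at least 2 dose levels")
  set.seed(seed)
  n_fit <- min(nrow(pts), max_points, max(200, ceiling(downsample_frac * nrow(pts))))
  fit_idx <- sample.int(nrow(pts), n_fit)
  fp <- pts[fit_idx, , drop = FALSE]
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  if (diam < 1e-12) diam <- 1
  # initialize along the first principal axis
  pc1 <- stats::prcomp(fp, rank. = 1)
  lambda <- as.numeric(pc1$x[, 1])
  grid_n <- min(100, max(10, n_fit %/% 2))
  objective <- numeric(0)
  prev_mean_d <- Inf
  curve <- NULL
  for (it in seq_len(max_iter)) {
    ord <- order(lambda)
    lam_s <- lambda[ord]
    # guard against ties for smooth.spline
    lam_s <- lam_s + seq_along(lam_s) * 1e-9 * max(diff(range(lam_s)), 1e-9)
    grid <- seq(min(lam_s), max(lam_s), length.out = grid_n)
    curve <- vapply(seq_len(ncol(fp)), function(j) {
      # degenerate (e.g. exactly collinear) inputs fall back to low df
      ss <- suppressWarnings(
        stats::smooth.spline(lam_s, fp[ord, j],
                             df = min(spline_df, n_fit - 1)))
      stats::predict(ss, grid)$y
    }, numeric(grid_n))
    pr <- project_polyline(fp, curve)
    lambda <- pr$lambda
    mean_d <- mean(sqrt(pr$d2))
    objective <- c(objective, mean(pr$d2))
    if (abs(prev_mean_d - mean_d) < tol * diam) break
    prev_mean_d <- mean_d
  }
  pr_all <- project_polyline(pts, curve)
  pt <- pr_all$lambda
  total_len <- max(pt)
  if (!is.null(is_control)) {
    ctl <- is_control[keep]
    if (any(ctl) && mean(pt[ctl]) > total_len / 2) pt <- total_len - pt
  }
  pseudotime <- rep(NA_real_, length(rows))
  pseudotime[keep] <- pt
  structure(list(curve = curve, pseudotime = pseudotime,
                 objective = objective,
                 excluded_clusters = exclude_clusters),
            class = "DoseTrajectory")
}
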