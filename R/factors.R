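# Multi-view latent factor analysis: assemble the five data views, fit a
# k-factor linear model by alternating least squares, decompose variance,
# project drug-induced phenotypes onto learned factors, and run
# loading-based enrichment / target-association tests.

#' Average DMSO morphology profiles per sample
#' @param scores per-organoid PC score matrix.
#' @param meta aligned metadata with `treatment` and a sample key column.
#' @param sample_col metadata column naming the sample (default
#'   `"batch_id"`, i.e. line x replicate).
#' @return matrix samples x components of mean DMSO profiles.
#' @export
average_dmso_profiles <- function(scores, meta, sample_col = "batch_id") {
  i <- meta$treatment == "DMSO"
  key <- meta[[sample_col]][i]
  m <- apply(scores[i, , drop = FALSE], 2,
             function(v) tapply(v, key, mean))
  as.matrix(m)
}

#' @importFrom mclust Mclust mclustBIC
fit_size_summary <- function(areas) {
  # location of the large component of a 2-component log-normal mixture;
  # falls back to a single log-normal on degenerate fits
  la <- log(areas[is.finite(areas) & areas > 0])
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(
      la, G = 2, modelNames = "V", verbose = FALSE,
      # deterministic initialization (mclust subsamples at random
      # above 2000 observations otherwise)
      initialization = list(subset = seq_len(min(2000L, length(la)))))),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters$mean))
    return(c(size = mean(la), fallback = 1))
  c(size = max(fit$parameters$mean), fallback = 0)
}

scale_view <- function(m) {
  center <- colMeans(m, na.rm = TRUE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  z <- sweep(sweep(m, 2, center), 2, sds, "/")
  total_var <- sum(apply(z, 2, stats::var, na.rm = TRUE))
  view_scale <- sqrt(max(total_var, 1e-12))
  list(x = z / view_scale,
       scaling = list(center = center, scale = sds, view_scale = view_scale))
}

apply_view_scaling <- function(m, scaling) {
  z <- sweep(sweep(m, 2, scaling$center), 2, scaling$scale, "/")
  z / scaling$view_scale
}

#' Assemble the five-view dataset describing unperturbed lines
#'
#' Builds the views used for factor analysis of unperturbed organoid
#' lines: `size` (location of the large component of a two-component
#' log-normal mixture over each sample's DMSO organoid areas),
#' `mutations` (binary somatic-mutation calls, passed through),
#' `expression` (restricted to the top fraction of genes by coefficient
#' of variation, ties broken by gene order), `morphology` (per-sample
#' mean DMSO PC profiles) and `drug_activity` (AUROC matrix restricted
#' to drugs active in at least one sample). Each view is feature-wise
#' z-scored then scaled to unit total variance; scaling state is
#' stored so new profiles can be projected later.
#'
#' @param dmso_areas named list, sample -> numeric vector of DMSO
#'   organoid areas (pixels).
#' @param morphology matrix samples x components, e.g. from
#'   [average_dmso_profiles()].
#' @param expression matrix samples x genes.
#' @param mutations binary matrix samples x genes (may omit samples).
#' @param drug_activity matrix samples x drugs of AUROC scores.
#' @param expression_top_frac fraction of genes kept by CV
#'   (default 0.1).
#' @param activity_threshold AUROC activity cutoff (default 0.85,
#'   strict inequality).
#' @return object of class `MultiViewDataset`: `views` (named list of
#'   scaled matrices), `scaling` (per view), `notes`.
#' @export
assemble_views <- function(dmso_areas, morphology, expression, mutations,
                           drug_activity, expression_top_frac = 0.1,
                           activity_threshold = 0.85) {
  size <- t(vapply(dmso_areas, fit_size_summary, numeric(2)))
  size_m <- size[, "size", drop = FALSE]
  colnames(size_m) <- "log_size_large"
  cv <- apply(expression, 2, function(v) {
    mu <- mean(v); if (abs(mu) < 1e-12) return(Inf)
    stats::sd(v) / abs(mu)
  })
  n_keep <- max(1L, ceiling(expression_top_frac * ncol(expression)))
  ord <- order(-cv, seq_along(cv))
  expr <- expression[, sort(ord[seq_len(n_keep)]), drop = FALSE]
  active_any <- apply(drug_activity, 2, function(v)
    any(v > activity_threshold, na.rm = TRUE))
  act <- drug_activity[, active_any, drop = FALSE]
  raw <- list(size = size_m, mutations = as.matrix(mutations),
              expression = expr, morphology = as.matrix(morphology),
              drug_activity = act)
  views <- list(); scaling <- list()
  for (v in names(raw)) {
    sv <- scale_view(raw[[v]])
    views[[v]] <- sv$x
    scaling[[v]] <- sv$scaling
  }
  structure(list(views = views, scaling = scaling,
                 notes = list(size_fallback = size[, "fallback"],
                              n_genes = ncol(expr),
                              n_active_drugs = ncol(act))),
            class = "MultiViewDataset")
}

#' Fit a k-factor multi-view linear factor model
#'
#' Alternating least squares on the joint reconstruction objective
#' `sum_v ||Y_v - Z W_v'||^2` with a small ridge penalty; samples
#' missing from a view are excluded from that view's objective. After
#' convergence the solution is rotated to the principal axes of the
#' scores so factors are ordered by explained variance, with a
#' deterministic sign convention (positive correlation with the size
#' view where applicable, else largest loading positive).
#' Variance explained per factor and view uses the factor alone:
#' `100 * (1 - SS(Y_v - z_f w_vf') / SS(Y_v))`.
#'
#' @param data a `MultiViewDataset` or plain named list of sample x
#'   feature matrices (rownames = sample keys).
#' @param k number of factors (default 3).
#' @param seed integer seed (initialization is deterministic; retained
#'   for interface stability).
#' @param max_iter maximum ALS sweeps (default 200).
#' @param tol relative objective-change convergence tolerance.
#' @param ridge ridge penalty (default 1e-6).
#' @return object of class `FactorModel`: `Z` (samples x k), `W`
#'   (named list, features_v x k), `var_explained` (k x views, %),
#'   `noise_var` per view, `objective` trace, `scaling` (from the
#'   dataset when available).
#' @export
fit_factor_model <- function(data, k = 3, seed = 1, max_iter = 200,
                             tol = 1e-12, ridge = 1e-8) {
  views <- if (inherits(data, "MultiViewDataset")) data$views else data
  scaling <- if (inherits(data, "MultiViewDataset")) data$scaling else NULL
  samples <- Reduce(union, lapply(views, rownames))
  n <- length(samples)
  if (n <= k) stop("number of samples must exceed k")
  set.seed(seed)
  # init: rank-k SVD of the concatenated views (missing rows as 0)
  concat <- do.call(cbind, lapply(views, function(Y) {
    M <- matrix(0, n, ncol(Y), dimnames = list(samples, colnames(Y)))
    M[rownames(Y), ] <- Y
    M
  }))
  sv <- svd(concat, nu = k, nv = 0)
  Z <- sv$u %*% diag(sv$d[seq_len(k)], k)
  rownames(Z) <- samples
  obs <- lapply(views, function(Y) match(rownames(Y), samples))
  W <- vector("list", length(views)); names(W) <- names(views)
  objective <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    for (v in names(views)) {
      Zv <- Z[obs[[v]], , drop = FALSE]
      A <- crossprod(Zv) + ridge * diag(k)
      W[[v]] <- t(solve(A, crossprod(Zv, views[[v]])))
    }
    # update Z rows grouped by view-membership pattern
    memb <- vapply(names(views), function(v) seq_len(n) %in% obs[[v]],
                   logical(n))
    pat <- apply(memb, 1, paste, collapse = "")
    for (pp in unique(pat)) {
      rows <- which(pat == pp)
      in_views <- names(views)[memb[rows[1], ]]
      A <- ridge * diag(k)
      B <- matrix(0, k, length(rows))
      for (v in in_views) {
        A <- A + crossprod(W[[v]])
        Yv <- views[[v]]
        B <- B + crossprod(W[[v]], t(Yv[match(rows, obs[[v]]), , drop = FALSE]))
      }
      Z[rows, ] <- t(solve(A, B))
    }
    obj <- ridge * sum(Z^2)
    for (v in names(views)) {
      R <- views[[v]] - Z[obs[[v]], , drop = FALSE] %*% t(W[[v]])
      obj <- obj + sum(R^2) + ridge * sum(W[[v]]^2)
    }
    objective <- c(objective, obj)
    if (is.finite(prev) && abs(prev - obj) < tol * max(obj, 1e-300)) break
    prev <- obj
  }
  # rotate to principal axes of the scores
  sz <- svd(Z)
  Z <- sz$u %*% diag(sz$d, k)
  rownames(Z) <- samples
  for (v in names(views)) W[[v]] <- W[[v]] %*% sz$v
  # deterministic sign convention
  for (f in seq_len(k)) {
    flip <- FALSE
    if ("size" %in% names(views) && ncol(views$size) == 1) {
      rows <- obs[["size"]]
      cc <- suppressWarnings(stats::cor(Z[rows, f], views$size[, 1]))
      if (is.finite(cc) && abs(cc) > 0.2) flip <- cc < 0
      else {
        wcat <- unlist(lapply(W, function(w) w[, f]))
        flip <- wcat[which.max(abs(wcat))] < 0
      }
    } else {
      wcat <- unlist(lapply(W, function(w) w[, f]))
      flip <- wcat[which.max(abs(wcat))] < 0
    }
    if (flip) {
      Z[, f] <- -Z[, f]
      for (v in names(views)) W[[v]][, f] <- -W[[v]][, f]
    }
  }
  ve <- variance_explained(views, Z, W, obs)
  noise_var <- vapply(names(views), function(v) {
    R <- views[[v]] - Z[obs[[v]], , drop = FALSE] %*% t(W[[v]])
    mean(R^2)
  }, numeric(1))
  structure(list(k = k, Z = Z, W = W, var_explained = ve,
                 noise_var = noise_var, objective = objective,
                 scaling = scaling, samples = samples),
            class = "FactorModel")
}

variance_explained <- function(views, Z, W, obs) {
  k <- ncol(Z)
  ve <- matrix(0, k, length(views),
               dimnames = list(sprintf("factor_%d", seq_len(k)),
                               names(views)))
  for (v in names(views)) {
    Y <- views[[v]]
    ss <- sum(Y^2)
    for (f in seq_len(k)) {
      R <- Y - Z[obs[[v]], f, drop = FALSE] %*% t(W[[v]][, f, drop = FALSE])
      ve[f, v] <- 100 * max(0, 1 - sum(R^2) / ss)
    }
  }
  ve
}

#' @export
print.FactorModel <- function(x, ...) {
  cat(sprintf("FactorModel: k = %d, %d samples, %d views\n",
              x$k, nrow(x$Z), length(x$W)))
  print(round(x$var_explained, 1))
  invisible(x)
}

#' Project phenotype profiles onto learned factors
#'
#' Maps per-treatment average morphology profiles into factor space via
#' the pseudoinverse of the transposed morphology loading matrix:
#' `Z_proj = Y %*% pinv(W')`, the least-squares solution of
#' `Y ~ Z_proj W'`. Profiles are standardized with the training view's
#' stored scaling when the model carries one.
#'
#' @param model a `FactorModel`.
#' @param profiles matrix (treatments x morphology features), raw scale
#'   if the model has scaling state, otherwise already scaled.
#' @param view which view's loadings to invert (default
#'   `"morphology"`).
#' @return matrix treatments x k of projected factor scores.
#' @export
project_onto_factors <- function(model, profiles, view = "morphology") {
  W <- model$W[[view]]
  if (is.null(W)) stop("model has no view ", view)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != nrow(W))
    stop("profile dimension does not match the view's feature count")
  if (!is.null(model$scaling) && !is.null(model$scaling[[view]]))
    profiles <- apply_view_scaling(profiles, model$scaling[[view]])
  kappa <- tryCatch(kappa(W), error = function(e) NA_real_)
  if (is.finite(kappa) && kappa > 1e8)
    message("morphology loading matrix is ill-conditioned (kappa = ",
            format(kappa, digits = 3), ")")
  zp <- profiles %*% MASS::ginv(t(W))
  colnames(zp) <- sprintf("factor_%d", seq_len(model$k))
  zp
}

# ---- preranked GSEA ------------------------------------------------------

gsea_es_from_positions <- function(pos_sorted, absr, cum_absr, n_total) {
  m <- length(pos_sorted)
  nr <- cum_absr[pos_sorted]
  hit_cum <- cumsum(absr[pos_sorted])
  nrm <- hit_cum[m]
  if (nrm <= 0) return(0)
  miss_step <- 1 / (n_total - m)
  after <- hit_cum / nrm - (pos_sorted - seq_len(m)) * miss_step
  before <- c(0, hit_cum[-m]) / nrm - (pos_sorted - seq_len(m)) * miss_step
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment with a permutation null
#'
#' Weighted Kolmogorov-Smirnov-like running-sum enrichment score over a
#' ranked gene list (weight exponent `weight`, default 1), with a
#' gene-label permutation null: `NES = ES / mean(|ES_null|)` over
#' same-sign null scores and
#' `p = (1 + #{same-sign |ES_null| >= |ES|}) / (n_same_sign + 1)`.
#'
#' @param stats named numeric vector of per-gene statistics (e.g.
#'   factor loadings); ranked internally in decreasing order.
#' @param gene_set character vector of gene ids; its intersection with
#'   the ranking must have at least 5 and fewer than all genes.
#' @param n_perm number of permutations (default 1e5).
#' @param weight running-sum weight exponent (default 1).
#' @param seed integer seed.
#' @return object of class `GSEAResult`: `es`, `nes`, `p`, `size`,
#'   `n_perm`.
#' @export
gsea_preranked <- function(stats, gene_set, n_perm = 1e5, weight = 1,
                           seed = 1) {
  stopifnot(!is.null(names(stats)))
  ord <- order(stats, decreasing = TRUE)
  r <- stats[ord]
  n <- length(r)
  hits <- which(names(r) %in% gene_set)
  m <- length(hits)
  if (m < 5) stop("gene set intersects fewer than 5 ranked genes")
  if (m >= n) stop("gene set must not contain every ranked gene")
  absr <- abs(r)^weight
  cum_absr <- cumsum(absr)
  es <- gsea_es_from_positions(hits, absr, cum_absr, n)
  set.seed(seed)
  es_null <- vapply(seq_len(n_perm), function(i) {
    gsea_es_from_positions(sort.int(sample.int(n, m)), absr, cum_absr, n)
  }, numeric(1))
  same <- if (es >= 0) es_null >= 0 else es_null < 0
  n_same <- sum(same)
  p <- (1 + sum(abs(es_null[same]) >= abs(es))) / (n_same + 1)
  denom <- mean(abs(es_null[same]))
  nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
  structure(list(es = es, nes = nes, p = p, size = m, n_perm = n_perm),
            class = "GSEAResult")
}

#' Preranked GSEA over multiple gene sets with BH correction
#' @param stats named numeric vector of per-gene statistics.
#' @param gene_sets named list of gene id vectors (e.g. read from GMT).
#' @param ... passed to [gsea_preranked()].
#' @return data.frame with one row per set: `set`, `size`, `es`,
#'   `nes`, `p`, `fdr`.
#' @export
gsea_preranked_sets <- function(stats, gene_sets, ...) {
  res <- lapply(gene_sets, function(gs) gsea_preranked(stats, gs, ...))
  out <- data.frame(set = names(gene_sets),
                    size = vapply(res, `[[`, numeric(1), "size"),
                    es = vapply(res, `[[`, numeric(1), "es"),
                    nes = vapply(res, `[[`, numeric(1), "nes"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#' @param path GMT file path (set name, description, genes per line).
#' @return named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1))
  sets
}

#' Test drug-target association of factor values
#'
#' For every target annotated with at least `min_drugs` drugs present
#' in the data, fits the linear model `value ~ is_target` (equivalent
#' to a two-group ANOVA across all observations, pooling organoid
#' lines where values carry one row per drug x line) and reports the
#' indicator's t statistic with BH-adjusted p-values across targets.
#'
#' @param values data.frame with columns `drug` and `value` (one row
#'   per drug, or per drug x line for projected scores), or a named
#'   numeric vector of per-drug values.
#' @param annotations data.frame with columns `drug`, `target`.
#' @param min_drugs minimum annotated drugs per tested target
#'   (default 3).
#' @return data.frame with `target`, `n_drugs`, `estimate`, `t`, `p`,
#'   `fdr`, `note`.
#' @export
test_target_association <- function(values, annotations, min_drugs = 3) {
  if (!is.data.frame(values))
    values <- data.frame(drug = names(values), value = as.numeric(values),
                         stringsAsFactors = FALSE)
  ann <- stats::setNames(as.character(annotations$target),
                         as.character(annotations$drug))
  values$target <- ann[values$drug]
  counts <- table(unique(values[, c("drug", "target")])$target)
  targets <- names(counts)[counts >= min_drugs]
  if (length(targets) < 2)
    stop("fewer than 2 targets pass the minimum drug count")
  rows <- lapply(targets, function(tg) {
    ind <- !is.na(values$target) & values$target == tg
    if (stats::sd(values$value) == 0)
      return(data.frame(target = tg, n_drugs = as.integer(counts[tg]),
                        estimate = 0, t = NA_real_, p = NA_real_,
                        note = "zero variance", stringsAsFactors = FALSE))
    fit <- stats::lm(values$value ~ ind)
    sm <- summary(fit)$coefficients
    data.frame(target = tg, n_drugs = as.integer(counts[tg]),
               estimate = sm["indTRUE", "Estimate"],
               t = sm["indTRUE", "t value"],
               p = sm["indTRUE", "Pr(>|t|)"],
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[order(out$p), ]
}
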