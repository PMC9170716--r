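# Drug-effect profiles: per line x treatment logistic regression against
# DMSO in PC space; AUROC as activity; cosine clustering of profiles and
# Fisher mechanism-of-action enrichment over the dendrogram.

auroc_score <- function(labels, scores) {
  # labels: factor/logical with TRUE/1 = treated
  as.numeric(pROC::auc(response = factor(labels, levels = c(FALSE, TRUE)),
                       predictor = scores, levels = c("FALSE", "TRUE"),
                       direction = "<", quiet = TRUE))
}

stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (l in unique(y)) {
    i <- which(y == l)
    folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  folds
}

#' Fit a drug-effect profile for one line and treatment
#'
#' Trains an L2-regularized logistic regression separating one drug's
#' organoids from DMSO controls of the same line in 25-PC feature
#' space. Organoids are split 50-50; the regularization strength is
#' chosen on the first half by 5-fold cross-validated AUROC over
#' `l2_grid`; the final model is refit on the second half, whose
#' 10-fold cross-validation yields the reported AUROC (pooled
#' out-of-fold predictions). The coefficient vector is the direction of
#' the normal of the separating hyperplane, read as the drug-induced
#' phenotype shift; AUROC is oriented to `>= 0.5` with a matching
#' coefficient sign flip.
#'
#' @param scores PC score matrix for one line's organoids.
#' @param meta data.frame aligned with `scores`; `treatment` (and
#'   optionally `concentration`) identify rows.
#' @param drug treatment name to contrast against `"DMSO"`.
#' @param concentration optional concentration filter for the drug.
#' @param l2_grid candidate L2 penalties (default 7 log-spaced values,
#'   1e-3 to 1e3).
#' @param cv_folds folds for the performance estimate (default 10).
#' @param seed integer seed.
#' @return object of class `DrugEffectProfile`: `coefficients`,
#'   `direction` (unit L2 norm), `auroc`, `lambda`, `mean_shift`
#'   (treated minus control PC means), `drug`, `line_id`,
#'   `concentration`, `n_treated`, `n_control`.
#' @export
fit_drug_effect_profile <- function(scores, meta, drug, concentration = NULL,
                                    l2_grid = 10^seq(-3, 3, length.out = 7),
                                    cv_folds = 10, seed = 1) {
  scores <- as.matrix(scores)
  treated <- meta$treatment == drug
  if (!is.null(concentration))
    treated <- treated & !is.na(meta$concentration) &
      abs(meta$concentration - concentration) < 1e-12 * max(concentration, 1)
  control <- meta$treatment == "DMSO"
  if (!any(treated) || !any(control))
    stop("need both treated and DMSO organoids")
  x <- rbind(scores[treated, , drop = FALSE], scores[control, , drop = FALSE])
  y <- c(rep(1L, sum(treated)), rep(0L, sum(control)))
  line_id <- unique(meta$line_id)[1]
  set.seed(seed)
  half <- stratified_folds(y, 2)
  x1 <- x[half == 1, , drop = FALSE]; y1 <- y[half == 1]
  x2 <- x[half == 2, , drop = FALSE]; y2 <- y[half == 2]
  # hyperparameter search: 5-fold CV AUROC on the first half
  grid_folds <- min(5L, min(table(y1)))
  if (grid_folds < 5L) warning("reduced CV folds due to class starvation")
  if (grid_folds < 2L) stop("too few organoids per class for CV")
  f1 <- stratified_folds(y1, grid_folds)
  cv_auc <- vapply(l2_grid, function(lam) {
    pred <- numeric(length(y1))
    for (fd in seq_len(grid_folds)) {
      fit <- glmnet::glmnet(x1[f1 != fd, , drop = FALSE], y1[f1 != fd],
                            family = "binomial", alpha = 0, lambda = lam,
                            standardize = FALSE)
      pred[f1 == fd] <- stats::predict(fit, x1[f1 == fd, , drop = FALSE],
                                       type = "link")
    }
    auroc_score(y1 == 1, pred)
  }, numeric(1))
  lambda <- l2_grid[which.max(cv_auc)]
  # performance: pooled out-of-fold predictions over the second half
  k <- min(cv_folds, min(table(y2)))
  if (k < cv_folds) warning("reduced CV folds due to class starvation")
  f2 <- stratified_folds(y2, max(2L, k))
  pred2 <- numeric(length(y2))
  for (fd in seq_len(max(2L, k))) {
    fit <- glmnet::glmnet(x2[f2 != fd, , drop = FALSE], y2[f2 != fd],
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE)
    pred2[f2 == fd] <- stats::predict(fit, x2[f2 == fd, , drop = FALSE],
                                      type = "link")
  }
  auc <- auroc_score(y2 == 1, pred2)
  final <- glmnet::glmnet(x2, y2, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
  beta <- as.numeric(final$beta)
  names(beta) <- colnames(x)
  if (auc < 0.5) {      # orientation: report max(a, 1 - a), flip direction
    auc <- 1 - auc
    beta <- -beta
  }
  nb <- sqrt(sum(beta^2))
  structure(list(
    coefficients = beta,
    direction = if (nb > 0) beta / nb else beta,
    auroc = auc, lambda = lambda,
    mean_shift = colMeans(scores[treated, , drop = FALSE]) -
      colMeans(scores[control, , drop = FALSE]),
    drug = drug, line_id = line_id, concentration = concentration,
    n_treated = sum(treated), n_control = sum(control)),
    class = "DrugEffectProfile")
}

#' Call active drugs from per-line effect profiles
#'
#' A drug is active when its mean AUROC across lines strictly exceeds
#' the threshold (mean of 0.85 exactly is not active).
#'
#' @param profiles list of `DrugEffectProfile` objects.
#' @param threshold activity threshold on mean AUROC (default 0.85).
#' @return data.frame with `drug`, `mean_auroc`, `n_lines`, `active`.
#' @export
call_active <- function(profiles, threshold = 0.85) {
  drugs <- vapply(profiles, `[[`, character(1), "drug")
  aurocs <- vapply(profiles, `[[`, numeric(1), "auroc")
  agg <- tapply(aurocs, drugs, mean)
  out <- data.frame(drug = names(agg), mean_auroc = as.numeric(agg),
                    n_lines = as.integer(table(drugs)[names(agg)]),
                    stringsAsFactors = FALSE)
  # strict inequality, robust to floating-point accumulation in the mean
  out$active <- (out$mean_auroc - threshold) > 1e-9
  rownames(out) <- NULL
  out[order(out$drug), ]
}

cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  sim <- tcrossprod(m / pmax(nrm, 1e-300))
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchically cluster drug-effect profiles
#'
#' In `"cosine"` mode each drug's vector is the concatenation over
#' lines of its unit-normalized coefficient direction scaled by
#' `(AUROC - 0.5) * 2`, so lines where the drug is more active weigh
#' more; lines without a profile contribute zeros. Distance is
#' `1 - cosine similarity`. `"euclidean"` clusters per-drug mean
#' phenotype shifts; `"pearson"` uses `1 - correlation` of the
#' concatenated vectors.
#'
#' @param profiles list of `DrugEffectProfile`s (active drugs only).
#' @param method `"cosine"` (default), `"euclidean"`, or `"pearson"`.
#' @param linkage hclust linkage (default `"average"`).
#' @return object of class `ClusterTree`: list with `hclust`, `drugs`,
#'   `method`, `vectors` (the drug x feature matrix clustered).
#' @export
cluster_drug_profiles <- function(profiles, method = "cosine",
                                  linkage = "average") {
  method <- match.arg(method, c("cosine", "euclidean", "pearson"))
  drugs <- vapply(profiles, `[[`, character(1), "drug")
  lines <- vapply(profiles, `[[`, character(1), "line_id")
  u_drugs <- sort(unique(drugs))
  u_lines <- sort(unique(lines))
  if (length(u_drugs) < 3) stop("need at least 3 drugs to cluster")
  p <- length(profiles[[1]]$direction)
  if (method %in% c("cosine", "pearson")) {
    vec <- matrix(0, length(u_drugs), p * length(u_lines),
                  dimnames = list(u_drugs, NULL))
    for (pr in profiles) {
      j <- (match(pr$line_id, u_lines) - 1L) * p + seq_len(p)
      vec[pr$drug, j] <- pr$direction * (pr$auroc - 0.5) * 2
    }
  } else {
    vec <- matrix(0, length(u_drugs), p, dimnames = list(u_drugs, NULL))
    cnt <- stats::setNames(numeric(length(u_drugs)), u_drugs)
    for (pr in profiles) {
      vec[pr$drug, ] <- vec[pr$drug, ] + pr$mean_shift
      cnt[pr$drug] <- cnt[pr$drug] + 1
    }
    vec <- vec / pmax(cnt, 1)
  }
  vec[!is.finite(vec)] <- 0   # degenerate directions count as zero vectors
  zero <- rowSums(vec^2) == 0
  if (any(zero)) {
    warning("excluding zero-vector drugs: ",
            paste(u_drugs[zero], collapse = ", "))
    vec <- vec[!zero, , drop = FALSE]
  }
  d <- switch(method,
              cosine = cosine_dist(vec),
              euclidean = stats::dist(vec),
              pearson = stats::as.dist(1 - stats::cor(t(vec))))
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, drugs = rownames(vec), method = method,
                 vectors = vec),
            class = "ClusterTree")
}

#' Export a cluster tree in Newick format
#' @param tree a `ClusterTree`.
#' @param file optional path; if omitted the string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
tree_to_newick <- function(tree, file = NULL) {
  hc <- tree$hclust
  rec <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%.6f", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6f", rec(hc$merge[i, 1], h), rec(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- length(hc$height)
  s <- sprintf("(%s,%s);", rec(hc$merge[n, 1], hc$height[n]),
               rec(hc$merge[n, 2], hc$height[n]))
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

node_leaves <- function(hc) {
  # list of leaf label sets for each internal node, in merge (height) order
  n <- nrow(hc$merge)
  leaves <- vector("list", n)
  for (i in seq_len(n)) {
    kids <- hc$merge[i, ]
    l <- c(if (kids[1] < 0) hc$labels[-kids[1]] else leaves[[kids[1]]],
           if (kids[2] < 0) hc$labels[-kids[2]] else leaves[[kids[2]]])
    leaves[[i]] <- l
  }
  leaves
}

#' Test mechanism-of-action enrichment over a drug dendrogram
#'
#' Every internal node with at least `min_size` leaves is tested,
#' iterating from the bottom of the tree to the top, for enrichment of
#' each drug-target annotation present among its leaves, with a
#' one-sided Fisher's exact test on the 2x2 table (in-node and target,
#' in-node not target, out-of-node and target, out-of-node not
#' target). Unannotated drugs count as non-target. p-values are
#' Benjamini-Hochberg adjusted across all node x target tests.
#'
#' @param tree a `ClusterTree` from [cluster_drug_profiles()].
#' @param annotations data.frame with columns `drug`, `target`.
#' @param min_size minimum node size tested (default 3).
#' @return data.frame with `node`, `height`, `size`, `target`, the 2x2
#'   counts, `odds_ratio`, `p`, `fdr`, ordered bottom-up.
#' @export
test_moa_enrichment <- function(tree, annotations, min_size = 3) {
  hc <- tree$hclust
  drugs <- tree$drugs
  ann <- stats::setNames(as.character(annotations$target),
                         as.character(annotations$drug))
  if (length(unique(ann[drugs])) < 2 && length(unique(stats::na.omit(ann[drugs]))) < 2)
    stop("annotations must cover at least 2 targets")
  leaves <- node_leaves(hc)
  ord <- order(hc$height)  # bottom to top
  rows <- list()
  for (i in ord) {
    inset <- leaves[[i]]
    if (length(inset) < min_size) next
    targets <- unique(stats::na.omit(ann[inset]))
    for (tg in targets) {
      is_t <- !is.na(ann[drugs]) & ann[drugs] == tg
      in_n <- drugs %in% inset
      a <- sum(in_n & is_t); b <- sum(in_n & !is_t)
      cc <- sum(!in_n & is_t); d <- sum(!in_n & !is_t)
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                               alternative = "greater")
      rows[[length(rows) + 1]] <- data.frame(
        node = i, height = hc$height[i], size = length(inset), target = tg,
        in_target = a, in_other = b, out_target = cc, out_other = d,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(node = integer(0), target = character(0),
                      p = numeric(0), fdr = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
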