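# Feature matrices pair a numeric matrix (organoids x named features) with
# per-organoid metadata (well, line, treatment, batch, area).

#' Construct a feature matrix
#'
#' @param x numeric matrix, rows = organoids, named columns = features.
#' @param meta data.frame with one row per organoid; expected columns
#'   include `organoid_id`, `line_id`, `treatment`, `concentration`,
#'   `role`, `batch_id`, `area_px` (extra columns are kept).
#' @return object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(x, meta) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == nrow(meta), !is.null(colnames(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  structure(list(x = x, meta = as.data.frame(meta)),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d organoids x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$x)

#' Subset a feature matrix by rows
#'
#' @param fm a [feature_matrix()].
#' @param i row index (logical or integer).
#' @return subsetted `FeatureMatrix`.
#' @export
fm_subset <- function(fm, i) {
  feature_matrix(fm$x[i, , drop = FALSE], fm$meta[i, , drop = FALSE])
}

#' Combine feature matrices by rows
#' @param ... `FeatureMatrix` objects with identical feature columns.
#' @return combined `FeatureMatrix`.
#' @export
fm_rbind <- function(...) {
  fms <- list(...)
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "x")),
                 do.call(rbind, lapply(fms, `[[`, "meta")))
}

hu_moments <- function(ys, xs, w) {
  # seven rotation-invariant moments from normalized central moments
  m00 <- sum(w)
  cy <- sum(w * ys) / m00; cx <- sum(w * xs) / m00
  mu <- function(p, q) sum(w * (ys - cy)^p * (xs - cx)^q)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(h1 = n20 + n02,
    h2 = (n20 - n02)^2 + 4 * n11^2,
    h3 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    h4 = (n30 + n12)^2 + (n21 + n03)^2,
    h5 = (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    h6 = (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    h7 = (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

object_solidity <- function(mask, label) {
  pix <- which(mask == label, arr.ind = TRUE)
  if (nrow(pix) < 3) return(1)
  hull <- grDevices::chull(pix[, 2], pix[, 1])
  hx <- pix[hull, 2]; hy <- pix[hull, 1]
  # shoelace area of the hull polygon plus half-perimeter correction is
  # unnecessary at this precision; plain polygon area suffices
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (a <= 0) return(1)
  min(nrow(pix) / a, 1)
}

#' Extract per-organoid phenotype features from a projected image
#'
#' Computes, per labelled object: shape features (area, perimeter,
#' radius statistics, solidity), image moments (centroid, axes,
#' eccentricity, Hu invariants on the composite intensity), per-channel
#' intensity statistics and per-channel Haralick texture features at
#' multiple pixel offsets, via EBImage. Channel-derived feature names
#' are prefixed with the channel name so channels can be masked
#' downstream.
#'
#' @param img a `ProjectedImage`.
#' @param mask integer `LabelMask` over the same pixels.
#' @param texture_scales Haralick co-occurrence offsets in pixels
#'   (default `c(1, 2, 4, 8)`).
#' @param meta optional single-row data.frame of well metadata recycled
#'   across organoids.
#' @return a [feature_matrix()] with one row per labelled object.
#' @export
extract_organoid_features <- function(img, mask,
                                      texture_scales = c(1, 2, 4, 8),
                                      meta = NULL) {
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labs) == 0) {
    return(feature_matrix(matrix(0, 0, 1, dimnames = list(NULL, "area")),
                          data.frame(organoid_id = character(0))))
  }
  chans <- dimnames(img$pixels)[[1]]
  ebmask <- EBImage::Image(t(mask))
  comp <- Reduce(`+`, lapply(chans, function(ch) img$pixels[ch, , ]))
  comp <- comp / max(comp, 1e-12)
  sh <- EBImage::computeFeatures.shape(ebmask)
  mo <- EBImage::computeFeatures.moment(ebmask, ref = t(comp))
  colnames(sh) <- sub("^s\\.", "shape_", colnames(sh))
  colnames(mo) <- sub("^m\\.", "moment_", colnames(mo))
  sol <- vapply(labs, function(l) object_solidity(mask, l), numeric(1))
  hu <- t(vapply(labs, function(l) {
    pix <- which(mask == l, arr.ind = TRUE)
    hu_moments(pix[, 1], pix[, 2], comp[pix])
  }, numeric(7)))
  colnames(hu) <- paste0("moment_hu_", colnames(hu))
  per_chan <- lapply(chans, function(ch) {
    ref <- img$pixels[ch, , ]
    ref <- ref / max(ref, 1e-12)
    b <- EBImage::computeFeatures.basic(ebmask, ref = t(ref))
    colnames(b) <- sub("^b\\.", paste0(ch, "_int_"), colnames(b))
    h <- EBImage::computeFeatures.haralick(ebmask, ref = t(ref),
                                           haralick.scales = texture_scales)
    colnames(h) <- sub("^h\\.", paste0(ch, "_tex_"), colnames(h))
    cbind(b, h)
  })
  x <- cbind(sh, shape_solidity = sol, mo, hu, do.call(cbind, per_chan))
  meta_df <- data.frame(
    organoid_id = sprintf("obj_%03d", labs),
    label = labs,
    area_px = as.integer(sh[, "shape_area"]),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    meta_df <- cbind(meta_df, meta[rep(1L, length(labs)), , drop = FALSE])
    rownames(meta_df) <- NULL
  }
  feature_matrix(x, meta_df)
}

haralick_scale_of <- function(feature_names) {
  # returns NA for non-texture features, else the pixel offset s<k>
  sc <- rep(NA_real_, length(feature_names))
  hit <- grepl("_tex_.*\\.s[0-9]+$", feature_names)
  sc[hit] <- as.numeric(sub(".*\\.s([0-9]+)$", "\\1", feature_names[hit]))
  sc
}

#' Filter to well-defined features and center by batch
#'
#' Applies the feature-hygiene rules: (1) drop texture features at
#' offsets larger than the dataset's smallest organoid diameter (5th
#' percentile of equivalent diameters, guarding against outliers);
#' (2) drop features undefined (NA) for any organoid; (3) drop every
#' feature whose median absolute deviation over all rows is 0 (a
#' feature is well-defined only if its MAD is strictly positive);
#' (4) subtract the per-batch mean from every retained feature. The
#' operation is idempotent.
#'
#' @param fm a [feature_matrix()]; `fm$meta$area_px` and
#'   `fm$meta$batch_id` are used when present.
#' @param texture_scale_rule apply rule (1) (default TRUE).
#' @return filtered, batch-centered `FeatureMatrix`.
#' @export
filter_and_center_features <- function(fm, texture_scale_rule = TRUE) {
  x <- fm$x
  keep <- rep(TRUE, ncol(x))
  if (texture_scale_rule && "area_px" %in% names(fm$meta)) {
    diam <- 2 * sqrt(fm$meta$area_px / pi)
    min_diam <- stats::quantile(diam, 0.05, names = FALSE)
    sc <- haralick_scale_of(colnames(x))
    keep <- keep & (is.na(sc) | sc <= min_diam)
  }
  keep <- keep & !apply(x, 2, anyNA)
  mads <- apply(x[, keep, drop = FALSE], 2, stats::mad)
  keep[keep] <- mads > 0
  if (!any(keep)) stop("all features dropped by filtering; check input scale")
  x <- x[, keep, drop = FALSE]
  batch <- if ("batch_id" %in% names(fm$meta)) fm$meta$batch_id
           else rep("batch_1", nrow(x))
  for (b in unique(batch)) {
    i <- batch == b
    x[i, ] <- sweep(x[i, , drop = FALSE], 2,
                    colMeans(x[i, , drop = FALSE]), "-")
  }
  stopifnot(!anyNA(x))
  feature_matrix(x, fm$meta)
}

#' Principal component compression via incremental moment accumulation
#'
#' Fits PCA by accumulating first and second moments over row chunks,
#' so datasets far larger than memory-resident chunks decompose into
#' exactly the same subspace as a full-batch fit. Scores are the
#' centered features times the component matrix.
#'
#' @param fm a [feature_matrix()] or plain numeric matrix.
#' @param n_components number of components (default 25).
#' @param chunk_size rows per accumulation chunk (default 5000).
#' @return list with `model` (class `PCAModel`: `rotation`
#'   features x k, `center`, `sdev`, `var_explained` per-component
#'   fractions of total variance) and `scores` (rows x k).
#' @export
fit_pca_transform <- function(fm, n_components = 25, chunk_size = 5000) {
  x <- if (inherits(fm, "FeatureMatrix")) fm$x else as.matrix(fm)
  n <- nrow(x); p <- ncol(x)
  if (n_components > p) stop("n_components exceeds feature count")
  if (n < n_components) stop("need at least n_components rows")
  xtx <- matrix(0, p, p)
  csum <- numeric(p)
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n)
    xc <- x[idx, , drop = FALSE]
    xtx <- xtx + crossprod(xc)
    csum <- csum + colSums(xc)
  }
  center <- csum / n
  covm <- (xtx - n * tcrossprod(center)) / (n - 1)
  eg <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- n_components
  rotation <- eg$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  rownames(rotation) <- colnames(x)
  colnames(rotation) <- sprintf("PC%02d", seq_len(k))
  scores <- sweep(x, 2, center) %*% rotation
  model <- structure(list(rotation = rotation, center = center,
                          sdev = sqrt(ev[seq_len(k)]),
                          var_explained = ev[seq_len(k)] / sum(ev)),
                     class = "PCAModel")
  list(model = model, scores = scores)
}

#' Apply a fitted PCA model to new data
#' @param model a `PCAModel` from [fit_pca_transform()].
#' @param fm a `FeatureMatrix` or matrix with the model's features.
#' @return score matrix rows x k.
#' @export
pca_apply <- function(model, fm) {
  x <- if (inherits(fm, "FeatureMatrix")) fm$x else as.matrix(fm)
  x <- x[, rownames(model$rotation), drop = FALSE]
  sweep(x, 2, model$center) %*% model$rotation
}

#' Flag out-of-focus organoids with a feature-based classifier
#'
#' Trains a random forest on a labelled subset of rows (in-focus vs
#' out-of-focus) and flags every row of the dataset; flagged rows are
#' excluded from downstream analysis.
#'
#' @param fm a [feature_matrix()].
#' @param labeled_idx row indices carrying focus labels.
#' @param labels logical vector (TRUE = out of focus) aligned with
#'   `labeled_idx`.
#' @param seed integer seed.
#' @return logical flags, one per row of `fm` (TRUE = out of focus).
#' @export
flag_out_of_focus <- function(fm, labeled_idx, labels, seed = 1) {
  if (length(labeled_idx) == 0) stop("labeled subset is empty")
  y <- factor(labels, levels = c(FALSE, TRUE))
  if (length(unique(labels)) < 2)
    stop("labeled subset must contain both classes")
  set.seed(seed)
  rf <- randomForest::randomForest(fm$x[labeled_idx, , drop = FALSE], y)
  as.logical(stats::predict(rf, fm$x) == "TRUE")
}
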