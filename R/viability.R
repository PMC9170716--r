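# Control-anchored live/dead classification, well viability scores,
# plate normalization and Hill dose-response summaries.

control_classes <- function(meta) {
  # negative controls = DMSO; positive (dead) controls = bortezomib and
  # SN-38 at their two highest concentrations
  lab <- rep(NA_character_, nrow(meta))
  lab[meta$treatment == "DMSO"] <- "live"
  for (drug in c("bortezomib", "SN-38")) {
    i <- meta$treatment == drug
    if (!any(i)) next
    top2 <- sort(unique(meta$concentration[i]), decreasing = TRUE)
    top2 <- top2[seq_len(min(2L, length(top2)))]
    lab[i & meta$concentration %in% top2] <- "dead"
  }
  lab
}

mask_channel_features <- function(feature_names, channel_mask) {
  aliases <- list(dna = "dna", actin = "actin",
                  permeability = c("permeability", "perm"))
  channel_mask <- match.arg(channel_mask, names(aliases), several.ok = TRUE)
  drop_prefix <- unlist(aliases[setdiff(names(aliases), channel_mask)])
  drop <- rep(FALSE, length(feature_names))
  for (p in drop_prefix)
    drop <- drop | startsWith(feature_names, paste0(p, "_"))
  feature_names[!drop]
}

#' Train a live/dead classifier for one organoid line
#'
#' A random forest with 10 trees is trained on single-organoid features
#' to separate DMSO-treated (live) from high-dose bortezomib / SN-38
#' (dead) control organoids of one line, with a 60/40 stratified
#' train-validation split. Channels can be masked by removing all
#' features derived from them before training and inference, the
#' ablation used to probe how much each stain contributes.
#'
#' @param fm a [feature_matrix()] with raw (pre-filter) features.
#' @param line_id organoid line to train on.
#' @param channel_mask channels available to the classifier (subset of
#'   `c("dna", "actin", "permeability")`; default all).
#' @param ntree number of trees (default 10).
#' @param seed integer seed.
#' @return object of class `LDCModel`: random forest, feature names,
#'   masked channels, and validation `metrics` (accuracy, auroc, n).
#' @export
train_live_dead_classifier <- function(fm, line_id,
                                       channel_mask = c("dna", "actin",
                                                        "permeability"),
                                       ntree = 10, seed = 1) {
  meta <- fm$meta
  cls <- control_classes(meta)
  sel <- which(meta$line_id == line_id & !is.na(cls))
  if (length(sel) == 0) stop("no control organoids for line ", line_id)
  y <- factor(cls[sel], levels = c("live", "dead"))
  if (nlevels(droplevels(y)) < 2)
    stop("missing control classes for line ", line_id)
  feats <- mask_channel_features(colnames(fm$x), channel_mask)
  x <- fm$x[sel, feats, drop = FALSE]
  set.seed(seed)
  train_idx <- unlist(lapply(levels(y), function(l) {
    i <- which(y == l)
    sample(i, round(0.6 * length(i)))
  }))
  val_idx <- setdiff(seq_along(sel), train_idx)
  rf <- randomForest::randomForest(x[train_idx, , drop = FALSE],
                                   y[train_idx], ntree = ntree)
  pred <- stats::predict(rf, x[val_idx, , drop = FALSE], type = "prob")[, "dead"]
  acc <- mean((pred > 0.5) == (y[val_idx] == "dead"))
  auc <- if (nlevels(droplevels(y[val_idx])) == 2)
    as.numeric(pROC::auc(response = y[val_idx], predictor = pred,
                         levels = c("live", "dead"), direction = "<",
                         quiet = TRUE)) else NA_real_
  structure(list(rf = rf, line_id = line_id, channel_mask = channel_mask,
                 features = feats,
                 metrics = list(accuracy = acc, auroc = auc,
                                n_train = length(train_idx),
                                n_validation = length(val_idx))),
            class = "LDCModel")
}

#' Per-organoid death probabilities from a live/dead classifier
#' @param model an `LDCModel`.
#' @param fm a `FeatureMatrix` with compatible features.
#' @return numeric vector of dead-class probabilities.
#' @export
ldc_predict <- function(model, fm) {
  missing <- setdiff(model$features, colnames(fm$x))
  if (length(missing) > 0)
    stop("feature name mismatch: ", paste(utils::head(missing, 3),
                                          collapse = ", "))
  stats::predict(model$rf, fm$x[, model$features, drop = FALSE],
                 type = "prob")[, "dead"]
}

#' Well-level viability scores from a live/dead classifier
#'
#' Per-organoid dead probabilities are binarized at 0.5 and averaged
#' within wells; `1 - mean(dead)` would be viability, and following the
#' well-score convention the returned `score` is the within-well dead
#' fraction in `[0, 1]` with `viability = 1 - score`. With
#' `cross_line = TRUE` the model is applied to wells of lines other
#' than its training line, the generalizability evaluation.
#'
#' @param model an `LDCModel`.
#' @param fm a [feature_matrix()].
#' @param cross_line if TRUE score only foreign lines; if FALSE only
#'   the model's own line (default).
#' @return data.frame keyed by (plate_id, row, col) with `line_id`,
#'   `treatment`, `concentration`, `n_organoids`, `score` (dead
#'   fraction) and `viability`.
#' @export
score_well_viability <- function(model, fm, cross_line = FALSE) {
  meta <- fm$meta
  sel <- if (cross_line) meta$line_id != model$line_id
         else meta$line_id == model$line_id
  if (!any(sel)) return(data.frame())
  fm2 <- fm_subset(fm, sel)
  p <- ldc_predict(model, fm2)
  dead <- as.integer(p > 0.5)
  key <- interaction(fm2$meta$plate_id, fm2$meta$row, fm2$meta$col,
                     drop = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, key, f))
  first <- function(v) as.vector(tapply(as.character(v), key,
                                        function(z) z[1]))
  out <- data.frame(
    plate_id = first(fm2$meta$plate_id),
    row = as.integer(first(fm2$meta$row)),
    col = as.integer(first(fm2$meta$col)),
    line_id = first(fm2$meta$line_id),
    treatment = first(fm2$meta$treatment),
    concentration = as.numeric(first(fm2$meta$concentration)),
    n_organoids = as.integer(agg(dead, length)),
    score = agg(dead, mean),
    stringsAsFactors = FALSE
  )
  out$viability <- 1 - out$score
  out[order(out$plate_id, out$row, out$col), ]
}

#' Normalize a CTG luminescence plate
#'
#' Two-step normalization of a 384-well luminescence readout: (1) a
#' robust loess surface over (row, col) absorbs spatial/edge trends and
#' every well is divided by the surface value at its position (surface
#' scaled to mean 1 so plate totals are preserved); (2) all wells are
#' divided by the median of the DMSO negative controls, which is
#' exactly 1 afterwards.
#'
#' @param luminescence data.frame with `row`, `col`, `value` for one
#'   plate, or a 16 x 24 matrix.
#' @param layout `PlateLayout` rows for the same plate (used to locate
#'   DMSO wells); alternatively `luminescence$treatment` may carry it.
#' @param loess_span loess span (default 0.75).
#' @return input data.frame with added `normalized` column.
#' @export
normalize_ctg_plate <- function(luminescence, layout = NULL,
                                loess_span = 0.75) {
  if (is.matrix(luminescence)) {
    luminescence <- data.frame(row = as.integer(row(luminescence)),
                               col = as.integer(col(luminescence)),
                               value = as.numeric(luminescence))
  }
  lum <- luminescence
  if (!is.null(layout)) {
    key_l <- paste(layout$row, layout$col)
    lum$treatment <- layout$treatment[match(paste(lum$row, lum$col), key_l)]
  }
  if (!"treatment" %in% names(lum))
    stop("treatment annotation required to locate DMSO wells")
  dmso <- lum$treatment == "DMSO" & !is.na(lum$treatment)
  if (sum(dmso) < 1) stop("no DMSO wells on plate")
  fit <- stats::loess(value ~ row + col, data = lum, span = loess_span,
                      degree = 1, family = "symmetric", normalize = FALSE)
  surface <- stats::predict(fit, lum)
  gain <- surface / mean(surface)
  gain <- pmax(gain, 1e-8)
  corrected <- lum$value / gain
  med <- stats::median(corrected[dmso])
  if (med <= 0) stop("non-positive DMSO median after correction")
  lum$normalized <- corrected / med
  lum
}

#' Evaluate a three-parameter Hill viability curve
#'
#' `v(c) = E_inf + (1 - E_inf) / (1 + (c / EC50)^h)` with the top
#' asymptote fixed at 1.
#'
#' @param conc concentration vector (molar).
#' @param ec50 half-maximal concentration (molar).
#' @param slope Hill coefficient (> 0, decreasing viability).
#' @param e_inf lower asymptote.
#' @return viability at each concentration.
#' @export
hill_curve <- function(conc, ec50, slope, e_inf) {
  e_inf + (1 - e_inf) / (1 + (conc / ec50)^slope)
}

hill_auc_value <- function(ec50, slope, e_inf, dose_range, n_grid = 201) {
  lg <- seq(log10(dose_range[1]), log10(dose_range[2]), length.out = n_grid)
  v <- hill_curve(10^lg, ec50, slope, e_inf)
  loss <- 1 - pmin(v, 1)
  # trapezoidal mean over the tested log10-dose interval
  sum((loss[-1] + loss[-n_grid]) / 2) / (n_grid - 1)
}

#' Fit a Hill dose-response curve and compute its AUC
#'
#' Least-squares fit of `v(c) = E_inf + (1 - E_inf) / (1 + (c/EC50)^h)`
#' with the top asymptote fixed at 1 (post plate normalization). The
#' AUC is the mean of `1 - min(v(c), 1)` over the tested log10-dose
#' interval: 0 for no effect, approaching 1 for complete kill at all
#' doses. If the optimizer fails, a trapezoid AUC over the observed
#' responses is returned with `converged = FALSE`.
#'
#' @param doses dose vector in molar (>= 4 distinct values).
#' @param responses normalized viability values (same length).
#' @return object of class `HillFit`: `ec50`, `slope`, `e_inf`, `auc`,
#'   `converged`, `residuals`.
#' @export
fit_hill_auc <- function(doses, responses) {
  if (any(!is.finite(doses)) || any(!is.finite(responses)))
    stop("doses and responses must be finite")
  if (length(unique(doses)) < 4) stop("need >= 4 distinct doses")
  if (any(responses < 0)) responses <- pmax(responses, 0)
  dr <- range(doses)
  e0 <- max(0, min(1, min(tapply(responses, doses, mean))))
  starts <- expand.grid(log_ec50 = log(c(sort(unique(doses)),
                                         exp(mean(log(dr))))),
                        slope = c(1, 2), e_inf = e0)
  fit <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ e_inf + (1 - e_inf) / (1 + (doses / exp(log_ec50))^slope),
        start = as.list(starts[i, ]),
        lower = c(log_ec50 = log(dr[1]) - log(1e4), slope = 0.05, e_inf = 0),
        upper = c(log_ec50 = log(dr[2]) + log(1e4), slope = 10, e_inf = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      rss <- sum(stats::residuals(cand)^2)
      if (rss < best_rss) { best_rss <- rss; fit <- cand }
    }
  }
  if (is.null(fit)) {
    ord <- order(doses)
    lg <- log10(doses[ord]); rs <- pmin(responses[ord], 1)
    loss <- 1 - rs
    auc <- sum(diff(lg) * (loss[-1] + loss[-length(loss)]) / 2) /
      (max(lg) - min(lg))
    return(structure(list(ec50 = NA_real_, slope = NA_real_,
                          e_inf = NA_real_, auc = auc, converged = FALSE,
                          residuals = rep(NA_real_, length(doses))),
                     class = "HillFit"))
  }
  cf <- stats::coef(fit)
  ec50 <- exp(cf[["log_ec50"]])
  auc <- hill_auc_value(ec50, cf[["slope"]], cf[["e_inf"]], dr)
  structure(list(ec50 = ec50, slope = cf[["slope"]], e_inf = cf[["e_inf"]],
                 auc = auc, converged = TRUE,
                 residuals = stats::residuals(fit)),
            class = "HillFit")
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf("HillFit: EC50 = %.3g M, slope = %.2f, E_inf = %.2f, AUC = %.3f%s\n",
              x$ec50, x$slope, x$e_inf, x$auc,
              if (x$converged) "" else " (fallback trapezoid)"))
  invisible(x)
}
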