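# ---- library specifications ---------------------------------------------

#' Clinical-style compound library specification
#'
#' One row per drug x concentration. Concentrations follow a five-fold
#' dilution series from `top_conc` downwards, the design used for
#' clinically relevant libraries screened at five doses.
#'
#' @param n_drugs number of drugs (default 63).
#' @param n_conc concentrations per drug (default 5, five-fold dilutions).
#' @param top_conc highest concentration in molar (default 2.5e-6).
#' @param targets optional character vector of target annotations recycled
#'   across drugs; defaults to generic target groups.
#' @return data.frame with columns `drug`, `target`, `concentration`.
#' @export
clinical_library_spec <- function(n_drugs = 63, n_conc = 5, top_conc = 2.5e-6,
                                  targets = NULL) {
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  if (is.null(targets)) {
    targets <- rep(sprintf("target_%02d", seq_len(max(1L, n_drugs %/% 5L))),
                   length.out = n_drugs)
  } else {
    targets <- rep(targets, length.out = n_drugs)
  }
  conc <- top_conc / 5^(seq_len(n_conc) - 1L)
  data.frame(
    drug = rep(drugs, each = n_conc),
    target = rep(targets, each = n_conc),
    concentration = rep(conc, n_drugs),
    stringsAsFactors = FALSE
  )
}

#' Kinase/stemness-style library specification (single dose)
#'
#' @param n_drugs number of drugs (default 464).
#' @param conc single screening concentration in molar (default 7.5e-6).
#' @param targets optional target annotations.
#' @return data.frame with columns `drug`, `target`, `concentration`.
#' @export
kistem_library_spec <- function(n_drugs = 464, conc = 7.5e-6, targets = NULL) {
  spec <- clinical_library_spec(n_drugs = n_drugs, n_conc = 1,
                                top_conc = conc, targets = targets)
  spec$drug <- sprintf("kdrug_%03d", match(spec$drug, unique(spec$drug)))
  spec
}

# ---- plate layout --------------------------------------------------------

#' Generate randomized 384-well plate layouts
#'
#' Assigns every drug x concentration unit of `library_spec` to wells of
#' 16 x 24 plates in a seeded random order. Each plate carries its own
#' DMSO negative controls and bortezomib / SN-38 positive controls (the
#' two highest concentrations of each). Libraries that exceed the free
#' capacity of one plate are split across as many plates as needed, each
#' with a full set of controls. One set of plates is produced per line
#' and replicate.
#'
#' @param n_lines number of organoid lines.
#' @param library_spec data.frame with columns `drug`, `target`,
#'   `concentration` (one row per treatment unit), e.g. from
#'   [clinical_library_spec()].
#' @param controls_per_plate number of DMSO negative-control wells per
#'   plate (default 16; the screening design leaves this free).
#' @param pos_controls_per_plate number of positive-control wells per
#'   plate, split evenly between bortezomib and SN-38 at their two
#'   highest concentrations (default 8).
#' @param replicates biological replicates per line (default 1).
#' @param seed integer seed; layouts are reproducible under it.
#' @return data.frame (class `PlateLayout`) with columns `plate_id`,
#'   `row`, `col`, `line_id`, `treatment`, `concentration`, `role`,
#'   `batch_id`, `replicate`.
#' @export
generate_plate_layout <- function(n_lines = 1, library_spec,
                                  controls_per_plate = 16,
                                  pos_controls_per_plate = 8,
                                  replicates = 1, seed = 1) {
  stopifnot(is.data.frame(library_spec),
            all(c("drug", "concentration") %in% names(library_spec)))
  n_controls <- controls_per_plate + pos_controls_per_plate
  capacity <- 384L - n_controls
  if (capacity < 1L)
    stop("requested control wells exceed 384-well plate capacity")
  n_units <- nrow(library_spec)
  n_plates <- max(1L, ceiling(n_units / capacity))

  pos_conc <- c(2.5e-6, 0.5e-6)  # top two of the five-fold series
  n_pos_each <- pos_controls_per_plate %/% 2L
  pos_df <- data.frame(
    treatment = rep(c("bortezomib", "SN-38"), each = n_pos_each),
    concentration = rep(rep(pos_conc, length.out = n_pos_each), 2L),
    stringsAsFactors = FALSE
  )

  set.seed(seed)
  out <- vector("list", n_lines * replicates * n_plates)
  idx <- 1L
  for (l in seq_len(n_lines)) {
    line_id <- sprintf("line_%02d", l)
    for (r in seq_len(replicates)) {
      for (p in seq_len(n_plates)) {
        units <- library_spec[seq.int(from = (p - 1L) * capacity + 1L,
                                      length.out = min(capacity, max(0L, n_units - (p - 1L) * capacity))), ,
                              drop = FALSE]
        n_assigned <- nrow(units) + n_controls
        if (n_assigned > 384L)
          stop("requested wells > 384 on a single plate")
        wells <- expand.grid(row = 1:16, col = 1:24)
        wells <- wells[sample.int(384L, n_assigned), , drop = FALSE]
        treatment <- c(rep("DMSO", controls_per_plate),
                       pos_df$treatment, units$drug)
        concentration <- c(rep(NA_real_, controls_per_plate),
                           pos_df$concentration, units$concentration)
        role <- c(rep("negative_control", controls_per_plate),
                  rep("positive_control", nrow(pos_df)),
                  rep("library", nrow(units)))
        out[[idx]] <- data.frame(
          plate_id = sprintf("%s_R%d_P%02d", line_id, r, p),
          row = wells$row, col = wells$col,
          line_id = line_id,
          treatment = treatment,
          concentration = concentration,
          role = role,
          batch_id = sprintf("%s_R%d", line_id, r),
          replicate = r,
          stringsAsFactors = FALSE
        )
        idx <- idx + 1L
      }
    }
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  class(layout) <- c("PlateLayout", "data.frame")
  layout
}

# ---- image stack simulation ---------------------------------------------

#' Parameters for synthetic organoid image stacks
#'
#' @param image_size y/x extent in pixels.
#' @param n_organoids organoids per field.
#' @param radius_range min/max organoid radius in pixels.
#' @param mode `"solid"`, `"cystic"`, or `"mixed"` architecture.
#' @param dead_fraction fraction of organoids rendered as dead particles
#'   (small, permeability-bright).
#' @param n_slices z-slices per stack (default 16, 5 um steps).
#' @param focus_sigma z-extent (in slices) of the in-focus intensity
#'   envelope around each organoid's focal plane.
#' @param noise_sd additive Gaussian noise sd.
#' @param blur_sd Gaussian PSF blur sd in pixels (0 = none).
#' @param ring_width cystic actin ring width in pixels.
#' @param ring_contrast actin intensity excess of the ring over the lumen.
#' @return list of validated parameters.
#' @export
image_sim_params <- function(image_size = c(96, 96), n_organoids = 8,
                             radius_range = c(8, 14), mode = "solid",
                             dead_fraction = 0, n_slices = 16,
                             focus_sigma = 2.5, noise_sd = 0.01,
                             blur_sd = 0, ring_width = 2,
                             ring_contrast = 0.4) {
  if (any(image_size <= 0)) stop("image dimensions must be positive")
  if (n_organoids < 0) stop("n_organoids must be >= 0")
  mode <- match.arg(mode, c("solid", "cystic", "mixed"))
  list(image_size = image_size, n_organoids = n_organoids,
       radius_range = radius_range, mode = mode,
       dead_fraction = dead_fraction, n_slices = n_slices,
       focus_sigma = focus_sigma, noise_sd = noise_sd, blur_sd = blur_sd,
       ring_width = ring_width, ring_contrast = ring_contrast)
}

render_field <- function(params) {
  ny <- params$image_size[1]; nx <- params$image_size[2]
  n <- params$n_organoids
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- matrix(0L, ny, nx)
  base <- list(dna = matrix(0, ny, nx), actin = matrix(0, ny, nx),
               permeability = matrix(0, ny, nx))
  truth <- data.frame(label = integer(0), cy = numeric(0), cx = numeric(0),
                      radius = numeric(0), z0 = integer(0),
                      dead = logical(0), cystic = logical(0))
  zmod <- matrix(0, nrow = max(n, 1L), ncol = params$n_slices)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 200L * max(n, 1L)) {
    tries <- tries + 1L
    dead <- stats::runif(1) < params$dead_fraction
    r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
    if (dead) r <- max(3, r * 0.5)
    cy <- stats::runif(1, r + 2, ny - r - 2)
    cx <- stats::runif(1, r + 2, nx - r - 2)
    if (placed > 0) {
      dd <- sqrt((truth$cy - cy)^2 + (truth$cx - cx)^2)
      if (any(dd < truth$radius + r + 3)) next
    }
    placed <- placed + 1L
    cystic <- switch(params$mode, solid = FALSE, cystic = TRUE,
                     mixed = stats::runif(1) < 0.5)
    d2 <- (yy - cy)^2 + (xx - cx)^2
    inside <- d2 <= r^2
    mask[inside] <- placed
    base$dna[inside] <- base$dna[inside] + 0.6
    if (cystic && !dead) {
      ring <- d2 <= r^2 & d2 >= (r - params$ring_width)^2
      lumen <- d2 < (r - params$ring_width)^2
      base$actin[ring] <- base$actin[ring] + 0.1 + params$ring_contrast
      base$actin[lumen] <- base$actin[lumen] + 0.1
    } else {
      base$actin[inside] <- base$actin[inside] + if (dead) 0.25 else 0.5
    }
    base$permeability[inside] <- base$permeability[inside] +
      if (dead) 0.8 else 0.05
    z0 <- sample(4:(params$n_slices - 4L), 1L)
    zmod[placed, ] <- exp(-0.5 * ((seq_len(params$n_slices) - z0) /
                                    params$focus_sigma)^2)
    truth <- rbind(truth, data.frame(label = placed, cy = cy, cx = cx,
                                     radius = r, z0 = z0, dead = dead,
                                     cystic = cystic))
  }
  list(base = base, mask = mask, truth = truth, zmod = zmod)
}

#' Simulate multi-channel 3D organoid image stacks with ground truth
#'
#' Renders fields of disk-shaped organoids into 3-channel (DNA, actin,
#' permeability) stacks of `n_slices` z-slices. Cystic organoids appear
#' as a bright actin ring around a dark lumen, solid organoids as filled
#' disks; dead organoids are small with a strong permeability signal.
#' Each organoid is sharpest at its own focal slice, with intensity
#' falling off along z, so maximum-contrast projection is exercised.
#'
#' @param n_fields number of independent fields to render.
#' @param params configuration from [image_sim_params()].
#' @param seed integer seed.
#' @return list of fields; each field is a list with `stack` (array
#'   `[channel, z, y, x]` with channel dimnames), `mask` (y x x integer
#'   ground-truth label matrix) and `truth` (per-organoid data.frame).
#' @export
simulate_image_stacks <- function(n_fields = 1, params = image_sim_params(),
                                  seed = 1) {
  if (any(params$image_size <= 0)) stop("image dimensions must be positive")
  set.seed(seed)
  fields <- vector("list", n_fields)
  ny <- params$image_size[1]; nx <- params$image_size[2]
  chans <- c("dna", "actin", "permeability")
  for (f in seq_len(n_fields)) {
    rf <- render_field(params)
    stack <- array(0, dim = c(3, params$n_slices, ny, nx),
                   dimnames = list(chans, NULL, NULL, NULL))
    bg <- 0.02
    for (z in seq_len(params$n_slices)) {
      for (ch in chans) {
        sl <- matrix(bg, ny, nx)
        if (nrow(rf$truth) > 0) {
          for (k in seq_len(nrow(rf$truth))) {
            pix <- rf$mask == k
            sl[pix] <- bg + (rf$base[[ch]][pix]) * rf$zmod[k, z]
          }
        }
        if (params$blur_sd > 0)
          sl <- t(as.matrix(EBImage::gblur(EBImage::Image(t(sl)),
                                           sigma = params$blur_sd)))
        if (params$noise_sd > 0)
          sl <- sl + matrix(stats::rnorm(ny * nx, 0, params$noise_sd), ny, nx)
        stack[ch, z, , ] <- pmax(sl, 0)
      }
    }
    fields[[f]] <- list(
      stack = image_stack(stack, pixel_size = 1.3, z_step = 5,
                          metadata = list(field = f)),
      mask = rf$mask, truth = rf$truth)
  }
  fields
}

# ---- feature table simulation -------------------------------------------

sim_feature_names <- function() {
  c("area", sprintf("morph_%02d", 1:10),
    "dna_int_mean", "dna_int_sd", "dna_tex_energy",
    "actin_int_mean", "actin_int_sd", "actin_tex_energy",
    "perm_int_mean", "perm_int_sd")
}

#' Effect configuration for the per-organoid feature simulator
#'
#' Defines line-specific bimodal (two-component log-normal) size
#' mixtures, per-treatment mean-shift directions shared within
#' mechanism-of-action (MoA) groups, and per-dose death fractions.
#'
#' @param lines named list; each element a list with `weights` (2),
#'   `logmeans` (2), `logsds` (2) for the size mixture and optionally
#'   `morph_base` (length-10 morphology baseline). Defaults to three
#'   lines spanning the size range seen across organoid donors.
#' @param treatments named list; each element a list with `shift`
#'   (length-10 morphology shift direction times magnitude), `moa`
#'   (group label) and `death_fraction` (scalar in `[0, 1]`, or a
#'   function of concentration given `max_conc`).
#' @param organoids_per_well organoids simulated per well.
#' @param shift_noise_sd sd of organoid-level noise on morphology axes.
#' @param positive_control_death death fraction in positive-control wells
#'   (default 1: high-dose proteasome/topoisomerase control wells kill
#'   essentially all organoids).
#' @param dead_logmean,dead_logsd log-normal parameters of the dead
#'   particle size cluster (default log(400) and 0.2: dead organoids
#'   collapse to small high-permeability particles).
#' @return list configuration.
#' @export
effect_config <- function(lines = NULL, treatments = NULL,
                          organoids_per_well = 50, shift_noise_sd = 1,
                          positive_control_death = 1,
                          dead_logmean = log(400), dead_logsd = 0.2) {
  if (is.null(lines)) {
    lines <- list(
      line_01 = list(weights = c(0.4, 0.6), logmeans = c(4.0, 6.5),
                     logsds = c(0.35, 0.35)),
      line_02 = list(weights = c(0.5, 0.5), logmeans = c(4.2, 7.2),
                     logsds = c(0.35, 0.3)),
      line_03 = list(weights = c(0.3, 0.7), logmeans = c(4.1, 6.0),
                     logsds = c(0.3, 0.35))
    )
  }
  for (nm in names(lines)) {
    if (is.null(lines[[nm]]$morph_base))
      lines[[nm]]$morph_base <- rep(0, 10)
  }
  if (is.null(treatments)) treatments <- list()
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    if (is.null(tr$death_fraction)) treatments[[nm]]$death_fraction <- 0
    if (is.null(tr$moa)) treatments[[nm]]$moa <- "unannotated"
    if (is.null(tr$shift)) treatments[[nm]]$shift <- rep(0, 10)
    df <- treatments[[nm]]$death_fraction
    if (is.numeric(df) && (any(df < 0) || any(df > 1)))
      stop("death fraction outside [0,1]")
  }
  list(lines = lines, treatments = treatments,
       organoids_per_well = organoids_per_well,
       shift_noise_sd = shift_noise_sd,
       positive_control_death = positive_control_death,
       dead_logmean = dead_logmean, dead_logsd = dead_logsd)
}

#' Orthogonal mechanism-of-action groups for simulation
#'
#' Builds a treatment configuration with `n_groups` MoA groups of
#' `drugs_per_group` drugs; drugs within a group share a base shift
#' direction (orthogonal unit morphology axes across groups) with a
#' small within-group angular perturbation.
#'
#' @param n_groups number of MoA groups (<= 10).
#' @param drugs_per_group drugs per group.
#' @param magnitude shift magnitude in units of organoid noise sd.
#' @param within_sd sd of within-group direction perturbation.
#' @param death_fraction death fraction applied to all drugs (scalar or
#'   per-group vector).
#' @param seed integer seed.
#' @return named list of treatment configurations for [effect_config()].
#' @export
moa_treatment_config <- function(n_groups = 3, drugs_per_group = 5,
                                 magnitude = 3, within_sd = 0.15,
                                 death_fraction = 0, seed = 1) {
  stopifnot(n_groups <= 10)
  set.seed(seed)
  death_fraction <- rep(death_fraction, length.out = n_groups)
  out <- list()
  for (g in seq_len(n_groups)) {
    dir0 <- rep(0, 10); dir0[g] <- 1
    for (d in seq_len(drugs_per_group)) {
      v <- dir0 + stats::rnorm(10, 0, within_sd)
      v <- v / sqrt(sum(v^2))
      out[[sprintf("moa%02d_drug%02d", g, d)]] <- list(
        shift = v * magnitude,
        moa = sprintf("moa_%02d", g),
        death_fraction = death_fraction[g])
    }
  }
  out
}

#' Simulate a per-organoid feature table with ground truth
#'
#' Per-organoid feature vectors are the line baseline plus the
#' treatment's shift direction scaled by dose plus organoid-level
#' Gaussian noise. Organoid sizes follow line-specific two-component
#' log-normal mixtures. Dead organoids are drawn from a distinct
#' small-size, high-permeability, low-actin-texture cluster; the
#' per-well dead count is binomial at the configured death fraction.
#'
#' @param layout `PlateLayout` from [generate_plate_layout()].
#' @param params configuration from [effect_config()].
#' @param seed integer seed.
#' @return list with `fm` (a [feature_matrix()]) and `truth` (list with
#'   per-organoid ground truth, treatment shift vectors and MoA map).
#' @export
simulate_feature_table <- function(layout, params = effect_config(), seed = 1) {
  stopifnot(is.data.frame(layout))
  set.seed(seed)
  fn <- sim_feature_names()
  meta_l <- list(); feat_l <- list(); truth_l <- list()
  max_conc <- suppressWarnings(max(layout$concentration, na.rm = TRUE))
  # dose scaling is linear in log-concentration across each drug's tested
  # series (equal steps for a geometric dilution series)
  conc_rank <- function(trt, conc) {
    cc <- sort(unique(layout$concentration[layout$treatment == trt &
                                             !is.na(layout$concentration)]))
    if (length(cc) == 0 || is.na(conc)) return(1)
    match(conc, cc) / length(cc)
  }
  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    line_cfg <- params$lines[[w$line_id]]
    if (is.null(line_cfg))
      line_cfg <- params$lines[[1L + (match(w$line_id, unique(layout$line_id)) - 1L) %% length(params$lines)]]
    n <- params$organoids_per_well
    tr <- params$treatments[[w$treatment]]
    dose_scale <- conc_rank(w$treatment, w$concentration)
    if (w$treatment == "DMSO") {
      shift <- rep(0, 10); dfrac <- 0
    } else if (!is.null(tr)) {
      shift <- tr$shift * dose_scale
      dfrac <- if (is.function(tr$death_fraction))
        tr$death_fraction(w$concentration, max_conc) else tr$death_fraction
    } else if (w$role == "positive_control") {
      shift <- rep(0, 10); dfrac <- params$positive_control_death
    } else {
      shift <- rep(0, 10); dfrac <- 0
    }
    if (dfrac < 0 || dfrac > 1) stop("death fraction outside [0,1]")
    dead <- stats::runif(n) < dfrac
    comp <- 1L + (stats::runif(n) < line_cfg$weights[2])
    area <- exp(stats::rnorm(n, line_cfg$logmeans[comp], line_cfg$logsds[comp]))
    area[dead] <- exp(stats::rnorm(sum(dead), params$dead_logmean,
                                   params$dead_logsd))
    morph <- matrix(stats::rnorm(n * 10, 0, params$shift_noise_sd), n, 10)
    morph <- sweep(morph, 2, line_cfg$morph_base + shift, "+")
    morph[dead, ] <- matrix(stats::rnorm(sum(dead) * 10, 0,
                                         0.5 * params$shift_noise_sd),
                            sum(dead), 10)
    morph[dead, 1] <- morph[dead, 1] - 4  # dead cluster offset
    x <- cbind(
      area,
      morph,
      dna_int_mean = stats::rnorm(n, ifelse(dead, 0.45, 0.55), 0.04),
      dna_int_sd = stats::rnorm(n, ifelse(dead, 0.05, 0.10), 0.01),
      dna_tex_energy = stats::rnorm(n, ifelse(dead, 0.5, 0.9), 0.08),
      actin_int_mean = stats::rnorm(n, ifelse(dead, 0.35, 0.55), 0.05),
      actin_int_sd = stats::rnorm(n, ifelse(dead, 0.04, 0.12), 0.015),
      actin_tex_energy = stats::rnorm(n, ifelse(dead, 0.30, 1.0), 0.08),
      perm_int_mean = stats::rnorm(n, ifelse(dead, 0.70, 0.08), 0.03),
      perm_int_sd = stats::rnorm(n, ifelse(dead, 0.12, 0.03), 0.01)
    )
    colnames(x) <- fn
    meta_l[[i]] <- data.frame(
      organoid_id = sprintf("%s_r%02dc%02d_o%03d", w$plate_id, w$row, w$col,
                            seq_len(n)),
      plate_id = w$plate_id, row = w$row, col = w$col, field = 1L,
      line_id = w$line_id, treatment = w$treatment,
      concentration = w$concentration, role = w$role,
      batch_id = w$batch_id, replicate = w$replicate,
      area_px = round(area),
      stringsAsFactors = FALSE
    )
    feat_l[[i]] <- x
    truth_l[[i]] <- data.frame(true_dead = dead,
                               true_size_component = c("small", "large")[comp],
                               true_line_id = w$line_id,
                               stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_l)
  rownames(meta) <- NULL
  shifts <- lapply(params$treatments, function(tr) tr$shift)
  moa <- vapply(params$treatments, function(tr) tr$moa, character(1))
  list(
    fm = feature_matrix(do.call(rbind, feat_l), meta),
    truth = list(organoids = do.call(rbind, truth_l),
                 shift_vectors = shifts, moa = moa)
  )
}

# ---- multi-view simulation ----------------------------------------------

#' Simulate a multi-view dataset from a known linear factor model
#'
#' Generates `n_samples` observations (paired replicates of
#' `n_samples / 2` lines sharing factor scores up to a small jitter)
#' with `k` latent factors and one data matrix per view:
#' `Y_v = Z W_v' + noise`. Factor strengths decay across factors,
#' emulating the decreasing per-factor variance typical of factor
#' analyses of multi-omic data. The mutation view is binarized by
#' thresholding its latent Gaussian at the configured prevalence and
#' may drop samples to mimic incomplete mutation profiling.
#'
#' @param n_samples number of samples (default 22 = 11 lines x 2).
#' @param k number of latent factors (default 3).
#' @param view_dims named integer vector of feature counts per view;
#'   defaults to `c(size = 1, mutations = 12, expression = 3222,
#'   morphology = 25, drug_activity = 252)`.
#' @param noise_frac named (or scalar) noise sd as a fraction of each
#'   view's signal sd (default 0.3).
#' @param factor_strength per-factor signal scale (default
#'   `c(1, 0.7, 0.45)` truncated/recycled to `k`).
#' @param replicate_jitter_sd sd of the replicate-level jitter on shared
#'   factor scores (default 0.1, i.e. 0.1 x signal sd).
#' @param mutation_prevalence expected fraction of 1s per mutation
#'   feature (default 0.3).
#' @param missing_mutation_samples number of samples absent from the
#'   mutation view (default 2, matching incomplete profiling).
#' @param seed integer seed.
#' @return list with `views` (named list of matrices with sample
#'   rownames), and `truth` (list with `Z`, `W`, `noise_sd`,
#'   `lines`).
#' @export
simulate_multiview <- function(n_samples = 22, k = 3,
                               view_dims = c(size = 1, mutations = 12,
                                             expression = 3222,
                                             morphology = 25,
                                             drug_activity = 252),
                               noise_frac = 0.3,
                               factor_strength = c(1, 0.7, 0.45),
                               replicate_jitter_sd = 0.1,
                               mutation_prevalence = 0.3,
                               missing_mutation_samples = 2,
                               seed = 1) {
  if (n_samples < k) stop("n_samples must be >= k")
  if (n_samples %% 2 != 0) stop("n_samples must be even (paired replicates)")
  set.seed(seed)
  n_lines <- n_samples %/% 2L
  strength <- rep(factor_strength, length.out = k)
  Zl <- matrix(stats::rnorm(n_lines * k), n_lines, k)
  # realized factor scores are decorrelated (factor models assume
  # uncorrelated scores); distinct strengths keep factors identifiable
  Zl <- qr.Q(qr(Zl)) * sqrt(n_lines)
  Z <- Zl[rep(seq_len(n_lines), each = 2L), , drop = FALSE] +
    matrix(stats::rnorm(n_samples * k, 0, replicate_jitter_sd), n_samples, k)
  Z <- sweep(Z, 2, strength, "*")
  samples <- sprintf("line_%02d_rep%d", rep(seq_len(n_lines), each = 2L),
                     rep(1:2, n_lines))
  rownames(Z) <- samples
  if (length(noise_frac) == 1L)
    noise_frac <- stats::setNames(rep(noise_frac, length(view_dims)),
                                  names(view_dims))
  views <- list(); W <- list(); noise_sd <- numeric(0)
  for (v in names(view_dims)) {
    d <- view_dims[[v]]
    Wv <- matrix(stats::rnorm(d * k), d, k)
    S <- Z %*% t(Wv)
    sig_sd <- stats::sd(as.numeric(S))
    ns <- noise_frac[[v]] * sig_sd
    Y <- S + matrix(stats::rnorm(n_samples * d, 0, ns), n_samples, d)
    rownames(Y) <- samples
    colnames(Y) <- sprintf("%s_f%04d", v, seq_len(d))
    if (v == "mutations") {
      thr <- apply(Y, 2, stats::quantile, probs = 1 - mutation_prevalence)
      Y <- sweep(Y, 2, thr, ">") * 1L
      if (missing_mutation_samples > 0) {
        drop <- sample(samples, missing_mutation_samples)
        Y <- Y[!(rownames(Y) %in% drop), , drop = FALSE]
      }
    }
    views[[v]] <- Y
    W[[v]] <- Wv
    noise_sd[v] <- ns
  }
  list(views = views,
       truth = list(Z = Z, W = W, noise_sd = noise_sd,
                    lines = rep(seq_len(n_lines), each = 2L)))
}
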