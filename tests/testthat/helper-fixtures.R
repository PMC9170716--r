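# Shared fixtures and independent oracles, built in code.

# brute-force maximum-contrast projection: per channel and pixel, loop
# over z and compute neighbourhood variance explicitly
oracle_max_contrast <- function(stack, window = 3) {
  px <- stack$pixels
  d <- dim(px)
  r <- (window - 1) %/% 2
  proj <- array(0, dim = d[c(1, 3, 4)], dimnames = dimnames(px)[c(1, 3, 4)])
  zmap <- array(0L, dim = d[c(1, 3, 4)])
  for (ch in seq_len(d[1])) {
    for (y in seq_len(d[3])) {
      for (x in seq_len(d[4])) {
        best <- -Inf; bz <- 1L
        for (z in seq_len(d[2])) {
          ys <- max(1, y - r):min(d[3], y + r)
          xs <- max(1, x - r):min(d[4], x + r)
          vals <- px[ch, z, ys, xs]
          v <- mean(vals^2) - mean(vals)^2
          if (v > best) { best <- v; bz <- z }
        }
        proj[ch, y, x] <- px[ch, bz, y, x]
        zmap[ch, y, x] <- bz - 1L
      }
    }
  }
  list(pixels = proj, z_index_map = zmap)
}

random_stack <- function(n_slices = 5, ny = 8, nx = 8, n_chan = 1,
                         seed = 1) {
  set.seed(seed)
  px <- array(stats::runif(n_chan * n_slices * ny * nx),
              dim = c(n_chan, n_slices, ny, nx),
              dimnames = list(c("dna", "actin", "permeability")[seq_len(n_chan)],
                              NULL, NULL, NULL))
  image_stack(px)
}

# brute-force GSEA running-sum enrichment score
oracle_gsea_es <- function(stats, gene_set, weight = 1) {
  r <- stats[order(stats, decreasing = TRUE)]
  hit <- names(r) %in% gene_set
  absr <- abs(r)^weight
  nr <- sum(absr[hit])
  run <- cumsum(ifelse(hit, absr / nr, -1 / sum(!hit)))
  run[which.max(abs(run))]
}

# two-component Gaussian mixture fit (EM oracle for size mixtures)
fit_mixture2 <- function(x) {
  mclustBIC <- mclust::mclustBIC
  mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
}

# small control-anchored plate with live and dead organoids for one or
# more lines; death is clearly separable (distinct dead cluster)
ldc_fixture <- function(n_lines = 1, organoids_per_well = 30,
                        extra_treatments = NULL, controls_per_plate = 16,
                        pos_controls_per_plate = 8, seed = 1) {
  spec <- clinical_library_spec(n_drugs = 2)
  lay <- generate_plate_layout(n_lines, spec,
                               controls_per_plate = controls_per_plate,
                               pos_controls_per_plate = pos_controls_per_plate,
                               seed = seed)
  cfg <- effect_config(treatments = extra_treatments,
                       organoids_per_well = organoids_per_well)
  simulate_feature_table(lay, cfg, seed = seed + 1)
}
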