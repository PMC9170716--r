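make_projected <- function(img_list) {
  # build a ProjectedImage from named (y, x) matrices
  chans <- names(img_list)
  ny <- nrow(img_list[[1]]); nx <- ncol(img_list[[1]])
  px <- array(0, c(length(chans), ny, nx),
              dimnames = list(chans, NULL, NULL))
  for (ch in chans) px[ch, , ] <- img_list[[ch]]
  structure(list(pixels = px,
                 z_index_map = array(0L, c(length(chans), ny, nx))),
            class = "ProjectedImage")
}

disk_mask <- function(ny, nx, cy, cx, r, label = 1L) {
  yy <- matrix(seq_len(ny), ny, nx); xx <- t(matrix(seq_len(nx), nx, ny))
  m <- matrix(0L, ny, nx)
  m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- label
  m
}

test_that("uniform disks yield zero intensity sd and sane shape features", {
  ny <- nx <- 64
  m <- disk_mask(ny, nx, 32, 32, 12)
  img <- make_projected(list(dna = 0.5 * (m > 0), actin = 0.5 * (m > 0),
                             permeability = 0.1 * (m > 0)))
  fm <- extract_organoid_features(img, m)
  expect_equal(nrow(fm$x), 1)
  expect_equal(unname(fm$x[1, "dna_int_sd"]), 0)
  expect_equal(unname(fm$x[1, "actin_int_sd"]), 0)
  expect_gt(fm$meta$area_px, 300)
  expect_gt(fm$x[1, "shape_solidity"], 0.9)
})

test_that("eccentricity orders a circle below a 3:1 ellipse of equal area", {
  ny <- nx <- 80
  yy <- matrix(seq_len(ny), ny, nx); xx <- t(matrix(seq_len(nx), nx, ny))
  r <- 12
  circ <- matrix(0L, ny, nx)
  circ[(yy - 40)^2 + (xx - 40)^2 <= r^2] <- 1L
  a <- r * sqrt(3); b <- r / sqrt(3)  # same area, axis ratio 3
  ell <- matrix(0L, ny, nx)
  ell[((yy - 40) / b)^2 + ((xx - 40) / a)^2 <= 1] <- 1L
  img <- make_projected(list(dna = matrix(0.5, ny, nx),
                             actin = matrix(0.5, ny, nx),
                             permeability = matrix(0.1, ny, nx)))
  f_c <- extract_organoid_features(img, circ)
  f_e <- extract_organoid_features(img, ell)
  expect_lt(f_c$x[1, "moment_eccentricity"], f_e$x[1, "moment_eccentricity"])
})

test_that("Haralick contrast separates checkerboard from uniform texture", {
  ny <- nx <- 34
  m <- matrix(0L, ny, nx); m[2:33, 2:33] <- 1L
  chk <- matrix(0.2, ny, nx)
  chk[2:33, 2:33] <- 0.2 + 0.6 * ((row(chk) + col(chk)) %% 2)[2:33, 2:33]
  uni <- matrix(0.5, ny, nx)
  base <- list(actin = matrix(0.3, ny, nx), permeability = matrix(0.1, ny, nx))
  f_chk <- extract_organoid_features(make_projected(c(list(dna = chk), base)), m)
  f_uni <- extract_organoid_features(make_projected(c(list(dna = uni), base)), m)
  expect_gt(f_chk$x[1, "dna_tex_con.s1"], f_uni$x[1, "dna_tex_con.s1"])
})

test_that("MAD filtering drops ill-defined columns by the strict > 0 rule", {
  set.seed(1)
  n <- 20
  x <- cbind(
    good = rnorm(n),
    constant = rep(3, n),
    half_tied = c(rep(0, n / 2), seq_len(n / 2)),      # MAD > 0 -> kept
    mostly_tied = c(rep(0, n / 2 + 1), seq_len(n / 2 - 1))  # MAD = 0 -> dropped
  )
  meta <- data.frame(organoid_id = sprintf("o%02d", 1:n),
                     area_px = rep(1000L, n), batch_id = "b1")
  out <- filter_and_center_features(feature_matrix(x, meta))
  expect_setequal(colnames(out$x), c("good", "half_tied"))
  # sanity: the dropped columns have MAD exactly 0
  expect_equal(stats::mad(x[, "constant"]), 0)
  expect_equal(stats::mad(x[, "mostly_tied"]), 0)
  expect_gt(stats::mad(x[, "half_tied"]), 0)
})

test_that("texture offsets above the smallest organoid diameter are dropped", {
  set.seed(2)
  n <- 40
  x <- cbind("dna_tex_con.s1" = rnorm(n), "dna_tex_con.s2" = rnorm(n),
             "dna_tex_con.s8" = rnorm(n), "dna_tex_con.s16" = rnorm(n),
             shape_area = rnorm(n, 100))
  # smallest organoids ~ radius 5 -> equivalent diameter ~ 10
  meta <- data.frame(area_px = as.integer(c(rep(78, 5), rep(700, 35))),
                     batch_id = "b1")
  out <- filter_and_center_features(feature_matrix(x, meta))
  expect_true("dna_tex_con.s8" %in% colnames(out$x))
  expect_false("dna_tex_con.s16" %in% colnames(out$x))
})

test_that("batch centering zeroes per-batch means and is idempotent", {
  set.seed(3)
  n <- 60
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  x[31:60, "f1"] <- x[31:60, "f1"] + 10
  meta <- data.frame(area_px = rep(800L, n),
                     batch_id = rep(c("b1", "b2"), each = 30))
  out <- filter_and_center_features(feature_matrix(x, meta))
  expect_equal(mean(out$x[1:30, "f1"]), 0, tolerance = 1e-12)
  expect_equal(mean(out$x[31:60, "f1"]), 0, tolerance = 1e-12)
  twice <- filter_and_center_features(out)
  expect_equal(twice$x, out$x)
  expect_false(anyNA(out$x))
  # NA columns are removed, never imputed
  x2 <- cbind(x, bad = c(NA, rnorm(n - 1)))
  out2 <- filter_and_center_features(feature_matrix(x2, meta))
  expect_false("bad" %in% colnames(out2$x))
  expect_error(filter_and_center_features(
    feature_matrix(cbind(k = rep(1, 10)),
                   data.frame(area_px = rep(500L, 10), batch_id = "b"))),
    "dropped")
})

test_that("PCA recovers exact low-rank structure and matches prcomp", {
  set.seed(4)
  n <- 400; p <- 30
  basis <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  x <- matrix(rnorm(n * 3), n, 3) %*% t(basis) + 5
  colnames(x) <- sprintf("f%02d", 1:p)
  res <- fit_pca_transform(x, n_components = 25)
  expect_lt(sum(res$model$var_explained[4:25]), 1e-10)
  expect_equal(sum(res$model$var_explained[1:3]), 1, tolerance = 1e-10)
  # scores are centered
  expect_lt(max(abs(colMeans(res$scores))), 1e-8)
  # full-batch oracle
  pc <- stats::prcomp(x)
  for (j in 1:3) {
    expect_gt(abs(stats::cor(res$scores[, j], pc$x[, j])), 0.999)
  }
})

test_that("chunked PCA equals the full-batch subspace", {
  set.seed(5)
  x <- matrix(rnorm(5000 * 100), 5000, 100) %*%
    diag(seq(3, 0.5, length.out = 100))
  colnames(x) <- sprintf("f%03d", 1:100)
  chunked <- fit_pca_transform(x, n_components = 10, chunk_size = 777)
  full <- fit_pca_transform(x, n_components = 10, chunk_size = 1e6)
  for (j in 1:10) {
    expect_gt(abs(stats::cor(chunked$scores[, j], full$scores[, j])), 0.999)
  }
  expect_error(fit_pca_transform(x, n_components = 101), "exceeds")
})

test_that("isotropic data spreads variance evenly over components", {
  # sample eigenvalues concentrate at 1 only for n >> p (Marchenko-Pastur
  # spread is ~ 2 sqrt(p/n)), so the even-spread check uses a tall matrix
  set.seed(6)
  p <- 100; n <- 40000
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("f%03d", 1:p)
  res <- fit_pca_transform(x, n_components = 25, chunk_size = 10000)
  got <- sum(res$model$var_explained)
  expect_lt(abs(got - 25 / p) / (25 / p), 0.10)
})

test_that("out-of-focus flagging separates blurred from sharp organoids", {
  sharp <- simulate_image_stacks(2, image_sim_params(n_organoids = 8,
                                                     noise_sd = 0.01,
                                                     image_size = c(128, 128)),
                                 seed = 21)
  blurred <- simulate_image_stacks(2, image_sim_params(n_organoids = 8,
                                                       noise_sd = 0.01,
                                                       blur_sd = 8,
                                                       image_size = c(128, 128)),
                                   seed = 22)
  fms <- lapply(c(sharp, blurred), function(f) {
    pr <- max_contrast_project(f$stack)
    extract_organoid_features(pr, f$mask)
  })
  fm <- do.call(fm_rbind, fms)
  n_sharp <- sum(vapply(fms[1:2], function(f) nrow(f$x), numeric(1)))
  is_blur <- c(rep(FALSE, n_sharp), rep(TRUE, nrow(fm$x) - n_sharp))
  # drop NA-containing columns before classification
  keep <- !apply(fm$x, 2, anyNA)
  fm2 <- feature_matrix(fm$x[, keep], fm$meta)
  set.seed(7)
  lab_idx <- sample(seq_len(nrow(fm2$x)), round(0.6 * nrow(fm2$x)))
  flags <- flag_out_of_focus(fm2, lab_idx, is_blur[lab_idx], seed = 8)
  held <- setdiff(seq_len(nrow(fm2$x)), lab_idx)
  expect_gte(mean(flags[held] == is_blur[held]), 0.95)
  expect_error(flag_out_of_focus(fm2, integer(0), logical(0)), "empty")
  expect_error(flag_out_of_focus(fm2, lab_idx, rep(FALSE, length(lab_idx))),
               "both classes")
})
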