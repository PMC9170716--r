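# ground-truth variance explained: true factor scores with per-view
# least-squares loadings (binarization and scaling change the loading
# scale, so loadings are refit with the true scores held fixed)
true_variance_explained <- function(sim) {
  Zt <- sim$truth$Z
  obsv <- lapply(sim$views, function(Y) match(rownames(Y), rownames(Zt)))
  Wr <- lapply(names(sim$views), function(v) {
    Y <- sim$views[[v]]
    Zv <- Zt[rownames(Y), , drop = FALSE]
    t(solve(crossprod(Zv), crossprod(Zv, Y)))
  })
  names(Wr) <- names(sim$views)
  orgprofiler:::variance_explained(sim$views, Zt, Wr, obsv)
}

match_factors <- function(Zhat, Ztrue) {
  C <- abs(stats::cor(Zhat, Ztrue))
  perm <- integer(ncol(Ztrue))
  avail <- seq_len(ncol(Zhat))
  for (f in order(-apply(C, 2, max))) {
    j <- avail[which.max(C[avail, f])]
    perm[f] <- j
    avail <- setdiff(avail, j)
  }
  perm
}

test_that("factor model recovers known factors from near-noiseless views", {
  sim <- simulate_multiview(noise_frac = 0.01, seed = 1)
  mod <- fit_factor_model(sim$views, k = 3)
  perm <- match_factors(mod$Z, sim$truth$Z)
  cors <- abs(diag(stats::cor(mod$Z[, perm], sim$truth$Z)))
  expect_true(all(cors >= 0.99))
  # objective is non-increasing
  expect_true(all(diff(mod$objective) < 1e-6))
})

test_that("factor recovery and variance decomposition hold at realistic noise", {
  sim <- simulate_multiview(noise_frac = 0.3, seed = 2)
  mod <- fit_factor_model(sim$views, k = 3)
  perm <- match_factors(mod$Z, sim$truth$Z)
  cors <- abs(diag(stats::cor(mod$Z[, perm], sim$truth$Z)))
  expect_true(all(cors >= 0.9))
  vet <- true_variance_explained(sim)
  expect_lt(max(abs(vet - mod$var_explained[perm, ])), 10)
  expect_true(all(mod$var_explained >= 0 & mod$var_explained <= 100))
})

test_that("a view independent of the factors explains almost nothing", {
  # at n = 22 even a random view absorbs ~ k/(n-1) of its variance into
  # refit loadings, so the independence check uses a larger cohort
  sim <- simulate_multiview(n_samples = 50,
                            view_dims = c(morphology = 25, expression = 100),
                            noise_frac = 0.1, seed = 3)
  set.seed(4)
  indep <- matrix(rnorm(50 * 30), 50, 30,
                  dimnames = list(rownames(sim$views$morphology),
                                  sprintf("i%02d", 1:30)))
  views <- c(sim$views, list(independent = indep))
  mod <- fit_factor_model(views, k = 3)
  expect_lt(sum(mod$var_explained[, "independent"]), 10)
  expect_error(fit_factor_model(sim$views, k = 50), "exceed")
})

test_that("missing-view samples are excluded, not imputed", {
  sim <- simulate_multiview(seed = 5)
  mod <- fit_factor_model(sim$views, k = 3)
  expect_equal(nrow(mod$Z), 22)
  # mutation view carries only its own 20 samples in the objective:
  # residual matrix dimensions match the observed rows
  expect_equal(nrow(sim$views$mutations), 20)
})

test_that("self-projection reproduces training scores through the pseudoinverse", {
  sim <- simulate_multiview(noise_frac = 0.3, seed = 6)
  mod <- fit_factor_model(sim$views, k = 3)
  zp <- project_onto_factors(mod, sim$views$morphology)
  cors <- abs(diag(stats::cor(zp, mod$Z)))
  expect_true(all(cors >= 0.95))
  # exactness on a noiseless morphology view at full rank
  sim0 <- simulate_multiview(noise_frac = 0, view_dims = c(morphology = 25),
                             seed = 7)
  mod0 <- fit_factor_model(sim0$views, k = 3)
  zp0 <- project_onto_factors(mod0, sim0$views$morphology)
  expect_lt(max(abs(zp0 - mod0$Z)) / max(abs(mod0$Z)), 1e-8)
  # linearity: zero profile projects to zero
  z0 <- project_onto_factors(mod, matrix(0, 1, 25))
  expect_equal(as.numeric(z0), rep(0, 3))
  expect_error(project_onto_factors(mod, matrix(0, 1, 7)), "dimension")
})

test_that("view assembly applies the stated selection and scaling rules", {
  set.seed(8)
  samples <- sprintf("s%02d", 1:8)
  # size view: areas from a mixture with large-component log-mean 6.5
  areas <- lapply(samples, function(s)
    exp(c(rnorm(2000, 4.0, 0.3), rnorm(3000, 6.5, 0.3))))
  names(areas) <- samples
  morph <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(samples, NULL))
  expr <- cbind(matrix(rnorm(8 * 30, 10, 0.1), 8, 30),   # low CV
                matrix(rnorm(8 * 10, 10, 3), 8, 10))     # high CV
  colnames(expr) <- sprintf("g%02d", 1:40)
  rownames(expr) <- samples
  mut <- matrix(rbinom(8 * 4, 1, 0.3), 8, 4,
                dimnames = list(samples, sprintf("m%d", 1:4)))
  act <- matrix(0.6, 8, 6, dimnames = list(samples, sprintf("d%d", 1:6)))
  act[1, 1] <- 0.9; act[3, 2] <- 0.95   # only d1, d2 active anywhere
  mv <- assemble_views(areas, morph, expr, mut, act)
  expect_s3_class(mv, "MultiViewDataset")
  # EM recovered the large-component location
  raw_size <- mv$views$size * mv$scaling$size$view_scale *
    mv$scaling$size$scale + mv$scaling$size$center
  expect_equal(mean(raw_size), 6.5, tolerance = 0.05 / 6.5)
  # top-10% CV genes selected (4 of 40), all from the high-CV block
  expect_equal(ncol(mv$views$expression), 4)
  expect_true(all(colnames(mv$views$expression) %in%
                    sprintf("g%02d", 31:40)))
  # inactive drugs excluded
  expect_setequal(colnames(mv$views$drug_activity), c("d1", "d2"))
  # unit total variance per view after scaling
  for (v in names(mv$views)) {
    tv <- sum(apply(mv$views[[v]], 2, stats::var))
    expect_equal(tv, 1, tolerance = 1e-9)
  }
  # assembling twice yields identical matrices (scaling idempotence at
  # the dataset level)
  mv2 <- assemble_views(areas, morph, expr, mut, act)
  expect_equal(mv$views, mv2$views)
})

test_that("equal-CV genes tie-break deterministically by gene order", {
  samples <- sprintf("s%02d", 1:6)
  set.seed(9)
  base <- rnorm(6, 10, 2)
  expr <- matrix(rep(base, 20), 6, 20,
                 dimnames = list(samples, sprintf("g%02d", 1:20)))
  cv <- apply(expr, 2, function(v) sd(v) / abs(mean(v)))
  expect_true(max(cv) - min(cv) < 1e-12)
  areas <- lapply(samples, function(s) exp(rnorm(500, 6, 0.3)))
  names(areas) <- samples
  morph <- matrix(rnorm(12), 6, 2, dimnames = list(samples, NULL))
  mut <- matrix(rbinom(12, 1, 0.5), 6, 2, dimnames = list(samples, NULL))
  act <- matrix(0.9, 6, 3, dimnames = list(samples, sprintf("d%d", 1:3)))
  mv <- assemble_views(areas, morph, expr, mut, act)
  expect_equal(colnames(mv$views$expression), c("g01", "g02"))
})

test_that("GSEA matches the running-sum oracle and flags degenerate input", {
  set.seed(10)
  stats_v <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  for (m in c(5, 12, 25)) {
    gs <- sample(names(stats_v), m)
    g <- gsea_preranked(stats_v, gs, n_perm = 50, seed = 11)
    expect_equal(g$es, oracle_gsea_es(stats_v, gs), tolerance = 1e-12)
  }
  # a top-loaded set is maximally enriched
  ranked <- setNames(sort(rnorm(1000), decreasing = TRUE),
                     sprintf("g%04d", 1:1000))
  top <- gsea_preranked(ranked, names(ranked)[1:20], n_perm = 2000,
                        seed = 12)
  expect_gt(top$es, 0.9)
  # p attains the permutation floor: no null |ES| reaches the observed
  expect_lte(top$p, 2 / 2000)
  expect_gt(top$nes, 0)
  expect_error(gsea_preranked(stats_v, names(stats_v)), "every")
  expect_error(gsea_preranked(stats_v, names(stats_v)[1:3], n_perm = 10),
               "fewer than 5")
})

test_that("GSEA null p-values are approximately uniform", {
  set.seed(13)
  ranked <- setNames(rnorm(500), sprintf("g%03d", 1:500))
  ps <- vapply(1:100, function(i) {
    gs <- sample(names(ranked), 30)
    gsea_preranked(ranked, gs, n_perm = 200, seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("target association finds shifted groups and applies the size rule", {
  set.seed(14)
  vals <- data.frame(drug = sprintf("d%02d", 1:25),
                     value = rnorm(25))
  vals$value[1:5] <- vals$value[1:5] + 2      # 5-drug target, +2 sd shift
  ann <- data.frame(drug = vals$drug,
                    target = c(rep("hit", 5), rep("bg", 18), "tiny", "tiny"))
  res <- test_target_association(vals, ann, min_drugs = 3)
  expect_false("tiny" %in% res$target)        # < 3 drugs -> excluded
  hit <- res[res$target == "hit", ]
  expect_gt(hit$t, 3)
  expect_lt(hit$fdr, 0.05)
  # all-identical values: zero-variance flag, no crash
  vals0 <- data.frame(drug = vals$drug, value = 1)
  res0 <- test_target_association(vals0, ann)
  expect_true(all(res0$note == "zero variance"))
  expect_true(all(is.na(res0$t)))
})

test_that("gmt round-trip parses set names and genes", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), tf)
  sets <- read_gmt(tf)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  unlink(tf)
})
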