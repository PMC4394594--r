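test_that("RDA eigenvalue conservation and degenerate designs", {
  tp <- toy_regression(n = 20L, p = 4L, seed = 1L)
  fit <- rda(tp$Y, tp$X)
  total <- sum(tp$Y^2) / (nrow(tp$Y) - 1)
  expect_equal(sum(fit$canonical) + sum(fit$noncanonical), total,
               tolerance = 1e-8)
  expect_lte(length(fit$canonical), ncol(tp$X))
  expect_equal(sum(fit$relative_canonical) +
                 sum(fit$relative_noncanonical), 1, tolerance = 1e-10)

  # exact linear dependence: residual variance vanishes
  B <- matrix(c(1, 0.5, -1, 2, 0.3, 0, 1, -0.5), 2, 4)
  Yl <- tp$X %*% B
  fit <- rda(Yl, tp$X)
  expect_equal(sum(fit$canonical), sum(Yl^2) / (nrow(Yl) - 1),
               tolerance = 1e-10)
  expect_equal(sum(fit$noncanonical), 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # orthogonal response: canonical eigenvalues collapse
  Yo <- tp$Y - tp$X %*% solve(crossprod(tp$X), crossprod(tp$X, tp$Y))
  fit <- rda(Yo, tp$X)
  expect_lt(sum(fit$canonical), 1e-10)

  expect_error(rda(tp$Y, cbind(tp$X, tp$X[, 1])), "rank")
  expect_error(rda(tp$Y[1:2, ], tp$X[1:2, ]), "more taxa")
})

test_that("RDA agrees with vegan and the brute-force lm oracle", {
  tp <- toy_regression(n = 24L, p = 5L, seed = 2L)
  fit <- rda(tp$Y, tp$X)
  expect_equal(fit$r2, oracle_trace_r2(tp$Y, tp$X), tolerance = 1e-10)
  vg <- vegan::rda(tp$Y ~ tp$X[, 1] + tp$X[, 2])
  expect_equal(unname(fit$canonical),
               unname(vg$CCA$eig), tolerance = 1e-8)
  expect_equal(unname(fit$noncanonical),
               unname(vg$CA$eig[seq_along(fit$noncanonical)]),
               tolerance = 1e-8)
  expect_equal(fit$r2, unname(vegan::RsquareAdj(vg)$r.squared),
               tolerance = 1e-8)
})

test_that("Ezekiel adjustment evaluates and guards", {
  expect_equal(adjusted_r2(1, 10, 2), 1)
  expect_equal(adjusted_r2(0, 71, 1), 1 - 70 / 69, tolerance = 1e-12)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9,
               tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 3, 2), "exceed")
  expect_error(adjusted_r2(1.2, 10, 1), "\\[0, 1\\]")
})

test_that("variation partitioning identities hold exactly", {
  tp <- toy_regression(n = 30L, p = 5L, seed = 3L)
  vp <- varpart(tp$Y, tp$X[, 1], tp$X[, 2])
  a <- vp$adjusted; f <- vp$fractions
  expect_equal(f[["AR|M"]], a[["AR+M"]] - a[["M"]], tolerance = 1e-15)
  expect_equal(f[["M|AR"]], a[["AR+M"]] - a[["AR"]], tolerance = 1e-15)
  expect_equal(f[["AR^M"]], a[["AR"]] + a[["M"]] - a[["AR+M"]],
               tolerance = 1e-15)
  expect_equal(f[["AR|M"]] + f[["M|AR"]] + f[["AR^M"]] + f[["residual"]],
               1, tolerance = 1e-12)
  # oracle: vegan's varpart on the same inputs
  vv <- vegan::varpart(tp$Y, ~ tp$X[, 1], ~ tp$X[, 2])
  ind <- vv$part$indfract$Adj.R.square
  expect_equal(unname(f[c("AR|M", "M|AR", "AR^M", "residual")]),
               ind, tolerance = 1e-8)
})

test_that("varpart recovers constructed signal and nulls", {
  set.seed(77)
  n <- 100L
  AR <- stats::rnorm(n); M <- stats::rnorm(n)
  # independent response: all fractions near zero
  Y0 <- matrix(stats::rnorm(n * 6L), n, 6L)
  vp0 <- varpart(scale(Y0, scale = FALSE), AR - mean(AR), M - mean(M))
  expect_true(all(abs(vp0$fractions[c("AR|M", "M|AR", "AR^M")]) < 0.05))
  # Y built from AR only, AR orthogonal to M
  Y1 <- Y0
  Y1[, 1] <- 0.3 * AR + 0.1 * stats::rnorm(n)
  vp1 <- varpart(scale(Y1, scale = FALSE), AR - mean(AR), M - mean(M))
  expect_equal(vp1$fractions[["AR|M"]], vp1$adjusted[["AR"]],
               tolerance = 0.02)
  expect_lt(abs(vp1$fractions[["AR^M"]]), 0.02)
})

test_that("permutation tests find signal and reject degenerate input", {
  B <- matrix(c(1, 0.5, -1, 2, 0.3, 0, 1, -0.5), 2, 4)
  tp <- toy_regression(n = 20L, p = 4L, seed = 4L)
  Yl <- tp$X %*% B  # perfect dependence
  pt <- permutation_tests(Yl, tp$X, n_perm = 999L, seed = 1L)
  expect_equal(unname(pt$axis_p[1]), 1 / 1000)
  expect_error(permutation_tests(matrix(1, 10, 3),
                                 matrix(stats::rnorm(20), 10, 2),
                                 n_perm = 99L), "degenerate")
  expect_error(permutation_tests(tp$Y, tp$X, n_perm = 10L), "99")
  # determinism under seed
  pt2 <- permutation_tests(tp$Y, tp$X, n_perm = 99L, seed = 5L)
  pt3 <- permutation_tests(tp$Y, tp$X, n_perm = 99L, seed = 5L)
  expect_identical(pt2, pt3)
})

test_that("star phylogeny reduces the whitened pipeline to plain RDA", {
  labs <- paste0("t", 1:8)
  st <- star_tree(labs, depth = 2)
  C <- phylo_covariance(st, labs)
  set.seed(9)
  Y <- matrix(stats::rnorm(8 * 3), 8, 3,
              dimnames = list(labs, paste0("PCO", 1:3)))
  X <- cbind(logAR = stats::rnorm(8), logM = stats::rnorm(8))
  rownames(X) <- labs
  Cl <- lambda_scale(C, 0.4)         # any lambda: star stays scalar
  cen <- center_and_range(cbind(Y, X), Cl,
                          range_vars = c("logAR", "logM"))
  wh <- pgls_whiten(cen, Cl)
  fit <- rda(wh[, 1:3], wh[, 4:5])
  # whitening by a scalar matrix cannot change R2 or relative structure
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  expect_equal(fit$r2, oracle_trace_r2(Yc, Xc), tolerance = 1e-8)
  vp <- varpart(wh[, 1:3], wh[, 4, drop = FALSE], wh[, 5, drop = FALSE])
  expect_equal(vp$r2[["AR"]], oracle_trace_r2(Yc, Xc[, 1, drop = FALSE]),
               tolerance = 1e-8)
  expect_equal(vp$r2[["M"]], oracle_trace_r2(Yc, Xc[, 2, drop = FALSE]),
               tolerance = 1e-8)
})

test_that("passive placement projects supplementary rows faithfully", {
  tp <- toy_regression(n = 20L, p = 4L, seed = 6L)
  fit <- rda(tp$Y, tp$X)
  # an extant taxon placed with its own (whitened-scale) row is identity
  placed <- place_passive_taxa(tp$Y[3:4, , drop = FALSE], fit)
  expect_equal(placed, fit$scores[3:4, , drop = FALSE],
               tolerance = 1e-12)
  # missing response columns are named
  expect_error(place_passive_taxa(tp$Y[1:2, 1:2], fit), "PCO3")
})

test_that("back-predicted AR inverts the whole transform chain", {
  labs <- paste0("t", 1:12)
  tr <- simulate_pure_birth_tree(12L, seed = 3L, tip_labels = labs)
  C <- phylo_covariance(tr)
  set.seed(10)
  Y <- matrix(stats::rnorm(12 * 3), 12, 3,
              dimnames = list(rownames(C), paste0("PCO", 1:3)))
  X <- cbind(logAR = log(8) + 0.3 * Y[, 1] + 0.05 * stats::rnorm(12),
             logM = stats::rnorm(12))
  rownames(X) <- rownames(C)
  Cl <- lambda_scale(C, 0.8)
  cen <- center_and_range(cbind(Y, X), Cl,
                          range_vars = c("logAR", "logM"))
  wh <- pgls_whiten(cen, Cl)
  fit <- rda(wh[, 1:3], wh[, 4:5])
  # a supplementary taxon at the centered origin recovers the root AR
  origin <- matrix(0, 1, 3,
                   dimnames = list("ghost", paste0("PCO", 1:3)))
  placed <- place_passive_taxa(origin, fit)
  bp <- back_predict_ar(placed, fit, cen)
  expect_equal(unname(bp$fitted_ar["ghost"]), bp$root_ar,
               tolerance = 1e-10)
  expect_equal(bp$root_ar, exp(cen$roots[["logAR"]]), tolerance = 1e-12)
})
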