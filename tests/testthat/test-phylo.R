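test_that("phylogenetic covariance is shared path length", {
  C <- phylo_covariance(ape::read.tree(text = "(A:1,B:1);"))
  expect_equal(unname(C), diag(2), ignore_attr = TRUE)
  C <- phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  C <- phylo_covariance(star_tree(c("x", "y", "z"), depth = 3.5))
  expect_equal(unname(C), 3.5 * diag(3))
  # ultrametric trees have constant diagonal
  tr <- simulate_pure_birth_tree(20L, seed = 5L)
  expect_equal(stats::sd(diag(phylo_covariance(tr))), 0, tolerance = 1e-10)
  expect_error(phylo_covariance(ape::unroot(
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))), "rooted")
})

test_that("lambda scaling touches only the off-diagonal", {
  C <- matrix(c(2, 0.8, 0.8, 2), 2, 2)
  expect_equal(lambda_scale(C, 1), C)
  expect_equal(lambda_scale(C, 0), diag(c(2, 2)))
  expect_equal(lambda_scale(C, 0.5)[1, 2], 0.4)
  expect_error(lambda_scale(C, 1.2), "\\[0, 1\\]")
})

test_that("profile likelihood matches a direct GLS oracle", {
  tr <- simulate_pure_birth_tree(16L, seed = 2L)
  C <- phylo_covariance(tr)
  x <- simulate_traits(tr, lambda_true = 0.6, sigma2 = 1, seed = 9L)
  x <- x[rownames(C)]
  for (lam in c(0, 0.3, 0.8, 1)) {
    Cl <- lambda_scale(C, lam)
    expect_equal(wingrda:::profile_loglik(as.numeric(x), Cl)$logL,
                 oracle_bm_loglik(as.numeric(x), C, lam),
                 tolerance = 1e-8)
  }
})

test_that("joint lambda ML beats a grid scan and flags edge cases", {
  tr <- simulate_pure_birth_tree(48L, seed = 7L)
  C <- phylo_covariance(tr)
  set.seed(21)
  data <- sapply(1:3, function(v)
    simulate_traits(tr, lambda_true = 0.7, sigma2 = 1)[rownames(C)])
  rownames(data) <- rownames(C)
  est <- joint_lambda_ml(data, C)
  expect_gte(est$lambda, 0); expect_lte(est$lambda, 1)
  expect_gte(est$logL, max(est$logL0, est$logL1) - 1e-6)
  grid <- seq(0, 1, length.out = 101L)
  gll <- vapply(grid, function(l) {
    Cl <- lambda_scale(C, l)
    sum(vapply(1:3, function(v)
      wingrda:::profile_loglik(data[, v], Cl)$logL, 0))
  }, 0)
  expect_gte(est$logL, max(gll) - 1e-6)

  expect_warning(joint_lambda_ml(cbind(data, konst = 1), C), "constant")
  expect_error(joint_lambda_ml(data[1:3, ], C[1:3, 1:3]), "at least 4")
})

test_that("lambda recovery at the Brownian and white-noise extremes", {
  tr <- simulate_pure_birth_tree(64L, seed = 31L)
  C <- phylo_covariance(tr)
  lam_bm <- lam_wn <- numeric(10L)
  set.seed(100)
  for (r in 1:10) {
    x <- simulate_traits(tr, lambda_true = 1, sigma2 = 1)
    lam_bm[r] <- joint_lambda_ml(cbind(x = x[rownames(C)]), C)$lambda
    y <- stats::setNames(stats::rnorm(64L), rownames(C))
    lam_wn[r] <- joint_lambda_ml(cbind(x = y), C)$lambda
  }
  expect_gte(mean(lam_bm), 0.8)
  expect_lte(mean(lam_wn), 0.2)
})

test_that("likelihood-ratio tests use chi-squared df = 1", {
  est <- structure(list(logL = 10, logL0 = 10 - 3.841 / 2,
                        logL1 = 10), class = "lambda_estimate")
  lr <- lambda_lr_test(est)
  expect_equal(lr["vs0", "p"], 0.05, tolerance = 1e-3)
  expect_equal(lr["vs1", "p"], 1)
  est$logL0 <- 10 - 10.83 / 2
  expect_equal(lambda_lr_test(est)["vs0", "p"], 0.001, tolerance = 1e-3)
  est$logL0 <- 11  # optimizer failure
  expect_error(lambda_lr_test(est), "negative")
})

test_that("centering and ranging follow the GLS root and [-1,1] bound", {
  labs <- paste0("t", 1:4)
  st <- star_tree(labs)
  C <- phylo_covariance(st, labs)
  x <- cbind(v = c(3, 1, 4, 8)); rownames(x) <- labs
  cen <- center_and_range(x, C)
  expect_equal(cen$roots[["v"]], mean(x))  # star tree: GLS = OLS mean
  expect_equal(unname(cen$centered[, "v"]), as.numeric(x - mean(x)))

  # ranging divides centered values by their max absolute value:
  # centered (-2, 0, 4) (mean already zero under this weighting) -> scale 4
  y <- cbind(w = c(-2, 0, 4)); rownames(y) <- paste0("s", 1:3)
  Cs <- diag(3); dimnames(Cs) <- list(rownames(y), rownames(y))
  cr <- center_and_range(y, Cs, range_vars = "w")
  cen_manual <- y[, "w"] - mean(y[, "w"])
  expect_equal(cr$scales[["w"]], max(abs(cen_manual)))
  expect_equal(unname(cr$centered[, "w"]),
               unname(cen_manual / max(abs(cen_manual))))
  expect_true(all(abs(cr$centered[, "w"]) <= 1 + 1e-12))
  expect_equal(max(abs(cr$centered[, "w"])), 1)
  expect_error(center_and_range(cbind(z = rep(1, 3)), Cs,
                                range_vars = "z"), "zero range")
})

test_that("whitening is the symmetric inverse square root", {
  x <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(pgls_whiten(x, diag(4)), x, ignore_attr = TRUE)
  expect_equal(pgls_whiten(x, 4 * diag(4)), x / 2, ignore_attr = TRUE)
  set.seed(8)
  for (r in 1:5) {
    A <- matrix(stats::rnorm(36), 6, 6)
    Cl <- crossprod(A) + diag(6)
    W <- whitening_operator(Cl)
    expect_equal(W, t(W), tolerance = 1e-10)
    expect_lt(max(abs(W %*% W - solve(Cl))), 1e-8)
  }
  expect_error(whitening_operator(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("whitened residual covariance approaches sigma2 * I", {
  tr <- simulate_pure_birth_tree(24L, seed = 12L)
  C <- phylo_covariance(tr)
  Cl <- lambda_scale(C, 0.7)
  W <- whitening_operator(Cl)
  set.seed(55)
  n_rep <- 400L
  S <- matrix(0, 24L, 24L)
  for (r in seq_len(n_rep)) {
    x <- as.numeric(crossprod(chol(Cl), stats::rnorm(24L)))
    wx <- as.numeric(W %*% x)
    S <- S + tcrossprod(wx)
  }
  S <- S / n_rep
  expect_lt(norm(S - diag(24L), "F") / norm(diag(24L), "F"), 0.25)
})
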