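# Shared builders and independent oracles for the test suite.

# Small character matrix with known scores (taxa x 6, valid ranges).
toy_cm <- function(n = 5L, seed = 42L) {
  set.seed(seed)
  sc <- sapply(wingrda:::CHARACTERS, function(ch)
    sample(0:wingrda:::CHAR_MAX[[ch]], n, replace = TRUE))
  rownames(sc) <- paste0("t", seq_len(n))
  character_matrix(sc)
}

# Star phylogeny of depth t over given labels (C = t * I), built as a
# rooted binary caterpillar with zero-length internal edges so that
# ape::is.rooted() accepts it.
star_tree <- function(labels, depth = 1) {
  txt <- paste0("(", labels[1L], ":", depth, ",", labels[2L], ":", depth, ")")
  for (k in seq_along(labels)[-(1:2)])
    txt <- paste0("(", txt, ":0,", labels[k], ":", depth, ")")
  ape::read.tree(text = paste0(txt, ";"))
}

# Brute-force Hamming distance by explicit double loop over characters.
oracle_hamming <- function(scores) {
  n <- nrow(scores)
  D <- matrix(0, n, n, dimnames = list(rownames(scores), rownames(scores)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sh <- 0L; ne <- 0L
    for (k in seq_len(ncol(scores))) {
      a <- scores[i, k]; b <- scores[j, k]
      if (!is.na(a) && !is.na(b)) {
        sh <- sh + 1L
        if (a != b) ne <- ne + 1L
      }
    }
    D[i, j] <- ne / sh
  }
  D
}

# Bisection oracle for the smallest additive constant making distances
# Euclidean-embeddable, judged by the Gower spectrum of (d + c)^2.
oracle_cailliez_bisect <- function(D, tol = 1e-9) {
  min_gower_eig <- function(cc) {
    Dc <- D + cc; diag(Dc) <- 0
    n <- nrow(Dc)
    J <- diag(n) - 1 / n
    B <- -0.5 * J %*% Dc^2 %*% J
    min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
  }
  lo <- 0; hi <- 2 * max(D) + 1
  if (min_gower_eig(0) >= -1e-10) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (min_gower_eig(mid) >= -1e-10) hi <- mid else lo <- mid
  }
  hi
}

# Direct GLS log-likelihood of a Brownian variable (no profiling
# shortcuts shared with the implementation path: explicit solve/det).
oracle_bm_loglik <- function(x, C, lambda) {
  Cl <- C * lambda; diag(Cl) <- diag(C)
  n <- length(x)
  Ci <- solve(Cl)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  r <- x - a
  s2 <- as.numeric(t(r) %*% Ci %*% r) / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) +
                       determinant(Cl)$modulus + n))
}

# Brute-force multivariate-regression R2 via per-column lm() fits.
oracle_trace_r2 <- function(Y, X) {
  sse_fit <- 0; ss_tot <- sum(Y^2)
  for (k in seq_len(ncol(Y))) {
    fit <- stats::lm(Y[, k] ~ X - 1)
    sse_fit <- sse_fit + sum(stats::fitted(fit)^2)
  }
  sse_fit / ss_tot
}

# Whitened toy regression problem: Y partially explained by X.
toy_regression <- function(n = 20L, p = 4L, seed = 1L, signal = 1) {
  set.seed(seed)
  X <- cbind(logAR = stats::rnorm(n), logM = stats::rnorm(n))
  Y <- matrix(stats::rnorm(n * p), n, p)
  Y[, 1] <- Y[, 1] + signal * X[, 1]
  Y <- scale(Y, scale = FALSE)
  X <- scale(X, scale = FALSE)
  rownames(Y) <- rownames(X) <- paste0("t", seq_len(n))
  colnames(Y) <- paste0("PCO", seq_len(p))
  list(Y = Y, X = X)
}
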