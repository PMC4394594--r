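#' Phylogenetic covariance matrix from a tree
#'
#' C[i,j] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip lengths.  This is the Brownian-motion tip
#' covariance (up to the rate).
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param taxa optional taxon labels to order/subset the matrix by
#'   (matched through \code{\link{match_tree_tips}}; rows are renamed to
#'   the study labels).
#' @return symmetric positive semi-definite matrix.
#' @export
phylo_covariance <- function(tree, taxa = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.null(taxa)) {
    m <- match_tree_tips(tree, taxa)
    if (anyNA(m$tip))
      stop("taxa missing from tree: ",
           paste(m$taxon[is.na(m$tip)], collapse = ", "))
    tree <- ape::keep.tip(tree, m$tip)
    C <- ape::vcv(tree)
    C <- C[m$tip, m$tip, drop = FALSE]
    dimnames(C) <- list(m$taxon, m$taxon)
    return(C)
  }
  ape::vcv(tree)
}

#' Scale off-diagonal covariances by Pagel's lambda
#'
#' lambda = 1 leaves C unchanged (pure Brownian motion); lambda = 0
#' removes all shared history, leaving \code{diag(C)}.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda value in [0, 1].
#' @return the scaled matrix C_lambda.
#' @export
lambda_scale <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Profile Brownian log-likelihood of one variable given C_lambda, with the
# root mean and rate profiled out analytically (ML, divisor n).
profile_loglik <- function(x, Cl) {
  n <- length(x)
  ch <- tryCatch(chol(Cl), error = function(e)
    stop("C_lambda is singular or not positive definite"))
  logdet <- 2 * sum(log(diag(ch)))
  Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- sum(Ci1 * x) / sum(Ci1)
  r <- x - a
  Cir <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Cir) / n
  if (s2 <= 0) stop("variable has zero GLS variance")
  list(logL = -0.5 * (n * log(2 * pi * s2) + logdet + n),
       root = a, sigma2 = s2)
}

#' Jointly estimate Pagel's lambda for a set of variables
#'
#' All variables are assumed independent but to share one lambda; the
#' joint log-likelihood is the sum of per-variable Brownian profile
#' log-likelihoods under covariance sigma2_v * C_lambda, maximized by
#' bounded 1-D search on [0, 1] with the endpoints also evaluated
#' (boundary estimates are allowed).
#'
#' @param data numeric matrix, taxa x variables; rownames must match C.
#' @param C phylogenetic covariance (lambda = 1), or a \code{phylo} tree.
#' @param tol optimizer tolerance.
#' @return an object of class \code{lambda_estimate}: \code{lambda},
#'   \code{logL}, \code{logL0}, \code{logL1}, per-variable \code{roots}
#'   and \code{sigma2}, and LR tests against lambda = 0 and 1.
#' @export
joint_lambda_ml <- function(data, C, tol = 1e-8) {
  data <- as.matrix(data)
  if (inherits(C, "phylo")) C <- phylo_covariance(C, rownames(data))
  if (!is.null(rownames(data)) && !is.null(rownames(C))) {
    if (!all(rownames(data) %in% rownames(C)))
      stop("data taxa missing from covariance matrix")
    C <- C[rownames(data), rownames(data)]
  }
  n <- nrow(data)
  if (n < 4L) stop("need at least 4 taxa")
  keep <- apply(data, 2L, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warning("excluding constant variable(s): ",
            paste(colnames(data)[!keep], collapse = ", "))
    data <- data[, keep, drop = FALSE]
  }
  if (ncol(data) == 0L) stop("no non-constant variables")
  jll <- function(lambda) {
    Cl <- lambda_scale(C, lambda)
    sum(vapply(seq_len(ncol(data)),
               function(v) profile_loglik(data[, v], Cl)$logL, 0))
  }
  opt <- stats::optimize(jll, c(0, 1), maximum = TRUE, tol = tol)
  l0 <- jll(0); l1 <- jll(1)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, l0), c(1, l1))
  best <- cand[which.max(cand[, 2L]), ]
  Cl <- lambda_scale(C, best[1L])
  per <- lapply(seq_len(ncol(data)), function(v)
    profile_loglik(data[, v], Cl))
  est <- structure(list(
    lambda = best[1L], logL = best[2L], logL0 = l0, logL1 = l1,
    roots = stats::setNames(vapply(per, `[[`, 0, "root"), colnames(data)),
    sigma2 = stats::setNames(vapply(per, `[[`, 0, "sigma2"), colnames(data)),
    n = n, n_var = ncol(data)), class = "lambda_estimate")
  est$lr <- lambda_lr_test(est)
  est
}

#' Likelihood-ratio tests of lambda against the boundaries
#'
#' Chi-squared test with one degree of freedom on 2 * (logL(lambda_hat) -
#' logL(boundary)); small negative statistics from optimizer round-off are
#' clamped to zero, larger ones are an error.
#'
#' @param est a \code{lambda_estimate}.
#' @param tol tolerance for negative LR statistics.
#' @return data.frame with rows \code{vs0} and \code{vs1}: statistic, p.
#' @export
lambda_lr_test <- function(est, tol = 1e-6) {
  stat <- 2 * (est$logL - c(vs0 = est$logL0, vs1 = est$logL1))
  if (any(stat < -tol))
    stop("negative likelihood-ratio statistic: optimizer failure")
  stat <- pmax(stat, 0)
  data.frame(statistic = stat,
             p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat("lambda_estimate: lambda =", format(x$lambda, digits = 4),
      " logL =", format(x$logL, digits = 6), "\n")
  cat("  LR vs 0: p =", format(x$lr["vs0", "p"], digits = 3),
      "; vs 1: p =", format(x$lr["vs1", "p"], digits = 3), "\n")
  invisible(x)
}

#' Phylogenetically center and (optionally) range variables
#'
#' Each variable is centered on its GLS estimate of the ancestral (root)
#' state under covariance C_lambda; variables named in \code{range_vars}
#' (typically log AR and log M, which carry heterogeneous units) are then
#' divided by their maximum absolute centered value so they span [-1, 1].
#'
#' @param data numeric matrix, taxa x variables.
#' @param Cl scaled covariance C_lambda over the same taxa.
#' @param range_vars column names to range after centering.
#' @return an object of class \code{centered_data}: \code{centered}
#'   matrix, \code{roots}, and \code{scales} (1 for un-ranged variables).
#' @export
center_and_range <- function(data, Cl, range_vars = character()) {
  data <- as.matrix(data)
  if (!is.null(rownames(data)) && !is.null(rownames(Cl)))
    Cl <- Cl[rownames(data), rownames(data)]
  bad <- setdiff(range_vars, colnames(data))
  if (length(bad)) stop("unknown range_vars: ", paste(bad, collapse = ", "))
  ch <- chol(Cl)
  Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, nrow(data))))
  denom <- sum(Ci1)
  roots <- as.numeric(crossprod(data, Ci1)) / denom
  names(roots) <- colnames(data)
  cen <- sweep(data, 2L, roots)
  scales <- rep(1, ncol(data))
  names(scales) <- colnames(data)
  for (v in range_vars) {
    s <- max(abs(cen[, v]))
    if (s == 0) stop("zero range for ranged variable '", v, "'")
    scales[v] <- s
    cen[, v] <- cen[, v] / s
  }
  structure(list(centered = cen, roots = roots, scales = scales),
            class = "centered_data")
}

#' Inverse-square-root whitening operator of C_lambda
#'
#' Symmetric (spectral) square root: W = U diag(1/sqrt(e)) U'.  W is
#' unique, symmetric, and satisfies W W = C_lambda^{-1}.
#'
#' @param Cl positive-definite covariance matrix.
#' @param tol smallest admissible eigenvalue.
#' @return the matrix W.
#' @export
whitening_operator <- function(Cl, tol = 1e-12) {
  e <- eigen(Cl, symmetric = TRUE)
  if (min(e$values) <= tol)
    stop("C_lambda not positive definite (smallest eigenvalue ",
         format(min(e$values)), ")")
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dimnames(W) <- dimnames(Cl)
  W
}

#' PGLS-whiten centered data
#'
#' Pre-multiplies by C_lambda^{-1/2} so that cross-products of whitened
#' matrices embed C^{-1}, the standard PGLS error weighting.
#'
#' @param centered a \code{centered_data} or plain numeric matrix.
#' @param Cl scaled covariance C_lambda.
#' @return whitened numeric matrix with the input dimnames.
#' @export
pgls_whiten <- function(centered, Cl) {
  x <- if (inherits(centered, "centered_data")) centered$centered
       else as.matrix(centered)
  if (!is.null(rownames(x)) && !is.null(rownames(Cl)))
    Cl <- Cl[rownames(x), rownames(x)]
  W <- whitening_operator(Cl)
  out <- W %*% x
  dimnames(out) <- dimnames(x)
  out
}
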