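#' Pairwise Hamming distances between taxa
#'
#' d(i,j) = (shared non-missing characters with unequal scores) /
#' (shared non-missing characters).  A multistate mismatch counts 1
#' regardless of score difference.  Missing data enter pairwise through
#' the shared-character denominator; no imputation.
#'
#' @param cm a \code{character_matrix}.
#' @return a \code{dist} object with taxon labels.
#' @export
hamming_distances <- function(cm) {
  X <- cm$scores
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 taxa")
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(shared))
      stop("taxa share no scored characters: ", rownames(X)[i], " / ",
           rownames(X)[j])
    D[i, j] <- D[j, i] <- sum(X[i, shared] != X[j, shared]) / sum(shared)
  }
  stats::as.dist(D)
}

gower_center <- function(M) {
  # B = -1/2 J M J with J = I - 11'/n, without forming J
  rm <- rowMeans(M); gm <- mean(M)
  -0.5 * (M - outer(rm, rm, function(a, b) a + b) + gm)
}

#' Cailliez constant of a distance matrix
#'
#' Smallest constant c such that the distances d(i,j) + c (i != j) are
#' embeddable in Euclidean space: the largest real eigenvalue of the
#' classic 2n x 2n companion matrix built from the Gower-centered
#' squared and plain distances.  Zero (up to tolerance) for a distance
#' matrix that is already Euclidean.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @return the constant c >= 0.
#' @export
cailliez_constant <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  d1 <- gower_center(D^2)
  d2 <- gower_center(D)
  Z <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(Z, only.values = TRUE)$values
  cc <- max(Re(ev[abs(Im(ev)) < 1e-8]))
  max(cc, 0)
}

#' Apply the Cailliez correction
#'
#' Adds the Cailliez constant to the off-diagonal distances so that the
#' corrected matrix has no negative Gower eigenvalues (beyond numerical
#' tolerance).  The constant is added to the distances themselves, not
#' to the squared distances.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param tol constants below \code{tol} are treated as zero.
#' @return list with \code{distances} (corrected \code{dist}) and
#'   \code{c} (the constant).
#' @export
cailliez_correction <- function(d, tol = 1e-10) {
  d <- stats::as.dist(as.matrix(d))
  cc <- cailliez_constant(d)
  if (cc < tol) cc <- 0
  list(distances = d + cc, c = cc)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the element-wise squared distances,
#' eigendecomposition, and coordinates scaled by the square roots of the
#' positive eigenvalues.  Relative eigenvalues are fractions of the sum of
#' positive eigenvalues; axes with non-positive eigenvalues are never
#' retained.  Each axis is oriented so that the taxon-order-weighted sum
#' of its coordinates is non-negative, making runs reproducible (PCO axis
#' signs are otherwise arbitrary).
#'
#' @param d a \code{dist} (typically Cailliez-corrected) or a
#'   \code{cailliez_correction} result.
#' @param n_axes number of axes to retain (default 12); reduced with a
#'   warning when fewer positive eigenvalues exist.
#' @param fix_signs apply the deterministic sign convention?
#' @return an object of class \code{pco}: eigenvalues, relative and
#'   cumulative relative eigenvalues, taxon coordinates, the Cailliez
#'   constant when known, and the retained axis count.
#' @export
principal_coordinates <- function(d, n_axes = 12L, fix_signs = TRUE) {
  cc <- NA_real_
  if (is.list(d) && !is.null(d$distances)) {
    cc <- d$c
    d <- d$distances
  }
  D <- as.matrix(d)
  n <- nrow(D)
  B <- gower_center(D^2)
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(1e-9, 1e-12 * abs(e$values[1L])))
  if (length(pos) == 0L) stop("no positive eigenvalues")
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalues; retaining ",
            length(pos), " axes instead of ", n_axes)
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  if (fix_signs) {
    w <- seq_len(n)
    for (k in seq_len(ncol(pts)))
      if (sum(w * pts[, k]) < 0) pts[, k] <- -pts[, k]
  }
  dimnames(pts) <- list(rownames(D), paste0("PCO", seq_len(ncol(pts))))
  rel <- e$values / sum(e$values[pos])
  structure(list(
    eigenvalues = e$values,
    relative = rel,
    cumulative = cumsum(rel),
    points = pts,
    cailliez = cc,
    n_axes = n_axes,
    n_positive = length(pos)),
    class = "pco")
}

#' @export
print.pco <- function(x, ...) {
  cat("pco: ", nrow(x$points), " taxa, ", x$n_axes, " retained axes (",
      x$n_positive, " positive); Cailliez c = ",
      format(x$cailliez, digits = 4), "\n", sep = "")
  tab <- data.frame(relative = round(x$relative[seq_len(x$n_axes)], 3),
                    cumulative = round(x$cumulative[seq_len(x$n_axes)], 3))
  rownames(tab) <- colnames(x$points)
  print(utils::head(tab, 8L))
  invisible(x)
}

#' Eigenvalue table of a PCO solution
#' @param pco a \code{pco}.
#' @param n_axes rows to report (default: retained axes).
#' @return data.frame with axis, eigenvalue, relative and cumulative
#'   relative eigenvalue.
#' @export
pco_eigenvalue_table <- function(pco, n_axes = pco$n_axes) {
  data.frame(axis = paste0("PCO", seq_len(n_axes)),
             eigenvalue = pco$eigenvalues[seq_len(n_axes)],
             relative = pco$relative[seq_len(n_axes)],
             cumulative = pco$cumulative[seq_len(n_axes)])
}

#' Project the original characters onto PCO axes
#'
#' Signed per-character, per-axis coefficients analogous to PCA loadings.
#' Two scalings are available: \code{"correlation"} (Pearson correlation
#' of scores with axis coordinates, bounded by 1) and \code{"regression"}
#' (slope of axis coordinates on standardized scores, unbounded).  A
#' constant character projects to 0 everywhere, with a warning.
#'
#' @param cm the \code{character_matrix} the PCO was built from.
#' @param pco the \code{pco} result.
#' @param scaling \code{"correlation"} or \code{"regression"}.
#' @return matrix, characters x retained axes.
#' @export
character_projections <- function(cm, pco,
                                  scaling = c("correlation", "regression")) {
  scaling <- match.arg(scaling)
  X <- cm$scores[rownames(pco$points), , drop = FALSE]
  P <- matrix(0, ncol(X), ncol(pco$points),
              dimnames = list(colnames(X), colnames(pco$points)))
  for (ch in seq_len(ncol(X))) {
    x <- X[, ch]
    ok <- !is.na(x)
    if (stats::sd(x[ok]) == 0) {
      warning("constant character '", colnames(X)[ch],
              "': projections set to 0")
      next
    }
    for (ax in seq_len(ncol(pco$points))) {
      y <- pco$points[ok, ax]
      P[ch, ax] <- switch(scaling,
        correlation = stats::cor(x[ok], y),
        # slope of axis coordinate on the standardized character score
        regression = stats::cov(x[ok], y) / stats::var(x[ok]) *
          stats::sd(x[ok]))
    }
  }
  P
}
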