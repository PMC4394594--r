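#' Redundancy analysis of a whitened response on whitened predictors
#'
#' Multivariate no-intercept regression of Yw on Xw (both are already
#' phylogenetically centered and whitened), followed by
#' eigendecomposition of the fitted cross-product: canonical axes span
#' the explained variation, non-canonical axes the residual.  Taxon
#' scores are the whitened response projected on the canonical
#' eigenvectors; loadings are correlations of the response and
#' explanatory columns with those scores.
#'
#' @param Yw whitened response matrix (taxa x variables).
#' @param Xw whitened explanatory matrix (same taxa, same order).
#' @param n_perm permutations for significance tests (0 = none).
#' @param seed RNG seed used when \code{n_perm > 0}.
#' @return an object of class \code{rda_result}: canonical and
#'   non-canonical eigenvalues, relative eigenvalues (fractions of total
#'   whitened-Y variance), eigenvectors, taxon scores, response and
#'   explanatory loadings, regression coefficients, R2, and permutation
#'   p-values when requested.
#' @export
rda <- function(Yw, Xw, n_perm = 0L, seed = NULL) {
  Yw <- as.matrix(Yw); Xw <- as.matrix(Xw)
  n <- nrow(Yw)
  if (nrow(Xw) != n) stop("Yw and Xw must share taxa")
  if (n <= ncol(Xw)) stop("need more taxa than predictors")
  if (qr(Xw)$rank < ncol(Xw)) stop("rank-deficient explanatory matrix")
  coef <- solve(crossprod(Xw), crossprod(Xw, Yw))
  Yhat <- Xw %*% coef
  Yres <- Yw - Yhat
  total <- sum(Yw^2) / (n - 1)
  if (total <= 0) stop("response has no variance")
  ec <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  n_can <- min(ncol(Xw), ncol(Yw))
  can_val <- ec$values[seq_len(n_can)]
  V <- ec$vectors[, seq_len(n_can), drop = FALSE]
  # deterministic axis orientation (signs of eigenvectors are arbitrary)
  for (k in seq_len(ncol(V)))
    if (sum(seq_len(nrow(V)) * V[, k]) < 0) V[, k] <- -V[, k]
  rownames(V) <- colnames(Yw)
  colnames(V) <- paste0("RDA", seq_len(n_can))
  er <- eigen(crossprod(Yres) / (n - 1), symmetric = TRUE)
  res_val <- er$values[er$values > 1e-12 * max(total, er$values[1L])]
  scores <- Yw %*% V
  loading_cor <- function(M) {
    L <- suppressWarnings(stats::cor(M, scores))
    L[is.na(L)] <- 0
    L
  }
  out <- structure(list(
    canonical = can_val,
    noncanonical = res_val,
    relative_canonical = can_val / (sum(can_val) + sum(res_val)),
    relative_noncanonical = res_val / (sum(can_val) + sum(res_val)),
    eigenvectors = V,
    scores = scores,
    loadings_response = loading_cor(Yw),
    loadings_explanatory = loading_cor(Xw),
    coef = coef,
    r2 = sum(Yhat^2) / sum(Yw^2),
    n = n), class = "rda_result")
  if (n_perm > 0L)
    out$permutation <- permutation_tests(Yw, Xw, n_perm = n_perm,
                                         seed = seed)
  out
}

#' @export
print.rda_result <- function(x, ...) {
  cat("rda_result: n =", x$n, " R2 =", format(x$r2, digits = 4), "\n")
  cat("  canonical eigenvalues:",
      paste(format(x$canonical, digits = 3), collapse = ", "), "\n")
  cat("  relative:",
      paste(sprintf("%.1f%%", 100 * x$relative_canonical), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ezekiel-adjusted coefficient of determination
#'
#' 1 - (1 - R2) (n - 1) / (n - m - 1); may be negative.
#'
#' @param r2 unadjusted R2 in [0, 1].
#' @param n sample size.
#' @param m number of predictors.
#' @return adjusted R2.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (any(r2 < 0 | r2 > 1)) stop("r2 must lie in [0, 1]")
  if (n - m - 1 <= 0) stop("n must exceed m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

trace_r2 <- function(Yw, Xw) {
  coef <- solve(crossprod(Xw), crossprod(Xw, Yw))
  sum((Xw %*% coef)^2) / sum(Yw^2)
}

#' Variation partitioning of morphology between AR and M
#'
#' Fits the three models (AR alone, M alone, AR + M), adjusts each R2
#' for its predictor count, and derives the unique fractions, the
#' intersection, and the residual through the standard identities:
#' \code{AR|M = adj(AR+M) - adj(M)}, \code{M|AR = adj(AR+M) - adj(AR)},
#' \code{AR^M = adj(AR) + adj(M) - adj(AR+M)},
#' \code{residual = 1 - adj(AR+M)}.
#'
#' @param Yw whitened response matrix.
#' @param ARw whitened aspect-ratio column (vector or 1-column matrix).
#' @param Mw whitened mass column.
#' @param n_perm permutations for the marginal-model tests (0 = none).
#' @param seed RNG seed.
#' @return an object of class \code{varpart_result} with
#'   \code{adjusted} (named: AR, M, AR+M), \code{fractions} (named:
#'   \code{AR|M}, \code{M|AR}, \code{AR^M}, \code{residual}), raw
#'   \code{r2}, and permutation p-values when requested.
#' @export
varpart <- function(Yw, ARw, Mw, n_perm = 0L, seed = NULL) {
  Yw <- as.matrix(Yw)
  ARw <- as.matrix(ARw); Mw <- as.matrix(Mw)
  n <- nrow(Yw)
  r2 <- c("AR" = trace_r2(Yw, ARw), "M" = trace_r2(Yw, Mw),
          "AR+M" = trace_r2(Yw, cbind(ARw, Mw)))
  adj <- c(adjusted_r2(r2[["AR"]], n, 1L),
           adjusted_r2(r2[["M"]], n, 1L),
           adjusted_r2(r2[["AR+M"]], n, 2L))
  names(adj) <- names(r2)
  fr <- c("AR|M" = adj[["AR+M"]] - adj[["M"]],
          "M|AR" = adj[["AR+M"]] - adj[["AR"]],
          "AR^M" = adj[["AR"]] + adj[["M"]] - adj[["AR+M"]],
          "residual" = 1 - adj[["AR+M"]])
  out <- structure(list(r2 = r2, adjusted = adj, fractions = fr, n = n),
                   class = "varpart_result")
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    stat_obs <- r2[c("AR", "M", "AR+M")]
    hits <- c(0L, 0L, 0L)
    for (b in seq_len(n_perm)) {
      Yp <- Yw[sample.int(n), , drop = FALSE]
      hits <- hits + (c(trace_r2(Yp, ARw), trace_r2(Yp, Mw),
                        trace_r2(Yp, cbind(ARw, Mw))) >= stat_obs)
    }
    out$p <- stats::setNames((1 + hits) / (1 + n_perm), names(stat_obs))
    out$n_perm <- n_perm
  }
  out
}

#' @export
print.varpart_result <- function(x, ...) {
  tab <- data.frame(adjusted_r2 = round(c(x$adjusted, x$fractions), 4))
  if (!is.null(x$p))
    tab$p <- round(c(x$p, rep(NA, length(x$fractions))), 4)
  print(tab)
  invisible(x)
}

#' Permutation tests for RDA axes and loadings
#'
#' Rows of the whitened response are permuted uniformly at random
#' (whitening has already absorbed the phylogenetic covariance); per
#' permutation the canonical eigenvalues and the absolute explanatory
#' loadings on the canonical axes are recomputed, and p-values use the
#' add-one rule p = (1 + #(perm >= obs)) / (1 + n_perm).
#'
#' @param Yw whitened response matrix.
#' @param Xw whitened explanatory matrix.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with \code{axis_p} (per canonical axis) and
#'   \code{loading_p} (explanatory variables x canonical axes).
#' @export
permutation_tests <- function(Yw, Xw, n_perm = 999L, seed = NULL) {
  Yw <- as.matrix(Yw); Xw <- as.matrix(Xw)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (sum(apply(Yw, 2L, stats::sd)) == 0)
    stop("degenerate response: no variance across taxa")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Yw)
  stats_of <- function(Y) {
    fit <- rda(Y, Xw)
    list(ev = fit$canonical,
         ld = abs(fit$loadings_explanatory))
  }
  obs <- stats_of(Yw)
  hits_ev <- rep(0L, length(obs$ev))
  hits_ld <- array(0L, dim(obs$ld))
  for (b in seq_len(n_perm)) {
    per <- stats_of(Yw[sample.int(n), , drop = FALSE])
    hits_ev <- hits_ev + (per$ev >= obs$ev)
    hits_ld <- hits_ld + (per$ld >= obs$ld)
  }
  axis_p <- (1 + hits_ev) / (1 + n_perm)
  names(axis_p) <- paste0("RDA", seq_along(axis_p))
  loading_p <- (1 + hits_ld) / (1 + n_perm)
  dimnames(loading_p) <- dimnames(obs$ld)
  list(axis_p = axis_p, loading_p = loading_p, n_perm = n_perm)
}

#' Passively place supplementary taxa in the constrained space
#'
#' Projects supplementary rows (typically extinct taxa unavailable to
#' the model fit) onto the canonical eigenvectors.  When a
#' \code{centered_data} is supplied, the rows are first centered by the
#' extant root estimates (and divided by ranging scales) of the
#' corresponding columns; rows already on the whitened/centered scale
#' can be passed with \code{centering = NULL}, in which case an extant
#' taxon's whitened row reproduces its active score exactly.
#'
#' @param scores supplementary rows, columns matching the response
#'   variables of the fit (the retained PCO axes).
#' @param rda_res an \code{rda_result}.
#' @param centering optional \code{centered_data} holding roots/scales
#'   for the response columns.
#' @return matrix of canonical-axis scores for the supplementary taxa.
#' @export
place_passive_taxa <- function(scores, rda_res, centering = NULL) {
  scores <- as.matrix(scores)
  ycols <- rownames(rda_res$eigenvectors)
  if (!is.null(colnames(scores)) && !is.null(ycols)) {
    if (!all(ycols %in% colnames(scores)))
      stop("supplementary scores lack response columns: ",
           paste(setdiff(ycols, colnames(scores)), collapse = ", "))
    scores <- scores[, ycols, drop = FALSE]
  }
  if (!is.null(centering)) {
    cols <- colnames(scores)
    scores <- sweep(scores, 2L, centering$roots[cols])
    scores <- sweep(scores, 2L, centering$scales[cols], "/")
  }
  scores %*% rda_res$eigenvectors
}

#' Back-predict aspect ratio for passively placed taxa
#'
#' Fits a no-intercept regression of the centered (and ranged) log AR of
#' the extant taxa on their centered canonical-space scores, evaluates
#' it at the supplementary scores, and inverts the transform chain in
#' order: ranging scale, root centering, log_e.  A taxon placed at the
#' origin of the centered space therefore back-predicts the root AR,
#' exp(root estimate of log AR).
#'
#' @param placed canonical scores of supplementary taxa, from
#'   \code{\link{place_passive_taxa}} with centering applied.
#' @param rda_res the extant-only \code{rda_result}.
#' @param centering the \code{centered_data} used for the fit; must hold
#'   the response columns and the AR column.
#' @param ar_col name of the AR column in the centered data.
#' @return list with \code{fitted_ar} (natural AR scale, named by
#'   supplementary taxon) and \code{root_ar}.
#' @export
back_predict_ar <- function(placed, rda_res, centering, ar_col = "logAR") {
  ycols <- rownames(rda_res$eigenvectors)
  Yc <- centering$centered[, ycols, drop = FALSE]
  S_extant <- Yc %*% rda_res$eigenvectors
  arc <- centering$centered[, ar_col]
  beta <- solve(crossprod(S_extant), crossprod(S_extant, arc))
  fitted_c <- as.numeric(as.matrix(placed) %*% beta)
  ar <- exp(fitted_c * centering$scales[[ar_col]] +
              centering$roots[[ar_col]])
  names(ar) <- rownames(placed)
  list(fitted_ar = ar, root_ar = exp(centering$roots[[ar_col]]))
}
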