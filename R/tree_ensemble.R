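#' Assemble the ordination dataset for the comparative pipeline
#'
#' Runs Hamming distances, Cailliez correction and PCO on the full
#' character matrix (extinct taxa included, as supplementary points for
#' later passive placement), and extracts the extant response matrix
#' (retained PCO axes) and explanatory variables (log AR, log M).
#'
#' @param cm a \code{character_matrix}.
#' @param tt a \code{trait_table}.
#' @param n_axes retained PCO axes (default 12).
#' @return an object of class \code{study_dataset}: \code{pco},
#'   \code{Y} (extant taxa x axes), \code{X} (extant log AR, log M),
#'   \code{extinct_scores}, and the taxon bookkeeping.
#' @export
study_dataset <- function(cm, tt, n_axes = 12L) {
  d <- hamming_distances(cm)
  corr <- cailliez_correction(d)
  pco <- principal_coordinates(corr, n_axes = n_axes)
  extant <- taxa(cm, extant_only = TRUE)
  idx <- match(extant, tt$taxon)
  if (anyNA(idx))
    stop("extant taxa missing from trait table: ",
         paste(extant[is.na(idx)], collapse = ", "))
  X <- cbind(logAR = tt$logAR[idx], logM = tt$logM[idx])
  rownames(X) <- extant
  keep <- stats::complete.cases(X)
  if (!all(keep))
    warning("dropping extant taxa without complete traits: ",
            paste(extant[!keep], collapse = ", "))
  extant <- extant[keep]
  structure(list(
    pco = pco,
    Y = pco$points[extant, , drop = FALSE],
    X = X[extant, , drop = FALSE],
    extinct_scores = pco$points[cm$extinct, , drop = FALSE],
    extant = extant,
    extinct = taxa(cm)[cm$extinct]), class = "study_dataset")
}

#' Fit the single-tree comparative pipeline
#'
#' For one tree: derive the phylogenetic covariance, jointly estimate
#' lambda over all model variables (the retained PCO axes plus log AR
#' and log M), scale and invert-square-root the covariance, center all
#' variables on their GLS root estimates, range AR and M to [-1, 1]
#' (heterogeneous units), whiten, and run VARPART and RDA.
#'
#' @param ds a \code{study_dataset}.
#' @param tree rooted \code{phylo} covering the extant taxa.
#' @param n_perm permutations for RDA/VARPART tests (0 = none).
#' @param range_y also range the PCO axes? (default FALSE; only AR and
#'   M carry heterogeneous units).
#' @param seed RNG seed for the permutation tests.
#' @return an object of class \code{tree_fit}: \code{lambda} (the
#'   \code{lambda_estimate}), \code{centering}, whitened matrices,
#'   \code{varpart}, and \code{rda}.
#' @export
fit_tree <- function(ds, tree, n_perm = 0L, range_y = FALSE, seed = NULL) {
  C <- phylo_covariance(tree, ds$extant)
  data <- cbind(ds$Y, ds$X)
  est <- joint_lambda_ml(data, C)
  Cl <- lambda_scale(C, est$lambda)
  range_vars <- c(colnames(ds$X), if (range_y) colnames(ds$Y))
  cen <- center_and_range(data, Cl, range_vars = range_vars)
  wh <- pgls_whiten(cen, Cl)
  Yw <- wh[, colnames(ds$Y), drop = FALSE]
  Xw <- wh[, colnames(ds$X), drop = FALSE]
  vp <- varpart(Yw, Xw[, "logAR"], Xw[, "logM"],
                n_perm = n_perm, seed = seed)
  fit <- rda(Yw, Xw, n_perm = n_perm, seed = seed)
  structure(list(lambda = est, covariance = Cl, centering = cen,
                 Yw = Yw, Xw = Xw, varpart = vp, rda = fit),
            class = "tree_fit")
}

VARPART_TERMS <- c("AR", "M", "AR+M", "AR|M", "M|AR", "AR^M", "residual")

term_vector <- function(vp) {
  c(vp$adjusted, vp$fractions)[VARPART_TERMS]
}

#' Run the pipeline across a tree ensemble
#'
#' One full fit per tree (lambda estimation through VARPART/RDA);
#' per-tree records collect the lambda estimate, the seven VARPART
#' terms, and the explanatory loadings on the canonical axes.  Failed
#' trees are logged and reported; more than 5\% failures aborts the run.
#' Permutation tests are deferred to the representative tree by default
#' (run them per-tree via \code{n_perm}).
#'
#' @param ds a \code{study_dataset}.
#' @param trees a \code{tree_set} (or \code{multiPhylo}).
#' @param n_perm per-tree permutations (default 0; see
#'   \code{\link{select_representative}} for the representative-only
#'   workflow).
#' @param range_y passed to \code{\link{fit_tree}}.
#' @param seed RNG seed.
#' @return an object of class \code{ensemble_result}: \code{records}
#'   (one row per tree), \code{loadings} (per-tree explanatory loadings),
#'   \code{failures}, and the representative tree index.
#' @export
run_ensemble <- function(ds, trees, n_perm = 0L, range_y = FALSE,
                         seed = NULL) {
  if (inherits(trees, "tree_set")) trees <- trees$trees
  if (inherits(trees, "phylo")) trees <- c(trees)
  k <- length(trees)
  rec <- vector("list", k)
  lds <- vector("list", k)
  failures <- character(0)
  for (i in seq_len(k)) {
    ft <- tryCatch(fit_tree(ds, trees[[i]], n_perm = n_perm,
                            range_y = range_y, seed = seed),
                   error = function(e) e)
    if (inherits(ft, "error")) {
      failures <- c(failures, paste0("tree ", i, ": ", conditionMessage(ft)))
      next
    }
    tv <- term_vector(ft$varpart)
    rec[[i]] <- data.frame(tree = i, lambda = ft$lambda$lambda,
                           logL = ft$lambda$logL, t(tv),
                           check.names = FALSE)
    L <- ft$rda$loadings_explanatory
    lds[[i]] <- data.frame(tree = i,
                           variable = rownames(L)[row(L)],
                           axis = colnames(L)[col(L)],
                           loading = as.numeric(L))
  }
  if (length(failures) > 0.05 * k)
    stop("more than 5% of trees failed:\n",
         paste(utils::head(failures, 5L), collapse = "\n"))
  records <- do.call(rbind, rec)
  er <- structure(list(records = records,
                       loadings = do.call(rbind, lds),
                       failures = failures,
                       count = k), class = "ensemble_result")
  er$representative <- select_representative(er)
  er
}

#' Select the representative tree of an ensemble
#'
#' The tree whose vector of seven VARPART adjusted-R2 terms is closest
#' (Euclidean distance, equal weights) to the component-wise ensemble
#' means; ties break to the lowest tree index.
#'
#' @param er an \code{ensemble_result}.
#' @return the representative tree index.
#' @export
select_representative <- function(er) {
  M <- as.matrix(er$records[, VARPART_TERMS])
  mu <- colMeans(M)
  d2 <- rowSums(sweep(M, 2L, mu)^2)
  er$records$tree[which.min(d2)]
}

#' Summarize an ensemble run
#'
#' Per VARPART term: ensemble mean, observed lower and upper bounds,
#' and the representative tree's value; plus the pooled lambda sample
#' (histogram source) and the per-tree loading scatter.
#'
#' @param er an \code{ensemble_result}.
#' @return list with \code{terms} (data.frame), \code{lambda}
#'   (mean/sd/sample), \code{loadings}, and \code{representative}.
#' @export
summarize_ensemble <- function(er) {
  M <- as.matrix(er$records[, VARPART_TERMS])
  rep_row <- which(er$records$tree == er$representative)
  terms <- data.frame(term = VARPART_TERMS,
                      mean = colMeans(M),
                      lower = apply(M, 2L, min),
                      upper = apply(M, 2L, max),
                      representative = as.numeric(M[rep_row, ]),
                      row.names = NULL)
  list(terms = terms,
       lambda = list(mean = mean(er$records$lambda),
                     sd = stats::sd(er$records$lambda),
                     sample = er$records$lambda),
       loadings = er$loadings,
       representative = er$representative)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("ensemble_result:", nrow(x$records), "of", x$count,
      "trees fitted; representative tree =", x$representative, "\n")
  cat("  mean lambda =", format(mean(x$records$lambda), digits = 3), "\n")
  invisible(x)
}
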