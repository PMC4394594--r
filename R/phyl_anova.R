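#' One-way ANOVA F statistic
#'
#' Between-group mean square over within-group mean square.
#'
#' @param values numeric trait vector.
#' @param groups group labels (coerced to factor).
#' @return the F statistic.
#' @export
anova_f <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) <= nlevels(groups))
    stop("need more observations than groups")
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssw / dfw <= 0)
    stop("zero within-group variance: F is infinite")
  (ssb / dfb) / (ssw / dfw)
}

#' Simulation-based phylogenetic ANOVA
#'
#' Compares the observed one-way F statistic against a null
#' distribution built by simulating the trait under Brownian motion on
#' the tree (rate and root from the observed trait's GLS fit), keeping
#' the observed group assignment fixed.  p = (1 + #(F_sim >= F_obs)) /
#' (1 + n_sim).
#'
#' @param trait named numeric vector of trait values (names = taxa).
#' @param groups group labels in the same order.
#' @param tree rooted \code{phylo} covering the taxa (or a covariance
#'   matrix).
#' @param n_sim number of Brownian simulations (default 1000).
#' @param seed RNG seed.
#' @return an object of class \code{anova_result}: \code{F},
#'   \code{p}, group sizes, \code{n_sim}, the simulated null sample,
#'   and the count of degenerate simulations discarded.
#' @export
phylogenetic_anova <- function(trait, groups, tree, n_sim = 1000L,
                               seed = NULL) {
  taxa <- names(trait)
  C <- if (inherits(tree, "phylo")) phylo_covariance(tree, taxa) else tree
  if (!is.null(taxa) && !is.null(rownames(C)))
    C <- C[taxa, taxa]
  F_obs <- anova_f(trait, groups)
  fit <- profile_loglik(as.numeric(trait), C)
  ch <- chol(fit$sigma2 * C)
  if (!is.null(seed)) set.seed(seed)
  n <- length(trait)
  F_sim <- numeric(n_sim)
  dropped <- 0L
  for (b in seq_len(n_sim)) {
    x <- fit$root + as.numeric(crossprod(ch, stats::rnorm(n)))
    F_sim[b] <- tryCatch(anova_f(x, groups), error = function(e) NA_real_)
  }
  dropped <- sum(is.na(F_sim))
  F_sim <- F_sim[!is.na(F_sim)]
  structure(list(
    F = F_obs,
    p = (1 + sum(F_sim >= F_obs)) / (1 + length(F_sim)),
    group_sizes = table(factor(groups)),
    n_sim = n_sim,
    dropped = dropped,
    null_sample = F_sim), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("phylogenetic ANOVA: F =", format(x$F, digits = 4),
      " p =", format(x$p, digits = 3),
      " (", length(x$null_sample), "simulations )\n")
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Sorts ascending, multiplies the k-th smallest p by (m - k + 1),
#' enforces monotonicity, caps at 1.  Output order matches input order.
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value family")
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, pvals[o] * (m - seq_len(m) + 1L))
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  names(out) <- names(pvals)
  out
}

#' Binarize an ordinal character into a grouping variable
#'
#' Presence/absence split at score > 0 by default (how the caudal-lobe
#' and flexor-process hypotheses are framed); an arbitrary threshold can
#' collapse 0/1/2 prominence grades differently.
#'
#' @param cm a \code{character_matrix}.
#' @param character one of the six character names.
#' @param threshold scores strictly greater are "present".
#' @return named integer vector (0/1) over taxa with non-missing scores.
#' @export
binarize_character <- function(cm, character, threshold = 0L) {
  if (!character %in% colnames(cm$scores))
    stop("unknown character: ", character)
  v <- cm$scores[, character]
  v <- v[!is.na(v)]
  stats::setNames(as.integer(v > threshold), names(v))
}

#' Phylogenetic ANOVA over a family of character/trait tests
#'
#' Runs \code{\link{phylogenetic_anova}} for each character-trait pair
#' and applies Holm adjustment within the declared family.
#'
#' @param cm a \code{character_matrix} (extant taxa used).
#' @param tt a \code{trait_table}.
#' @param tree rooted \code{phylo}.
#' @param characters characters to binarize and test.
#' @param traits trait columns of \code{tt} (log scale by default,
#'   consistent with the model transforms).
#' @param thresholds named binarization cutpoints per character.  The
#'   default splits \code{iip2} and \code{dpf} at presence (score > 0)
#'   and \code{fp} at prominence (score > 1): every extant study taxon
#'   carries at least a weak flexor process, so a presence split is
#'   degenerate there.
#' @param n_sim simulations per test.
#' @param seed RNG seed (test-specific seeds are derived from it).
#' @return data.frame: character, trait, F, p_raw, p_holm, n_sim.
#' @export
anova_family <- function(cm, tt, tree,
                         characters = c("iip2", "fp", "dpf"),
                         traits = c("logAR", "logM"),
                         thresholds = c(iip2 = 0L, fp = 1L, dpf = 0L),
                         n_sim = 1000L, seed = 1L) {
  rows <- expand.grid(character = characters, trait = traits,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    th <- thresholds[[rows$character[i]]]
    grp <- binarize_character(cm, rows$character[i],
                              threshold = th %||% 0L)
    keep <- intersect(names(grp),
                      tt$taxon[!is.na(tt[[rows$trait[i]]])])
    keep <- setdiff(keep, taxa(cm)[cm$extinct])
    tr <- stats::setNames(tt[[rows$trait[i]]][match(keep, tt$taxon)], keep)
    a <- phylogenetic_anova(tr, grp[keep], tree, n_sim = n_sim,
                            seed = seed + i)
    res[[i]] <- data.frame(character = rows$character[i],
                           trait = rows$trait[i],
                           F = a$F, p_raw = a$p, n_sim = n_sim)
  }
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p_raw)
  out
}
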