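#' Configuration for the synthetic study generator
#'
#' Defaults mirror the shape of the study data: 74 taxa of which 3 are
#' extinct, Brownian log AR and log M with phylogenetic signal 0.7
#' (close to the ensemble-mean lambda of the study), and six ordinal
#' characters produced by thresholding liabilities coupled to log AR.
#'
#' @param n_taxa total taxa (>= 4).
#' @param n_extinct taxa flagged extinct (traits masked).
#' @param birth_rate pure-birth speciation rate (per unit time).
#' @param lambda_true phylogenetic signal of the simulated traits.
#' @param sigma2 named Brownian rates for \code{logAR} and \code{logM}
#'   (trait variance per unit branch length).
#' @param root named root states for \code{logAR} and \code{logM}.
#' @param beta coupling of each character's liability to log AR
#'   (recycled to 6).
#' @param thresholds list of ascending threshold vectors, one per
#'   character (binary iip1 has a single cutpoint).
#' @param n_trees trees in the synthetic ensemble (perturbations of the
#'   true tree over the extant taxa).
#' @param n_nni nearest-neighbour-interchange moves per ensemble tree
#'   (topology noise).
#' @param jitter_sd standard deviation of the multiplicative log-normal
#'   branch-length jitter per ensemble tree.
#' @param seed RNG seed (mandatory).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_taxa = 74L, n_extinct = 3L, birth_rate = 1,
                       lambda_true = 0.7,
                       sigma2 = c(logAR = 0.015, logM = 0.5),
                       root = c(logAR = log(7.6), logM = log(0.6)),
                       beta = 1, thresholds = NULL, n_trees = 10L,
                       n_nni = 2L, jitter_sd = 0.1, seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory")
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  if (lambda_true < 0 || lambda_true > 1) stop("lambda_true must be in [0,1]")
  beta <- rep_len(beta, length(CHARACTERS))
  names(beta) <- CHARACTERS
  if (is.null(thresholds))
    thresholds <- stats::setNames(lapply(CHARACTERS, function(ch)
      if (CHAR_MAX[[ch]] == 1L) 0 else c(-0.6, 0.6)), CHARACTERS)
  for (th in thresholds)
    if (is.unsorted(th, strictly = TRUE)) stop("thresholds must ascend")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_extinct = as.integer(n_extinct),
                 birth_rate = birth_rate, lambda_true = lambda_true,
                 sigma2 = sigma2, root = root, beta = beta,
                 thresholds = thresholds, n_trees = as.integer(n_trees),
                 n_nni = as.integer(n_nni), jitter_sd = jitter_sd,
                 seed = as.integer(seed)), class = "sim_config")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Exponential waiting times between speciation events (rate k * birth
#' rate with k extant lineages), a uniformly chosen lineage splitting at
#' each event, and a final Exp(n * birth rate) stretch so all tips end
#' at the same depth.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @param tip_labels optional tip labels (default t1..tn, shuffled onto
#'   tips at random).
#' @return an ultrametric rooted \code{phylo}.
#' @export
simulate_pure_birth_tree <- function(n, birth_rate = 1, seed = NULL,
                                     tip_labels = NULL) {
  if (n < 2L) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  max_nodes <- 2L * n - 1L
  parent <- integer(max_nodes)
  btime <- numeric(max_nodes)      # time the node's subtending branch ends
  root <- 1L
  btime[root] <- 0
  nxt <- 2L
  active <- integer(0)
  split <- function(v, t) {
    kids <- c(nxt, nxt + 1L)
    parent[kids] <<- v
    btime[v] <<- t
    nxt <<- nxt + 2L
    kids
  }
  t <- 0
  active <- split(root, 0)
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    active <- c(active[-i], split(active[i], t))
  }
  t_end <- t + stats::rexp(1L, rate = n * birth_rate)
  btime[active] <- t_end
  # renumber to ape convention: tips 1..n, root n+1, internals follow
  is_tip <- seq_len(max_nodes) %in% active
  newid <- integer(max_nodes)
  newid[active] <- seq_len(n)
  newid[!is_tip] <- n + seq_len(n - 1L)
  edge <- cbind(newid[parent[-root]], newid[-root])
  len <- btime[-root] - btime[parent[-root]]
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = sample(tip_labels),
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a continuous trait under lambda-scaled Brownian motion
#'
#' A single draw from N(root, sigma2 * C_lambda) over the tips.
#'
#' @param tree rooted \code{phylo}.
#' @param lambda_true signal in [0, 1].
#' @param sigma2 Brownian rate (>= 0).
#' @param root root state.
#' @param seed RNG seed.
#' @return named numeric vector over tips.
#' @export
simulate_traits <- function(tree, lambda_true = 1, sigma2 = 1, root = 0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(tree)
  n <- nrow(C)
  if (sigma2 == 0) return(stats::setNames(rep(root, n), rownames(C)))
  Cl <- lambda_scale(C, lambda_true)
  x <- root + as.numeric(crossprod(chol(sigma2 * Cl), stats::rnorm(n)))
  stats::setNames(x, rownames(C))
}

#' Simulate ordinal characters from a latent liability
#'
#' Per character, liability = beta * (standardized latent trait) +
#' Brownian noise on the tree (unit tip variance on average), and the
#' ordinal score counts the thresholds lying below the liability.
#'
#' @param tree rooted \code{phylo}.
#' @param latent named continuous driver (e.g. simulated log AR).
#' @param beta per-character coupling (recycled to 6).
#' @param thresholds list of ascending cutpoints per character; default
#'   as in \code{\link{sim_config}}.
#' @param seed RNG seed.
#' @param extinct optional logical vector flagging extinct taxa.
#' @return a \code{character_matrix}.
#' @export
simulate_characters <- function(tree, latent, beta = 1, thresholds = NULL,
                                seed = NULL, extinct = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- rep_len(beta, length(CHARACTERS))
  if (is.null(thresholds))
    thresholds <- lapply(CHARACTERS, function(ch)
      if (CHAR_MAX[[ch]] == 1L) 0 else c(-0.6, 0.6))
  C <- phylo_covariance(tree)
  taxa <- rownames(C)
  z <- as.numeric(scale(latent[taxa]))
  Cn <- C / mean(diag(C))          # unit average tip variance for the noise
  ch_chol <- chol(Cn)
  sc <- matrix(NA_integer_, length(taxa), length(CHARACTERS),
               dimnames = list(taxa, CHARACTERS))
  for (j in seq_along(CHARACTERS)) {
    noise <- as.numeric(crossprod(ch_chol, stats::rnorm(length(taxa))))
    liab <- beta[j] * z + noise
    s <- vapply(liab, function(l) sum(l > thresholds[[j]]), 0L)
    sc[, j] <- pmin(s, CHAR_MAX[[CHARACTERS[j]]])
  }
  character_matrix(sc, extinct = extinct %||% rep(FALSE, length(taxa)))
}

#' Perturb a tree with topology and branch-length noise
#'
#' A configurable number of random nearest-neighbour interchanges
#' followed by multiplicative log-normal branch-length jitter
#' (mean-one), emulating the spread of credible trees around a point
#' estimate.
#'
#' @param tree rooted \code{phylo}.
#' @param n_nni NNI moves (0 keeps the topology).
#' @param jitter_sd log-scale sd of the branch jitter (0 keeps lengths).
#' @param seed RNG seed.
#' @return a perturbed \code{phylo}.
#' @export
perturb_tree <- function(tree, n_nni = 2L, jitter_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- if (n_nni > 0L) phangorn::rNNI(tree, moves = n_nni) else tree
  if (jitter_sd > 0)
    out$edge.length <- out$edge.length *
      exp(stats::rnorm(length(out$edge.length), -jitter_sd^2 / 2,
                       jitter_sd))
  out
}

#' Generate a complete synthetic study dataset
#'
#' A "true" pure-birth tree over all taxa carries Brownian log AR and
#' log M (shared signal lambda_true) and the thresholded characters;
#' the returned tree set holds NNI/branch-jitter perturbations of the
#' true tree pruned to the extant taxa, emulating phylogenetic
#' uncertainty around a credible estimate.  (Fully independent random
#' topologies degenerate: the joint lambda collapses to the zero
#' boundary on every tree, where an ultrametric covariance is scalar
#' and all trees yield identical fits.)  Extinct taxa keep their
#' character scores but have traits masked.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{characters}, \code{traits}, \code{trees}
#'   (a \code{tree_set}), and \code{true_tree}.
#' @export
make_synthetic_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  labels <- sprintf("s%02d", seq_len(n))
  true_tree <- simulate_pure_birth_tree(n, config$birth_rate,
                                        tip_labels = labels)
  logAR <- simulate_traits(true_tree, config$lambda_true,
                           config$sigma2[["logAR"]],
                           config$root[["logAR"]])
  logM <- simulate_traits(true_tree, config$lambda_true,
                          config$sigma2[["logM"]],
                          config$root[["logM"]])
  extinct <- stats::setNames(rep(FALSE, n), names(logAR))
  if (config$n_extinct > 0L)
    extinct[sample(names(logAR), config$n_extinct)] <- TRUE
  cm <- simulate_characters(true_tree, logAR, beta = config$beta,
                            thresholds = config$thresholds,
                            extinct = extinct[rownames(phylo_covariance(true_tree))])
  ord <- taxa(cm)
  AR <- exp(logAR[ord]); M <- exp(logM[ord])
  AR[extinct[ord]] <- NA; M[extinct[ord]] <- NA
  tt <- trait_table(ord, AR = AR, M = M)
  extant <- ord[!extinct[ord]]
  extant_tree <- ape::keep.tip(true_tree, extant)
  trees <- lapply(seq_len(config$n_trees), function(i)
    perturb_tree(extant_tree, n_nni = config$n_nni,
                 jitter_sd = config$jitter_sd))
  class(trees) <- "multiPhylo"
  list(characters = cm, traits = tt,
       trees = tree_set(trees, taxa = extant),
       true_tree = true_tree)
}
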