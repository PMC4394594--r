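---
title: "Methods: phylogenetic ordination of flight-feather attachment osteology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic ordination of flight-feather attachment osteology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wing aspect ratio ($AR = b^2/S$, span squared over area) governs the
induced-drag/inertia trade-off of avian flight, but the feathers that
define it rarely fossilize. Bony correlates of flight-feather
attachment — ulnar quill knobs (`drp`, `crp`), dorsal phalangeal fossae
(`dpf`), the internal index process and its caudal lobe (`iip1`,
`iip2`), and the flexor process of digit III (`fp`) — do fossilize.
`wingrda` asks, across a phylogenetically diverse extant sample, how
much of the variation in these six ordinal characters is statistically
explained by $AR$ and body mass $M$, and what that implies for
inferring wing shape in extinct taxa.

The package ships the study dataset (74 taxa: 71 extant with complete
traits, 3 extinct with characters only) and implements the full
analysis as reusable, tested modules.

## The model chain

1. **Ordination of characters.** Pairwise Hamming distances
   (mismatches over shared non-missing characters; a multistate
   mismatch counts 1) are made Euclidean-embeddable by the Cailliez
   correction — the smallest constant $c$ added to every off-diagonal
   distance such that the Gower-centered squared-distance matrix
   $B = -\tfrac12 J D^2 J$ has no negative eigenvalues. Principal
   coordinates are the eigenvectors of $B$ scaled by
   $\sqrt{\lambda_k}$; the first 12 axes (the published choice) form
   the response matrix $Y$.
2. **Phylogenetic signal.** For each candidate tree, the Brownian tip
   covariance $C$ (shared root-to-MRCA path lengths) is scaled by
   Pagel's $\lambda$ on the off-diagonal. One joint $\hat\lambda$ is
   estimated by maximizing the *sum* of per-variable profile
   log-likelihoods over the 12 PCO axes plus $\log AR$ and $\log M$,
   with each variable's root state and rate profiled out analytically
   ($\hat a = (\mathbf 1^\top C_\lambda^{-1}\mathbf 1)^{-1}
   \mathbf 1^\top C_\lambda^{-1}x$, $\hat\sigma^2 = r^\top
   C_\lambda^{-1} r/n$). Boundary values are allowed; likelihood-ratio
   tests against $\lambda = 0$ and $1$ use $\chi^2_1$.
3. **Centering, ranging, whitening.** Every variable is centered on
   its GLS root estimate; $\log AR$ and $\log M$ (heterogeneous units)
   are then divided by their maximum absolute centered value so they
   span $[-1, 1]$; finally everything is premultiplied by the
   symmetric inverse square root $C_\lambda^{-1/2}$, so that
   cross-products of transformed matrices embed $C^{-1}$ — ordinary
   least squares on the whitened data is PGLS.
4. **RDA and VARPART.** Redundancy analysis is the eigendecomposition
   of the fitted cross-product from the no-intercept multivariate
   regression of whitened $Y$ on whitened $X = (\log AR, \log M)$;
   canonical axes carry explained variation, non-canonical axes the
   residual. Variation partitioning adjusts each of the three model
   $R^2$ values (Ezekiel: $1-(1-R^2)(n-1)/(n-m-1)$) and derives unique
   fractions, intersection, and residual from the additivity
   identities (held to $10^{-12}$ by construction and by test).
5. **Tree ensemble.** The whole chain runs once per tree; the
   representative tree minimizes the Euclidean distance between its
   seven VARPART terms and the ensemble means (ties to the lowest
   index). Permutation tests (999 by default) run on the
   representative tree.
6. **Extinct taxa.** Fossils never enter any fit. Their PCO scores
   (computed jointly in step 1) are centered with the *extant* root
   estimates and projected onto the canonical eigenvectors; a fitted
   $AR$ comes from inverting the transform chain (below).
7. **Phylogenetic ANOVA.** One-way $F$ for binarized characters
   against $\log AR$ / $\log M$, with the null $F$ distribution built
   from Brownian simulations on the tree (rate and root from the
   observed trait's GLS fit) and Holm adjustment across the declared
   six-test family.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| retained PCO axes | 12 | the published choice; 8 axes carry >1% each |
| permutations | 999 | standard add-one permutation resolution of 0.001 |
| ANOVA simulations | 1000 | the published setting |
| $\lambda$ search tolerance | 1e-8 | bounded 1-D optimize plus endpoint checks |
| ranging | $\log AR$, $\log M$ only | only $X$ has heterogeneous units; a flag ranges $Y$ too |
| ANOVA trait scale | $\log_e$ | consistent with the model transforms; flag exposed |

## Numerical choices

- **Cailliez constant** via the largest real eigenvalue of the
  classic $2n \times 2n$ companion matrix; verified in tests against a
  bisection oracle on the Gower spectrum. The constant is added to
  *distances*, not squared distances, and the correction deliberately
  separates taxa with identical scorings (their corrected distance is
  $c$, not 0).
- **Relative eigenvalues** are fractions of the sum of *positive*
  eigenvalues of the corrected solution, which reproduces the
  published eigenvalue table.
- **Axis signs** in PCO and RDA are arbitrary; both are oriented by a
  fixed taxon-order-weighted rule so runs are bit-reproducible.
- **Symmetric (spectral) square root** rather than Cholesky for the
  whitening operator: it is unique, symmetric, and order-independent.
- **Character projections**: the published projection table contains
  values outside $\pm 1$, so its scaling cannot be plain correlation
  and is not otherwise specified. Both a correlation scaling (bounded)
  and a regression scaling (correlation times axis standard deviation,
  unbounded) are computed; neither is asserted against the published
  table.
- **Back-predicted AR** for passively placed fossils inverts, in
  order: a no-intercept regression of centered/ranged $\log AR$ on the
  extant centered canonical scores, the ranging scale, the root
  centering, and the $\log_e$ transform. A fossil at the centered
  origin therefore back-predicts the root $AR$ exactly — matching the
  published observation that fossil placements fall near the root
  value.
- **Permutation scheme**: whole rows of the whitened response are
  permuted (whitening has already absorbed the phylogenetic
  covariance). The published second-axis test against "a random
  rearrangement of the original PCO axes" suggests an axis-shuffle
  variant; only the taxon-permutation default is implemented and
  asserted.
- **fp binarization**: every extant study taxon has at least a weak
  flexor process, so presence/absence (score > 0) is degenerate; the
  ANOVA family splits `fp` at prominence (score > 1) by default, with
  the threshold map exposed as configuration.

## What the synthetic generator emulates — and what it does not

`make_synthetic_study()` draws an ultrametric pure-birth tree
(exponential waiting times), Brownian $\log AR$ and $\log M$ sharing
one true $\lambda$ (default 0.7, near the study's ensemble mean of
0.67), and six ordinal characters from a threshold model: liability =
$\beta \times$ standardized $\log AR$ + Brownian noise with unit
average tip variance, cut at fixed thresholds ($\{-0.6, 0.6\}$ for
three-state characters, $\{0\}$ for the binary one). Defaults (74
taxa, 3 extinct, roots $\log 7.6$ and $\log 0.6$, rates 0.015 and 0.5
giving tip spreads like the real $\log AR$ and $\log M$) were chosen
once from the shape of the study data.

Tree-set uncertainty is emulated by NNI moves plus mean-one log-normal
branch-length jitter around the true tree. Fully independent random
topologies were tried first and are degenerate: with data generated on
a different tree, the joint $\hat\lambda$ collapses to the 0 boundary
on every tree, where an ultrametric covariance is scalar and all
ensemble records coincide — no spread, and the whitening path never
exercised. Perturbed trees behave like a posterior sample around a
credible estimate, which is what a supertree subset is.

The generator does **not** emulate: correlated character liabilities
beyond the shared driver, missing scores, fossil non-ultrametricity
(extinct taxa sit at the present), measurement error in $AR$ and $M$,
or diversified taxon sampling. A green synthetic test therefore
establishes that the estimators recover known truth under the stated
model, not that the biological model is adequate for any real clade.

## Known limitations

- The published tree-dependent numbers (VARPART table, mean
  $\hat\lambda$ = 0.67, canonical eigenvalues, fossil $AR$ fits)
  require the external 1,000-tree supertree subset, which is not
  redistributable inside the package; they are encoded as data targets
  with a runnable recipe (`inst/scripts/reproduce_published.R`).
- One $\lambda$ is assumed shared across all variables (the joint
  estimate of the source protocol); per-variable $\lambda$ is out of
  scope, as are other signal models (OU, Blomberg's K).
- Characters are treated as unordered for distance purposes (any
  mismatch counts 1), exactly as a Hamming metric demands — ordinal
  magnitude information is deliberately discarded at that step.
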