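---
title: "Phylogenetic geometric morphometrics of the abelisaurid maxilla: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic geometric morphometrics of the abelisaurid maxilla: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Late Cretaceous abelisaurid theropods are hypothesized to have been
specialist hunters — short, tall, highly mineralized skulls adapted to
seize-and-hold predation — whereas their Jurassic relatives and the
ceratosaurian/tetanuran outgroups retain a generalist strike-and-tear
morphology. The maxilla, as the main tooth-bearing rostral bone, is both
well preserved in the fossil record and mechanically central to either
strategy. `phylomorph` implements a complete quantitative pipeline for
asking whether maxillary shape tracks predation strategy on a
time-calibrated phylogeny: 2D geometric morphometrics of landmark
configurations, phylogenetic ordination, phylogenetic signal and
phylogenetic regression, disparity through time, and competitive fitting
of multivariate evolutionary models under alternative regime paintings —
a *prior* hypothesis (only Late Cretaceous abelisaurids are specialists)
against a *posterior* hypothesis discovered by an unsupervised
regime-shift search (which additionally recruits the Early Cretaceous
*Spectrovenator* into the specialist regime).

# The pipeline, stage by stage

## Landmarks and superimposition

Input configurations (6 fixed landmarks + 13 curve semilandmarks in the
bundled template) are read from TPS files (`read_tps()`), right elements
are mirrored explicitly (`mirror_config()`; reflection is never applied
silently during alignment), and incomplete specimens are completed by
thin-plate-spline interpolation from a reference (`estimate_missing_tps()`).
The TPS interpolant uses the standard 2D kernel $U(r) = r^2\log r$ and
reproduces affine deformations exactly, which the tests exploit as an
oracle. The default reference is the consensus of a preliminary
superimposition of the complete specimens only; this mirrors the usual
behavior of missing-landmark estimators in the field's software.

`gpa_align()` performs Generalized Procrustes Analysis: center, scale to
unit centroid size, rotate by SVD (determinant forced positive), update
the consensus, iterate to a consensus root-mean-square change below
`tol = 1e-8` (at most 100 iterations). Semilandmarks then slide along
finite-difference tangents of their curves, by default minimizing
thin-plate-spline bending energy against the consensus (the
Procrustes-distance criterion is available by flag). The joint
slide-and-re-average problem is degenerate along common curve
reparameterizations — all specimens can drift together along their curves
without changing bending energy to first order — so the sliding phase is
explicitly monitored: each sliding pass is accepted only if it lowers the
total Procrustes sum of squares, and sliding stops at the first
non-improving pass before a final plain re-superimposition. This keeps
the classical descent guarantee while still removing the arbitrary
spacing of curve points (in the bundled fixture it reduces total bending
energy by roughly two thirds relative to the unslid alignment). Final
coordinates are orthogonally projected to the tangent space at the
consensus; the exact unit-centroid-size invariant therefore holds for the
pre-projection coordinates (`project = FALSE`), and only to second order
in shape dispersion afterwards. Centroid sizes are taken from the raw
configurations before scaling, as the allometry proxy.

## Phylogenetic ordination and axis retention

`phylo_pca()` eigendecomposes the GLS (evolutionary) covariance
$R = (Y-1a)^\top C^{-1}(Y-1a)/(n-1)$, where $C$ is the Brownian-motion
tree covariance and $a$ the GLS mean; scores are projections of the
GLS-centered data. `paca()` instead rotates the centered data onto the
eigenvectors of $Y_c^\top C\,Y_c$, concentrating phylogenetic signal in
the leading axes, with axis importance reported as tip dispersion
(summed squared scores). Both reduce exactly to ordinary PCA when
$C = I$, which is tested. Axis signs follow a deterministic convention
(largest-magnitude loading positive). Variance proportions for Phylo-PCA
are reported from the eigenvalues of the GLS covariance; because the
field is ambiguous about whether such percentages are eigenvalue- or
tip-variance-based, both vectors are stored on every ordination object.
`select_axes()` retains the smallest leading block reaching 90%
cumulative proportion — variance for Phylo-PCA, tip dispersion for PACA.

## Signal, regression, disparity

`kmult()` is the multivariate generalization of Blomberg's K: the ratio
of ordinary to GLS-weighted sums of squares around the phylogenetic
mean, normalized so Brownian data give $K \approx 1$ (verified by
simulation calibration). Significance comes from permuting specimens
across tips; the effect size $Z$ standardizes $\log K$ against the
permutation distribution. When `optimize_lambda = TRUE` the tree
covariance is first rescaled by a maximum-likelihood Pagel $\lambda$
(profile ML over $[0,1]$; the univariate profile matches
`phytools::phylosig()` to six decimals in the tests). A boundary estimate
$\hat\lambda = 0$ means a star phylogeny explains the data best, and K,
p, Z and logL are reported as `NA` sentinels, following the convention of
the reference implementation's output tables. With more variables than
specimens the ML rate matrix is singular, so the $\lambda$ profile is
computed on the non-degenerate principal axes of the data (a rotation
dropping only zero-variance directions).

`pgls_anova()` fits shape against the predation-strategy factor and log
centroid size (plus interaction) by GLS, with sequential (type I) sums of
squares, the factor entered first (order configurable); significance and
$Z$ come from residual randomization of the reduced model (RRPP) in the
whitened space, with $p = (b+1)/(n_{perm}+1)$ and $n_{perm} = 999$ by
default. On a star tree the F statistics equal ordinary sequential ANOVA
exactly, and the empirical type-I error of the factor test is checked to
sit at the nominal 5%. Centroid size enters log-transformed (standard
allometric practice), with a flag for the raw scale.
`compare_hypotheses_pgls()` runs both regime codings under an identical
permutation schedule and reports $\Delta Z$ and $\Delta R^2$.

`dtt()` computes mean relative subclade disparity (mean pairwise squared
score distance, each subclade divided by the total) at every divergence
time: a lineage is *present* at time $t$ if its branch spans $t$, the
lineage splitting exactly at $t$ included, so the curve starts at 1 at
the root. The envelope is the pointwise 2.5–97.5% band over Brownian
simulations (default 1000) whose rate matrix is the GLS estimate from
the data.

## Discrete regimes

The binary strategy character is modelled by the symmetric (equal-rates)
2-state Markov chain, fitted by Felsenstein pruning with a stationary
(uniform) root prior, the default of the reference implementation. `simmap_sample()` draws stochastic character maps by sampling
node states from their conditional distributions and then branch
histories by endpoint-conditioned uniformization: for the 2-state
equal-rates chain the uniformized kernel is the deterministic state swap,
so the number of transitions on a branch is a parity-constrained Poisson
draw and the histories are exact — no rejection loop is needed.
`paint_from_hypothesis()` builds the deterministic clade paintings of the
two hypotheses, placing the shift on the stem branch of the smallest
clade containing all specialists (a crown-node convention is available;
the figure-level evidence does not distinguish the two).

## Evolutionary models

`fit_evo_model()` fits five multivariate Gaussian models on the retained
Phylo-PC scores: BM, multi-rate BM over a regime painting (BMM), OU with
one optimum (OU1), OU with per-regime optima (OUM) and early burst (EB).
Every likelihood is evaluated exactly through the dense
$nm \times nm$ covariance implied by the model — BM: $R \otimes C$; BMM:
$\sum_k R_k \otimes S_k$ with $S_k$ the shared time in regime $k$; EB:
$R \otimes (e^{bC}-1)/b$; OU: the path-integral kernel with a diagonal
pull matrix $\alpha$ (scalar/diagonal per trait; a full $\alpha$ is out
of scope) and the root fixed at the (root-regime) optimum, so optima
weights sum to one. Mean parameters are always profiled out by GLS, so
the optimizer works only on covariance parameters, with rate matrices
parameterized by log-diagonal Cholesky factors (positive definiteness by
construction). BM and EB have closed-form profiles (EB is a 1-D search in
$b \le 0$); BMM/OU use Nelder-Mead followed by BFGS from 5 seeded starts
(first start moment-based, the rest jittered). The engine is tested to
$10^{-8}$ against an independently coded dense oracle that integrates
covariance kernels numerically, for all five model types.

Parameter counts per model (m traits, K regimes): BM
$m(m{+}1)/2 + m$; BMM $2\cdot m(m{+}1)/2 + m$; OU1
$m(m{+}1)/2 + 2m$; OUM $m(m{+}1)/2 + m + Km$; EB BM$+1$. Model
comparison uses plain AIC weights within the declared set (AICc is also
reported); "best" models are those within 2 AIC units of the minimum.
When a list of stochastic maps is supplied for BMM/OUM the model is
fitted on each and the median-logL fit returned with the dispersion
recorded; the deterministic hypothesis paintings used by the pipeline
need a single fit.

`adequacy_bootstrap()` simulates from the fitted model (default 500
datasets), refits, and builds 95% percentile intervals for the diagonal
parameters; refits warm-start at the generating values. A model is
adequate when every observed diagonal parameter lies inside its interval.

## Regime-shift discovery

`surface_forward()` is the forward phase of the stepwise adaptive
landscape search: starting from a single-regime OU model it proposes a
new regime originating at every branch, scores each painting by a joint
small-sample AIC over traits (each trait an independent univariate OU
with its own $\alpha$ and $\sigma^2$ profiled analytically, optima by
GLS), and accepts the best proposal while the criterion improves by more
than 2 units — the conventional substantial-support cutoff for stepwise
information-criterion searches. The parameter count includes one location
parameter per accepted shift in addition to the per-trait optima, which
is what gives the criterion its guard against spurious shifts on small
trees; without it the greedy search accepts noise shifts on a majority of
null datasets at this study's size (n = 17). Even with the guard,
calibration simulations show the forward-only search retains an
appreciable false-positive appetite under weak-pull (BM-like) nulls at
n = 17 — a known property of greedy shift searches — which is why the
pipeline, like the study design it follows, emphasizes agreement of the
discovered shift across the four clade/removal configurations rather
than any single run. The backward (convergence-collapsing) phase is out
of scope.

# The synthetic data generator

Because the original landmark and tree files are not redistributable
inside this package, every integration test runs on generators with the
statistical structure the analysis assumes. `sim_tree()` produces
birth-death trees with a fraction of tips truncated before the present
(fossil, non-ultrametric sampling). `sim_landmarks()` evolves shape in
the Procrustes tangent space of a mean configuration — deviations are
drawn from any `simulate_from_model()` model on a small set of latent
orthonormal deformation axes, mapped into coordinate space, then
perturbed by i.i.d. digitization noise and optionally masked.

`study_fixture()` freezes one such dataset at the study's dimensions: a
17-taxon calibrated tree (9 abelisaurids including *Spectrovenator* + 8
outgroups, branch lengths in Myr, tips ending at their approximate
stratigraphic ages), a 19-point maxilla-like template, and the two
strategy codings. The landmark data evolve under a two-rate Brownian
model painted by the posterior clade (specialists 3x faster), with a
fixed displacement at the clade stem emulating the rapid divergence the
shift search is meant to detect, a decaying variance spectrum across the
four latent axes (50/25/15/10% of a total rate of
$8\times10^{-5}$ per Myr — shape data concentrate variance on leading
axes), digitization noise of 1% of structure size, random per-specimen
similarity transforms, and missing landmarks on *Llukalkan* and
*Abelisaurus* (the study's two estimated taxa). What the fixture does
*not* emulate: anatomically realistic deformation modes, correlated
digitization error, taphonomic biases in which landmarks go missing, or
the exact variance partition of the real maxillae — so tests passing on
the fixture demonstrate correctness and calibration of the methods under
the study's conditions, not numerical reproduction of the published
tables, whose values require the original supplementary files.

# Numerical choices and degenerate inputs

* Zero-length branches are replaced by 0.1 Myr before any model fitting.
* Label joins are exact after whitespace-to-underscore normalization; any
  mismatch across landmarks/tree/strategy inputs aborts with an explicit
  diff.
* `lambda = 0` triggers sentinel (`NA`) signal output rather than
  undefined arithmetic; monomorphic discrete characters return a boundary
  rate instead of erroring.
* OU covariances use `expm1`-based kernels so $\alpha \to 0$ degrades
  smoothly to BM (tested at $\alpha = 10^{-8}$).
* All stochastic operations take explicit seeds; the pipeline derives
  per-stage seeds deterministically from the master seed and stage name,
  making whole runs bit-reproducible.
* Ties in model selection (within 2 AIC units) are reported as a best-model
  set, never broken silently.

# Problem sizes used by the test-suite

The statistical property checks run at sizes chosen to keep the full
suite comfortably re-runnable on one CPU while leaving the Monte-Carlo
error well below the asserted margins: Kmult calibration 200 BM
simulations; PGLS type-I error 500 simulations at 99 permutations;
parameter recovery 100 (BM) / 30 (BMM) / 20 (OU) replicates at the
study's n = 17, m = 4; shift-search calibration 20 null and 15 shifted
searches; adequacy coverage 30 meta-replicates at 100 bootstrap
simulations; dtt coverage 50 replicates at 60 simulations. The acceptance script runs the
full pipeline (999 permutations, 500 dtt simulations, 100 adequacy
simulations) on all four clade/removal cells.

# Known limitations

* OU pull matrices are diagonal; fully coupled multivariate OU and >2
  regimes are not implemented.
* At the study's sample size (17 fossil tips) the OU pull and diffusion
  parameters are jointly weakly identified: only their ratio (the
  stationary variance) is estimated reliably, and maximum-likelihood
  diffusion diagonals carry a substantial upward bias. The calibration
  tests report this honestly; BM and multi-rate BM rates do not share the
  problem.
* The shift search implements only the forward phase; convergent regimes
  are never merged.
* PGLS offers sequential sums of squares only.
* The dtt stage reports the curve and envelope but no disparity-index
  significance test.
* 3D landmarks, curve resampling from outlines, and digitization-replicate
  error analysis are out of scope.
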