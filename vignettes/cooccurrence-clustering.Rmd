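---
title: "Clustering genomic regions by track co-occurrence"
author: "intervalmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering genomic regions by track co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervalmix)
```

## The problem

A ChIP-seq experiment reduces a protein's binding (or a histone mark's
presence) to a *track*: a list of genomic intervals in BED format. Given
D such tracks, a biologist routinely asks how they co-occur: which
factors bind together, which exclude each other, and what fraction of
the regions bound by A and B is also bound by C. Pairwise overlap
statistics do not scale past a handful of tracks, and marginal
(genome-wide) correlations miss co-binding that is confined to a small
compartment of the genome.

`intervalmix` answers these questions with a model-based clustering of
the regions themselves. Given N regions of interest — supplied by the
user, or taken as the merged union of all track intervals — it forms the
binary overlap matrix

$$Y_{id} = \mathbf{1}\{\text{region } i \text{ overlaps track } d\},$$

and clusters the rows of $Y$.

## The model

Regions are assumed to come from a mixture of $K$ latent classes. Class
$k$ has prior probability $\pi_k$ and, within a class, tracks occur
independently with class-specific probabilities:

$$P(Y_{i\cdot} \mid Z_i = k) \;=\; \prod_{d=1}^{D}
  q_{kd}^{\,Y_{id}} (1 - q_{kd})^{1 - Y_{id}},$$

a product-of-Bernoulli (latent class) mixture. The $K \times D$ matrix
$Q = (q_{kd})$ *is* the co-occurrence summary: row $k$ reads as "in
cluster $k$, track $d$ occurs with probability $q_{kd}$". Independence
holds only *within* a class; the mixture over classes induces arbitrary
marginal dependence among tracks, which is exactly what makes the model
useful with a modest parameter count ($K(D+1) - 1$ free parameters).

Parameters are estimated by EM on the observed-data (marginal)
log-likelihood

$$\ell(\Psi) = \sum_{i=1}^N \log \sum_{k=1}^K \pi_k
  \prod_d q_{kd}^{Y_{id}}(1-q_{kd})^{1-Y_{id}}.$$

The E-step computes responsibilities
$\mu_{ik} = P(Z_i = k \mid Y_i, \Psi)$ by Bayes' rule; the M-step has
the closed form $\pi_k = \sum_i \mu_{ik} / N$ and
$q_{kd} = \sum_i \mu_{ik} Y_{id} / \sum_i \mu_{ik}$. Both are evaluated
in log space with a log-sum-exp, so extreme probabilities cannot
underflow.

Because EM only guarantees a local optimum, starting values matter. We
run K-means on the raw 0/1 rows ten times, keep the run with the
smallest total within-cluster sum of squares, and use its centers
(clamped into the open unit interval) and relative cluster sizes as the
initial $Q$ and $\pi$.

```{r fit}
truth <- sim_params(K = 3, D = 6)
sim <- simulate_matrix(truth, n = 1000, seed = 1)
fit <- fit_em(sim$Y, K = 3, seed = 1)
fit
match_components(fit, truth)$q_mae
```

## Choosing the number of clusters

`scan_k()` fits every $K$ in a range independently (fresh K-means
initialization per $K$; no warm starts, so the fits stay comparable) and
reports two suggestions:

* the minimizer of
  $\mathrm{BIC}_K = -2\ell_K + (K(D+1)-1)\log(ND)$, and
* the *elbow* of the log-likelihood-versus-$K$ curve.

With genomic sample sizes ($N$ in the $10^4$–$10^5$ range) the BIC
penalty is routinely too weak: the likelihood gain of one more component
exceeds $C\log(ND)$ even for small real effects, so BIC keeps drifting
upward in $K$. The elbow — the point where the per-component
likelihood gain collapses — is then the more interpretable choice. The
visual rule is formalized here as the interior $K$ maximizing the
negative discrete second difference $-(\ell_{K+1} - 2\ell_K +
\ell_{K-1})$, with ties (including an exactly linear curve) broken
toward the smaller $K$ and flagged as degenerate. Both curves are always
returned, and users are expected to override either suggestion when the
curves say otherwise.

```{r scan}
scan <- scan_k(sim$Y, k_min = 1, k_max = 6, seed = 1)
scan
```

Independent fits can land in local optima, which occasionally makes the
likelihood curve locally non-monotone in $K$; `scan_k()` warns rather
than fails, since a small dip is diagnostic information, not an error.

## Querying co-occurrence from the parameters alone

Within-class independence makes $(\pi, Q)$ a sufficient summary: for
any subset $S$ of tracks with required values $v_d$,

$$P(Y_{id} = v_d,\ d \in S) = \sum_k \pi_k \prod_{d \in S}
  q_{kd}^{v_d}(1-q_{kd})^{1-v_d},$$

with unconstrained tracks marginalizing out exactly. Conditionals are
ratios of two such joints. No raw data, no $2^D$ enumeration:

```{r query}
es <- read_params(system.file("extdata", "mouse_es15_params.tsv",
  package = "intervalmix"))
query_probability(es, "Nanog=1")
query_probability(es, "Nanog=1 | Oct4=1")
```

The shipped table holds published parameter estimates from a
15-protein mouse embryonic stem cell co-binding analysis. Printed
tables round probabilities to two decimals, so `read_params()`
renormalizes a $\pi$ row that misses 1 by up to 0.05 and clamps
boundary entries (see below); queries on such tables are reproducible
but inherit the table's printed precision.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tol` | `1e-6` | relative change in $\ell$ that stops EM |
| `max_iter` | `1000` | EM iteration cap |
| `n_restarts` | `10` | K-means restarts for initialization |
| `seed` | `1` | drives K-means restarts (restart $r$ uses `seed + r - 1`) and, in `scan_k()`, the per-$K$ seeds `seed + 97K` |
| clamp $\varepsilon$ | `1e-6` | bounds on estimated $q_{kd}$ |

Numerical choices worth knowing about:

* **Clamping.** Well-separated data push $\hat q_{kd}$ to exactly 0
  or 1, where $\log q$ diverges. Estimation (M-step, K-means centers,
  `read_params()`) stores values clamped to $[\varepsilon,
  1-\varepsilon]$, and every likelihood evaluation clamps defensively.
  The raw `mixture_params()` constructor and the simulator, however,
  accept exact 0/1, so degenerate generative settings (e.g. $q = 1$
  giving a column of all ones) behave exactly.
* **Empty components.** If a component's total responsibility reaches
  zero mid-run, its $q$ row is reset to 0.5 and the fit is flagged
  `degenerate` instead of dividing by zero; treat that flag as "K is
  too large for this data".
* **Label order and ties.** Mixture labels are arbitrary, so fitted
  components are relabelled by decreasing $\pi$ before return; hard
  assignments take the maximum-responsibility cluster with ties going
  to the lowest index. `match_components()` undoes label switching
  against a reference by best-permutation matching (exhaustive for
  $K \le 7$, greedy above).
* **Convergence.** EM stops when the relative change in $\ell$ drops
  below `tol`; at that point one further EM cycle moves parameters by
  a comparable relative amount, which the tests verify.

## Interval handling conventions

BED input is 0-based half-open, and overlap means sharing at least one
base pair under that convention, so `[100, 200)` and `[200, 300)` do
*not* overlap. Strand is parsed but ignored everywhere. When the user
supplies no region list, the regions of interest are the merged union
of all tracks; the merge fuses abutting intervals (the common
`bedtools merge` convention), which keeps zero-gap fragments from
inflating the region count — users comparing region counts across tools
should check that convention first. Duplicated regions in a
user-supplied list are kept as distinct rows: the user's list is
authoritative.

`cluster_feature_overlap()` reports, per cluster and feature track, the
observed fraction of cluster regions hitting the feature next to the
fraction expected for randomly placed regions, namely the feature's
merged length divided by an explicit genome size (a TSS track covering
1% of the genome has expected fraction 0.01). The genome size is never
inferred from data extents. Building a mutually exclusive feature
partition (TSS/TES/exon/intron/intergenic) is the caller's
responsibility; the function warns when feature tracks overlap each
other, in which case per-cluster fractions need not sum to 1.

## What the simulator does and does not emulate

`simulate_matrix()` draws directly from the generative model;
`simulate_beds()` additionally realizes a drawn matrix as BED files —
non-overlapping regions on up to 9 synthetic chromosomes (the cap keeps
lexicographic chromosome order equal to layout order), with one random
sub-interval per (region, occurring track) — and guarantees that
re-reading the files and recomputing the overlap matrix reproduces the
simulated $Y$ bit-exactly.

`sim_params()` builds the ground truth used across the package's
simulation studies: baseline occurrence 0.1 everywhere, and for each
component its own disjoint block of $\lfloor D/K \rfloor$ consecutive
tracks at 0.9, leftover tracks staying at baseline, uniform $\pi$.
This makes the components exchangeable — equally strong and pairwise
equidistant — which matters for model-order studies: unequal or
overlapping signature blocks create coarse hierarchical structure whose
early splits dominate the likelihood gains, and the elbow then reflects
that coarse structure rather than the true component count.

The default study sizes are $N = 2000$ regions and $D = 10$ tracks with
$K = 3$ (three tracks per signature). A model-order study at true
$K = 8$ instead uses $D = 16$: with only 10 tracks, eight disjoint
signatures can be one track wide at most, and a one-track signature at
0.9-versus-0.1 carries so little information (per-split likelihood
gains comparable to EM restart noise) that no order-selection method
can resolve $K = 8$ there. $D = 2K$ is the smallest design in which
every component carries a multi-track signature of the same geometry as
the $K = 3$ default. The parameter-recovery study uses $N = 2000$,
$D = 5$, $K = 3$ with signature blocks of widths (2, 2, 1), every pair
of components differing by 0.8 in at least two tracks.

What passing these studies shows — and what it does not: simulated
matrices satisfy the model exactly (independence within class,
identical $q$ for all regions of a class). Real peak data violate both:
occurrence probabilities vary with region length and signal strength,
and residual dependence within a class is common. Recovery of $(\pi,
Q, K)$ under the model therefore validates the estimation machinery,
not the model's adequacy for any particular data set; on real data the
fitted $Q$ is a descriptive summary whose resolution is bounded by the
elbow's subjectivity.

## Known limitations

* Regions are modelled as exchangeable and independent; no spatial
  smoothing along the genome (this is a clustering of regions, not a
  segmentation of the genome).
* Binary overlap discards peak strength and overlap extent; a ≥ 1 bp
  intersection counts fully.
* The elbow rule is a formalized heuristic. On data whose likelihood
  curve bends gradually, the suggestion is weakly determined; inspect
  both curves.
* Enrichment output is descriptive (observed versus length-expected
  fractions); no significance testing is attached.
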