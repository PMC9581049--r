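---
title: "K-Neighbourhood Analysis of SMLM Point Patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{K-Neighbourhood Analysis of SMLM Point Patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(kna)
```

Single molecule localisation microscopy (SMLM) produces point sets rather
than pixel images: each detected fluorophore contributes one or more
localisations with nanometre-scale coordinates. **K-Neighbourhood Analysis
(KNA)** describes each localisation by its local spatial topology, in a way
that is invariant to the absolute density of points, and projects that
description into a universal two-dimensional coordinate system in which
aggregation, randomness and segregation occupy distinct regions. This
vignette walks through the model, the numerical choices the package makes,
and the scope of each component.

## 1. The neighbourhood feature table

For every localisation $i$ in an image, the distances to its $K$ nearest
neighbours form the *nearest-neighbour vector*
$\mathrm{NNV}_i = (D_{i1}, D_{i2}, \dots, D_{iK})$, with
$D_{i1} \le D_{i2} \le \dots \le D_{iK}$. Stacking the vectors of all $N$
localisations gives the $N \times K$ *nearest-neighbour feature table*
(NNFT). The package computes it with a cell-list grid search
(`compute_nnft()`), which is validated against an $O(N^2)$ brute-force
oracle in the test suite; the two agree exactly.

Dividing each vector by its own last entry yields the *normalised* vector
$\mathrm{nNNV}_i = \mathrm{NNV}_i / D_{iK}$, a non-decreasing sequence on
$(0, 1]$ ending at 1. Normalisation removes scale: a dense cluster and a
sparse cluster with the same internal geometry produce the same nNNV. All
shape information about the local point arrangement is retained.

Under complete spatial randomness (CSR, a homogeneous Poisson process with
intensity $\lambda$), the expected $j$-th neighbour distance has the closed
form $E[D_j] = \Gamma(j + \tfrac12) / (\Gamma(j)\sqrt{\pi\lambda})
\approx \sqrt{j / (\pi\lambda)}$, so the expected normalised profile is
approximately $\sqrt{j/K}$ — a square-root ramp. Clustered neighbourhoods
fall below this ramp early (many close neighbours), segregated or isolated
neighbourhoods rise above it. These closed forms are used as oracles in the
acceptance tests.

A related by-product is the local density estimate
$\mathrm{Den}_i = (K/2) / (\pi \bar{D}_i^2)$ with
$\bar{D}_i = \frac{1}{K}\sum_j D_{ij}$. Under CSR this estimator carries a
known multiplicative bias of $9/8$ (a consequence of
$E[D_j] \propto \sqrt{j}$), which the tests verify; the estimator is used
as a *relative* density axis (`log10Den`), where a constant factor is
immaterial.

## 2. The SNPCA basis: a universal coordinate system

Rather than fit a new PCA per image, the package projects every image onto
one fixed basis trained on CSR — *spatial neighbourhood PCA* (SNPCA). The
shipped basis (`default_basis()`) was trained on a Poisson pattern with
$\lambda = 10^5$ points in the unit square at $K = 100$:

1. simulate the CSR pattern (`simulate_csr()`);
2. compute and normalise the NNFT;
3. discard localisations closer to the window boundary than their own
   $D_{iK}$ (`filter_edge_points()`), so no neighbourhood is truncated by
   the edge;
4. mean-centre the columns and take the eigenvectors of the covariance
   (`fit_snpca()`).

Because the training data are normalised, the basis applies to any image at
the same $K$, regardless of magnification or density. Two conventions are
fixed so that results are comparable across installations:

* **Sign convention.** Each loading vector is flipped so that its
  largest-magnitude coefficient is positive. With this convention SNPC1 is
  *positive* for sparse/segregated profiles and *negative* for clustered
  ones, and within a cluster SNPC1 increases from the core to the rim.
* **Persistence.** The basis is stored as JSON at 17 significant digits
  (`write_basis()` / `read_basis()`), which makes round trips bit-exact.

Projecting an image's edge-unfiltered, normalised NNFT onto the first two
components gives per-localisation coordinates $(\mathrm{PC1},
\mathrm{PC2})$, usually re-expressed in polar form $(r, \theta)$
(`polar_coords()`). Empirically, $r$ grows with how far the local
neighbourhood departs from CSR, and $\theta$ encodes the *kind* of
departure; together with `log10Den` these are the per-localisation KNA
features (`kna_features()`).

## 3. The simulator and its ground truth

`simulate_clustered_pattern()` generates the reference testbed: parent
molecules from a Poisson process, each replaced by a bivariate-normal
cluster of localisations with a uniform random count, plus Poisson
background noise. The defaults (parent intensity 5 on a 10 × 10 window,
per-axis variance 0.000625, counts uniform on 10–90, noise intensity 50)
are the package's reference design and are used throughout validation.

Each of the four stages draws from its own RNG sub-stream, so changing the
noise intensity does not perturb the signal draw. Each point carries ground
truth: `D_B` (distance to its parent; for noise, to the nearest parent),
`D_BNN` (its parent's distance to the nearest other parent) and `N_clus`
(its cluster's localisation count). The acceptance tests verify the
qualitative recoveries that motivate the method: $r$ correlates with
cluster isolation (`D_BNN`), $\theta$ separates noise from signal, and
relative SNPC1 within a cluster tracks `D_B`.

## 4. Grouping localisations across an ensemble

To compare images, each localisation is placed in a 3-D histogram over
(`log10Den`, PC1, PC2) with `n_bins` equal-width bins per axis over the
pooled range of all images (`build_grid()`, `bin_localisations()`). The
per-image bin counts form a compositional *frequency table* (rows sum to
one). Bins not occupied in **every** image are set aside as a pooled
"leftover" set (`filter_common_bins()`).

The *nine-group scheme* (`nine_group_scheme()`) then reduces the bins to
interpretable groups:

1. k-means with $k = 4$ (50 restarts, seeded) on the common bins'
   frequency profiles;
2. the leftover set split at its median `log10Den` into two groups
   (4 + 2 = 6);
3. every cluster whose bins straddle SNPC1 = 0 with at least 10% of its
   localisations on each side is split at SNPC1 = 0, turning clustered and
   non-clustered sub-populations into separate groups. With three
   straddling clusters this yields 9 groups; the provenance of each split
   is recorded.

Localisations inherit their bin's group (`assign_localisation_groups()`),
giving per-image group frequency vectors.

**A note on scale.** The default `n_bins = 50` (125,000 cells) presumes
millions of localisations per image, as in real SMLM data. On the small
simulated ensembles used in the examples and tests, almost no cell is
occupied in every image at that resolution, so those analyses set
`n_bins = 12`. This is a deliberate package-level scale choice, exposed as
a parameter; the scheme itself is unchanged.

## 5. Comparing conditions

Group (or bin) frequencies are compositional, so Euclidean machinery is
applied after a centred log-ratio (CLR) transform
(`logratio_transform()`; zeros receive a 0.5 pseudocount by default, or an
error under `zero_policy = "strict"`). `ordinate()` computes a PCA of the
CLR rows plus a *between-component analysis* (BCA): a size-weighted PCA of
the condition means with every image projected onto it, separating
between-condition from within-condition structure.

Two seeded permutation tests operate on the ordination scores, both with
the exact p-value identity
$p = (1 + \#\{\text{null} \ge \text{observed}\}) / (1 + n_\text{perm})$:

* `dispersion_test()` — an F statistic on distances to group centroids
  (the test suite cross-checks the observed statistic against an
  independent implementation of the same dispersion measure);
* `mean_difference_test()` — a size-weighted sum of squared distances of
  condition means from the grand mean.

Both are calibrated in the acceptance suite: type-I error within
[0.03, 0.07] at $\alpha = 0.05$, with power ≥ 80% at the tested effect
sizes.

## 6. Co-localisation enrichment

With a second channel, `colocalise()` flags channel-A localisations within
a distance threshold (default 10 nm) of any channel-B localisation. The
*enrichment score* of group $g$ is
$\log_{10}(\mathrm{Freq}^{TRUE}_g / \mathrm{Freq}_g)$ — the group's share
among co-localised points relative to its overall share. A group holding
20% of all points but 40% of co-localised ones scores
$\log_{10} 2 \approx 0.301$. Groups with zero co-localised points receive
the same 0.5 pseudocount (or $-\infty$ under the strict policy).

Significance is assessed against a multinomial null
(`null_enrichment()`): co-localised labels are drawn from the observed
group frequencies 10,000 times and the 5th/95th percentile band of the
null scores is reported, with the same pseudocount policy applied inside
the null. `multi_threshold_profile()` repeats the analysis over several
thresholds; at a threshold comparable to the image diameter every point
co-localises and all scores collapse to zero, a useful negative control.

## 7. Visualisation

`theta_to_hue()` maps the polar angle bijectively onto the hue circle;
`auto_hue_offset()` rotates the map so the angular mode of the densest
quartile (the large-cluster signature) lands on blue/violet (hue 0.7).
`render_points()` is a deterministic rasteriser — the same inputs always
produce byte-identical PNG files, which the determinism tests rely on.

## 8. End-to-end runs

`run_single_image()` and `run_ensemble()` wire the stages together from a
`run_config()` (or a YAML file via `read_run_config()`), log per-stage
localisation counts, and write feature tables, group assignments,
provenance and renders to an output directory. Every stochastic stage is
seeded from the configuration, so reruns are bit-identical. A thin
command-line front end is installed at
`system.file("cli", "kna.R", package = "kna")`.

## Limitations

* Strictly 2-D; no handling of localisation uncertainty, blinking-induced
  overcounting, or drift (assumed corrected upstream).
* The universal basis requires $N > K$ localisations per image and a fixed
  $K$ shared between basis and analysis; the shipped basis uses $K = 100$.
* The nine-group scheme's k-means step is seeded and restarted but still a
  local optimiser; provenance records what was split.
* The simulator covers Poisson parents with isotropic Gaussian clusters
  and uniform counts — the reference design — not arbitrary cluster shape
  distributions.
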