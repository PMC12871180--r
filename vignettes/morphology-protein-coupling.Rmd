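---
title: "Modeling morphology-protein coupling with geographically weighted regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling morphology-protein coupling with geographically weighted regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphgwr)
```

## The problem and the model

Multiplexed ion beam imaging (MIBI) yields, per tissue spot, a cell
segmentation mask and one intensity raster per protein marker. A recurring
question in spatial proteomics is whether a marker's per-cell abundance is
coupled to cell morphology — and whether that coupling is *spatially
homogeneous*. A single global regression assumes one slope for the whole
spot; diffusion barriers, paracrine gradients and local microenvironments
make that assumption suspect.

`morphgwr` models the per-cell response $y_i$ (a marker intensity feature)
as a linear function of morphology whose coefficients vary continuously
over the tissue coordinates $(u_i, v_i)$:

$$y_i = \beta_0(u_i, v_i) + \sum_{k=1}^{p}\beta_k(u_i, v_i)\,x_{ik} + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2).$$

Geographically weighted regression (GWR) estimates the coefficient surfaces
by solving, at every observation location, a kernel-weighted least-squares
problem

$$\hat\beta(u, v) = (X^\top W(u, v)\, X)^{-1} X^\top W(u, v)\, y,$$

where $W(u, v) = \mathrm{diag}(w_{i1}, \ldots, w_{in})$ downweights
observations by their Euclidean pixel distance $d_{ij}$ from the fitting
location. Two kernels are provided:

* gaussian (default): $w = \exp(-d^2 / 2b^2)$;
* bisquare: $w = (1 - (d/b)^2)^2$ for $d < b$, zero beyond the bandwidth.

The bandwidth $b$ (pixels) is the one structural tuning parameter. It is
selected by minimizing the corrected Akaike criterion

$$\mathrm{AICc} = 2n\log\hat\sigma + n\log 2\pi +
  n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},$$

with $\mathrm{tr}(S)$ the trace of the hat matrix of the local fits (the
model's effective parameter count) and $\hat\sigma = \sqrt{\mathrm{RSS}/n}$.
The global OLS baseline is scored with the same formula at
$\mathrm{tr}(S) = p$, so $\Delta\mathrm{AICc} =
\mathrm{AICc}_{\mathrm{OLS}} - \mathrm{AICc}_{\mathrm{GWR}}$ compares the
two models on a common scale; positive values favor the local model.

## Pipeline stages and their parameters

1. **Normalization** (`robust_rescale`). Each channel is clipped to its 1st
   and 99th intensity percentiles and rescaled affinely to $[0, 1]$.
   Percentiles are computed over all pixels (background included) with the
   standard linear-interpolation convention, per spot. The rescale is
   invariant to positive affine transforms of the raw channel, so the
   choice of raw intensity units upstream is immaterial. Constant channels
   map to zero and are flagged degenerate rather than producing NaN.
2. **Per-cell features** (`build_cell_table`). Per marker and cell:
   fraction of positive pixels, integrated density, mean, top-5% mean
   ($\lceil 0.05 n\rceil$ pixels, at least one), maximum, Gini coefficient
   ($0$ for a constant signal, defined $0$ at zero mean), number of
   positive-signal blobs (8-connected components), and $\log(1+x)$ /
   $\sqrt{x}$ transforms of integrated density and top-5% mean. Positivity
   thresholds are Li's minimum cross-entropy per cell, falling back to an
   exhaustive Otsu search when the iteration fails or the pixel vector has
   too few distinct values, and to $+\infty$ (no positives) for a constant
   cell. A config switch computes one threshold per image instead of per
   cell. The $\log(1+x)$ form is used for "log" so zero-signal cells stay
   finite.
3. **Morphometrics and MorphScore** (`morph_score`). Area, perimeter
   (count of exposed 4-neighbor pixel edges), eccentricity (second central
   moments), solidity (pixel count over pixels inside the convex hull of
   member pixel centers), extent, and equivalent diameter
   $\sqrt{4\,\mathrm{area}/\pi}$ are z-scored and reduced by PCA; the
   MorphScore is the first principal component score, with the sign fixed
   so the loading on area is nonnegative (larger cells score higher).
   Constant columns are dropped before the PCA — on purely Voronoi
   synthetic data solidity is one such column, since Voronoi cells are
   convex. The MorphScore is the default (and only default) morphometric
   predictor $x_{i1}$; all six morphometrics can be used instead via the
   `predictors` argument.
4. **Spatial graph and marker screen** (`build_graph`, `autocorr_screen`).
   The adjacency graph over cell centroids is the Delaunay triangulation;
   edges longer than the 99th percentile of edge lengths (inverted-ECDF
   convention, so small graphs are never pruned) are removed as hull
   artifacts, and if the triangulation fails or the graph is disconnected,
   symmetric k-nearest-neighbor edges ($k = 6$, doubling until connected)
   restore connectivity. Weights are binary, row-standardized. Moran's I
   and Geary's C of each marker's response (default: log1p integrated
   density) are tested with a two-sided permutation test, $p = (1 +
   \#\{|T_b - E_0| \ge |T_{\mathrm{obs}} - E_0|\})/(B + 1)$, using the null
   expectations $E_0 = -1/(n-1)$ and $1$ respectively; the $+1$ correction
   keeps p-values positive. Markers with Moran p-value $\le \alpha = 0.05$
   are retained, ranked by $|I|$, truncated to the top 8 — mirroring a
   screen that carries only spatially structured markers into the local
   regression.
5. **Regression and diagnostics** (`fit_gwr`, `fit_ols`, `fit_ridge`,
   `residual_autocorrelation`). Per retained marker the package fits OLS,
   ridge ($\lambda = 1$ on z-scored predictors, intercept unpenalized; the
   closed-form solve is cross-checked in the tests against the
   augmented-least-squares identity), and GWR with AICc-selected
   bandwidth, and reports $R^2$/MAE/MSE, AICc, $\Delta$AICc, and residual
   Moran's I / Geary's C. A local model that has truly captured the
   spatial heterogeneity leaves residuals with near-null autocorrelation.

## The synthetic generator

Real MIBI spots are unavailable at desk scale, so the generator produces
spots with *known* coefficient surfaces — the exact structure GWR assumes —
making every stage verifiable:

* **Geometry.** Centroids are sampled on a jittered grid (jitter 40% of
  the grid pitch, clamped so centroids stay $\ge 2$ px apart) and the spot
  is tessellated by nearest centroid. This yields convex, Voronoi-like
  cells whose area and elongation vary naturally; grid capacity is
  $\lfloor H/2\rfloor\lfloor W/2\rfloor$ cells.
* **Coupling.** Per marker, cell $i$'s mean intensity is
  $\beta_0(u_i, v_i) + \beta_1(u_i, v_i)\,s_i + \varepsilon_i$ where $s_i$
  is the same MorphScore the analysis side recomputes (the generator runs
  the morphometric PCA on its own tessellation), so the generative model
  is exactly linear in the fitted predictor. Coefficient surfaces are
  declared as `field_spec`s: constant, linear gradient, gaussian bump, or
  zero-mean sinusoid.
* **Defaults.** The heterogeneous cohort uses a gaussian-bump intercept
  (amplitude 6, length scale 256 px) and a zero-mean sinusoidal slope
  (amplitude 1, wavelength 256 px — two full periods across a 512 px
  spot), cell noise SD 0.3, 300 cells per 512 × 512 spot. These were fixed
  from a variance budget: the bump keeps rendered intensities positive (so
  the clip-at-zero of nonnegative intensities almost never binds), the
  slope wavelength is an order of magnitude above the ~30 px cell spacing
  (resolvable by a local kernel), and the noise is small against the
  ~1.5-unit spatial signal while dominating what a *global* line can
  explain — the zero-mean slope makes the population-level slope
  approximately zero, which is precisely the regime where a global model
  fails and a local one should not.
* **Rendering.** Pixels within a cell share the cell value plus i.i.d.
  pixel noise at 10% of the cell-level noise SD (per-cell aggregates are
  the analysis unit, so pixel noise is deliberately subdominant), clipped
  at zero.

What the generator does **not** emulate: mass-spectrometry counting noise,
antibody binding efficiency, channel crosstalk, cell-type mixtures,
nucleus/membrane compartments, multi-spot patient hierarchies, or
segmentation errors. Passing tests therefore demonstrate that the pipeline
recovers spatially varying linear couplings when they exist in the stated
form — not that real tissue satisfies that form.

## Numerical choices

* Local solves use a rank-revealing QR with tolerance $10^{-10}$;
  a bandwidth too small to support $p$ coefficients raises a localized
  singularity error naming the location rather than silently regularizing.
* The hat-matrix trace is accumulated location-by-location from the
  fitting point's leverage $x_i^\top (X^\top W X)^{-1} x_i w_{ii}$; no
  $n \times n$ smoother matrix is materialized.
* Bandwidth search: golden-section on $[1.5\,\mathrm{med\,NN}, \mathrm{diameter}]$
  with 0.01 px tolerance; singular candidate fits score $+\infty$; the
  endpoints are evaluated explicitly and a winner at (or within tolerance
  of) an endpoint is flagged as a boundary solution. On pixel coordinates
  AICc often prefers very small kernels, so boundary flags at the lower
  floor are common and are surfaced rather than hidden.
* Local $R^2$ uses the locally weighted RSS against the locally weighted
  TSS about the locally weighted mean.
* Voronoi pixel ties go to the lower cell id; tessellation is strict
  nearest-centroid and is checked against a brute-force oracle in tests.
* Constant-image normalization, zero-mean Gini, all-constant morphometric
  tables and zero-variance responses are explicit degenerate cases with
  defined outputs or typed errors — never NaN propagation.

## Problem sizes in the test suite

The packaged tests run the full study geometry (512 × 512 px, 300 cells,
8 markers) for the headline GWR-vs-OLS comparison, 50 replicates of 150
cells for the residual-whitening property, 200 replicates at $n = 200$
with 999 permutations for type-I calibration of the Moran test, and
$n \in \{100, 300, 1000\}$ for slope-surface recovery. These sizes were
chosen to estimate each property stably at desk scale.

## Known limitations

* One bandwidth is shared by all coefficients (no multiscale GWR) and the
  model is strictly linear in the predictors; mixed or neural variants are
  out of scope.
* The marker screen tests marginal spatial autocorrelation of the response,
  not of the morphology coupling itself; a marker with spatially varying
  slope but spatially flat response variance can evade the screen.
* Permutation tests treat cells as exchangeable under the null; strong
  density gradients in the graph can make the test conservative.
* AICc-based selection can return boundary solutions at the minimum
  feasible bandwidth; downstream interpretation should treat the flagged
  bandwidth as a selector artifact, not a biological length scale.
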