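# morphgwr

Spatially varying regression of morphology–protein coupling in multiplexed
imaging. `morphgwr` is for spatial-proteomics analysts who suspect that the
relationship between single-cell morphology and a protein marker's
abundance is not constant across a tissue spot — because of diffusion
barriers, local signaling, or microenvironment structure — and who want to
quantify that heterogeneity instead of averaging over it.

Per spot (a segmentation mask plus one raster per marker), the pipeline:

1. normalizes channels by 1st/99th-percentile robust rescaling;
2. extracts per-cell marker-intensity features (positive fraction,
   integrated density, top-5% mean, Gini coefficient, blob count, …) with
   Li/Otsu thresholding, and six morphometrics reduced by PCA to a single
   **MorphScore**;
3. screens markers by permutation-tested Moran's I / Geary's C on a
   Delaunay adjacency graph (kNN fallback, row-standardized weights);
4. fits, per retained marker, **geographically weighted regression**

   y_i = β0(u_i, v_i) + β1(u_i, v_i)·MorphScore_i + ε_i,
   β̂(u, v) = (XᵀW(u,v)X)⁻¹XᵀW(u,v)y,

   with a gaussian or bisquare kernel and AICc-selected bandwidth, against
   global OLS and ridge baselines, reporting R²/MAE/MSE, ΔAICc and
   residual spatial autocorrelation.

A synthetic-data module generates MIBI-like Voronoi spots with *known*
coefficient surfaces, so every stage — screening, fitting, bandwidth
selection, residual diagnostics — is verified against ground truth.

## Worked example

The numbered scripts under `analysis/` run the workflow on a simulated
spot (300 cells, four spatially coupled markers `hot1–hot4`, four
unstructured controls `ctrl1–ctrl4`):

```sh
Rscript analysis/01_simulate.R    # writes results/spot/
Rscript analysis/02_features.R    # writes results/cells.csv
Rscript analysis/03_autocorr.R    # writes results/autocorr.csv
Rscript analysis/04_fit_models.R  # writes results/report.csv
Rscript analysis/05_benchmark.R   # writes results/benchmark.csv
```

The screen keeps exactly the coupled markers:

```
  marker morans_i gearys_c p_morans p_gearys
1   hot1  0.23526    0.791    0.001    0.001
5  ctrl1  0.04276    0.938    0.144    0.125
selected (p <= 0.05, ranked by |Moran's I|): hot1, hot4, hot3, hot2
```

and the model comparison shows what the local model buys:

```
  marker r2_ols r2_gwr delta_aicc morans_resid_ols morans_resid_gwr bandwidth
1   hot1 0.0870  0.748        243            0.251          -0.0679      38.2
2   hot4 0.0984  0.746        237            0.237          -0.0408      38.2
```

Read: global OLS explains ~9% of the variance of `hot1`'s log intensity,
GWR explains ~75% with a 38 px kernel; the AICc difference (+243) strongly
favors the local model even after charging it for its effective
parameters, and the residual Moran's I drops from clearly positive (0.25,
spatially structured errors) to near the permutation null — the local
model has absorbed the spatial structure. The `boundary_flag` column marks
bandwidths pinned at the search floor, which AICc on pixel coordinates
tends to produce.

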