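# nucflux

Quantification of **passive nuclear transport kinetics** from two-channel
time-lapse fluorescence microscopy of permeabilized cells, with a fully
ground-truthed synthetic-data generator, the complete measurement chain
(segmentation → traces → kinetic metrics → ratiometrics → statistics),
and a giant-unilamellar-vesicle (GUV) control analysis.

## The problem and who this is for

In permeabilized-cell uptake assays, the plasma membrane is perforated
(digitonin or streptolysin O) so that fluorescent cargo of a chosen
molecular weight (MW) reaches the nuclear envelope directly; a
cell-impermeant DNA stain imaged at *t* = 0 marks the nuclei of
successfully permeabilized cells, and the cargo channel is imaged over
time. Biophysicists use such assays to ask whether passive transport
through nuclear pore complexes is Fickian — i.e. whether bigger cargo is
always slower — and how that depends on cell line, tissue and pathology.
`nucflux` implements the analysis end of such a study as tested,
reusable R functions.

## The model and metrics

Nuclear influx is summarized model-free from a polynomial fit of each
nucleus's uptake trace (intensities rescaled to [0, 1] by
2^bit-depth − 1, so 65,535 → 1.0 at 16 bit):

* **T1/2** — first time the fitted nuclear curve crosses half of its
  total (plateau) uptake, interpolated between frames;
* **normalized Y1/2** — nuclear / peri-nuclear fitted intensity at T1/2,
  where the peri-nuclear ring (nucleus mask dilated 3 px, minus all
  nuclei, within the cell) cancels each cell's permeabilization extent,
  photobleaching and local cargo availability;
* **max uptake rate** — maximum of the analytic derivative of the fit.

Per cell line, cross-MW ratios `metric_MWhigh / metric_MWlow` cancel any
line-specific multiplicative factor: with per-pore unit diffusion
`UD_MW` and pore count `N`, `(UD_high·N)/(UD_low·N) = UD_high/UD_low`.
The log10 ratio table is the study's heatmap; entries whose direction
contradicts Fickian size dependence (or that sit within a ±0.02 log10
band of equality, "equal or faster") are starred non-Fickian.

The synthetic generator drives all verification: first-order exchange
`dFn/dt = k (Fperi − Fn/P)` with `k = UD_MW · N`, partition `P ≥ 1`,
instantaneous bath step, optional bleaching, scaled-Poisson shot noise,
Gaussian read noise and quantization — every nucleus carries its true
`k`, half-time and plateau.

## Worked example

```r
library(nucflux)

cargoes <- default_cargoes()             # free dye 700 Da, 3 kDa, 10 kDa
line    <- default_cell_lines()$MCF10A   # healthy breast model, N = 1000 pores
acq     <- acquisition_spec(frame_interval = 0.56, duration = 45, seed = 42)

sim <- simulate_field(line, cargoes$alexa488, acq, n_nuclei = 12)
q   <- quantify_stack(sim$stack, cell_mask = sim$truth$cell_mask,
                      total_cells = sim$truth$n_cells)
head(q$metrics[, c("nucleus_id", "population", "t_half_s",
                   "y_half_normalized", "max_rate_per_s")])
#>   nucleus_id population t_half_s y_half_normalized max_rate_per_s
#> 1          1     bright 3.519679          1.002449     0.06504697
#> 2          2     bright 3.518306          1.002556     0.06519067
#> 3          3     bright 3.512653          1.001365     0.06514665
#> 4          4     bright 3.522516          1.002881     0.06510001
#> 5          5     bright 3.523483          1.003162     0.06516545
#> 6          6        dim 3.517104          1.001419     0.06510572
```

The true half-time of this condition is `log(2) * 2 / 0.407 = 3.41` s —
recovered within ~3.5% per nucleus. `y_half_normalized ≈ 1` is the
closed-form value for partition 2 (at T1/2 the nucleus holds exactly the
bath level). From many such fields, `grid_metrics()` +
`population_medians()` + `ratio_heatmap()` build the starred log10
heatmap (`plot_ratio_heatmap()`), `fold_change_to_control()` computes
control-normalized fold changes with propagated SE, and
`three_way_anova()` / `ttest_independent()` / `correlate()` run the
inferential stage. The numbered drivers under `analysis/` run these
stages as a narrative workflow, writing tables under `results/`.

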