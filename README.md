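# ricianfit

Quantitative MRI estimates tissue properties — here the intravoxel
incoherent motion (IVIM) parameters of diffusion-weighted imaging — by
fitting a biophysical model to the signals measured in each voxel. MR
*magnitude* data are Rician distributed: the centre of the measurement
distribution sits **above** the noise-free signal, increasingly so as SNR
falls. Any fitting procedure that matches predictions to the data in the
least squares sense (including self-supervised neural networks trained
with the MSE loss, now a standard IVIM fitting tool) therefore
overestimates low signals and underestimates decay rates.

`ricianfit` implements the fix: a numerically stable **negative log Rician
likelihood (NLR) loss**,

```
L_NLR = (1/N) Σ_j  −Σ_i [ log(M_ij/σ²) − (M_ij² + Â_ij²)/(2σ²)
                           + log I0(M_ij Â_ij / σ²) ]
```

evaluated through the exponentially scaled Bessel function
(`log I0(x) = log I0e(x) + x`), so nothing overflows even at SNR 40 where
the Bessel argument reaches 1600. Minimising it — by self-supervised
network training or conventional per-voxel optimisation — is maximum
likelihood estimation under the correct noise model, trading a little
precision for substantially less bias at low SNR.

The package is aimed at quantitative-imaging researchers who want to

* train a self-supervised IVIM network (`build_network()`,
  `train_network()`, `predict()`) with the NLR or MSE loss and compare
  them from a shared initialisation (`common_initialisation()`);
* fit voxels conventionally by Rician maximum likelihood or least squares
  (`fit_voxel()`, `fit_volume()`);
* simulate Rician-distributed IVIM data over factorial parameter grids
  with seeded reproducibility (`make_parameter_grid()`,
  `add_rician_noise()`, `build_dataset()`, `simulate_ivim_study()`);
* estimate the noise level from a background region via the Rayleigh mean
  (`estimate_sigma()`);
* quantify bias / precision / RMSE of parameter recovery
  (`error_table()`, `metrics_by_combination()`, `boxplot_summary()`).

The IVIM forward model is
`Â(b) = S0 [ f e^(−b(Dp+Dt)) + (1−f) e^(−b Dt) ]` with b-values in
ms/μm² and diffusivities in μm²/ms (s/mm² protocols convert on input).

## Worked example

Four hundred noisy voxels of one fast-diffusing tissue
(Dt = 2.5 μm²/ms, Dp = 60 μm²/ms, f = 0.25, S0 = 1) at SNR 10, fitted
voxel-wise with both objectives:

```r
library(ricianfit)
protocol <- default_ivim_protocol()
truth <- ivim_params(Dt = 2.5, Dp = 60, f = 0.25, S0 = 1)
A <- ivim_signal(truth, protocol)
round(A, 3)
#>  [1] 1.000 0.865 0.785 0.734 0.673 0.616 0.585 0.455 0.276 0.102

sigma <- 0.1  # SNR 10
M <- add_rician_noise(matrix(A, nrow = 400, ncol = 10, byrow = TRUE),
                      sigma, seed = 42)

# noise level from 10,000 background voxels (Rayleigh-mean estimator)
bg <- add_rician_noise(numeric(10000), sigma, seed = 7)
estimate_sigma(bg)
#> <noise_spec> sigma = 0.100401 (SNR = 9.96007 at S0 = 1, b = 0)

lsq <- fit_volume(M, "LSQ", protocol = protocol, multistart = 1)
nlr <- fit_volume(M, "NLR", sigma = sigma, protocol = protocol,
                  multistart = 1)
data.frame(objective = c("LSQ", "NLR"),
           mean_Dt = c(mean(lsq$Dt), mean(nlr$Dt)),
           bias_pct = 100 * (c(mean(lsq$Dt), mean(nlr$Dt)) - 2.5) / 2.5,
           sd_Dt = c(sd(lsq$Dt), sd(nlr$Dt)))
#>   objective  mean_Dt   bias_pct     sd_Dt
#> 1       LSQ 2.023179 -19.072825 0.8729390
#> 2       NLR 2.443263  -2.269463 0.9689114
```

The least squares fit underestimates Dt by ~19% because the Rician noise
floor props up the high-b signals; the Rician-likelihood fit cuts that
bias to ~2%, at the cost of a slightly wider estimate distribution. The
same pattern — and its disappearance at high SNR — is what the
self-supervised training experiments reproduce at scale.

A command-line front end covering the full pipeline
(`simulate`, `train`, `predict`, `fit`, `estimate-sigma`, `evaluate`)
ships at `inst/cli/ricianfit`; see `?cli_dispatch`.

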