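# diffimpute

Conditional denoising-diffusion imputation of a missing 3D structural MRI
visit in a longitudinal trajectory, for studies (e.g. of Alzheimer's disease
progression) where participants miss scans and downstream analyses —
regional volumes, atrophy rates — need a complete image series.  The package
imputes the *whole 3D image* at the missing visit, conditioning on the
adjacent past visit ("P") or on the past and following visits ("PF"), so any
image-derived phenotype can then be computed with standard tools.

## The model

A denoising diffusion probabilistic model corrupts the missing-visit image
x₀ through a fixed Markov chain q(xₜ | xₜ₋₁) = N(√(1−βₜ) xₜ₋₁, βₜ I), with
closed form xₜ = √ᾱₜ x₀ + √(1−ᾱₜ) ε, ᾱₜ = ∏ₛ≤ₜ (1−βₛ).  A UNet-style
network ε_θ(xₜ, t, C) is trained to predict the injected noise given the
condition images C (past, or past + following), minimising

    E‖ε − ε_θ(√ᾱₜ x₀ + √(1−ᾱₜ) ε, t, C)‖²,

and imputation runs the learned reverse chain from pure noise, with
posterior mean combining the algebraic clean-image estimate
x̂₀ = (xₜ − √(1−ᾱₜ) ε_θ)/√ᾱₜ and the current state, variance
β̃ₜ = βₜ(1−ᾱₜ₋₁)/(1−ᾱₜ).  Conditions are never diffused; they are
concatenated with the noisy target along the channel axis.

Volumes are handled with a parameter-efficient slicing scheme: the slice
axis is split into K uniform segments and clips of 2J+1 consecutive slices
(one per segment) are stacked into K(2J+1)-channel 2D units — local slice
continuity plus global coverage for a 2D network.  At generation time clips
are taken in order and the generated units reassemble exactly into the full
volume.

Comparators: forward filling (`naive-p`), adjacent-visit averaging
(`naive-pf`), and an autoencoder with the same backbone trained under an ℓ2
objective (`ae-p`/`ae-pf`).  Evaluation: masked SSIM/PSNR/MSE against the
retained true image, regional volume error rate |ŷ−y|/y, progression rate
|vᵢ−vᵢ₋₁|/vᵢ₋₁ and its imputed-vs-observed gap, and an annualized-atrophy
scenario comparison.  A synthetic phantom generator (ellipsoidal brain with
atrophying/expanding labelled regions, known ground-truth volumes) makes the
whole pipeline testable without patient data.

## Worked example

Generate a phantom cohort, mark the middle visit of each observed triple as
missing, fit the tiny past+following-conditioned diffusion imputer, and
evaluate the held-out subjects:

```r
library(diffimpute)

coh <- apply_missingness(generate_cohort(cohort_spec(), seed = 42), "pf")
fit <- diffimpute(coh, method = "ddpm", conditioning = "pf",
                  schedule = tiny_schedule(50),
                  control = train_control(lr = 1e-3, batch_size = 4,
                                          max_steps = 2000, lr_decay_at = 1500),
                  subjects = 1:20, seed = 11)
print(fit)
#> Longitudinal imputation model: conditional diffusion, conditioning on past + following visits
#>   network: 141263 parameters, trained 2000 steps
#>   schedule: T = 50, beta in [0.002, 0.4]
#>   final running loss: 0.11357

imp <- predict(fit, coh, subjects = 21:24, seed = 5)
rep <- rbind(
  evaluate_imputation(imp, coh$records[21:24], imputer = "ddpm-pf"),
  evaluate_imputation(predict(diffimpute(coh, method = "naive",
                                         conditioning = "p"),
                              coh, subjects = 21:24),
                      coh$records[21:24], imputer = "naive-p"))
aggregate_report(rep)
#>     imputer           metric      mean        sd n
#>     naive-p       error_rate  0.152319 0.0204340 4
#>   ddpm-pf       error_rate 10.132356 0.3655364 4
#>     naive-p              mse  0.001925 0.0001152 4
#>   ddpm-pf              mse  0.047494 0.0019883 4
#>     naive-p progression_rate  0.000000 0.0000000 4
#>     naive-p             ssim  0.920649 0.0052411 4
#>   ddpm-pf             ssim  0.421619 0.0131704 4
```

(abridged to the headline rows).  The report lists, per imputer, the masked
SSIM/PSNR/MSE of the imputed against the observed image and the regional
volume error and progression statistics, averaged over regions within
subject and then over subjects (mean ± sd).  Forward filling always shows
`progression_rate` exactly 0 — it copies the past image — which is the
signature the volumetric metrics are designed to expose.  See the vignette
(`vignettes/diffusion-imputation.Rmd`) for the model, the unit scheme, all
conventions, and what desk-scale results do and do not show: at this desk
scale (16 base channels, 2,000 steps) the diffusion sampler tracks the
target structurally but does not reach the raw-MSE level of the naive
copy-based imputers — that requires reference-scale training (200,000 steps,
64–128 channels) — while the converged autoencoder comparator does pass the
naive baseline in the test suite.

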