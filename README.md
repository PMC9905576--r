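# pinncal

Unsupervised, physics-informed calibration of emission spectra: estimate
analyte concentrations from measurements contaminated by a non-stationary
background and noise, **without any labelled calibration data**.

## The problem

A measured spectrum on a wavelength grid is modelled as

    I(λ) = Σⱼ cⱼ · I₀ⱼ(λ) + I_b(λ) + I_n(λ)

where `I₀ⱼ` is the known emission spectrum of agent *j* at unit
concentration (the *reference spectrum*), `I_b` an unknown background that
may change amplitude and shape between shots, and `I_n` zero-mean noise.
When controlled experiments with known concentrations are impossible,
supervised calibration is off the table; the only usable knowledge is the
physics above.

`pinncal` trains a two-part 1-D convolutional network on nothing but raw
measured spectra: a convolutional autoencoder predicts each measurement's
background `I_p,b`; after subtracting it, a small convolutional +
fully-connected head predicts the concentrations `c_p`. The training signal
is a physics-informed loss instead of labels:

    L_tot = Σ_λ ( I − Σⱼ c_p,j·I₀ⱼ − I_p,b )²  +  α · Σ_λ ( dI_p,b/dλ )²

i.e. the reconstruction must add up, and the background must be smooth —
the term that prevents the trivial solution "everything is background".
The weight α is estimated from the reference spectrum alone
(`alpha_heuristic()`). Training uses mini-batch ADAM; concentration labels,
even when present in a dataset object, are never read.

The package also ships seeded generators for six synthetic benchmark
families (N01–N06: Gaussian two-peak references with constant, shaped, or
randomly varying backgrounds plus Gaussian noise), a per-spectrum
least-squares baseline, evaluation metrics (R², mean relative error), and
plain-text spectrum/dataset IO. It is aimed at spectroscopists —
fluorescence, Raman, plasma emission — who need calibration-free
concentration estimates, and at anyone who wants a fully reproducible
testbed for background-separation methods.

## Worked example

Generate a benchmark dataset (peaked reference over a steady background
plus noise), train unsupervised, and evaluate against the generating
concentrations:

```r
library(pinncal)

train <- synthesize_dataset(scenario_config("N01", n_samples = 300, seed = 1))
test  <- synthesize_dataset(scenario_config("N01", n_samples = 300, seed = 2))

model <- pinn_model(pinn_config(700, input_scale = 200), init_seed = 1)
fit   <- train_pinn(model, train, config = train_config(epochs = 2000, seed = 1))

pred <- predict(fit, test)
evaluate_predictions(test$concentrations, pred$concentrations)
```

```
<pinn_evaluation> 300 samples, 1 agent(s)
  agent 1: R^2 = 0.9978, mean rel. error (c >= 0.1) = 3.772%, mean abs. error = 0.02373
```

Read: on 300 held-out spectra the unsupervised network explains 99.8% of
the concentration variance; predictions are on average ~4% off for
concentrations at or above 0.1 (about 0.024 in absolute units across all
samples). For comparison, the supervised-equivalent least-squares oracle
`lsq_concentrations(test)` — optimal here because the N01 background is
constant — reaches 1.78% on the same draw: the network, which was never
told any concentration, sits within about two points of it at this desk
scale. The predicted backgrounds are available as `pred$background`, the
implied agent spectra as `pred$agent`.

A command-line interface wrapping the same functions (simulate / train /
predict / evaluate) is in `inst/cli/pinncal.R`.

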