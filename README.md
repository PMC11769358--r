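# eegtranslate

Scalp EEG is cheap and noninvasive, but the skull attenuates and smears the
signals it records: in mesial temporal lobe epilepsy, only a small minority of
interictal epileptiform discharges (IEDs) — the spike/sharp-wave transients
that mark epileptic tissue between seizures — are visible to a reader of the
scalp traces, while intracranial electrodes such as foramen-ovale (FO) wires
see them clearly. `eegtranslate` implements a generative translation model
that maps multichannel scalp EEG segments to their concurrent intracranial
counterparts, and then detects IEDs from the *estimated* intracranial
signals, so that scalp-only recordings yield closer-to-intracranial
diagnostic information.

## The model

Let `X ∈ R^{L×M}` be a scalp segment (`L` = 64 time samples at 200 Hz, `M` =
20 sensors) and `Y ∈ R^{L×M̄}` the time-aligned intracranial segment (`M̄` =
12 sensors). Scalp observations are modeled as `X = F(Y) + noise` for a
nonlinear mixing `F`; the package learns the inverse map with a variational
conditional GAN:

* an **encoder** `E` (strided temporal convolutions, instance norm, leaky
  ReLU) maps `X` to a Gaussian posterior `(μ, σ)` over a latent code of
  dimension `Z = 256`, sampled by reparameterization `z = μ + ε ⊙ σ`,
  `ε ~ N(0, I)`;
* a **generator** `G` produces `Ỹ = G(X, z)`: a dense expansion of `z` passes
  through SPADE residual blocks — normalization whose scale `γ` and shift `β`
  are convolved from the (temporally downsampled) scalp input, so
  `SPADE(A) = γ(X) ⊙ Â + β(X)` — alternating with ×2 temporal upsampling,
  then two LSTM layers over all `L` steps and a time-distributed dense + tanh
  head;
* a per-sensor **patch discriminator** `D` scores each intracranial sensor
  trace as real or estimated (patch size `1 × M̄`).

Training alternates a hinge-loss discriminator step with an
encoder+generator step minimizing

```
L_G = L_hinge + λ1·L_KL + λ2·L_L1 + λ3·L_FM
```

(KL divergence of the posterior from `N(0, I)`, L1 reconstruction against
the real `Y`, and discriminator feature matching). IEDs are then detected
from `Ỹ` with a compact EEGNet-style convolutional classifier (no batch
normalization, max pooling), evaluated intra-subject (70/10/20 stratified
split) and inter-subject (leave-one-subject-out, averaging the output
probabilities of the per-subject classifiers whose intra-subject accuracy
exceeds 70%).

Because the clinical recordings behind the reference tables are not public,
the package ships a synthetic cohort simulator that reproduces their
structure: intracranial spike + damped-oscillation transients on 1/f-like
background, a nonlinear attenuating forward mixture to the scalp, and a
calibration step that tunes spike transmission until a fixed peak-threshold
detector sees the target scalp-visible fraction (18.8% by default).

## Worked example

```r
library(eegtranslate)

# simulate one subject of paired scalp/intracranial segments (easy regime)
cfg <- simulation_config(n_subjects = 1, segments_per_subject = 128,
                         target_visible_fraction = NULL, snr_db = 25)
fwd <- forward_model(default_mixing(20, 12, width = 0.6),
                     nonlinearity = "identity", attenuation = 1)
rec <- simulate_subject(cfg, fwd, subject_seed = 5)

# fit the translation model
arch <- arch_config(latent_dim = 16, encoder_layers = 3,
                    encoder_base_filters = 4, generator_stages = 1,
                    generator_base_filters = 12, lstm_hidden_units = 32,
                    disc_layers = 3, disc_base_filters = 4,
                    spade_embed_filters = 16)
fit <- vaecgan(rec, arch,
               train_control(epochs = 30, batch_size = 8, lr_g = 5e-3,
                             lr_d = 2e-3, g_steps = 2, seed = 1,
                             weights = loss_weights(0.05, 100, 1)))
print(fit)
#> Scalp-to-intracranial translation model (VAE-cGAN)
#>   geometry: L=64, M=20 scalp -> M_bar=12 intracranial, Z=16
#>   trained 30 epochs on 128 segments; final L_L1 = 0.0379, L_D = 1.6939

# translate held-out scalp segments and score the mapping
hold <- simulate_subject(cfg, fwd, subject_seed = 99)
X <- hold$segments[[1]]$scalp$samples
Y <- hold$segments[[1]]$intracranial$samples
Y_est <- translate(fit, X, mode = "mean")
report <- evaluate_mapping(list(list(Y, Y_est)))
print(report$cohort_mean)
#>         MSE       PCORR      COSSIM
#> 0.006709862 0.747433980 0.767935887
```

The final training L1 of about 0.038 is down from about 0.095 at
initialization (signal amplitudes are normalized to `[-1, 1]`), and the
held-out per-sensor Pearson correlation of ~0.7 means the estimated
intracranial traces track the real ones closely in this high-SNR regime;
`intra_subject_eval(rec, fit)` then classifies IED versus non-IED segments
from the translated signals. `run_simulate()` and `run_pipeline()` (or the
wrapper script in `inst/cli/`) chain the full simulate → train → translate →
evaluate → classify sequence and write CSV tables with per-subject rows and
a `Mean` row.

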