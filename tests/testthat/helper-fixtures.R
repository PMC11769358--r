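# Shared fixtures: small deterministic cohorts and reduced-width network
# configurations that keep the suite fast while exercising the full
# geometry (64 samples, 20 scalp / 12 intracranial sensors).

tiny_arch <- function(...) {
  arch_config(latent_dim = 16, encoder_layers = 3, encoder_base_filters = 4,
              generator_stages = 2, generator_base_filters = 8,
              lstm_hidden_units = 16, disc_layers = 3, disc_base_filters = 4,
              spade_embed_filters = 8, ...)
}

# reduced-width configuration used for the synthetic recovery checks
recovery_arch <- function(...) {
  arch_config(latent_dim = 16, encoder_layers = 3, encoder_base_filters = 4,
              generator_stages = 1, generator_base_filters = 12,
              lstm_hidden_units = 32, disc_layers = 3, disc_base_filters = 4,
              spade_embed_filters = 16, ...)
}

# an "easy" high-SNR, linear-mixing, unattenuated subject: sharp
# (well-conditioned) sensitivity profiles make the intracranial signal close
# to linearly recoverable from the scalp
easy_forward <- function() {
  forward_model(default_mixing(20, 12, width = 0.6),
                nonlinearity = "identity", attenuation = 1)
}

easy_subject <- function(n_segments = 96, subject_seed = 5, snr_db = 25,
                         subject_id = "S1") {
  cfg <- simulation_config(n_subjects = 1, segments_per_subject = n_segments,
                           target_visible_fraction = NULL, snr_db = snr_db)
  simulate_subject(cfg, easy_forward(), subject_seed = subject_seed,
                   subject_id = subject_id)
}

small_cohort <- function(n_subjects = 2, n_segments = 10, seed = 1) {
  cfg <- simulation_config(n_subjects = n_subjects,
                           segments_per_subject = n_segments,
                           target_visible_fraction = NULL, seed = seed)
  simulate_cohort(cfg)
}
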