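# Training mechanics: smoke run with finite losses, per-seed determinism,
# update isolation between the discriminator and encoder/generator, the
# translate modes, cohort training, and checkpoint round trips.

small_train_setup <- function(n = 24, seed = 2) {
  rec <- easy_subject(n_segments = n, subject_seed = seed)
  arch <- arch_config(latent_dim = 8, encoder_layers = 2,
                      encoder_base_filters = 2, generator_stages = 2,
                      generator_base_filters = 4, lstm_hidden_units = 6,
                      disc_layers = 3, disc_base_filters = 2,
                      spade_embed_filters = 4)
  list(rec = rec, arch = arch)
}

test_that("a tiny configuration trains end-to-end with finite logged losses", {
  su <- small_train_setup()
  m <- vaecgan(su$rec, su$arch, train_control(epochs = 2, batch_size = 8,
                                              seed = 1))
  expect_s3_class(m, "vaecgan")
  expect_identical(nrow(m$history), 2L)
  expect_true(all(is.finite(as.matrix(m$history))))
  expect_named(m$history, c("L_D", "L_Gh", "L_KL", "L_L1", "L_FM", "L_G"))
})

test_that("the same seed reproduces the same training trajectory", {
  su <- small_train_setup(n = 16)
  ctrl <- train_control(epochs = 2, batch_size = 8, seed = 5)
  m1 <- vaecgan(su$rec, su$arch, ctrl)
  m2 <- vaecgan(su$rec, su$arch, ctrl)
  expect_identical(m1$history$L_G, m2$history$L_G)
  expect_identical(predict(m1), predict(m2))
})

test_that("discriminator updates never touch encoder/generator parameters and vice versa", {
  ns <- asNamespace("eegtranslate")
  su <- small_train_setup(n = 16)
  arr <- ns$seg_input(su$rec)
  set.seed(3)
  params <- init_translation_params(su$arch, seed = 11)
  ctrl <- train_control(seed = 3)
  xb <- arr$scalp[1:8, , ]
  yb <- arr$intracranial[1:8, , ]
  ds <- ns$d_step(params, xb, yb, su$arch,  ctrl,
                  ns$adam_init(params$discriminator))
  expect_identical(ds$params$encoder, params$encoder)
  expect_identical(ds$params$generator, params$generator)
  expect_false(identical(ds$params$discriminator, params$discriminator))
  gs <- ns$g_step(params, xb, yb, su$arch, ctrl,
                  ns$adam_init(list(encoder = params$encoder,
                                    generator = params$generator)))
  expect_identical(gs$params$discriminator, params$discriminator)
  expect_false(identical(gs$params$encoder, params$encoder))
  expect_false(identical(gs$params$generator, params$generator))
})

test_that("translate modes: mean is deterministic, sample is stochastic", {
  su <- small_train_setup(n = 16)
  m <- vaecgan(su$rec, su$arch, train_control(epochs = 1, batch_size = 8,
                                              seed = 7))
  X <- su$rec$segments[[1]]$scalp$samples
  o1 <- translate(m, X, mode = "mean")
  o2 <- translate(m, X, mode = "mean")
  expect_identical(o1, o2)
  expect_identical(dim(o1), c(64L, 12L))
  set.seed(1)
  s1 <- translate(m, X, mode = "sample")
  set.seed(2)
  s2 <- translate(m, X, mode = "sample")
  expect_gt(max(abs(s1 - s2)), 0)
})

test_that("the encoder-free ablation ignores the scalp posterior entirely", {
  su <- small_train_setup(n = 16)
  arch_ne <- su$arch
  arch_ne$ablation <- "no_encoder"
  m <- vaecgan(su$rec, su$arch, train_control(epochs = 1, batch_size = 8,
                                              seed = 4))
  m_ne <- m
  m_ne$arch <- arch_ne
  X <- su$rec$segments[[1]]$scalp$samples
  base <- translate(m_ne, X, mode = "mean")
  # perturbing encoder parameters cannot change the encoder-free output
  m_ne2 <- m_ne
  m_ne2$params$encoder <- eegtranslate:::tree_map(function(p) p + 1,
                                                  m_ne$params$encoder)
  expect_identical(base, translate(m_ne2, X, mode = "mean"))
  # KL term is identically zero during encoder-free training
  m3 <- vaecgan(su$rec, arch_ne, train_control(epochs = 1, batch_size = 8,
                                               seed = 4))
  expect_identical(m3$history$L_KL, 0)
})

test_that("train_cohort produces one distinct, reproducible model per subject", {
  co <- small_cohort(n_subjects = 3, n_segments = 8, seed = 9)
  arch <- small_train_setup()$arch
  ctrl <- train_control(epochs = 1, batch_size = 8, seed = 10)
  ms <- train_cohort(co, arch, ctrl)
  expect_named(ms, c("S1", "S2", "S3"))
  c1 <- coef(ms$S1)
  c2 <- coef(ms$S2)
  expect_gt(max(abs(c1 - c2)), 0)
  expect_false(identical(ms$S1$history$L_G, ms$S2$history$L_G))
  ms2 <- train_cohort(co, arch, ctrl)
  expect_identical(coef(ms$S3), coef(ms2$S3))
})

test_that("checkpoints round-trip parameters, architecture and history", {
  su <- small_train_setup(n = 16)
  m <- vaecgan(su$rec, su$arch, train_control(epochs = 2, batch_size = 8,
                                              seed = 12))
  path <- withr::local_tempfile(fileext = ".npz")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  X <- su$rec$segments[[2]]$scalp$samples
  expect_identical(translate(m, X), translate(back, X))
  expect_equal(back$history$L_G, m$history$L_G)
  expect_equal(back$arch$latent_dim, m$arch$latent_dim)
})

test_that("model methods print, summarize, simulate and expose coefficients", {
  su <- small_train_setup(n = 16)
  m <- vaecgan(su$rec, su$arch, train_control(epochs = 1, batch_size = 8,
                                              seed = 13))
  expect_output(print(m), "VAE-cGAN")
  expect_output(print(summary(m)), "reconstruction")
  expect_type(coef(m), "double")
  r <- residuals(m)
  expect_identical(dim(r), c(16L, 64L, 12L))
  sims <- simulate(m, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), c(16L, 64L, 12L))
  pdf(NULL)
  expect_silent(plot(m))
  dev.off()
})
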