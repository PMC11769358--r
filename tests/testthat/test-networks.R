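# Architecture contracts: output shapes and ranges of the three networks,
# the reparameterization identity, SPADE against its elementwise oracle, the
# residual behavior of the SPADE-ResNet, and the shape algebra across
# encoder/generator depths.

test_that("encoder emits (256, 256)-dimensional (mu, sigma) with sigma > 0", {
  arch <- arch_config()
  params <- init_translation_params(arch, seed = 1)
  set.seed(51)
  X <- matrix(runif(64 * 20, -1, 1), 64, 20)
  enc <- encode(X, params, arch)
  expect_length(enc$mu, 256)
  expect_length(enc$sigma, 256)
  expect_true(all(enc$sigma > 0))
  enc2 <- encode(X, params, arch)
  expect_identical(enc$mu, enc2$mu)
  # input sensitivity: different inputs give different posterior means
  encz <- encode(matrix(0, 64, 20), params, arch)
  enco <- encode(matrix(1, 64, 20), params, arch)
  expect_gt(max(abs(encz$mu - enco$mu)), 0)
  expect_error(encode(matrix(0, 32, 20), params, arch), "expected")
})

test_that("reparameterize implements z = mu + eps * sigma exactly", {
  expect_identical(reparameterize(c(1, 2), c(3, 4), c(0, 0)), c(1, 2))
  eps <- rnorm(5)
  expect_identical(reparameterize(rep(0, 5), rep(1, 5), eps), eps)
  expect_identical(reparameterize(c(1, 2), c(0.5, 2), c(2, -1)), c(2, 0))
  expect_error(reparameterize(1:3, 1:2, 1:3), "equal length")
})

test_that("spade_block equals the brute-force elementwise oracle", {
  ad <- asNamespace("eegtranslate")
  set.seed(52)
  n_ch <- 5; Tn <- 12; M <- 4; B <- 3
  sp <- ad$init_spade(3, M, n_ch, 6)
  act <- array(rnorm(B * Tn * n_ch), c(B, Tn, n_ch))
  cond <- array(rnorm(B * Tn * M), c(B, Tn, M))
  out <- spade_block(act, cond, sp)
  # independent elementwise evaluation: gamma * normalized + beta, with the
  # modulation maps taken from the same convolutional sub-computations
  wp <- ad$wrap_params(sp, trainable = FALSE)
  emb <- ad$ad_value(ad$ad_lrelu(ad$conv1d_fwd(ad$ad_const(cond), wp$embed, 3L,
                                               pad = ad$same_pad(3L)), 0.2))
  gamma <- ad$ad_value(ad$conv1d_fwd(ad$ad_const(emb), wp$gamma, 3L,
                                     pad = ad$same_pad(3L)))
  beta <- ad$ad_value(ad$conv1d_fwd(ad$ad_const(emb), wp$beta, 3L,
                                    pad = ad$same_pad(3L)))
  v2 <- matrix(act, B * Tn, n_ch)
  mu <- colMeans(v2)
  sd2 <- sqrt(colMeans(sweep(v2, 2, mu)^2) + 1e-5)
  ref <- array(0, dim(act))
  for (b in 1:B) for (t in 1:Tn) for (cc in 1:n_ch) {
    a_hat <- (act[b, t, cc] - mu[cc]) / sd2[cc]
    ref[b, t, cc] <- gamma[b, t, cc] * a_hat + beta[b, t, cc]
  }
  expect_equal(out, ref, tolerance = 1e-10)
  # normalization contract: per-channel zero mean, unit variance pre-modulation
  sp1 <- sp
  sp1$gamma$w[] <- 0; sp1$gamma$b[] <- 1
  sp1$beta$w[] <- 0; sp1$beta$b[] <- 0
  normed <- spade_block(act, cond, sp1)
  nm <- matrix(normed, B * Tn, n_ch)
  expect_lt(max(abs(colMeans(nm))), 1e-10)
  expect_equal(colMeans(nm^2), rep(1, n_ch), tolerance = 1e-4)
  expect_error(spade_block(act, cond[, 1:6, , drop = FALSE], sp), "temporal")
})

test_that("spade_resnet is residual: zeroed main path returns the skip path", {
  ad <- asNamespace("eegtranslate")
  set.seed(53)
  act <- matrix(rnorm(16 * 6), 16, 6)
  cond <- matrix(rnorm(16 * 4), 16, 4)
  rn <- ad$init_spade_resnet(6, 6, 4, 4)
  rn0 <- rn
  rn0$conv2$w[] <- 0; rn0$conv2$b[] <- 0
  expect_equal(spade_resnet(act, cond, rn0), act)
  # unequal channels: skip path projects to the output channel count
  rn2 <- ad$init_spade_resnet(6, 3, 4, 4)
  out <- spade_resnet(act, cond, rn2)
  expect_identical(dim(out), c(16L, 3L))
})

test_that("generator output is (64, 12), tanh-bounded, for full and ablated variants", {
  set.seed(54)
  X <- matrix(runif(64 * 20, -1, 1), 64, 20)
  for (ab in c("full", "no_spade_resnet")) {
    arch <- tiny_arch(ablation = ab)
    params <- init_translation_params(arch, seed = 2)
    z <- rnorm(arch$latent_dim)
    out <- generate(X, z, params, arch)
    expect_identical(dim(out), c(64L, 12L))
    expect_lt(max(abs(out)), 1)
  }
  arch <- tiny_arch()
  params <- init_translation_params(arch, seed = 2)
  expect_error(generate(X, rnorm(7), params, arch), "length")
})

test_that("discriminator emits one unbounded score per sensor plus all feature maps", {
  arch <- tiny_arch()
  params <- init_translation_params(arch, seed = 3)
  set.seed(55)
  Y <- matrix(runif(64 * 12, -1, 1), 64, 12)
  d <- discriminate(Y, params, arch)
  expect_identical(dim(d$scores), c(1L, 12L))
  expect_length(d$feature_maps, arch$disc_layers)
  d2 <- discriminate(Y, params, arch)
  expect_identical(d$scores, d2$scores)
  expect_error(discriminate(matrix(0, 64, 5), params, arch), "expected")
})

test_that("temporal shape algebra holds across encoder/generator depths", {
  ad <- asNamespace("eegtranslate")
  for (geom in list(c(32, 2, 2), c(64, 3, 2), c(64, 4, 4), c(16, 1, 1))) {
    L <- as.integer(geom[1])
    arch <- arch_config(latent_dim = 8, encoder_layers = geom[2],
                        encoder_base_filters = 2, generator_stages = geom[3],
                        generator_base_filters = 2, lstm_hidden_units = 4,
                        disc_layers = 3, disc_base_filters = 2,
                        spade_embed_filters = 2, L = L, M = 4, M_bar = 3)
    params <- init_translation_params(arch, seed = 4)
    X <- matrix(runif(L * 4, -1, 1), L, 4)
    enc <- encode(X, params, arch)
    expect_length(enc$mu, 8)
    out <- generate(X, rnorm(8), params, arch)
    expect_identical(dim(out), c(L, 3L))
  }
  expect_error(arch_config(L = 60), "is not TRUE")
})
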