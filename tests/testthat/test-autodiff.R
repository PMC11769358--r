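# Gradient correctness of the reverse-mode engine: every op family checked
# against central finite differences on random small tensors.

fd_check <- function(build, pars, h = 1e-6, n_probe = 6) {
  wp <- lapply(pars, eegtranslate:::ad_param)
  loss <- build(wp)
  eegtranslate:::ad_backward(loss)
  maxerr <- 0
  for (j in seq_along(pars)) {
    g <- if (is.null(wp[[j]]$grad)) eegtranslate:::zeros_like(pars[[j]])
    else wp[[j]]$grad
    for (i in sample(length(pars[[j]]), min(n_probe, length(pars[[j]])))) {
      pp <- pars
      pp[[j]][i] <- pp[[j]][i] + h
      lp <- build(lapply(pp, eegtranslate:::ad_const))$value
      pm <- pars
      pm[[j]][i] <- pm[[j]][i] - h
      lm <- build(lapply(pm, eegtranslate:::ad_const))$value
      fd <- (lp - lm) / (2 * h)
      maxerr <- max(maxerr, abs(fd - g[i]) / max(1, abs(fd)))
    }
  }
  maxerr
}

test_that("convolution, normalization and pooling gradients match finite differences", {
  ad <- asNamespace("eegtranslate")
  set.seed(11)
  B <- 2; Tn <- 8; Cin <- 3; Cout <- 4; k <- 3
  x <- array(rnorm(B * Tn * Cin), c(B, Tn, Cin))
  w <- ad$glorot(k * Cin, Cout)
  b <- rnorm(Cout)
  expect_lt(fd_check(function(p)
    ad$ad_mean(ad$ad_tanh(ad$ad_conv1d(p[[1]], p[[2]], p[[3]], k, 1L,
                                       ad$same_pad(k)))),
    list(x, w, b)), 1e-6)
  expect_lt(fd_check(function(p)
    ad$ad_mean(ad$ad_abs(ad$ad_conv1d(p[[1]], p[[2]], p[[3]], k, 2L,
                                      ad$same_pad(k)))),
    list(x, w, b)), 1e-6)
  expect_lt(fd_check(function(p)
    ad$ad_mean(ad$ad_mul(ad$ad_norm(p[[1]], "instance"), p[[1]])),
    list(x)), 1e-6)
  expect_lt(fd_check(function(p)
    ad$ad_mean(ad$ad_mul(ad$ad_norm(p[[1]], "channel"), p[[1]])),
    list(x)), 1e-6)
  expect_lt(fd_check(function(p)
    ad$ad_mean(ad$ad_mul(ad$ad_upsample_time(ad$ad_avgpool_time(p[[1]], 2), 2),
                         ad$ad_tanh(p[[1]]))),
    list(x)), 1e-6)
  expect_lt(fd_check(function(p) ad$ad_mean(ad$ad_maxpool_time(p[[1]], 2)),
                     list(x)), 1e-6)
})

test_that("fused LSTM backward implements BPTT correctly", {
  ad <- asNamespace("eegtranslate")
  set.seed(12)
  B <- 3; Tn <- 7; Cin <- 4; H <- 5
  x <- array(rnorm(B * Tn * Cin), c(B, Tn, Cin))
  lp <- ad$init_lstm(Cin, H)
  err <- fd_check(function(p)
    ad$ad_mean(ad$ad_tanh(ad$ad_lstm(p[[1]], p[[2]], p[[3]], p[[4]], H))),
    list(x, lp$wx, lp$wh, lp$b))
  expect_lt(err, 1e-6)
})

test_that("elementwise and dense ops have exact gradients", {
  ad <- asNamespace("eegtranslate")
  set.seed(13)
  x <- array(rnorm(24), c(2, 4, 3))
  w <- ad$glorot(4, 2)
  b2 <- rnorm(2)
  err <- fd_check(function(p)
    ad$ad_mean(ad$ad_sigmoid(ad$tdd_fwd(ad$ad_permute(p[[1]], c(1, 3, 2)),
                                        list(w = p[[2]], b = p[[3]])))),
    list(x, w, b2))
  expect_lt(err, 1e-6)
  err2 <- fd_check(function(p)
    ad$ad_mean(ad$ad_add(ad$ad_softplus(p[[1]]),
                         ad$ad_add(ad$ad_relu(p[[1]]),
                                   ad$ad_lrelu(p[[1]], 0.2)))),
    list(x))
  expect_lt(err2, 1e-6)
})

test_that("a scalar loss on the generator output back-propagates nonzero gradients everywhere", {
  ad <- asNamespace("eegtranslate")
  arch <- arch_config(latent_dim = 8, encoder_layers = 2,
                      encoder_base_filters = 2, generator_stages = 2,
                      generator_base_filters = 2, lstm_hidden_units = 4,
                      disc_layers = 3, disc_base_filters = 2,
                      spade_embed_filters = 2, L = 16, M = 3, M_bar = 2)
  params <- init_translation_params(arch, seed = 7)
  set.seed(7)
  xb <- array(runif(2 * 16 * 3, -1, 1), c(2, 16, 3))
  we <- ad$wrap_params(params$encoder)
  wg <- ad$wrap_params(params$generator)
  wd <- ad$wrap_params(params$discriminator)
  enc <- ad$encode_graph(ad$ad_const(xb), we, arch)
  sigma <- ad$ad_exp(ad$ad_scale(enc$logvar, 0.5))
  eps <- ad$ad_const(matrix(rnorm(2 * 8), 2))
  z <- ad$ad_add(enc$mu, ad$ad_mul(eps, sigma))
  yf <- ad$generate_graph(ad$ad_const(xb), z, wg, arch)
  df <- ad$discriminate_graph(yf, wd, arch)
  loss <- ad$ad_add(ad$ad_mean(ad$ad_mul(yf, yf)),
                    ad$ad_mean(df$scores))
  ad$ad_backward(loss)
  norm_of <- function(wp) sqrt(sum(ad$flatten_leaves(ad$collect_grads(wp))^2))
  expect_gt(norm_of(we), 0)
  expect_gt(norm_of(wg), 0)
  expect_gt(norm_of(wd), 0)
})
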