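# The three networks of the translation model, as pure forward computations
# over explicit parameter lists:
#
#  * encoder E: strided temporal convolutions (instance norm + leaky ReLU)
#    projecting a scalp segment onto the mean and standard deviation of a
#    Gaussian posterior over a Z-dimensional latent code;
#  * generator G: a dense expansion of z followed by SPADE-ResNet stages
#    conditioned on temporally downsampled scalp input, nearest-neighbour
#    x2 upsampling, a two-layer LSTM over all L time steps, and a
#    time-distributed dense + tanh head producing the estimated intracranial
#    segment;
#  * discriminator D: a per-sensor Markovian (patch) stack of strided
#    temporal convolutions emitting one unbounded real/fake score per
#    intracranial sensor (patch size 1 x Mbar) and exposing every
#    intermediate feature map for the feature-matching loss.
#
# Graph-building internals (`*_graph`) operate on autodiff nodes; the
# exported operations wrap them for plain numeric arrays.

#' Architecture configuration
#'
#' Depths and widths the translation networks are parameterized by. The
#' temporal dimension is halved `encoder_layers` times in the encoder and
#' doubled `generator_stages` times in the generator, so `L` must be
#' divisible by both `2^encoder_layers` and `2^generator_stages`.
#'
#' @param latent_dim latent code dimension Z
#' @param encoder_layers number of strided conv layers in the encoder
#' @param encoder_filter_len temporal filter length in the encoder
#' @param encoder_base_filters filters in the first encoder layer (doubled
#'   each layer)
#' @param generator_stages number of SPADE-ResNet + upsample stages
#' @param generator_base_filters channel width reached at the final stage
#' @param lstm_hidden_units hidden units per LSTM layer
#' @param disc_filter_len temporal filter length in the discriminator
#' @param disc_layers total discriminator conv layers (the last has no
#'   normalization or activation)
#' @param disc_base_filters filters in the first discriminator layer
#' @param spade_embed_filters width of the SPADE condition embedding
#' @param leaky_slope negative slope of the leaky ReLU
#' @param ablation `"full"`, `"no_encoder"` (latent replaced by unit-norm
#'   Gaussian noise) or `"no_spade_resnet"` (SPADE-ResNet stages replaced by
#'   plain convolutions)
#' @param L,M,M_bar segment geometry
#' @return an object of class `arch_config`
#' @export
arch_config <- function(latent_dim = 256, encoder_layers = 4,
                        encoder_filter_len = 5, encoder_base_filters = 16,
                        generator_stages = 4, generator_base_filters = 8,
                        lstm_hidden_units = 64, disc_filter_len = 5,
                        disc_layers = 4, disc_base_filters = 8,
                        spade_embed_filters = 8, leaky_slope = 0.2,
                        ablation = c("full", "no_encoder", "no_spade_resnet"),
                        L = 64, M = 20, M_bar = 12) {
  ablation <- match.arg(ablation)
  stopifnot(latent_dim >= 1,
            L %% 2^encoder_layers == 0, L %/% 2^encoder_layers >= 1,
            L %% 2^generator_stages == 0, L %/% 2^generator_stages >= 1,
            L %/% 2^(disc_layers - 1) >= 1)
  structure(list(latent_dim = latent_dim, encoder_layers = encoder_layers,
                 encoder_filter_len = encoder_filter_len,
                 encoder_base_filters = encoder_base_filters,
                 generator_stages = generator_stages,
                 generator_base_filters = generator_base_filters,
                 lstm_hidden_units = lstm_hidden_units,
                 disc_filter_len = disc_filter_len, disc_layers = disc_layers,
                 disc_base_filters = disc_base_filters,
                 spade_embed_filters = spade_embed_filters,
                 leaky_slope = leaky_slope, ablation = ablation,
                 L = L, M = M, M_bar = M_bar),
            class = "arch_config")
}

gen_channel_plan <- function(arch) {
  # widest at the coarsest temporal resolution, halving as length doubles
  rev(arch$generator_base_filters * 2^(seq_len(arch$generator_stages) - 1))
}

init_spade <- function(ke, c_cond, c_act, c_embed) {
  list(embed = init_conv1d(ke, c_cond, c_embed),
       gamma = init_conv1d(ke, c_embed, c_act),
       beta = init_conv1d(ke, c_embed, c_act))
}

init_spade_resnet <- function(c_in, c_out, c_cond, c_embed) {
  p <- list(spade1 = init_spade(3, c_cond, c_in, c_embed),
            conv1 = init_conv1d(3, c_in, c_out),
            spade2 = init_spade(3, c_cond, c_out, c_embed),
            conv2 = init_conv1d(3, c_out, c_out))
  if (c_in != c_out) {
    p$spade_skip <- init_spade(3, c_cond, c_in, c_embed)
    p$conv_skip <- init_conv1d(1, c_in, c_out)
  }
  p
}

#' Initialize all three networks
#'
#' @param arch an [arch_config()]
#' @param seed RNG seed for the (Glorot-uniform) initialization
#' @return nested parameter list with components `encoder`, `generator`,
#'   `discriminator`
#' @export
init_translation_params <- function(arch, seed = 1) {
  set.seed(seed %% 2147483647)
  k <- arch$encoder_filter_len
  enc <- list(convs = list())
  c_in <- arch$M
  for (i in seq_len(arch$encoder_layers)) {
    c_out <- arch$encoder_base_filters * 2^(i - 1)
    enc$convs[[i]] <- init_conv1d(k, c_in, c_out)
    c_in <- c_out
  }
  flat <- (arch$L %/% 2^arch$encoder_layers) * c_in
  enc$mu <- init_dense(flat, arch$latent_dim)
  enc$logvar <- init_dense(flat, arch$latent_dim)

  plan <- gen_channel_plan(arch)
  L0 <- arch$L %/% 2^arch$generator_stages
  gen <- list(fc = init_dense(arch$latent_dim, L0 * plan[1]), stages = list())
  for (i in seq_len(arch$generator_stages)) {
    c_i <- plan[i]
    c_next <- if (i < arch$generator_stages) plan[i + 1] else arch$generator_base_filters
    stage <- if (arch$ablation == "no_spade_resnet") {
      list(conv = init_conv1d(3, c_i, c_i))
    } else {
      list(resnet = init_spade_resnet(c_i, c_i, arch$M, arch$spade_embed_filters))
    }
    stage$post <- init_conv1d(3, c_i, c_next)
    gen$stages[[i]] <- stage
  }
  gen$lstm1 <- init_lstm(arch$generator_base_filters, arch$lstm_hidden_units)
  gen$lstm2 <- init_lstm(arch$lstm_hidden_units, arch$lstm_hidden_units)
  gen$head <- init_dense(arch$lstm_hidden_units, arch$M_bar)

  kd <- arch$disc_filter_len
  disc <- list(convs = list())
  c_in <- 1L
  for (i in seq_len(arch$disc_layers - 1L)) {
    c_out <- arch$disc_base_filters * 2^(i - 1)
    disc$convs[[i]] <- init_conv1d(kd, c_in, c_out)
    c_in <- c_out
  }
  k_last <- arch$L %/% 2^(arch$disc_layers - 1L)
  disc$final <- init_conv1d(k_last, c_in, 1L)

  list(encoder = enc, generator = gen, discriminator = disc)
}

# ---- encoder ---------------------------------------------------------------

encode_graph <- function(x, wp, arch) {
  k <- arch$encoder_filter_len
  h <- x
  for (i in seq_len(arch$encoder_layers)) {
    h <- ad_conv1d(h, wp$convs[[i]]$w, wp$convs[[i]]$b, k, stride = 2L,
                   pad = same_pad(k))
    h <- ad_lrelu(ad_norm(h, "instance"), arch$leaky_slope)
  }
  d <- dim(ad_value(h))
  flat <- ad_reshape(h, c(d[1], d[2] * d[3]))
  list(mu = dense_fwd(flat, wp$mu), logvar = dense_fwd(flat, wp$logvar))
}

as_batch <- function(x, L, M) {
  if (length(dim(x)) == 2) {
    stopifnot(nrow(x) == L, ncol(x) == M)
    array(x, c(1, L, M))
  } else x
}

#' Encode a scalp segment to its latent posterior
#'
#' @param X scalp samples, an `L x M` matrix (or a [scalp_segment()], or an
#'   `(n, L, M)` array for a batch)
#' @param params parameter list from [init_translation_params()]
#' @param arch the matching [arch_config()]
#' @return list with `mu` and `sigma`, each of length `latent_dim` (matrices
#'   for batched input); `sigma = exp(logvar / 2)` is strictly positive
#' @export
encode <- function(X, params, arch) {
  if (inherits(X, "scalp_segment")) X <- X$samples
  if (length(dim(X)) == 2 &&
      !(nrow(X) == arch$L && ncol(X) == arch$M))
    stop("scalp input has shape (", nrow(X), ", ", ncol(X),
         "); expected (", arch$L, ", ", arch$M, ")")
  xb <- as_batch(X, arch$L, arch$M)
  wp <- wrap_params(params$encoder, trainable = FALSE)
  out <- encode_graph(ad_const(xb), wp, arch)
  mu <- ad_value(out$mu)
  sigma <- exp(ad_value(out$logvar) / 2)
  if (nrow(mu) == 1) list(mu = as.numeric(mu), sigma = as.numeric(sigma))
  else list(mu = mu, sigma = sigma)
}

#' Reparameterization of the latent sample
#'
#' `z = mu + epsilon * sigma`, elementwise, the sampling step that moves the
#' stochasticity into the auxiliary standard-normal variable `epsilon`.
#'
#' @param mu,sigma posterior mean and standard deviation vectors
#' @param epsilon standard-normal draw of the same length
#' @return latent vector `z`
#' @export
reparameterize <- function(mu, sigma, epsilon) {
  if (length(mu) != length(sigma) || length(mu) != length(epsilon))
    stop("mu, sigma and epsilon must have equal length")
  mu + epsilon * sigma
}

# ---- SPADE -----------------------------------------------------------------

spade_graph <- function(act, cond, wp, slope = 0.2) {
  da <- dim(ad_value(act))
  dc <- dim(ad_value(cond))
  if (da[2] != dc[2])
    stop("SPADE condition temporal length (", dc[2],
         ") does not match the activation (", da[2], ")")
  emb <- ad_lrelu(conv1d_fwd(cond, wp$embed, 3L, pad = same_pad(3L)), slope)
  gamma <- conv1d_fwd(emb, wp$gamma, 3L, pad = same_pad(3L))
  beta <- conv1d_fwd(emb, wp$beta, 3L, pad = same_pad(3L))
  ad_add(ad_mul(gamma, ad_norm(act, "channel")), beta)
}

#' Spatially-adaptive denormalization block
#'
#' Normalizes the activation sensor-wise (zero mean, unit variance per
#' channel over batch and time), then rescales and shifts it elementwise with
#' modulation maps `gamma` and `beta` convolved from the scalp condition.
#'
#' @param activation numeric `(n, T, C)` array (or `T x C` matrix)
#' @param condition scalp condition at the same temporal resolution,
#'   `(n, T, M)` array or `T x M` matrix
#' @param params SPADE parameter list (`embed`, `gamma`, `beta` conv layers),
#'   e.g. `init_translation_params(...)$generator$stages[[i]]$resnet$spade1`
#' @return modulated activation, same shape as `activation`
#' @export
spade_block <- function(activation, condition, params) {
  a3 <- if (length(dim(activation)) == 2)
    array(activation, c(1, dim(activation))) else activation
  c3 <- if (length(dim(condition)) == 2)
    array(condition, c(1, dim(condition))) else condition
  wp <- wrap_params(params, trainable = FALSE)
  out <- ad_value(spade_graph(ad_const(a3), ad_const(c3), wp))
  if (length(dim(activation)) == 2) matrix(out, dim(out)[2], dim(out)[3]) else out
}

spade_resnet_graph <- function(act, cond, wp, slope = 0.2) {
  h <- spade_graph(act, cond, wp$spade1, slope)
  h <- conv1d_fwd(ad_tanh(h), wp$conv1, 3L, pad = same_pad(3L))
  h <- spade_graph(h, cond, wp$spade2, slope)
  h <- conv1d_fwd(ad_tanh(h), wp$conv2, 3L, pad = same_pad(3L))
  skip <- if (!is.null(wp$conv_skip)) {
    conv1d_fwd(spade_graph(act, cond, wp$spade_skip, slope), wp$conv_skip, 1L)
  } else act
  ad_add(h, skip)
}

#' SPADE residual block
#'
#' Two SPADE -> tanh -> convolution units on the main path, added to a skip
#' path; when input and output channel counts differ the skip is itself a
#' SPADE-modulated 1x1 convolution projection.
#'
#' @inheritParams spade_block
#' @param params parameter list from `init_spade_resnet()` (e.g.
#'   `...$generator$stages[[i]]$resnet`)
#' @return output activation
#' @export
spade_resnet <- function(activation, condition, params) {
  a3 <- if (length(dim(activation)) == 2)
    array(activation, c(1, dim(activation))) else activation
  c3 <- if (length(dim(condition)) == 2)
    array(condition, c(1, dim(condition))) else condition
  wp <- wrap_params(params, trainable = FALSE)
  out <- ad_value(spade_resnet_graph(ad_const(a3), ad_const(c3), wp))
  if (length(dim(activation)) == 2) matrix(out, dim(out)[2], dim(out)[3]) else out
}

# ---- generator -------------------------------------------------------------

generate_graph <- function(x, z, wp, arch) {
  plan <- gen_channel_plan(arch)
  L0 <- arch$L %/% 2^arch$generator_stages
  B <- dim(ad_value(x))[1]
  h <- dense_fwd(z, wp$fc)
  h <- ad_reshape(h, c(B, L0, plan[1]))
  len <- L0
  for (i in seq_len(arch$generator_stages)) {
    st <- wp$stages[[i]]
    if (arch$ablation == "no_spade_resnet") {
      h <- ad_tanh(conv1d_fwd(h, st$conv, 3L, pad = same_pad(3L)))
    } else {
      cond <- ad_avgpool_time(x, arch$L %/% len)
      h <- spade_resnet_graph(h, cond, st$resnet, arch$leaky_slope)
    }
    h <- ad_upsample_time(h, 2L)
    len <- len * 2L
    h <- ad_lrelu(conv1d_fwd(h, st$post, 3L, pad = same_pad(3L)),
                  arch$leaky_slope)
  }
  h <- lstm_fwd(h, wp$lstm1, arch$lstm_hidden_units)
  h <- lstm_fwd(h, wp$lstm2, arch$lstm_hidden_units)
  ad_tanh(tdd_fwd(h, wp$head))
}

#' Generate an estimated intracranial segment from scalp input and a latent
#' code
#'
#' @param X scalp samples (`L x M` matrix, [scalp_segment()], or batch array)
#' @param z latent vector of length `latent_dim` (matrix rows for a batch)
#' @param params parameter list from [init_translation_params()]
#' @param arch the matching [arch_config()]
#' @return estimated intracranial samples: `L x M_bar` matrix (or batch
#'   array), values strictly inside `(-1, 1)`
#' @export
generate <- function(X, z, params, arch) {
  if (inherits(X, "scalp_segment")) X <- X$samples
  single <- length(dim(X)) == 2
  xb <- as_batch(X, arch$L, arch$M)
  zb <- if (is.matrix(z)) z else matrix(z, 1, length(z))
  if (ncol(zb) != arch$latent_dim)
    stop("latent z has length ", ncol(zb), "; expected ", arch$latent_dim)
  wp <- wrap_params(params$generator, trainable = FALSE)
  out <- ad_value(generate_graph(ad_const(xb), ad_const(zb), wp, arch))
  if (single) matrix(out, arch$L, arch$M_bar) else out
}

# ---- discriminator ---------------------------------------------------------

discriminate_graph <- function(y, wp, arch) {
  d <- dim(ad_value(y))
  B <- d[1]
  kd <- arch$disc_filter_len
  # fold sensors into the batch: the same temporal stack scores each sensor
  h <- ad_reshape(ad_permute(y, c(1, 3, 2)), c(B * arch$M_bar, arch$L, 1))
  feats <- list()
  for (i in seq_len(arch$disc_layers - 1L)) {
    h <- ad_conv1d(h, wp$convs[[i]]$w, wp$convs[[i]]$b, kd, stride = 2L,
                   pad = same_pad(kd))
    h <- ad_lrelu(ad_norm(h, "instance"), arch$leaky_slope)
    feats[[i]] <- h
  }
  k_last <- dim(ad_value(h))[2]
  s <- ad_conv1d(h, wp$final$w, wp$final$b, k_last, stride = 1L)
  scores <- ad_reshape(s, c(B, 1, arch$M_bar))
  feats[[arch$disc_layers]] <- scores
  list(scores = scores, features = feats)
}

#' Score an intracranial segment as real or estimated, per sensor
#'
#' @param candidate intracranial samples (`L x M_bar` matrix,
#'   [intracranial_segment()], or batch array)
#' @param params parameter list from [init_translation_params()]
#' @param arch the matching [arch_config()]
#' @return list with `scores` (`1 x M_bar` matrix per segment, unbounded) and
#'   `feature_maps` (one activation array per discriminator layer)
#' @export
discriminate <- function(candidate, params, arch) {
  if (inherits(candidate, "intracranial_segment")) candidate <- candidate$samples
  single <- length(dim(candidate)) == 2
  if (single && !(nrow(candidate) == arch$L && ncol(candidate) == arch$M_bar))
    stop("intracranial input has shape (", nrow(candidate), ", ",
         ncol(candidate), "); expected (", arch$L, ", ", arch$M_bar, ")")
  yb <- as_batch(candidate, arch$L, arch$M_bar)
  wp <- wrap_params(params$discriminator, trainable = FALSE)
  out <- discriminate_graph(ad_const(yb), wp, arch)
  scores <- ad_value(out$scores)
  feats <- lapply(out$features, ad_value)
  if (single)
    list(scores = matrix(scores, 1, arch$M_bar), feature_maps = feats)
  else list(scores = scores, feature_maps = feats)
}

# latent draw for the encoder-free ablation: standard normal scaled to unit
# Euclidean norm
noise_latent <- function(n, Z) {
  eps <- matrix(stats::rnorm(n * Z), n, Z)
  eps / sqrt(rowSums(eps^2))
}
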