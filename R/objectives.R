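# Training objectives: hinge adversarial losses for generator and
# discriminator, the KL divergence of the variational posterior from the
# standard-normal prior, L1 reconstruction, and discriminator feature
# matching. Each is a standalone function over numeric arrays; the trainer
# rebuilds the same expressions on the autodiff tape.
#
# Expectations are realized as means over the batch and all patch elements;
# the feature-matching L1 is summed per layer and scaled by 1/F_i, F_i being
# the layer's feature-channel count.

#' Loss weights of the generator objective
#'
#' The generator total is `hinge + lambda1 * KL + lambda2 * L1 +
#' lambda3 * FM`. Defaults follow the conventions of conditional
#' image-translation systems: a small KL penalty, a strong reconstruction
#' term and moderate feature matching.
#'
#' @param lambda1 KL divergence weight
#' @param lambda2 L1 reconstruction weight
#' @param lambda3 feature matching weight
#' @return an object of class `loss_weights`
#' @export
loss_weights <- function(lambda1 = 0.05, lambda2 = 100, lambda3 = 10) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' KL divergence of the latent posterior from the standard-normal prior
#'
#' `-1/2 * sum_z (1 + log sigma_z^2 - mu_z^2 - sigma_z^2)`, averaged over the
#' batch when `mu`/`sigma` are matrices (rows = samples). Nonnegative, zero
#' exactly at `mu = 0`, `sigma = 1`.
#'
#' @param mu,sigma posterior mean and standard deviation (vectors, or
#'   matrices with one row per sample)
#' @return scalar loss
#' @export
kl_loss <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (length(mu) != length(sigma)) stop("mu and sigma must have equal length")
  per <- -0.5 * (1 + log(sigma^2) - mu^2 - sigma^2)
  if (is.matrix(mu)) mean(rowSums(per)) else sum(per)
}

#' Hinge loss for the discriminator
#'
#' `-E[min(0, -1 + D(Y))] - E[min(0, -1 - D(Y_est))]`: real scores are pushed
#' above +1, fake scores below -1; zero once every margin is satisfied.
#'
#' @param scores_real,scores_fake patch score arrays of equal shape
#' @return scalar loss (>= 0)
#' @export
hinge_d_loss <- function(scores_real, scores_fake) {
  mean(pmax(0, 1 - scores_real)) + mean(pmax(0, 1 + scores_fake))
}

#' Hinge loss for the generator
#'
#' `-E[D(G(X, z))]`: the generator raises the discriminator's scores on its
#' output.
#'
#' @param scores_fake patch score array for generated segments
#' @return scalar loss
#' @export
hinge_g_loss <- function(scores_fake) {
  -mean(scores_fake)
}

#' L1 reconstruction loss
#'
#' Mean absolute elementwise difference between the real and estimated
#' intracranial segments.
#'
#' @param Y,Y_est arrays of equal shape (matrices or
#'   [intracranial_segment()]s)
#' @return scalar loss (0 iff identical)
#' @export
l1_loss <- function(Y, Y_est) {
  if (inherits(Y, "intracranial_segment")) Y <- Y$samples
  if (inherits(Y_est, "intracranial_segment")) Y_est <- Y_est$samples
  if (!identical(dim(Y), dim(Y_est)))
    stop("Y and Y_est have different shapes")
  mean(abs(Y - Y_est))
}

#' Discriminator feature matching loss
#'
#' `sum_i (1/F_i) * ||D_i(Y) - D_i(Y_est)||_1` over the discriminator's
#' layers, `F_i` the feature-channel count of layer `i`; the L1 norm is
#' summed over all elements and averaged over the batch (the leading array
#' dimension).
#'
#' @param features_real,features_fake equal-length lists of conformable
#'   feature arrays, batch first
#' @return scalar loss
#' @export
feature_matching_loss <- function(features_real, features_fake) {
  if (length(features_real) != length(features_fake))
    stop("feature lists have different lengths")
  total <- 0
  for (i in seq_along(features_real)) {
    fr <- features_real[[i]]
    fk <- features_fake[[i]]
    if (!identical(dim(fr), dim(fk)))
      stop("feature maps of layer ", i, " have different shapes")
    f_i <- dim(fr)[length(dim(fr))] # feature channels
    batch <- dim(fr)[1]
    total <- total + sum(abs(fr - fk)) / f_i / batch
  }
  total
}

#' Total generator objective
#'
#' @param h hinge generator loss
#' @param kl KL divergence loss
#' @param l1 L1 reconstruction loss
#' @param fm feature matching loss
#' @param w a [loss_weights()]
#' @return `h + lambda1 * kl + lambda2 * l1 + lambda3 * fm`
#' @export
generator_total_loss <- function(h, kl, l1, fm, w = loss_weights()) {
  h + w$lambda1 * kl + w$lambda2 * l1 + w$lambda3 * fm
}
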