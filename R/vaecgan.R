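# Joint adversarial training of encoder E, generator G and discriminator D,
# exposed through the classic modelling interface: vaecgan() fits per-subject
# segment data and returns a classed object with predict/residuals/plot/...
# methods. Updates alternate per batch: the discriminator minimizes the hinge
# loss on real versus detached generated segments, then encoder+generator
# jointly minimize hinge + lambda1*KL + lambda2*L1 + lambda3*FM with a fresh
# reparameterization draw per sample.

#' Training configuration
#'
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param lr_g,lr_d generator/discriminator Adam step sizes
#' @param beta1,beta2 Adam momentum parameters
#' @param weights a [loss_weights()]
#' @param g_steps encoder+generator updates per discriminator update
#' @param seed seed determining the whole training trajectory
#' @param verbose print one line per `verbose` epochs (0 = silent)
#' @return an object of class `train_control`
#' @export
train_control <- function(epochs = 200, batch_size = 16, lr_g = 2e-4,
                          lr_d = 2e-4, beta1 = 0.5, beta2 = 0.999,
                          weights = loss_weights(), g_steps = 1, seed = 1,
                          verbose = 0) {
  structure(list(epochs = epochs, batch_size = batch_size, lr_g = lr_g,
                 lr_d = lr_d, beta1 = beta1, beta2 = beta2, weights = weights,
                 g_steps = g_steps, seed = seed, verbose = verbose),
            class = "train_control")
}

seg_input <- function(segments) {
  if (inherits(segments, "subject_record")) segments <- segments$segments
  if (inherits(segments, "paired_segment")) segments <- list(segments)
  arr <- segments_to_arrays(segments)
  if (is.null(arr$scalp)) stop("no segments to train on")
  arr
}

# one discriminator update; returns params, state and the realized loss
d_step <- function(params, xb, yb, arch, ctrl, state_d) {
  fake <- gen_forward_value(params, xb, arch, sample_eps = TRUE)
  wd <- wrap_params(params$discriminator)
  dr <- discriminate_graph(ad_const(yb), wd, arch)
  df <- discriminate_graph(ad_const(fake), wd, arch)
  loss <- ad_add(ad_mean(ad_relu(ad_shift(ad_scale(dr$scores, -1), 1))),
                 ad_mean(ad_relu(ad_shift(df$scores, 1))))
  ad_backward(loss)
  upd <- adam_step(params$discriminator, collect_grads(wd), state_d,
                   lr = ctrl$lr_d, beta1 = ctrl$beta1, beta2 = ctrl$beta2)
  params$discriminator <- upd$params
  list(params = params, state = upd$state, loss = loss$value)
}

# numeric generator forward (no gradients): encode, reparameterize, generate
gen_forward_value <- function(params, xb, arch, sample_eps = TRUE) {
  B <- dim(xb)[1]
  if (arch$ablation == "no_encoder") {
    z <- noise_latent(B, arch$latent_dim)
  } else {
    wp <- wrap_params(params$encoder, trainable = FALSE)
    enc <- encode_graph(ad_const(xb), wp, arch)
    mu <- ad_value(enc$mu)
    sigma <- exp(ad_value(enc$logvar) / 2)
    eps <- if (sample_eps) matrix(stats::rnorm(B * arch$latent_dim), B) else 0
    z <- mu + eps * sigma
  }
  wg <- wrap_params(params$generator, trainable = FALSE)
  ad_value(generate_graph(ad_const(xb), ad_const(z), wg, arch))
}

# one encoder+generator update; discriminator parameters stay constant
g_step <- function(params, xb, yb, arch, ctrl, state_g) {
  B <- dim(xb)[1]
  w <- ctrl$weights
  we <- wrap_params(params$encoder)
  wg <- wrap_params(params$generator)
  wdc <- wrap_params(params$discriminator, trainable = FALSE)

  if (arch$ablation == "no_encoder") {
    z <- ad_const(noise_latent(B, arch$latent_dim))
    kl <- ad_const(0)
  } else {
    enc <- encode_graph(ad_const(xb), we, arch)
    mu <- enc$mu
    logvar <- enc$logvar
    sigma <- ad_exp(ad_scale(logvar, 0.5))
    eps <- ad_const(matrix(stats::rnorm(B * arch$latent_dim), B))
    z <- ad_add(mu, ad_mul(eps, sigma))
    inner <- ad_sub(ad_sub(ad_shift(logvar, 1), ad_mul(mu, mu)),
                    ad_exp(logvar))
    kl <- ad_scale(ad_sum(inner), -0.5 / B)
  }
  yf <- generate_graph(ad_const(xb), z, wg, arch)
  df <- discriminate_graph(yf, wdc, arch)
  real <- discriminate(yb, params, arch)

  lgh <- ad_scale(ad_mean(df$scores), -1)
  l1 <- ad_mean(ad_abs(ad_sub(ad_const(yb), yf)))
  fm <- ad_const(0)
  for (i in seq_along(df$features)) {
    dmi <- dim(real$feature_maps[[i]])
    diff_i <- ad_abs(ad_sub(ad_const(real$feature_maps[[i]]), df$features[[i]]))
    fm <- ad_add(fm, ad_scale(ad_sum(diff_i), 1 / (dmi[3] * dmi[1])))
  }
  total <- ad_add(ad_add(lgh, ad_scale(kl, w$lambda1)),
                  ad_add(ad_scale(l1, w$lambda2), ad_scale(fm, w$lambda3)))
  ad_backward(total)
  eg <- list(encoder = params$encoder, generator = params$generator)
  gr <- list(encoder = collect_grads(we), generator = collect_grads(wg))
  upd <- adam_step(eg, gr, state_g, lr = ctrl$lr_g, beta1 = ctrl$beta1,
                   beta2 = ctrl$beta2)
  params$encoder <- upd$params$encoder
  params$generator <- upd$params$generator
  list(params = params, state = upd$state,
       losses = c(L_Gh = lgh$value, L_KL = kl$value, L_L1 = l1$value,
                  L_FM = fm$value, L_G = total$value))
}

#' Fit a scalp-to-intracranial translation model
#'
#' Trains the variational encoder, SPADE-conditioned generator and per-sensor
#' patch discriminator jointly on one subject's paired segments.
#'
#' @param segments list of [paired_segment()]s (or a [subject_record()])
#' @param arch an [arch_config()]
#' @param control a [train_control()]
#' @return an object of class `vaecgan` with components `params`, `arch`,
#'   `control`, `history` (per-epoch data frame of all loss terms) and the
#'   training data
#' @seealso [predict.vaecgan()], [translate()], [train_cohort()]
#' @export
vaecgan <- function(segments, arch = arch_config(), control = train_control()) {
  arr <- seg_input(segments)
  stopifnot(dim(arr$scalp)[2] == arch$L, dim(arr$scalp)[3] == arch$M,
            dim(arr$intracranial)[3] == arch$M_bar)
  n <- dim(arr$scalp)[1]
  set.seed(control$seed %% 2147483647)
  params <- init_translation_params(arch, seed = stats::runif(1, 1, 2^30))
  state_d <- adam_init(params$discriminator)
  state_g <- adam_init(list(encoder = params$encoder,
                            generator = params$generator))
  hist <- matrix(NA_real_, control$epochs, 6,
                 dimnames = list(NULL, c("L_D", "L_Gh", "L_KL", "L_L1",
                                         "L_FM", "L_G")))
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    acc <- matrix(0, length(batches), 6)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      xb <- arr$scalp[b, , , drop = FALSE]
      yb <- arr$intracranial[b, , , drop = FALSE]
      ds <- d_step(params, xb, yb, arch, control, state_d)
      params <- ds$params
      state_d <- ds$state
      n_g <- if (is.null(control$g_steps)) 1L else control$g_steps
      for (gi in seq_len(n_g)) {
        gs <- g_step(params, xb, yb, arch, control, state_g)
        params <- gs$params
        state_g <- gs$state
      }
      acc[bi, ] <- c(ds$loss, gs$losses)
      if (!all(is.finite(acc[bi, ])))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", batch ", bi)
    }
    hist[ep, ] <- colMeans(acc)
    if (control$verbose > 0 && ep %% control$verbose == 0)
      message(sprintf("epoch %3d  L_D %.4f  L_G %.4f  L_L1 %.4f",
                      ep, hist[ep, "L_D"], hist[ep, "L_G"], hist[ep, "L_L1"]))
  }
  structure(list(params = params, arch = arch, control = control,
                 history = as.data.frame(hist), data = arr),
            class = "vaecgan")
}

#' Translate scalp segments to estimated intracranial segments
#'
#' @param model a fitted [vaecgan()]
#' @param X scalp input: `L x M` matrix, [scalp_segment()], [paired_segment()]
#'   or `(n, L, M)` batch array
#' @param mode `"mean"` uses `epsilon = 0` (`z = mu`) for deterministic
#'   output; `"sample"` draws `epsilon ~ N(0, I)`
#' @return estimated intracranial samples, `L x M_bar` matrix or batch array
#' @export
translate <- function(model, X, mode = c("mean", "sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "vaecgan"))
  if (inherits(X, "paired_segment")) X <- X$scalp
  if (inherits(X, "scalp_segment")) X <- X$samples
  single <- length(dim(X)) == 2
  xb <- as_batch(X, model$arch$L, model$arch$M)
  if (model$arch$ablation == "no_encoder" && mode == "mean")
    set.seed(model$control$seed %% 2147483647)
  out <- gen_forward_value(model$params, xb, model$arch,
                           sample_eps = (mode == "sample"))
  if (single) matrix(out, model$arch$L, model$arch$M_bar) else out
}

#' @rdname translate
#' @param object a fitted [vaecgan()]
#' @param newdata scalp input as in [translate()]; defaults to the training
#'   scalp segments
#' @param ... ignored
#' @export
predict.vaecgan <- function(object, newdata = NULL, mode = c("mean", "sample"),
                            ...) {
  if (is.null(newdata)) newdata <- object$data$scalp
  if (is.list(newdata) && !is.array(newdata))
    newdata <- seg_input(newdata)$scalp
  translate(object, newdata, mode = match.arg(mode))
}

#' @export
print.vaecgan <- function(x, ...) {
  a <- x$arch
  cat("Scalp-to-intracranial translation model (VAE-cGAN)\n")
  cat(sprintf("  geometry: L=%d, M=%d scalp -> M_bar=%d intracranial, Z=%d\n",
              a$L, a$M, a$M_bar, a$latent_dim))
  if (a$ablation != "full") cat("  ablation:", a$ablation, "\n")
  n_ep <- nrow(x$history)
  cat(sprintf("  trained %d epochs on %d segments; final L_L1 = %.4f, L_D = %.4f\n",
              n_ep, dim(x$data$scalp)[1], x$history$L_L1[n_ep],
              x$history$L_D[n_ep]))
  invisible(x)
}

#' @export
summary.vaecgan <- function(object, ...) {
  res <- residuals(object)
  out <- list(arch = object$arch, history = object$history,
              n_segments = dim(object$data$scalp)[1],
              train_l1 = mean(abs(res)),
              train_mse = mean(res^2))
  class(out) <- "summary.vaecgan"
  out
}

#' @export
print.summary.vaecgan <- function(x, ...) {
  cat("VAE-cGAN translation model\n")
  cat(sprintf("  segments: %d, epochs: %d\n", x$n_segments, nrow(x$history)))
  cat(sprintf("  training reconstruction: L1 %.4f, MSE %.4f\n",
              x$train_l1, x$train_mse))
  cat("  final epoch losses:\n")
  print(round(x$history[nrow(x$history), ], 4))
  invisible(x)
}

#' @export
coef.vaecgan <- function(object, ...) {
  unlist(lapply(c("encoder", "generator", "discriminator"), function(nm) {
    stats::setNames(flatten_leaves(object$params[[nm]]), NULL)
  }))
}

#' @export
residuals.vaecgan <- function(object, ...) {
  est <- predict(object)
  object$data$intracranial - est
}

#' @export
plot.vaecgan <- function(x, ...) {
  h <- x$history
  graphics::matplot(seq_len(nrow(h)), cbind(h$L_D, h$L_G / max(1, stats::median(abs(h$L_G)))),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L_D", "L_G (scaled)"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
simulate.vaecgan <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data$scalp
  lapply(seq_len(nsim), function(i) translate(object, newdata, mode = "sample"))
}

#' Train one translation model per subject
#'
#' Per-subject seeds are offset deterministically from `control$seed`.
#'
#' @param cohort a [subject_cohort()]
#' @param arch an [arch_config()]
#' @param control a [train_control()]
#' @return named list of [vaecgan()] models, one per subject
#' @export
train_cohort <- function(cohort, arch = arch_config(),
                         control = train_control()) {
  stopifnot(inherits(cohort, "subject_cohort"))
  models <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (!length(s$segments)) stop("subject ", s$subject_id, " has no segments")
    ctrl_i <- control
    ctrl_i$seed <- (control$seed + 101 * i) %% 2147483647
    models[[s$subject_id]] <- tryCatch(
      vaecgan(s$segments, arch, ctrl_i),
      error = function(e) stop("subject ", s$subject_id, ": ",
                               conditionMessage(e)))
  }
  models
}

# ---- checkpointing ---------------------------------------------------------

flatten_named <- function(p, prefix = "") {
  if (is.list(p)) {
    out <- list()
    nms <- names(p)
    if (is.null(nms)) nms <- as.character(seq_along(p))
    nms[nms == ""] <- as.character(which(nms == ""))
    for (i in seq_along(p)) {
      out <- c(out, flatten_named(p[[i]], paste0(prefix, nms[i], "/")))
    }
    out
  } else {
    stats::setNames(list(p), sub("/$", "", prefix))
  }
}

unflatten_named <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    path <- strsplit(nm, "/", fixed = TRUE)[[1]]
    out <- assign_path(out, path, flat[[nm]])
  }
  out
}

assign_path <- function(lst, path, value) {
  k <- path[1]
  kk <- suppressWarnings(as.integer(k))
  key <- if (!is.na(kk) && as.character(kk) == k) kk else k
  if (length(path) == 1) {
    lst[[key]] <- value
  } else {
    cur <- if (length(lst) >= 1 && !is.null(tryCatch(lst[[key]],
                                                     error = function(e) NULL)))
      lst[[key]] else list()
    lst[[key]] <- assign_path(cur, path[-1], value)
  }
  lst
}

#' Save a fitted model as a portable NPZ checkpoint
#'
#' All three networks' arrays are stored under slash-separated keys
#' (`encoder/convs/1/w`, ...) beside the architecture and per-epoch loss
#' history, so checkpoints can be inspected from any NPZ reader.
#'
#' @param model a fitted [vaecgan()]
#' @param path output file
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  flat <- flatten_named(model$params)
  flat$`arch.json` <- charToRaw(jsonlite::toJSON(unclass(model$arch),
                                                 auto_unbox = TRUE))
  ctrl <- unclass(model$control)
  ctrl$weights <- unclass(ctrl$weights)
  flat$`control.json` <- charToRaw(jsonlite::toJSON(ctrl, auto_unbox = TRUE))
  flat$history <- as.matrix(model$history)
  npz_write(flat, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file
#' @return a [vaecgan()] model (without the training data)
#' @export
load_checkpoint <- function(path) {
  flat <- npz_read(path)
  arch <- jsonlite::fromJSON(rawToChar(flat$`arch.json`))
  class(arch) <- "arch_config"
  ctrl <- jsonlite::fromJSON(rawToChar(flat$`control.json`))
  ctrl$weights <- do.call(loss_weights, ctrl$weights)
  class(ctrl) <- "train_control"
  hist <- flat$history
  colnames(hist) <- c("L_D", "L_Gh", "L_KL", "L_L1", "L_FM", "L_G")
  params <- unflatten_named(flat[setdiff(names(flat),
                                         c("arch.json", "control.json",
                                           "history"))])
  structure(list(params = params, arch = arch, control = ctrl,
                 history = as.data.frame(hist),
                 data = list(scalp = NULL, intracranial = NULL)),
            class = "vaecgan")
}
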