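# Layer parameter containers and composite forward helpers shared by the
# encoder, generator, discriminator and the IED classifier. Parameters are
# plain nested lists of numeric arrays; `wrap_params`/`collect_grads` move
# them on and off the autodiff tape.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

init_conv1d <- function(k, c_in, c_out) {
  list(w = glorot(k * c_in, c_out), b = numeric(c_out))
}

init_dense <- function(n_in, n_out) {
  list(w = glorot(n_in, n_out), b = numeric(n_out))
}

init_lstm <- function(n_in, hidden) {
  b <- numeric(4 * hidden)
  b[hidden + seq_len(hidden)] <- 1 # forget-gate bias
  list(wx = glorot(n_in, 4 * hidden), wh = glorot(hidden, 4 * hidden), b = b)
}

dense_fwd <- function(x, p) ad_add_rowvec(ad_matmul(x, p$w), p$b)

conv1d_fwd <- function(x, p, k, stride = 1L, pad = c(0L, 0L)) {
  ad_conv1d(x, p$w, p$b, k, stride = stride, pad = pad)
}

# "same"-style padding for stride-s convolutions on even lengths
same_pad <- function(k) c((k - 1L) %/% 2L, k %/% 2L)

# x: (B, T, Cin) -> (B, T, hidden); states initialized to zero
lstm_fwd <- function(x, p, hidden) {
  ad_lstm(x, p$wx, p$wh, p$b, hidden)
}

# time-distributed dense: (B, T, Cin) -> (B, T, n_out)
tdd_fwd <- function(x, p) {
  d <- dim(ad_value(x))
  x2 <- ad_reshape(x, c(d[1] * d[2], d[3]))
  y2 <- dense_fwd(x2, p)
  ad_reshape(y2, c(d[1], d[2], ncol(ad_value(y2))))
}

# ---- parameter tree utilities ---------------------------------------------

wrap_params <- function(p, trainable = TRUE) {
  if (is.list(p)) lapply(p, wrap_params, trainable = trainable)
  else if (trainable) ad_param(p) else ad_const(p)
}

collect_grads <- function(wp) {
  if (is.list(wp)) lapply(wp, collect_grads)
  else if (is.null(wp$grad)) zeros_like(wp$value)
  else wp$grad
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) tree_map2(f, x, y), a, b)
  else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x))
  else f(a)
}

flatten_leaves <- function(a) {
  if (is.list(a)) unlist(lapply(a, flatten_leaves), use.names = FALSE)
  else as.numeric(a)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(zeros_like, params), v = tree_map(zeros_like, params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
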