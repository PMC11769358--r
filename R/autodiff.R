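# Reverse-mode automatic differentiation on a dynamically built tape.
#
# Every network forward pass in this package (encoder, generator, discriminator,
# classifier) is expressed in the small op vocabulary below; gradients are
# obtained by traversing the tape in reverse creation order. Values are plain
# numeric vectors/matrices/3-D arrays (3-D layout: batch x time x channel).

.ad <- new.env(parent = emptyenv())
.ad$n <- 0L

ad_node <- function(value, parents = list(), backfn = NULL,
                    req = any(vapply(parents, function(p) p$req, logical(1)))) {
  .ad$n <- .ad$n + 1L
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$id <- .ad$n
  e$req <- req
  e$grad <- NULL
  class(e) <- "adnode"
  e
}

ad_param <- function(value) ad_node(value, req = TRUE)
ad_const <- function(value) ad_node(value, req = FALSE)
as_ad <- function(x) if (inherits(x, "adnode")) x else ad_const(x)
ad_value <- function(x) if (inherits(x, "adnode")) x$value else x

zeros_like <- function(v) {
  z <- v
  z[] <- 0
  z
}

#' @noRd
ad_backward <- function(root, seed = 1) {
  # collect the reachable subgraph that can influence a parameter
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) if (p$req) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(n_nodes)]
  ids <- vapply(nodes, function(nd) nd$id, integer(1))
  ord <- order(ids, decreasing = TRUE)

  g0 <- root$value
  g0[] <- seed
  root$grad <- g0
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!p$req || is.null(gs[[i]])) next
      if (is.null(p$grad)) p$grad <- gs[[i]] else p$grad <- p$grad + gs[[i]]
    }
  }
  invisible(root)
}

# ---- elementwise ----------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_shift <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$value + k, list(a), function(g) list(g))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  y <- tanh(a$value)
  ad_node(y, list(a), function(g) list(g * (1 - y * y)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  y <- 1 / (1 + exp(-a$value))
  ad_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_exp <- function(a) {
  a <- as_ad(a)
  y <- exp(a$value)
  ad_node(y, list(a), function(g) list(g * y))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  v <- a$value
  y <- v
  neg <- v < 0
  y[neg] <- 0
  ad_node(y, list(a), function(g) {
    gg <- g
    gg[neg] <- 0
    list(gg)
  })
}

ad_lrelu <- function(a, slope = 0.2) {
  a <- as_ad(a)
  v <- a$value
  y <- v
  neg <- v < 0
  y[neg] <- slope * v[neg]
  ad_node(y, list(a), function(g) {
    gg <- g
    gg[neg] <- slope * g[neg]
    list(gg)
  })
}

ad_abs <- function(a) {
  a <- as_ad(a)
  v <- a$value
  ad_node(abs(v), list(a), function(g) list(g * sign(v)))
}

ad_softplus <- function(a) {
  a <- as_ad(a)
  v <- a$value
  y <- log1p(exp(-abs(v))) + pmax(v, 0)
  dim(y) <- dim(v)
  ad_node(y, list(a), function(g) list(g / (1 + exp(-v))))
}

# ---- reductions -----------------------------------------------------------

ad_sum <- function(a) {
  a <- as_ad(a)
  v <- a$value
  ad_node(sum(v), list(a), function(g) {
    gg <- v
    gg[] <- g
    list(gg)
  })
}

ad_mean <- function(a) {
  a <- as_ad(a)
  v <- a$value
  n <- length(v)
  ad_node(sum(v) / n, list(a), function(g) {
    gg <- v
    gg[] <- g / n
    list(gg)
  })
}

# ---- linear algebra -------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

# X (n, k) plus a length-k bias vector broadcast over rows
ad_add_rowvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  xv <- x$value
  ad_node(xv + rep(b$value, each = nrow(xv)), list(x, b),
          function(g) list(g, colSums(g)))
}

# ---- shape ops ------------------------------------------------------------

ad_reshape <- function(a, dm) {
  a <- as_ad(a)
  od <- dim(a$value)
  if (is.null(od)) od <- length(a$value)
  ad_node(array(a$value, dm), list(a), function(g) list(array(g, od)))
}

ad_permute <- function(a, perm) {
  a <- as_ad(a)
  inv <- order(perm)
  ad_node(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

ad_cols <- function(a, idx) {
  a <- as_ad(a)
  v <- a$value
  ad_node(v[, idx, drop = FALSE], list(a), function(g) {
    z <- zeros_like(v)
    z[, idx] <- g
    list(z)
  })
}

# (B, T, C) -> matrix (B, C) at time t
ad_slice_time <- function(a, t) {
  a <- as_ad(a)
  v <- a$value
  d <- dim(v)
  ad_node(matrix(v[, t, ], d[1], d[3]), list(a), function(g) {
    z <- zeros_like(v)
    z[, t, ] <- g
    list(z)
  })
}

# list of T matrices (B, C) -> (B, T, C)
ad_stack_time <- function(slices) {
  slices <- lapply(slices, as_ad)
  Tn <- length(slices)
  d <- dim(slices[[1]]$value)
  out <- array(0, c(d[1], Tn, d[2]))
  for (t in seq_len(Tn)) out[, t, ] <- slices[[t]]$value
  ad_node(out, slices, function(g) {
    lapply(seq_len(Tn), function(t) matrix(g[, t, ], d[1], d[2]))
  })
}

# ---- temporal resampling ---------------------------------------------------

ad_avgpool_time <- function(a, f) {
  a <- as_ad(a)
  v <- a$value
  d <- dim(v) # (B, T, C)
  stopifnot(d[2] %% f == 0)
  To <- d[2] %/% f
  vp <- aperm(v, c(2, 1, 3))                 # (T, B, C)
  blk <- array(vp, c(f, To, d[1], d[3]))
  m <- colMeans(blk)                          # (To, B, C)
  ad_node(aperm(m, c(2, 1, 3)), list(a), function(g) {
    gp <- aperm(g, c(2, 1, 3))                # (To, B, C)
    ge <- array(0, c(f, To, d[1], d[3]))
    for (j in seq_len(f)) ge[j, , , ] <- gp / f
    list(aperm(array(ge, c(d[2], d[1], d[3])), c(2, 1, 3)))
  })
}

ad_upsample_time <- function(a, f) {
  a <- as_ad(a)
  v <- a$value
  d <- dim(v)
  vp <- aperm(v, c(2, 1, 3))
  up <- vp[rep(seq_len(d[2]), each = f), , , drop = FALSE]
  ad_node(aperm(up, c(2, 1, 3)), list(a), function(g) {
    gp <- aperm(g, c(2, 1, 3))                # (T*f, B, C)
    blk <- array(gp, c(f, d[2], d[1], d[3]))
    list(aperm(colSums(blk), c(2, 1, 3)))
  })
}

ad_maxpool_time <- function(a, f) {
  a <- as_ad(a)
  v <- a$value
  d <- dim(v)
  stopifnot(d[2] %% f == 0)
  To <- d[2] %/% f
  vp <- aperm(v, c(2, 1, 3))
  a2 <- matrix(vp, f, To * d[1] * d[3])
  ncols <- ncol(a2)
  idx <- max.col(t(a2), ties.method = "first")
  pos <- idx + (seq_len(ncols) - 1L) * f
  vals <- a2[pos]
  out <- aperm(array(vals, c(To, d[1], d[3])), c(2, 1, 3))
  ad_node(out, list(a), function(g) {
    gp <- as.vector(aperm(g, c(2, 1, 3)))
    z2 <- matrix(0, f, ncols)
    z2[pos] <- gp
    list(aperm(array(z2, c(d[2], d[1], d[3])), c(2, 1, 3)))
  })
}

# ---- LSTM (fused) ----------------------------------------------------------

# Whole-sequence LSTM as one tape node with hand-written BPTT: dramatically
# fewer nodes than composing per-timestep ops. x: (B, T, Cin); wx: (Cin, 4H);
# wh: (H, 4H); b: length 4H with gate order (input, forget, output, cell).
ad_lstm <- function(x, wx, wh, b, hidden) {
  x <- as_ad(x); wx <- as_ad(wx); wh <- as_ad(wh); b <- as_ad(b)
  xv <- x$value; wxv <- wx$value; whv <- wh$value; bv <- b$value
  d <- dim(xv)
  B <- d[1]; Tn <- d[2]; H <- hidden
  i1 <- seq_len(H)
  ig <- fg <- og <- gg <- cs <- tc <- hs <- xs <- vector("list", Tn)
  out <- array(0, c(B, Tn, H))
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  brep <- rep(bv, each = B)
  for (t in seq_len(Tn)) {
    xt <- matrix(xv[, t, ], B, d[3])
    a <- xt %*% wxv + h %*% whv + brep
    i_t <- 1 / (1 + exp(-a[, i1, drop = FALSE]))
    f_t <- 1 / (1 + exp(-a[, H + i1, drop = FALSE]))
    o_t <- 1 / (1 + exp(-a[, 2L * H + i1, drop = FALSE]))
    g_t <- tanh(a[, 3L * H + i1, drop = FALSE])
    cc <- f_t * cc + i_t * g_t
    tc_t <- tanh(cc)
    h <- o_t * tc_t
    ig[[t]] <- i_t; fg[[t]] <- f_t; og[[t]] <- o_t; gg[[t]] <- g_t
    cs[[t]] <- cc; tc[[t]] <- tc_t; hs[[t]] <- h; xs[[t]] <- xt
    out[, t, ] <- h
  }
  ad_node(out, list(x, wx, wh, b), function(gr) {
    dwx <- matrix(0, d[3], 4L * H)
    dwh <- matrix(0, H, 4L * H)
    db <- numeric(4L * H)
    dx <- array(0, d)
    zero_bh <- matrix(0, B, H)
    dh_carry <- zero_bh
    dc_carry <- zero_bh
    twx <- t(wxv)
    twh <- t(whv)
    for (t in rev(seq_len(Tn))) {
      i_t <- ig[[t]]; f_t <- fg[[t]]; o_t <- og[[t]]; g_t <- gg[[t]]
      tc_t <- tc[[t]]
      c_prev <- if (t > 1) cs[[t - 1]] else zero_bh
      h_prev <- if (t > 1) hs[[t - 1]] else zero_bh
      dh <- matrix(gr[, t, ], B, H) + dh_carry
      do_ <- dh * tc_t
      dct <- dh * o_t * (1 - tc_t^2) + dc_carry
      dc_carry <- dct * f_t
      da <- cbind((dct * g_t) * i_t * (1 - i_t),
                  (dct * c_prev) * f_t * (1 - f_t),
                  do_ * o_t * (1 - o_t),
                  (dct * i_t) * (1 - g_t^2))
      dwx <- dwx + crossprod(xs[[t]], da)
      dwh <- dwh + crossprod(h_prev, da)
      db <- db + colSums(da)
      dx[, t, ] <- da %*% twx
      dh_carry <- da %*% twh
    }
    list(dx, dwx, dwh, db)
  })
}

# ---- convolution -----------------------------------------------------------

# 1-D convolution along time. x: (B, T, Cin); w: matrix (k*Cin, Cout) with row
# layout dt fastest within channel blocks; b: length Cout; zero padding
# (pad_l, pad_r) then stride s.
ad_conv1d <- function(x, w, b, k, stride = 1L, pad = c(0L, 0L)) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  v <- x$value
  d <- dim(v)
  B <- d[1]; Tn <- d[2]; Cin <- d[3]
  Tp <- Tn + pad[1] + pad[2]
  if (pad[1] > 0 || pad[2] > 0) {
    vp <- array(0, c(B, Tp, Cin))
    vp[, pad[1] + seq_len(Tn), ] <- v
  } else vp <- v
  To <- (Tp - k) %/% stride + 1L
  stopifnot(To >= 1L)
  # gather/scatter per kernel tap (k is small), all channels at once
  dt_cols <- lapply(seq_len(k), function(dt) (seq_len(To) - 1L) * stride + dt)
  X2 <- matrix(0, B * To, k * Cin)
  tap_of <- rep(seq_len(k), Cin)
  for (dt in seq_len(k)) {
    blk <- matrix(vp[, dt_cols[[dt]], , drop = FALSE], B * To, Cin)
    X2[, which(tap_of == dt)] <- blk
  }
  wv <- w$value
  Cout <- ncol(wv)
  Y2 <- X2 %*% wv + rep(b$value, each = nrow(X2))
  out <- array(Y2, c(B, To, Cout))
  ad_node(out, list(x, w, b), function(g) {
    G2 <- matrix(g, B * To, Cout)
    dw <- crossprod(X2, G2)
    db <- colSums(G2)
    dX2 <- tcrossprod(G2, wv)                  # (B*To, k*Cin)
    dvp <- array(0, c(B, Tp, Cin))
    for (dt in seq_len(k)) {
      blk <- array(dX2[, which(tap_of == dt), drop = FALSE], c(B, To, Cin))
      dvp[, dt_cols[[dt]], ] <- dvp[, dt_cols[[dt]], , drop = FALSE] + blk
    }
    dx <- dvp[, pad[1] + seq_len(Tn), , drop = FALSE]
    list(dx, dw, db)
  })
}

# ---- normalization ---------------------------------------------------------

# mode "instance": each (segment, channel) normalized over time;
# mode "channel": each channel normalized over batch and time (the sensor-wise
# convention used inside SPADE blocks).
ad_norm <- function(x, mode = c("instance", "channel"), eps = 1e-5) {
  mode <- match.arg(mode)
  x <- as_ad(x)
  v <- x$value
  d <- dim(v) # (B, T, C)
  if (mode == "channel") {
    v2 <- matrix(v, d[1] * d[2], d[3])
    unshape <- function(m) array(m, d)
    reshape_g <- function(g) matrix(g, d[1] * d[2], d[3])
  } else {
    vp <- aperm(v, c(2, 1, 3))
    v2 <- matrix(vp, d[2], d[1] * d[3])
    unshape <- function(m) aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
    reshape_g <- function(g) matrix(aperm(g, c(2, 1, 3)), d[2], d[1] * d[3])
  }
  nr <- nrow(v2)
  mu <- colMeans(v2)
  ctr <- v2 - rep(mu, each = nr)
  sd2 <- sqrt(colMeans(ctr * ctr) + eps)
  inv_sd <- rep(1 / sd2, each = nr)
  xhat <- ctr * inv_sd
  ad_node(unshape(xhat), list(x), function(g) {
    g2 <- reshape_g(g)
    gm <- colMeans(g2)
    gx <- colMeans(g2 * xhat)
    dx2 <- (g2 - rep(gm, each = nr) - xhat * rep(gx, each = nr)) * inv_sd
    list(unshape(dx2))
  })
}
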