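# Layer arithmetic: forward and backward passes for the building blocks of
# the five architectures (Conv1D, max-pool, GRU, LSTM, dropout, flatten,
# dense). Each pass operates on one sample; inputs flow as matrices with
# time on the rows and channels/features on the columns. Backward passes
# are validated against central finite differences in the test suite.

act_fwd <- function(pre, kind) {
  switch(kind,
         relu = pmax(pre, 0),
         tanh = tanh(pre),
         linear = pre,
         abort(sprintf("unknown activation %s", kind)))
}

# derivative wrt pre-activation, evaluated elementwise
act_deriv <- function(pre, kind) {
  switch(kind,
         relu = (pre > 0) * 1,
         tanh = 1 - tanh(pre)^2,
         linear = array(1, dim(pre) %||% length(pre)),
         abort(sprintf("unknown activation %s", kind)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

new_layer <- function(type, ...) {
  structure(list(type = type, config = list(...), params = NULL),
            class = "glucast_layer")
}

# ---- parameter initialisation (consumes the active RNG stream) ----------

init_layer <- function(layer, input_dim) {
  cfg <- layer$config
  layer$params <- switch(
    layer$type,
    conv1d = list(W = glorot(cfg$kernel, cfg$filters),
                  b = numeric(cfg$filters)),
    dense = list(W = glorot(input_dim, cfg$units),
                 b = numeric(cfg$units)),
    gru = {
      U <- cfg$units
      list(Wz = glorot(input_dim, U), Uz = glorot(U, U), bz = numeric(U),
           Wr = glorot(input_dim, U), Ur = glorot(U, U), br = numeric(U),
           Wh = glorot(input_dim, U), Uh = glorot(U, U), bh = numeric(U))
    },
    lstm = {
      U <- cfg$units
      list(Wi = glorot(input_dim, U), Ui = glorot(U, U), bi = numeric(U),
           Wf = glorot(input_dim, U), Uf = glorot(U, U),
           bf = rep(1, U),            # unit forget-gate bias
           Wo = glorot(input_dim, U), Uo = glorot(U, U), bo = numeric(U),
           Wg = glorot(input_dim, U), Ug = glorot(U, U), bg = numeric(U))
    },
    maxpool = ,
    flatten = ,
    dropout = list(),
    abort(sprintf("unknown layer type %s", layer$type)))
  layer
}

# parameter names subject to L2 weight decay (recurrent and dense kernels)
l2_param_names <- function(layer) {
  switch(layer$type,
         dense = "W",
         gru = c("Wz", "Uz", "Wr", "Ur", "Wh", "Uh"),
         lstm = c("Wi", "Ui", "Wf", "Uf", "Wo", "Uo", "Wg", "Ug"),
         character(0))
}

# ---- forward ------------------------------------------------------------

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
         conv1d = conv1d_forward(layer, x),
         maxpool = maxpool_forward(layer, x),
         gru = gru_forward(layer, x),
         lstm = lstm_forward(layer, x),
         dropout = dropout_forward(layer, x, training),
         flatten = list(out = matrix(as.vector(x), 1), cache = dim(x)),
         dense = dense_forward(layer, x))
}

conv1d_forward <- function(layer, x) {
  k <- layer$config$kernel
  t_in <- nrow(x)
  t_out <- t_in - k + 1L
  Xcol <- matrix(0, t_out, k)
  for (j in seq_len(k)) Xcol[, j] <- x[j:(j + t_out - 1L), 1L]
  pre <- sweep(Xcol %*% layer$params$W, 2, layer$params$b, "+")
  list(out = act_fwd(pre, "relu"),
       cache = list(Xcol = Xcol, pre = pre, t_in = t_in))
}

maxpool_forward <- function(layer, x) {
  t_in <- nrow(x)
  t_out <- t_in %/% 2L
  if (t_out == 0L) {
    # window too short to pool; pass through so short lags stay usable
    return(list(out = x, cache = list(passthrough = TRUE, t_in = t_in)))
  }
  a <- x[seq(1L, 2L * t_out, 2L), , drop = FALSE]
  b <- x[seq(2L, 2L * t_out, 2L), , drop = FALSE]
  take_a <- a >= b
  win <- ifelse(take_a,
                matrix(seq(1L, 2L * t_out, 2L), t_out, ncol(x)),
                matrix(seq(2L, 2L * t_out, 2L), t_out, ncol(x)))
  list(out = pmax(a, b),
       cache = list(passthrough = FALSE, t_in = t_in, win = win))
}

gru_forward <- function(layer, x) {
  p <- layer$params
  act <- layer$config$activation
  t_len <- nrow(x)
  U <- layer$config$units
  h <- matrix(0, 1, U)
  H <- matrix(0, t_len, U)
  steps <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    xt <- x[t, , drop = FALSE]
    z <- sigmoid(xt %*% p$Wz + h %*% p$Uz +
                   matrix(p$bz, 1, U))
    r <- sigmoid(xt %*% p$Wr + h %*% p$Ur +
                   matrix(p$br, 1, U))
    rh <- r * h
    pre_h <- xt %*% p$Wh + rh %*% p$Uh + matrix(p$bh, 1, U)
    hh <- act_fwd(pre_h, act)
    h_new <- z * h + (1 - z) * hh
    steps[[t]] <- list(xt = xt, h_prev = h, z = z, r = r, rh = rh,
                       pre_h = pre_h, hh = hh)
    h <- h_new
    H[t, ] <- h
  }
  out <- if (layer$config$return_sequences) H else h
  list(out = out, cache = list(steps = steps, t_len = t_len))
}

lstm_forward <- function(layer, x) {
  p <- layer$params
  act <- layer$config$activation
  t_len <- nrow(x)
  U <- layer$config$units
  h <- matrix(0, 1, U)
  cc <- matrix(0, 1, U)
  H <- matrix(0, t_len, U)
  steps <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    xt <- x[t, , drop = FALSE]
    i <- sigmoid(xt %*% p$Wi + h %*% p$Ui + matrix(p$bi, 1, U))
    f <- sigmoid(xt %*% p$Wf + h %*% p$Uf + matrix(p$bf, 1, U))
    o <- sigmoid(xt %*% p$Wo + h %*% p$Uo + matrix(p$bo, 1, U))
    pre_g <- xt %*% p$Wg + h %*% p$Ug + matrix(p$bg, 1, U)
    g <- act_fwd(pre_g, act)
    c_new <- f * cc + i * g
    h_new <- o * act_fwd(c_new, act)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, i = i, f = f,
                       o = o, pre_g = pre_g, g = g, c_new = c_new)
    h <- h_new
    cc <- c_new
    H[t, ] <- h
  }
  out <- if (layer$config$return_sequences) H else h
  list(out = out, cache = list(steps = steps, t_len = t_len))
}

dropout_forward <- function(layer, x, training) {
  rate <- layer$config$rate
  if (!training || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- matrix((runif(length(x)) >= rate) / (1 - rate), nrow(x), ncol(x))
  list(out = x * mask, cache = mask)
}

dense_forward <- function(layer, x) {
  pre <- x %*% layer$params$W + matrix(layer$params$b, nrow(x),
                                       layer$config$units, byrow = TRUE)
  list(out = act_fwd(pre, layer$config$activation),
       cache = list(x = x, pre = pre))
}

# ---- backward -----------------------------------------------------------
# Each returns list(dx = gradient wrt the layer input,
#                   grads = named list matching layer$params).

nn_backward <- function(layer, dout, cache) {
  switch(layer$type,
         conv1d = conv1d_backward(layer, dout, cache),
         maxpool = maxpool_backward(layer, dout, cache),
         gru = gru_backward(layer, dout, cache),
         lstm = lstm_backward(layer, dout, cache),
         dropout = list(dx = if (is.null(cache)) dout else dout * cache,
                        grads = list()),
         flatten = list(dx = matrix(dout, cache[1], cache[2]), grads = list()),
         dense = dense_backward(layer, dout, cache))
}

conv1d_backward <- function(layer, dout, cache) {
  dpre <- dout * act_deriv(cache$pre, "relu")
  dW <- t(cache$Xcol) %*% dpre
  db <- colSums(dpre)
  dXcol <- dpre %*% t(layer$params$W)
  k <- layer$config$kernel
  t_out <- nrow(dpre)
  dx <- matrix(0, cache$t_in, 1)
  for (j in seq_len(k)) {
    idx <- j:(j + t_out - 1L)
    dx[idx, 1L] <- dx[idx, 1L] + dXcol[, j]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_backward <- function(layer, dout, cache) {
  if (cache$passthrough) {
    return(list(dx = dout, grads = list()))
  }
  n_col <- ncol(dout)
  t_out <- nrow(dout)
  dx <- matrix(0, cache$t_in, n_col)
  dx[cbind(as.vector(cache$win), rep(seq_len(n_col), each = t_out))] <-
    as.vector(dout)
  list(dx = dx, grads = list())
}

gru_backward <- function(layer, dout, cache) {
  p <- layer$params
  act <- layer$config$activation
  seq_out <- layer$config$return_sequences
  t_len <- cache$t_len
  g <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  dx <- matrix(0, t_len, nrow(p$Wz))
  dh_next <- matrix(0, 1, ncol(p$Wz))
  for (t in rev(seq_len(t_len))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (seq_out) {
      dh <- dh + dout[t, , drop = FALSE]
    } else if (t == t_len) {
      dh <- dh + dout
    }
    dz <- dh * (st$h_prev - st$hh)
    dhh <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    dpre_h <- dhh * act_deriv(st$pre_h, act)
    g$Wh <- g$Wh + t(st$xt) %*% dpre_h
    g$Uh <- g$Uh + t(st$rh) %*% dpre_h
    g$bh <- g$bh + as.vector(dpre_h)
    drh <- dpre_h %*% t(p$Uh)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    dpre_z <- dz * st$z * (1 - st$z)
    dpre_r <- dr * st$r * (1 - st$r)
    g$Wz <- g$Wz + t(st$xt) %*% dpre_z
    g$Uz <- g$Uz + t(st$h_prev) %*% dpre_z
    g$bz <- g$bz + as.vector(dpre_z)
    g$Wr <- g$Wr + t(st$xt) %*% dpre_r
    g$Ur <- g$Ur + t(st$h_prev) %*% dpre_r
    g$br <- g$br + as.vector(dpre_r)
    dx[t, ] <- dpre_z %*% t(p$Wz) + dpre_r %*% t(p$Wr) + dpre_h %*% t(p$Wh)
    dh_next <- dh_prev + dpre_z %*% t(p$Uz) + dpre_r %*% t(p$Ur)
  }
  list(dx = dx, grads = g)
}

lstm_backward <- function(layer, dout, cache) {
  p <- layer$params
  act <- layer$config$activation
  seq_out <- layer$config$return_sequences
  t_len <- cache$t_len
  g <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  dx <- matrix(0, t_len, nrow(p$Wi))
  dh_next <- matrix(0, 1, ncol(p$Wi))
  dc_next <- matrix(0, 1, ncol(p$Wi))
  for (t in rev(seq_len(t_len))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (seq_out) {
      dh <- dh + dout[t, , drop = FALSE]
    } else if (t == t_len) {
      dh <- dh + dout
    }
    do_ <- dh * act_fwd(st$c_new, act)
    dc <- dc_next + dh * st$o * act_deriv(st$c_new, act)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dpre_i <- di * st$i * (1 - st$i)
    dpre_f <- df * st$f * (1 - st$f)
    dpre_o <- do_ * st$o * (1 - st$o)
    dpre_g <- dg * act_deriv(st$pre_g, act)
    g$Wi <- g$Wi + t(st$xt) %*% dpre_i
    g$Ui <- g$Ui + t(st$h_prev) %*% dpre_i
    g$bi <- g$bi + as.vector(dpre_i)
    g$Wf <- g$Wf + t(st$xt) %*% dpre_f
    g$Uf <- g$Uf + t(st$h_prev) %*% dpre_f
    g$bf <- g$bf + as.vector(dpre_f)
    g$Wo <- g$Wo + t(st$xt) %*% dpre_o
    g$Uo <- g$Uo + t(st$h_prev) %*% dpre_o
    g$bo <- g$bo + as.vector(dpre_o)
    g$Wg <- g$Wg + t(st$xt) %*% dpre_g
    g$Ug <- g$Ug + t(st$h_prev) %*% dpre_g
    g$bg <- g$bg + as.vector(dpre_g)
    dx[t, ] <- dpre_i %*% t(p$Wi) + dpre_f %*% t(p$Wf) +
      dpre_o %*% t(p$Wo) + dpre_g %*% t(p$Wg)
    dh_next <- dpre_i %*% t(p$Ui) + dpre_f %*% t(p$Uf) +
      dpre_o %*% t(p$Uo) + dpre_g %*% t(p$Ug)
  }
  list(dx = dx, grads = g)
}

dense_backward <- function(layer, dout, cache) {
  dpre <- dout * act_deriv(cache$pre, layer$config$activation)
  list(dx = dpre %*% t(layer$params$W),
       grads = list(W = t(cache$x) %*% dpre, b = colSums(dpre)))
}
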