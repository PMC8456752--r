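# Minimal neural-network core
#
# The classifier is small and fixed: one convolutional layer whose
# filters each span one full grid row across all bands (on a scrambled
# grid a "row" is just a random sample of edges, so the convolution is a
# weight-sharing regularizer, not a spatial prior), batch normalization
# and ReLU, then three dense layers (batch norm, ReLU, dropout between
# them) and a two-way softmax, trained with Adam under categorical
# cross-entropy. Forward, backward, Adam, guided backpropagation and
# Grad-CAM are implemented here directly with base matrix algebra;
# gradients are verified against finite differences in the test suite.
#
# Data layout: a batch is a 3D array (n, rows, rowlen) with
# rowlen = grid_cols * n_bands (bands as contiguous column blocks). The
# convolution stacks it to (n*rows, rowlen) with the row index
# (s-1)*rows + r, applies a dense map to (n*rows, F), and the flatten
# back to (n, rows*F) keeps r fastest within s.

.bn_eps <- 1e-3
.bn_momentum <- 0.99

# stack (n, rows, rowlen) -> (n*rows, rowlen); inverse of .unstack_rows
.stack_rows <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3)), d[1] * d[2], d[3])
}

# (n*rows, F) -> (n, rows*F), r fastest within s and within each filter
.flatten_conv <- function(a, n, rows) {
  matrix(aperm(array(a, c(rows, n, ncol(a))), c(2, 1, 3)), n,
         rows * ncol(a))
}

# inverse of .flatten_conv
.unflatten_conv <- function(flat, n, rows) {
  nf <- ncol(flat) / rows
  matrix(aperm(array(flat, c(n, rows, nf)), c(2, 1, 3)), n * rows, nf)
}

# inverse of .stack_rows
.unstack_rows <- function(xs, n, rows) {
  aperm(array(xs, c(rows, n, ncol(xs))), c(2, 1, 3))
}

#' Configuration of one ensemble member
#'
#' Defaults follow the reference architecture: 256 row-spanning filters
#' (each convolving `grid_cols` x `n_bands` = 58 x 3 scrambled values),
#' three dense layers of 64 units with batch normalization, ReLU and 0.5
#' dropout, a two-way softmax head, Adam with categorical cross-entropy,
#' 100 epochs, and a 4:1:1 train/validation/test split.
#'
#' @param n_filters convolutional filters.
#' @param dense_units hidden units of the three dense layers.
#' @param dropout dropout rate in `[0, 1)` between dense layers.
#' @param epochs training epochs; the epoch with the highest validation
#'   accuracy is kept (ties broken by the earliest epoch).
#' @param batch_size minibatch size (unspecified upstream; default 64).
#' @param learning_rate Adam step size (framework-default 1e-3).
#' @param split train:validation:test proportions (default `c(4, 1, 1)`).
#' @param use_conv `FALSE` gives the fully-connected baseline: the same
#'   dense stack applied to the flattened grid with no convolution.
#' @param grid_rows,grid_cols scrambled grid shape (115 x 58 for the full
#'   6670-edge grid; 115 x 29 in half-edge occlusion mode).
#' @param n_bands wavelet bands stacked as channels.
#' @param seed member seed; weight init, split and batch order use
#'   substreams derived from it.
#' @return object of class `member_config`.
#' @export
member_config <- function(n_filters = 256L, dense_units = c(64L, 64L, 64L),
                          dropout = 0.5, epochs = 100L, batch_size = 64L,
                          learning_rate = 1e-3, split = c(4, 1, 1),
                          use_conv = TRUE,
                          grid_rows = 115L, grid_cols = 58L, n_bands = 3L,
                          seed = 1L) {
  if (!(dropout >= 0 && dropout < 1)) stop2("dropout must lie in [0, 1)")
  stopifnot(is_count(n_filters), n_filters >= 1, is_count(epochs),
            epochs >= 1, is_count(batch_size), batch_size >= 1,
            length(split) == 3L, all(split > 0))
  structure(list(n_filters = as.integer(n_filters),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, split = split,
                 use_conv = isTRUE(use_conv),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_bands = as.integer(n_bands), seed = as.integer(seed)),
            class = "member_config")
}

# He-initialised parameters + unit running statistics
nn_init <- function(cfg, seed = cfg$seed) {
  rowlen <- cfg$grid_cols * cfg$n_bands
  with_seed(substream_seed(seed, "init"), {
    p <- list()
    r <- list()
    if (cfg$use_conv) {
      p$conv_W <- matrix(stats::rnorm(rowlen * cfg$n_filters,
                                      sd = sqrt(2 / rowlen)),
                         rowlen, cfg$n_filters)
      p$conv_b <- numeric(cfg$n_filters)
      p$bn0_g <- rep(1, cfg$n_filters)
      p$bn0_b <- numeric(cfg$n_filters)
      r$mean0 <- numeric(cfg$n_filters)
      r$var0 <- rep(1, cfg$n_filters)
      d_in <- cfg$grid_rows * cfg$n_filters
    } else {
      d_in <- cfg$grid_rows * rowlen
    }
    for (i in seq_along(cfg$dense_units)) {
      u <- cfg$dense_units[i]
      p[[paste0("W", i)]] <- matrix(stats::rnorm(d_in * u, sd = sqrt(2 / d_in)),
                                    d_in, u)
      p[[paste0("b", i)]] <- numeric(u)
      p[[paste0("g", i)]] <- rep(1, u)
      p[[paste0("beta", i)]] <- numeric(u)
      r[[paste0("mean", i)]] <- numeric(u)
      r[[paste0("var", i)]] <- rep(1, u)
      d_in <- u
    }
    p$W_out <- matrix(stats::rnorm(d_in * 2, sd = sqrt(1 / d_in)), d_in, 2)
    p$b_out <- numeric(2)
    list(params = p, run = r)
  })
}

bn_forward_train <- function(x, g, b) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + .bn_eps)
  xh <- sweep(xc, 2, inv, "*")
  list(out = sweep(sweep(xh, 2, g, "*"), 2, b, "+"),
       xh = xh, inv = inv, mu = mu, v = v)
}

bn_forward_eval <- function(x, g, b, rmean, rvar) {
  xh <- sweep(sweep(x, 2, rmean), 2, 1 / sqrt(rvar + .bn_eps), "*")
  sweep(sweep(xh, 2, g, "*"), 2, b, "+")
}

bn_backward <- function(dout, cache, g) {
  xh <- cache$xh
  dg <- colSums(dout * xh)
  db <- colSums(dout)
  dxh <- sweep(dout, 2, g, "*")
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xh)
  # dx = inv * (dxh - mean(dxh) - xh * mean(dxh * xh))
  dx <- sweep(sweep(dxh, 2, m1) - sweep(xh, 2, m2, "*"), 2, cache$inv, "*")
  list(dx = dx, dg = dg, db = db)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# full training-mode forward pass; returns probabilities and every cache
# needed by nn_backward
nn_forward_train <- function(p, x, cfg, drop_masks) {
  n <- dim(x)[1]
  cache <- list(n = n)
  if (cfg$use_conv) {
    xs <- .stack_rows(x)
    z <- sweep(xs %*% p$conv_W, 2, p$conv_b, "+")
    bn <- bn_forward_train(z, p$bn0_g, p$bn0_b)
    a <- pmax(bn$out, 0)
    cache$xs <- xs; cache$bn0 <- bn; cache$relu0 <- bn$out > 0
    h <- .flatten_conv(a, n, cfg$grid_rows)
  } else {
    h <- matrix(x, n, dim(x)[2] * dim(x)[3])
  }
  cache$h0 <- h
  for (i in seq_along(cfg$dense_units)) {
    z <- sweep(h %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], "+")
    bn <- bn_forward_train(z, p[[paste0("g", i)]], p[[paste0("beta", i)]])
    a <- pmax(bn$out, 0)
    m <- drop_masks[[i]]
    h <- if (is.null(m)) a else a * m
    cache[[paste0("in", i)]] <- if (i == 1) cache$h0 else cache[[paste0("out", i - 1)]]
    cache[[paste0("bn", i)]] <- bn
    cache[[paste0("relu", i)]] <- bn$out > 0
    cache[[paste0("mask", i)]] <- m
    cache[[paste0("out", i)]] <- h
  }
  logits <- sweep(h %*% p$W_out, 2, p$b_out, "+")
  cache$h_last <- h
  list(probs = softmax(logits), cache = cache)
}

# gradient of mean categorical cross-entropy w.r.t. every parameter
nn_backward <- function(p, y_onehot, fwd, cfg) {
  cache <- fwd$cache
  n <- cache$n
  g <- list()
  dlog <- (fwd$probs - y_onehot) / n
  g$W_out <- crossprod(cache$h_last, dlog)
  g$b_out <- colSums(dlog)
  dh <- tcrossprod(dlog, p$W_out)
  for (i in rev(seq_along(cfg$dense_units))) {
    m <- cache[[paste0("mask", i)]]
    if (!is.null(m)) dh <- dh * m
    dh <- dh * cache[[paste0("relu", i)]]
    bb <- bn_backward(dh, cache[[paste0("bn", i)]], p[[paste0("g", i)]])
    g[[paste0("g", i)]] <- bb$dg
    g[[paste0("beta", i)]] <- bb$db
    hin <- cache[[paste0("in", i)]]
    g[[paste0("W", i)]] <- crossprod(hin, bb$dx)
    g[[paste0("b", i)]] <- colSums(bb$dx)
    dh <- tcrossprod(bb$dx, p[[paste0("W", i)]])
  }
  if (cfg$use_conv) {
    da <- .unflatten_conv(dh, n, cfg$grid_rows)
    da <- da * cache$relu0
    bb <- bn_backward(da, cache$bn0, p$bn0_g)
    g$bn0_g <- bb$dg
    g$bn0_b <- bb$db
    g$conv_W <- crossprod(cache$xs, bb$dx)
    g$conv_b <- colSums(bb$dx)
  }
  g
}

# inference forward pass (running statistics, no dropout); optionally
# keeps the caches needed for saliency
nn_forward_eval <- function(p, run, x, cfg, keep_cache = FALSE) {
  n <- dim(x)[1]
  cache <- list(n = n)
  if (cfg$use_conv) {
    xs <- .stack_rows(x)
    z <- sweep(xs %*% p$conv_W, 2, p$conv_b, "+")
    zb <- bn_forward_eval(z, p$bn0_g, p$bn0_b, run$mean0, run$var0)
    a <- pmax(zb, 0)
    if (keep_cache) { cache$pre0 <- zb; cache$act0 <- a }
    h <- .flatten_conv(a, n, cfg$grid_rows)
  } else {
    h <- matrix(x, n, dim(x)[2] * dim(x)[3])
  }
  if (keep_cache) cache$h0 <- h
  for (i in seq_along(cfg$dense_units)) {
    z <- sweep(h %*% p[[paste0("W", i)]], 2, p[[paste0("b", i)]], "+")
    zb <- bn_forward_eval(z, p[[paste0("g", i)]], p[[paste0("beta", i)]],
                          run[[paste0("mean", i)]], run[[paste0("var", i)]])
    h <- pmax(zb, 0)
    if (keep_cache) cache[[paste0("pre", i)]] <- zb
  }
  logits <- sweep(h %*% p$W_out, 2, p$b_out, "+")
  if (keep_cache) cache$h_last <- h
  list(probs = softmax(logits), logits = logits, cache = cache)
}

adam_init <- function(p) {
  list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0),
       t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  corr <- sqrt(1 - beta2^st$t) / (1 - beta1^st$t)
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * corr * st$m[[nm]] / (sqrt(st$v[[nm]]) + eps)
  }
  list(params = p, state = st)
}

# backward pass to the INPUT in inference mode, w.r.t. the target-class
# logit. guided = TRUE applies the guided-backprop rule at every ReLU
# (zero where the forward activation was negative OR the incoming
# gradient is negative); FALSE is the plain gradient. Also returns the
# conv feature maps and their (plain) gradient for Grad-CAM.
nn_input_gradient <- function(p, run, x, cfg, class_idx, guided = TRUE) {
  fwd <- nn_forward_eval(p, run, x, cfg, keep_cache = TRUE)
  n <- dim(x)[1]
  cache <- fwd$cache
  nd <- length(cfg$dense_units)
  relu_back <- function(grad, pre) {
    grad <- grad * (pre > 0)
    if (guided) grad <- grad * (grad > 0)
    grad
  }
  # d logit_c / d h_last = W_out[, c]
  dh <- matrix(p$W_out[, class_idx], n, nrow(p$W_out), byrow = TRUE)
  for (i in rev(seq_len(nd))) {
    dh <- relu_back(dh, cache[[paste0("pre", i)]])
    # through eval-mode batch norm: scale by g * inv_run
    scale_i <- p[[paste0("g", i)]] / sqrt(run[[paste0("var", i)]] + .bn_eps)
    dz <- sweep(dh, 2, scale_i, "*")
    dh <- tcrossprod(dz, p[[paste0("W", i)]])
  }
  if (!cfg$use_conv) {
    return(list(input_grad = array(dh, dim(x)), conv_act = NULL,
                conv_grad = NULL))
  }
  da <- .unflatten_conv(dh, n, cfg$grid_rows)      # grad at post-ReLU maps
  conv_grad_plain <- da * (cache$pre0 > 0)          # plain grad at pre-ReLU
  da <- relu_back(da, cache$pre0)
  scale0 <- p$bn0_g / sqrt(run$var0 + .bn_eps)
  dz <- sweep(da, 2, scale0, "*")
  dxs <- tcrossprod(dz, p$conv_W)
  list(input_grad = .unstack_rows(dxs, n, cfg$grid_rows),
       conv_act = cache$act0,       # (n*rows, F) post-ReLU feature maps
       conv_grad = conv_grad_plain) # same shape, plain gradient
}
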