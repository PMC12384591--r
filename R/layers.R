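# Internal sequential-network engine.
#
# A network is an ordered list of layer records. Activations flow through as
# col-major arrays (H, W, C, B) = (time, electrode, feature map, batch) until
# the flatten layer, after which they are (features, B) matrices. Residual
# skips are expressed with two layer types: `tap` records its input under a
# tag; `resadd` adds the tagged activation (through an optional 1x1 channel
# projection, executed as a 1x1 convolution) to its input. Dropout and batch
# norm switch behaviour on the `training` flag; at inference both are
# deterministic affine maps, so inference is batch-size invariant.

layer_conv <- function(name, kh, kw, cin, cout) {
  list(type = "conv", name = name, kh = kh, kw = kw, cin = cin, cout = cout,
       W = NULL, b = NULL)
}
layer_bn <- function(name, n_feat, kind = c("spatial", "dense")) {
  list(type = "bn", name = name, kind = match.arg(kind),
       gamma = rep(1, n_feat), beta = rep(0, n_feat),
       rmean = rep(0, n_feat), rvar = rep(1, n_feat),
       momentum = 0.9, eps = 1e-5)
}
layer_relu <- function(name) list(type = "relu", name = name)
layer_dropout <- function(name, keep, spatial = TRUE)
  list(type = "dropout", name = name, keep = keep, spatial = spatial)
layer_pool <- function(name, ph = 2L, pw = 1L)
  list(type = "pool", name = name, ph = ph, pw = pw)
layer_tap <- function(name, tag) list(type = "tap", name = name, tag = tag)
layer_resadd <- function(name, from, cin_skip, cout)
  list(type = "resadd", name = name, from = from,
       cin_skip = cin_skip, cout = cout, P = NULL)
layer_flatten <- function(name) list(type = "flatten", name = name)
layer_gap <- function(name) list(type = "gap", name = name)
layer_dense <- function(name, nin, nout)
  list(type = "dense", name = name, nin = nin, nout = nout, W = NULL, b = NULL)

# fan-in-scaled (He) initialization
init_layer_params <- function(l) {
  if (l$type == "conv") {
    fan_in <- l$kh * l$kw * l$cin
    l$W <- matrix(stats::rnorm(fan_in * l$cout, sd = sqrt(2 / fan_in)), fan_in, l$cout)
    l$b <- rep(0, l$cout)
  } else if (l$type == "dense") {
    l$W <- matrix(stats::rnorm(l$nin * l$nout, sd = sqrt(2 / l$nin)), l$nin, l$nout)
    l$b <- rep(0, l$nout)
  } else if (l$type == "resadd" && l$cin_skip != l$cout) {
    # 1x1 projection on the skip path, stored in conv-kernel layout
    l$P <- matrix(stats::rnorm(l$cin_skip * l$cout, sd = sqrt(2 / l$cin_skip)),
                  l$cin_skip, l$cout)
  }
  l
}

# ---- per-layer forward -------------------------------------------------------

# x: array (H,W,C,B) or matrix (F,B). Returns list(y, cache).
layer_fwd <- function(l, x, training, taps) {
  switch(l$type,
    conv = list(y = conv2d_fwd_cpp(x, l$W, l$b, l$kh, l$kw), cache = list(x = x)),
    bn = bn_fwd(l, x, training),
    relu = {
      y <- relu_fwd_cpp(x)
      attributes(y) <- attributes(x)
      list(y = y, cache = list(y = y))
    },
    dropout = {
      if (!training || l$keep >= 1) return(list(y = x, cache = NULL))
      if (is.matrix(x) || !isTRUE(l$spatial)) {
        m <- (stats::runif(length(x)) < l$keep) / l$keep
        y <- x * m
        attributes(y) <- attributes(x)
        list(y = y, cache = list(m = m))
      } else {
        # structured noise: drop entire feature maps per sample
        d <- dim(x)
        m <- (stats::runif(d[3] * d[4]) < l$keep) / l$keep
        y <- col_affine_cpp(x, d[1] * d[2], m, 0)
        dim(y) <- d
        list(y = y, cache = list(m = m))
      }
    },
    pool = {
      r <- maxpool_fwd_cpp(x, l$ph, l$pw)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
    },
    tap = list(y = x, cache = NULL),
    resadd = {
      s <- taps[[l$from]]
      if (is.null(l$P)) {
        list(y = x + s, cache = list(s = NULL))
      } else {
        proj <- conv2d_fwd_cpp(s, l$P, rep(0, l$cout), 1L, 1L)
        list(y = x + proj, cache = list(s = s))
      }
    },
    flatten = {
      d <- dim(x)
      dim(x) <- c(prod(d[1:3]), d[4])
      list(y = x, cache = list(xdim = d))
    },
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
      list(y = y, cache = list(xdim = d))
    },
    dense = list(y = crossprod(l$W, x) + l$b, cache = list(x = x)),
    stop("unknown layer type ", l$type))
}

bn_fwd <- function(l, x, training) {
  if (!is.matrix(x)) {
    d <- dim(x)
    hw <- d[1] * d[2]
    cidx <- rep(seq_len(d[3]), d[4])
    if (training) {
      colm <- colMeans(matrix(x, hw, d[3] * d[4]))
      colsq <- col_dot_cpp(x, x, hw) / hw
      mu <- as.vector(tapply(colm, cidx, mean))
      v <- pmax(as.vector(tapply(colsq, cidx, mean)) - mu^2, 0)
    } else {
      mu <- l$rmean; v <- l$rvar
    }
    inv <- 1 / sqrt(v + l$eps)
    xhat <- col_affine_cpp(x, hw, inv[cidx], (-mu * inv)[cidx])
    y <- col_affine_cpp(xhat, hw, l$gamma[cidx], l$beta[cidx])
    dim(xhat) <- d; dim(y) <- d
    cache <- if (training) list(xhat = xhat, inv = inv, cidx = cidx, d = d,
                                mu = mu, v = v) else NULL
    list(y = y, cache = cache)
  } else {
    if (training) {
      mu <- rowMeans(x)
      cent <- x - mu
      v <- rowMeans(cent^2)
    } else {
      mu <- l$rmean; v <- l$rvar
      cent <- x - mu
    }
    inv <- 1 / sqrt(v + l$eps)
    xhat <- cent * inv
    y <- xhat * l$gamma + l$beta
    cache <- if (training) list(xhat = xhat, inv = inv, mu = mu, v = v) else NULL
    list(y = y, cache = cache)
  }
}

# running-statistics update (training only); returns the updated layer
bn_update_running <- function(l, cache) {
  l$rmean <- l$momentum * l$rmean + (1 - l$momentum) * cache$mu
  l$rvar  <- l$momentum * l$rvar  + (1 - l$momentum) * cache$v
  l
}

# ---- per-layer backward ------------------------------------------------------

# Returns list(gx, pgrads = named list of parameter gradients, gskip for resadd)
layer_bwd <- function(l, cache, g) {
  switch(l$type,
    conv = {
      r <- conv2d_bwd_cpp(cache$x, l$W, g, l$kh, l$kw)
      list(gx = r$gx, pgrads = list(W = r$gW, b = as.vector(r$gb)))
    },
    bn = bn_bwd(l, cache, g),
    relu = {
      gx <- relu_bwd_cpp(cache$y, g)
      attributes(gx) <- attributes(g)
      list(gx = gx, pgrads = NULL)
    },
    dropout = {
      if (is.null(cache)) return(list(gx = g, pgrads = NULL))
      if (is.matrix(g) || !isTRUE(l$spatial)) {
        gx <- g * cache$m
        attributes(gx) <- attributes(g)
        list(gx = gx, pgrads = NULL)
      } else {
        d <- dim(g)
        gx <- col_affine_cpp(g, d[1] * d[2], cache$m, 0)
        dim(gx) <- d
        list(gx = gx, pgrads = NULL)
      }
    },
    pool = list(gx = maxpool_bwd_cpp(cache$idx, g, cache$xdim), pgrads = NULL),
    tap = list(gx = g, pgrads = NULL),
    resadd = {
      if (is.null(l$P)) {
        list(gx = g, pgrads = NULL, gskip = g)
      } else {
        r <- conv2d_bwd_cpp(cache$s, l$P, g, 1L, 1L)
        list(gx = g, pgrads = list(P = r$gW), gskip = r$gx)
      }
    },
    flatten = {
      dim(g) <- cache$xdim
      list(gx = g, pgrads = NULL)
    },
    gap = {
      d <- cache$xdim
      hw <- d[1] * d[2]
      gx <- col_affine_cpp(array(1, dim = d), hw, as.vector(g) / hw, 0)
      dim(gx) <- d
      list(gx = gx, pgrads = NULL)
    },
    dense = list(gx = l$W %*% g,
                 pgrads = list(W = tcrossprod(cache$x, g), b = rowSums(g))),
    stop("unknown layer type ", l$type))
}

bn_bwd <- function(l, cache, g) {
  if (is.null(cache)) {
    # inference mode: a fixed per-feature affine map y = gamma * inv * x + c
    scale <- l$gamma / sqrt(l$rvar + l$eps)
    if (is.matrix(g)) return(list(gx = g * scale, pgrads = NULL))
    d <- dim(g)
    gx <- col_affine_cpp(g, d[1] * d[2], scale[rep(seq_len(d[3]), d[4])], 0)
    dim(gx) <- d
    return(list(gx = gx, pgrads = NULL))
  }
  if (!is.null(cache$d)) {
    d <- cache$d
    hw <- d[1] * d[2]
    cidx <- cache$cidx
    n_per <- hw * d[4]
    dgamma <- as.vector(tapply(col_dot_cpp(g, cache$xhat, hw), cidx, sum))
    dbeta  <- as.vector(tapply(colSums(matrix(g, hw, d[3] * d[4])), cidx, sum))
    # gx = inv * (gxhat - mean(gxhat) - xhat * mean(gxhat * xhat)), per map
    sum_g  <- l$gamma * dbeta
    sum_gx <- l$gamma * dgamma
    ax <- (l$gamma * cache$inv)[cidx]
    ay <- (-cache$inv * sum_gx / n_per)[cidx]
    ad <- (-cache$inv * sum_g / n_per)[cidx]
    gx <- col_affine2_cpp(g, cache$xhat, hw, ax, ay, ad)
    dim(gx) <- d
    list(gx = gx, pgrads = list(gamma = dgamma, beta = dbeta))
  } else {
    dgamma <- rowSums(g * cache$xhat)
    dbeta <- rowSums(g)
    gxhat <- g * l$gamma
    gx <- (gxhat - rowMeans(gxhat) - cache$xhat * rowMeans(gxhat * cache$xhat)) *
      cache$inv
    list(gx = gx, pgrads = list(gamma = dgamma, beta = dbeta))
  }
}

# ---- network-level passes ----------------------------------------------------

# Forward through `layers`; stop_after (layer index) truncates the pass;
# record_at stores that layer's output in the result.
net_forward <- function(layers, x, training = FALSE, stop_after = NULL,
                        start_at = 1L, record_at = NULL) {
  taps <- list()
  recorded <- NULL
  caches <- vector("list", length(layers))
  for (li in start_at:length(layers)) {
    l <- layers[[li]]
    r <- layer_fwd(l, x, training, taps)
    x <- r$y
    caches[[li]] <- r$cache
    if (l$type == "tap") taps[[l$tag]] <- x
    if (!is.null(record_at) && li == record_at) recorded <- x
    if (!is.null(stop_after) && li == stop_after) break
  }
  list(out = x, caches = caches, taps = taps, recorded = recorded)
}

# Backward from gradient `g` at the output of the last layer. If `wrt` is
# set, returns the gradient at the OUTPUT of layer `wrt` and stops there;
# otherwise accumulates parameter gradients for every layer down to the
# input. Residual skip gradients are routed through the tap accumulator.
net_backward <- function(layers, caches, g, wrt = NULL) {
  tap_grads <- list()
  pgrads <- vector("list", length(layers))
  for (li in length(layers):1L) {
    if (!is.null(wrt) && li == wrt) {
      return(list(g_at = g, pgrads = pgrads))
    }
    l <- layers[[li]]
    if (l$type == "tap") {
      tg <- tap_grads[[l$tag]]
      if (!is.null(tg)) g <- g + tg
      next
    }
    r <- layer_bwd(l, caches[[li]], g)
    if (!is.null(r$pgrads)) pgrads[[li]] <- r$pgrads  # NULL would delete the slot
    if (l$type == "resadd") {
      prev <- tap_grads[[l$from]]
      tap_grads[[l$from]] <- if (is.null(prev)) r$gskip else prev + r$gskip
    }
    g <- r$gx
  }
  list(g_input = g, pgrads = pgrads)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}
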