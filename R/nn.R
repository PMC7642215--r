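# Minimal sequential conv-net engine backing the patch classifiers and the
# translation networks. Tensors are numeric arrays with dim (H, W, C, N).
# Layers are plain lists; forward/backward are explicit so the whole stack is
# deterministic and gradient-checkable.

layer_conv <- function(cin, cout, k, s = 1L, p = 0L, init_sd = 0.02) {
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       s = as.integer(s), p = as.integer(p),
       w = matrix(stats::rnorm(k * k * cin * cout, 0, init_sd), k * k * cin, cout),
       b = numeric(cout))
}

layer_convt <- function(cin, cout, k, s = 2L, p = 1L, op = 1L, init_sd = 0.02) {
  list(type = "convt", cin = cin, cout = cout, k = as.integer(k),
       s = as.integer(s), p = as.integer(p), op = as.integer(op),
       w = matrix(stats::rnorm(k * k * cout * cin, 0, init_sd), k * k * cout, cin),
       b = numeric(cout))
}

layer_inorm <- function(channels, eps = 1e-5) {
  list(type = "inorm", channels = channels, eps = eps)
}

layer_relu <- function() list(type = "relu")
layer_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
layer_tanh <- function() list(type = "tanh")
layer_gap <- function() list(type = "gap")

layer_linear <- function(cin, cout, init_sd = sqrt(2 / cin)) {
  list(type = "linear", cin = cin, cout = cout,
       w = matrix(stats::rnorm(cin * cout, 0, init_sd), cin, cout),
       b = numeric(cout))
}

new_net <- function(layers) structure(list(layers = layers), class = "sc_net")

# Forward pass. Returns list(out, cache); cache[[i]] holds what layer i's
# backward needs (NULL when cache = FALSE for inference-only calls).
net_forward <- function(net, x, cache = TRUE) {
  caches <- if (cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      if (cache) caches[[i]] <- x
      x <- nn_conv2d_forward(x, l$w, l$b, l$k, l$s, l$p)
    } else if (l$type == "convt") {
      if (cache) caches[[i]] <- x
      x <- nn_convt2d_forward(x, l$w, l$b, l$k, l$s, l$p, l$op)
    } else if (l$type == "inorm") {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2])
      mu <- colMeans(m)
      v <- colMeans(m * m) - mu * mu
      inv_sd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(m, 2, mu, "-"), 2, inv_sd, "*")
      if (cache) caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd, d = d)
      x <- array(xhat, d)
    } else if (l$type == "relu") {
      mask <- x > 0
      if (cache) caches[[i]] <- mask
      x <- x * mask
    } else if (l$type == "lrelu") {
      mask <- x > 0
      if (cache) caches[[i]] <- mask
      x <- ifelse(mask, x, l$alpha * x)
      dim(x) <- dim(mask)
    } else if (l$type == "tanh") {
      x <- tanh(x)
      if (cache) caches[[i]] <- x
    } else if (l$type == "gap") {
      d <- dim(x)
      if (cache) caches[[i]] <- d
      x <- t(matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4]))  # N x C
    } else if (l$type == "linear") {
      if (cache) caches[[i]] <- x
      x <- sweep(x %*% l$w, 2, l$b, "+")
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, cache = caches)
}

# Backward pass from dout (gradient w.r.t. net output). Returns per-layer
# parameter gradients and the gradient w.r.t. the input.
net_backward <- function(net, cache, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      g <- nn_conv2d_backward(cache[[i]], l$w, dx, l$k, l$s, l$p)
      grads[[i]] <- list(w = g$dw, b = as.vector(g$db))
      dx <- g$dx
    } else if (l$type == "convt") {
      g <- nn_convt2d_backward(cache[[i]], l$w, dx, l$k, l$s, l$p, l$op)
      grads[[i]] <- list(w = g$dw, b = as.vector(g$db))
      dx <- g$dx
    } else if (l$type == "inorm") {
      cc <- cache[[i]]
      g <- matrix(dx, cc$d[1] * cc$d[2])
      gm <- colMeans(g)
      gx <- colMeans(g * cc$xhat)
      m <- sweep(sweep(g, 2, gm, "-") - sweep(cc$xhat, 2, gx, "*"),
                 2, cc$inv_sd, "*")
      dx <- array(m, cc$d)
    } else if (l$type == "relu") {
      dx <- dx * cache[[i]]
    } else if (l$type == "lrelu") {
      mask <- cache[[i]]
      dx <- ifelse(mask, dx, l$alpha * dx)
      dim(dx) <- dim(mask)
    } else if (l$type == "tanh") {
      y <- cache[[i]]
      dx <- dx * (1 - y * y)
    } else if (l$type == "gap") {
      d <- cache[[i]]
      per_px <- t(dx) / (d[1] * d[2])                 # C x N
      dx <- array(rep(as.vector(per_px), each = d[1] * d[2]), d)
    } else if (l$type == "linear") {
      x_in <- cache[[i]]
      grads[[i]] <- list(w = crossprod(x_in, dx), b = colSums(dx))
      dx <- dx %*% t(l$w)
    }
  }
  list(grads = grads, dx = dx)
}

net_predict <- function(net, x) net_forward(net, x, cache = FALSE)$out

has_params <- function(l) l$type %in% c("conv", "convt", "linear")

n_params <- function(net) {
  sum(vapply(net$layers, function(l)
    if (has_params(l)) length(l$w) + length(l$b) else 0L, numeric(1)))
}

# Adam optimiser over the parameterised layers of one or more networks.
adam_init <- function(net) {
  st <- lapply(net$layers, function(l) {
    if (!has_params(l)) return(NULL)
    list(mw = l$w * 0, vw = l$w * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(layers = st, t = 0L)
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    s <- state$layers[[i]]
    s$mw <- beta1 * s$mw + (1 - beta1) * grads[[i]]$w
    s$vw <- beta2 * s$vw + (1 - beta2) * grads[[i]]$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$b
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$b^2
    net$layers[[i]]$w <- net$layers[[i]]$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$layers[[i]] <- s
  }
  list(net = net, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    a[[i]]$w <- a[[i]]$w + b[[i]]$w
    a[[i]]$b <- a[[i]]$b + b[[i]]$b
  }
  a
}

scale_grads <- function(g, f) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    g[[i]]$w <- g[[i]]$w * f
    g[[i]]$b <- g[[i]]$b * f
  }
  g
}

# Softmax cross-entropy on logits (N x K); labels are 1-based class indices.
softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(logits, labels) {
  p <- softmax(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
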