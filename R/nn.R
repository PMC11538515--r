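# Minimal dense-network engine used by the generators and discriminators.
# Rows are samples, columns are features. All stochastic elements (init,
# dropout masks) draw from the current RNG stream so one master seed fixes
# the whole training run.

mlp_init <- function(sizes, alpha = 0.2, out_act = c("sigmoid", "identity"),
                     dropout = NULL) {
  out_act <- match.arg(out_act)
  L <- length(sizes) - 1L
  stopifnot(L >= 1L)
  n_hidden <- L - 1L
  if (is.null(dropout)) dropout <- rep(0, max(n_hidden, 0L))
  stopifnot(length(dropout) == n_hidden, all(dropout >= 0 & dropout < 1))
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- if (l < L) sqrt(2 / (fan_in * (1 + alpha^2))) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sd),
                     fan_in, sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(sizes = sizes, W = W, b = b, alpha = alpha, out_act = out_act,
       dropout = dropout)
}

lrelu <- function(z, alpha) ifelse(z > 0, z, alpha * z)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. train = TRUE samples inverted-dropout masks from the RNG.
mlp_forward <- function(net, X, train = FALSE) {
  L <- length(net$W)
  a <- X
  acts <- vector("list", L)   # post-activation (post-dropout) inputs to layer l+1
  zs <- vector("list", L)
  masks <- vector("list", L)
  inputs <- vector("list", L)
  for (l in seq_len(L)) {
    inputs[[l]] <- a
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], `+`)
    zs[[l]] <- z
    if (l < L) {
      a <- lrelu(z, net$alpha)
      p <- net$dropout[l]
      if (!is.na(p) && p > 0 && train) {
        m <- matrix(stats::runif(length(a)) >= p, nrow(a), ncol(a)) / (1 - p)
        a <- a * m
        masks[[l]] <- m
      }
    } else {
      a <- switch(net$out_act, sigmoid = sigmoid(z), identity = z)
    }
    acts[[l]] <- a
  }
  list(out = a, logits = zs[[L]],
       cache = list(inputs = inputs, zs = zs, masks = masks))
}

# Backward pass. d_top is the gradient of the loss w.r.t. the output-layer
# pre-activation (logits) when from_logits = TRUE, otherwise w.r.t. the
# network output. Returns weight/bias gradients and the gradient w.r.t. X
# (needed to chain through composed networks).
mlp_backward <- function(net, fwd, d_top, from_logits = TRUE) {
  L <- length(net$W)
  cache <- fwd$cache
  if (from_logits) {
    dz <- d_top
  } else {
    dz <- switch(net$out_act,
                 sigmoid = d_top * fwd$out * (1 - fwd$out),
                 identity = d_top)
  }
  dW <- vector("list", L)
  db <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$inputs[[l]], dz)
    db[[l]] <- colSums(dz)
    da <- tcrossprod(dz, net$W[[l]])
    if (l > 1L) {
      lm1 <- l - 1L
      if (!is.null(cache$masks[[lm1]])) da <- da * cache$masks[[lm1]]
      zprev <- cache$zs[[lm1]]
      dz <- da * ifelse(zprev > 0, 1, net$alpha)
    } else {
      dz <- NULL
      dX <- da
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# Numerically stable binary cross-entropy from logits, with the matching
# logit gradient (mean over all elements).
bce_from_logits <- function(logits, target) {
  loss <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  grad <- (sigmoid(logits) - target) / length(logits)
  list(loss = loss, grad = grad)
}

opt_init <- function(net, kind = c("adam", "sgd"), lr = 1e-4,
                     beta1 = 0.5, beta2 = 0.999, eps = 1e-8, momentum = 0.9) {
  kind <- match.arg(kind)
  zeros <- function(x) lapply(x, function(m) array(0, dim = dim(m) %||% length(m)))
  st <- list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
             momentum = momentum, t = 0L,
             mW = zeros(net$W), mb = zeros(net$b))
  if (kind == "adam") {
    st$vW <- zeros(net$W)
    st$vb <- zeros(net$b)
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opt_step <- function(net, grads, st) {
  L <- length(net$W)
  if (st$kind == "adam") {
    st$t <- st$t + 1L
    bc1 <- 1 - st$beta1^st$t
    bc2 <- 1 - st$beta2^st$t
    for (l in seq_len(L)) {
      st$mW[[l]] <- st$beta1 * st$mW[[l]] + (1 - st$beta1) * grads$dW[[l]]
      st$vW[[l]] <- st$beta2 * st$vW[[l]] + (1 - st$beta2) * grads$dW[[l]]^2
      net$W[[l]] <- net$W[[l]] -
        st$lr * (st$mW[[l]] / bc1) / (sqrt(st$vW[[l]] / bc2) + st$eps)
      st$mb[[l]] <- st$beta1 * st$mb[[l]] + (1 - st$beta1) * grads$db[[l]]
      st$vb[[l]] <- st$beta2 * st$vb[[l]] + (1 - st$beta2) * grads$db[[l]]^2
      net$b[[l]] <- net$b[[l]] -
        st$lr * (st$mb[[l]] / bc1) / (sqrt(st$vb[[l]] / bc2) + st$eps)
    }
  } else {
    for (l in seq_len(L)) {
      st$mW[[l]] <- st$momentum * st$mW[[l]] - st$lr * grads$dW[[l]]
      net$W[[l]] <- net$W[[l]] + st$mW[[l]]
      st$mb[[l]] <- st$momentum * st$mb[[l]] - st$lr * grads$db[[l]]
      net$b[[l]] <- net$b[[l]] + st$mb[[l]]
    }
  }
  list(net = net, state = st)
}
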