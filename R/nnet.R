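# Multilayer perceptrons and Adam, on top of the autodiff engine. Internal.

# withr-style deferred cleanup in the caller's frame
defer <- function(expr, env = parent.frame()) {
  thunk <- as.call(list(function() expr))
  do.call(on.exit, list(thunk, add = TRUE), envir = env)
}

# Seed the RNG locally; the caller's previous RNG state is restored on exit.
local_seed <- function(seed, env = parent.frame()) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, env = env)
  invisible(NULL)
}

# He-uniform initialization for a dense layer
init_dense <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = matrix(0, 1L, n_out))
}

# params: list of layers, each list(W, b); widths includes output size
init_mlp <- function(n_in, widths) {
  sizes <- c(n_in, widths)
  lapply(seq_len(length(sizes) - 1L), function(i) init_dense(sizes[i], sizes[i + 1L]))
}

# Wrap plain parameter matrices as autodiff leaves (one step's graph).
wrap_params <- function(params) {
  rapply(params, ad_leaf, classes = "matrix", how = "replace")
}

# Forward through an MLP. x: ad node or matrix. ReLU on all but the last
# layer; optional inverted dropout on hidden activations during training.
mlp_forward <- function(x, layers, dropout_p = 0, train = FALSE) {
  h <- if (is_ad(x)) x else ad_const(x)
  n_layers <- length(layers)
  for (i in seq_len(n_layers)) {
    hidden <- i < n_layers
    mask <- if (hidden && train && dropout_p > 0) {
      matrix(stats::rbinom(nrow(h$value) * ncol(layers[[i]]$W$value), 1L,
                           1 - dropout_p), nrow(h$value)) / (1 - dropout_p)
    } else NULL
    h <- ad_dense(h, layers[[i]]$W, layers[[i]]$b, relu = hidden,
                  drop_mask = mask)
  }
  h
}

# Plain (no-graph) forward for inference; params are raw matrices.
mlp_infer <- function(x, params) {
  h <- as_mat(x)
  n_layers <- length(params)
  for (i in seq_len(n_layers)) {
    h <- sweep(h %*% params[[i]]$W, 2L, params[[i]]$b, "+")
    if (i < n_layers) h <- pmax(h, 0)
  }
  h
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- rapply(params, function(m) array(0, dim(m)), classes = "matrix",
                  how = "replace")
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros, v = zeros)
}

# params: nested list of matrices; grads: matching nested list (from leaves).
# Returns list(params, state).
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    if (is.matrix(p)) {
      if (is.null(g)) g <- array(0, dim(p))
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      p <- p - state$lr * (m / corr1) / (sqrt(v / corr2) + state$eps)
      list(p = p, m = m, v = v)
    } else {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  }
  out <- walk(params, grads, state$m, state$v)
  state$m <- out$m
  state$v <- out$v
  list(params = out$p, state = state)
}

# Extract gradients from a wrapped (leaf) parameter tree, preserving shape.
grads_of <- function(wrapped) {
  rapply2 <- function(x) {
    if (is_ad(x)) {
      if (is.null(x$grad)) array(0, dim(x$value)) else x$grad
    } else {
      lapply(x, rapply2)
    }
  }
  rapply2(wrapped)
}

# Polyak averaging of two matching parameter trees: rate * src + (1-rate) * dst
polyak <- function(dst, src, rate) {
  if (is.matrix(dst)) return((1 - rate) * dst + rate * src)
  Map(polyak, dst, src, MoreArgs = list(rate = rate))
}
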