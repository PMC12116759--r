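# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient, parent
# pointers and a backward closure. Graphs are built eagerly per training step
# and discarded; parameters enter as leaf nodes wrapped around plain matrices,
# so optimizers read gradients off the leaves after ad_backward(). All heavy
# work is base-R matrix arithmetic (BLAS); the engine only orchestrates.
#
# Internal: not exported. Gradients are verified against central finite
# differences in the test suite.

ad_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(value, parents = list(), backfn = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value)
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$leaf <- leaf
  e$id <- ad_counter()
  class(e) <- "ad_node"
  e
}

# Leaf with gradient tracking (a parameter).
ad_leaf <- function(value) ad_node(value, leaf = TRUE)

# Constant: participates in forward values only.
ad_const <- function(value) ad_node(value)

is_ad <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad(x)) x$value else as_mat(x)

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Reverse pass from a scalar loss node. Topological order via iterative DFS.
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  order <- vector("list", 64L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  loss$grad <- matrix(1, 1, 1)
  for (i in seq_len(n_ord)) {
    node <- order[[n_ord - i + 1L]]
    if (!is.null(node$backfn) && !is.null(node$grad)) {
      gs <- node$backfn(node$grad)
      for (j in seq_along(node$parents)) {
        if (!is.null(gs[[j]])) accumulate_grad(node$parents[[j]], gs[[j]])
      }
    }
  }
  invisible(loss)
}

# ---- primitives ------------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(av %*% bv, parents = list(a, b), backfn = function(g) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

# a + b where b is same-shape, a 1-row bias (broadcast over rows), or 1x1.
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  if (identical(dim(av), dim(bv))) {
    ad_node(av + bv, parents = list(a, b), backfn = function(g) list(g, g))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    ad_node(sweep(av, 2L, bv, "+"), parents = list(a, b), backfn = function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else if (length(bv) == 1L) {
    ad_node(av + bv[1L], parents = list(a, b), backfn = function(g) {
      list(g, matrix(sum(g), 1L, 1L))
    })
  } else {
    stop("ad_add: incompatible shapes")
  }
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

# elementwise product; shapes must match, or b 1x1
ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  if (length(bv) == 1L) {
    ad_node(av * bv[1L], parents = list(a, b), backfn = function(g) {
      list(g * bv[1L], matrix(sum(g * av), 1L, 1L))
    })
  } else {
    stopifnot(identical(dim(av), dim(bv)))
    ad_node(av * bv, parents = list(a, b), backfn = function(g) {
      list(g * bv, g * av)
    })
  }
}

# multiply by a constant scalar
ad_scale <- function(a, k) {
  av <- ad_value(a)
  ad_node(av * k, parents = list(a), backfn = function(g) list(g * k))
}

# multiply by a constant matrix (same shape), e.g. dropout masks, tau weights
ad_mulc <- function(a, m) {
  av <- ad_value(a)
  stopifnot(identical(dim(av), dim(m)) || length(m) == 1L)
  ad_node(av * m, parents = list(a), backfn = function(g) list(g * m))
}

# add a constant (scalar or same-shape matrix)
ad_addc <- function(a, cst) {
  av <- ad_value(a)
  ad_node(av + cst, parents = list(a), backfn = function(g) list(g))
}

# Fused dense layer: x %*% W + b, optional ReLU and dropout mask, one node.
ad_dense <- function(x, W, b, relu = FALSE, drop_mask = NULL) {
  xv <- ad_value(x); Wv <- ad_value(W); bv <- ad_value(b)
  pre <- sweep(xv %*% Wv, 2L, bv, "+")
  if (relu) {
    mask <- pre > 0
    out <- pre * mask
  } else {
    mask <- NULL
    out <- pre
  }
  if (!is.null(drop_mask)) out <- out * drop_mask
  ad_node(out, parents = list(x, W, b), backfn = function(g) {
    if (!is.null(drop_mask)) g <- g * drop_mask
    if (relu) g <- g * mask
    list(tcrossprod(g, Wv), crossprod(xv, g), matrix(colSums(g), 1L))
  })
}

ad_relu <- function(a) {
  av <- ad_value(a)
  mask <- av > 0
  ad_node(av * mask, parents = list(a), backfn = function(g) list(g * mask))
}

ad_tanh <- function(a) {
  v <- tanh(ad_value(a))
  ad_node(v, parents = list(a), backfn = function(g) list(g * (1 - v^2)))
}

ad_exp <- function(a) {
  v <- exp(ad_value(a))
  ad_node(v, parents = list(a), backfn = function(g) list(g * v))
}

ad_log <- function(a) {
  av <- ad_value(a)
  ad_node(log(av), parents = list(a), backfn = function(g) list(g / av))
}

ad_square <- function(a) {
  av <- ad_value(a)
  ad_node(av^2, parents = list(a), backfn = function(g) list(2 * g * av))
}

ad_mean <- function(a) {
  av <- ad_value(a)
  n <- length(av)
  ad_node(matrix(mean(av), 1L, 1L), parents = list(a), backfn = function(g) {
    list(matrix(g[1L] / n, nrow(av), ncol(av)))
  })
}

ad_sum <- function(a) {
  av <- ad_value(a)
  ad_node(matrix(sum(av), 1L, 1L), parents = list(a), backfn = function(g) {
    list(matrix(g[1L], nrow(av), ncol(av)))
  })
}

# row means -> n x 1 column
ad_row_means <- function(a) {
  av <- ad_value(a)
  k <- ncol(av)
  ad_node(matrix(rowMeans(av), ncol = 1L), parents = list(a), backfn = function(g) {
    list(matrix(g, nrow(av), k) / k)
  })
}

# logsumexp over each row -> n x 1 column; grad is row-softmax
ad_logsumexp_rows <- function(a) {
  av <- ad_value(a)
  m <- apply(av, 1L, max)
  lse <- m + log(rowSums(exp(av - m)))
  sm <- exp(av - lse)
  ad_node(matrix(lse, ncol = 1L), parents = list(a), backfn = function(g) {
    list(sm * matrix(g, nrow(av), ncol(av)))
  })
}

ad_cbind <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(nrow(av) == nrow(bv))
  ka <- ncol(av)
  ad_node(cbind(av, bv), parents = list(a, b), backfn = function(g) {
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE])
  })
}

# Huber of the residual node u, elementwise: 0.5 u^2 if |u|<=kappa else
# kappa (|u| - kappa/2). d/du = u or kappa*sign(u).
ad_huber <- function(u, kappa = 1) {
  uv <- ad_value(u)
  small <- abs(uv) <= kappa
  v <- 0.5 * uv^2 * small + kappa * (abs(uv) - 0.5 * kappa) * !small
  dv <- uv * small + kappa * sign(uv) * !small
  ad_node(v, parents = list(u), backfn = function(g) list(g * dv))
}

# Select (possibly repeating) columns by index; gradient accumulates back.
ad_cols <- function(a, idx) {
  av <- ad_value(a)
  ad_node(av[, idx, drop = FALSE], parents = list(a), backfn = function(g) {
    gr <- matrix(0, nrow(av), ncol(av))
    for (j in seq_along(idx)) gr[, idx[j]] <- gr[, idx[j]] + g[, j]
    list(gr)
  })
}

# Reshape an (n*k) x 1 column (rows tiled k per sample) into an n x k matrix.
ad_col_to_mat <- function(a, n, k) {
  av <- ad_value(a)
  stopifnot(ncol(av) == 1L, nrow(av) == n * k)
  ad_node(matrix(av, n, k, byrow = TRUE), parents = list(a), backfn = function(g) {
    list(matrix(t(g), n * k, 1L))
  })
}

# Repeat rows of a node k times each (for quantile tiling). Constant pattern.
ad_repeat_rows <- function(a, k) {
  av <- ad_value(a)
  idx <- rep(seq_len(nrow(av)), each = k)
  ad_node(av[idx, , drop = FALSE], parents = list(a), backfn = function(g) {
    # sum gradient over each block of k tiled rows
    list(rowsum(g, group = idx, reorder = FALSE))
  })
}
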