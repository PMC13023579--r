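# Reverse-mode automatic differentiation on a linear tape.
#
# Every network component in the package (graph convolution, graph attention,
# the convolutional time-domain branch, cross-attention, the classifier head)
# is expressed as a composition of the primitive operations below. Each
# primitive records a backward closure; ad_backward() walks the tape in
# reverse creation order (a valid reverse topological order, since the graph
# is built forward) and accumulates gradients into the named parameters.
#
# Node handles are plain lists (id, value); values are numeric vectors,
# matrices or arrays. Gradients always carry the same dim() as the value.

#' Create a fresh autodiff tape
#'
#' @return An environment holding the tape state. Pass it as the first
#'   argument to every `ad_*` constructor.
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$recs <- vector("list", 512L)
  t$params <- list() # name -> node id
  t
}

.ad_push <- function(t, value, parents = integer(0), backward = NULL) {
  # force promises before claiming an id: nested op calls inside an argument
  # expression must finish registering their own nodes first
  force(value)
  force(parents)
  force(backward)
  t$n <- t$n + 1L
  if (t$n > length(t$recs)) {
    t$recs <- c(t$recs, vector("list", length(t$recs)))
  }
  t$recs[[t$n]] <- list(parents = parents, backward = backward)
  list(id = t$n, value = value)
}

#' Wrap a constant (no gradient tracked)
#' @param t tape
#' @param v numeric vector/matrix/array
#' @export
ad_const <- function(t, v) .ad_push(t, v)

#' Wrap a trainable parameter
#'
#' After [ad_backward()] the gradient is available under `name`.
#' @param t tape
#' @param v parameter value
#' @param name unique parameter name on this tape
#' @export
ad_param <- function(t, v, name) {
  node <- .ad_push(t, v)
  t$params[[name]] <- node$id
  node
}

#' Backpropagate from a scalar loss node
#'
#' @param t tape
#' @param loss node with a scalar value
#' @return named list of gradients, one per parameter registered with
#'   [ad_param()]; parameters the loss does not depend on get a zero gradient.
#' @export
ad_backward <- function(t, loss) {
  stopifnot(length(loss$value) == 1L)
  grads <- vector("list", t$n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    rec <- t$recs[[i]]
    if (is.null(rec$backward)) next
    pg <- rec$backward(g)
    ps <- rec$parents
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[[k]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  out <- vector("list", length(t$params))
  names(out) <- names(t$params)
  for (nm in names(t$params)) {
    id <- t$params[[nm]]
    g <- grads[[id]]
    if (is.null(g)) {
      v <- t$recs[[id]] # placeholder; value lives in handles, re-zero by dim
      g <- 0
    }
    out[[nm]] <- g
  }
  out
}

# ---- elementwise ----

#' @rdname ad_ops
#' @param a,b tape nodes
#' @export
ad_add <- function(t, a, b) {
  .ad_push(t, a$value + b$value, c(a$id, b$id), function(g) list(g, g))
}

#' @rdname ad_ops
#' @export
ad_sub <- function(t, a, b) {
  .ad_push(t, a$value - b$value, c(a$id, b$id), function(g) list(g, -g))
}

#' @rdname ad_ops
#' @param k plain numeric scalar
#' @export
ad_scale <- function(t, a, k) {
  .ad_push(t, a$value * k, a$id, function(g) list(g * k))
}

#' @rdname ad_ops
#' @export
ad_mul <- function(t, a, b) {
  av <- a$value
  bv <- b$value
  .ad_push(t, av * bv, c(a$id, b$id), function(g) list(g * bv, g * av))
}

#' @rdname ad_ops
#' @param p exponent (value assumed positive where p is fractional)
#' @export
ad_pow <- function(t, a, p) {
  av <- a$value
  .ad_push(t, av^p, a$id, function(g) list(g * p * av^(p - 1)))
}

#' @rdname ad_ops
#' @param m clamp threshold
#' @export
ad_clamp_min <- function(t, a, m) {
  av <- a$value
  .ad_push(t, pmax(av, m), a$id, function(g) {
    gi <- g * (av > m)
    dim(gi) <- dim(av)
    list(gi)
  })
}

#' @rdname ad_ops
#' @export
ad_relu <- function(t, a) {
  av <- a$value
  .ad_push(t, pmax(av, 0), a$id, function(g) {
    gi <- g * (av > 0)
    dim(gi) <- dim(av)
    list(gi)
  })
}

#' @rdname ad_ops
#' @param alpha negative-side slope
#' @export
ad_leaky_relu <- function(t, a, alpha = 0.01) {
  av <- a$value
  w <- alpha + (1 - alpha) * (av > 0)
  dim(w) <- dim(av)
  .ad_push(t, av * w, a$id, function(g) list(g * w))
}

#' Square activation with overflow clamp
#'
#' `f(x) = min(x^2, cap)`; the clamp keeps z-scored inputs from overflowing
#' through stacked square activations.
#' @rdname ad_ops
#' @param cap clamp ceiling
#' @export
ad_square <- function(t, a, cap = 1e4) {
  av <- a$value
  v <- av * av
  inside <- v < cap
  v2 <- pmin(v, cap)
  dim(v2) <- dim(av)
  .ad_push(t, v2, a$id, function(g) {
    gi <- g * 2 * av * inside
    dim(gi) <- dim(av)
    list(gi)
  })
}

#' Inverted dropout (scales kept units by 1/(1-p))
#' @rdname ad_ops
#' @param p drop probability; `training = FALSE` is the identity
#' @param training logical
#' @export
ad_dropout <- function(t, a, p, training = TRUE) {
  if (!training || p <= 0) {
    return(a)
  }
  av <- a$value
  mask <- (stats::runif(length(av)) >= p) / (1 - p)
  dim(mask) <- dim(av)
  .ad_push(t, av * mask, a$id, function(g) list(g * mask))
}

# ---- shape ----

#' @rdname ad_ops
#' @param dims new dimensions (same total length)
#' @export
ad_reshape <- function(t, a, dims) {
  od <- dim(a$value)
  if (is.null(od)) od <- length(a$value)
  v <- a$value
  dim(v) <- dims
  .ad_push(t, v, a$id, function(g) {
    dim(g) <- od
    list(g)
  })
}

#' @rdname ad_ops
#' @param perm dimension permutation
#' @export
ad_aperm <- function(t, a, perm) {
  if (all(perm == seq_along(perm))) {
    return(a)
  }
  inv <- order(perm)
  .ad_push(t, aperm(a$value, perm), a$id, function(g) list(aperm(g, inv)))
}

#' @rdname ad_ops
#' @export
ad_t <- function(t, a) {
  .ad_push(t, t(a$value), a$id, function(g) list(t(g)))
}

#' Row gather with implicit zero row
#'
#' `idx[k] == 0` selects a zero row, giving cheap zero padding for shifts.
#' @rdname ad_ops
#' @param idx integer vector of source rows (0 = zeros)
#' @export
ad_gather_rows <- function(t, a, idx) {
  av <- a$value
  nr <- nrow(av)
  nc <- ncol(av)
  sel <- idx > 0L
  out <- matrix(0, length(idx), nc)
  out[sel, ] <- av[idx[sel], , drop = FALSE]
  .ad_push(t, out, a$id, function(g) {
    gz <- matrix(0, nr, nc)
    if (any(sel)) {
      acc <- rowsum(g[sel, , drop = FALSE], group = idx[sel])
      gz[as.integer(rownames(acc)), ] <- acc
    }
    list(gz)
  })
}

#' Column-bind a list of nodes
#' @rdname ad_ops
#' @param nodes list of 2-D nodes with equal row counts
#' @export
ad_cbind <- function(t, nodes) {
  vals <- lapply(nodes, `[[`, "value")
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  .ad_push(t, do.call(cbind, vals), vapply(nodes, `[[`, 0L, "id"), function(g) {
    lapply(seq_along(widths), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# ---- linear algebra ----

#' @rdname ad_ops
#' @export
ad_mm <- function(t, a, b) {
  av <- a$value
  bv <- b$value
  .ad_push(t, av %*% bv, c(a$id, b$id), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

#' Blocked batched matrix multiply
#'
#' `a` is an (n*B) x k matrix whose rows are B contiguous n-row blocks (row
#' `i + (b-1) n` belongs to batch element `b`); `y` is (k, m, B). Returns
#' (n, m, B) with `out[,,b] = a_block_b %*% y[,,b]`. Avoids permuting large
#' attention matrices into 3-D layout.
#' @rdname ad_ops
#' @export
ad_bmm_blocked <- function(t, a, y) {
  av <- a$value
  yv <- y$value
  k <- ncol(av)
  m <- dim(yv)[2]
  B <- dim(yv)[3]
  n <- nrow(av) %/% B
  v <- array(0, c(n, m, B))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * n + 1L):(b * n)
    v[, , b] <- av[rows, , drop = FALSE] %*% matrix(yv[, , b], k, m)
  }
  .ad_push(t, v, c(a$id, y$id), function(g) {
    ga <- matrix(0, nrow(av), k)
    gy <- array(0, dim(yv))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * n + 1L):(b * n)
      gb <- matrix(g[, , b], n, m)
      ga[rows, ] <- gb %*% t(matrix(yv[, , b], k, m))
      gy[, , b] <- t(av[rows, , drop = FALSE]) %*% gb
    }
    list(ga, gy)
  })
}

#' Batched matrix multiply over the third dimension
#'
#' `a` is (n, k, B), `b` is (k, m, B); returns (n, m, B).
#' @rdname ad_ops
#' @export
ad_bmm <- function(t, a, b) {
  av <- a$value
  bv <- b$value
  B <- dim(av)[3]
  n <- dim(av)[1]
  k <- dim(av)[2]
  m <- dim(bv)[2]
  sl <- function(x, i, nr, nc) matrix(x[, , i], nr, nc) # keep degenerate dims
  v <- array(0, c(n, m, B))
  for (i in seq_len(B)) v[, , i] <- sl(av, i, n, k) %*% sl(bv, i, k, m)
  .ad_push(t, v, c(a$id, b$id), function(g) {
    ga <- array(0, dim(av))
    gb <- array(0, dim(bv))
    for (i in seq_len(B)) {
      gi <- matrix(g[, , i], n, m)
      ga[, , i] <- gi %*% t(sl(bv, i, k, m))
      gb[, , i] <- t(sl(av, i, n, k)) %*% gi
    }
    list(ga, gb)
  })
}

# ---- broadcasting ----

# expand a vector spanning dimension `dim_b` of an array with dims `d` into
# the full recycled pattern (head dims repeat each element, tail dims recycle)
.ad_expand_bias <- function(bv, d, dim_b) {
  head_n <- if (dim_b > 1L) prod(d[seq_len(dim_b - 1L)]) else 1L
  rep(bv, each = head_n)
}

# sum g over every dimension except `dim_keep`, without permuting
.ad_sum_except <- function(g, dim_keep) {
  d <- dim(g)
  if (is.null(d)) {
    return(sum(g))
  }
  head_n <- if (dim_keep > 1L) prod(d[seq_len(dim_keep - 1L)]) else 1L
  tail_n <- length(g) / (head_n * d[dim_keep])
  cs <- if (head_n > 1L) {
    colSums(matrix(g, head_n, d[dim_keep] * tail_n))
  } else {
    as.numeric(g)
  }
  if (tail_n > 1L) rowSums(matrix(cs, d[dim_keep], tail_n)) else cs
}

#' Broadcast-add a vector along one dimension of an array
#' @rdname ad_ops
#' @param dim_b dimension of `a` that `b` spans
#' @export
ad_add_bias <- function(t, a, b, dim_b) {
  av <- a$value
  d <- dim(av)
  v <- av + .ad_expand_bias(b$value, d, dim_b)
  dim(v) <- d
  .ad_push(t, v, c(a$id, b$id), function(g) {
    list(g, .ad_sum_except(g, dim_b))
  })
}

#' Broadcast-multiply a vector along one dimension of an array
#' @rdname ad_ops
#' @export
ad_mul_bias <- function(t, a, b, dim_b) {
  av <- a$value
  d <- dim(av)
  bb <- .ad_expand_bias(b$value, d, dim_b)
  v <- av * bb
  dim(v) <- d
  .ad_push(t, v, c(a$id, b$id), function(g) {
    gi <- g * bb
    dim(gi) <- d
    list(gi, .ad_sum_except(g * av, dim_b))
  })
}

#' Pairwise outer sum: out[i, j, b] = f1[i, b] + f2[j, b]
#'
#' Used for additive graph-attention logits.
#' @rdname ad_ops
#' @export
ad_outer_sum <- function(t, f1, f2) {
  v1 <- f1$value
  v2 <- f2$value
  n1 <- nrow(v1)
  n2 <- nrow(v2)
  B <- ncol(v1)
  a1 <- aperm(array(v1, c(n1, B, n2)), c(1, 3, 2))
  a2 <- aperm(array(v2, c(n2, B, n1)), c(3, 1, 2))
  .ad_push(t, a1 + a2, c(f1$id, f2$id), function(g) {
    list(colSums(aperm(g, c(2, 1, 3))), colSums(g))
  })
}

# ---- reductions ----

#' @rdname ad_ops
#' @export
ad_rowsum <- function(t, a) {
  av <- a$value
  m <- ncol(av)
  .ad_push(t, matrix(rowSums(av), ncol = 1), a$id, function(g) {
    list(matrix(g, nrow(av), m))
  })
}

#' @rdname ad_ops
#' @export
ad_rowmean <- function(t, a) {
  av <- a$value
  m <- ncol(av)
  .ad_push(t, matrix(rowMeans(av), ncol = 1), a$id, function(g) {
    list(matrix(g / m, nrow(av), m))
  })
}

#' @rdname ad_ops
#' @export
ad_colmean <- function(t, a) {
  av <- a$value
  n <- nrow(av)
  .ad_push(t, matrix(colMeans(av), nrow = 1), a$id, function(g) {
    list(matrix(g / n, n, ncol(av), byrow = TRUE))
  })
}

#' Row-wise maximum (returns an n x 1 matrix)
#' @rdname ad_ops
#' @export
ad_rowmax <- function(t, a) {
  av <- a$value
  j <- max.col(av, ties.method = "first")
  n <- nrow(av)
  v <- matrix(av[cbind(seq_len(n), j)], ncol = 1)
  .ad_push(t, v, a$id, function(g) {
    gz <- matrix(0, n, ncol(av))
    gz[cbind(seq_len(n), j)] <- g
    list(gz)
  })
}

#' Column-wise maximum (returns a vector of length ncol)
#'
#' Implemented as a row-at-a-time pmax reduction so no transpose of the
#' (possibly large) input is needed.
#' @rdname ad_ops
#' @export
ad_colmax <- function(t, a) {
  av <- a$value
  n <- nrow(av)
  m <- ncol(av)
  tv <- t(av)
  arg <- max.col(tv, ties.method = "first")
  mx <- tv[cbind(seq_len(m), arg)]
  .ad_push(t, mx, a$id, function(g) {
    gz <- matrix(0, n, m)
    gz[cbind(arg, seq_len(m))] <- g
    list(gz)
  })
}

#' @rdname ad_ops
#' @export
ad_mean_all <- function(t, a) {
  av <- a$value
  n <- length(av)
  .ad_push(t, sum(av) / n, a$id, function(g) {
    gi <- array(g / n, dim(av) %||% n)
    list(gi)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- normalizations ----

#' Row-wise softmax
#' @rdname ad_ops
#' @export
ad_softmax_rows <- function(t, a) {
  av <- a$value
  mx <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  y <- e / rowSums(e)
  .ad_push(t, y, a$id, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

#' Row-wise layer normalization (zero mean, unit variance per row)
#' @rdname ad_ops
#' @param eps variance floor
#' @export
ad_layernorm_rows <- function(t, a, eps = 1e-5) {
  av <- a$value
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  .ad_push(t, y, a$id, function(g) {
    list(inv * (g - rowMeans(g) - y * rowMeans(g * y)))
  })
}

# ---- loss ----

#' Mean cross-entropy over rows of a logit matrix
#' @rdname ad_ops
#' @param labels integer class labels in 1..ncol(a)
#' @export
ad_cross_entropy <- function(t, a, labels) {
  av <- a$value
  n <- nrow(av)
  mx <- av[cbind(seq_len(n), max.col(av, ties.method = "first"))]
  e <- exp(av - mx)
  se <- rowSums(e)
  lse <- mx + log(se)
  loss <- mean(lse - av[cbind(seq_len(n), labels)])
  .ad_push(t, loss, a$id, function(g) {
    p <- e / se
    p[cbind(seq_len(n), labels)] <- p[cbind(seq_len(n), labels)] - 1
    list(g * p / n)
  })
}

# ---- composite helpers (no new primitives) ----

#' Concatenate nodes along one dimension of equal-shaped arrays
#' @rdname ad_ops
#' @param dim_c dimension to concatenate along
#' @export
ad_cat <- function(t, nodes, dim_c) {
  d <- dim(nodes[[1]]$value)
  nd <- length(d)
  perm <- c(seq_len(nd)[-dim_c], dim_c)
  mats <- lapply(nodes, function(nd_) {
    x <- ad_aperm(t, nd_, perm)
    dd <- dim(x$value)
    ad_reshape(t, x, c(prod(dd[-length(dd)]), dd[length(dd)]))
  })
  bound <- ad_cbind(t, mats)
  total <- sum(vapply(nodes, function(x) dim(x$value)[dim_c], 0))
  newd <- d[perm[-nd]]
  x <- ad_reshape(t, bound, c(newd, total))
  ad_aperm(t, x, order(c(perm[-nd], dim_c)))
}

#' Shift an array along one dimension with zero padding
#' @rdname ad_ops
#' @param dim_s dimension to shift along
#' @param offset signed shift; `out[i] = in[i + offset]`
#' @export
ad_shift <- function(t, a, dim_s, offset) {
  d <- dim(a$value)
  n <- d[dim_s]
  idx <- seq_len(n) + offset
  idx[idx < 1L | idx > n] <- 0L
  nd <- length(d)
  perm <- c(dim_s, seq_len(nd)[-dim_s])
  x <- ad_aperm(t, a, perm)
  x <- ad_reshape(t, x, c(n, prod(d[-dim_s])))
  x <- ad_gather_rows(t, x, idx)
  x <- ad_reshape(t, x, d[perm])
  ad_aperm(t, x, order(perm))
}

#' Linear layer on a 2-D node: x W + b (bias along columns)
#' @rdname ad_ops
#' @export
ad_linear <- function(t, x, w, b) {
  ad_add_bias(t, ad_mm(t, x, w), b, 2)
}
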