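# Reverse-mode automatic differentiation over dense R arrays.
#
# The graph is dynamic: every operation creates a node that records its parent
# nodes and a vector-Jacobian product (vjp) closure. Gradients only flow into
# subgraphs that contain trainable parameters (ng = "needs gradient"), so
# constant inputs (data tensors, graph Laplacians) cost nothing on the
# backward pass. Nodes are environments; creation order is a valid topological
# order, so the backward sweep simply walks ids in decreasing order.

`%||%` <- function(a, b) if (is.null(a)) b else a

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_node <- function(val, parents = list(), vjp = NULL, ng = FALSE) {
  .ad$id <- .ad$id + 1L
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- parents
  n$vjp <- vjp
  n$grad <- NULL
  n$id <- .ad$id
  n$ng <- ng
  class(n) <- "ad_node"
  n
}

ad_const <- function(x) if (inherits(x, "ad_node")) x else ad_node(x)
ad_param <- function(x) ad_node(x, ng = TRUE)
ad_val <- function(x) if (inherits(x, "ad_node")) x$val else x

ad_op <- function(val, parents, vjp) {
  ng <- FALSE
  for (p in parents) if (p$ng) { ng <- TRUE; break }
  ad_node(val, parents, if (ng) vjp else NULL, ng = ng)
}

# Backward sweep from a scalar root; accumulates $grad on every reachable
# gradient-bearing node (in particular all ad_param leaves).
ad_backward <- function(root) {
  stopifnot(inherits(root, "ad_node"), length(root$val) == 1L)
  if (!root$ng) return(invisible(root))
  seen <- new.env(parent = emptyenv())
  nodes <- list()
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[key]] <- nd
    for (p in nd$parents) if (p$ng) stack[[length(stack) + 1L]] <- p
  }
  ids <- sort(as.integer(names(nodes)), decreasing = TRUE)
  root$grad <- 1
  for (id in ids) {
    nd <- nodes[[as.character(id)]]
    if (is.null(nd$vjp)) next
    if (!is.null(nd$grad)) {
      gs <- nd$vjp(nd$grad)
      ps <- nd$parents
      for (k in seq_along(ps)) {
        g <- if (k <= length(gs)) gs[[k]] else NULL
        if (is.null(g)) next
        p <- ps[[k]]
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    # this node is fully consumed: drop its activation, gradient and closure
    # so memory is reclaimed while the sweep is still running (leaf nodes
    # have no vjp and keep their grads for the optimizer)
    nd$vjp <- NULL
    nd$grad <- NULL
    nd$parents <- list()
    if (nd$id != root$id) nd$val <- NULL
  }
  invisible(root)
}

# ---- elementwise ----

ad_add <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_op(a$val + b$val, list(a, b),
        function(g) list(if (a$ng) g, if (b$ng) g))
}

ad_sub <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_op(a$val - b$val, list(a, b),
        function(g) list(if (a$ng) g, if (b$ng) -g))
}

ad_mul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_op(a$val * b$val, list(a, b),
        function(g) list(if (a$ng) g * b$val, if (b$ng) g * a$val))
}

ad_relu <- function(a) {
  a <- ad_const(a)
  mask <- a$val > 0
  ad_op(a$val * mask, list(a), function(g) list(g * mask))
}

ad_sigmoid <- function(a) {
  a <- ad_const(a)
  s <- 1 / (1 + exp(-a$val))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

# ---- shape ----

ad_reshape <- function(a, dims) {
  a <- ad_const(a)
  od <- dim(a$val) %||% length(a$val)
  v <- a$val
  dim(v) <- dims
  ad_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

ad_aperm <- function(a, perm) {
  a <- ad_const(a)
  inv <- order(perm)
  ad_op(aperm(a$val, perm), list(a), function(g) list(aperm(g, inv)))
}

# Concatenate along the trailing (feature) dimension.
ad_concat_last <- function(xs) {
  xs <- lapply(xs, ad_const)
  ds <- lapply(xs, function(x) dim(x$val))
  nd <- length(ds[[1L]])
  lead <- ds[[1L]][-nd]
  ks <- vapply(ds, function(d) d[nd], numeric(1))
  M <- prod(lead)
  mats <- lapply(xs, function(x) { v <- x$val; dim(v) <- c(M, dim(x$val)[nd]); v })
  out <- do.call(cbind, mats)
  dim(out) <- c(lead, sum(ks))
  ends <- cumsum(ks)
  starts <- c(1, head(ends, -1) + 1)
  ad_op(out, xs, function(g) {
    dim(g) <- c(M, sum(ks))
    lapply(seq_along(xs), function(i) {
      if (!xs[[i]]$ng) return(NULL)
      gi <- g[, starts[i]:ends[i], drop = FALSE]
      dim(gi) <- c(lead, ks[i])
      gi
    })
  })
}

# ---- linear algebra ----

# Batched matrix multiply: a is (M, n, k), b is (M, k, m); batch along dim 1.
# The kernels are compiled (src/ops.cpp); the inner loop runs over the
# contiguous batch index.
ad_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- ad_const(a); b <- ad_const(b)
  da <- dim(a$val); db <- dim(b$val)
  out <- .bmm_fwd_cpp(a$val, b$val, da, db, ta, tb)
  ad_op(out, list(a, b), function(g) {
    gs <- .bmm_bwd_cpp(g, a$val, b$val, da, db, ta, tb, a$ng, b$ng)
    list(if (a$ng) gs$ga, if (b$ng) gs$gb)
  })
}

# Softmax along the trailing dimension of an array; the optional scalar
# `scale` multiplies the logits first (folds the attention temperature in
# without materializing an intermediate).
ad_softmax_last <- function(a, scale = 1) {
  a <- ad_const(a)
  d <- dim(a$val)
  nd <- length(d)
  K <- d[nd]
  M <- prod(d) / K
  m <- a$val
  dim(m) <- c(M, K)
  if (scale != 1) m <- m * scale
  mx <- m[cbind(seq_len(M), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  s <- e / rowSums(e)
  val <- s
  dim(val) <- d
  ad_op(val, list(a), function(g) {
    gm <- g
    dim(gm) <- c(M, K)
    gx <- (gm - rowSums(gm * s)) * s * scale
    dim(gx) <- d
    list(gx)
  })
}

# Mean over time and node dims of a (B, T, N, C) tensor -> (B, C).
ad_mean_tn <- function(a) {
  a <- ad_const(a)
  d <- dim(a$val)
  B <- d[1]; TT <- d[2]; N <- d[3]; C <- d[4]
  val <- apply(a$val, c(1, 4), mean)
  dim(val) <- c(B, C)
  ad_op(val, list(a), function(g) {
    gx <- array(0, d)
    for (cc in seq_len(C)) gx[, , , cc] <- array(g[, cc] / (TT * N), c(B, TT, N))
    list(gx)
  })
}

# Mean softmax cross-entropy between logits (B, C) and 1-based class labels.
ad_softmax_ce <- function(logits, classes) {
  logits <- ad_const(logits)
  lv <- logits$val
  B <- nrow(lv)
  mx <- apply(lv, 1, max)
  e <- exp(lv - mx)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(B), classes)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  ad_op(loss, list(logits), function(g) {
    gp <- p
    gp[idx] <- gp[idx] - 1
    list(gp * (g / B))
  })
}

# Apply a linear map (+ optional bias) along the trailing dimension of any
# array, flattening the leading dims. Fused into one node so the flatten /
# unflatten round trip costs a single copy each way.
nn_linear <- function(x, W, b = NULL) {
  x <- ad_const(x); W <- ad_const(W)
  if (!is.null(b)) b <- ad_const(b)
  d <- dim(x$val)
  nd <- length(d)
  Fin <- d[nd]
  M <- prod(d) / Fin
  Fout <- ncol(W$val)
  xm <- x$flat
  if (is.null(xm)) {
    xm <- x$val
    dim(xm) <- c(M, Fin)
    x$flat <- xm  # reused when several layers read the same activation
  }
  out <- xm %*% W$val
  if (!is.null(b)) out <- out + rep(b$val, each = M)
  dim(out) <- c(d[-nd], Fout)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_op(out, parents, function(g) {
    dim(g) <- c(M, Fout)
    gx <- if (x$ng) { v <- g %*% t(W$val); dim(v) <- d; v }
    gW <- if (W$ng) crossprod(xm, g)
    gb <- if (!is.null(b) && b$ng) colSums(g)
    if (is.null(b)) list(gx, gW) else list(gx, gW, gb)
  })
}


# Depthwise 1-D convolution along the time dimension of a (B, T, N, F)
# tensor with per-feature kernel W (kernel x F), zero padding preserving T.
ad_depthwise_time <- function(x, W) {
  x <- ad_const(x); W <- ad_const(W)
  d <- dim(x$val)
  TT <- d[2]; F <- d[4]
  kernel <- nrow(W$val)
  pad <- (kernel - 1) %/% 2
  xv <- x$val; Wv <- W$val
  out <- array(0, d)
  for (j in seq_len(kernel)) {
    s <- j - 1L - pad
    ot <- max(1, 1 + s):min(TT, TT + s)
    it <- ot - s
    wrep <- rep(Wv[j, ], each = d[1] * length(ot) * d[3])
    out[, ot, , ] <- out[, ot, , ] + xv[, it, , , drop = FALSE] * wrep
  }
  ad_op(out, list(x, W), function(g) {
    gx <- if (x$ng) array(0, d)
    gW <- if (W$ng) matrix(0, kernel, F)
    for (j in seq_len(kernel)) {
      s <- j - 1L - pad
      ot <- max(1, 1 + s):min(TT, TT + s)
      it <- ot - s
      gs <- g[, ot, , , drop = FALSE]
      if (x$ng) {
        wrep <- rep(Wv[j, ], each = d[1] * length(ot) * d[3])
        gx[, it, , ] <- gx[, it, , ] + gs * wrep
      }
      if (W$ng) {
        pf <- gs * xv[, it, , , drop = FALSE]
        dim(pf) <- c(length(pf) / F, F)
        gW[j, ] <- colSums(pf)
      }
    }
    list(gx, gW)
  })
}
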