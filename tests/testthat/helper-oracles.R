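# Independent brute-force oracles used to validate the implementation.
# These are written as plain loops over the defining formulas and share no
# code with the package internals.

# Per-query loop implementation of multi-head dot-product attention with the
# three-layer feed-forward and input residual (the spatial path: per batch
# entry and time step, nodes attend over nodes).
oracle_spatial_attention <- function(x4, p, n_heads, scale = "sqrt_d") {
  d <- dim(x4)
  out <- array(0, d)
  N <- d[3]; F <- d[4]
  bias_mat <- function(b) matrix(b, N, length(b), byrow = TRUE)
  for (b in seq_len(d[1])) for (t in seq_len(d[2])) {
    X <- matrix(x4[b, t, , ], N, F)
    heads <- list()
    for (h in seq_len(n_heads)) {
      Q <- X %*% p$W_q[[h]]
      K <- X %*% p$W_k[[h]]
      V <- X %*% p$W_v[[h]]
      dh <- ncol(Q)
      den <- if (scale == "d") dh else sqrt(dh)
      ctx <- matrix(0, N, dh)
      for (i in seq_len(N)) {
        sc <- numeric(N)
        for (j in seq_len(N)) sc[j] <- sum(Q[i, ] * K[j, ]) / den
        w <- exp(sc - max(sc)); w <- w / sum(w)
        for (j in seq_len(N)) ctx[i, ] <- ctx[i, ] + w[j] * V[j, ]
      }
      heads[[h]] <- ctx
    }
    m <- do.call(cbind, heads) %*% p$W_o + bias_mat(p$b_o)
    h1 <- pmax(m %*% p$W_1 + bias_mat(p$b_1), 0)
    h2 <- pmax(h1 %*% p$W_2 + bias_mat(p$b_2), 0)
    out[b, t, , ] <- X + (h2 %*% p$W_3 + bias_mat(p$b_3))
  }
  out
}

# Per-time-step loop implementation of the temporal path: per batch entry and
# node, time steps attend over time steps.
oracle_temporal_attention <- function(x4, p, n_heads, scale = "sqrt_d") {
  d <- dim(x4)
  out <- array(0, d)
  TT <- d[2]; F <- d[4]
  bias_mat <- function(b) matrix(b, TT, length(b), byrow = TRUE)
  for (b in seq_len(d[1])) for (n in seq_len(d[3])) {
    X <- matrix(x4[b, , n, ], TT, F)
    heads <- list()
    for (h in seq_len(n_heads)) {
      Q <- X %*% p$W_q[[h]]
      K <- X %*% p$W_k[[h]]
      V <- X %*% p$W_v[[h]]
      dh <- ncol(Q)
      den <- if (scale == "d") dh else sqrt(dh)
      ctx <- matrix(0, TT, dh)
      for (i in seq_len(TT)) {
        sc <- numeric(TT)
        for (j in seq_len(TT)) sc[j] <- sum(Q[i, ] * K[j, ]) / den
        w <- exp(sc - max(sc)); w <- w / sum(w)
        for (j in seq_len(TT)) ctx[i, ] <- ctx[i, ] + w[j] * V[j, ]
      }
      heads[[h]] <- ctx
    }
    m <- do.call(cbind, heads) %*% p$W_o + bias_mat(p$b_o)
    h1 <- pmax(m %*% p$W_1 + bias_mat(p$b_1), 0)
    h2 <- pmax(h1 %*% p$W_2 + bias_mat(p$b_2), 0)
    out[b, , n, ] <- X + (h2 %*% p$W_3 + bias_mat(p$b_3))
  }
  out
}

# Dense explicit-polynomial Chebyshev GCN: forms every T_k as a full matrix
# from the definition and applies the filter per batch entry and time step.
oracle_cheb_gcn <- function(x4, adjacency, thetas) {
  N <- nrow(adjacency)
  W <- abs(adjacency)
  diag(W) <- 1
  Dm <- diag(1 / sqrt(rowSums(W)))
  L <- diag(N) - Dm %*% W %*% Dm
  # power iteration for lambda_max, written out independently
  v <- rep(1 / sqrt(N), N)
  lam <- 2
  for (i in 1:20) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { lam <- 2; break }
    v <- w / nw
    lam <- sum(v * (L %*% v))
  }
  if (!is.finite(lam) || lam <= 1e-8) lam <- 2
  Lt <- (2 / lam) * L - diag(N)
  K <- length(thetas)
  Ts <- list(diag(N))
  if (K >= 2) Ts[[2]] <- Lt
  if (K >= 3) for (k in 3:K) Ts[[k]] <- 2 * Lt %*% Ts[[k - 1]] - Ts[[k - 2]]
  d <- dim(x4)
  out <- array(0, c(d[1], d[2], d[3], ncol(thetas[[1]])))
  for (b in seq_len(d[1])) for (t in seq_len(d[2])) {
    X <- matrix(x4[b, t, , ], d[3], d[4])
    acc <- matrix(0, d[3], ncol(thetas[[1]]))
    for (k in seq_len(K)) acc <- acc + Ts[[k]] %*% X %*% thetas[[k]]
    out[b, t, , ] <- pmax(acc, 0)
  }
  out
}

# Brute-force sliding-window enumerator: walk starts one step at a time and
# keep those where a full window fits at the stated stride.
oracle_segment_starts <- function(L, window, overlap) {
  stride <- window - overlap
  starts <- integer(0)
  s <- 0
  while (s + window <= L) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# Element-by-element Pearson correlation from the raw sum formula.
oracle_pearson <- function(x) {
  N <- ncol(x); n <- nrow(x)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    xi <- x[, i]; xj <- x[, j]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    out[i, j] <- num / den
  }
  out
}

# Exhaustive pair-count AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Structural components of the DeLong variance, direct double loop.
oracle_delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

# Model-exchange permutation test for the paired AUC difference: under the
# null the two models are exchangeable, so swap their scores per observation.
oracle_delong_permutation <- function(scores_a, scores_b, labels, draws = 20000,
                                      seed = 1) {
  set.seed(seed)
  obs <- abs(oracle_auc(scores_a, labels) - oracle_auc(scores_b, labels))
  n <- length(labels)
  hits <- 0
  for (d in seq_len(draws)) {
    swap <- stats::runif(n) < 0.5
    sa <- ifelse(swap, scores_b, scores_a)
    sb <- ifelse(swap, scores_a, scores_b)
    if (abs(roc_auc(sa, labels) - roc_auc(sb, labels)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / draws
}

# Relative L2 error between analytic and central finite-difference gradients
# of the training loss on a tiny model.
fd_gradient_error <- function(model, batch, n_coords = Inf, h = 1e-5, seed = 1) {
  out <- stfc:::forward_node(model, batch, labels = batch$labels)
  stfc:::ad_backward(out$loss)
  flat <- function(p) unlist(p, use.names = FALSE)
  g_an <- flat(stfc:::collect_grads(out$wrapped))
  v0 <- flat(model$params)
  set_vec <- function(model, vec) {
    i <- 0
    walk <- function(p) {
      if (is.numeric(p)) {
        v <- vec[i + seq_along(p)]; i <<- i + length(p)
        dim(v) <- dim(p); v
      } else lapply(p, function(q) if (is.null(q)) NULL else walk(q))
    }
    model$params <- walk(model$params)
    model
  }
  idx <- if (is.finite(n_coords) && n_coords < length(v0)) {
    set.seed(seed); sort(sample(length(v0), n_coords))
  } else seq_along(v0)
  g_fd <- numeric(length(idx))
  for (j in seq_along(idx)) {
    vp <- v0; vp[idx[j]] <- vp[idx[j]] + h
    vm <- v0; vm[idx[j]] <- vm[idx[j]] - h
    lp <- stfc:::ad_val(stfc:::forward_node(set_vec(model, vp), batch,
                                            labels = batch$labels)$loss)
    lm <- stfc:::ad_val(stfc:::forward_node(set_vec(model, vm), batch,
                                            labels = batch$labels)$loss)
    g_fd[j] <- (lp - lm) / (2 * h)
  }
  sqrt(sum((g_fd - g_an[idx])^2)) / max(sqrt(sum(g_fd^2)), 1e-12)
}
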