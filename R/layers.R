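# Transformer building blocks. Internal *_node functions operate on autodiff
# nodes and are shared between training, inference and the exported
# array-level wrappers, so there is exactly one forward implementation.

# ---- shared pieces -------------------------------------------------------

# Multi-head scaled dot-product attention over dim 2 of a (M, n, F) tensor.
# p$W_q / p$W_k / p$W_v are per-head lists of (F x d_head) projections.
# Returns the merged head output (before feed-forward/residual) and, when
# requested, the per-head softmax maps as a plain array (H, M, n, n).
mha_node <- function(x3, p, n_heads, attention_scale = "sqrt_d",
                     collect_maps = TRUE) {
  if (any(!is.finite(ad_val(x3)))) {
    stop("non-finite values in attention input", call. = FALSE)
  }
  d <- dim(ad_val(x3))
  F <- d[3]
  dh <- F / n_heads
  denom <- if (identical(attention_scale, "d")) dh else sqrt(dh)
  ctx <- vector("list", n_heads)
  maps <- if (collect_maps) array(0, c(n_heads, d[1], d[2], d[2]))
  for (h in seq_len(n_heads)) {
    Qh <- nn_linear(x3, p$W_q[[h]])
    Kh <- nn_linear(x3, p$W_k[[h]])
    Vh <- nn_linear(x3, p$W_v[[h]])
    S <- ad_softmax_last(ad_bmm(Qh, Kh, tb = TRUE), scale = 1 / denom)
    if (collect_maps) maps[h, , , ] <- S$val
    ctx[[h]] <- ad_bmm(S, Vh)
  }
  merged <- nn_linear(ad_concat_last(ctx), p$W_o, p$b_o)
  list(out = merged, maps = maps)
}

# Three-layer position-wise feed-forward network, ReLU after layers 1 and 2.
ffn3_node <- function(x, p) {
  h <- ad_relu(nn_linear(x, p$W_1, p$b_1))
  h <- ad_relu(nn_linear(h, p$W_2, p$b_2))
  nn_linear(h, p$W_3, p$b_3)
}

# 1x1 convolution of the concatenated (signal, temporal, spatial) encodings
# followed by a depthwise 1-D convolution along time (zero padding preserves
# the window length). consts$tenc is (B,T,N,Fe), consts$senc is (B,T,N,N).
embed_node <- function(x4, consts, p) {
  xe <- ad_concat_last(list(x4, consts$tenc, consts$senc))
  xe <- nn_linear(xe, p$embed_W, p$embed_b)
  ad_depthwise_time(xe, p$dw_W)
}

# Chebyshev graph convolution ReLU(sum_k T_k(Ltil) X Theta_k), applied
# independently at every time step. trep is a list of K constant (B*T, N, N)
# polynomial stacks.
cheb_gcn_node <- function(x4, trep, thetas) {
  d <- dim(ad_val(x4))
  x3 <- ad_reshape(x4, c(d[1] * d[2], d[3], d[4]))
  acc <- NULL
  for (k in seq_along(thetas)) {
    zk <- if (k == 1) x3 else ad_bmm(ad_const(trep[[k]]), x3)
    zk <- nn_linear(zk, thetas[[k]])
    acc <- if (is.null(acc)) zk else ad_add(acc, zk)
  }
  ad_reshape(ad_relu(acc), d)
}

# Sigmoid gate fusion: alpha = sigmoid(linear(US + UG)), Y = alpha*US + (1-alpha)*UG.
gate_node <- function(us, ug, p) {
  alpha <- ad_sigmoid(nn_linear(ad_add(us, ug), p$gate_W, p$gate_b))
  ad_add(ug, ad_mul(alpha, ad_sub(us, ug)))
}

# ---- spatial block -------------------------------------------------------

# Full spatial transformer block. Returns the gated output y, the embedded
# input xtilde (which feeds the temporal residual), and the attention maps
# reshaped to (H, B, T, N, N). `ablation` drops the named branch.
spatial_block_node <- function(x4, consts, p, n_heads,
                               attention_scale = "sqrt_d", ablation = "none",
                               collect_maps = TRUE) {
  xt <- embed_node(x4, consts, p)
  if (ablation == "no_spatial") {
    return(list(y = NULL, xtilde = xt, maps = NULL))
  }
  d <- dim(ad_val(xt))
  us <- ug <- NULL
  maps <- NULL
  if (ablation != "no_attention") {
    x3 <- ad_reshape(xt, c(d[1] * d[2], d[3], d[4]))
    att <- mha_node(x3, p, n_heads, attention_scale, collect_maps)
    us <- ad_add(xt, ad_reshape(ffn3_node(att$out, p), d))
    if (collect_maps) {
      maps <- att$maps
      dim(maps) <- c(n_heads, d[1], d[2], d[3], d[3])
    }
  }
  if (ablation != "no_gcn") {
    ug <- cheb_gcn_node(xt, consts$trep, p$theta)
  }
  y <- if (is.null(us)) ug else if (is.null(ug)) us else gate_node(us, ug, p)
  list(y = y, xtilde = xt, maps = maps)
}

# ---- temporal block ------------------------------------------------------

# Temporal transformer block. xs is the spatial block's embedded input
# (X^S = xtilde), ys its gated output; the residual X^T = X^S + Y^S is
# concatenated with the sinusoidal temporal encoding, mapped back to N_f by a
# 1x1 convolution, then per-node bidirectional attention over the window's
# time steps with a shared feed-forward and a residual from the embedding.
# Returns y (= Y^T), the block hand-off y + X^T, and maps (H, B, N, T, T).
temporal_block_node <- function(xs, ys, consts, p, n_heads,
                                attention_scale = "sqrt_d",
                                collect_maps = TRUE) {
  xt <- if (is.null(ys)) xs else ad_add(xs, ys)
  xe <- nn_linear(ad_concat_last(list(xt, consts$tenc)), p$embed_W, p$embed_b)
  d <- dim(ad_val(xe))  # (B, T, N, F)
  xp <- ad_aperm(xe, c(1, 3, 2, 4))  # (B, N, T, F)
  x3 <- ad_reshape(xp, c(d[1] * d[3], d[2], d[4]))
  att <- mha_node(x3, p, n_heads, attention_scale, collect_maps)
  f4 <- ad_aperm(ad_reshape(ffn3_node(att$out, p), c(d[1], d[3], d[2], d[4])),
                 c(1, 3, 2, 4))
  y <- ad_add(xe, f4)
  maps <- NULL
  if (collect_maps) {
    maps <- att$maps
    dim(maps) <- c(n_heads, d[1], d[3], d[2], d[2])
  }
  list(y = y, handoff = ad_add(y, xt), maps = maps)
}

# ---- constant encodings per batch ---------------------------------------

# Builds the constant positional tensors for one batch:
#   tenc (B,T,N,Fe): sinusoidal encoding of each entry's absolute window times
#   senc (B,T,N,N): adjacency-row (connectomic) encoding of each node
#   trep: list of K constant (B*T, N, N) Chebyshev stacks
batch_consts <- function(batch, n_features, use_cache = TRUE) {
  cache <- batch$cache
  key <- paste0("consts_", n_features)
  if (use_cache && !is.null(cache[[key]])) return(cache[[key]])
  d <- dim(batch$series)
  B <- d[1]; T_ <- d[2]; N <- d[3]
  tenc <- array(0, c(B, T_, n_features))
  for (b in seq_len(B)) {
    tenc[b, , ] <- temporal_positional_encoding(batch$start[b] + 0:(T_ - 1),
                                                n_features)
  }
  tenc4 <- aperm(array(tenc, c(B, T_, n_features, N)), c(1, 2, 4, 3))
  sp <- aperm(batch$adjacency, c(3, 1, 2))  # (B, N, N), row n = node n's profile
  senc4 <- aperm(array(sp, c(B, N, N, T_)), c(1, 4, 2, 3))
  trep <- lapply(batch$cheb, function(Tk) {
    Tk[rep(seq_len(B), T_), , , drop = FALSE]
  })
  out <- list(tenc = ad_const(tenc4), senc = ad_const(senc4), trep = trep)
  if (use_cache) cache[[key]] <- out
  out
}

# ---- exported array-level wrappers --------------------------------------

# Coerce x to a (B, T, N, F) array: accepts (T,N) segment matrices,
# (B,T,N) arrays, or 4-D arrays.
as_feature_tensor <- function(x) {
  if (inherits(x, "fc_segment")) x <- x$series
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array", call. = FALSE)
  if (length(d) == 2) x <- array(x, c(1, d[1], d[2], 1))
  else if (length(d) == 3) x <- array(x, c(d, 1))
  else if (length(d) != 4) stop("input must have 2, 3 or 4 dimensions", call. = FALSE)
  x
}

# Stack single network / list of networks to (N, N, B).
as_adjacency_stack <- function(network, B) {
  if (inherits(network, "fc_network")) network <- network$adjacency
  if (is.list(network)) {
    mats <- lapply(network, spatial_positional_encoding)
    N <- nrow(mats[[1]])
    arr <- array(0, c(N, N, length(mats)))
    for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
    return(arr)
  }
  d <- dim(network)
  if (length(d) == 2) network <- array(network, c(d[1], d[2], B))
  network
}

# Build a pseudo-batch from raw tensors so the wrappers can reuse
# batch_consts().
tensor_batch <- function(x4, adjacency, starts, cheb_order) {
  d <- dim(x4)
  B <- d[1]
  adj <- as_adjacency_stack(adjacency, B)
  cheb <- lapply(seq_len(cheb_order), function(k) array(0, c(B, d[3], d[3])))
  for (b in seq_len(B)) {
    Ts <- chebyshev_basis(adj[, , b], cheb_order)
    for (k in seq_len(cheb_order)) cheb[[k]][b, , ] <- Ts[[k]]
  }
  list(series = array(x4[, , , 1], d[1:3]), adjacency = adj, cheb = cheb,
       start = rep_len(starts, B), cache = new.env(parent = emptyenv()))
}

#' Positional embedding of a windowed segment
#'
#' Concatenates, per node and time step, the raw signal features, the
#' sinusoidal temporal encoding of the absolute window time, and the
#' connectomic spatial encoding (the node's adjacency row); maps the result to
#' `n_features` channels with a 1x1 convolution; and refines it with a
#' depthwise 1-D convolution along time (zero padding preserves the length).
#'
#' @param x segment matrix (T x N), or (B,T,N) / (B,T,N,F) array.
#' @param network an `fc_network`, adjacency matrix, or (N,N,B) stack.
#' @param params a `SpatialParams` list (see [build_model()]), fields
#'   `embed_W`, `embed_b`, `dw_W`.
#' @param starts 0-based absolute start time of each entry's window.
#' @return (B, T, N, n_features) array.
#' @export
embed_positions <- function(x, network, params, starts = 0L) {
  x4 <- as_feature_tensor(x)
  n_features <- ncol(params$embed_W)
  bt <- tensor_batch(x4, network, starts, 1)
  consts <- batch_consts(bt, n_features, use_cache = FALSE)
  ad_val(embed_node(ad_const(x4), consts, params))
}

#' Multi-head spatial graph attention
#'
#' Per time step, every node attends over all nodes of its window:
#' `Q = X W_Q`, `K = X W_K`, `V = X W_V` per head, row-softmax of the scaled
#' query-key dot products, weighted value sum, head concatenation + merge,
#' three-layer feed-forward (ReLU after layers 1 and 2), and a residual from
#' the input.
#'
#' @param x (B, T, N, F) feature array.
#' @param params a `SpatialParams` list with `W_q`, `W_k`, `W_v`, `W_o`,
#'   `b_o`, `W_1..W_3`, `b_1..b_3`.
#' @param n_heads number of attention heads (divides F).
#' @param attention_scale `"sqrt_d"` (default, scaled dot product) or `"d"`.
#' @return list with `features` (B,T,N,F) and `maps` (heads, B, T, N, N);
#'   every length-N map row sums to 1.
#' @export
spatial_attention <- function(x, params, n_heads = 2, attention_scale = "sqrt_d") {
  x4 <- as_feature_tensor(x)
  d <- dim(x4)
  xt <- ad_const(x4)
  x3 <- ad_reshape(xt, c(d[1] * d[2], d[3], d[4]))
  att <- mha_node(x3, params, n_heads, attention_scale)
  us <- ad_add(xt, ad_reshape(ffn3_node(att$out, params), d))
  maps <- att$maps
  dim(maps) <- c(n_heads, d[1], d[2], d[3], d[3])
  list(features = ad_val(us), maps = maps)
}

#' Chebyshev graph convolution on a window's FC network
#'
#' Computes `ReLU(sum_{k<K} T_k(Ltil) X Theta_k)` independently at each time
#' step, where `Ltil` is the scaled normalized Laplacian of the network built
#' from absolute Pearson weights with unit self-loops.
#'
#' @param x (B, T, N, F) feature array (or matrix/3-D array, promoted).
#' @param network `fc_network`, adjacency matrix, or (N,N,B) stack.
#' @param params `SpatialParams` list whose `theta` field is a list of K
#'   coefficient matrices, or the list of matrices itself.
#' @param K Chebyshev order (defaults to the number of coefficient matrices).
#' @return (B, T, N, F_out) array.
#' @export
chebyshev_gcn <- function(x, network, params, K = NULL) {
  x4 <- as_feature_tensor(x)
  thetas <- if (!is.null(params$theta)) params$theta else params
  if (is.null(K)) K <- length(thetas)
  if (K < 1) stop("Chebyshev order K must be >= 1", call. = FALSE)
  thetas <- thetas[seq_len(K)]
  bt <- tensor_batch(x4, network, 0L, K)
  consts <- batch_consts(bt, 2L, use_cache = FALSE)
  ad_val(cheb_gcn_node(ad_const(x4), consts$trep, thetas))
}

#' Sigmoid-gate fusion of the attention and graph-convolution branches
#'
#' `alpha = sigmoid(linear(U_S + U_G))` elementwise in (0,1);
#' `Y = alpha * U_S + (1 - alpha) * U_G`, so the fused output always lies
#' between its two inputs.
#'
#' @param us,ug equally shaped feature arrays (attention and GCN branches).
#' @param params list with `gate_W`, `gate_b`.
#' @return array of the same shape.
#' @export
gate_fuse <- function(us, ug, params) {
  if (!identical(dim(us), dim(ug))) stop("gate inputs must have identical shapes", call. = FALSE)
  ad_val(gate_node(ad_const(as_feature_tensor(us)),
                   ad_const(as_feature_tensor(ug)), params))
}

#' Full spatial transformer block
#'
#' Composes [embed_positions()] with the parallel attention and Chebyshev-GCN
#' branches and the sigmoid gate.
#'
#' @inheritParams embed_positions
#' @param params full `SpatialParams` list.
#' @param n_heads attention heads.
#' @param attention_scale see [spatial_attention()].
#' @param ablation `"none"`, `"no_attention"` or `"no_gcn"`.
#' @return list with `features` (the gated Y_S), `xtilde` (the embedded
#'   input) and `maps`.
#' @export
spatial_block_forward <- function(x, network, params, starts = 0L, n_heads = 2,
                                  attention_scale = "sqrt_d", ablation = "none") {
  x4 <- as_feature_tensor(x)
  bt <- tensor_batch(x4, network, starts, length(params$theta %||% list(1)))
  consts <- batch_consts(bt, ncol(params$embed_W), use_cache = FALSE)
  out <- spatial_block_node(ad_const(x4), consts, params, n_heads,
                            attention_scale, ablation)
  list(features = if (is.null(out$y)) NULL else ad_val(out$y),
       xtilde = ad_val(out$xtilde), maps = out$maps)
}

#' Temporal embedding of the spatial block's output
#'
#' Forms the residual `X_T = X_S + Y_S`, concatenates the sinusoidal temporal
#' encoding along features, and maps back to N_f channels by a 1x1
#' convolution.
#'
#' @param xs the spatial block's embedded input (B,T,N,F).
#' @param ys the spatial block's gated output, same shape (or NULL).
#' @param params `TemporalParams` list with `embed_W`, `embed_b`.
#' @param starts absolute 0-based window start per entry.
#' @return (B, T, N, F) array.
#' @export
temporal_embed <- function(xs, ys, params, starts = 0L) {
  xs <- as_feature_tensor(xs)
  if (!is.null(ys)) {
    ys <- as_feature_tensor(ys)
    if (!identical(dim(xs), dim(ys))) stop("xs and ys must have identical shapes", call. = FALSE)
  }
  d <- dim(xs)
  F <- nrow(params$embed_W) - d[4]
  tenc <- array(0, c(d[1], d[2], F))
  starts <- rep_len(starts, d[1])
  for (b in seq_len(d[1])) {
    tenc[b, , ] <- temporal_positional_encoding(starts[b] + 0:(d[2] - 1), F)
  }
  tenc4 <- aperm(array(tenc, c(d[1], d[2], F, d[3])), c(1, 2, 4, 3))
  xt <- if (is.null(ys)) ad_const(xs) else ad_add(ad_const(xs), ad_const(ys))
  ad_val(nn_linear(ad_concat_last(list(xt, ad_const(tenc4))),
                   params$embed_W, params$embed_b))
}

#' Per-node bidirectional temporal attention
#'
#' For each node independently, every time step of the window attends over
#' all time steps (no causal masking), followed by the shared three-layer
#' feed-forward and a residual from the input.
#'
#' @param x (B, T, N, F) feature array.
#' @param params `TemporalParams` list.
#' @param n_heads attention heads.
#' @param attention_scale see [spatial_attention()].
#' @return list with `features` (B,T,N,F) and `maps` (heads, B, N, T, T).
#' @export
temporal_attention <- function(x, params, n_heads = 2, attention_scale = "sqrt_d") {
  x4 <- as_feature_tensor(x)
  d <- dim(x4)
  xe <- ad_const(x4)
  x3 <- ad_reshape(ad_aperm(xe, c(1, 3, 2, 4)), c(d[1] * d[3], d[2], d[4]))
  att <- mha_node(x3, params, n_heads, attention_scale)
  f4 <- ad_aperm(ad_reshape(ffn3_node(att$out, params), c(d[1], d[3], d[2], d[4])),
                 c(1, 3, 2, 4))
  y <- ad_add(xe, f4)
  maps <- att$maps
  dim(maps) <- c(n_heads, d[1], d[3], d[2], d[2])
  list(features = ad_val(y), maps = maps)
}

#' Full temporal transformer block
#'
#' Composes [temporal_embed()] and [temporal_attention()]; the value handed to
#' the next ST block is `Y_T + X_T`.
#'
#' @inheritParams temporal_embed
#' @param n_heads attention heads.
#' @param attention_scale see [spatial_attention()].
#' @return list with `features` (Y_T), `handoff` (Y_T + X_T) and `maps`.
#' @export
temporal_block_forward <- function(xs, ys, params, starts = 0L, n_heads = 2,
                                   attention_scale = "sqrt_d") {
  xs4 <- as_feature_tensor(xs)
  d <- dim(xs4)
  F <- d[4]
  tenc <- array(0, c(d[1], d[2], F))
  sts <- rep_len(starts, d[1])
  for (b in seq_len(d[1])) {
    tenc[b, , ] <- temporal_positional_encoding(sts[b] + 0:(d[2] - 1), F)
  }
  tenc4 <- aperm(array(tenc, c(d[1], d[2], F, d[3])), c(1, 2, 4, 3))
  consts <- list(tenc = ad_const(tenc4))
  ysn <- if (is.null(ys)) NULL else ad_const(as_feature_tensor(ys))
  out <- temporal_block_node(ad_const(xs4), ysn, consts, params, n_heads,
                             attention_scale)
  list(features = ad_val(out$y), handoff = ad_val(out$handoff), maps = out$maps)
}
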