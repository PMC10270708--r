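#' Sinusoidal temporal positional encoding
#'
#' Standard trigonometric encoding of absolute time indices: feature pair
#' `(2k, 2k+1)` holds `sin(t / 10000^(2k/F))` and `cos(t / 10000^(2k/F))`.
#'
#' @param time_indices integer vector of absolute (0-based) time indices.
#' @param n_features even number of encoding features F.
#' @return `length(time_indices) x n_features` matrix with entries in
#'   `[-1, 1]`.
#' @export
temporal_positional_encoding <- function(time_indices, n_features) {
  if (n_features %% 2 != 0) stop("n_features must be even", call. = FALSE)
  t <- as.numeric(time_indices)
  k <- 0:(n_features / 2 - 1)
  freq <- 1 / 10000^(2 * k / n_features)
  ang <- outer(t, freq)
  out <- matrix(0, length(t), n_features)
  out[, 2 * k + 1] <- sin(ang)
  out[, 2 * k + 2] <- cos(ang)
  out
}

#' Connectomic spatial positional encoding
#'
#' Node i's positional feature vector is row i of the functional-connectivity
#' adjacency matrix, i.e. its connectomic neighborhood profile.
#'
#' @param network an `fc_network` (or a plain adjacency matrix).
#' @return the `N x N` matrix of row encodings.
#' @export
spatial_positional_encoding <- function(network) {
  A <- if (inherits(network, "fc_network")) network$adjacency else network
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A
}

# Chebyshev polynomial basis of a window's FC network.
#
# Edge weights are |Pearson r| with unit self-loops (a signed normalized
# Laplacian is not well defined), L = I - D^{-1/2} W D^{-1/2}, lambda_max
# estimated by 20 power-iteration steps with fallback 2, Ltil = 2L/lambda - I,
# and T_0 = I, T_1 = Ltil, T_k = 2 Ltil T_{k-1} - T_{k-2}.
chebyshev_basis <- function(adjacency, K) {
  if (K < 1) stop("Chebyshev order K must be >= 1", call. = FALSE)
  N <- nrow(adjacency)
  W <- abs(adjacency)
  diag(W) <- 1
  d <- rowSums(W)
  dmh <- 1 / sqrt(d)
  L <- diag(N) - (dmh * W) * rep(dmh, each = N)  # I - D^-1/2 W D^-1/2
  lam <- power_iteration_lmax(L)
  Ltil <- (2 / lam) * L - diag(N)
  Ts <- vector("list", K)
  Ts[[1]] <- diag(N)
  if (K >= 2) Ts[[2]] <- Ltil
  if (K >= 3) for (k in 3:K) Ts[[k]] <- 2 * (Ltil %*% Ts[[k - 1]]) - Ts[[k - 2]]
  Ts
}

power_iteration_lmax <- function(L, steps = 20, fallback = 2) {
  N <- nrow(L)
  v <- rep(1 / sqrt(N), N)
  lam <- fallback
  for (i in seq_len(steps)) {
    w <- L %*% v
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw < 1e-12) return(fallback)
    v <- as.numeric(w / nw)
    lam <- as.numeric(crossprod(v, L %*% v))
  }
  if (!is.finite(lam) || lam <= 1e-8) fallback else lam
}
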