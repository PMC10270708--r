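#' Model configuration
#'
#' Architecture and training hyperparameters of the spatiotemporal
#' transformer. Defaults follow the reference setup: three ST blocks with
#' 2-head dot-product attention, embedding feature size 64, window length 25
#' with overlap 5, batches of 50 entries, initial learning rate 1e-4 with a
#' multiplicative decay of 0.5 on validation plateau, and a 70/15/15
#' subject-level split downstream.
#'
#' @param n_blocks number of stacked ST blocks.
#' @param n_heads attention heads (must divide `n_features`).
#' @param n_features embedding feature size N_f.
#' @param cheb_order Chebyshev order K of the graph convolution.
#' @param window_length,window_overlap segmentation parameters T_tau, T_phi.
#' @param n_classes number of classes (binary tasks use 2).
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay multiplicative decay applied when validation loss fails to
#'   improve for `lr_patience` epochs; training early-stops after
#'   `2 * lr_patience` stagnant epochs.
#' @param lr_patience plateau patience in epochs.
#' @param max_epochs training epoch cap.
#' @param batch_size entries per batch N_b.
#' @param seed integer seed controlling initialization and per-epoch shuffles.
#' @param ablation one of `"none"`, `"no_attention"`, `"no_gcn"`,
#'   `"no_spatial"`, `"no_temporal"`.
#' @param attention_scale `"sqrt_d"` (scaled dot product) or `"d"`.
#' @param dw_kernel depthwise temporal convolution kernel size (odd).
#' @param head_hidden hidden width of the prediction head (default N_f).
#' @return a `model_config` list.
#' @export
model_config <- function(n_blocks = 3, n_heads = 2, n_features = 64,
                         cheb_order = 3, window_length = 25, window_overlap = 5,
                         n_classes = 2, learning_rate = 1e-4, lr_decay = 0.5,
                         lr_patience = 3, max_epochs = 50, batch_size = 50,
                         seed = 1L, ablation = "none",
                         attention_scale = "sqrt_d", dw_kernel = 3,
                         head_hidden = NULL) {
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  if (n_features %% n_heads != 0) {
    stop(sprintf("n_features (%d) must be divisible by n_heads (%d)",
                 n_features, n_heads), call. = FALSE)
  }
  if (n_features %% 2 != 0) stop("n_features must be even", call. = FALSE)
  ablation <- match.arg(ablation, c("none", "no_attention", "no_gcn",
                                    "no_spatial", "no_temporal"))
  attention_scale <- match.arg(attention_scale, c("sqrt_d", "d"))
  if (cheb_order < 1) stop("cheb_order must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]", call. = FALSE)
  if (dw_kernel %% 2 != 1) stop("dw_kernel must be odd", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 n_features = as.integer(n_features),
                 cheb_order = as.integer(cheb_order),
                 window_length = as.integer(window_length),
                 window_overlap = as.integer(window_overlap),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 ablation = ablation, attention_scale = attention_scale,
                 dw_kernel = as.integer(dw_kernel),
                 head_hidden = as.integer(head_hidden %||% n_features)),
            class = "model_config")
}

#' Read a model configuration from a YAML or JSON file
#' @param path config file; keys are the arguments of [model_config()]
#'   (`window_length`, `window_overlap`, `batch_size`, `seed`, ...).
#' @return a `model_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  do.call(model_config, vals[names(vals) %in% names(formals(model_config))])
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

# Per-head (N_f x d_head) query/key/value projections.
init_heads <- function(F, n_heads) {
  dh <- F %/% n_heads
  lapply(seq_len(n_heads), function(h) glorot(F, dh))
}

init_attention_params <- function(F, n_heads) {
  list(W_q = init_heads(F, n_heads), W_k = init_heads(F, n_heads),
       W_v = init_heads(F, n_heads),
       W_o = glorot(F, F), b_o = numeric(F),
       W_1 = glorot(F, F), b_1 = numeric(F),
       W_2 = glorot(F, F), b_2 = numeric(F),
       W_3 = glorot(F, F), b_3 = numeric(F))
}

init_spatial_params <- function(cfg, n_nodes, in_features) {
  F <- cfg$n_features
  p <- list(
    embed_W = glorot(in_features + F + n_nodes, F),
    embed_b = numeric(F),
    dw_W = glorot(cfg$dw_kernel, F) * 0.1
  )
  # start the depthwise convolution near an identity pass-through
  p$dw_W[(cfg$dw_kernel + 1) %/% 2, ] <- p$dw_W[(cfg$dw_kernel + 1) %/% 2, ] + 1
  if (cfg$ablation != "no_attention") {
    p <- c(p, init_attention_params(F, cfg$n_heads))
  }
  if (cfg$ablation != "no_gcn") {
    p$theta <- lapply(seq_len(cfg$cheb_order), function(k) glorot(F, F))
  }
  if (!cfg$ablation %in% c("no_attention", "no_gcn")) {
    p$gate_W <- glorot(F, F)
    p$gate_b <- numeric(F)
  }
  p
}

init_temporal_params <- function(cfg) {
  F <- cfg$n_features
  c(list(embed_W = glorot(2 * F, F), embed_b = numeric(F)),
    init_attention_params(F, cfg$n_heads))
}

#' Build a spatiotemporal transformer model
#'
#' Initializes all trainable weights from the seeded stream (scaled-uniform
#' Glorot initialization; biases zero). Ablation variants simply omit the
#' corresponding parameter sets: `no_attention` keeps only the GCN branch,
#' `no_gcn` only the attention branch, `no_spatial` keeps the positional
#' embedding but removes attention/GCN/gate, and `no_temporal` removes the
#' temporal transformer while preserving the residual chain.
#'
#' @param config a [model_config()].
#' @param n_nodes number of graph nodes N the model operates on.
#' @return an `st_model` with fields `config`, `n_nodes`, `params`.
#' @export
build_model <- function(config, n_nodes) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  blocks <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    in_features <- if (i == 1) 1L else config$n_features
    blocks[[i]] <- list(
      spatial = if (config$ablation == "no_spatial") {
        # keep the embedding so features exist; drop attention/GCN/gate
        init_spatial_params(modifyList(config, list(ablation = "no_attention")),
                            n_nodes, in_features)[c("embed_W", "embed_b", "dw_W")]
      } else {
        init_spatial_params(config, n_nodes, in_features)
      },
      temporal = if (config$ablation == "no_temporal") NULL
                 else init_temporal_params(config)
    )
  }
  # final classifier layer starts at zero so the initial prediction is the
  # uniform distribution (first-epoch loss ~ ln n_classes on balanced data)
  head <- list(W_1 = glorot(config$n_features, config$head_hidden),
               b_1 = numeric(config$head_hidden),
               W_2 = matrix(0, config$head_hidden, config$n_classes),
               b_2 = numeric(config$n_classes))
  structure(list(config = config, n_nodes = as.integer(n_nodes),
                 params = list(blocks = blocks, head = head)),
            class = "st_model")
}

# Recursively wrap every numeric leaf of the parameter structure as a
# gradient-bearing tape node.
wrap_params <- function(p) {
  if (is.numeric(p)) return(ad_param(p))
  if (is.list(p)) return(lapply(p, function(q) if (is.null(q)) NULL else wrap_params(q)))
  p
}

# Read accumulated gradients back out of a wrapped structure.
collect_grads <- function(w) {
  if (inherits(w, "ad_node")) {
    g <- w$grad
    if (is.null(g)) g <- array(0, dim(w$val) %||% length(w$val))
    return(g)
  }
  if (is.list(w)) return(lapply(w, function(q) if (is.null(q)) NULL else collect_grads(q)))
  w
}

# Elementwise recursion over two (or three) parallel parameter structures.
map_params <- function(f, a, b = NULL, cc = NULL) {
  if (is.numeric(a) || is.array(a)) return(f(a, b, cc))
  out <- lapply(seq_along(a), function(i) {
    if (is.null(a[[i]])) NULL
    else map_params(f, a[[i]], if (is.null(b)) NULL else b[[i]],
                    if (is.null(cc)) NULL else cc[[i]])
  })
  names(out) <- names(a)
  out
}

# Core forward pass on one batch. Returns tape nodes plus plain-array
# side outputs (probabilities, per-entry score matrices, attention maps).
forward_node <- function(model, batch, wrapped = NULL, collect_maps = FALSE,
                         labels = NULL) {
  cfg <- model$config
  w <- wrapped %||% wrap_params(model$params)
  d <- dim(batch$series)
  x <- ad_const(array(batch$series, c(d, 1)))
  consts <- batch_consts(batch, cfg$n_features)
  maps <- list()
  for (i in seq_len(cfg$n_blocks)) {
    bl <- w$blocks[[i]]
    sp <- spatial_block_node(x, consts, bl$spatial, cfg$n_heads,
                             cfg$attention_scale, cfg$ablation, collect_maps)
    if (is.null(bl$temporal)) {
      # no_temporal: hand Y_S + X_tilde (residual chain preserved)
      x <- if (is.null(sp$y)) sp$xtilde else ad_add(sp$y, sp$xtilde)
      if (collect_maps) maps[[i]] <- list(spatial = sp$maps, temporal = NULL)
    } else {
      tp <- temporal_block_node(sp$xtilde, sp$y, consts, bl$temporal,
                                cfg$n_heads, cfg$attention_scale, collect_maps)
      x <- tp$handoff
      if (collect_maps) maps[[i]] <- list(spatial = sp$maps, temporal = tp$maps)
    }
  }
  h <- ad_relu(nn_linear(x, w$head$W_1, w$head$b_1))
  scores <- nn_linear(h, w$head$W_2, w$head$b_2)  # (B, T, N, C)
  logits <- ad_mean_tn(scores)
  lv <- logits$val
  e <- exp(lv - apply(lv, 1, max))
  probs <- e / rowSums(e)
  loss <- if (!is.null(labels)) ad_softmax_ce(logits, as.integer(labels) + 1L)
  list(wrapped = w, features = x, scores = scores, logits = logits,
       probs = probs, maps = maps, loss = loss)
}

#' Run the model forward on one batch
#'
#' @param model an `st_model`.
#' @param batch an `fc_batch` from [assemble_batches()].
#' @param collect_maps collect per-head attention maps.
#' @return list with `probabilities` (B x n_classes, rows sum to 1), `scores`
#'   (per-entry node-by-time score matrices, B x N x T_tau x n_classes),
#'   `features` (B, T, N, N_f), and `maps` (per block: `spatial`
#'   (H,B,T,N,N) and `temporal` (H,B,N,T,T)).
#' @export
forward <- function(model, batch, collect_maps = FALSE) {
  out <- forward_node(model, batch, collect_maps = collect_maps)
  list(probabilities = out$probs,
       scores = aperm(ad_val(out$scores), c(1, 3, 2, 4)),
       features = ad_val(out$features),
       maps = out$maps)
}

# ---- optimizer -----------------------------------------------------------

adam_init <- function(params) {
  list(m = map_params(function(a, ...) array(0, dim(a) %||% length(a)), params),
       v = map_params(function(a, ...) array(0, dim(a) %||% length(a)), params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g, ...) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g, ...) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- training ------------------------------------------------------------

eval_loss <- function(model, batches) {
  tot <- 0; n <- 0; scores <- numeric(0); labels <- integer(0)
  for (b in batches) {
    out <- forward_node(model, b, labels = b$labels)
    nb <- length(b$labels)
    tot <- tot + ad_val(out$loss) * nb
    n <- n + nb
    scores <- c(scores, out$probs[, 2])
    labels <- c(labels, b$labels)
  }
  list(loss = tot / n, scores = scores, labels = labels)
}

#' Train a spatiotemporal transformer
#'
#' Minimizes entry-level cross-entropy with Adam. Entries are pooled and
#' re-partitioned into fresh batches every epoch with a seed derived from
#' `config$seed` and the epoch number, so training is invariant to the order
#' of the supplied batch list. The learning rate is multiplied by
#' `lr_decay` whenever validation loss fails to improve for `lr_patience`
#' epochs, and training early-stops after `2 * lr_patience` stagnant epochs.
#'
#' @param model an `st_model` from [build_model()].
#' @param train_batches,val_batches lists of `fc_batch`es; `val_batches` may
#'   be `NULL` (then training loss drives the plateau logic).
#' @param verbose print per-epoch progress.
#' @return list with the trained `model` and `log` (data frame: epoch, lr,
#'   train_loss, val_loss, val_auc, seed).
#' @export
train_st <- function(model, train_batches, val_batches = NULL, verbose = FALSE) {
  cfg <- model$config
  if (!length(train_batches)) stop("empty training fold", call. = FALSE)
  entries <- unlist(lapply(train_batches, function(b) b$entries), recursive = FALSE)
  # canonical entry order, so training depends only on the entry set and the
  # seed, not on how the caller happened to batch them
  key <- vapply(entries, function(e) sprintf("%s_%06d", e$segment$subject_id,
                                             e$segment$window_index), character(1))
  entries <- entries[order(key)]
  params <- model$params
  state <- adam_init(params)
  lr <- cfg$learning_rate
  best <- Inf
  stagnant <- 0L
  log <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    eseed <- (cfg$seed %% 100000L) * 1000L + epoch
    ebatches <- partition_entries(entries, cfg$batch_size, seed = eseed)
    tr_loss <- 0; n_tr <- 0
    for (b in ebatches) {
      model$params <- params
      out <- tryCatch(forward_node(model, b, labels = b$labels),
                      error = function(e) {
                        if (grepl("non-finite", conditionMessage(e))) {
                          stop(sprintf("training diverged (non-finite values) at epoch %d",
                                       epoch), call. = FALSE)
                        }
                        stop(e)
                      })
      lv <- ad_val(out$loss)
      if (!is.finite(lv)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      ad_backward(out$loss)
      grads <- collect_grads(out$wrapped)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + lv * length(b$labels)
      n_tr <- n_tr + length(b$labels)
    }
    model$params <- params
    if (!is.null(val_batches) && length(val_batches)) {
      ev <- eval_loss(model, val_batches)
      val_loss <- ev$loss
      val_auc <- if (length(unique(ev$labels)) == 2) roc_auc(ev$scores, ev$labels) else NA_real_
    } else {
      val_loss <- tr_loss / n_tr
      val_auc <- NA_real_
    }
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                               train_loss = tr_loss / n_tr,
                               val_loss = val_loss, val_auc = val_auc,
                               seed = cfg$seed)
    if (verbose) {
      message(sprintf("epoch %d lr %.2g train %.4f val %.4f auc %.3f",
                      epoch, lr, tr_loss / n_tr, val_loss, val_auc))
    }
    if (val_loss < best - 1e-6) {
      best <- val_loss
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant %% cfg$lr_patience == 0L) lr <- lr * cfg$lr_decay
      if (stagnant >= 2L * cfg$lr_patience) break
    }
  }
  list(model = model, log = do.call(rbind, log))
}

# ---- prediction ----------------------------------------------------------

#' Entry-level predictions
#'
#' @param model a trained `st_model`.
#' @param batches list of `fc_batch`es.
#' @return data frame: `entry` id, `subject_id`, `prob1` (class-1
#'   probability), `pred` (0.5 threshold), `label`.
#' @export
predict_entries <- function(model, batches) {
  rows <- lapply(batches, function(b) {
    out <- forward_node(model, b)
    data.frame(entry = paste0(b$subject_id, "_w", b$window_index),
               subject_id = b$subject_id,
               prob1 = out$probs[, 2],
               pred = as.integer(out$probs[, 2] > 0.5),
               label = b$labels,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate entry predictions to subject level
#'
#' A subject's score is the mean class-1 probability of its window entries;
#' the label uses a 0.5 threshold.
#'
#' @param entry_table output of [predict_entries()].
#' @return data frame: `subject_id`, `score`, `pred`, `label`.
#' @export
predict_subject <- function(entry_table) {
  sids <- unique(entry_table$subject_id)
  out <- data.frame(
    subject_id = sids,
    score = vapply(sids, function(s) mean(entry_table$prob1[entry_table$subject_id == s]),
                   numeric(1)),
    stringsAsFactors = FALSE
  )
  out$pred <- as.integer(out$score > 0.5)
  if ("label" %in% names(entry_table)) {
    out$label <- vapply(sids, function(s) entry_table$label[entry_table$subject_id == s][1],
                        entry_table$label[1])
  }
  rownames(out) <- NULL
  out
}

#' Region-wise ensemble majority vote
#'
#' Final subject label is the majority of region-level labels; ties are broken
#' by the subject's mean region-level score against 0.5.
#'
#' @param votes regions x subjects matrix of 0/1 labels.
#' @param scores optional matching matrix of region-level scores (required to
#'   break ties when the number of regions is even).
#' @return integer vector of final labels, one per subject (column).
#' @export
ensemble_vote <- function(votes, scores = NULL) {
  votes <- as.matrix(votes)
  if (!nrow(votes)) stop("empty vote set", call. = FALSE)
  n1 <- colSums(votes == 1)
  n0 <- colSums(votes == 0)
  out <- as.integer(n1 > n0)
  tie <- n1 == n0
  if (any(tie)) {
    if (is.null(scores)) stop("tied votes need region-level scores", call. = FALSE)
    out[tie] <- as.integer(colMeans(as.matrix(scores))[tie] > 0.5)
  }
  out
}

# ---- persistence ---------------------------------------------------------

#' Save / load a trained model
#'
#' Parameters are serialized with base R (`.rds`); the config travels with
#' them.
#' @param model an `st_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
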