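#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic via midranks: the fraction of
#' (positive, negative) pairs in which the positive outscores the negative,
#' ties counting one half.
#'
#' @param scores numeric scores (higher = more class-1-like).
#' @param labels 0/1 labels of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix and derived rates
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold decision threshold on the score (default 0.5).
#' @return list with the 2x2 `table` (rows = true label, columns = predicted),
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tab <- matrix(c(tp, fn, fp, tn), 2, 2,
                dimnames = list(true = c("positive", "negative"),
                                predicted = c("positive", "negative")))
  tab["positive", ] <- c(tp, fn)
  tab["negative", ] <- c(fp, tn)
  list(table = tab,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Midranks helper for the fast DeLong variance estimate.
midranks <- function(x) rank(x, ties.method = "average")

# Structural components V10 (per positive) and V01 (per negative).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- midranks(c(pos, neg))
  r_pos <- midranks(pos)
  r_neg <- midranks(neg)
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong's test for two correlated AUCs
#'
#' Fast structural-components estimate of the covariance of two paired AUCs
#' (both models scored the same observations), z statistic for their
#' difference, and a two-sided normal p value. The null hypothesis is that
#' the true performance of the two models is equal.
#'
#' @param scores_a,scores_b paired score vectors from the two models.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  dauc <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(dauc) < 1e-12) {
      return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p = 1))
    }
    stop("zero variance of the AUC difference with unequal AUCs", call. = FALSE)
  }
  z <- dauc / sqrt(var_diff)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Extract attention maps from a trained model
#'
#' Deterministically re-runs the forward pass and collects the requested
#' per-head maps.
#'
#' @param model a trained `st_model`.
#' @param batches list of `fc_batch`es.
#' @param block 1-based ST block index.
#' @param head 1-based head index, or `NULL` for all heads.
#' @param scope `"spatial"` (maps are N x N per time step) or `"temporal"`
#'   (T_tau x T_tau per node).
#' @return list of arrays, one per batch: `(heads, B, T, N, N)` for spatial,
#'   `(heads, B, N, T, T)` for temporal (head dim dropped when `head` given).
#' @export
extract_attention <- function(model, batches, block = 1, head = NULL,
                              scope = c("spatial", "temporal")) {
  scope <- match.arg(scope)
  if (block < 1 || block > model$config$n_blocks) {
    stop(sprintf("block index %d outside 1..%d", block, model$config$n_blocks),
         call. = FALSE)
  }
  if (!is.null(head) && (head < 1 || head > model$config$n_heads)) {
    stop("head index out of range", call. = FALSE)
  }
  lapply(batches, function(b) {
    out <- forward_node(model, b, collect_maps = TRUE)
    m <- out$maps[[block]][[scope]]
    if (is.null(m)) stop(sprintf("model has no %s attention maps (ablation %s)",
                                 scope, model$config$ablation), call. = FALSE)
    if (!is.null(head)) {
      d <- dim(m)
      m <- array(m[head, , , , ], d[-1])
    }
    m
  })
}

#' Average attention received, for a set of query nodes
#'
#' Arithmetic mean over subjects, windows, heads and time steps of the
#' attention rows belonging to the query nodes.
#'
#' @param maps list of spatial attention arrays `(heads, B, T, N, N)` (one per
#'   batch/subject, as returned by [extract_attention()]).
#' @param query_nodes 1-based node indices whose rows are averaged.
#' @param top_half if `TRUE`, zero out entries below the median of the
#'   averaged map (top-half score cutoff).
#' @return `length(query_nodes) x N` matrix of mean attention weights.
#' @export
average_attention <- function(maps, query_nodes, top_half = FALSE) {
  if (!is.list(maps)) maps <- list(maps)
  N <- dim(maps[[1]])[5]
  acc <- matrix(0, length(query_nodes), N)
  cnt <- 0
  for (m in maps) {
    d <- dim(m)
    for (qi in seq_along(query_nodes)) {
      rows <- m[, , , query_nodes[qi], , drop = FALSE]
      acc[qi, ] <- acc[qi, ] + apply(rows, 5, sum)
    }
    cnt <- cnt + prod(d[1:3])
  }
  out <- acc / cnt
  if (top_half) out[out < stats::median(out)] <- 0
  out
}

#' Mean-percentage-error similarity of two attention maps
#'
#' `MPE = 100 * mean(|a - b| / (|a| + eps))`. The denominator uses the first
#' (reference) map's magnitudes, so the measure is ordered (reference,
#' candidate) and intentionally non-symmetric. Identical maps give 0; doubling
#' a strictly positive map gives 100 (up to eps).
#'
#' @param map_a reference map (any array).
#' @param map_b candidate map of identical dimensions.
#' @param eps stabilizer for near-zero reference cells.
#' @return nonnegative percent value.
#' @export
mpe_similarity <- function(map_a, map_b, eps = 1e-8) {
  if (!identical(dim(map_a) %||% length(map_a), dim(map_b) %||% length(map_b))) {
    stop("maps must have identical dimensions (different window sizes are not comparable cell-wise)",
         call. = FALSE)
  }
  100 * mean(abs(map_a - map_b) / (abs(map_a) + eps))
}

#' Window/overlap sweep of classification performance
#'
#' For every valid (window, overlap) grid cell (overlap < window <= series
#' length), re-segments the cohort, trains `trials` seeded models and records
#' the mean subject-level test AUC. Cells whose window exceeds the series
#' length are skipped with a warning.
#'
#' @param records list of `subject_record`s.
#' @param windows,overlaps candidate window lengths and overlaps.
#' @param trials seeded repetitions per cell.
#' @param config base [model_config()]; its window fields are overridden per
#'   cell and its seed offset per trial.
#' @param seed sweep-level seed.
#' @return data frame: `window_length`, `overlap`, `mean_auc`, `n` (trials).
#' @export
window_sweep <- function(records, windows, overlaps, trials = 10,
                         config = model_config(), seed = 1L) {
  L <- nrow(records[[1]]$series)
  rows <- list()
  for (w in windows) {
    for (o in overlaps) {
      if (o >= w) next  # lower triangle: overlap never exceeds the window
      if (w > L) {
        warning(sprintf("window %d exceeds series length %d; cell skipped", w, L))
        next
      }
      aucs <- numeric(trials)
      for (tr in seq_len(trials)) {
        cfg <- modifyList(config, list(window_length = as.integer(w),
                                       window_overlap = as.integer(o),
                                       seed = as.integer(seed + 1000L * tr)))
        class(cfg) <- "model_config"
        fit <- fit_st_model(records, cfg)
        aucs[tr] <- fit$test_auc_subject
      }
      rows[[length(rows) + 1L]] <- data.frame(window_length = w, overlap = o,
                                              mean_auc = mean(aucs), n = trials)
    }
  }
  do.call(rbind, rows)
}

#' Write evaluation metrics as JSON
#' @param metrics named list of scalar metrics.
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
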