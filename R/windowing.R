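#' Sliding-window segmentation of a subject's time series
#'
#' Slices the `L x N` series into windows of `window` time points whose
#' consecutive windows share exactly `overlap` time points, i.e. stride
#' `window - overlap`. A trailing remainder shorter than `window` is dropped.
#'
#' @param record a `subject_record` (or a plain numeric matrix, in which case
#'   the subject id is `"anon"`).
#' @param window window length T_tau (default 25).
#' @param overlap shared time points T_phi between consecutive windows
#'   (default 5); must satisfy `0 <= overlap < window <= L`.
#' @return list of segments; each has `subject_id`, `window_index` (1-based),
#'   `start` (0-based time index) and the `window x N` matrix `series`.
#' @export
segment_series <- function(record, window = 25, overlap = 5) {
  if (is.matrix(record)) {
    record <- list(subject_id = "anon", label = NA_integer_, series = record)
  }
  x <- record$series
  L <- nrow(x)
  if (overlap >= window) stop("window overlap must be smaller than the window length", call. = FALSE)
  if (overlap < 0) stop("window overlap must be non-negative", call. = FALSE)
  if (window > L) stop("window length exceeds the series length", call. = FALSE)
  stride <- window - overlap
  starts <- seq.int(0L, L - window, by = stride)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    structure(list(subject_id = record$subject_id,
                   window_index = i,
                   start = as.integer(s),
                   series = x[(s + 1):(s + window), , drop = FALSE]),
              class = "fc_segment")
  })
}

#' Pearson functional-connectivity network of one window
#'
#' Edge weight (i, j) is the sample Pearson correlation of node columns i and
#' j over the window. Zero-variance columns get correlation 0 against every
#' other node (the diagonal stays 1) with a warning, so degenerate inputs do
#' not abort a training run.
#'
#' @param segment an `fc_segment` or a numeric matrix (time x nodes).
#' @return an `fc_network`: list with the symmetric `adjacency` matrix
#'   (unit diagonal, entries in `[-1, 1]`).
#' @export
pearson_fc <- function(segment) {
  x <- if (inherits(segment, "fc_segment")) segment$series else segment
  if (nrow(x) < 2) stop("a window needs at least 2 time points for correlation", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  A <- suppressWarnings(stats::cor(x))
  if (any(sds == 0)) {
    warning("zero-variance column(s) in window; their correlations set to 0")
    A[sds == 0, ] <- 0
    A[, sds == 0] <- 0
  }
  A[!is.finite(A)] <- 0
  A <- (A + t(A)) / 2
  A[A > 1] <- 1
  A[A < -1] <- -1
  diag(A) <- 1
  structure(list(adjacency = A), class = "fc_network")
}

#' Export a functional-connectivity network as an edge list
#' @param network an `fc_network`.
#' @param path TSV output path (`node_i  node_j  weight`, upper triangle).
#' @export
write_fc_edges <- function(network, path) {
  A <- network$adjacency
  idx <- which(upper.tri(A), arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1], node_j = idx[, 2], weight = A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# One batch entry: windowed segment + its FC network + subject label,
# plus the Chebyshev basis of the network (computed once, reused every epoch).
make_entry <- function(segment, label, cheb_order) {
  net <- pearson_fc(segment)
  structure(list(segment = segment,
                 network = net,
                 label = as.integer(label),
                 cheb = chebyshev_basis(net$adjacency, cheb_order)),
            class = "fc_entry")
}

# All windowed entries of a record list.
cohort_entries <- function(records, window, overlap, cheb_order = 3) {
  out <- list()
  for (r in records) {
    segs <- segment_series(r, window, overlap)
    for (s in segs) out[[length(out) + 1L]] <- make_entry(s, r$label, cheb_order)
  }
  out
}

# Stack a list of entries into one batch with dense tensors:
#   series (B, T, N), adjacency (N, N, B), cheb[[k]] (B, N, N),
#   labels, subject ids, window starts.
entries_batch <- function(entries) {
  B <- length(entries)
  T_ <- nrow(entries[[1]]$segment$series)
  N <- ncol(entries[[1]]$segment$series)
  series <- array(0, c(B, T_, N))
  adjacency <- array(0, c(N, N, B))
  K <- length(entries[[1]]$cheb)
  cheb <- lapply(seq_len(K), function(k) array(0, c(B, N, N)))
  labels <- integer(B)
  subject_id <- character(B)
  start <- integer(B)
  window_index <- integer(B)
  for (i in seq_len(B)) {
    e <- entries[[i]]
    series[i, , ] <- e$segment$series
    adjacency[, , i] <- e$network$adjacency
    for (k in seq_len(K)) cheb[[k]][i, , ] <- e$cheb[[k]]
    labels[i] <- e$label
    subject_id[i] <- e$segment$subject_id
    start[i] <- e$segment$start
    window_index[i] <- e$segment$window_index
  }
  structure(list(series = series, adjacency = adjacency, cheb = cheb,
                 labels = labels, subject_id = subject_id, start = start,
                 window_index = window_index, entries = entries,
                 cache = new.env(parent = emptyenv())),
            class = "fc_batch")
}

# Partition a shuffled entry list into batches of size N_b (last may be smaller).
partition_entries <- function(entries, batch_size, seed = NULL) {
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    entries <- entries[sample.int(length(entries))]
  }
  n <- length(entries)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  lapply(idx, function(i) entries_batch(entries[i]))
}

#' Assemble shuffled training batches from subject records
#'
#' Windows every record, pairs each window with its Pearson FC network and the
#' subject label, shuffles all entries with the seeded stream, and groups them
#' into batches of `batch_size` (the final batch may be smaller).
#'
#' @param records list of `subject_record`s.
#' @param window,overlap segmentation parameters, see [segment_series()].
#' @param batch_size entries per batch N_b (default 50).
#' @param seed integer seed for the shuffle.
#' @param cheb_order Chebyshev order K of the graph-convolution basis cached
#'   on each entry.
#' @return list of `fc_batch` objects.
#' @export
assemble_batches <- function(records, window = 25, overlap = 5,
                             batch_size = 50, seed = 1L, cheb_order = 3) {
  entries <- cohort_entries(records, window, overlap, cheb_order)
  if (!length(entries)) stop("no segments available", call. = FALSE)
  partition_entries(entries, batch_size, seed)
}

#' Subject-level stratified train/validation/test split
#'
#' Splits at the subject level (never the segment level) so overlapping
#' windows of one subject can never leak across folds, stratified by class.
#' Per class, training gets `floor(n * f1)` subjects, validation
#' `floor(n * f2)`, and test the remainder.
#'
#' @param manifest data frame with columns `subject_id` and `label`.
#' @param fractions length-3 fractions summing to 1 (default 70/15/15).
#' @param seed integer seed for the shuffle.
#' @return named list of three manifests: `train`, `validation`, `test`.
#' @export
split_cohort <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stop("fractions must be three values summing to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  folds <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (lab in sort(unique(manifest$label))) {
    rows <- which(manifest$label == lab)
    rows <- rows[sample.int(length(rows))]
    n <- length(rows)
    n_tr <- floor(n * fractions[1])
    n_va <- floor(n * fractions[2])
    n_te <- n - n_tr - n_va
    if (n_tr < 1 || n_va < 1 || n_te < 1) {
      stop(sprintf("too few subjects in class %s to stratify a %d/%d/%d split",
                   lab, n_tr, n_va, n_te), call. = FALSE)
    }
    folds$train <- c(folds$train, rows[seq_len(n_tr)])
    folds$validation <- c(folds$validation, rows[n_tr + seq_len(n_va)])
    folds$test <- c(folds$test, rows[n_tr + n_va + seq_len(n_te)])
  }
  lapply(folds, function(i) manifest[sort(i), , drop = FALSE])
}
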