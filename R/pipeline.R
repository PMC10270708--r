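#' End-to-end fit of the spatiotemporal transformer on a cohort
#'
#' Performs the subject-level stratified 70/15/15 split, windows and batches
#' each fold, builds and trains a model, and evaluates entry- and
#' subject-level test AUC.
#'
#' @param records list of `subject_record`s (in-memory cohort).
#' @param config a [model_config()].
#' @param fractions subject-level split fractions.
#' @param verbose print training progress.
#' @return list with `model`, `log`, `split` (the three manifests),
#'   `test_entries`, `test_subjects`, `test_auc_entry`, `test_auc_subject`.
#' @export
fit_st_model <- function(records, config, fractions = c(0.70, 0.15, 0.15),
                         verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  manifest <- records_manifest(records)
  split <- split_cohort(manifest, fractions, seed = config$seed)
  by_id <- stats::setNames(records, manifest$subject_id)
  fold_batches <- function(m) {
    assemble_batches(by_id[m$subject_id], config$window_length,
                     config$window_overlap, config$batch_size,
                     seed = config$seed, cheb_order = config$cheb_order)
  }
  train_b <- fold_batches(split$train)
  val_b <- fold_batches(split$validation)
  test_b <- fold_batches(split$test)
  n_nodes <- ncol(records[[1]]$series)
  model <- build_model(config, n_nodes)
  fit <- train_st(model, train_b, val_b, verbose = verbose)
  entries <- predict_entries(fit$model, test_b)
  subjects <- predict_subject(entries)
  list(model = fit$model, log = fit$log, split = split,
       test_batches = test_b,
       test_entries = entries, test_subjects = subjects,
       test_auc_entry = roc_auc(entries$prob1, entries$label),
       test_auc_subject = roc_auc(subjects$score, subjects$label))
}

#' Mean spatial attention received per node
#'
#' Averages, over the given batches (optionally restricted to entries of one
#' class), heads, time steps and query nodes of the chosen block, the
#' attention weight each node *receives* (its column mass).
#'
#' @param model trained `st_model`.
#' @param batches list of `fc_batch`es.
#' @param block ST block index.
#' @param class_label optional 0/1; restrict to entries with this label.
#' @return numeric vector of length N: mean received attention per node.
#' @export
attention_received <- function(model, batches, block = 1, class_label = NULL) {
  maps <- extract_attention(model, batches, block = block, scope = "spatial")
  N <- dim(maps[[1]])[5]
  acc <- numeric(N)
  cnt <- 0
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    keep <- if (is.null(class_label)) seq_len(dim(m)[2])
            else which(batches[[i]]$labels == class_label)
    if (!length(keep)) next
    m <- m[, keep, , , , drop = FALSE]
    acc <- acc + apply(m, 5, sum)
    cnt <- cnt + prod(dim(m)[1:4])
  }
  acc / cnt
}

#' Export an attention map as TSV
#' @param map a 2-D attention matrix (e.g. a slice of
#'   [extract_attention()] output or an [average_attention()] result).
#' @param path output TSV path.
#' @export
write_attention_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
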