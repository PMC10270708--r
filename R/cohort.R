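#' Specify a synthetic two-class resting-state cohort
#'
#' Defines the generative law for a balanced two-class cohort of BOLD-like
#' multivariate time series. Every node follows a stationary AR(1) noise
#' process; nodes in the planted subnetwork additionally load, with a
#' class-specific coupling strength, on a shared latent AR(1) factor. That
#' shared factor is what creates within-subnetwork correlation, so the two
#' classes differ only through their dynamic functional connectivity, which is
#' the structure the spatiotemporal model is meant to detect.
#'
#' @param n_per_class subjects per class (>= 1).
#' @param n_nodes number of nodes N (voxels of one region, or ROIs).
#' @param series_length number of time points L (>= 2).
#' @param planted_nodes integer vector of 0-based node indices forming the
#'   planted subnetwork; nonempty, all in `0:(n_nodes-1)`.
#' @param coupling_by_class length-2 numeric in `[0, 1]`: latent-factor loading
#'   of the planted nodes for class 0 and class 1 respectively.
#' @param coupling_window optional half-open 0-based time interval
#'   `c(from, to)` during which the coupling is active; `NULL` means the whole
#'   series (time-varying coupling gives the temporal attention branch a
#'   localized signal to find).
#' @param ar_coefficient AR(1) coefficient in (-1, 1) shared by the latent
#'   factor and the node noise.
#' @param noise_sd innovation standard deviation of the node noise (> 0).
#' @param seed integer seed for cohort generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class, n_nodes, series_length, planted_nodes,
                        coupling_by_class, coupling_window = NULL,
                        ar_coefficient = 0.4, noise_sd = 1, seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(n_per_class) && length(n_per_class) == 1 && n_per_class >= 1,
      "n_per_class", "must be a single count >= 1")
  chk(is.numeric(n_nodes) && length(n_nodes) == 1 && n_nodes >= 2,
      "n_nodes", "must be a single count >= 2")
  chk(is.numeric(series_length) && length(series_length) == 1 && series_length >= 2,
      "series_length", "must be a single count >= 2")
  chk(length(planted_nodes) >= 1 && all(planted_nodes == floor(planted_nodes)) &&
        all(planted_nodes >= 0) && all(planted_nodes < n_nodes) &&
        !anyDuplicated(planted_nodes),
      "planted_nodes", "must be distinct 0-based indices within 0..n_nodes-1")
  chk(is.numeric(coupling_by_class) && length(coupling_by_class) == 2 &&
        all(coupling_by_class >= 0) && all(coupling_by_class <= 1),
      "coupling_by_class", "must be two values in [0, 1]")
  if (!is.null(coupling_window)) {
    chk(is.numeric(coupling_window) && length(coupling_window) == 2 &&
          coupling_window[1] >= 0 && coupling_window[2] > coupling_window[1] &&
          coupling_window[2] <= series_length,
        "coupling_window", "must be a half-open interval within [0, series_length]")
  }
  chk(is.numeric(ar_coefficient) && length(ar_coefficient) == 1 &&
        abs(ar_coefficient) < 1,
      "ar_coefficient", "must be in (-1, 1)")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd > 0,
      "noise_sd", "must be > 0")
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_nodes = as.integer(n_nodes),
    series_length = as.integer(series_length),
    planted_nodes = as.integer(sort(planted_nodes)),
    coupling_by_class = as.numeric(coupling_by_class),
    coupling_window = if (is.null(coupling_window)) NULL else as.numeric(coupling_window),
    ar_coefficient = as.numeric(ar_coefficient),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a single synthetic subject
#'
#' Simulates `x_i(t) = phi * x_i(t-1) + beta * f(t) * 1[i planted, t in window]
#' + eps_i(t)` with a shared latent AR(1) factor `f` and Gaussian innovations,
#' then z-scores each column so per-window Pearson correlations are scale-free.
#'
#' @param spec a [cohort_spec()].
#' @param label class label, 0 or 1; selects the coupling strength.
#' @param seed integer seed for this subject's random stream.
#' @param subject_id subject identifier string.
#' @return A `subject_record`: list with `subject_id`, `label`, and the
#'   `series_length x n_nodes` matrix `series` (columns named `node_1..N`).
#' @export
generate_subject <- function(spec, label, seed = spec$seed,
                             subject_id = sprintf("subj_%d_%d", label, seed)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!label %in% c(0, 1)) stop("invalid `label`: must be 0 or 1", call. = FALSE)
  L <- spec$series_length
  N <- spec$n_nodes
  phi <- spec$ar_coefficient
  beta <- spec$coupling_by_class[label + 1]
  set.seed(as.integer(seed))
  # shared latent AR(1) factor with unit innovations
  f <- numeric(L)
  f[1] <- rnorm(1)
  for (t in 2:L) f[t] <- phi * f[t - 1] + rnorm(1)
  active <- rep(TRUE, L)
  if (!is.null(spec$coupling_window)) {
    tt <- seq_len(L) - 1  # 0-based time
    active <- tt >= spec$coupling_window[1] & tt < spec$coupling_window[2]
  }
  eps <- matrix(rnorm(L * N, sd = spec$noise_sd), L, N)
  x <- matrix(0, L, N)
  planted <- spec$planted_nodes + 1L
  load <- numeric(N)
  load[planted] <- beta
  drive <- outer(f * active, load)  # L x N
  x[1, ] <- eps[1, ] + drive[1, ]
  for (t in 2:L) x[t, ] <- phi * x[t - 1, ] + drive[t, ] + eps[t, ]
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  x <- scale(x, center = TRUE, scale = sds)
  attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  colnames(x) <- paste0("node_", seq_len(N))
  structure(list(subject_id = subject_id, label = as.integer(label), series = x),
            class = "subject_record")
}

#' Generate a balanced two-class cohort
#'
#' @param spec a [cohort_spec()].
#' @return A list with `records` (list of `subject_record`, `2 * n_per_class`
#'   of them, balanced labels, unique ids) and `manifest` (data frame with
#'   columns `subject_id`, `label`, `path`; `path` is `NA` until
#'   [write_cohort()] is called).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- list()
  k <- 0L
  for (label in c(0L, 1L)) {
    for (i in seq_len(spec$n_per_class)) {
      k <- k + 1L
      sid <- sprintf("subj_%03d", k)
      # per-subject seed derived from the cohort seed; kept within 32-bit range
      sseed <- (spec$seed %% 1000000L) * 1000L + k
      records[[k]] <- generate_subject(spec, label, seed = sseed, subject_id = sid)
    }
  }
  list(records = records, manifest = records_manifest(records))
}

#' Build the manifest table for a list of subject records
#' @param records list of `subject_record`s.
#' @param paths optional character vector of file paths (default `NA`).
#' @return data frame with columns `subject_id`, `label`, `path`.
#' @export
records_manifest <- function(records, paths = NA_character_) {
  data.frame(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    label = vapply(records, function(r) r$label, integer(1)),
    path = paths,
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to disk as TSV files plus a manifest
#'
#' Each subject's series is written as a tab-delimited file (rows = time
#' points, columns = nodes, header row of node names) with 15 significant
#' digits, and a three-column manifest `subject_id  label  path` is written as
#' `manifest.tsv`.
#'
#' @param records list of `subject_record`s.
#' @param directory output directory (created if needed).
#' @return the manifest file path, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(records, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    paths[i] <- file.path(directory, paste0(r$subject_id, ".tsv"))
    df <- as.data.frame(format(r$series, digits = 15, trim = TRUE, scientific = FALSE))
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- records_manifest(records, paths)
  mpath <- file.path(directory, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath
}

#' Read a cohort back from a manifest file
#'
#' @param manifest_path path to a `manifest.tsv` written by [write_cohort()]
#'   (or hand-built with the same three columns).
#' @return list of `subject_record`s.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest file not found: %s", manifest_path), call. = FALSE)
  }
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns subject_id, label, path", call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) {
      p2 <- file.path(base, basename(p))
      if (file.exists(p2)) p <- p2
      else stop(sprintf("series file not found: %s", manifest$path[i]), call. = FALSE)
    }
    series <- read_series_tsv(p)
    structure(list(subject_id = as.character(manifest$subject_id[i]),
                   label = as.integer(manifest$label[i]),
                   series = series),
              class = "subject_record")
  })
}

# Strict TSV reader: header row of node names, equal-length numeric rows.
read_series_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop(sprintf("series file %s has no data rows", path), call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1) {
    stop(sprintf("ragged matrix in %s: row lengths %s", path,
                 paste(unique(lens), collapse = "/")), call. = FALSE)
  }
  header <- cells[[1]]
  body <- cells[-1]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(lens[1])))
  if (anyNA(vals)) stop(sprintf("non-numeric cell in %s", path), call. = FALSE)
  m <- t(matrix(vals, nrow = lens[1]))
  colnames(m) <- header
  m
}
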