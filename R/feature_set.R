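#' Differential-entropy feature set
#'
#' Container for per-sample differential-entropy (DE) band-power features:
#' a numeric tensor of shape `[N, C, F]` (samples x channels x frequency
#' bands, log-power units) together with one emotion label, subject id,
#' session id and trial id per sample. The band axis is always the five
#' canonical EEG bands in the fixed order delta, theta, alpha, beta, gamma.
#'
#' All samples belonging to one `(subject, session, trial)` must carry the
#' same label (a trial is one film-clip presentation and has a single
#' emotion annotation). Labels and trial ids are 0-based integers.
#'
#' @param values numeric array `[N, C, F]`, or an `N x (C*F)` matrix of
#'   flat feature vectors which is reshaped channel-major (see
#'   [de_unflatten()]).
#' @param labels integer vector of length N, values in `0..K-1`.
#' @param subject,session,trial integer vectors of length N (0-based ids);
#'   scalars are recycled.
#' @param band_names character vector naming the band axis; must have
#'   length `dim(values)[3]`. Defaults to the five canonical bands.
#' @param n_channels number of channels C used when `values` is a flat
#'   matrix (default 62, the SEED montage).
#'
#' @return An object of class `de_feature_set`: a list with elements
#'   `values` (`[N,C,F]` array), `labels`, `subject`, `session`, `trial`
#'   (integer vectors) and `band_names`.
#' @seealso [de_flatten()], [read_feature_set()], [write_feature_set()]
#' @export
#' @examples
#' x <- de_feature_set(array(rnorm(4 * 62 * 5), c(4, 62, 5)),
#'                     labels = c(0L, 0L, 1L, 1L),
#'                     trial = c(0L, 0L, 1L, 1L))
#' dim(x$values)
de_feature_set <- function(values, labels,
                           subject = 0L, session = 0L, trial = 0L,
                           band_names = CATE_BANDS, n_channels = 62L) {
  if (is.matrix(values)) {
    values <- de_unflatten(values, n_channels = n_channels,
                           n_bands = length(band_names))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be an [N, C, F] array or an N x (C*F) matrix",
         call. = FALSE)
  }
  n <- dim(values)[1]
  labels  <- as.integer(labels)
  subject <- rep_len(as.integer(subject), n)
  session <- rep_len(as.integer(session), n)
  trial   <- rep_len(as.integer(trial), n)
  fs <- structure(
    list(values = values, labels = labels, subject = subject,
         session = session, trial = trial,
         band_names = as.character(band_names)),
    class = "de_feature_set")
  validate_feature_set(fs)
}

validate_feature_set <- function(fs) {
  d <- dim(fs$values)
  n <- d[1]
  if (length(fs$band_names) != d[3]) {
    stop("band_names length (", length(fs$band_names),
         ") does not match band axis (", d[3], ")", call. = FALSE)
  }
  for (fld in c("labels", "subject", "session", "trial")) {
    if (length(fs[[fld]]) != n) {
      stop("`", fld, "` has length ", length(fs[[fld]]),
           " but there are ", n, " samples", call. = FALSE)
    }
  }
  if (n > 0 && !all(is.finite(fs$values))) {
    stop("feature values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (n > 0 && any(fs$labels < 0L)) {
    stop("labels must be non-negative 0-based integers", call. = FALSE)
  }
  # one label per (subject, session, trial)
  key <- paste(fs$subject, fs$session, fs$trial, sep = "/")
  lab_per_trial <- tapply(fs$labels, key, function(l) length(unique(l)))
  if (n > 0 && any(lab_per_trial > 1L)) {
    bad <- names(lab_per_trial)[lab_per_trial > 1L][1]
    stop("trial ", bad, " carries more than one label", call. = FALSE)
  }
  fs
}

#' @export
print.de_feature_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<de_feature_set> %d samples x %d channels x %d bands (%s)\n",
    d[1], d[2], d[3], paste(x$band_names, collapse = ", ")))
  cat(sprintf("  classes: %s | subjects: %d | trials/subject-session: %d\n",
              paste(sort(unique(x$labels)), collapse = ","),
              length(unique(x$subject)),
              length(unique(x$trial))))
  invisible(x)
}

#' @export
dim.de_feature_set <- function(x) dim(x$values)

#' Coerce a feature set to a tibble
#'
#' One row per sample; feature columns are named `ch<channel>_<band>` in
#' channel-major order, matching the flat 310-vector layout, preceded by
#' the metadata columns.
#'
#' @param x a [de_feature_set].
#' @param ... unused.
#' @return A tibble with columns `sample`, `subject`, `session`, `trial`,
#'   `label`, then `C*F` feature columns.
#' @export
as_tibble.de_feature_set <- function(x, ...) {
  m <- de_flatten(x$values)
  cf <- expand.grid(band = x$band_names,
                    channel = seq_len(dim(x$values)[2]) - 1L)[, 2:1]
  colnames(m) <- sprintf("ch%02d_%s", cf$channel, cf$band)
  dplyr::bind_cols(
    tibble::tibble(sample = seq_len(nrow(m)) - 1L,
                   subject = x$subject, session = x$session,
                   trial = x$trial, label = x$labels),
    tibble::as_tibble(m))
}

#' Flatten a feature tensor to the trials x 310 layout
#'
#' Reshapes `[N, C, F]` to `[N, C*F]` in channel-major order: the flat
#' index of channel c, band f (both 0-based) is `c*F + f`, i.e. the channel
#' index varies slowest and the band index fastest, matching the
#' conventional "62 x 5" flattening of SEED-style DE matrices.
#'
#' @param x numeric array `[N, C, F]` or a [de_feature_set].
#' @return numeric matrix `[N, C*F]`.
#' @seealso [de_unflatten()] for the inverse.
#' @export
de_flatten <- function(x) {
  if (inherits(x, "de_feature_set")) x <- x$values
  d <- dim(x)
  stopifnot(length(d) == 3L)
  # aperm to [F, C, N] so the vectorisation runs band-fastest, channel next
  t(matrix(aperm(x, c(3, 2, 1)), nrow = d[2] * d[3], ncol = d[1]))
}

#' Reshape flat feature vectors back to [N, C, F]
#'
#' Inverse of [de_flatten()]: interprets each row as C consecutive blocks
#' of F band values (channel-major order).
#'
#' @param m numeric matrix `[N, C*F]`.
#' @param n_channels number of channels C.
#' @param n_bands number of bands F.
#' @return numeric array `[N, C, F]`.
#' @export
de_unflatten <- function(m, n_channels = 62L, n_bands = 5L) {
  m <- as.matrix(m)
  if (ncol(m) != n_channels * n_bands) {
    stop("flat width ", ncol(m), " is not ", n_channels, " x ", n_bands,
         call. = FALSE)
  }
  aperm(array(t(m), dim = c(n_bands, n_channels, nrow(m))), c(3, 2, 1))
}

#' Write a feature set to disk
#'
#' Two plain layouts are supported. `"csv"` writes a directory holding
#' `values.csv` (flat `N x C*F` matrix, full `%.17g` precision so doubles
#' survive a round trip bitwise), `meta.csv` (labels/subject/session/trial)
#' and `bands.txt`. `"rds"` writes a single native R file.
#'
#' @param fs a [de_feature_set].
#' @param path target directory (`csv`) or file (`rds`).
#' @param layout `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fs, path, layout = c("csv", "rds")) {
  layout <- match.arg(layout)
  stopifnot(inherits(fs, "de_feature_set"))
  if (layout == "rds") {
    saveRDS(fs, path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- de_flatten(fs$values)
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, file.path(path, "values.csv"))
  meta <- data.frame(label = fs$labels, subject = fs$subject,
                     session = fs$session, trial = fs$trial)
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE)
  writeLines(fs$band_names, file.path(path, "bands.txt"))
  invisible(path)
}

#' Read a feature set from disk
#'
#' @param path directory (`csv` layout) or file (`rds` layout) produced by
#'   [write_feature_set()].
#' @param layout `"csv"` or `"rds"`.
#' @param n_channels channels C used to unflatten the csv layout.
#' @return a validated [de_feature_set].
#' @export
read_feature_set <- function(path, layout = c("csv", "rds"),
                             n_channels = 62L) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  if (layout == "rds") {
    fs <- readRDS(path)
    if (!inherits(fs, "de_feature_set")) {
      stop("file does not contain a de_feature_set", call. = FALSE)
    }
    return(validate_feature_set(fs))
  }
  vfile <- file.path(path, "values.csv")
  if (!file.exists(vfile) || file.size(vfile) == 0) {
    stop("empty or missing values.csv in ", path, call. = FALSE)
  }
  lines <- readLines(vfile)
  m <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
  bands <- readLines(file.path(path, "bands.txt"))
  if (ncol(m) %% length(bands) != 0 ||
      ncol(m) != n_channels * length(bands)) {
    stop("flat width ", ncol(m), " does not factor into ", n_channels,
         " channels x ", length(bands), " bands", call. = FALSE)
  }
  meta <- utils::read.csv(file.path(path, "meta.csv"))
  if (nrow(meta) != nrow(m)) {
    stop("meta.csv rows (", nrow(meta), ") do not match values rows (",
         nrow(m), ")", call. = FALSE)
  }
  de_feature_set(de_unflatten(m, n_channels, length(bands)),
                 labels = meta$label, subject = meta$subject,
                 session = meta$session, trial = meta$trial,
                 band_names = bands)
}

# Subset a feature set by a logical/integer sample index.
fs_subset <- function(fs, idx) {
  de_feature_set(fs$values[idx, , , drop = FALSE],
                 labels = fs$labels[idx], subject = fs$subject[idx],
                 session = fs$session[idx], trial = fs$trial[idx],
                 band_names = fs$band_names)
}
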